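#' FEP protocol parameters
#'
#' Bookkeeping for the alchemical relative-binding-free-energy protocol:
#' each mutant is evaluated over `lambda_windows` windows of
#' `ns_per_window` nanoseconds, `replicas` independent replicas, in both
#' the bound (peptide-HLA complex) and unbound (free peptide) states.
#' At the defaults (16 windows x 3 ns x 3 replicas x 2 states) one
#' mutant costs 288 ns of simulation.
#'
#' @param lambda_windows Number of alchemical windows spanning
#'   lambda 0..1.
#' @param ns_per_window Simulation length per window (ns).
#' @param replicas Independent replicas per state.
#' @param temperature Kelvin. @param pressure Bar. @param salt_mM NaCl
#'   concentration, mM.
#' @return An `fep_protocol` list with `states` fixed at 2.
#' @export
fep_protocol <- function(lambda_windows = 16L, ns_per_window = 3,
                         replicas = 3L, temperature = 310, pressure = 1,
                         salt_mM = 150) {
  stopifnot(lambda_windows >= 1L, ns_per_window > 0, replicas >= 1L,
            temperature > 0, pressure > 0, salt_mM >= 0)
  structure(
    list(lambda_windows = as.integer(lambda_windows),
         ns_per_window = ns_per_window, replicas = as.integer(replicas),
         states = 2L, temperature = temperature, pressure = pressure,
         salt_mM = salt_mM),
    class = "fep_protocol"
  )
}

#' Emit an FEP job manifest for a mutant
#'
#' Lists every (state, replica, window) simulation leg with its lambda
#' value on a uniform, endpoint-inclusive 0..1 schedule, plus the total
#' simulated time `total_ns = ns_per_window * lambda_windows * replicas
#' * 2 states`. The manifest is the hand-off boundary to an external MD
#' engine; nothing is executed here.
#'
#' @param mutant_code Canonical mutant code, e.g. `"R7K"`.
#' @param protocol An [fep_protocol()].
#' @return An `fep_manifest`: list with `mutant_code`, `protocol`,
#'   `total_ns`, and a `legs` tibble
#'   (`state`, `replica`, `window`, `lambda`, `ns`).
#' @export
emit_fep_manifest <- function(mutant_code, protocol = fep_protocol()) {
  stopifnot(inherits(protocol, "fep_protocol"), length(mutant_code) == 1L)
  lam <- if (protocol$lambda_windows == 1L) 0 else
    seq(0, 1, length.out = protocol$lambda_windows)
  legs <- tidyr::expand_grid(
    state = c("bound", "unbound"),
    replica = seq_len(protocol$replicas),
    window = seq_len(protocol$lambda_windows)
  )
  legs <- dplyr::mutate(legs, lambda = lam[.data$window],
                        ns = protocol$ns_per_window)
  total_ns <- protocol$ns_per_window * protocol$lambda_windows *
    protocol$replicas * protocol$states
  structure(
    list(mutant_code = mutant_code, protocol = protocol,
         total_ns = total_ns, legs = legs),
    class = "fep_manifest"
  )
}

#' Write an FEP manifest as structured text
#'
#' A commented summary header followed by one tab-separated line per
#' simulation leg.
#'
#' @param manifest An [emit_fep_manifest()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fep_manifest <- function(manifest, path) {
  p <- manifest$protocol
  header <- c(
    sprintf("# mutant\t%s", manifest$mutant_code),
    sprintf("# lambda_windows\t%d", p$lambda_windows),
    sprintf("# ns_per_window\t%g", p$ns_per_window),
    sprintf("# replicas\t%d", p$replicas),
    sprintf("# temperature_K\t%g", p$temperature),
    sprintf("# pressure_bar\t%g", p$pressure),
    sprintf("# salt_mM\t%g", p$salt_mM),
    sprintf("# total_ns\t%g", manifest$total_ns),
    "state\treplica\twindow\tlambda\tns"
  )
  lines <- sprintf("%s\t%d\t%d\t%.10g\t%g",
                   manifest$legs$state, manifest$legs$replica,
                   manifest$legs$window, manifest$legs$lambda,
                   manifest$legs$ns)
  writeLines(c(header, lines), path)
  invisible(path)
}

# ---- synthetic landscape surrogate ---------------------------------------

# Deterministic small integer derived from a seed and a mutant code, so a
# surrogate observation depends only on (landscape seed, code), not on
# call order.
code_seed <- function(seed, code) {
  h <- sum(utf8ToInt(code) * seq_along(utf8ToInt(code)) * 131L)
  as.integer((abs(seed) * 7919 + h) %% 2147483123)
}

# True (noise-free) ddG of mutants under a landscape, including optional
# pairwise couplings to the unmutated background.
landscape_true_ddg <- function(landscape, mutants) {
  e <- landscape$e
  base <- e[cbind(mutants$to_res, mutants$position)] -
    e[cbind(mutants$from_res, mutants$position)]
  if (!is.null(landscape$J)) {
    res <- peptide_residues(landscape$parent)
    idx <- match(res, amino_acids)
    L <- length(res)
    J <- landscape$J
    coup <- vapply(seq_len(nrow(mutants)), function(i) {
      p <- mutants$position[i]
      a_to <- match(mutants$to_res[i], amino_acids)
      a_from <- match(mutants$from_res[i], amino_acids)
      others <- setdiff(seq_len(L), p)
      sum(J[cbind(pmin(p, others), pmax(p, others),
                  ifelse(p < others, a_to, idx[others]),
                  ifelse(p < others, idx[others], a_to))]) -
        sum(J[cbind(pmin(p, others), pmax(p, others),
                    ifelse(p < others, a_from, idx[others]),
                    ifelse(p < others, idx[others], a_from))])
    }, numeric(1))
    base <- base + coup
  }
  base
}

# Absolute dG of arbitrary equal-length peptides under the additive
# extension of a landscape (couplings included if present).
landscape_dg <- function(landscape, sequences) {
  e <- landscape$e
  L <- ncol(e)
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)),
                  nrow = length(sequences), byrow = TRUE)
  site <- matrix(e[cbind(as.vector(chars),
                         rep(seq_len(L), each = length(sequences)))],
                 nrow = length(sequences))
  out <- landscape$dg_parent + rowSums(site)
  if (!is.null(landscape$J)) {
    idx <- matrix(match(chars, amino_acids), nrow = length(sequences))
    J <- landscape$J
    pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      p <- pairs[r, 1]; q <- pairs[r, 2]
      out <- out + J[cbind(p, q, idx[, p], idx[, q])]
    }
  }
  out
}

#' Query the synthetic landscape surrogate for a mutant's ddG
#'
#' The desk-scale stand-in for an FEP evaluation: the landscape's true
#' ddG plus Gaussian replicate noise of standard deviation
#' `landscape$noise_sd`, averaged over `replicas` draws, with the
#' replicate spread reported as `sd`. Reproducible: the draws depend
#' only on `(seed, code)`, not on call order.
#'
#' @param landscape A landscape from [generate_landscape()].
#' @param code Mutant code(s) on the landscape's parent.
#' @param replicas Number of replicate draws (default 3).
#' @param seed Base seed; defaults to the landscape's own.
#' @return Tibble with `code`, `ddg`, `sd`, `n_replicas`, `source`.
#' @export
surrogate_ddg <- function(landscape, code, replicas = 3L, seed = NULL) {
  stopifnot(inherits(landscape, "mimoscan_landscape"))
  seed <- seed %||% landscape$seed
  mut <- parse_mutant_code(code, landscape$parent)
  truth <- landscape_true_ddg(landscape, mut)
  obs <- purrr::map2_dfr(mut$code, truth, function(cd, tr) {
    draws <- withr_seed(code_seed(seed, cd), {
      tr + rnorm(replicas, 0, landscape$noise_sd)
    })
    tibble(code = cd, ddg = mean(draws),
           sd = if (replicas > 1L) sd(draws) else 0,
           n_replicas = as.integer(replicas), source = "surrogate")
  })
  obs
}

# Evaluate `expr` under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Build a ddG oracle from a landscape
#'
#' Returns a function of mutant codes -> observation tibble, the
#' pluggable oracle interface consumed by [run_screen()]. Swap in a
#' function backed by real FEP results (see [ingest_fep_results()]) for
#' production campaigns.
#'
#' @inheritParams surrogate_ddg
#' @return `function(codes) -> tibble(code, ddg, sd, n_replicas, source)`.
#' @export
landscape_oracle <- function(landscape, replicas = 3L, seed = NULL) {
  force(landscape); force(replicas); force(seed)
  function(codes) surrogate_ddg(landscape, codes, replicas, seed)
}

#' Ingest externally computed FEP results
#'
#' Accepts either per-replica long format (`mutant_code`, `replica`,
#' `ddg`) or precomputed summaries (`mutant_code`, `ddg`, optionally
#' `sd`). Replicas are aggregated by arithmetic mean with the sample
#' standard deviation. Duplicate mutant codes (after aggregation) are an
#' error; single-replica entries get `sd = 0` with a warning.
#'
#' @param table Data frame of FEP results.
#' @param parent Parent peptide the codes refer to.
#' @return Observation tibble (`code`, `ddg`, `sd`, `n_replicas`,
#'   `source = "fep_import"`).
#' @export
ingest_fep_results <- function(table, parent) {
  stopifnot(is.data.frame(table), "mutant_code" %in% names(table))
  if (!"ddg" %in% names(table)) {
    abort("Results must contain a numeric `ddg` column.")
  }
  if (!is.numeric(table$ddg) || anyNA(table$ddg)) {
    abort("`ddg` must be numeric and complete.")
  }
  parse_mutant_code(unique(table$mutant_code), parent) # validates codes
  if ("replica" %in% names(table)) {
    out <- dplyr::summarise(
      dplyr::group_by(as_tibble(table), code = .data$mutant_code),
      n_replicas = dplyr::n(),
      sd = if (dplyr::n() > 1L) sd(.data$ddg) else 0,
      ddg = mean(.data$ddg),
      .groups = "drop"
    )
  } else {
    if (anyDuplicated(table$mutant_code)) {
      dup <- table$mutant_code[duplicated(table$mutant_code)][1]
      abort(sprintf("Duplicate rows for mutant '%s' in FEP results.", dup))
    }
    out <- tibble(
      code = table$mutant_code, ddg = table$ddg,
      sd = if ("sd" %in% names(table)) table$sd else 0,
      n_replicas = if ("n_replicas" %in% names(table)) {
        as.integer(table$n_replicas)
      } else 1L
    )
  }
  if (any(out$n_replicas == 1L)) {
    warn("Single-replica FEP entries: sd reported as 0.")
  }
  if (any(out$sd < 0)) abort("Negative replicate sd in FEP results.")
  out$source <- "fep_import"
  dplyr::select(out, "code", "ddg", "sd", "n_replicas", "source")
}
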