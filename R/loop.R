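#' Run the active-learning screening loop
#'
#' Iterates the Bayesian-optimization cycle: predict ddG over the full
#' single-mutant space, elect candidates under the acquisition policy,
#' query the precise oracle on the elected (never-repeated) mutants,
#' and fine-tune on the binary data plus the cumulative oracle set.
#' Each fine-tune restarts from the supplied pretrained checkpoint with
#' the full cumulative ddG set, so the final model depends only on
#' which mutants were sampled, not the order. The loop stops when an
#' oracle-confirmed observation reaches the objective threshold, the
#' oracle budget is exhausted, or the mutant space is exhausted.
#'
#' @param model A pretrained `mimoscan_predictor` (see [pretrain()]).
#' @param binary Binary records tibble used in every fine-tune.
#' @param oracle Oracle function `function(codes) -> tibble(code, ddg,
#'   sd, ...)`, e.g. [landscape_oracle()].
#' @param parent Parent peptide whose single-mutant space is screened.
#' @param policy An [acquisition_policy()].
#' @param budget Maximum total oracle observations (>= 1).
#' @param train A [train_config()] used for each fine-tune.
#' @param record_predictions Keep the full post-fine-tune prediction
#'   table per iteration (needed by [evaluate_vs_truth()]).
#' @return A `mimoscan_screen` object: `observations` (all oracle
#'   results with the iteration that acquired them), `history`
#'   (per-iteration tibble with list-columns `elected` and
#'   `predictions`), `model` (final fine-tuned state), `stop_reason`,
#'   and the objective `threshold` in kcal/mol.
#' @export
run_screen <- function(model, binary, oracle, parent,
                       policy = acquisition_policy(), budget = 25L,
                       train = train_config(),
                       record_predictions = TRUE) {
  check_model(model)
  if (!model$trained) abort("Pretrain the model before screening.")
  stopifnot(budget >= 1L)
  parent <- parse_peptide(parent)
  muts <- enumerate_single_mutants(parent)
  threshold <- objective_threshold(policy)

  pretrained <- model
  observations <- tibble(code = character(0), ddg = numeric(0),
                         sd = numeric(0), n_replicas = integer(0),
                         source = character(0), iteration = integer(0))
  failed <- character(0)
  history <- list()
  stop_reason <- NULL
  it <- 0L

  while (is.null(stop_reason)) {
    it <- it + 1L
    preds <- predict_ddg(model, muts)
    blocked <- c(observations$code, failed)
    cand <- tryCatch(
      elect_candidates(preds, policy, blocked),
      error = function(e) NULL
    )
    if (is.null(cand)) {
      stop_reason <- "space_exhausted"
      break
    }
    if (nrow(cand) == 0L) {
      # BFS may legitimately find no improving, unsampled candidate left
      stop_reason <- "no_candidates"
      break
    }
    remaining <- budget - nrow(observations)
    cand <- head(cand, remaining)

    obs <- purrr::map_dfr(cand$code, function(cd) {
      tryCatch(oracle(cd), error = function(e) {
        warn(sprintf("Oracle failed on %s: %s; skipping.", cd,
                     conditionMessage(e)))
        failed <<- c(failed, cd)
        tibble()
      })
    })
    if (nrow(obs) > 0L) {
      obs$iteration <- it
      observations <- dplyr::bind_rows(observations, obs)
      targets <- anchor_ddg(observations, pretrained, parent)
      model <- finetune(pretrained, binary, targets, train)
    }
    post <- if (record_predictions) predict_ddg(model, muts) else NULL
    history[[it]] <- tibble(
      iteration = it,
      n_elected = nrow(cand),
      n_new = nrow(obs),
      n_sampled = nrow(observations),
      best_observed = if (nrow(observations)) min(observations$ddg) else NA_real_,
      elected = list(cand$code),
      predictions = list(post)
    )
    if (nrow(observations) > 0L && min(observations$ddg) <= threshold) {
      stop_reason <- "objective_met"
    } else if (nrow(observations) >= budget) {
      stop_reason <- "budget_exhausted"
    } else if (nrow(observations) + length(failed) >= nrow(muts)) {
      stop_reason <- "space_exhausted"
    }
  }

  structure(
    list(parent = parent, policy = policy, budget = as.integer(budget),
         threshold = threshold, observations = observations,
         failed = failed, history = dplyr::bind_rows(history),
         model = model, pretrained = pretrained,
         stop_reason = stop_reason),
    class = "mimoscan_screen"
  )
}

#' @export
print.mimoscan_screen <- function(x, ...) {
  cat(sprintf(
    "<mimoscan_screen> %s | %s%s | %d oracle obs in %d iteration(s) | %s\n",
    x$parent, x$policy$strategy,
    if (x$policy$strategy == "DFS_Bn") paste0("(n=", x$policy$breadth, ")") else "",
    nrow(x$observations), nrow(x$history), x$stop_reason
  ))
  if (nrow(x$observations)) {
    best <- x$observations[which.min(x$observations$ddg), ]
    cat(sprintf("  best observed: %s at %.2f kcal/mol (objective %.2f)\n",
                best$code, best$ddg, x$threshold))
  }
  invisible(x)
}

#' Score each loop iteration against an exhaustive truth table
#'
#' For every recorded post-fine-tune model snapshot, computes the
#' regression precision and recall (and Spearman correlation) of the
#' predicted ddG against the reference over the whole single-mutant
#' space -- the sample-efficiency curve of the campaign.
#'
#' @param screen A [run_screen()] result with recorded predictions.
#' @param truth Tibble covering every mutant of the parent, with `code`
#'   and a reference column (`ddg_true` if present, else `ddg`), e.g.
#'   from [generate_fep_truth()].
#' @param params A [metric_params()].
#' @return Tibble: `iteration`, `n_samples`, `precision`, `recall`,
#'   `srcc`.
#' @export
evaluate_vs_truth <- function(screen, truth, params = metric_params()) {
  stopifnot(inherits(screen, "mimoscan_screen"))
  ref_col <- if ("ddg_true" %in% names(truth)) "ddg_true" else "ddg"
  muts <- enumerate_single_mutants(screen$parent)
  missing <- setdiff(muts$code, truth$code)
  if (length(missing) > 0L) {
    abort(sprintf("Truth table is missing %d mutant(s), e.g. %s.",
                  length(missing), missing[1]))
  }
  ref <- setNames(truth[[ref_col]], truth$code)
  purrr::map_dfr(seq_len(nrow(screen$history)), function(i) {
    preds <- screen$history$predictions[[i]]
    if (is.null(preds)) {
      abort("Screen was run with record_predictions = FALSE.")
    }
    y <- unname(ref[preds$code])
    tibble(
      iteration = screen$history$iteration[i],
      n_samples = screen$history$n_sampled[i],
      precision = precision_regression(preds$ddg_pred, y, params),
      recall = recall_regression(preds$ddg_pred, y, params),
      srcc = srcc(preds$ddg_pred, y)
    )
  })
}

#' Benchmark acquisition strategies on synthetic landscapes
#'
#' The harness behind strategy-comparison curves: for each seed it
#' generates a landscape and binary dataset, pretrains once, then runs
#' the screening loop under every supplied policy against the
#' landscape's surrogate oracle, scoring every iteration against the
#' noise-free truth. Strategies therefore share pretraining and data
#' within a seed, isolating the acquisition effect.
#'
#' @param policies Named list of [acquisition_policy()] objects.
#' @param seeds Integer vector of generator seeds (one benchmark
#'   repetition each).
#' @param config A [generator_config()] (its `seed` is replaced per
#'   repetition).
#' @param budget Oracle budget per screening run.
#' @param train A [train_config()] for the per-iteration fine-tunes.
#' @param pretrain_config Optional separate [train_config()] for
#'   pretraining (defaults to `train`).
#' @param model_config An [encoder_config()].
#' @param params A [metric_params()].
#' @return Tibble: `strategy`, `seed`, `iteration`, `n_samples`,
#'   `precision`, `recall`, `srcc`.
#' @export
benchmark_strategies <- function(policies, seeds, config = generator_config(),
                                 budget = 25L, train = train_config(),
                                 pretrain_config = NULL,
                                 model_config = encoder_config(),
                                 params = metric_params()) {
  stopifnot(length(names(policies)) == length(policies))
  pretrain_config <- pretrain_config %||% train
  purrr::map_dfr(seeds, function(sd_i) {
    cfg <- config
    cfg$seed <- as.integer(sd_i)
    ls <- generate_landscape(cfg)
    binary <- generate_binary_dataset(ls, cfg)
    pt <- pretrain_config
    pt$seed <- as.integer(sd_i)
    tr <- train
    tr$seed <- as.integer(sd_i)
    model <- pretrain(binary, pt, model_config)
    truth <- generate_fep_truth(ls, noise_sd = 0)
    oracle <- landscape_oracle(ls)
    purrr::imap_dfr(policies, function(pol, nm) {
      sc <- run_screen(model, binary, oracle, cfg$parent, pol,
                       budget = budget, train = tr)
      ev <- evaluate_vs_truth(sc, truth, params)
      dplyr::mutate(ev, strategy = nm, seed = sd_i,
                    .before = 1L)
    })
  })
}

#' Average benchmark curves at matched oracle-call counts
#'
#' Aligns each run's precision/recall series on a common grid of
#' cumulative sample counts (last-observation-carried-forward, since a
#' snapshot stays current until more samples arrive) and averages over
#' seeds.
#'
#' @param bench A [benchmark_strategies()] result.
#' @param grid Sample counts at which to compare; defaults to every
#'   count reached by all strategies.
#' @return Tibble: `strategy`, `n_samples`, `precision`, `recall`.
#' @export
benchmark_curves <- function(bench, grid = NULL) {
  if (is.null(grid)) {
    rng <- dplyr::summarise(
      dplyr::group_by(bench, .data$strategy, .data$seed),
      first = min(.data$n_samples), last = max(.data$n_samples),
      .groups = "drop"
    )
    grid <- seq(max(rng$first), min(rng$last))
    if (length(grid) == 0L) {
      abort("Benchmark runs share no common sample-count range.")
    }
  }
  runs <- dplyr::group_split(bench, .data$strategy, .data$seed)
  purrr::map_dfr(runs, function(r) {
    r <- dplyr::arrange(r, .data$n_samples)
    idx <- findInterval(grid, r$n_samples)
    keep <- idx >= 1L
    tibble(strategy = r$strategy[1], seed = r$seed[1],
           n_samples = grid[keep],
           precision = r$precision[idx[keep]],
           recall = r$recall[idx[keep]])
  }) |>
    dplyr::group_by(.data$strategy, .data$n_samples) |>
    dplyr::summarise(precision = mean(.data$precision),
                     recall = mean(.data$recall), .groups = "drop")
}
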