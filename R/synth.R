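#' Configuration for the synthetic benchmark generator
#'
#' The generator builds an additive (optionally pairwise-coupled)
#' ground-truth energy landscape around a parent peptide and derives
#' every pipeline input from it: a large binary "presented / not
#' presented" dataset whose labels come from thresholding the same
#' energies, and FEP-style replicate ddG observations over the full
#' single-mutant space. Because both data types share one underlying
#' dG, fine-tuning on ddG observations can genuinely improve ddG
#' ranking -- the structural premise of the screening strategy.
#'
#' Defaults: site-energy spread 1 kcal/mol with a +1 kcal/mol shift (so
#' most substitutions worsen binding and roughly 15% improve it, the
#' typical deep-mutational-scanning picture), replicate noise 0.5
#' kcal/mol (typical FEP-scale error), 5% binary label noise, and
#' 20 000 binary records (a desk-scale stand-in for database-sized
#' extractions).
#'
#' @param parent Parent peptide (default the p53 R175H 9-mer
#'   HMTEVVRHC).
#' @param n_binary Number of random peptides in the binary dataset.
#' @param binder_threshold dG threshold separating binders; `NULL`
#'   (default) calibrates it to the median generated dG so classes are
#'   balanced.
#' @param label_noise Probability each binary label is flipped.
#' @param spread Position-specific site-energy standard deviation
#'   (kcal/mol).
#' @param residue_effect_sd Standard deviation of the shared per-residue
#'   energy component (kcal/mol). Real substitution effects are
#'   partially consistent across positions (hydrophobicity, charge,
#'   proline breaking the backbone), and positional scanning strategies
#'   rely on exactly that transfer; this component controls how much of
#'   it the landscape carries.
#' @param shift Mean site energy of non-wild-type residues (kcal/mol);
#'   positive values make improving mutations rare.
#' @param coupling_density Fraction of position pairs carrying pairwise
#'   couplings (0 disables them).
#' @param coupling_scale Standard deviation of coupling energies.
#' @param noise_sd Replicate noise of the surrogate oracle (kcal/mol).
#' @param mutant_rate Fraction of binary records drawn from the
#'   parent's single mutants rather than uniformly random peptides.
#' @param seed Integer seed; every generated artifact is reproducible
#'   under it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(parent = "HMTEVVRHC", n_binary = 20000L,
                             binder_threshold = NULL, label_noise = 0.05,
                             spread = 0.7, residue_effect_sd = 0.7,
                             shift = 1,
                             coupling_density = 0, coupling_scale = 0,
                             noise_sd = 0.5, mutant_rate = 0.02,
                             seed = 1L) {
  stopifnot(label_noise >= 0, label_noise <= 1, spread >= 0,
            residue_effect_sd >= 0,
            coupling_density >= 0, coupling_density <= 1,
            noise_sd >= 0, mutant_rate >= 0, mutant_rate <= 1,
            n_binary >= 1L)
  structure(
    list(parent = parse_peptide(parent), n_binary = as.integer(n_binary),
         binder_threshold = binder_threshold, label_noise = label_noise,
         spread = spread, residue_effect_sd = residue_effect_sd,
         shift = shift,
         coupling_density = coupling_density,
         coupling_scale = coupling_scale, noise_sd = noise_sd,
         mutant_rate = mutant_rate, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic ground-truth energy landscape
#'
#' Site energies decompose into a shared per-residue effect (how good a
#' residue is anywhere on the peptide) plus an independent
#' position-specific term: `mu[r] + delta[p, r]` with
#' `mu ~ N(0, residue_effect_sd^2)` and `delta ~ N(0, spread^2)`.
#' Energies are reported relative to the wild-type residue of each
#' position and substitutions additionally carry the systematic `shift`
#' penalty (the parent already binds, so most substitutions hurt):
#' `e[p, r] = mu[r] + delta[p, r] - (mu[wt_p] + delta[p, wt_p]) + shift`
#' for every non-wild-type residue, and `e[p, wt] = 0` exactly. Optional sparse pairwise couplings add
#' epistasis. The parent's absolute dG sits 1 kcal/mol below the binder
#' threshold used downstream, reflecting that the neoantigen itself is
#' presented.
#'
#' @param config A [generator_config()].
#' @return A `mimoscan_landscape`: parent, site-energy matrix `e`
#'   (residues x positions), optional coupling array `J`, `noise_sd`,
#'   `dg_parent`, `seed`.
#' @export
generate_landscape <- function(config = generator_config()) {
  parent <- config$parent
  res <- peptide_residues(parent)
  L <- length(res)
  set.seed(config$seed)
  mu <- rnorm(20L, mean = 0, sd = config$residue_effect_sd)
  delta <- matrix(rnorm(20L * L, mean = 0, sd = config$spread), nrow = 20L)
  E <- mu + delta
  dimnames(E) <- list(amino_acids, as.character(1:L))
  wt_e <- E[cbind(res, seq_len(L))]
  e <- sweep(E, 2, wt_e)
  # the parent is a presented binder: substitutions carry a systematic
  # penalty, so improving mutations are the exception
  e <- e + config$shift
  e[cbind(res, seq_len(L))] <- 0
  J <- NULL
  if (config$coupling_density > 0 && config$coupling_scale > 0) {
    J <- array(0, dim = c(L, L, 20L, 20L))
    pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    on_pairs <- runif(nrow(pairs)) < config$coupling_density
    for (r in which(on_pairs)) {
      J[pairs[r, 1], pairs[r, 2], , ] <-
        matrix(rnorm(400L, sd = config$coupling_scale), 20L, 20L)
    }
  }
  structure(
    list(parent = parent, e = e, J = J, noise_sd = config$noise_sd,
         dg_parent = -1, seed = config$seed),
    class = "mimoscan_landscape"
  )
}

#' Generate a binary immunogenicity dataset from a landscape
#'
#' Random peptides of the parent's length (plus the parent itself and a
#' `mutant_rate` share of its single mutants) are scored with the
#' additive extension of the landscape; label 1 means dG below the
#' binder threshold, then each label is flipped with probability
#' `label_noise`. Duplicate sequences are dropped.
#'
#' @param landscape A [generate_landscape()] result.
#' @param config The same [generator_config()].
#' @return Tibble (`sequence`, `label`) with attributes `threshold` and
#'   `class_balance` (fraction of positives).
#' @export
generate_binary_dataset <- function(landscape, config = generator_config()) {
  stopifnot(inherits(landscape, "mimoscan_landscape"))
  parent <- landscape$parent
  L <- nchar(parent)
  set.seed(config$seed + 1L)
  n_mut <- round(config$n_binary * config$mutant_rate)
  n_rand <- config$n_binary - n_mut
  rand <- vapply(seq_len(n_rand), function(i) {
    paste(sample(amino_acids, L, replace = TRUE), collapse = "")
  }, character(1))
  muts <- enumerate_single_mutants(parent)$sequence
  seqs <- unique(c(parent,
                   if (n_mut > 0L) sample(muts, min(n_mut, length(muts))),
                   rand))
  dg <- landscape_dg(landscape, seqs)
  threshold <- config$binder_threshold %||% median(dg)
  label <- as.integer(dg < threshold)
  if (length(unique(label)) < 2L) {
    abort(paste(
      "Binder threshold produced a single class;",
      "use binder_threshold = NULL for automatic calibration",
      "or pick a threshold inside the generated dG range."
    ))
  }
  flip <- runif(length(label)) < config$label_noise
  label[flip] <- 1L - label[flip]
  out <- tibble(sequence = seqs, label = label)
  attr(out, "threshold") <- threshold
  attr(out, "class_balance") <- mean(label)
  out
}

#' Exhaustive FEP-style truth table over the single-mutant space
#'
#' One replicate-averaged surrogate observation per single-site mutant
#' (171 for a 9-mer), plus the noise-free landscape value in
#' `ddg_true`. With `noise_sd = 0` observations equal the truth.
#'
#' @param landscape A [generate_landscape()] result.
#' @param replicas Replicates per mutant (default 3).
#' @param noise_sd Override of the landscape's replicate noise.
#' @param seed Override of the landscape's seed.
#' @return Observation tibble with columns `code`, `ddg`, `sd`,
#'   `n_replicas`, `source`, `ddg_true`.
#' @export
generate_fep_truth <- function(landscape, replicas = 3L, noise_sd = NULL,
                               seed = NULL) {
  stopifnot(inherits(landscape, "mimoscan_landscape"))
  ls2 <- landscape
  if (!is.null(noise_sd)) ls2$noise_sd <- noise_sd
  muts <- enumerate_single_mutants(ls2$parent)
  obs <- surrogate_ddg(ls2, muts$code, replicas = replicas, seed = seed)
  obs$ddg_true <- landscape_true_ddg(ls2, muts)
  obs
}
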