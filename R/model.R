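#' Token vocabulary for peptide encoding
#'
#' The 20 natural amino acids plus a classification token `[CLS]` that
#' is prepended to every sequence and whose latent vector carries the
#' sequence-level representation. Size is therefore exactly 21, and the
#' token-to-id mapping is fixed across runs.
#'
#' @return Named integer vector of token ids (0-based; `[CLS]` is 0).
#' @export
peptide_vocabulary <- function() {
  setNames(0:20, c("[CLS]", amino_acids))
}

#' Encoder hyperparameters
#'
#' Defaults are the working optimum for allele-specific 9-mer
#' peptide-HLA models of this size: embedding dimension 32, four
#' attention heads, one attention layer. The feed-forward width uses
#' the conventional 4x expansion.
#'
#' @param embed_dim Embedding/latent dimension (divisible by `heads`).
#' @param heads Number of attention heads.
#' @param layers Number of encoder blocks.
#' @param max_length Peptide length the model accepts (9 for the
#'   HLA-A*02:01 systems modelled here). Sequences of any other length
#'   are rejected.
#' @param ffn_dim Hidden width of the position-wise feed-forward block.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(embed_dim = 32L, heads = 4L, layers = 1L,
                           max_length = 9L, ffn_dim = 4L * embed_dim) {
  stopifnot(embed_dim %% heads == 0L, layers >= 1L, max_length >= 1L)
  structure(
    list(embed_dim = as.integer(embed_dim), heads = as.integer(heads),
         layers = as.integer(layers), max_length = as.integer(max_length),
         ffn_dim = as.integer(ffn_dim)),
    class = "encoder_config"
  )
}

# Fixed sinusoidal positional encoding, rows = positions (CLS first).
sinusoidal_pe <- function(n_pos, d) {
  pos <- 0:(n_pos - 1)
  i <- 0:(d - 1)
  angle <- outer(pos, 10000^(-(2 * (i %/% 2)) / d))
  pe <- matrix(0, n_pos, d)
  even <- seq(1, d, by = 2) # holds sin terms (0-based even dims)
  odd <- seq(2, d, by = 2)
  pe[, even] <- sin(angle[, even])
  pe[, odd] <- cos(angle[, odd])
  pe
}

# Gaussian(0, 0.02) initialisation for projection weights, zeros for
# biases, identity-like layer norms; reproducible under `seed`.
init_params <- function(config, seed) {
  d <- config$embed_dim
  dff <- config$ffn_dim
  vsize <- length(peptide_vocabulary())
  set.seed(seed)
  w <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  layer <- function() {
    list(Wq = w(d, d), bq = numeric(d), Wk = w(d, d), bk = numeric(d),
         Wv = w(d, d), bv = numeric(d), Wo = w(d, d), bo = numeric(d),
         ln1_g = rep(1, d), ln1_b = numeric(d),
         W1 = w(d, dff), c1 = numeric(dff), W2 = w(dff, d), c2 = numeric(d),
         ln2_g = rep(1, d), ln2_b = numeric(d))
  }
  list(
    emb = w(vsize, d),
    pe = sinusoidal_pe(config$max_length + 1L, d),
    layers = lapply(seq_len(config$layers), function(i) layer()),
    head_w = rnorm(d, sd = 0.02),
    head_b = 0
  )
}

#' Create a peptide free-energy predictor
#'
#' A transformer encoder over tokenized peptides whose `[CLS]` latent is
#' projected to a scalar binding free energy dG (kcal/mol); a single
#' learnable offset `b` converts dG to a binding probability through
#' `plogis(-(dG + b))`, the inverse-sigmoid link between free energy and
#' the log-odds of binding. Weights are randomly initialised; train with
#' [pretrain()] and [finetune()].
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `mimoscan_predictor` object.
#' @export
new_predictor <- function(config = encoder_config(), seed = 1L) {
  structure(
    list(config = config, vocab = peptide_vocabulary(),
         params = init_params(config, seed), offset = 0,
         trained = FALSE, version = "mimoscan-checkpoint-1"),
    class = "mimoscan_predictor"
  )
}

#' @export
print.mimoscan_predictor <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<mimoscan_predictor> %d-mer, dim %d, %d head(s), %d layer(s), %s\n",
    cfg$max_length, cfg$embed_dim, cfg$heads, cfg$layers,
    if (x$trained) "trained" else "untrained"
  ))
  invisible(x)
}

#' Tokenize peptides
#'
#' Prepends the classification token and maps residues to stable ids.
#'
#' @param peptides Character vector of equal-length peptide sequences.
#' @param vocab Vocabulary from [peptide_vocabulary()].
#' @return Integer matrix, one row per peptide, `length + 1` columns,
#'   first column the `[CLS]` id (0).
#' @export
tokenize <- function(peptides, vocab = peptide_vocabulary()) {
  if (length(peptides) == 0L) abort("No peptides to tokenize.")
  lens <- nchar(peptides)
  if (length(unique(lens)) != 1L) {
    abort("All peptides in a batch must have equal length.")
  }
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE)),
                  nrow = length(peptides), byrow = TRUE)
  ids <- matrix(vocab[chars], nrow = length(peptides))
  if (anyNA(ids)) abort("Peptide contains residues outside the vocabulary.")
  unname(cbind(vocab[["[CLS]"]], ids))
}

# Internal batched forward pass; returns dG per sequence.
nn_predict <- function(model, sequences, chunk = 4096L) {
  check_model(model)
  L <- model$config$max_length
  if (any(nchar(sequences) != L)) {
    abort(sprintf("This model accepts only %d-mer peptides.", L))
  }
  out <- numeric(length(sequences))
  idx <- split(seq_along(sequences),
               ceiling(seq_along(sequences) / chunk))
  for (ii in idx) {
    tok <- tokenize(sequences[ii], model$vocab)
    out[ii] <- .nn_core(model$params, tok, model$config$heads,
                        numeric(0), FALSE)$dg
  }
  out
}

check_model <- function(model) {
  if (!inherits(model, "mimoscan_predictor") || is.null(model$params)) {
    abort("`model` must be an initialised mimoscan_predictor.")
  }
  invisible(model)
}

#' Predict binding free energy
#'
#' @param model A trained [new_predictor()] object.
#' @param peptides Character vector of peptide sequences (must match the
#'   model's training length).
#' @return Numeric vector of predicted dG in kcal/mol; lower values mean
#'   stronger predicted binding.
#' @export
predict_dG <- function(model, peptides) {
  peptides <- vapply(peptides, parse_peptide, character(1), USE.NAMES = FALSE)
  nn_predict(model, peptides)
}

#' Predict binding probability
#'
#' The Boltzmann-motivated link between free energy and binding: the
#' probability is `plogis(-(dG + b))` where `b` is the learned threshold
#' offset, so probability decreases strictly in dG and equals 0.5 at
#' `dG = -b`.
#'
#' @inheritParams predict_dG
#' @return Probabilities in (0, 1).
#' @export
predict_binding_prob <- function(model, peptides) {
  dg_to_prob(predict_dG(model, peptides), model$offset)
}

dg_to_prob <- function(dg, offset) plogis(-(dg + offset))
prob_to_dg <- function(p, offset) -stats::qlogis(p) - offset

#' Predict relative binding free energies for mutants
#'
#' ddG = dG(mutant) - dG(parent); negative values mean the mutant is
#' predicted to bind more strongly than the parent (mimotope-favourable).
#'
#' @param model A [new_predictor()] object.
#' @param mutants Mutant tibble (e.g. from
#'   [enumerate_single_mutants()]), or a character vector of mutant
#'   codes together with `parent`.
#' @param parent Parent sequence, required when `mutants` is a character
#'   vector of codes.
#' @return The mutant tibble with a `ddg_pred` column (kcal/mol).
#' @export
predict_ddg <- function(model, mutants, parent = NULL) {
  if (is.character(mutants)) {
    mutants <- parse_mutant_code(mutants, parent)
  }
  stopifnot(is.data.frame(mutants))
  seqs <- unique(c(mutants$parent, mutants$sequence))
  dg <- setNames(predict_dG(model, seqs), seqs)
  dplyr::mutate(as_tibble(mutants),
                ddg_pred = unname(dg[.data$sequence] - dg[.data$parent]))
}

#' Lay mutant values out as a position x residue matrix
#'
#' Heatmap-ready wide layout: one row per substituted residue (19 per
#' column appear; the wild-type cell is `NA`), one column per position.
#'
#' @param mutants Mutant tibble containing a value column.
#' @param value Name of the value column (default `"ddg_pred"`).
#' @return Numeric matrix, rownames = residues, colnames = positions.
#' @export
mutant_matrix <- function(mutants, value = "ddg_pred") {
  stopifnot(value %in% names(mutants))
  L <- nchar(mutants$parent[1])
  m <- matrix(NA_real_, length(amino_acids), L,
              dimnames = list(amino_acids, as.character(seq_len(L))))
  m[cbind(mutants$to_res, mutants$position)] <- mutants[[value]]
  m
}

#' Write / read a model checkpoint
#'
#' A single JSON file holding the config, vocabulary, all weights and
#' the binary-threshold offset, tagged with a format version. JSON keeps
#' checkpoints portable and diffable; the numbers round-trip at full
#' double precision.
#'
#' @param model A `mimoscan_predictor`.
#' @param path File path.
#' @return `write_checkpoint` returns `path` invisibly;
#'   `read_checkpoint` returns the restored model.
#' @export
write_checkpoint <- function(model, path) {
  check_model(model)
  payload <- list(
    version = model$version,
    config = unclass(model$config),
    vocab = as.list(model$vocab),
    offset = model$offset,
    trained = model$trained,
    params = model$params
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (!identical(raw$version, "mimoscan-checkpoint-1")) {
    abort("Unrecognised checkpoint version.")
  }
  cfg <- do.call(encoder_config, raw$config[c("embed_dim", "heads", "layers",
                                              "max_length", "ffn_dim")])
  params <- raw$params
  params$layers <- lapply(seq_len(cfg$layers), function(l) {
    lapply(params$layers[[l]], identity)
  })
  # vectors come back as plain numeric; matrices as matrices -- both are
  # what the C++ core expects
  structure(
    list(config = cfg, vocab = unlist(raw$vocab), params = params,
         offset = raw$offset, trained = isTRUE(raw$trained),
         version = raw$version),
    class = "mimoscan_predictor"
  )
}
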