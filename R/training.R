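#' Training hyperparameters
#'
#' Defaults are the production optima for the pretraining stage (batch
#' size 1024, learning rate 1e-4, five folds) and the dual-loss
#' fine-tuning stage (loss weight k self-adapting within
#' `[k_init, k_max] = [1e-4, 1]`). `layer_lr_decay` is the geometric
#' factor by which the learning rate shrinks per block moving backwards
#' from the output head during fine-tuning; `patience`/`tolerance`
#' define AUC convergence for pretraining.
#'
#' @param batch_size Minibatch size for binary data.
#' @param learning_rate Base Adam learning rate.
#' @param folds Number of cross-validation folds for the binary data.
#' @param seed Seed controlling fold assignment and batch order.
#' @param k_init,k_max Range of the adaptive dual-loss weight.
#' @param layer_lr_decay Per-group learning-rate decay in (0, 1], applied
#'   only during fine-tuning.
#' @param patience Epochs without validation-AUC improvement before
#'   pretraining stops.
#' @param tolerance Minimum AUC improvement that counts as progress.
#' @param max_epochs Hard cap on pretraining epochs.
#' @param finetune_epochs Number of fine-tuning epochs.
#' @param finetune_lr_schedule `"constant"` (default) keeps the
#'   fine-tuning learning rate fixed; `"cosine"` anneals it to 10% of
#'   `learning_rate` over the run. Pretraining always uses a constant
#'   rate.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 1024L, learning_rate = 1e-4,
                         folds = 5L, seed = 1L, k_init = 1e-4, k_max = 1,
                         layer_lr_decay = 0.5, patience = 10L,
                         tolerance = 1e-3, max_epochs = 100L,
                         finetune_epochs = 30L,
                         finetune_lr_schedule = c("constant", "cosine")) {
  stopifnot(batch_size >= 1L, learning_rate > 0, folds >= 2L,
            k_init > 0, k_max >= k_init,
            layer_lr_decay > 0, layer_lr_decay <= 1)
  structure(
    list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
         folds = as.integer(folds), seed = as.integer(seed),
         k_init = k_init, k_max = k_max, layer_lr_decay = layer_lr_decay,
         patience = as.integer(patience), tolerance = tolerance,
         max_epochs = as.integer(max_epochs),
         finetune_epochs = as.integer(finetune_epochs),
         finetune_lr_schedule = match.arg(finetune_lr_schedule)),
    class = "train_config"
  )
}

#' Dual-loss combination
#'
#' Total fine-tuning loss: binary cross-entropy on the large binary
#' dataset plus `k` times the mean-squared error on the small
#' free-energy dataset, `bce + k * mse`.
#'
#' @param bce,mse Non-negative loss values.
#' @param k Loss weight in `[k_init, k_max]`.
#' @return The combined scalar loss.
#' @export
dual_loss <- function(bce, mse, k) {
  if (any(c(bce, mse) < 0)) abort("Losses must be non-negative.")
  bce + k * mse
}

#' Self-adaptive update of the dual-loss weight k
#'
#' k is raised to the current BCE/MSE ratio whenever that ratio exceeds
#' it, and clamped to `[k_init, k_max]`; it therefore increases
#' monotonically from `k_init` toward `k_max` as the MSE term is
#' minimised. With `mse = 0` (degenerate perfect fit) k is left
#' unchanged.
#'
#' @inheritParams dual_loss
#' @param k_init,k_max Clamp range (defaults 1e-4 and 1).
#' @return Updated k.
#' @export
update_k <- function(k, bce, mse, k_init = 1e-4, k_max = 1) {
  if (mse == 0) return(k)
  min(k_max, max(k, bce / mse, k_init))
}

# ---- parameter flattening / optimiser ------------------------------------

LAYER_PARS <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
                "ln1_g", "ln1_b", "W1", "c1", "W2", "c2", "ln2_g", "ln2_b")

# All trainable leaves in canonical order (positional encoding is fixed).
flatten_params <- function(model) {
  p <- model$params
  pieces <- list(as.numeric(p$emb))
  for (l in seq_along(p$layers)) {
    for (nm in LAYER_PARS) pieces[[length(pieces) + 1L]] <-
        as.numeric(p$layers[[l]][[nm]])
  }
  pieces[[length(pieces) + 1L]] <- as.numeric(p$head_w)
  pieces[[length(pieces) + 1L]] <- p$head_b
  pieces[[length(pieces) + 1L]] <- model$offset
  unlist(pieces, use.names = FALSE)
}

flatten_grads <- function(grads, d_offset, model) {
  pieces <- list(as.numeric(grads$emb))
  for (l in seq_along(model$params$layers)) {
    gl <- grads$layers[[l]]
    for (nm in LAYER_PARS) pieces[[length(pieces) + 1L]] <-
        as.numeric(gl[[nm]])
  }
  pieces[[length(pieces) + 1L]] <- as.numeric(grads$head_w)
  pieces[[length(pieces) + 1L]] <- grads$head_b
  pieces[[length(pieces) + 1L]] <- d_offset
  unlist(pieces, use.names = FALSE)
}

unflatten_params <- function(model, theta) {
  p <- model$params
  i <- 0L
  take <- function(n) {
    out <- theta[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  p$emb <- matrix(take(length(p$emb)), nrow(p$emb), ncol(p$emb))
  for (l in seq_along(p$layers)) {
    for (nm in LAYER_PARS) {
      leaf <- p$layers[[l]][[nm]]
      if (is.matrix(leaf)) {
        p$layers[[l]][[nm]] <- matrix(take(length(leaf)), nrow(leaf), ncol(leaf))
      } else {
        p$layers[[l]][[nm]] <- take(length(leaf))
      }
    }
  }
  p$head_w <- take(length(p$head_w))
  p$head_b <- take(1L)
  model$params <- p
  model$offset <- take(1L)
  stopifnot(i == length(theta))
  model
}

# Learning-rate group per element: 0 = head (+ binary offset), 1..N the
# encoder blocks counted backwards from the head, N+1 the embedding.
lr_groups <- function(model) {
  p <- model$params
  nl <- length(p$layers)
  groups <- rep(nl + 1L, length(p$emb))
  for (l in seq_along(p$layers)) {
    n_l <- sum(vapply(p$layers[[l]][LAYER_PARS], length, integer(1)))
    groups <- c(groups, rep(nl + 1L - l, n_l))
  }
  c(groups, rep(0L, length(p$head_w) + 2L))
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(opt, theta, grad, lr_elem) {
  opt$t <- opt$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  opt$m <- b1 * opt$m + (1 - b1) * grad
  opt$v <- b2 * opt$v + (1 - b2) * grad^2
  mhat <- opt$m / (1 - b1^opt$t)
  vhat <- opt$v / (1 - b2^opt$t)
  theta <- theta - lr_elem * mhat / (sqrt(vhat) + eps)
  list(opt = opt, theta = theta)
}

# ---- losses ---------------------------------------------------------------

# BCE on binding probability plogis(-(dg + offset)); returns loss and the
# gradients wrt dg and the offset. Gradient of the mean loss.
bce_pieces <- function(dg, offset, y) {
  p <- dg_to_prob(dg, offset)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  n <- length(y)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  g_dg <- (y - p) / n
  list(loss = loss, g_dg = g_dg, g_offset = sum(y - p) / n)
}

mse_pieces <- function(dg, target) {
  n <- length(target)
  r <- dg - target
  list(loss = mean(r^2), g_dg = 2 * r / n)
}

# ---- data validation ------------------------------------------------------

# Binary records: tibble(sequence, label). Consistent duplicates are
# collapsed; conflicting duplicates are an input error.
validate_binary <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("sequence", "label") %in% names(data)))
  data <- dplyr::distinct(as_tibble(data[c("sequence", "label")]))
  if (!all(data$label %in% c(0, 1))) {
    abort("Binary labels must be 0 or 1.")
  }
  conflicts <- dplyr::count(data, .data$sequence)
  conflicts <- dplyr::filter(conflicts, .data$n > 1L)
  if (nrow(conflicts) > 0L) {
    abort(sprintf(
      "%d sequence(s) carry conflicting binary labels (e.g. '%s').",
      nrow(conflicts), conflicts$sequence[1]
    ))
  }
  data$sequence <- vapply(data$sequence, parse_peptide, character(1),
                          USE.NAMES = FALSE)
  data
}

# ---- pretraining ----------------------------------------------------------

#' Pretrain the predictor on binary immunogenicity data
#'
#' Trains the encoder plus the inverse-sigmoid binary head with binary
#' cross-entropy until the validation AUC converges (no improvement
#' greater than `tolerance` for `patience` epochs). Records are assigned
#' to `folds` balanced folds; one fold is held out as the validation set
#' and the weights from the best-AUC epoch are kept.
#'
#' @param data Tibble with columns `sequence`, `label` (1 = presented /
#'   binder). At least two records per class.
#' @param config A [train_config()].
#' @param model_config An [encoder_config()].
#' @param val_fold Which fold to hold out (default 1).
#' @return A trained `mimoscan_predictor` with `$history` (per-epoch
#'   tibble: `epoch`, `loss_bce`, `loss_mse`, `k`, `val_auc`) and
#'   `$folds` (fold assignment per record).
#' @export
pretrain <- function(data, config = train_config(),
                     model_config = encoder_config(), val_fold = 1L) {
  data <- validate_binary(data)
  if (min(table(data$label)) < 2L) {
    abort("Need at least two records per class to pretrain.")
  }
  if (nrow(data) < config$folds) {
    abort("Fewer records than cross-validation folds.")
  }
  set.seed(config$seed)
  folds <- sample(rep(seq_len(config$folds), length.out = nrow(data)))
  val <- which(folds == val_fold)
  tr <- which(folds != val_fold)
  if (length(unique(data$label[val])) < 2L) {
    abort("Validation fold ended up single-class; use more data.")
  }

  model <- new_predictor(model_config, seed = config$seed)
  theta <- flatten_params(model)
  opt <- adam_init(length(theta))
  lr_elem <- rep(config$learning_rate, length(theta)) # uniform in pretraining
  cfg <- model$config
  pe <- model$params$pe

  tok_all <- tokenize(data$sequence, model$vocab)
  tok_tr <- tok_all[tr, , drop = FALSE]; y_tr <- data$label[tr]
  tok_val <- tok_all[val, , drop = FALSE]; y_val <- data$label[val]

  history <- list()
  best_auc <- -Inf; best_theta <- theta; stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(nrow(tok_tr))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    bce_sum <- 0
    for (b in batches) {
      out <- .nn_step_flat(theta, pe, tok_tr[b, , drop = FALSE],
                           cfg$heads, cfg$layers, cfg$ffn_dim,
                           length(model$vocab), y_tr[b], numeric(0), 0)
      st <- adam_step(opt, theta, out$grad, lr_elem)
      opt <- st$opt; theta <- st$theta
      bce_sum <- bce_sum + out$loss_bce
    }
    model <- unflatten_params(model, theta)
    val_auc <- auc(-.nn_core(model$params, tok_val, cfg$heads,
                             numeric(0), FALSE)$dg, y_val)
    history[[epoch]] <- tibble(
      epoch = epoch, loss_bce = bce_sum / length(batches),
      loss_mse = NA_real_, k = NA_real_, val_auc = val_auc
    )
    if (val_auc > best_auc + config$tolerance) {
      best_auc <- val_auc; best_theta <- theta; stall <- 0L
    } else {
      if (val_auc > best_auc) { best_auc <- val_auc; best_theta <- theta }
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  model <- unflatten_params(model, best_theta)
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(history)
  model$folds <- folds
  model$stage <- "pretrained"
  model
}

# ---- fine-tuning ----------------------------------------------------------

#' Anchor relative free energies to absolute regression targets
#'
#' The regression head predicts absolute dG, but FEP-style oracles yield
#' only differences ddG relative to the parent. Targets are therefore
#' anchored: `dG_target = dG_model(parent) + ddG`, with the parent
#' prediction frozen at the supplied model state so targets stay stable
#' across fine-tuning epochs.
#'
#' @param observations Tibble with columns `code` and `ddg` (kcal/mol).
#' @param model Model providing the frozen parent anchor.
#' @param parent Parent peptide sequence.
#' @return Tibble with columns `sequence`, `dg` ready for [finetune()].
#' @export
anchor_ddg <- function(observations, model, parent) {
  stopifnot(all(c("code", "ddg") %in% names(observations)))
  parent <- parse_peptide(parent)
  anchor <- predict_dG(model, parent)
  mut <- parse_mutant_code(observations$code, parent)
  tibble(sequence = mut$sequence, dg = anchor + observations$ddg)
}

#' Fine-tune with the dual-loss mechanism
#'
#' Each epoch runs one pass of binary minibatches; every gradient step
#' also includes the full (small) free-energy set, so the step loss is
#' `BCE(batch) + k * MSE(dg set)`. After each epoch k is raised to the
#' epoch-mean BCE/MSE ratio if that exceeds the current k (clamped to
#' `[k_init, k_max]`), so k starts at `k_init` and increases
#' monotonically. Learning rates decay geometrically by
#' `layer_lr_decay` per group moving backwards from the output head
#' (head, then encoder blocks in reverse, then the embedding).
#'
#' @param model A pretrained `mimoscan_predictor`.
#' @param binary Binary records tibble (`sequence`, `label`).
#' @param dg Free-energy targets tibble (`sequence`, `dg` in kcal/mol),
#'   e.g. from [anchor_ddg()]. Must be non-empty.
#' @param config A [train_config()].
#' @return The fine-tuned model; `$history` gains per-epoch `loss_bce`,
#'   `loss_mse`, `k`, `val_auc` rows.
#' @export
finetune <- function(model, binary, dg, config = train_config()) {
  check_model(model)
  if (is.null(dg) || nrow(dg) == 0L) {
    abort("Empty free-energy set: use pretrain() for binary-only training.")
  }
  stopifnot(all(c("sequence", "dg") %in% names(dg)))
  binary <- validate_binary(binary)
  set.seed(config$seed + 1L)
  folds <- sample(rep(seq_len(config$folds), length.out = nrow(binary)))
  val <- which(folds == 1L)
  tr <- which(folds != 1L)

  theta <- flatten_params(model)
  opt <- adam_init(length(theta))
  lr_elem <- config$learning_rate *
    config$layer_lr_decay^lr_groups(model)
  cfg <- model$config
  pe <- model$params$pe

  tok_bin <- tokenize(binary$sequence, model$vocab)
  tok_tr <- tok_bin[tr, , drop = FALSE]; y_tr <- binary$label[tr]
  tok_val <- tok_bin[val, , drop = FALSE]; y_val <- binary$label[val]
  tok_dg <- tokenize(dg$sequence, model$vocab)
  dg_target <- dg$dg

  k <- config$k_init
  history <- list()
  n_ep <- config$finetune_epochs
  for (epoch in seq_len(n_ep)) {
    lr_mult <- if (identical(config$finetune_lr_schedule, "cosine") && n_ep > 1L) {
      0.1 + 0.9 * 0.5 * (1 + cos(pi * (epoch - 1) / (n_ep - 1)))
    } else 1
    ord <- sample(nrow(tok_tr))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    bce_sum <- 0; mse_sum <- 0
    for (b in batches) {
      tok <- rbind(tok_tr[b, , drop = FALSE], tok_dg)
      out <- .nn_step_flat(theta, pe, tok, cfg$heads, cfg$layers,
                           cfg$ffn_dim, length(model$vocab),
                           y_tr[b], dg_target, k)
      st <- adam_step(opt, theta, out$grad, lr_mult * lr_elem)
      opt <- st$opt; theta <- st$theta
      bce_sum <- bce_sum + out$loss_bce
      mse_sum <- mse_sum + out$loss_mse
    }
    model <- unflatten_params(model, theta)
    bce_mean <- bce_sum / length(batches)
    mse_mean <- mse_sum / length(batches)
    val_auc <- if (length(unique(y_val)) > 1L) {
      auc(-.nn_core(model$params, tok_val, cfg$heads, numeric(0), FALSE)$dg,
          y_val)
    } else NA_real_
    history[[epoch]] <- tibble(
      epoch = epoch, loss_bce = bce_mean, loss_mse = mse_mean,
      k = k, val_auc = val_auc
    )
    k <- update_k(k, bce_mean, mse_mean, config$k_init, config$k_max)
  }
  model$trained <- TRUE
  prev <- model$history
  ft <- dplyr::bind_rows(history)
  ft$stage <- "finetune"
  if (!is.null(prev)) {
    if (!"stage" %in% names(prev)) prev$stage <- "pretrain"
    model$history <- dplyr::bind_rows(prev, ft)
  } else {
    model$history <- ft
  }
  model$stage <- "finetuned"
  model
}
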