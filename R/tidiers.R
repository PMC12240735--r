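#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a predictor's training history
#'
#' One row per training epoch with the losses, the dual-loss weight k
#' (fine-tuning only) and the validation AUC.
#'
#' @param x A `mimoscan_predictor`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mimoscan_predictor <- function(x, ...) {
  if (is.null(x$history)) {
    abort("Model has no training history yet; run pretrain().")
  }
  as_tibble(x$history)
}

#' @rdname tidy.mimoscan_predictor
#' @export
glance.mimoscan_predictor <- function(x, ...) {
  h <- x$history
  tibble(
    stage = x$stage %||% "initialized",
    epochs = if (is.null(h)) 0L else nrow(h),
    final_val_auc = if (is.null(h)) NA_real_ else dplyr::last(h$val_auc),
    final_k = if (is.null(h)) NA_real_ else dplyr::last(h$k),
    offset = x$offset
  )
}

#' Tidy a screening run
#'
#' Per-iteration summary of the loop: how many candidates were elected
#' and newly observed, the cumulative oracle count and the best
#' observed ddG so far.
#'
#' @param x A `mimoscan_screen`.
#' @param ... Unused.
#' @return A tibble without list-columns.
#' @export
tidy.mimoscan_screen <- function(x, ...) {
  dplyr::select(x$history, -"elected", -"predictions")
}

#' @rdname tidy.mimoscan_screen
#' @export
glance.mimoscan_screen <- function(x, ...) {
  tibble(
    strategy = x$policy$strategy,
    breadth = x$policy$breadth,
    iterations = nrow(x$history),
    n_sampled = nrow(x$observations),
    best_ddg = if (nrow(x$observations)) min(x$observations$ddg) else NA_real_,
    objective_threshold = x$threshold,
    stop_reason = x$stop_reason
  )
}
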