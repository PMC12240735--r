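#' Metric parameters for regression precision and recall
#'
#' Defaults: deviation threshold `epsilon` = 1 kcal/mol, scale-function
#' center `c` = 0 kcal/mol, scale shape `s` = 5, hit shape `k_hit` = 10.
#' Mutants with ddG < 0 (binding improved over the parent) are the
#' positive class; `scale_phi` weights samples softly toward it.
#'
#' @param epsilon Maximum prediction deviation (kcal/mol) that still
#'   counts as a hit.
#' @param center Center `c` of the scale function (kcal/mol).
#' @param shape Shape `s` of the scale function.
#' @param k_hit Shape of the hit function.
#' @return A `metric_params` list.
#' @export
metric_params <- function(epsilon = 1, center = 0, shape = 5, k_hit = 10) {
  stopifnot(epsilon > 0, shape > 0, k_hit > 0)
  structure(list(epsilon = epsilon, center = center, shape = shape,
                 k_hit = k_hit),
            class = "metric_params")
}

#' Scale function: soft positive-class weight of a ddG value
#'
#' `phi(y) = 1 / (1 + exp(s * (y - c)))`, a decreasing logistic mapping
#' of ddG onto (0, 1): strongly improving mutants (very negative ddG)
#' approach weight 1, worsening mutants approach 0, and `phi(c) = 0.5`.
#'
#' @param y ddG values (kcal/mol); vectorised.
#' @param params A [metric_params()].
#' @return Values in (0, 1).
#' @export
scale_phi <- function(y, params = metric_params()) {
  stopifnot(all(is.finite(y)))
  1 / (1 + exp(params$shape * (y - params$center)))
}

#' Hit function: smooth within-epsilon prediction accuracy
#'
#' `alpha(yhat, y) = I(|yhat - y| <= eps) *
#' (1 - exp(-k_hit * (|yhat - y| - eps)^2 / eps^2))`. Zero whenever the
#' deviation reaches or exceeds `epsilon` (continuously from both
#' sides), and maximal, `1 - exp(-k_hit)`, at zero deviation.
#'
#' @param y_hat Predicted ddG (kcal/mol); vectorised.
#' @param y Reference ddG (kcal/mol).
#' @inheritParams scale_phi
#' @return Values in `[0, 1 - exp(-k_hit)]`.
#' @export
hit_alpha <- function(y_hat, y, params = metric_params()) {
  stopifnot(all(is.finite(y_hat)), all(is.finite(y)))
  d <- abs(y_hat - y)
  eps <- params$epsilon
  ifelse(d <= eps,
         1 - exp(-params$k_hit * (d - eps)^2 / eps^2),
         0)
}

#' Regression precision and recall for mimotope screening
#'
#' Weighted extensions of precision and recall to the regression
#' setting. Precision weights each sample's hit score by the predicted
#' positive weight `phi(y_hat)` -- "of what I call a strong binder, how
#' much did I get right"; recall weights by the actual positive weight
#' `phi(y)` -- "of the true strong binders, how much did I capture":
#' \deqn{Precision = \sum_i \alpha_i \varphi(\hat y_i) / \sum_i \varphi(\hat y_i)}
#' \deqn{Recall    = \sum_i \alpha_i \varphi(y_i)      / \sum_i \varphi(y_i)}
#'
#' @param y_hat Predicted ddG values (kcal/mol).
#' @param y Reference (e.g. FEP) ddG values, same length.
#' @inheritParams scale_phi
#' @return Scalar in `[0, 1 - exp(-k_hit)]`.
#' @export
precision_regression <- function(y_hat, y, params = metric_params()) {
  check_pairs(y_hat, y)
  a <- hit_alpha(y_hat, y, params)
  w <- scale_phi(y_hat, params)
  sum(a * w) / sum(w)
}

#' @rdname precision_regression
#' @export
recall_regression <- function(y_hat, y, params = metric_params()) {
  check_pairs(y_hat, y)
  a <- hit_alpha(y_hat, y, params)
  w <- scale_phi(y, params)
  sum(a * w) / sum(w)
}

check_pairs <- function(y_hat, y) {
  if (length(y_hat) == 0L || length(y_hat) != length(y)) {
    abort("`y_hat` and `y` must be non-empty vectors of equal length.")
  }
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midranks for ties: the probability
#' that a random positive scores above a random negative.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) {
    abort("AUC needs both classes present.")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spearman's rank correlation coefficient
#'
#' @param a,b Numeric vectors of length >= 2; neither may be constant.
#' @return Correlation in `[-1, 1]`.
#' @export
srcc <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (sd(a) == 0 || sd(b) == 0) {
    abort("SRCC is undefined for a constant vector.")
  }
  cor(a, b, method = "spearman")
}

#' One-row metric report for a set of ddG predictions
#'
#' @param y_hat Predicted ddG values.
#' @param y Reference ddG values.
#' @inheritParams scale_phi
#' @return Tibble with `auc` (positives = `y < 0`), `srcc`, `precision`,
#'   `recall`.
#' @export
metric_report <- function(y_hat, y, params = metric_params()) {
  tibble(
    auc = auc(-y_hat, as.numeric(y < 0)),
    srcc = srcc(y_hat, y),
    precision = precision_regression(y_hat, y, params),
    recall = recall_regression(y_hat, y, params)
  )
}
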