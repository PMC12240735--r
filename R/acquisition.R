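#' Acquisition policy for electing the next oracle samples
#'
#' Three deterministic strategies drive the active-learning loop:
#' exploitation (`"DFS"`: the single unsampled mutant with the most
#' negative predicted ddG), exploration (`"BFS"`: per position, the
#' best-predicted unsampled substitution, kept only if it points in the
#' improving direction), and their hybrid (`"DFS_Bn"`: the DFS candidate
#' plus an X-scan of its mutated residue across `breadth` neighbouring
#' positions).
#'
#' @param strategy One of `"DFS"`, `"BFS"`, `"DFS_Bn"`.
#' @param breadth Neighbourhood half-width n for `"DFS_Bn"`.
#' @param objective_fold_increase Desired fold-increase in binding
#'   affinity defining the screening objective (default 100).
#' @param temperature Temperature in kelvin for converting the fold
#'   increase into a free-energy threshold (default 310, body/simulation
#'   temperature).
#' @return An `acquisition_policy` list.
#' @export
acquisition_policy <- function(strategy = c("DFS", "BFS", "DFS_Bn"),
                               breadth = 0L,
                               objective_fold_increase = 100,
                               temperature = 310) {
  strategy <- match.arg(strategy)
  stopifnot(breadth >= 0L, temperature > 0)
  if (objective_fold_increase <= 1) {
    abort("`objective_fold_increase` must exceed 1.")
  }
  structure(
    list(strategy = strategy, breadth = as.integer(breadth),
         objective_fold_increase = objective_fold_increase,
         temperature = temperature),
    class = "acquisition_policy"
  )
}

#' ddG threshold corresponding to a fold-increase objective
#'
#' A `fold`-times stronger binding constant corresponds to
#' `ddG = -R T ln(fold)` with `R = 1.9872e-3` kcal/(mol K); at 310 K a
#' 100-fold increase is about -2.84 kcal/mol.
#'
#' @param policy An [acquisition_policy()].
#' @return Threshold in kcal/mol (negative).
#' @export
objective_threshold <- function(policy = acquisition_policy()) {
  -GAS_CONSTANT_KCAL * policy$temperature * log(policy$objective_fold_increase)
}

# Predictions table contract: mutant tibble with `ddg_pred`, canonical
# codes unique. `sampled` is a character vector of codes.
check_preds <- function(preds) {
  stopifnot(is.data.frame(preds),
            all(c("code", "position", "to_res", "ddg_pred") %in% names(preds)))
  if (anyDuplicated(preds$code)) abort("Duplicate mutant codes in predictions.")
  if (!all(is.finite(preds$ddg_pred))) abort("Non-finite ddG predictions.")
  invisible(preds)
}

# Canonical order: position ascending then substituted residue.
canonical_order <- function(tbl) {
  dplyr::arrange(tbl, .data$position, .data$to_res)
}

#' Depth-first election: the best unsampled mutant
#'
#' Returns the non-repetitive (not yet sampled) mutant with the minimal
#' predicted ddG; ties break by canonical order (position, then
#' substituted residue).
#'
#' @param preds Mutant tibble with a `ddg_pred` column
#'   (see [predict_ddg()]).
#' @param sampled Character vector of already-sampled mutant codes.
#' @return One-row mutant tibble.
#' @export
elect_dfs <- function(preds, sampled = character(0)) {
  check_preds(preds)
  pool <- dplyr::filter(preds, !.data$code %in% sampled)
  if (nrow(pool) == 0L) {
    abort("All mutants have been sampled; the space is exhausted.")
  }
  pool <- canonical_order(pool)
  pool[which.min(pool$ddg_pred), , drop = FALSE]
}

#' Breadth-first election: one recommended substitution per position
#'
#' For each position, the unsampled substitution with the minimal
#' predicted ddG -- kept only when that minimum is negative, i.e. aligns
#' with the optimization direction. Positions whose best candidate is
#' already sampled or non-improving contribute nothing, so the result
#' may be empty.
#'
#' @inheritParams elect_dfs
#' @return Mutant tibble with at most one row per position.
#' @export
elect_bfs <- function(preds, sampled = character(0)) {
  check_preds(preds)
  pool <- dplyr::filter(preds, !.data$code %in% sampled)
  pool <- canonical_order(pool)
  pool <- dplyr::group_by(pool, .data$position)
  pool <- dplyr::slice_min(pool, .data$ddg_pred, n = 1L, with_ties = FALSE)
  pool <- dplyr::ungroup(pool)
  canonical_order(dplyr::filter(pool, .data$ddg_pred < 0))
}

#' DFS+Bn election: the DFS candidate plus its positional X-scan
#'
#' The depth-first candidate, followed by substitutions of its mutated
#' residue X at positions within `n` of it (see
#' [x_scan_neighborhood()]), already-sampled codes removed. With
#' `n = 0` this reduces exactly to [elect_dfs()].
#'
#' @inheritParams elect_dfs
#' @param n Neighbourhood half-width.
#' @return Mutant tibble; the DFS candidate first, then neighbours in
#'   canonical order.
#' @export
elect_dfs_bn <- function(preds, sampled = character(0), n = 0L) {
  cand <- elect_dfs(preds, sampled)
  if (n == 0L) return(cand)
  scan <- x_scan_neighborhood(cand$parent, cand$code, n)
  scan <- dplyr::filter(scan, !.data$code %in% c(sampled, cand$code))
  dplyr::bind_rows(cand, canonical_order(scan))
}

#' Elect candidates under a policy
#'
#' Dispatches to [elect_dfs()], [elect_bfs()] or [elect_dfs_bn()].
#'
#' @inheritParams elect_dfs
#' @param policy An [acquisition_policy()].
#' @return Mutant tibble of elected, unsampled candidates.
#' @export
elect_candidates <- function(preds, policy, sampled = character(0)) {
  switch(policy$strategy,
    DFS = elect_dfs(preds, sampled),
    BFS = elect_bfs(preds, sampled),
    DFS_Bn = elect_dfs_bn(preds, sampled, policy$breadth)
  )
}
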