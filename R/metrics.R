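#' Category-concordance AUC from a joint-exposure table
#'
#' Treats the table's categories as a discrete risk score ordered by their
#' case:control odds and computes the probability that a random case ranks
#' above a random control, counting ties (including a case and a control in
#' the same category) as one half. This equals the Mann-Whitney concordance
#' of the category risk score at the individual level, and is the ROC AUC
#' of the grouped classifier.
#'
#' @param t a non-degenerate `pair_table`, or any pair of case/control count
#'   vectors via [auc_categories()].
#' @return AUC in [0, 1].
#' @export
auc_from_table <- function(t) {
  stopifnot(inherits(t, "pair_table"))
  if (t$degenerate) stop("degenerate table")
  auc_categories(t$cases, t$controls)
}

#' @rdname auc_from_table
#' @param cases,controls aligned per-category counts.
#' @export
auc_categories <- function(cases, controls) {
  stopifnot(length(cases) == length(controls), sum(cases) > 0,
            sum(controls) > 0)
  p <- cases / sum(cases)
  q <- controls / sum(controls)
  odds <- ifelse(controls == 0, Inf, cases / controls)
  odds[cases == 0 & controls == 0] <- NA        # empty category: no mass
  k <- length(p)
  auc <- 0
  for (a in seq_len(k)) {
    if (p[a] == 0) next
    for (b in seq_len(k)) {
      if (q[b] == 0) next
      if (odds[a] > odds[b]) auc <- auc + p[a] * q[b]
      else if (odds[a] == odds[b]) auc <- auc + 0.5 * p[a] * q[b]
    }
  }
  unname(auc)
}

#' Sensitivity and specificity of a binary high-risk rule over categories
#'
#' @param t a `pair_table` (or use `cases`/`controls` count vectors).
#' @param high_risk logical vector over categories (`TRUE` = classified
#'   high risk).
#' @return list with `sensitivity` (case mass in high-risk categories) and
#'   `specificity` (control mass in low-risk categories).
#' @export
sens_spec <- function(t, high_risk) {
  stopifnot(inherits(t, "pair_table"),
            length(high_risk) == length(t$cases))
  list(sensitivity = sum(t$cases[high_risk]) / sum(t$cases),
       specificity = sum(t$controls[!high_risk]) / sum(t$controls))
}

#' Attributable fraction from a joint-exposure table (Miettinen form)
#'
#' Case-load attributable fraction:
#' `AF = sum over non-baseline categories of pc_i * (OR_i - 1) / OR_i`,
#' where `pc_i` is the proportion of cases in category `i` and `OR_i` its
#' odds ratio versus the baseline category. Algebraically equal to
#' `1 - sum_i pc_i / OR_i` (baseline OR = 1). Categories with `OR_i < 1`
#' contribute negatively, so the value lies in (-Inf, 1]. A zero baseline
#' cell triggers a 0.5 continuity correction on all cells, flagged via a
#' warning.
#'
#' @param t a non-degenerate `pair_table`.
#' @param baseline index of the baseline category (default 1, the `00`
#'   cell).
#' @return the attributable fraction.
#' @export
paf <- function(t, baseline = 1L) {
  stopifnot(inherits(t, "pair_table"))
  if (t$degenerate) stop("degenerate table")
  ca <- t$cases; co <- t$controls
  if (ca[baseline] == 0 || co[baseline] == 0) {
    warning("zero baseline cell; 0.5 continuity correction applied")
    ca <- ca + 0.5; co <- co + 0.5
  }
  pc <- ca / sum(ca)
  or <- (ca / co) / (ca[baseline] / co[baseline])
  idx <- setdiff(seq_along(ca), baseline)
  contrib <- pc[idx] * (1 - 1 / or[idx])   # = pc * (OR - 1) / OR
  contrib[pc[idx] == 0] <- 0               # no case mass, no contribution
  sum(contrib)
}
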