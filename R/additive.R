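#' Additive-scale interaction: RERI and attributable proportion
#'
#' Fits the saturated model for a 2 x 2 joint-exposure table. With all four
#' cells populated in both strata the maximum-likelihood odds ratios of the
#' saturated logistic model coincide with the cross-product ratios against
#' the `00` cell, so the point estimates are computed in closed form:
#' `RERI = OR11 - OR01 - OR10 + 1` and `AP = RERI / OR11`. The variance of
#' AP comes from the delta method on the three log-odds-ratio coefficients
#' (the Hosmer-Lemeshow formulation), using the saturated-model covariance
#' whose entries are sums of reciprocal cell counts. The 95% interval is
#' `AP +/- 1.96 se` and the two-sided P value comes from `z = AP / se`.
#'
#' AP is never truncated: values below -1 are reported as estimated (they
#' arise when the doubly-exposed odds ratio in the denominator is small) and
#' flagged, since their magnitude resists quantitative interpretation.
#'
#' @param t a `pair_table`, normally after [recode_preventive()].
#' @return a list of class `additive_result`: `or01`, `or10`, `or11`,
#'   `reri`, `ap`, `ap_se`, `ap_ci`, `p.value`, `recoding`, and `flags`
#'   (`small_cell`: a zero cell, 0.5-corrected for the variance only;
#'   `ap_below_m1`: AP < -1).
#' @export
additive_fit <- function(t) {
  stopifnot(inherits(t, "pair_table"))
  if (t$degenerate) stop("degenerate table: empty case or control stratum")
  ca <- t$cases; co <- t$controls
  or <- function(i) (ca[i] * co[1L]) / (co[i] * ca[1L])
  or01 <- unname(or(2L)); or10 <- unname(or(3L)); or11 <- unname(or(4L))
  reri <- or11 - or01 - or10 + 1
  ap <- reri / or11
  small_cell <- any(c(ca, co) == 0)
  cc <- if (small_cell) 0.5 else 0
  cac <- ca + cc; coc <- co + cc             # corrected counts, variance only
  v <- 1 / cac + 1 / coc                     # per-cell logit variances
  # b1 = log OR10, b2 = log OR01, b3 = log(OR11/(OR10*OR01))
  V <- matrix(c(v[3L] + v[1L], v[1L],          -v[3L] - v[1L],
                v[1L],         v[2L] + v[1L],  -v[2L] - v[1L],
                -v[3L] - v[1L], -v[2L] - v[1L], sum(v)),
              3L, 3L, byrow = TRUE)
  # gradient evaluated at the corrected coefficients so it stays finite
  # alongside the corrected covariance when a cell is empty
  orc <- function(i) (cac[i] * coc[1L]) / (coc[i] * cac[1L])
  b1 <- log(orc(3L)); b2 <- log(orc(2L))
  b3 <- log(orc(4L)) - b1 - b2
  grad <- c(exp(-b1 - b3) - exp(-b1 - b2 - b3),
            exp(-b2 - b3) - exp(-b1 - b2 - b3),
            exp(-b2 - b3) + exp(-b1 - b3) - exp(-b1 - b2 - b3))
  ap_var <- drop(grad %*% V %*% grad)
  ap_se <- sqrt(ap_var)
  z <- ap / ap_se
  structure(list(or01 = or01, or10 = or10, or11 = or11, reri = reri,
                 ap = ap, ap_se = ap_se,
                 ap_ci = ap + c(-1, 1) * 1.96 * ap_se,
                 p.value = 2 * stats::pnorm(-abs(z)),
                 recoding = t$recoding,
                 flags = list(small_cell = small_cell,
                              ap_below_m1 = is.finite(ap) && ap < -1)),
            class = "additive_result")
}

#' @export
print.additive_result <- function(x, ...) {
  cat(sprintf(
    "additive interaction: AP = %.3f (95%% CI %.3f..%.3f), P = %.3g\n",
    x$ap, x$ap_ci[1L], x$ap_ci[2L], x$p.value))
  cat(sprintf("OR01 = %.3f, OR10 = %.3f, OR11 = %.3f, RERI = %.3f\n",
              x$or01, x$or10, x$or11, x$reri))
  invisible(x)
}

#' Convenience wrapper: table, recoding and additive fit for one pair
#'
#' @inheritParams build_pair_table
#' @return an `additive_result` (see [additive_fit()]).
#' @export
additive_test <- function(g, pair, coding = c("dominant", "recessive")) {
  additive_fit(recode_preventive(build_pair_table(g, pair, coding)))
}

#' Diagnostics for pathological (strongly negative) AP estimates
#'
#' Attributable-proportion estimates can fall below -1 when the
#' doubly-exposed odds ratio (AP's denominator) is small, typically in
#' tables with a sparse exposure cell. For each fitted pair this tabulates
#' the AP, the minimum cell count over the eight case/control cells, and the
#' smaller and larger of the two single-exposure odds ratios; it then
#' reports the Pearson correlation of AP with each of these, restricted to
#' pairs with AP < 0, together with the fraction of estimates below -1.
#'
#' @param fits list of `additive_result` objects.
#' @param tables list of the matching `pair_table` objects.
#' @return a list of class `ap_diagnostics`: `table` (per-pair
#'   `data.frame`), `cor_min_cell`, `cor_or_small`, `cor_or_large`
#'   (correlations with AP among AP < 0; `NA` when fewer than 3 such
#'   pairs), `frac_below_m1`.
#' @export
ap_diagnostics <- function(fits, tables) {
  stopifnot(length(fits) == length(tables), length(fits) >= 1L)
  rows <- mapply(function(f, t) {
    ors <- sort(c(f$or01, f$or10))
    data.frame(ap = f$ap,
               min_cell = min(c(t$cases, t$controls)),
               or_small = ors[1L], or_large = ors[2L])
  }, fits, tables, SIMPLIFY = FALSE)
  tab <- do.call(rbind, rows)
  neg <- tab[is.finite(tab$ap) & tab$ap < 0, , drop = FALSE]
  safe_cor <- function(x, y) {
    if (nrow(neg) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }
  structure(list(table = tab,
                 cor_min_cell = safe_cor(neg$ap, neg$min_cell),
                 cor_or_small = safe_cor(neg$ap, neg$or_small),
                 cor_or_large = safe_cor(neg$ap, neg$or_large),
                 frac_below_m1 = mean(tab$ap < -1, na.rm = TRUE)),
            class = "ap_diagnostics")
}
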