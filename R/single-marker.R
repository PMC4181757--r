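#' Cochran-Armitage trend test for a single marker
#'
#' Tests case-control association of a marker under an additive genotype
#' model, scoring dosages 0/1/2. Complete-case: samples with a missing
#' genotype at this marker are dropped. Also reports the allelic odds ratio
#' with a 95% Wald confidence interval from the 2 x 2 allele-count table
#' (0.5 continuity correction when a cell is empty).
#'
#' @param g a [genotype_data] object.
#' @param marker a `marker_id` in `g`.
#' @return a list of class `marker_assoc`: `marker_id`, `statistic`
#'   (chi-squared, 1 df), `p.value`, `or` (allelic), `ci`, `counts`
#'   (status x genotype), `degenerate` (statistic undefined; `p.value` then
#'   reported as 1).
#' @export
trend_test <- function(g, marker) {
  d <- g$dosages[, marker_index(g, marker)]
  ok <- !is.na(d)
  d <- d[ok]; y <- g$status[ok]
  counts <- matrix(0, 2L, 3L,
                   dimnames = list(c("control", "case"), c("0", "1", "2")))
  tab <- table(factor(y, levels = 0:1), factor(d, levels = 0:2))
  counts[] <- tab
  cases <- counts["case", ]
  totals <- colSums(counts)
  degenerate <- sum(totals > 0) < 2L || sum(cases) == 0L ||
    sum(counts["control", ]) == 0L
  if (degenerate) {
    stat <- NA_real_; p <- 1
  } else {
    tt <- suppressWarnings(
      stats::prop.trend.test(cases, totals, score = 0:2))
    stat <- unname(tt$statistic); p <- tt$p.value
    if (is.na(p)) { degenerate <- TRUE; p <- 1 }
  }
  # allelic 2x2: allele counts (minor, major) by status
  minor_ca <- sum(cases * 0:2)
  minor_co <- sum(counts["control", ] * 0:2)
  cells <- c(minor_ca, 2 * sum(cases) - minor_ca,
             minor_co, 2 * sum(counts["control", ]) - minor_co)
  cc <- if (any(cells == 0)) 0.5 else 0
  lor <- log((cells[1] + cc) * (cells[4] + cc) /
               ((cells[2] + cc) * (cells[3] + cc)))
  se <- sqrt(sum(1 / (cells + cc)))
  structure(list(marker_id = marker, statistic = stat, p.value = p,
                 or = exp(lor), ci = exp(lor + c(-1, 1) * 1.96 * se),
                 counts = counts, degenerate = degenerate),
            class = "marker_assoc")
}

#' Trend tests for every marker
#'
#' @param g a [genotype_data] object.
#' @return `data.frame` with one row per marker: `marker_id`, `statistic`,
#'   `p.value`, `or`, `degenerate`.
#' @export
assoc_scan <- function(g) {
  res <- lapply(g$markers$marker_id, function(m) {
    r <- trend_test(g, m)
    data.frame(marker_id = m, statistic = r$statistic, p.value = r$p.value,
               or = r$or, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Bonferroni family-wise threshold
#'
#' @param alpha family-wise error level.
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Two-cohort (or more) meta-analysis of allelic odds ratios
#'
#' Per-study log odds ratios and variances come from 2 x 2 allele-count
#' tables (rows case/control, columns minor/major allele; 0.5 continuity
#' correction applied to all cells of a table containing a zero, and
#' flagged). Heterogeneity is assessed with Woolf's inverse-variance Q test;
#' when its P value is at or above `het_alpha` the pooled odds ratio is the
#' Mantel-Haenszel fixed-effect estimate, otherwise the DerSimonian-Laird
#' random-effects estimate. The pooled P value is a two-sided Wald test on
#' the pooled log odds ratio.
#'
#' @param tables list of >= 2 numeric 2 x 2 matrices (case/control x
#'   minor/major allele counts).
#' @param het_alpha heterogeneity threshold for switching to random effects
#'   (default 0.05).
#' @return a list of class `meta_result`: `pooled_or`, `pooled_ci`,
#'   `pooled_p`, `study_or`, `woolf_q`, `woolf_p`, `method`
#'   (`"fixed"`/`"random"`), `continuity` flag.
#' @export
meta_analyze <- function(tables, het_alpha = 0.05) {
  stopifnot(length(tables) >= 2L)
  continuity <- FALSE
  lor <- vi <- numeric(length(tables))
  ai <- bi <- ci_ <- di <- numeric(length(tables))
  for (i in seq_along(tables)) {
    tb <- as.matrix(tables[[i]])
    stopifnot(identical(dim(tb), c(2L, 2L)))
    cc <- 0
    if (any(tb == 0)) { cc <- 0.5; continuity <- TRUE }
    a <- tb[1, 1] + cc; b <- tb[1, 2] + cc
    c2 <- tb[2, 1] + cc; d <- tb[2, 2] + cc
    lor[i] <- log(a * d / (b * c2))
    vi[i] <- 1 / a + 1 / b + 1 / c2 + 1 / d
    ai[i] <- tb[1, 1]; bi[i] <- tb[1, 2]; ci_[i] <- tb[2, 1]; di[i] <- tb[2, 2]
  }
  w <- 1 / vi
  lbar <- sum(w * lor) / sum(w)
  woolf_q <- sum(w * (lor - lbar)^2)
  woolf_p <- stats::pchisq(woolf_q, df = length(tables) - 1L,
                           lower.tail = FALSE)
  if (woolf_p >= het_alpha) {
    method <- "fixed"
    fit <- metafor::rma.mh(ai = ai, bi = bi, ci = ci_, di = di,
                           measure = "OR")
  } else {
    method <- "random"
    fit <- metafor::rma(yi = lor, vi = vi, method = "DL")
  }
  b <- as.numeric(fit$beta)
  se <- fit$se
  structure(list(pooled_or = exp(b),
                 pooled_ci = exp(b + c(-1, 1) * 1.96 * se),
                 pooled_p = 2 * stats::pnorm(-abs(b / se)),
                 study_or = exp(lor), woolf_q = woolf_q, woolf_p = woolf_p,
                 method = method, continuity = continuity),
            class = "meta_result")
}
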