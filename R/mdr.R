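#' Multifactor dimensionality reduction for marker combinations
#'
#' MDR collapses a multi-locus genotype into one binary attribute: every
#' joint-genotype cell is labelled high- or low-risk by comparing its
#' case:control ratio with the sample-wide ratio, and the resulting
#' classifier is scored by balanced accuracy. Missing genotypes form their
#' own category per marker (a 4 x 4 grid for a pair), so no samples are
#' dropped. Cells with cases but no controls are labelled high (their ratio
#' is infinite); entirely empty cells are labelled low.
#'
#' @name mdr
NULL

# per-sample joint-cell index for a combo: levels 0,1,2 plus 3 = missing
mdr_cell_index <- function(g, combo) {
  idx <- marker_index(g, combo)
  cell <- rep(0L, length(g$status))
  for (i in idx) {
    d <- g$dosages[, i]
    d[is.na(d)] <- 3L
    cell <- cell * 4L + d
  }
  cell + 1L
}

mdr_cell_counts <- function(cell, status, n_cells) {
  list(cases = tabulate(cell[status == 1L], n_cells),
       controls = tabulate(cell[status == 0L], n_cells))
}

mdr_labels_from_counts <- function(cases, controls, threshold) {
  (cases > 0 & controls == 0) | (controls > 0 & cases / controls >= threshold)
}

#' High/low risk labels for the joint-genotype cells of a combo
#'
#' @param g a [genotype_data] object.
#' @param combo character vector of 2 (or 3) marker ids.
#' @param train optional logical/integer vector selecting the training
#'   samples (default: all). Must contain at least one case and one control.
#' @return logical vector over the `4^order` joint cells (`TRUE` = high
#'   risk), ordered with marker 1's category varying slowest; categories per
#'   marker are dosage 0, 1, 2, missing.
#' @export
mdr_label <- function(g, combo, train = NULL) {
  cell <- mdr_cell_index(g, combo)
  status <- g$status
  if (!is.null(train)) { cell <- cell[train]; status <- status[train] }
  if (sum(status == 1L) < 1L || sum(status == 0L) < 1L)
    stop("training data must contain at least one case and one control")
  n_cells <- 4L^length(combo)
  cnt <- mdr_cell_counts(cell, status, n_cells)
  thr <- sum(status == 1L) / sum(status == 0L)
  mdr_labels_from_counts(cnt$cases, cnt$controls, thr)
}

#' Classification metrics from high/low risk group counts
#'
#' Computes the MDR summary statistics from the 2 x 2 classification table:
#' balanced accuracy `(TPR + 1 - FPR) / 2`, the high/low odds ratio
#' `(hc * ln) / (lc * hn)` with a 95% Wald interval on the log scale (0.5
#' continuity correction when a cell is zero, flagged), a Pearson chi-square
#' P value, the true positive rate (sensitivity) and the false positive
#' rate (1 - specificity).
#'
#' @param high_cases,high_controls,low_cases,low_controls counts of cases
#'   and controls classified high and low risk.
#' @return list with `ba`, `or`, `or_ci`, `p.value`, `tpr`, `fpr`, `high`,
#'   `low`, `continuity`.
#' @export
mdr_classification_metrics <- function(high_cases, high_controls,
                                       low_cases, low_controls) {
  n_cases <- high_cases + low_cases
  n_controls <- high_controls + low_controls
  tpr <- high_cases / n_cases
  fpr <- high_controls / n_controls
  ba <- (tpr + 1 - fpr) / 2
  cells <- c(high_cases, high_controls, low_cases, low_controls)
  cc <- if (any(cells == 0)) 0.5 else 0
  lor <- log((high_cases + cc) * (low_controls + cc) /
               ((low_cases + cc) * (high_controls + cc)))
  se <- sqrt(sum(1 / (cells + cc)))
  tab <- matrix(cells, 2L, 2L)                # rows high/low, cols case/ctrl
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  list(ba = ba, or = exp(lor), or_ci = exp(lor + c(-1, 1) * 1.96 * se),
       p.value = p, tpr = tpr, fpr = fpr,
       high = c(cases = high_cases, controls = high_controls),
       low = c(cases = low_cases, controls = low_controls),
       continuity = cc > 0)
}

# stratified fold assignment: within each status, folds as equal as possible
mdr_folds <- function(status, k_folds, seed) {
  set.seed(seed)
  fold <- integer(length(status))
  for (s in c(1L, 0L)) {
    idx <- which(status == s)
    fold[idx] <- sample(rep(seq_len(k_folds), length.out = length(idx)))
  }
  fold
}

#' Evaluate one marker combination with MDR
#'
#' Full-data cell labels give the reported classification metrics (balanced
#' accuracy, odds ratio, chi-square P, TPR, FPR); stratified k-fold
#' cross-validation gives the mean testing balanced accuracy. Fold
#' construction depends only on `seed`.
#'
#' @param g a [genotype_data] object.
#' @param combo character vector of 2 (or 3) marker ids.
#' @param k_folds number of cross-validation folds (default 10).
#' @param seed seed for fold assignment.
#' @return a list of class `mdr_model`: `combo`, `labels` (full-data),
#'   `ba_full`, `ba_cv`, `ba_cv_folds`, classification metrics as in
#'   [mdr_classification_metrics()], and `threshold` (the full-data
#'   case:control ratio).
#' @export
mdr_evaluate <- function(g, combo, k_folds = 10L, seed = 1L) {
  cell <- mdr_cell_index(g, combo)
  status <- g$status
  n_cells <- 4L^length(combo)
  cnt <- mdr_cell_counts(cell, status, n_cells)
  thr <- sum(status == 1L) / sum(status == 0L)
  labels <- mdr_labels_from_counts(cnt$cases, cnt$controls, thr)
  met <- mdr_classification_metrics(sum(cnt$cases[labels]),
                                    sum(cnt$controls[labels]),
                                    sum(cnt$cases[!labels]),
                                    sum(cnt$controls[!labels]))
  fold <- mdr_folds(status, k_folds, seed)
  ba_cv <- vapply(seq_len(k_folds), function(f) {
    tr <- fold != f
    cnt_tr <- mdr_cell_counts(cell[tr], status[tr], n_cells)
    thr_tr <- sum(status[tr] == 1L) / max(1L, sum(status[tr] == 0L))
    lab <- mdr_labels_from_counts(cnt_tr$cases, cnt_tr$controls, thr_tr)
    cnt_te <- mdr_cell_counts(cell[!tr], status[!tr], n_cells)
    tpr <- sum(cnt_te$cases[lab]) / max(1, sum(cnt_te$cases))
    fpr <- sum(cnt_te$controls[lab]) / max(1, sum(cnt_te$controls))
    (tpr + 1 - fpr) / 2
  }, numeric(1L))
  structure(c(list(combo = combo, labels = labels,
                   ba_full = met$ba, ba_cv = mean(ba_cv),
                   ba_cv_folds = ba_cv, threshold = thr),
              met[c("or", "or_ci", "p.value", "tpr", "fpr", "high", "low",
                    "continuity")]),
            class = "mdr_model")
}

#' @export
print.mdr_model <- function(x, ...) {
  cat("MDR model:", paste(x$combo, collapse = " x "), "\n")
  cat(sprintf("BA(full) = %.4f, BA(cv) = %.4f, OR = %.2f, P = %.3g\n",
              x$ba_full, x$ba_cv, x$or, x$p.value))
  cat(sprintf("high %d/%d, low %d/%d, TPR %.3f, FPR %.3f\n",
              x$high[1L], x$high[2L], x$low[1L], x$low[2L], x$tpr, x$fpr))
  invisible(x)
}

# level indicator matrices (n x m) for dosage levels 0..2 and missing
mdr_level_indicators <- function(dosages) {
  lapply(0:3, function(u) {
    d <- dosages
    d[is.na(d)] <- 3L
    (d == u) * 1
  })
}

#' Exhaustive MDR scan over marker combinations
#'
#' Evaluates every unordered combination of `order` markers, ranks by mean
#' testing balanced accuracy (ties broken by full-data balanced accuracy,
#' then by combination order), and reports the cross-validation consistency
#' (CVC): the number of folds in which a combination attains the best
#' *training* balanced accuracy. The 2-way scan is vectorised over all
#' pairs; the 3-way scan loops and is intended for modest marker counts.
#'
#' @param g a [genotype_data] object.
#' @param order 2 or 3.
#' @param k_folds cross-validation folds (default 10).
#' @param seed seed for fold assignment.
#' @return a `data.frame` of class `mdr_scan_result` with columns `marker1`,
#'   `marker2` (and `marker3` for order 3), `ba_cv`, `ba_full`, `cvc`, `or`,
#'   `p.value`, `tpr`, `fpr`, sorted best-first; attribute `n_tests` holds
#'   the number of combinations evaluated.
#' @export
mdr_scan <- function(g, order = 2L, k_folds = 10L, seed = 1L) {
  stopifnot(order %in% c(2L, 3L))
  m <- nrow(g$markers)
  stopifnot(m >= order)
  if (order == 3L) return(mdr_scan_loop(g, 3L, k_folds, seed))
  status <- g$status
  fold <- mdr_folds(status, k_folds, seed)
  pairs <- utils::combn(m, 2L)
  i <- pairs[1L, ]; j <- pairs[2L, ]
  np <- ncol(pairs)
  ind <- mdr_level_indicators(g$dosages)

  pair_counts <- function(rows) {
    # 16 x np case and control counts for all pairs restricted to `rows`
    out <- list(cases = matrix(0, 16L, np), controls = matrix(0, 16L, np))
    for (s in c(1L, 0L)) {
      sel <- rows & (status == s)
      tgt <- if (s == 1L) "cases" else "controls"
      for (u in 0:3) {
        Au <- ind[[u + 1L]][sel, , drop = FALSE]
        for (v in 0:3) {
          Cuv <- crossprod(Au, ind[[v + 1L]][sel, , drop = FALSE])
          out[[tgt]][4L * u + v + 1L, ] <- Cuv[cbind(i, j)]
        }
      }
    }
    out
  }
  ba_from <- function(cnt, labels) {
    tot_ca <- colSums(cnt$cases); tot_co <- colSums(cnt$controls)
    tpr <- colSums(cnt$cases * labels) / pmax(1, tot_ca)
    fpr <- colSums(cnt$controls * labels) / pmax(1, tot_co)
    list(ba = (tpr + 1 - fpr) / 2, tpr = tpr, fpr = fpr)
  }
  all_rows <- rep(TRUE, length(status))
  cnt_full <- pair_counts(all_rows)
  thr <- sum(status == 1L) / sum(status == 0L)
  lab_full <- mdr_labels_from_counts(cnt_full$cases, cnt_full$controls, thr)
  full <- ba_from(cnt_full, lab_full)
  hc <- colSums(cnt_full$cases * lab_full)
  hn <- colSums(cnt_full$controls * lab_full)
  lc <- colSums(cnt_full$cases) - hc
  ln <- colSums(cnt_full$controls) - hn
  cc <- ifelse(hc == 0 | hn == 0 | lc == 0 | ln == 0, 0.5, 0)
  or <- (hc + cc) * (ln + cc) / ((lc + cc) * (hn + cc))
  ntot <- hc + hn + lc + ln
  chi <- ntot * (hc * ln - lc * hn)^2 /
    pmax(1, (hc + hn) * (lc + ln) * (hc + lc) * (hn + ln))
  p <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)

  ba_cv <- matrix(0, np, k_folds)
  cvc <- integer(np)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    cnt_tr <- pair_counts(tr)
    thr_tr <- sum(status[tr] == 1L) / max(1L, sum(status[tr] == 0L))
    lab_tr <- mdr_labels_from_counts(cnt_tr$cases, cnt_tr$controls, thr_tr)
    ba_tr <- ba_from(cnt_tr, lab_tr)$ba
    cnt_te <- pair_counts(!tr)
    ba_cv[, f] <- ba_from(cnt_te, lab_tr)$ba
    best <- which.max(ba_tr)              # ties -> first, i.e. lexicographic
    cvc[best] <- cvc[best] + 1L
  }
  res <- data.frame(marker1 = g$markers$marker_id[i],
                    marker2 = g$markers$marker_id[j],
                    ba_cv = rowMeans(ba_cv), ba_full = full$ba, cvc = cvc,
                    or = or, p.value = p, tpr = full$tpr, fpr = full$fpr,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$ba_cv, -res$ba_full, res$marker1, res$marker2), ]
  rownames(res) <- NULL
  attr(res, "n_tests") <- np
  class(res) <- c("mdr_scan_result", class(res))
  res
}

mdr_scan_loop <- function(g, order, k_folds, seed) {
  m <- nrow(g$markers)
  combos <- utils::combn(m, order)
  status <- g$status
  fold <- mdr_folds(status, k_folds, seed)
  n_cells <- 4L^order
  nc <- ncol(combos)
  ba_full <- ba_cv <- or <- p <- tpr <- fpr <- numeric(nc)
  ba_tr_fold <- matrix(0, nc, k_folds)
  thr <- sum(status == 1L) / sum(status == 0L)
  for (k in seq_len(nc)) {
    combo <- g$markers$marker_id[combos[, k]]
    cell <- mdr_cell_index(g, combo)
    cnt <- mdr_cell_counts(cell, status, n_cells)
    lab <- mdr_labels_from_counts(cnt$cases, cnt$controls, thr)
    met <- mdr_classification_metrics(sum(cnt$cases[lab]),
                                      sum(cnt$controls[lab]),
                                      sum(cnt$cases[!lab]),
                                      sum(cnt$controls[!lab]))
    ba_full[k] <- met$ba; or[k] <- met$or; p[k] <- met$p.value
    tpr[k] <- met$tpr; fpr[k] <- met$fpr
    bas <- numeric(k_folds)
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      cnt_tr <- mdr_cell_counts(cell[tr], status[tr], n_cells)
      thr_tr <- sum(status[tr] == 1L) / max(1L, sum(status[tr] == 0L))
      lab_tr <- mdr_labels_from_counts(cnt_tr$cases, cnt_tr$controls, thr_tr)
      tpr_tr <- sum(cnt_tr$cases[lab_tr]) / max(1, sum(cnt_tr$cases))
      fpr_tr <- sum(cnt_tr$controls[lab_tr]) / max(1, sum(cnt_tr$controls))
      ba_tr_fold[k, f] <- (tpr_tr + 1 - fpr_tr) / 2
      cnt_te <- mdr_cell_counts(cell[!tr], status[!tr], n_cells)
      tpr_te <- sum(cnt_te$cases[lab_tr]) / max(1, sum(cnt_te$cases))
      fpr_te <- sum(cnt_te$controls[lab_tr]) / max(1, sum(cnt_te$controls))
      bas[f] <- (tpr_te + 1 - fpr_te) / 2
    }
    ba_cv[k] <- mean(bas)
  }
  cvc <- integer(nc)
  for (f in seq_len(k_folds)) {
    best <- which.max(ba_tr_fold[, f])
    cvc[best] <- cvc[best] + 1L
  }
  ids <- matrix(g$markers$marker_id[combos], nrow = order)
  res <- data.frame(marker1 = ids[1L, ], marker2 = ids[2L, ],
                    marker3 = ids[3L, ], ba_cv = ba_cv, ba_full = ba_full,
                    cvc = cvc, or = or, p.value = p, tpr = tpr, fpr = fpr,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$ba_cv, -res$ba_full, res$marker1, res$marker2,
                   res$marker3), ]
  rownames(res) <- NULL
  attr(res, "n_tests") <- nc
  class(res) <- c("mdr_scan_result", class(res))
  res
}
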