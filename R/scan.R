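#' ReliefF relevance scores for markers
#'
#' Feature-relevance filter used to prioritise markers that show no
#' marginal effect but carry predictive dependencies: for each sampled
#' instance the `n_neighbors` nearest same-class (hits) and other-class
#' (misses) neighbours are found under a genotype distance (mean absolute
#' dosage difference scaled to [0, 1]; a comparison involving a missing
#' genotype contributes 0.5), and each marker's weight is decreased by its
#' mean difference to hits and increased by its mean difference to misses.
#'
#' @param g a [genotype_data] object.
#' @param n_neighbors neighbours per class (default 10).
#' @param sample_size instances to sample (default: all, capped at 200).
#' @param seed RNG seed for the instance sample.
#' @return named numeric vector of weights (one per marker, higher = more
#'   relevant).
#' @export
relieff_scores <- function(g, n_neighbors = 10L, sample_size = NULL,
                           seed = 1L) {
  d <- g$dosages / 2                      # scale dosage differences to [0,1]
  n <- nrow(d); m <- ncol(d)
  set.seed(seed)
  if (is.null(sample_size)) sample_size <- min(n, 200L)
  pick <- sample.int(n, min(sample_size, n))
  w <- numeric(m)
  for (r in pick) {
    diff <- abs(d - matrix(d[r, ], n, m, byrow = TRUE))
    diff[is.na(diff)] <- 0.5
    dist <- rowMeans(diff)
    dist[r] <- Inf
    same <- g$status == g$status[r]
    hits <- order(ifelse(same, dist, Inf))[seq_len(min(n_neighbors,
                                                       sum(same) - 1L))]
    miss <- order(ifelse(same, Inf, dist))[seq_len(min(n_neighbors,
                                                       sum(!same)))]
    w <- w - colSums(diff[hits, , drop = FALSE]) / length(hits) +
      colSums(diff[miss, , drop = FALSE]) / length(miss)
  }
  stats::setNames(w / length(pick), g$markers$marker_id)
}

#' Select seed markers for the pairwise interaction scan
#'
#' Seeds are the union of (A) markers with a single-marker trend-test
#' P value below `p_threshold` and (B) the `n_filter` markers with the
#' highest ReliefF relevance among those *not* in A — capturing markers
#' whose contribution is expected only through dependencies.
#'
#' @param g a [genotype_data] object.
#' @param p_threshold main-effect threshold (default 0.05).
#' @param n_filter how many no-main-effect markers to add by ReliefF score.
#' @param assoc optional precomputed [assoc_scan()] result.
#' @param ... passed to [relieff_scores()].
#' @return a list of class `seed_marker_set`: `main_effect`, `filtered`
#'   (disjoint character vectors of marker ids) and `seeds` (their union).
#' @export
prioritize <- function(g, p_threshold = 0.05, n_filter = 0L, assoc = NULL,
                       ...) {
  if (is.null(assoc)) assoc <- assoc_scan(g)
  main <- assoc$marker_id[!assoc$degenerate & assoc$p.value < p_threshold]
  rest <- setdiff(g$markers$marker_id, main)
  filtered <- character(0)
  if (n_filter > 0L && length(rest) > 0L) {
    if (n_filter > length(rest)) {
      warning("n_filter (", n_filter, ") exceeds available markers (",
              length(rest), "); truncated")
      n_filter <- length(rest)
    }
    w <- relieff_scores(g, ...)[rest]
    filtered <- names(sort(w, decreasing = TRUE))[seq_len(n_filter)]
  }
  structure(list(main_effect = main, filtered = filtered,
                 seeds = union(main, filtered)),
            class = "seed_marker_set")
}

#' @export
print.seed_marker_set <- function(x, ...) {
  cat("seed markers:", length(x$seeds), "(", length(x$main_effect),
      "main-effect +", length(x$filtered), "filter-selected )\n")
  invisible(x)
}

#' Enumerate marker pairs for a scan
#'
#' `mode = "seeds_x_all"` streams every (seed, marker) combination —
#' `length(seeds) * n_markers` evaluations, the bookkeeping count a
#' seed-against-all design reports — and deduplicates to unique unordered
#' non-self pairs for ranking. `mode = "exhaustive"` enumerates all
#' `choose(n, 2)` unordered pairs.
#'
#' @param g a [genotype_data] object.
#' @param seeds character vector of seed marker ids (or a
#'   `seed_marker_set`); required for `seeds_x_all`.
#' @param mode `"seeds_x_all"` or `"exhaustive"`.
#' @return a list of class `pair_enumeration`: `pairs` (2 x K integer
#'   matrix of marker column indices, unique unordered), `n_evaluations`
#'   (raw stream size), `n_unique` (= K), `mode`.
#' @export
enumerate_pairs <- function(g, seeds = NULL,
                            mode = c("seeds_x_all", "exhaustive")) {
  mode <- match.arg(mode)
  m <- nrow(g$markers)
  if (mode == "exhaustive") {
    pairs <- utils::combn(m, 2L)
    n_eval <- ncol(pairs)
  } else {
    if (inherits(seeds, "seed_marker_set")) seeds <- seeds$seeds
    stopifnot(length(seeds) >= 1L)
    si <- marker_index(g, seeds)
    n_eval <- length(si) * m
    grid <- cbind(rep(si, each = m), rep(seq_len(m), length(si)))
    grid <- grid[grid[, 1L] != grid[, 2L], , drop = FALSE]
    key <- paste(pmin(grid[, 1L], grid[, 2L]),
                 pmax(grid[, 1L], grid[, 2L]))
    grid <- grid[!duplicated(key), , drop = FALSE]
    pairs <- rbind(pmin(grid[, 1L], grid[, 2L]),
                   pmax(grid[, 1L], grid[, 2L]))
  }
  structure(list(pairs = pairs, n_evaluations = n_eval,
                 n_unique = ncol(pairs), mode = mode),
            class = "pair_enumeration")
}

# 8 joint-exposure cell counts for many pairs at once via indicator
# cross-products. Returns K x 4 case and control count matrices (cells
# 00, 01, 10, 11; first index = first row of `pairs`).
pair_cell_counts <- function(E, status, pairs) {
  i <- pairs[1L, ]; j <- pairs[2L, ]
  E1 <- (E == 1L); E1[is.na(E1)] <- FALSE
  E0 <- (E == 0L); E0[is.na(E0)] <- FALSE
  ui <- sort(unique(i)); uj <- sort(unique(j))
  ri <- match(i, ui); rj <- match(j, uj)
  out <- list()
  for (s in c(1L, 0L)) {
    sel <- status == s
    A0 <- E0[sel, ui, drop = FALSE] * 1; A1 <- E1[sel, ui, drop = FALSE] * 1
    B0 <- E0[sel, uj, drop = FALSE] * 1; B1 <- E1[sel, uj, drop = FALSE] * 1
    cnt <- cbind(crossprod(A0, B0)[cbind(ri, rj)],
                 crossprod(A0, B1)[cbind(ri, rj)],
                 crossprod(A1, B0)[cbind(ri, rj)],
                 crossprod(A1, B1)[cbind(ri, rj)])
    colnames(cnt) <- c("00", "01", "10", "11")
    out[[if (s == 1L) "cases" else "controls"]] <- cnt
  }
  out
}

# vectorised preventive-factor recoding over K pairs: the cell with the
# lowest case:control odds becomes the new reference (ties broken by the
# fixed preference order), exactly as recode_preventive does per table
recode_counts <- function(CA, CO) {
  K <- nrow(CA)
  odds <- CA / CO
  odds[CA == 0 & CO == 0] <- Inf          # empty cell: never the reference
  ref <- rep(1L, K)
  for (cell in reference_preference) {
    upd <- odds[, cell] < odds[cbind(seq_len(K), ref)]
    ref[upd] <- cell
  }
  chosen <- scheme_for_cell[ref]
  outCA <- CA; outCO <- CO
  for (s in names(recoding_schemes)) {
    rows <- chosen == s
    if (s == "identity" || !any(rows)) next
    perm <- recoding_schemes[[s]]
    outCA[rows, ] <- CA[rows, perm, drop = FALSE]
    outCO[rows, ] <- CO[rows, perm, drop = FALSE]
  }
  or01 <- outCA[, 2L] * outCO[, 1L] / (outCO[, 2L] * outCA[, 1L])
  or10 <- outCA[, 3L] * outCO[, 1L] / (outCO[, 3L] * outCA[, 1L])
  failed <- is.na(or01) | is.na(or10) | or01 < 1 | or10 < 1
  list(cases = outCA, controls = outCO, recoding = chosen, failed = failed)
}

# closed-form additive statistics for K pairs (rows of CA/CO already
# recoded). Zero cells get a 0.5 correction for the variance only.
additive_stats_vec <- function(CA, CO) {
  or01 <- CA[, 2L] * CO[, 1L] / (CO[, 2L] * CA[, 1L])
  or10 <- CA[, 3L] * CO[, 1L] / (CO[, 3L] * CA[, 1L])
  or11 <- CA[, 4L] * CO[, 1L] / (CO[, 4L] * CA[, 1L])
  reri <- or11 - or01 - or10 + 1
  ap <- reri / or11
  zero <- rowSums(CA == 0 | CO == 0) > 0
  cc <- ifelse(zero, 0.5, 0)
  CAc <- CA + cc; COc <- CO + cc            # corrected, variance path only
  v <- 1 / CAc + 1 / COc
  # coefficients for the delta-method gradient from the corrected counts,
  # matching additive_fit's handling of empty cells
  oc <- function(i) CAc[, i] * COc[, 1L] / (COc[, i] * CAc[, 1L])
  b1 <- log(oc(3L)); b2 <- log(oc(2L)); b3 <- log(oc(4L)) - b1 - b2
  g1 <- exp(-b1 - b3) - exp(-b1 - b2 - b3)
  g2 <- exp(-b2 - b3) - exp(-b1 - b2 - b3)
  g3 <- exp(-b2 - b3) + exp(-b1 - b3) - exp(-b1 - b2 - b3)
  v00 <- v[, 1L]; v01 <- v[, 2L]; v10 <- v[, 3L]; v11 <- v[, 4L]
  V11 <- v10 + v00; V22 <- v01 + v00; V33 <- v11 + v10 + v01 + v00
  V12 <- v00; V13 <- -v10 - v00; V23 <- -v01 - v00
  ap_var <- g1^2 * V11 + g2^2 * V22 + g3^2 * V33 +
    2 * (g1 * g2 * V12 + g1 * g3 * V13 + g2 * g3 * V23)
  se <- sqrt(ap_var)
  z <- ap / se
  list(estimate = ap, se = se, statistic = abs(z),
       p.value = 2 * stats::pnorm(-abs(z)), reri = reri,
       or01 = or01, or10 = or10, or11 = or11, small_cell = zero)
}

# closed-form multiplicative statistics for K pairs
multiplicative_stats_vec <- function(CA, CO) {
  zero <- rowSums(CA == 0 | CO == 0) > 0
  cc <- ifelse(zero, 0.5, 0)
  ca <- CA + cc; co <- CO + cc
  b3 <- log(ca[, 4L] * co[, 4L]^-1) - log(ca[, 3L] / co[, 3L]) -
    log(ca[, 2L] / co[, 2L]) + log(ca[, 1L] / co[, 1L])
  se <- sqrt(rowSums(1 / ca) + rowSums(1 / co))
  z <- b3 / se
  list(estimate = exp(b3), se = se, statistic = abs(z),
       p.value = 2 * stats::pnorm(-abs(z)), small_cell = zero)
}

#' Pairwise interaction scan on the additive or multiplicative scale
#'
#' Computes the per-pair interaction statistic for every enumerated pair
#' using closed-form count arithmetic (identical to the saturated logistic
#' fits of [additive_fit()] / [multiplicative_fit()] on all-positive
#' tables, and continuity-corrected otherwise). Additive-scale pairs are
#' first passed through the preventive-factor recoding. Results are sorted
#' by P value.
#'
#' @param g a [genotype_data] object.
#' @param method `"additive"` or `"multiplicative"` (for MDR use
#'   [mdr_scan()]).
#' @param coding `"dominant"` or `"recessive"`.
#' @param pairs a `pair_enumeration`, a 2 x K index matrix, or `NULL` for
#'   the exhaustive scan.
#' @param status optional status override (used by the permutation engine).
#' @return a `data.frame` of class `scan_result`: `marker1`, `marker2`,
#'   `estimate` (AP or interaction OR), `statistic` (|z|), `p.value`,
#'   cell counts `ca00..co11`, `recoding` (additive only), `small_cell`;
#'   attributes `method`, `coding`, `n_tests` (raw evaluation count) and
#'   `n_unique`.
#' @export
scan_pairs <- function(g, method = c("additive", "multiplicative"),
                       coding = c("dominant", "recessive"), pairs = NULL,
                       status = NULL) {
  method <- match.arg(method)
  coding <- match.arg(coding)
  if (is.null(pairs)) pairs <- enumerate_pairs(g, mode = "exhaustive")
  if (inherits(pairs, "pair_enumeration")) {
    n_eval <- pairs$n_evaluations
    pairs <- pairs$pairs
  } else {
    pairs <- as.matrix(pairs)
    n_eval <- ncol(pairs)
  }
  if (is.null(status)) status <- g$status
  E <- matrix(code_dosage(g$dosages, coding), nrow(g$dosages))
  cnt <- pair_cell_counts(E, status, pairs)
  CA <- cnt$cases; CO <- cnt$controls
  recoding <- rep("identity", ncol(pairs))
  if (method == "additive") {
    rc <- recode_counts(CA, CO)
    CA <- rc$cases; CO <- rc$controls; recoding <- rc$recoding
    st <- additive_stats_vec(CA, CO)
  } else {
    st <- multiplicative_stats_vec(CA, CO)
  }
  res <- data.frame(marker1 = g$markers$marker_id[pairs[1L, ]],
                    marker2 = g$markers$marker_id[pairs[2L, ]],
                    estimate = st$estimate, statistic = st$statistic,
                    p.value = st$p.value,
                    ca00 = CA[, 1L], ca01 = CA[, 2L], ca10 = CA[, 3L],
                    ca11 = CA[, 4L],
                    co00 = CO[, 1L], co01 = CO[, 2L], co10 = CO[, 3L],
                    co11 = CO[, 4L],
                    recoding = recoding, small_cell = st$small_cell,
                    stringsAsFactors = FALSE)
  ord <- order(res$p.value, -res$statistic, res$marker1, res$marker2)
  res <- res[ord, ]
  rownames(res) <- NULL
  attr(res, "method") <- paste0(method, "_",
                                substr(coding, 1L, 3L))
  attr(res, "coding") <- coding
  attr(res, "n_tests") <- n_eval
  attr(res, "n_unique") <- ncol(pairs)
  class(res) <- c("scan_result", class(res))
  res
}

scan_statistic <- function(scan) {
  if (inherits(scan, "mdr_scan_result")) scan$ba_cv else scan$statistic
}

#' Permutation-based family-wise error correction for a scan
#'
#' Re-runs the scan `B` times with case/control labels permuted, recording
#' the best statistic of each permuted scan (the max-statistic method). The
#' permutation-adjusted P value of an observed record is
#' `(1 + #\{permutation best >= observed\}) / (B + 1)` and the family-wise
#' 5% significance threshold is the 95th percentile of the permutation-best
#' distribution.
#'
#' @param g a [genotype_data] object.
#' @param method `"additive"`, `"multiplicative"` or `"mdr"`.
#' @param coding exposure coding (ignored for `"mdr"`).
#' @param pairs pair set for the regression scans (see [scan_pairs()]).
#' @param B number of permutations (>= 1).
#' @param seed RNG seed for the permutations.
#' @param k_folds folds for the MDR scan.
#' @return a list of class `permutation_result`: `scan` (observed, with a
#'   `permuted_p` column appended), `perm_best` (length-B vector),
#'   `threshold` (95th percentile of `perm_best`), `B`.
#' @export
permute_fwer <- function(g, method = c("additive", "multiplicative", "mdr"),
                         coding = c("dominant", "recessive"), pairs = NULL,
                         B = 1000L, seed = 1L, k_folds = 10L) {
  method <- match.arg(method)
  coding <- match.arg(coding)
  stopifnot(B >= 1L)
  run <- function(status) {
    if (method == "mdr") {
      gg <- g; gg$status <- status
      mdr_scan(gg, order = 2L, k_folds = k_folds, seed = seed)
    } else {
      scan_pairs(g, method, coding, pairs, status = status)
    }
  }
  obs <- run(g$status)
  obs_stat <- scan_statistic(obs)
  set.seed(seed)
  perm_best <- vapply(seq_len(B), function(b) {
    max(scan_statistic(run(sample(g$status))), na.rm = TRUE)
  }, numeric(1L))
  obs$permuted_p <- vapply(obs_stat, function(s) {
    (1 + sum(perm_best >= s)) / (B + 1)
  }, numeric(1L))
  structure(list(scan = obs,
                 perm_best = perm_best,
                 threshold = stats::quantile(perm_best, 0.95, names = FALSE),
                 B = B),
            class = "permutation_result")
}

#' Best fraction of a ranked scan
#'
#' @param scan a `scan_result` or `mdr_scan_result` (already ranked
#'   best-first).
#' @param q fraction in (0, 1]; the best `ceiling(q * n_tests)` records are
#'   returned, where `n_tests` is the scan's raw evaluation count.
#' @return the subset of rows.
#' @export
top_fraction <- function(scan, q) {
  stopifnot(q > 0, q <= 1)
  n <- ceiling(q * attr(scan, "n_tests"))
  utils::head(scan, max(1L, min(n, nrow(scan))))
}

#' Correlate interaction statistics of two methods
#'
#' Selects the top fraction `q` of scan `a`, joins on unordered marker-pair
#' keys present in scan `b`, and computes the Pearson correlation between
#' the transformed statistics (`-log10(P)` for regression scans, balanced
#' accuracy for MDR).
#'
#' @param a,b scan results (`scan_result` or `mdr_scan_result`).
#' @param q fraction of `a` to select (default 0.005).
#' @return a list of class `method_correlation`: `r`, `p.value`, `n_joined`
#'   and the joined `table`; `r` is `NA` with a warning when fewer than 3
#'   pairs join.
#' @export
correlate_methods <- function(a, b, q = 0.005) {
  transform_stat <- function(s) {
    if (inherits(s, "mdr_scan_result")) s$ba_cv else -log10(s$p.value)
  }
  key <- function(s) paste(pmin(s$marker1, s$marker2),
                           pmax(s$marker1, s$marker2))
  ta <- top_fraction(a, q)
  ka <- key(ta); kb <- key(b)
  idx <- match(ka, kb)
  ok <- !is.na(idx)
  tab <- data.frame(pair = ka[ok], stat_a = transform_stat(ta)[ok],
                    stat_b = transform_stat(b)[idx[ok]],
                    stringsAsFactors = FALSE)
  if (nrow(tab) < 3L) {
    warning("fewer than 3 joined pairs; correlation undefined")
    return(structure(list(r = NA_real_, p.value = NA_real_,
                          n_joined = nrow(tab), table = tab),
                     class = "method_correlation"))
  }
  ct <- stats::cor.test(tab$stat_a, tab$stat_b)
  structure(list(r = unname(ct$estimate), p.value = ct$p.value,
                 n_joined = nrow(tab), table = tab),
            class = "method_correlation")
}
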