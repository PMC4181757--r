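test_that("cell labelling follows the case:control ratio threshold", {
  # balanced training data: threshold T = 1
  dos <- cbind(rsA = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
               rsB = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  g <- genotype_data(dos, c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L))
  lab <- mdr_label(g, c("rsA", "rsB"))
  # cell (0,0): 3 cases / 1 control -> high; cell (1,0): 1/3 -> low
  expect_true(lab[1L])            # dosages (0,0)
  expect_false(lab[4L * 1L + 0L + 1L])   # dosages (1,0)
  # empty cells are low
  expect_false(any(lab[-c(1L, 5L)]))
})

test_that("uniform case:control ratios give an uninformative classifier", {
  # one case and one control in every joint-genotype cell
  dos <- cbind(rsA = rep(0:2, each = 6L),
               rsB = rep(rep(0:2, each = 2L), 3L))
  g <- genotype_data(dos, rep(c(1L, 0L), 9L))
  m <- mdr_evaluate(g, c("rsA", "rsB"), k_folds = 2L)
  expect_equal(m$ba_full, 0.5)
})

test_that("labels agree with brute-force per-cell counting", {
  g <- null_sim(n = 120L, m = 3L, seed = 77L, missing_rate = 0.1)
  combo <- g$markers$marker_id[1:2]
  lab <- mdr_label(g, combo)
  d1 <- g$dosages[, combo[1L]]; d1[is.na(d1)] <- 3L
  d2 <- g$dosages[, combo[2L]]; d2[is.na(d2)] <- 3L
  thr <- sum(g$status == 1L) / sum(g$status == 0L)
  for (u in 0:3) for (v in 0:3) {
    ca <- sum(d1 == u & d2 == v & g$status == 1L)
    co <- sum(d1 == u & d2 == v & g$status == 0L)
    expected <- if (ca == 0 && co == 0) FALSE
    else if (co == 0) ca > 0
    else ca / co >= thr
    expect_identical(unname(lab[4L * u + v + 1L]), expected)
  }
})

test_that("published MDR classification metrics are reproduced from counts", {
  m <- mdr_classification_metrics(907, 751, 825, 1032)
  expect_equal(round(m$ba, 4), 0.5512)        # printed table rounds to 0.5513
  expect_equal(round(m$or, 2), 1.51)
  expect_equal(round(m$tpr, 3), 0.524)
  expect_equal(round(m$fpr, 3), 0.421)
  expect_equal(signif(m$p.value, 3), 1.17e-9)
  expect_equal(round(m$or_ci, 2), c(1.32, 1.73), tolerance = 0.01)
})

test_that("balanced accuracy equals (TPR + 1 - FPR) / 2 identically", {
  set.seed(83)
  for (i in 1:20) {
    cnt <- sample.int(500, 4L)
    m <- mdr_classification_metrics(cnt[1L], cnt[2L], cnt[3L], cnt[4L])
    expect_equal(m$ba, (m$tpr + 1 - m$fpr) / 2, tolerance = 1e-12)
  }
})

test_that("a perfectly separating pair attains BA 1, TPR 1, FPR 0", {
  dos <- cbind(rsA = rep(c(2L, 0L), each = 10L),
               rsB = rep(c(2L, 0L), each = 10L))
  g <- genotype_data(dos, rep(c(1L, 0L), each = 10L))
  m <- mdr_evaluate(g, c("rsA", "rsB"), k_folds = 2L)
  expect_equal(m$ba_full, 1)
  expect_equal(m$tpr, 1)
  expect_equal(m$fpr, 0)
})

test_that("evaluation is invariant to sample order and marker swap", {
  g <- null_sim(n = 200L, m = 3L, seed = 87L, missing_rate = 0.05)
  combo <- g$markers$marker_id[1:2]
  m1 <- mdr_evaluate(g, combo, seed = 5L)
  # permute samples
  perm <- sample(length(g$status))
  g2 <- genotype_data(g$dosages[perm, ], g$status[perm],
                      markers = g$markers)
  m2 <- mdr_evaluate(g2, combo, seed = 5L)
  expect_equal(m2$ba_full, m1$ba_full)
  expect_equal(m2$high, m1$high)
  # swapping the markers relabels cells but preserves the partition
  m3 <- mdr_evaluate(g, rev(combo), seed = 5L)
  expect_equal(m3$ba_full, m1$ba_full)
  expect_equal(m3$high, m1$high)
})

test_that("scan evaluates every combination and agrees with mdr_evaluate", {
  g <- null_sim(n = 150L, m = 6L, seed = 91L, missing_rate = 0.05)
  sc <- mdr_scan(g, 2L, k_folds = 5L, seed = 3L)
  expect_equal(nrow(sc), choose(6L, 2L))
  expect_equal(attr(sc, "n_tests"), choose(6L, 2L))
  expect_equal(sum(sc$cvc), 5L)
  for (r in c(1L, 8L, 15L)) {
    m <- mdr_evaluate(g, c(sc$marker1[r], sc$marker2[r]), k_folds = 5L,
                      seed = 3L)
    expect_equal(sc$ba_full[r], m$ba_full, tolerance = 1e-12)
    expect_equal(sc$ba_cv[r], m$ba_cv, tolerance = 1e-12)
    expect_equal(sc$or[r], unname(m$or), tolerance = 1e-9)
  }
})

test_that("a lone candidate wins every fold (CVC = k)", {
  g <- null_sim(n = 100L, m = 2L, seed = 95L)
  sc <- mdr_scan(g, 2L, k_folds = 10L, seed = 1L)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$cvc, 10L)
})

test_that("three-way scan enumerates triples and finds embedded signal", {
  pen <- matrix(c(0.05, 0.30, 0.05,
                  0.30, 0.05, 0.30,
                  0.05, 0.30, 0.05), 3L, 3L, byrow = TRUE)
  cfg <- sim_config(n_cases = 300L, n_controls = 300L, n_markers = 4L,
                    maf_range = c(0.4, 0.5), missing_rate = 0, seed = 19L,
                    effects = effect_grid(c(1L, 2L), pen))
  g <- simulate_case_control(cfg)$genotypes
  sc <- mdr_scan(g, 3L, k_folds = 5L, seed = 2L)
  expect_equal(nrow(sc), choose(4L, 3L))
  # the epistatic pair is inside the winning triple
  top <- unlist(sc[1L, c("marker1", "marker2", "marker3")])
  expect_true(all(g$markers$marker_id[1:2] %in% top))
})

test_that("an embedded XOR pair among nulls is ranked first in most runs", {
  pen <- matrix(c(0.05, 0.30, 0.05,
                  0.30, 0.05, 0.30,
                  0.05, 0.30, 0.05), 3L, 3L, byrow = TRUE)
  wins <- vapply(1:15, function(s) {
    cfg <- sim_config(n_cases = 500L, n_controls = 500L, n_markers = 12L,
                      maf_range = c(0.4, 0.5), missing_rate = 0, seed = s,
                      effects = effect_grid(c(1L, 2L), pen))
    g <- simulate_case_control(cfg)$genotypes
    sc <- mdr_scan(g, 2L, k_folds = 10L, seed = s)
    setequal(c(sc$marker1[1L], sc$marker2[1L]), g$markers$marker_id[1:2])
  }, logical(1L))
  expect_gte(mean(wins), 0.9)
})
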