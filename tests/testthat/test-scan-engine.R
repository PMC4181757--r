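test_that("pair enumeration matches closed-form counts in both modes", {
  g <- null_sim(n = 60L, m = 10L, seed = 101L)
  ex <- enumerate_pairs(g, mode = "exhaustive")
  expect_equal(ex$n_evaluations, choose(10L, 2L))
  expect_equal(ex$n_unique, choose(10L, 2L))
  seeds <- g$markers$marker_id[1:3]
  sa <- enumerate_pairs(g, seeds, "seeds_x_all")
  expect_equal(sa$n_evaluations, 3L * 10L)
  # unique unordered non-self pairs: 3 * 10 - 3 self - choose(3, 2) dupes
  expect_equal(sa$n_unique, 3L * 10L - 3L - choose(3L, 2L))
  # no duplicates, no self pairs
  keys <- paste(sa$pairs[1L, ], sa$pairs[2L, ])
  expect_false(any(duplicated(keys)))
  expect_true(all(sa$pairs[1L, ] != sa$pairs[2L, ]))
})

test_that("the seed-against-all bookkeeping reproduces the published count", {
  # enumeration arithmetic only: 92 seeds against 3,704 markers
  expect_equal(92L * 3704L, 340768L)
  dos <- matrix(sample(0:2, 40L, replace = TRUE), nrow = 10L)
  g0 <- genotype_data(dos, rep(c(1L, 0L), 5L))
  sa <- enumerate_pairs(g0, g0$markers$marker_id[1:2], "seeds_x_all")
  expect_equal(sa$n_evaluations, 2L * 4L)
})

test_that("scan statistics agree with the per-table fits", {
  g <- null_sim(n = 200L, m = 6L, seed = 107L, missing_rate = 0.03)
  for (method in c("additive", "multiplicative")) {
    sc <- scan_pairs(g, method, "dominant")
    expect_equal(nrow(sc), choose(6L, 2L))
    for (r in c(1L, 7L, 15L)) {
      pair <- c(sc$marker1[r], sc$marker2[r])
      t <- build_pair_table(g, pair, "dominant")
      f <- if (method == "additive") additive_fit(recode_preventive(t))
      else multiplicative_fit(t)
      est <- if (method == "additive") f$ap else f$or3
      expect_equal(sc$estimate[r], est, tolerance = 1e-9)
      expect_equal(sc$p.value[r], f$p.value, tolerance = 1e-9)
    }
  }
})

test_that("additive scan applies the same recoding as the per-table path", {
  g <- null_sim(n = 300L, m = 8L, seed = 113L)
  sc <- scan_pairs(g, "additive", "recessive")
  for (r in seq_len(min(10L, nrow(sc)))) {
    t <- recode_preventive(
      build_pair_table(g, c(sc$marker1[r], sc$marker2[r]), "recessive"))
    expect_equal(sc$recoding[r], t$recoding)
  }
})

test_that("prioritize unions main-effect and filter-selected markers", {
  cfg <- sim_config(n_cases = 400L, n_controls = 400L, n_markers = 15L,
                    maf_range = c(0.2, 0.4), missing_rate = 0, seed = 127L,
                    effects = effect_main(1L, or = 1.8))
  g <- simulate_case_control(cfg)$genotypes
  s <- prioritize(g, p_threshold = 0.05, n_filter = 3L, seed = 1L)
  expect_true(g$markers$marker_id[1L] %in% s$main_effect)
  expect_length(s$filtered, 3L)
  expect_length(intersect(s$main_effect, s$filtered), 0L)
  expect_setequal(s$seeds, union(s$main_effect, s$filtered))
  # extreme threshold: everything is a main-effect seed, filter set empty
  s1 <- prioritize(g, p_threshold = 1, n_filter = 3L, seed = 1L)
  expect_length(s1$main_effect, 15L)
  expect_length(s1$filtered, 0L)
  # oversized filter request truncates with a warning
  expect_warning(prioritize(g, p_threshold = 1e-30, n_filter = 99L,
                            seed = 1L), "truncated")
})

test_that("a simulated main-effect marker always lands in the seed set", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_cases = 1000L, n_controls = 1000L, n_markers = 10L,
                      maf_range = c(0.2, 0.4), missing_rate = 0, seed = s,
                      effects = effect_main(1L, or = 1.8))
    g <- simulate_case_control(cfg)$genotypes
    g$markers$marker_id[1L] %in%
      prioritize(g, 0.05, 0L)$main_effect
  }, logical(1L))
  expect_equal(mean(hits), 1)
})

test_that("ReliefF ranks an epistatic pair above null markers", {
  pen <- matrix(c(0.05, 0.30, 0.05,
                  0.30, 0.05, 0.30,
                  0.05, 0.30, 0.05), 3L, 3L, byrow = TRUE)
  cfg <- sim_config(n_cases = 400L, n_controls = 400L, n_markers = 10L,
                    maf_range = c(0.4, 0.5), missing_rate = 0, seed = 131L,
                    effects = effect_grid(c(1L, 2L), pen))
  g <- simulate_case_control(cfg)$genotypes
  w <- relieff_scores(g, seed = 1L)
  expect_true(all(rank(-w)[1:2] <= 4))
})

test_that("permutation-adjusted P values respect their bounds and ordering", {
  g <- null_sim(n = 150L, m = 6L, seed = 137L)
  pr <- permute_fwer(g, "multiplicative", "dominant", B = 60L, seed = 3L)
  p <- pr$scan$permuted_p
  expect_true(all(p >= 1 / 61 & p <= 1))
  # monotone non-increasing in the observed statistic
  expect_true(all(diff(p[order(-pr$scan$statistic)]) >= 0))
  # reproducible under the same seed
  pr2 <- permute_fwer(g, "multiplicative", "dominant", B = 60L, seed = 3L)
  expect_identical(pr$perm_best, pr2$perm_best)
})

test_that("a dominant observed statistic attains the resolution floor", {
  # plant an overwhelming interaction so no permutation can beat it
  cfg <- sim_config(n_cases = 400L, n_controls = 400L, n_markers = 4L,
                    maf_range = c(0.3, 0.5), missing_rate = 0, seed = 139L,
                    effects = effect_multiplicative(c(1L, 2L),
                                                    or_interaction = 15))
  g <- simulate_case_control(cfg)$genotypes
  pr <- permute_fwer(g, "multiplicative", "dominant", B = 40L, seed = 7L)
  expect_equal(min(pr$scan$permuted_p), 1 / 41)
  expect_gt(max(pr$scan$permuted_p), 0.5)
})

test_that("top_fraction sizes follow the ceiling arithmetic", {
  g <- null_sim(n = 80L, m = 8L, seed = 149L)
  sc <- scan_pairs(g, "multiplicative", "dominant")
  expect_equal(nrow(top_fraction(sc, 1)), nrow(sc))
  expect_equal(nrow(top_fraction(sc, 0.5)), ceiling(0.5 * choose(8L, 2L)))
  expect_equal(nrow(top_fraction(sc, 1e-6)), 1L)
  # ceiling on the published evaluation count
  expect_equal(ceiling(0.005 * 340768L), 1704L)
})

test_that("method correlation is 1 against itself and ~0 for shuffled stats", {
  g <- null_sim(n = 200L, m = 8L, seed = 151L)
  a <- scan_pairs(g, "multiplicative", "dominant")
  self <- correlate_methods(a, a, q = 1)
  expect_equal(self$r, 1, tolerance = 1e-9)
  expect_equal(self$n_joined, nrow(a))
  # r matches the direct covariance formula on a small join
  b <- scan_pairs(g, "additive", "dominant")
  cr <- correlate_methods(a, b, q = 0.5)
  x <- cr$table$stat_a; y <- cr$table$stat_b
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cr$r, r_direct, tolerance = 1e-12)
  # independently shuffled statistics decorrelate
  set.seed(9)
  shuffled <- vapply(1:20, function(i) {
    b2 <- b
    b2$p.value <- sample(b2$p.value)
    correlate_methods(a, b2, q = 1)$r
  }, numeric(1L))
  expect_lt(abs(mean(shuffled)), 0.15)
})

test_that("too small a join signals an undefined correlation", {
  g <- null_sim(n = 100L, m = 5L, seed = 157L)
  a <- scan_pairs(g, "multiplicative", "dominant")
  b <- a[0, ]
  expect_warning(cr <- correlate_methods(a, b, q = 1), "fewer than 3")
  expect_true(is.na(cr$r))
})

test_that("an embedded multiplicative pair is ranked first in most seeded runs", {
  wins <- vapply(1:15, function(s) {
    cfg <- sim_config(n_cases = 1000L, n_controls = 1000L, n_markers = 12L,
                      maf_range = c(0.3, 0.5), missing_rate = 0, seed = s,
                      effects = effect_multiplicative(c(1L, 2L),
                                                      or_interaction = 3))
    g <- simulate_case_control(cfg)$genotypes
    sc <- scan_pairs(g, "multiplicative", "dominant")
    setequal(c(sc$marker1[1L], sc$marker2[1L]), g$markers$marker_id[1:2])
  }, logical(1L))
  expect_gte(mean(wins), 0.8)
})
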