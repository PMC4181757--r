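test_that("TSV parsing maps tokens to dosages and NA to missing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tstatus\trsA\trsB",
               "s1\tcase\t0\t2",
               "s2\tcase\t1\t1",
               "s3\tcontrol\t2\t0",
               "s4\tcontrol\tNA\t1"), path)
  g <- read_genotypes(path, "tsv")
  expect_equal(dim(g), c(4L, 2L))
  expect_equal(unname(g$dosages[, "rsA"]), c(0L, 1L, 2L, NA))
  expect_equal(sum(is.na(g$dosages)), 1L)
  expect_equal(g$status, c(1L, 1L, 0L, 0L))
})

test_that("PED alleles become minor-allele dosages", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- sub("\\.ped$", ".map", ped)
  # G is the minor allele (3 of 10 called alleles); phenotype 2 = case
  writeLines(c("f1 s1 0 0 1 2 A A",
               "f2 s2 0 0 1 2 A G",
               "f3 s3 0 0 1 1 G G",
               "f4 s4 0 0 1 1 0 0",
               "f5 s5 0 0 1 1 A A"), ped)
  writeLines("1 rsX 0 12345", map)
  g <- read_genotypes(ped, "ped")
  expect_equal(unname(g$dosages[, "rsX"]), c(0L, 1L, 2L, NA, 0L))
  expect_equal(g$status, c(1L, 1L, 0L, 0L, 0L))
  expect_equal(g$markers$position, 12345L)
})

test_that("write/read round trip reproduces a simulated matrix exactly", {
  g <- null_sim(n = 50L, m = 50L, seed = 7L, missing_rate = 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- suppressWarnings(read_genotypes(path, "tsv"))
  expect_identical(unname(g2$dosages), unname(g$dosages))
  expect_identical(g2$status, g$status)
  expect_identical(g2$sample_ids, g$sample_ids)
})

test_that("ped/map dimension mismatch is a format error", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- sub("\\.ped$", ".map", ped)
  writeLines("f1 s1 0 0 1 2 A A G G", ped)   # two markers of alleles
  writeLines("1 rsX 0 1", map)               # but only one mapped
  expect_error(read_genotypes(ped, "ped"), "expected")
})

test_that("monomorphic markers are retained but flagged", {
  dos <- cbind(rsA = c(1L, 1L, 1L, 1L), rsB = c(0L, 1L, 2L, 0L))
  expect_warning(
    g <- episcape:::flag_monomorphic(genotype_data(dos, c(1, 1, 0, 0))),
    "monomorphic")
  expect_equal(attr(g, "monomorphic"), "rsA")
  expect_equal(ncol(g$dosages), 2L)
})

test_that("exposure codings follow the dominant/recessive definitions", {
  dos <- cbind(rsA = c(0L, 1L, 2L, NA), rsB = c(1L, 1L, 1L, 1L))
  g <- genotype_data(dos, c(1, 1, 0, 0))
  expect_equal(code_exposure(g, "rsA", "dominant"), c(0L, 1L, 1L, NA))
  expect_equal(code_exposure(g, "rsA", "recessive"), c(0L, 0L, 1L, NA))
  # all-heterozygote marker is never recessive-exposed
  expect_equal(code_exposure(g, "rsB", "recessive"), rep(0L, 4L))
  expect_error(code_exposure(g, "rsZ"), "unknown marker")
})

test_that("dominant exposure dominates recessive elementwise", {
  g <- null_sim(n = 100L, m = 5L, seed = 3L, missing_rate = 0.1)
  for (m in g$markers$marker_id) {
    dom <- code_exposure(g, m, "dominant")
    rec <- code_exposure(g, m, "recessive")
    ok <- !is.na(dom)
    expect_true(all(dom[ok] >= rec[ok]))
  }
})

test_that("ld_r2 matches brute-force correlation and is symmetric", {
  dos <- cbind(rsA = c(0L, 1L, 2L, 2L, 1L, 0L),
               rsB = c(0L, 2L, 1L, 2L, 0L, 1L))
  g <- genotype_data(dos, c(1, 1, 1, 0, 0, 0))
  # brute-force Pearson correlation by exhaustive summation
  a <- dos[, 1L]; b <- dos[, 2L]
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  expect_equal(ld_r2(g, "rsA", "rsB"), (num / den)^2, tolerance = 1e-12)
  expect_equal(ld_r2(g, "rsA", "rsB"), ld_r2(g, "rsB", "rsA"))
  expect_equal(ld_r2(g, "rsA", "rsA"), 1)
})

test_that("ld_r2 is invariant to relabelling the minor allele", {
  g <- null_sim(n = 200L, m = 4L, seed = 11L)
  flipped <- g
  flipped$dosages[, 2L] <- 2L - flipped$dosages[, 2L]
  ids <- g$markers$marker_id
  expect_equal(ld_r2(flipped, ids[1L], ids[2L]), ld_r2(g, ids[1L], ids[2L]),
               tolerance = 1e-12)
})

test_that("ld_r2 signals undefined LD for constant markers", {
  dos <- cbind(rsA = c(1L, 1L, 1L, 1L), rsB = c(0L, 1L, 2L, 0L))
  g <- genotype_data(dos, c(1, 1, 0, 0))
  expect_true(is.na(ld_r2(g, "rsA", "rsB")))
})

test_that("independent markers have near-zero r2 at large n", {
  g <- null_sim(n = 2500L, m = 2L, seed = 5L)
  expect_lt(ld_r2(g, g$markers$marker_id[1L], g$markers$marker_id[2L]),
            0.01)
})

test_that("prune_top_list keeps pairs sharing one marker but drops full duplicates", {
  # marker D duplicates marker B exactly (perfect LD)
  dos <- cbind(A = c(0L, 1L, 2L, 0L, 1L, 2L, 1L, 0L),
               B = c(2L, 0L, 1L, 1L, 0L, 2L, 2L, 0L),
               C = c(0L, 0L, 1L, 2L, 2L, 1L, 0L, 1L),
               D = c(2L, 0L, 1L, 1L, 0L, 2L, 2L, 0L))
  g <- genotype_data(dos, c(1, 1, 1, 1, 0, 0, 0, 0))
  ranked <- data.frame(marker1 = c("A", "A", "C"),
                       marker2 = c("B", "D", "D"),
                       stringsAsFactors = FALSE)
  kept <- prune_top_list(ranked, g, r2_max = 0.2, k = 10L)
  # A-D duplicates A-B (D==B); C-D shares only one redundant slot -> kept
  expect_equal(kept$marker2, c("B", "D"))
  expect_equal(kept$marker1, c("A", "C"))
  # stricter marker-level rule drops anything touching B or its duplicate
  kept2 <- prune_top_list(ranked, g, r2_max = 0.2, k = 10L, rule = "marker")
  expect_equal(nrow(kept2), 1L)
})

test_that("prune_top_list with r2_max = 1 returns the first k unchanged", {
  g <- null_sim(n = 50L, m = 6L, seed = 2L)
  ids <- g$markers$marker_id
  ranked <- data.frame(marker1 = ids[c(1, 1, 2, 3)],
                       marker2 = ids[c(2, 3, 4, 5)])
  expect_equal(prune_top_list(ranked, g, r2_max = 1, k = 3L),
               ranked[1:3, ])
})

test_that("no within-list duplicate pairs survive pruning of an LD block", {
  cfg <- sim_config(n_cases = 150L, n_controls = 150L, n_markers = 12L,
                    missing_rate = 0, seed = 9L,
                    ld_blocks = list(list(markers = 1:4, copy_prob = 1)))
  g <- simulate_case_control(cfg)$genotypes
  ids <- g$markers$marker_id
  ranked <- data.frame(
    marker1 = ids[c(1, 2, 3, 5, 1)],
    marker2 = ids[c(5, 5, 6, 6, 7)], stringsAsFactors = FALSE)
  kept <- prune_top_list(ranked, g, r2_max = 0.2, k = 10L)
  # pairwise check over the kept list: no kept pair duplicates another
  if (nrow(kept) > 1L) {
    for (a in seq_len(nrow(kept) - 1L)) for (b in (a + 1L):nrow(kept)) {
      r2 <- function(x, y) if (x == y) 1 else ld_r2(g, x, y)
      straight <- min(r2(kept$marker1[a], kept$marker1[b]),
                      r2(kept$marker2[a], kept$marker2[b]))
      crossed <- min(r2(kept$marker1[a], kept$marker2[b]),
                     r2(kept$marker2[a], kept$marker1[b]))
      # a kept pair is a duplicate of another if some alignment has both
      # marker r2 above threshold, i.e. max over alignments of the
      # within-alignment minimum exceeds r2_max
      expect_lte(max(straight, crossed), 0.2)
    }
  }
})
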