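# Shared fixtures: tiny hand-built genotype sets and published count tables.

# 4 samples x 2 markers with one missing entry
tiny_genotypes <- function() {
  dos <- matrix(c(0L, 1L, 2L, NA_integer_,
                  2L, 1L, 0L, 1L), nrow = 4L,
                dimnames = list(NULL, c("rsA", "rsB")))
  genotype_data(dos, status = c(1L, 1L, 0L, 0L))
}

# deterministic pair table from explicit cell counts
counts_table <- function(cases, controls, ...) {
  pair_table_from_counts(cases, controls, ...)
}

# published per-pair exposure-cell counts used across tests
published_counts <- list(
  add_dom_top = list(cases = c(1009, 169, 475, 78),
                     controls = c(1073, 174, 500, 33)),
  add_rec_top = list(cases = c(377, 1296, 12, 46),
                     controls = c(446, 1305, 14, 14)),
  add_rec_2nd = list(cases = c(1105, 22, 582, 22),
                     controls = c(1176, 23, 571, 6)),
  mult_rec_top = list(cases = c(41, 29, 695, 948),
                      controls = c(13, 44, 742, 970)),
  mult_dom_5th = list(cases = c(80, 46, 1165, 357),
                      controls = c(111, 14, 1221, 342)))

# simulate a small null dataset quickly
null_sim <- function(n = 200L, m = 10L, seed = 1L, missing_rate = 0) {
  simulate_case_control(sim_config(n_cases = n, n_controls = n,
                                   n_markers = m,
                                   missing_rate = missing_rate,
                                   seed = seed))$genotypes
}

# random non-degenerate pair table for property-style loops
random_table <- function(max_count = 50L) {
  repeat {
    ca <- sample.int(max_count, 4L, replace = TRUE)
    co <- sample.int(max_count, 4L, replace = TRUE)
    t <- pair_table_from_counts(ca, co)
    if (!t$degenerate) return(t)
  }
}
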