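#' Effect specifications for the case-control simulator
#'
#' Constructors for the two-locus (and single-locus) effects understood by
#' [simulate_case_control()]. All exposures are binary collapses of the
#' genotype under the given coding (see [code_exposure()]).
#'
#' `effect_main` adds `log(or)` to the disease log-odds for exposed samples.
#' `effect_multiplicative` adds `log(or1)`, `log(or2)` and
#' `log(or_interaction)` for the two single exposures and their product —
#' the generative counterpart of the saturated logistic interaction model.
#' `effect_additive` specifies exposure-category risks on the risk-ratio
#' scale: relative risks `rr01`, `rr10` for the single exposures and a
#' target relative excess risk due to interaction `reri`, so that
#' `RR11 = rr01 + rr10 - 1 + reri`; absolute risks are obtained by scaling
#' with the baseline prevalence. `effect_grid` gives a full 3 x 3 penetrance
#' grid over the joint genotype (rows: dosage of marker 1).
#'
#' @param marker,markers marker column index (1-based) or indices (length 2,
#'   distinct) the effect acts on.
#' @param or,or1,or2,or_interaction odds ratios (> 0) on the logistic scale.
#' @param rr01,rr10 single-exposure relative risks (risk-ratio scale).
#' @param reri target relative excess risk due to interaction on the
#'   risk-ratio scale. Exactly one of `reri` and `target_ap` must be given.
#' @param target_ap alternatively, the target attributable proportion on the
#'   risk-ratio scale; converted via
#'   `reri = target_ap * (rr01 + rr10 - 1) / (1 - target_ap)`.
#' @param penetrance numeric 3 x 3 matrix of disease risks in [0, 1].
#' @param coding `"dominant"` or `"recessive"`.
#' @return a list of class `effect_spec`.
#' @name effect_spec
NULL

effect_spec <- function(kind, markers, coding, ...) {
  stopifnot(coding %in% c("dominant", "recessive"))
  if (anyDuplicated(markers)) stop("effect markers must be distinct")
  structure(c(list(kind = kind, markers = as.integer(markers),
                   coding = coding), list(...)),
            class = "effect_spec")
}

#' @rdname effect_spec
#' @export
effect_main <- function(marker, or, coding = "dominant") {
  stopifnot(or > 0, length(marker) == 1L)
  effect_spec("main", marker, coding, or = or)
}

#' @rdname effect_spec
#' @export
effect_multiplicative <- function(markers, or1 = 1, or2 = 1, or_interaction,
                                  coding = "dominant") {
  stopifnot(length(markers) == 2L, or1 > 0, or2 > 0, or_interaction > 0)
  effect_spec("multiplicative_pair", markers, coding,
              or1 = or1, or2 = or2, or_interaction = or_interaction)
}

#' @rdname effect_spec
#' @export
effect_additive <- function(markers, rr01 = 1, rr10 = 1, reri = NULL,
                            target_ap = NULL, coding = "dominant") {
  stopifnot(length(markers) == 2L, rr01 > 0, rr10 > 0)
  if (is.null(reri) + is.null(target_ap) != 1L)
    stop("give exactly one of reri and target_ap")
  if (is.null(reri)) {
    stopifnot(target_ap < 1)
    reri <- target_ap * (rr01 + rr10 - 1) / (1 - target_ap)
  }
  rr11 <- rr01 + rr10 - 1 + reri
  if (rr11 <= 0) stop("implied RR11 must be positive")
  effect_spec("additive_pair", markers, coding,
              rr01 = rr01, rr10 = rr10, reri = reri, rr11 = rr11)
}

#' @rdname effect_spec
#' @export
effect_grid <- function(markers, penetrance) {
  penetrance <- as.matrix(penetrance)
  stopifnot(length(markers) == 2L, identical(dim(penetrance), c(3L, 3L)),
            all(penetrance >= 0), all(penetrance <= 1))
  effect_spec("epistatic_grid", markers, "dominant", penetrance = penetrance)
}

#' Simulation configuration
#'
#' Default sizes mirror a candidate-gene case-control design: 1,732 cases
#' and 1,783 controls, 3,704 biallelic autosomal markers grouped into 63
#' genes, a baseline disease prevalence of 15% (the high-prevalence regime
#' of major depressive disorder), sporadic missing genotypes at 0.1%.
#' Genotypes are drawn under Hardy-Weinberg equilibrium at per-marker minor
#' allele frequencies uniform over `maf_range`.
#'
#' @param n_cases,n_controls target group sizes (>= 1).
#' @param n_markers number of biallelic markers.
#' @param maf_range length-2 interval within (0, 0.5].
#' @param missing_rate per-genotype missing probability in [0, 1).
#' @param baseline_prevalence disease risk of the unexposed (reference)
#'   category, in (0, 1).
#' @param effects list of [effect_spec] objects. At most one risk-scale
#'   effect (`effect_additive` / `effect_grid`) may be present, and it may
#'   not be combined with logistic-scale effects.
#' @param n_genes number of gene groups for marker metadata.
#' @param ld_blocks optional list of `list(markers = <indices>,
#'   copy_prob = <p>)`: within a block, each listed marker copies the
#'   block's first marker's genotype with probability `copy_prob` per sample
#'   (otherwise an independent HWE draw), creating tunable LD for pruning
#'   tests.
#' @param seed RNG seed (integer).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 1732L, n_controls = 1783L,
                       n_markers = 3704L, maf_range = c(0.05, 0.5),
                       missing_rate = 0.001, baseline_prevalence = 0.15,
                       effects = list(), n_genes = 63L, ld_blocks = list(),
                       seed = 1L) {
  stopifnot(n_cases >= 1L, n_controls >= 1L, n_markers >= 1L,
            length(maf_range) == 2L, maf_range[1L] > 0,
            maf_range[2L] <= 0.5, maf_range[1L] <= maf_range[2L],
            missing_rate >= 0, missing_rate < 1,
            baseline_prevalence > 0, baseline_prevalence < 1)
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  stopifnot(all(vapply(effects, inherits, TRUE, "effect_spec")))
  kinds <- vapply(effects, `[[`, "", "kind")
  risky <- kinds %in% c("additive_pair", "epistatic_grid")
  if (sum(risky) > 1L || (any(risky) && length(effects) > 1L))
    stop("a risk-scale effect (additive/grid) must be the only effect")
  for (e in effects)
    if (any(e$markers > n_markers)) stop("effect marker index out of range")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_markers = as.integer(n_markers),
                 maf_range = maf_range, missing_rate = missing_rate,
                 baseline_prevalence = baseline_prevalence,
                 effects = effects, n_genes = as.integer(n_genes),
                 ld_blocks = ld_blocks, seed = as.integer(seed)),
            class = "sim_config")
}

sim_marker_info <- function(n_markers, n_genes) {
  gene <- sprintf("GENE%02d", 1L + (seq_len(n_markers) - 1L) %/%
                    ceiling(n_markers / n_genes))
  gidx <- as.integer(factor(gene, levels = unique(gene)))
  data.frame(marker_id = sprintf("rs%06d", seq_len(n_markers)),
             chromosome = ((gidx - 1L) %% 22L) + 1L,
             position = seq_len(n_markers) * 1000L,
             gene = gene, stringsAsFactors = FALSE)
}

draw_genotypes <- function(n, mafs, ld_blocks) {
  m <- length(mafs)
  u <- matrix(stats::runif(n * m), n, m)
  p1 <- rep((1 - mafs)^2, each = n)               # P(dosage 0)
  p2 <- rep((1 - mafs)^2 + 2 * mafs * (1 - mafs), each = n)
  dos <- matrix(0L, n, m)
  dos[u > p1] <- 1L
  dos[u > p2] <- 2L
  for (blk in ld_blocks) {
    idx <- blk$markers
    base <- dos[, idx[1L]]
    for (j in idx[-1L]) {
      copy <- stats::runif(n) < blk$copy_prob
      dos[copy, j] <- base[copy]
    }
  }
  dos
}

risk_from_effects <- function(dos, config) {
  effects <- config$effects
  kinds <- vapply(effects, `[[`, "", "kind")
  n <- nrow(dos)
  if (length(effects) && kinds[1L] == "additive_pair") {
    e <- effects[[1L]]
    x1 <- code_dosage(dos[, e$markers[1L]], e$coding)
    x2 <- code_dosage(dos[, e$markers[2L]], e$coding)
    rr <- cell_rr(e)
    risk <- config$baseline_prevalence * rr[1L + x1 * 2L + x2]
    if (any(risk > 1)) stop("additive_pair risks exceed 1; lower the ",
                            "baseline prevalence or the effect sizes")
    return(risk)
  }
  if (length(effects) && kinds[1L] == "epistatic_grid") {
    e <- effects[[1L]]
    return(e$penetrance[cbind(dos[, e$markers[1L]] + 1L,
                              dos[, e$markers[2L]] + 1L)])
  }
  eta <- rep(stats::qlogis(config$baseline_prevalence), n)
  for (e in effects) {
    if (e$kind == "main") {
      eta <- eta + log(e$or) * code_dosage(dos[, e$markers[1L]], e$coding)
    } else {                                       # multiplicative_pair
      x1 <- code_dosage(dos[, e$markers[1L]], e$coding)
      x2 <- code_dosage(dos[, e$markers[2L]], e$coding)
      eta <- eta + log(e$or1) * x1 + log(e$or2) * x2 +
        log(e$or_interaction) * x1 * x2
    }
  }
  stats::plogis(eta)
}

# category relative risks (00, 01, 10, 11) of an additive_pair effect
cell_rr <- function(e) c(1, e$rr01, e$rr10, e$rr11)

#' Simulate a case-control genotype dataset with known interaction structure
#'
#' Population genotypes are drawn under Hardy-Weinberg equilibrium; disease
#' status follows the risk model implied by `config$effects` (logistic for
#' main and multiplicative effects, exposure-category risks for additive
#' effects, direct penetrance lookup for an epistatic grid). Individuals are
#' accumulated by rejection sampling until exactly `n_cases` cases and
#' `n_controls` controls are collected, matching a fixed-quota case-control
#' design. Missing genotypes are then inserted independently at
#' `missing_rate`. The same seed reproduces the dataset exactly.
#'
#' @param config a [sim_config].
#' @return a list with elements `genotypes` (a [genotype_data]) and `truth`
#'   (generating parameters: per-marker MAFs, the effect list, and — for an
#'   additive pair — the exact odds-scale odds ratios, RERI and AP implied
#'   by the generating risks under case-control sampling).
#' @export
simulate_case_control <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mafs <- stats::runif(config$n_markers, config$maf_range[1L],
                       config$maf_range[2L])
  n_want_ca <- config$n_cases
  n_want_co <- config$n_controls
  cases <- list(); controls <- list()
  n_ca <- 0L; n_co <- 0L
  batch <- max(1000L, 2L * (n_want_ca + n_want_co))
  for (attempt in seq_len(500L)) {
    dos <- draw_genotypes(batch, mafs, config$ld_blocks)
    risk <- risk_from_effects(dos, config)
    y <- stats::runif(batch) < risk
    if (n_ca < n_want_ca && any(y)) {
      take <- which(y)[seq_len(min(sum(y), n_want_ca - n_ca))]
      cases[[length(cases) + 1L]] <- dos[take, , drop = FALSE]
      n_ca <- n_ca + length(take)
    }
    if (n_co < n_want_co && any(!y)) {
      take <- which(!y)[seq_len(min(sum(!y), n_want_co - n_co))]
      controls[[length(controls) + 1L]] <- dos[take, , drop = FALSE]
      n_co <- n_co + length(take)
    }
    if (n_ca >= n_want_ca && n_co >= n_want_co) break
  }
  if (n_ca < n_want_ca || n_co < n_want_co)
    stop("could not reach the requested case/control quotas; ",
         "check that the risk model admits both outcomes")
  dos <- rbind(do.call(rbind, cases), do.call(rbind, controls))
  status <- rep(c(1L, 0L), c(n_want_ca, n_want_co))
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(dos)) < config$missing_rate
    dos[miss] <- NA_integer_
  }
  markers <- sim_marker_info(config$n_markers, config$n_genes)
  g <- genotype_data(dos, status, markers = markers,
                     sample_ids = sprintf("sim%05d", seq_len(nrow(dos))))
  truth <- list(config = config, mafs = mafs, effects = config$effects)
  kinds <- vapply(config$effects, `[[`, "", "kind")
  if (length(kinds) && kinds[1L] == "additive_pair")
    truth$implied <- implied_odds_scale(config$effects[[1L]], mafs, config)
  list(genotypes = g, truth = truth)
}

# Exact odds-scale estimand for an additive_pair effect under case-control
# sampling: cell probabilities from HWE exposure frequencies, case/control
# strata proportional to P(cell) * risk and P(cell) * (1 - risk).
implied_odds_scale <- function(e, mafs, config) {
  pexp <- function(maf) {
    if (e$coding == "dominant") 1 - (1 - maf)^2 else maf^2
  }
  p1 <- pexp(mafs[e$markers[1L]])
  p2 <- pexp(mafs[e$markers[2L]])
  pcell <- c(`00` = (1 - p1) * (1 - p2), `01` = (1 - p1) * p2,
             `10` = p1 * (1 - p2), `11` = p1 * p2)
  risk <- config$baseline_prevalence * cell_rr(e)
  pcase <- pcell * risk / sum(pcell * risk)
  pctrl <- pcell * (1 - risk) / sum(pcell * (1 - risk))
  odds <- pcase / pctrl
  or <- odds / odds[1L]
  reri_or <- or[4L] - or[2L] - or[3L] + 1
  list(or01 = unname(or[2L]), or10 = unname(or[3L]), or11 = unname(or[4L]),
       reri = unname(reri_or), ap = unname(reri_or / or[4L]),
       risk = risk, p_cell = pcell)
}
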