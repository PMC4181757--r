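#' Pipeline configuration
#'
#' Bundles the inputs and thresholds of the full analysis: data source
#' (either a [sim_config] to simulate from, or a path to a TSV/PED genotype
#' file), the interaction methods and codings to run, and the scan
#' thresholds.
#'
#' @param input a `sim_config`, a `genotype_data`, or a file path readable
#'   by [read_genotypes()].
#' @param methods subset of `"additive"`, `"multiplicative"`, `"mdr"`.
#' @param codings subset of `"dominant"`, `"recessive"` (regression methods
#'   run once per coding).
#' @param p_threshold main-effect seed threshold (default 0.05).
#' @param n_filter ReliefF-selected seed count (default 0).
#' @param q top-fraction for cross-method correlation (default 0.005).
#' @param r2_max LD threshold for pruning top lists (default 0.2).
#' @param k top-list size (default 10).
#' @param k_folds MDR cross-validation folds (default 10).
#' @param B permutations for family-wise correction (0 disables).
#' @param pair_mode `"seeds_x_all"` or `"exhaustive"` for the regression
#'   scans (MDR always scans exhaustively).
#' @param format input file format when `input` is a path.
#' @param seed master seed; every stochastic stage derives from it.
#' @return a list of class `run_config`.
#' @export
run_config <- function(input, methods = c("additive", "multiplicative",
                                          "mdr"),
                       codings = c("dominant", "recessive"),
                       p_threshold = 0.05, n_filter = 0L, q = 0.005,
                       r2_max = 0.2, k = 10L, k_folds = 10L, B = 0L,
                       pair_mode = c("seeds_x_all", "exhaustive"),
                       format = "tsv", seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  codings <- match.arg(codings, several.ok = TRUE)
  pair_mode <- match.arg(pair_mode)
  stopifnot(length(methods) >= 1L)
  structure(list(input = input, methods = methods, codings = codings,
                 p_threshold = p_threshold, n_filter = as.integer(n_filter),
                 q = q, r2_max = r2_max, k = as.integer(k),
                 k_folds = as.integer(k_folds), B = as.integer(B),
                 pair_mode = pair_mode, format = format,
                 seed = as.integer(seed)),
            class = "run_config")
}

round_sig <- function(p) ifelse(is.na(p), NA_character_,
                                formatC(p, format = "e", digits = 2))

#' Format a ranked scan in the published top-table layout
#'
#' Columns mirror the conventional per-pair report: marker metadata for
#' both markers, the interaction estimate (AP or OR, 2 d.p.) with its 95%
#' interval, the P value in scientific notation, attributable fraction and
#' AUC (4 d.p.), and the four case/control cell counts.
#'
#' @param scan a `scan_result` (regression methods).
#' @param g the [genotype_data] scanned.
#' @return a `data.frame`, one row per pair in scan order.
#' @export
format_top_table <- function(scan, g) {
  meta <- g$markers[match(scan$marker1, g$markers$marker_id), ]
  meta2 <- g$markers[match(scan$marker2, g$markers$marker_id), ]
  rows <- lapply(seq_len(nrow(scan)), function(r) {
    t <- pair_table_from_counts(
      unlist(scan[r, c("ca00", "ca01", "ca10", "ca11")]),
      unlist(scan[r, c("co00", "co01", "co10", "co11")]))
    data.frame(paf = round(paf(t), 3), auc = round(auc_from_table(t), 4))
  })
  extra <- do.call(rbind, rows)
  data.frame(chr1 = meta$chromosome, gene1 = meta$gene, rs1 = scan$marker1,
             chr2 = meta2$chromosome, gene2 = meta2$gene,
             rs2 = scan$marker2,
             estimate = round(scan$estimate, 2),
             p = round_sig(scan$p.value),
             permuted_p = if ("permuted_p" %in% names(scan))
               round(scan$permuted_p, 3) else NA_real_,
             paf = extra$paf, auc = extra$auc,
             n00 = paste0(scan$ca00, "/", scan$co00),
             n01 = paste0(scan$ca01, "/", scan$co01),
             n10 = paste0(scan$ca10, "/", scan$co10),
             n11 = paste0(scan$ca11, "/", scan$co11),
             recoding = scan$recoding,
             stringsAsFactors = FALSE)
}

write_stage <- function(tab, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full interaction-analysis pipeline
#'
#' Stages: ingest or simulate genotypes; single-marker trend tests; seed
#' prioritisation (main effects + ReliefF); pairwise scans per method and
#' coding; optional permutation-based family-wise correction; LD-pruned
#' top-k tables with attributable-fraction and AUC metrics; AP diagnostics
#' over the additive scans; cross-method correlations. Every output is a
#' pure function of the configuration and its seed; files are written as
#' TSV under `out_dir`.
#'
#' @param config a [run_config].
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @return a list with elements `genotypes`, `assoc`, `seeds`, `scans`
#'   (named list), `top` (pruned top-k tables), `permutation` (if `B > 0`),
#'   `ap_diag`, `correlations`, `files`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  files <- character(0)

  g <- config$input
  if (inherits(g, "sim_config")) g <- simulate_case_control(g)$genotypes
  else if (is.character(g)) g <- read_genotypes(g, config$format)
  stopifnot(inherits(g, "genotype_data"))

  assoc <- assoc_scan(g)
  seeds <- prioritize(g, config$p_threshold, config$n_filter, assoc = assoc,
                      seed = config$seed)
  pairs <- if (config$pair_mode == "seeds_x_all" && length(seeds$seeds))
    enumerate_pairs(g, seeds, "seeds_x_all")
  else enumerate_pairs(g, mode = "exhaustive")

  scans <- list()
  for (method in config$methods) {
    if (method == "mdr") {
      scans$mdr <- mdr_scan(g, 2L, config$k_folds, seed = config$seed)
    } else {
      for (coding in config$codings) {
        key <- paste0(method, "_", substr(coding, 1L, 3L))
        scans[[key]] <- scan_pairs(g, method, coding, pairs)
      }
    }
  }

  permutation <- NULL
  if (config$B > 0L) {
    permutation <- list()
    for (key in names(scans)) {
      parts <- strsplit(key, "_")[[1L]]
      method <- parts[1L]
      coding <- if (length(parts) > 1L && parts[2L] == "rec")
        "recessive" else "dominant"
      permutation[[key]] <- permute_fwer(g, method, coding, pairs,
                                         B = config$B, seed = config$seed,
                                         k_folds = config$k_folds)
      scans[[key]] <- permutation[[key]]$scan
    }
  }

  top <- lapply(scans, function(s)
    prune_top_list(s, g, config$r2_max, config$k))

  ap_diag <- NULL
  add_keys <- grep("^additive", names(scans), value = TRUE)
  if (length(add_keys)) {
    s <- scans[[add_keys[1L]]]
    fits <- tables <- vector("list", nrow(s))
    for (r in seq_len(nrow(s))) {
      tables[[r]] <- pair_table_from_counts(
        unlist(s[r, c("ca00", "ca01", "ca10", "ca11")]),
        unlist(s[r, c("co00", "co01", "co10", "co11")]),
        recoding = s$recoding[r])
      fits[[r]] <- additive_fit(tables[[r]])
    }
    ap_diag <- ap_diagnostics(fits, tables)
  }

  correlations <- list()
  keys <- names(scans)
  if (length(keys) >= 2L) {
    for (a in keys) for (b in setdiff(keys, a)) {
      cr <- suppressWarnings(
        correlate_methods(scans[[a]], scans[[b]], config$q))
      correlations[[paste(a, "vs", b)]] <-
        data.frame(top_of = a, against = b, r = cr$r,
                   p.value = cr$p.value, n_joined = cr$n_joined)
    }
  }

  if (!is.null(out_dir)) {
    files <- c(files, write_stage(assoc, out_dir, "single_marker"))
    for (key in names(scans)) {
      files <- c(files, write_stage(scans[[key]], out_dir,
                                    paste0("scan_", key)))
      tt <- if (inherits(scans[[key]], "mdr_scan_result"))
        top[[key]] else format_top_table(top[[key]], g)
      files <- c(files, write_stage(tt, out_dir, paste0("top_", key)))
    }
    if (length(correlations))
      files <- c(files, write_stage(do.call(rbind, correlations), out_dir,
                                    "method_correlations"))
    if (!is.null(ap_diag))
      files <- c(files, write_stage(ap_diag$table, out_dir,
                                    "ap_diagnostics"))
  }

  list(genotypes = g, assoc = assoc, seeds = seeds, scans = scans,
       top = top, permutation = permutation, ap_diag = ap_diag,
       correlations = correlations, files = files)
}

#' Published top-interaction tables bundled with the package
#'
#' Per-pair case/control counts in the four joint-exposure cells for the
#' ten strongest interactions reported by a published candidate-gene
#' case-control study of major depressive disorder, one table per
#' method/coding panel, plus the high/low risk classification counts of its
#' MDR panel. These provide real published count data against which the
#' package's statistics can be recomputed.
#'
#' @param panel one of `"additive_dominant"`, `"additive_recessive"`,
#'   `"multiplicative_dominant"`, `"multiplicative_recessive"`, `"mdr"`.
#' @return a `data.frame` of the panel rows.
#' @export
published_top_pairs <- function(panel = c("additive_dominant",
                                          "additive_recessive",
                                          "multiplicative_dominant",
                                          "multiplicative_recessive",
                                          "mdr")) {
  panel <- match.arg(panel)
  path <- system.file("extdata", paste0("top_pairs_", panel, ".tsv"),
                      package = "episcape", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
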