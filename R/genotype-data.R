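#' Case-control genotype data
#'
#' Container for a samples x markers grid of minor-allele dosages together
#' with the aligned case/control status and per-marker metadata. Dosages are
#' integers in \{0, 1, 2\} counting copies of the minor allele (defined per
#' marker from the pooled allele frequency); missing genotypes are `NA`.
#'
#' @param dosages integer matrix, samples in rows, markers in columns, values
#'   in \{0, 1, 2, NA\}.
#' @param status integer or logical vector, one element per sample; 1/`TRUE`
#'   marks a case, 0/`FALSE` a control. Character vectors with values
#'   `"case"`/`"control"` are also accepted.
#' @param markers `data.frame` with columns `marker_id`, `chromosome`,
#'   `position`, `gene` (one row per marker). If `NULL`, minimal metadata is
#'   created from the column names of `dosages`.
#' @param sample_ids character vector of sample identifiers; defaults to the
#'   row names of `dosages` or `s1..sn`.
#'
#' @return An object of class `genotype_data`: a list with elements
#'   `dosages`, `status`, `markers`, `sample_ids`.
#' @export
genotype_data <- function(dosages, status, markers = NULL, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (!all(dosages %in% c(0L, 1L, 2L, NA_integer_)))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.character(status)) {
    if (!all(status %in% c("case", "control")))
      stop("character status must be 'case' or 'control'")
    status <- as.integer(status == "case")
  }
  status <- as.integer(status)
  if (length(status) != nrow(dosages))
    stop("status length (", length(status), ") != number of samples (",
         nrow(dosages), ")")
  if (!all(status %in% c(0L, 1L))) stop("status must be 0/1")
  if (sum(status == 1L) < 1L || sum(status == 0L) < 1L)
    stop("need at least one case and one control")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(dosages)))
  }
  if (is.null(markers)) {
    ids <- colnames(dosages)
    if (is.null(ids)) ids <- paste0("m", seq_len(ncol(dosages)))
    markers <- data.frame(marker_id = ids,
                          chromosome = 1L,
                          position = seq_len(ncol(dosages)),
                          gene = NA_character_,
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(markers),
            all(c("marker_id", "chromosome", "position", "gene") %in%
                  names(markers)))
  if (nrow(markers) != ncol(dosages))
    stop("markers rows (", nrow(markers), ") != number of marker columns (",
         ncol(dosages), ")")
  if (anyDuplicated(markers$marker_id))
    stop("marker_id values must be unique")
  chr <- markers$chromosome
  if (any(!is.na(chr) & (chr < 1L | chr > 22L)))
    stop("chromosome must be autosomal (1-22)")
  dimnames(dosages) <- list(sample_ids, markers$marker_id)
  structure(list(dosages = dosages, status = status, markers = markers,
                 sample_ids = sample_ids),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data: ", length(x$sample_ids), " samples (",
      sum(x$status == 1L), " cases / ", sum(x$status == 0L), " controls) x ",
      nrow(x$markers), " markers\n", sep = "")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("missing dosages: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosages)

marker_index <- function(g, marker) {
  i <- match(marker, g$markers$marker_id)
  if (anyNA(i)) stop("unknown marker_id: ",
                     paste(marker[is.na(i)], collapse = ", "))
  i
}

#' Read genotypes from PLINK text or TSV dosage files
#'
#' Two dialects are supported. `format = "tsv"`: a self-describing table with
#' a header row, first two columns `sample_id` and `status`
#' (case/control or 1/0), remaining columns one marker each holding
#' minor-allele dosages 0/1/2 with `NA` (or any unparseable token) for
#' missing. `format = "ped"`: white-space separated PLINK `.ped` with the
#' companion `.map`; alleles are two tokens per marker, `0` meaning missing;
#' phenotype column uses 1 = control, 2 = case. The minor allele of each
#' marker is determined from the pooled allele frequency, so dosages count
#' the rarer allele.
#'
#' @param path path to the `.tsv` or `.ped` file.
#' @param format `"tsv"` or `"ped"`.
#' @param map path to the `.map` file (defaults to `path` with its extension
#'   replaced); 4 columns chromosome, marker_id, cM, position, with an
#'   optional 5th gene column.
#' @return a [genotype_data] object. Monomorphic markers are retained and
#'   listed in the `monomorphic` attribute.
#' @export
read_genotypes <- function(path, format = c("tsv", "ped"), map = NULL) {
  format <- match.arg(format)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_ped(path, map)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 3L) stop("TSV must have sample_id, status and >=1 marker")
  if (!identical(tolower(names(tab)[1:2]), c("sample_id", "status")))
    stop("first two TSV columns must be sample_id and status")
  status <- tab[[2L]]
  if (all(status %in% c("0", "1"))) status <- as.integer(status)
  dos <- suppressWarnings(
    vapply(tab[-(1:2)], function(col) as.integer(col), integer(nrow(tab))))
  dos[!(dos %in% c(0L, 1L, 2L))] <- NA_integer_
  dos <- matrix(dos, nrow = nrow(tab),
                dimnames = list(tab[[1L]], names(tab)[-(1:2)]))
  g <- genotype_data(dos, status, sample_ids = tab[[1L]])
  flag_monomorphic(g)
}

read_genotypes_ped <- function(path, map = NULL) {
  if (is.null(map)) map <- sub("\\.ped$", ".map", path)
  if (!file.exists(map)) stop("map file not found: ", map)
  mp <- utils::read.table(map, header = FALSE, colClasses = "character")
  if (ncol(mp) < 4L) stop("map needs 4 columns: chr, marker, cM, position")
  markers <- data.frame(marker_id = mp[[2L]],
                        chromosome = as.integer(mp[[1L]]),
                        position = as.integer(mp[[4L]]),
                        gene = if (ncol(mp) >= 5L) mp[[5L]] else NA_character_,
                        stringsAsFactors = FALSE)
  ped <- utils::read.table(path, header = FALSE, colClasses = "character")
  n_mark <- nrow(markers)
  if (ncol(ped) != 6L + 2L * n_mark)
    stop("ped has ", ncol(ped), " columns; expected ", 6L + 2L * n_mark,
         " for ", n_mark, " mapped markers")
  status <- as.integer(ped[[6L]])
  status[!status %in% c(1L, 2L)] <- NA_integer_
  if (anyNA(status)) stop("ped phenotype must be 1 (control) or 2 (case)")
  status <- status - 1L
  dos <- matrix(NA_integer_, nrow(ped), n_mark)
  for (j in seq_len(n_mark)) {
    a1 <- ped[[5L + 2L * j]]
    a2 <- ped[[6L + 2L * j]]
    a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
    ok <- !is.na(a1) & !is.na(a2)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) == 0L) next               # all missing
    counts <- table(factor(c(a1[ok], a2[ok]), levels = alleles))
    minor <- alleles[which.min(counts)]           # rarer allele; ties -> first
    dos[ok, j] <- (a1[ok] == minor) + (a2[ok] == minor)
  }
  colnames(dos) <- markers$marker_id
  g <- genotype_data(dos, status, markers = markers, sample_ids = ped[[2L]])
  flag_monomorphic(g)
}

flag_monomorphic <- function(g) {
  mono <- apply(g$dosages, 2L, function(d) {
    d <- d[!is.na(d)]
    length(unique(d)) <= 1L
  })
  attr(g, "monomorphic") <- g$markers$marker_id[mono]
  if (any(mono))
    warning(sum(mono), " monomorphic marker(s) retained: ",
            paste(utils::head(g$markers$marker_id[mono], 5L), collapse = ", "),
            if (sum(mono) > 5L) ", ..." else "")
  g
}

#' Write genotypes in the TSV dosage dialect
#'
#' @param g a [genotype_data] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  tab <- data.frame(sample_id = g$sample_ids,
                    status = ifelse(g$status == 1L, "case", "control"),
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(g$dosages))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse a genotype to a binary exposure
#'
#' Dominant coding marks carriers (dosage 1 or 2) as exposed; recessive
#' coding marks minor-allele homozygotes (dosage 2) only. Missing dosages
#' stay missing.
#'
#' @param g a [genotype_data] object.
#' @param marker a `marker_id` present in `g`.
#' @param coding `"dominant"` or `"recessive"`.
#' @return integer vector over samples in \{0, 1, NA\}.
#' @export
code_exposure <- function(g, marker, coding = c("dominant", "recessive")) {
  coding <- match.arg(coding)
  d <- g$dosages[, marker_index(g, marker)]
  code_dosage(d, coding)
}

code_dosage <- function(d, coding) {
  if (coding == "dominant") as.integer(d >= 1L) else as.integer(d == 2L)
}

#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' Composite (genotypic) r-squared: the squared Pearson correlation of the
#' two dosage vectors over samples where both are non-missing. With unphased
#' data this is the standard haplotype-free LD measure.
#'
#' @param g a [genotype_data] object.
#' @param marker_a,marker_b marker ids.
#' @return r-squared in [0, 1], or `NA` when either marker is constant on
#'   the pairwise-complete samples (LD undefined, distinct from 0).
#' @export
ld_r2 <- function(g, marker_a, marker_b) {
  i <- marker_index(g, c(marker_a, marker_b))
  a <- g$dosages[, i[1L]]
  b <- g$dosages[, i[2L]]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' LD-prune a ranked list of marker pairs
#'
#' Greedy scan from the most significant pair: a candidate pair is dropped
#' when it is redundant with an already-kept pair, and kept otherwise, until
#' `k` pairs are retained. Two redundancy rules are available. Under the
#' default `"pair"` rule a candidate is redundant only when *both* of its
#' markers are in LD (r-squared > `r2_max`; an identical marker counts) with
#' the two markers of a kept pair under some alignment — so two pairs that
#' share one marker but differ in the other survive together, as in
#' published top-interaction tables. The stricter `"marker"` rule drops a
#' candidate when *either* of its markers is in LD with any marker of a kept
#' pair.
#'
#' @param results `data.frame` with columns `marker1`, `marker2`, already
#'   sorted by significance (best first).
#' @param g the [genotype_data] the markers came from.
#' @param r2_max LD threshold (default 0.2).
#' @param k number of pairs to retain (default 10).
#' @param rule `"pair"` (default) or `"marker"`, see Details.
#' @return the kept subset of `results` (at most `k` rows).
#' @export
prune_top_list <- function(results, g, r2_max = 0.2, k = 10L,
                           rule = c("pair", "marker")) {
  rule <- match.arg(rule)
  stopifnot(all(c("marker1", "marker2") %in% names(results)))
  kept <- integer(0)
  r2 <- function(a, b) {
    if (a == b) return(1)
    v <- ld_r2(g, a, b)
    if (is.na(v)) 0 else v         # undefined LD cannot justify pruning
  }
  for (i in seq_len(nrow(results))) {
    if (length(kept) >= k) break
    b1 <- results$marker1[i]; b2 <- results$marker2[i]
    redundant <- FALSE
    for (j in kept) {
      a1 <- results$marker1[j]; a2 <- results$marker2[j]
      if (rule == "pair") {
        straight <- r2(b1, a1) > r2_max && r2(b2, a2) > r2_max
        crossed  <- r2(b1, a2) > r2_max && r2(b2, a1) > r2_max
        if (straight || crossed) { redundant <- TRUE; break }
      } else {
        if (r2(b1, a1) > r2_max || r2(b1, a2) > r2_max ||
            r2(b2, a1) > r2_max || r2(b2, a2) > r2_max) {
          redundant <- TRUE; break
        }
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  results[kept, , drop = FALSE]
}
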