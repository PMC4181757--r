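#' Joint-exposure table for a marker pair
#'
#' Collapses two markers into binary exposures under a genetic coding and
#' cross-tabulates cases and controls over the four joint-exposure cells
#' `00`, `01`, `10`, `11` (marker 1's exposure first). Complete-case:
#' samples missing either genotype are dropped.
#'
#' @param g a [genotype_data] object.
#' @param pair character vector of two `marker_id`s.
#' @param coding `"dominant"` or `"recessive"` (applied to both markers).
#' @return an object of class `pair_table`: named numeric vectors `cases`
#'   and `controls` over cells `00/01/10/11`, the `coding`, `recoding`
#'   applied (initially `"identity"`), `n_complete`, `degenerate` flag (an
#'   empty case or control stratum), and the `pair` of marker ids.
#' @export
build_pair_table <- function(g, pair, coding = c("dominant", "recessive")) {
  coding <- match.arg(coding)
  stopifnot(length(pair) == 2L)
  e1 <- code_exposure(g, pair[1L], coding)
  e2 <- code_exposure(g, pair[2L], coding)
  ok <- !is.na(e1) & !is.na(e2)
  cell <- factor(paste0(e1[ok], e2[ok]), levels = c("00", "01", "10", "11"))
  y <- g$status[ok]
  cases <- as.numeric(table(cell[y == 1L]))
  controls <- as.numeric(table(cell[y == 0L]))
  pair_table_from_counts(cases, controls, coding = coding, pair = pair)
}

#' Build a pair table directly from cell counts
#'
#' Used for tables whose counts are given (e.g. published per-pair
#' case/control counts) rather than derived from raw genotypes.
#'
#' @param cases,controls numeric vectors of length 4, counts in cells
#'   `00, 01, 10, 11` (marker 1's exposure first).
#' @param coding coding label to record.
#' @param pair optional marker ids.
#' @param recoding relabelling already applied (default `"identity"`).
#' @return a `pair_table` (see [build_pair_table()]).
#' @export
pair_table_from_counts <- function(cases, controls, coding = "dominant",
                                   pair = c(NA_character_, NA_character_),
                                   recoding = "identity") {
  stopifnot(length(cases) == 4L, length(controls) == 4L,
            all(cases >= 0), all(controls >= 0))
  cells <- c("00", "01", "10", "11")
  cases <- stats::setNames(as.numeric(cases), cells)
  controls <- stats::setNames(as.numeric(controls), cells)
  structure(list(cases = cases, controls = controls, coding = coding,
                 recoding = recoding, n_complete = sum(cases) + sum(controls),
                 degenerate = sum(cases) == 0 || sum(controls) == 0,
                 pair = pair),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat("pair_table (", x$coding, ", recoding: ", x$recoding, ")",
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  if (!anyNA(x$pair)) cat("pair:", x$pair[1L], "x", x$pair[2L], "\n")
  print(rbind(cases = x$cases, controls = x$controls))
  invisible(x)
}

# The four cell-relabelling schemes. Entry i of a permutation gives the old
# cell whose counts land in new cell i (cells ordered 00, 01, 10, 11):
#   identity  —
#   flipA     exposure of marker 1 inverted: new 00 takes old 10
#   swap_flip markers swapped, one exposure inverted: new 00 takes old 01
#   flip_both both exposures inverted: new 00 takes old 11
# Each permutation is a genuine exposure relabelling, so the new reference
# cell can be any of the four old cells.
recoding_schemes <- list(identity = 1:4, flipA = c(3L, 4L, 1L, 2L),
                         swap_flip = c(2L, 4L, 1L, 3L),
                         flip_both = c(4L, 3L, 2L, 1L))

# tie-break preference over candidate reference cells (old 00, 10, 01, 11)
# and, indexed by cell, the scheme that moves that cell into the new 00 slot
reference_preference <- c(1L, 3L, 2L, 4L)
scheme_for_cell <- c("identity", "swap_flip", "flipA", "flip_both")
# scheme_for_cell[2] handles old 01 (swap_flip), [3] old 10 (flipA)

apply_recoding <- function(t, scheme) {
  perm <- recoding_schemes[[scheme]]
  out <- t
  out$cases <- stats::setNames(t$cases[perm], names(t$cases))
  out$controls <- stats::setNames(t$controls[perm], names(t$controls))
  out$recoding <- scheme
  out
}

single_exposure_ors <- function(cases, controls) {
  or <- function(i) (cases[i] * controls[1L]) / (controls[i] * cases[1L])
  c(or01 = unname(or(2L)), or10 = unname(or(3L)))
}

#' Recode preventive factors so both single exposures confer risk
#'
#' Additive-scale interaction measures (RERI, AP) presume that each single
#' exposure is risk-conferring relative to the joint reference cell. This
#' relabels the four joint-exposure cells by one of four exposure-inverting
#' schemes — identity, inverting marker 1's exposure, swapping the markers
#' with one exposure inverted, or inverting both exposures — so that the
#' cell with the *lowest* case:control odds becomes the new reference `00`.
#' All three odds ratios versus the new reference are then at least 1 by
#' construction, which is the required postcondition on the two
#' single-exposure odds ratios. Ties are broken by a fixed preference order
#' (keep `00`, then prefer old `10`, `01`, `11`), making the choice
#' deterministic. Counts never change; only the cell labels move. Recoding
#' an already-recoded table is a no-op (idempotent).
#'
#' @param t a non-degenerate `pair_table`.
#' @return the relabelled `pair_table`, with `recoding` set to the scheme
#'   used and a logical `recoding_failed` flag (`TRUE` when empty cells
#'   leave a single-exposure odds ratio undefined or below 1).
#' @export
recode_preventive <- function(t) {
  stopifnot(inherits(t, "pair_table"))
  if (t$degenerate) stop("cannot recode a degenerate table")
  odds <- t$cases / t$controls
  odds[t$cases == 0 & t$controls == 0] <- Inf   # empty cell: never reference
  ref <- 1L
  for (cell in reference_preference)
    if (odds[cell] < odds[ref]) ref <- cell
  rt <- apply_recoding(t, scheme_for_cell[ref])
  if (ref == 1L) rt$recoding <- t$recoding      # no-op keeps provenance
  ors <- single_exposure_ors(rt$cases, rt$controls)
  rt$recoding_failed <- anyNA(ors) || any(ors < 1)
  rt
}
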