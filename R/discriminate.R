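# Subfamily-discriminating positions, subfamily-specific insertions,
# reference-numbering mapping and pairwise identities.

#' Detect subfamily-discriminating alignment positions
#'
#' Scans every alignment column for the strict conservation criterion
#' used to characterise paralog subfunctionalisation: a column is
#' discriminating iff every member of subfamily A carries one identical
#' residue, every member of subfamily B carries one identical residue,
#' the two residues differ, and neither is a gap.  Ambiguity codes
#' (X, B, Z, J) never count as conserved, and a column containing any
#' gap within a subfamily is not perfectly conserved for that family, so
#' subfamily-specific insertions (all-gap in one family) are excluded
#' here and reported by [detect_insertions()] instead.
#'
#' @param aln A [labeled_alignment()].
#' @return A data frame of class `discriminating_positions` with one row
#'   per detected column, sorted by column: `column` (1-based alignment
#'   column), `ref_position` (reference numbering via
#'   [map_to_reference()], `NA` if the alignment has no reference),
#'   `residue_a`, `residue_b` (the residues fixed in the alphabetically
#'   first and second subfamily respectively; the names are carried in
#'   attributes `subfamily_a` / `subfamily_b`).
#' @export
detect_discriminating_positions <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  mat <- aln_matrix(aln)
  fam_a <- aln$subfamilies[1]
  fam_b <- aln$subfamilies[2]
  rows_a <- mat[subfamily_ids(aln, fam_a), , drop = FALSE]
  rows_b <- mat[subfamily_ids(aln, fam_b), , drop = FALSE]

  fixed_residue <- function(col) {
    # The single residue a subfamily is fixed to at this column, or NA.
    u <- unique(col)
    if (length(u) == 1L && u %in% AA_STANDARD) u else NA_character_
  }
  res_a <- apply(rows_a, 2L, fixed_residue)
  res_b <- apply(rows_b, 2L, fixed_residue)
  hit <- !is.na(res_a) & !is.na(res_b) & res_a != res_b
  cols <- which(hit)
  ref <- if (is.null(aln$reference_id)) rep(NA_character_, length(cols))
         else map_to_reference(aln, cols)
  out <- data.frame(column = cols,
                    ref_position = ref,
                    residue_a = unname(res_a[cols]),
                    residue_b = unname(res_b[cols]),
                    stringsAsFactors = FALSE)
  attr(out, "subfamily_a") <- fam_a
  attr(out, "subfamily_b") <- fam_b
  class(out) <- c("discriminating_positions", "data.frame")
  out
}

#' Detect subfamily-specific insertions
#'
#' Finds maximal runs of alignment columns that are all-gap in one
#' subfamily and majority-residue (more than half the members non-gap)
#' in the other — the signature of a subfamily-specific insertion such
#' as the two-residue RT insert of mtRF1 (between reference positions
#' Thr-115 and Gly-116) or its three-residue GLS insert directly after
#' the PXT motif.
#'
#' @param aln A [labeled_alignment()] with a reference sequence (needed
#'   to anchor each insert in reference numbering).
#' @return Data frame with one row per insertion event: `subfamily`
#'   (the family carrying the insert), `anchor_ref_position` (reference
#'   position immediately preceding the insert; 0 if the insert precedes
#'   the first reference residue), `length` (residue count),
#'   `consensus` (per-column majority residue of the carrying family,
#'   alphabetical tie-break), `start_column` (1-based first alignment
#'   column of the run).
#' @export
detect_insertions <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  if (is.null(aln$reference_id))
    stop_mitorf("insertion detection requires a reference sequence",
                "precondition_error")
  mat <- aln_matrix(aln)
  ref_chars <- split1(aln$seqs[[aln$reference_id]])
  ref_count <- cumsum(!is_gap(ref_chars))

  events <- list()
  for (i in 1:2) {
    carrier <- aln$subfamilies[i]
    other <- aln$subfamilies[3 - i]
    rows_c <- mat[subfamily_ids(aln, carrier), , drop = FALSE]
    rows_o <- mat[subfamily_ids(aln, other), , drop = FALSE]
    all_gap_other <- apply(rows_o, 2L, function(col) all(is_gap(col)))
    majority_carrier <- colMeans(apply(rows_c, 2L, is_gap)) < 0.5
    flag <- all_gap_other & majority_carrier
    if (!any(flag)) next
    runs <- rle(flag)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      cols <- starts[k]:ends[k]
      consensus <- paste(vapply(cols, function(j) {
        res <- rows_c[, j]
        res <- res[!is_gap(res)]
        tab <- sort(table(res), decreasing = TRUE)
        names(tab)[tab == max(tab)][1]   # alphabetical tie-break via table order
      }, character(1)), collapse = "")
      anchor <- if (starts[k] == 1L) 0L else ref_count[starts[k] - 1L]
      events[[length(events) + 1L]] <- data.frame(
        subfamily = carrier, anchor_ref_position = as.integer(anchor),
        length = length(cols), consensus = consensus,
        start_column = starts[k], stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0L)
    return(data.frame(subfamily = character(), anchor_ref_position = integer(),
                      length = integer(), consensus = character(),
                      start_column = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, events)
  out[order(out$start_column), , drop = FALSE]
}

#' Map alignment columns to reference numbering
#'
#' Converts 1-based alignment columns to positions in the ungapped
#' numbering reference (e.g. the *T. thermophilus* RF1 sequence).  When
#' the reference carries a residue at the column the result is the
#' 1-based count of non-gap reference characters up to and including it
#' (`"115"`); when the column falls in a reference gap the result is
#' `"anchor+offset"` (`"115+1"` for the first inserted column after
#' reference position 115).
#'
#' @param aln A [labeled_alignment()] with a reference sequence.
#' @param column Integer vector of 1-based alignment columns.
#' @return Character vector of reference positions, same length as
#'   `column`.  Strictly non-decreasing in the column index.
#' @export
map_to_reference <- function(aln, column) {
  stopifnot(inherits(aln, "labeled_alignment"))
  if (is.null(aln$reference_id))
    stop_mitorf("alignment has no reference sequence", "precondition_error")
  ref_chars <- split1(aln$seqs[[aln$reference_id]])
  n <- length(ref_chars)
  column <- as.integer(column)
  if (any(column < 1L | column > n))
    stop_mitorf(sprintf("column out of range 1..%d", n), "bounds_error")
  gap <- is_gap(ref_chars)
  count <- cumsum(!gap)
  vapply(column, function(j) {
    if (!gap[j]) as.character(count[j])
    else {
      anchor <- count[j]               # last reference position before j
      # offset: how many gap columns since that reference residue
      run_start <- j
      while (run_start > 1L && gap[run_start - 1L]) run_start <- run_start - 1L
      sprintf("%d+%d", anchor, j - run_start + 1L)
    }
  }, character(1))
}

#' Percent identity between two aligned sequences
#'
#' Identity is computed over jointly non-gap columns only:
#' `100 * identical / jointly_non_gap`, rounded to the nearest integer.
#' Symmetric in its two sequence arguments.
#'
#' @param aln A [labeled_alignment()].
#' @param id_a,id_b Sequence ids present in the alignment.
#' @return Integer percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(aln, id_a, id_b) {
  stopifnot(inherits(aln, "labeled_alignment"))
  for (id in c(id_a, id_b))
    if (!id %in% names(aln$seqs))
      stop_mitorf(sprintf("sequence '%s' not in alignment", id),
                  "label_error")
  a <- split1(aln$seqs[[id_a]])
  b <- split1(aln$seqs[[id_b]])
  joint <- !is_gap(a) & !is_gap(b)
  if (!any(joint))
    stop_mitorf("no jointly aligned (non-gap) columns", "undefined_identity")
  round(100 * sum(a[joint] == b[joint]) / sum(joint))
}
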