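# Deterministic synthetic two-subfamily alignments with planted
# discriminating columns and planted subfamily-specific insertions.

#' Recipe for a synthetic two-subfamily alignment
#'
#' Describes a labeled alignment with a known (planted) ground truth:
#' `k_discriminating` columns satisfying the strict discrimination
#' criterion, optional subfamily-specific insertion blocks, and a
#' gapless numbering reference carrying no subfamily label.  The planted
#' truth is returned alongside the alignment by [gen_alignment()] as a
#' machine-readable manifest, so detectors can be tested against exactly
#' what was planted rather than against re-derived truth.
#'
#' @param n_per_subfamily Members per subfamily (>= 2).
#' @param length Total alignment columns (reference length plus all
#'   insertion columns).
#' @param k_discriminating Number of planted discriminating columns.
#' @param insertions List of insertion specs, each a list with `anchor`
#'   (reference position immediately preceding the insert), `length`
#'   (residue count) and `subfamily` (the carrying family); optional
#'   `consensus` string of that length.
#' @param background_conservation Probability that a background column
#'   is fully conserved across both subfamilies; the remaining
#'   background columns receive within-family substitutions that break
#'   perfect conservation, so exactly `k_discriminating` columns meet
#'   the criterion.
#' @param subfamilies Character vector of the two subfamily names.
#' @param reference_id Id given to the reference sequence.
#' @param positions Optional integer vector (length `k_discriminating`)
#'   of reference positions at which to plant the discriminating
#'   columns; drawn uniformly at random when `NULL`.
#' @param residue_pairs Optional named list (names = reference
#'   positions) of length-2 character vectors `c(residue_A, residue_B)`
#'   fixing the planted residues at specific positions.
#' @param seed Integer seed; identical recipe and seed give
#'   byte-identical output files.
#' @return An object of class `alignment_recipe`.
#' @export
alignment_recipe <- function(n_per_subfamily = 5, length = 100,
                             k_discriminating = 0, insertions = list(),
                             background_conservation = 0.5,
                             subfamilies = c("famA", "famB"),
                             reference_id = "REF",
                             positions = NULL, residue_pairs = NULL,
                             seed = 1) {
  r <- structure(list(n_per_subfamily = as.integer(n_per_subfamily),
                      length = as.integer(length),
                      k_discriminating = as.integer(k_discriminating),
                      insertions = insertions,
                      background_conservation = background_conservation,
                      subfamilies = sort(as.character(subfamilies)),
                      reference_id = as.character(reference_id),
                      positions = positions,
                      residue_pairs = residue_pairs,
                      seed = as.integer(seed)),
                 class = "alignment_recipe")
  validate_alignment_recipe(r)
  r
}

validate_alignment_recipe <- function(r) {
  errs <- character()
  if (r$n_per_subfamily < 2L)
    errs <- c(errs, "n_per_subfamily must be >= 2")
  if (length(r$subfamilies) != 2L || anyDuplicated(r$subfamilies))
    errs <- c(errs, "exactly two distinct subfamily names required")
  if (r$background_conservation < 0 || r$background_conservation > 1)
    errs <- c(errs, "background_conservation must be in [0, 1]")
  ins_len <- sum(vapply(r$insertions, function(i) as.integer(i$length),
                        integer(1)))
  n_ref <- r$length - ins_len
  if (r$k_discriminating + ins_len > r$length)
    errs <- c(errs, "k_discriminating + insertion columns exceed length")
  if (r$k_discriminating > n_ref)
    errs <- c(errs, "more discriminating columns than reference positions")
  for (ins in r$insertions) {
    if (!all(c("anchor", "length", "subfamily") %in% names(ins))) {
      errs <- c(errs, "insertion spec needs anchor, length, subfamily")
      next
    }
    if (ins$length < 1L) errs <- c(errs, "insertion length must be >= 1")
    if (ins$anchor < 0L || ins$anchor > n_ref)
      errs <- c(errs, sprintf("insertion anchor %s outside reference 0..%d",
                              ins$anchor, n_ref))
    if (!ins$subfamily %in% r$subfamilies)
      errs <- c(errs, sprintf("unknown insertion subfamily '%s'",
                              ins$subfamily))
    if (!is.null(ins$consensus) && nchar(ins$consensus) != ins$length)
      errs <- c(errs, "insertion consensus length mismatch")
  }
  anchors <- vapply(r$insertions, function(i) as.integer(i$anchor), integer(1))
  if (anyDuplicated(anchors))
    errs <- c(errs, "insertion anchors must be distinct")
  if (!is.null(r$positions)) {
    if (length(r$positions) != r$k_discriminating)
      errs <- c(errs, "positions must have length k_discriminating")
    if (anyDuplicated(r$positions))
      errs <- c(errs, "planted positions must be distinct")
    if (length(r$positions) && (min(r$positions) < 1L || max(r$positions) > n_ref))
      errs <- c(errs, sprintf("planted positions outside reference 1..%d", n_ref))
  }
  if (length(errs) > 0L)
    stop_mitorf(paste(errs, collapse = "; "), "validation_error")
  invisible(r)
}

#' Recipe emulating the 17-species mtRF1/mtRF1a study alignment
#'
#' A study-scale instance of [alignment_recipe()]: 17 members per
#' subfamily over a 360-residue reference (the *T. thermophilus* RF1
#' length scale), 24 planted discriminating positions distributed as in
#' the mtRF1/mtRF1a comparison — 20 in the codon-recognition domain 2
#' (including Glu-119→Ile, Thr-186→Val of the PXT motif and
#' Ser-195→Gly), two in the switch loop (Arg-298→Gln, Lys-301→Arg), one
#' in domain 1 and one in domain 3 — plus the two mtRF1-specific
#' insertions: the RT insert between Thr-115 and Gly-116 and the GLS
#' insert directly after the PXT motif.
#'
#' @param seed Integer seed.
#' @return An `alignment_recipe`.
#' @export
study_alignment_recipe <- function(seed = 1) {
  domain2 <- c(111, 114, 117, 119, 122, 150, 154, 158, 162, 166,
               170, 174, 178, 182, 186, 188, 190, 192, 195, 200)
  positions <- c(45,            # domain 1
                 domain2,       # domain 2 (codon recognition)
                 240,           # domain 3 (GGQ side)
                 298, 301)      # switch loop
  # first residue = mtRF1 subfamily, second = mtRF1a subfamily
  pairs <- list(`119` = c("I", "E"),   # Glu-119 -> Ile
                `186` = c("V", "T"),   # PXT Thr-186 -> Val
                `195` = c("G", "S"),   # Ser-195 -> Gly
                `298` = c("Q", "R"),   # switch loop Arg-298 -> Gln
                `301` = c("R", "K"))   # switch loop Lys-301 -> Arg
  alignment_recipe(
    n_per_subfamily = 17, length = 365, k_discriminating = 24,
    insertions = list(
      list(anchor = 115, length = 2, subfamily = "mtRF1", consensus = "RT"),
      list(anchor = 186, length = 3, subfamily = "mtRF1", consensus = "GLS")),
    background_conservation = 0.5,
    subfamilies = c("mtRF1", "mtRF1a"),
    reference_id = "TthRF1",
    positions = positions, residue_pairs = pairs, seed = seed)
}

#' Generate a synthetic labeled alignment with planted ground truth
#'
#' Builds the alignment described by an [alignment_recipe()].  Exactly
#' `k_discriminating` columns satisfy the discrimination criterion (all
#' other columns are either fully conserved across both families or
#' carry a within-family substitution that breaks perfect conservation);
#' insertion blocks are all-gap in the non-carrying subfamily and in the
#' reference.  Identical recipe and seed produce byte-identical files.
#'
#' @param recipe An `alignment_recipe`.
#' @param dir Optional output directory; when given, writes
#'   `alignment.fasta`, `alignment.aln` (Clustal), `labels.tsv` and
#'   `manifest.json` there.
#' @return List with elements `alignment` (a [labeled_alignment()]) and
#'   `manifest` (planted truth: discriminating columns with residues,
#'   insertion blocks, seed).
#' @export
gen_alignment <- function(recipe, dir = NULL) {
  validate_alignment_recipe(recipe)
  fams <- recipe$subfamilies
  n <- recipe$n_per_subfamily
  ins <- recipe$insertions
  ins_len <- sum(vapply(ins, function(i) as.integer(i$length), integer(1)))
  n_ref <- recipe$length - ins_len

  # column index of each reference position, given the insert blocks
  anchors <- vapply(ins, function(i) as.integer(i$anchor), integer(1))
  lens <- vapply(ins, function(i) as.integer(i$length), integer(1))
  col_of_ref <- function(p) p + sum(lens[anchors < p])

  with_seed(recipe$seed, {
    planted_ref <- recipe$positions %||%
      sort(sample.int(n_ref, recipe$k_discriminating))
    planted_ref <- sort(as.integer(planted_ref))

    ids_a <- sprintf("%s_%02d", fams[1], seq_len(n))
    ids_b <- sprintf("%s_%02d", fams[2], seq_len(n))
    ids <- c(ids_a, ids_b, recipe$reference_id)
    mat <- matrix("-", nrow = length(ids), ncol = recipe$length,
                  dimnames = list(ids, NULL))

    planted <- data.frame(ref_position = integer(), column = integer(),
                          residue_a = character(), residue_b = character(),
                          stringsAsFactors = FALSE)
    for (p in seq_len(n_ref)) {
      j <- col_of_ref(p)
      if (p %in% planted_ref) {
        pair <- recipe$residue_pairs[[as.character(p)]] %||%
          sample(AA_STANDARD, 2L)
        mat[ids_a, j] <- pair[1]
        mat[ids_b, j] <- pair[2]
        mat[recipe$reference_id, j] <- pair[2]
        planted <- rbind(planted, data.frame(
          ref_position = p, column = j,
          residue_a = pair[1], residue_b = pair[2],
          stringsAsFactors = FALSE))
      } else if (stats::runif(1) < recipe$background_conservation) {
        x <- sample(AA_STANDARD, 1L)
        mat[, j] <- x
      } else {
        # break perfect conservation inside each family so the column
        # can never satisfy the criterion
        x <- sample(AA_STANDARD, 1L)
        mat[, j] <- x
        mat[sample(ids_a, 1L), j] <- sample(setdiff(AA_STANDARD, x), 1L)
        mat[sample(ids_b, 1L), j] <- sample(setdiff(AA_STANDARD, x), 1L)
      }
    }

    ins_manifest <- NULL
    for (k in seq_along(ins)) {
      start <- col_of_ref(anchors[k]) + 1L
      cols <- seq.int(start, length.out = lens[k])
      carrier_ids <- if (ins[[k]]$subfamily == fams[1]) ids_a else ids_b
      cons <- ins[[k]]$consensus %||%
        paste(sample(AA_STANDARD, lens[k], replace = TRUE), collapse = "")
      cons_chars <- split1(cons)
      for (m in seq_along(cols)) mat[carrier_ids, cols[m]] <- cons_chars[m]
      ins_manifest <- rbind(ins_manifest, data.frame(
        subfamily = ins[[k]]$subfamily,
        anchor_ref_position = anchors[k], length = lens[k],
        consensus = cons, start_column = start, stringsAsFactors = FALSE))
    }

    seqs <- apply(mat, 1L, paste, collapse = "")
    labels <- stats::setNames(rep(fams, each = n), c(ids_a, ids_b))
    aln <- labeled_alignment(seqs, labels,
                             reference_id = recipe$reference_id)
    manifest <- list(
      generator = "gen_alignment", seed = recipe$seed,
      subfamilies = fams, n_per_subfamily = n, length = recipe$length,
      k_discriminating = recipe$k_discriminating,
      background_conservation = recipe$background_conservation,
      discriminating = planted,
      insertions = ins_manifest %||% list())

    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_alignment_fasta(aln, file.path(dir, "alignment.fasta"))
      write_alignment_clustal(aln, file.path(dir, "alignment.aln"))
      write_label_map(aln, file.path(dir, "labels.tsv"))
      write_json_file(manifest, file.path(dir, "manifest.json"))
    }
    list(alignment = aln, manifest = manifest)
  })
}
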