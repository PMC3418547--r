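# Labeled two-subfamily alignments: container, readers, writers.

#' Construct a labeled two-subfamily alignment
#'
#' A labeled alignment holds aligned protein sequences partitioned into
#' exactly two named subfamilies (for example `mtRF1` and `mtRF1a`), plus
#' an optional reference sequence (typically *Thermus thermophilus* RF1)
#' used only for residue numbering; the reference belongs to neither
#' subfamily.
#'
#' @param seqs Named character vector of aligned sequences (equal length;
#'   `-` and `.` read as gaps; case-insensitive).
#' @param labels Named character vector mapping sequence id to subfamily
#'   name.  Exactly two distinct subfamily names must occur, each with at
#'   least two members.  The reference id, if any, must not be labeled.
#' @param reference_id Optional id of the numbering reference sequence.
#' @return An object of class `labeled_alignment` with elements `seqs`
#'   (upper-cased aligned strings), `labels`, `subfamilies` (the two
#'   names, sorted) and `reference_id`.
#' @seealso [read_labeled_alignment()] to build one from files,
#'   [gen_alignment()] to simulate one.
#' @export
labeled_alignment <- function(seqs, labels, reference_id = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_mitorf("sequences must have unique names", "format_error")
  seqs <- toupper(vapply(seqs, as.character, character(1)))
  seqs <- chartr(".", "-", seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop_mitorf("aligned sequences differ in length", "format_error")
  if (!is.null(reference_id)) {
    if (!reference_id %in% names(seqs))
      stop_mitorf(sprintf("reference id '%s' not present in alignment",
                          reference_id), "label_error")
    if (reference_id %in% names(labels))
      stop_mitorf("reference sequence must not carry a subfamily label",
                  "label_error")
  }
  member_ids <- setdiff(names(seqs), reference_id)
  missing <- setdiff(member_ids, names(labels))
  if (length(missing) > 0L)
    stop_mitorf(sprintf("unlabeled record(s): %s",
                        paste(missing, collapse = ", ")), "label_error")
  labels <- labels[member_ids]
  fams <- sort(unique(unname(labels)))
  if (length(fams) != 2L)
    stop_mitorf(sprintf("expected exactly 2 subfamilies, found %d",
                        length(fams)), "cardinality_error")
  sizes <- table(factor(labels, levels = fams))
  if (any(sizes < 2L))
    stop_mitorf("each subfamily needs at least 2 members",
                "cardinality_error")
  structure(list(seqs = seqs, labels = labels, subfamilies = fams,
                 reference_id = reference_id),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  sizes <- table(factor(x$labels, levels = x$subfamilies))
  cat("Labeled alignment:", length(x$seqs), "sequences x",
      nchar(x$seqs[[1]]), "columns\n")
  cat("  subfamilies:",
      paste(sprintf("%s (n=%d)", x$subfamilies, as.integer(sizes)),
            collapse = ", "), "\n")
  cat("  reference:", x$reference_id %||% "<none>", "\n")
  invisible(x)
}

# Alignment as a character matrix (rows = sequences, columns = alignment
# columns).
aln_matrix <- function(aln) {
  do.call(rbind, lapply(aln$seqs, split1))
}

subfamily_ids <- function(aln, fam) names(aln$labels)[aln$labels == fam]

#' Read an alignment plus subfamily labels from files
#'
#' Reads an aligned FASTA or Clustal file together with a two-column
#' label map (TSV: id, subfamily) and assembles a [labeled_alignment()].
#' The two renderings of the same alignment produce identical in-memory
#' objects.
#'
#' @param alignment_file Path to the aligned FASTA or Clustal file.
#' @param label_file Path to a two-column TSV (no header) mapping
#'   sequence id to subfamily name.
#' @param reference_id Optional id of the numbering reference.
#' @param format `"auto"` (sniff the first line), `"fasta"` or
#'   `"clustal"`.
#' @return A `labeled_alignment`.
#' @export
read_labeled_alignment <- function(alignment_file, label_file,
                                   reference_id = NULL,
                                   format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(alignment_file, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  seqs <- if (format == "fasta") {
    x <- Biostrings::readAAStringSet(alignment_file)
    stats::setNames(as.character(x), names(x))
  } else {
    m <- Biostrings::readAAMultipleAlignment(alignment_file,
                                             format = "clustal")
    x <- Biostrings::unmasked(m)
    stats::setNames(as.character(x), names(x))
  }
  lab <- utils::read.table(label_file, sep = "\t", header = FALSE,
                           colClasses = "character",
                           col.names = c("id", "subfamily"))
  labels <- stats::setNames(lab$subfamily, lab$id)
  labeled_alignment(seqs, labels, reference_id = reference_id)
}

#' Write an alignment to aligned FASTA
#'
#' @param aln A `labeled_alignment`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln$seqs), path)
  invisible(path)
}

#' Write an alignment in Clustal format
#'
#' Emits standard Clustal blocks (60 columns per block, padded names,
#' conservation line left blank) readable by
#' [Biostrings::readAAMultipleAlignment()].
#'
#' @inheritParams write_alignment_fasta
#' @return The path, invisibly.
#' @export
write_alignment_clustal <- function(aln, path) {
  ids <- names(aln$seqs)
  width <- max(nchar(ids)) + 4L
  ncol_aln <- nchar(aln$seqs[[1]])
  lines <- c("CLUSTAL W multiple sequence alignment", "", "")
  for (start in seq(1L, ncol_aln, by = 60L)) {
    end <- min(start + 59L, ncol_aln)
    block <- vapply(seq_along(ids), function(i) {
      paste0(formatC(ids[i], width = -width),
             substr(aln$seqs[[i]], start, end))
    }, character(1))
    cons <- strrep(" ", width + (end - start + 1L))
    lines <- c(lines, block, cons, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the subfamily label map as TSV
#'
#' @inheritParams write_alignment_fasta
#' @param path Output TSV path (two columns: id, subfamily; no header).
#' @return The path, invisibly.
#' @export
write_label_map <- function(aln, path) {
  utils::write.table(data.frame(id = names(aln$labels),
                                subfamily = unname(aln$labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
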