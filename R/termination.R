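# Terminability of mitochondrial protein-coding genes by mtRF1a:
# standard stops, U-preceded AGA/AGG minus-one frameshift termination,
# incomplete-stop polyadenylation completion.

#' Classify the terminus of a mitochondrial protein-coding gene
#'
#' Applies the vertebrate mitochondrial terminability rules (genetic
#' code table 2, where UGA codes tryptophan and the only standard stops
#' are UAA and UAG) in fixed decision order:
#'
#' 1. in-frame terminal codon UAA or UAG — `standard`;
#' 2. terminal codon AGA or AGG with a U immediately 5' of it — a
#'    one-nucleotide backward (-1) shift presents UAG in the A-site:
#'    `frameshift_terminable`;
#' 3. (`polyA_completion` on) coding length mod 3 of 1 or 2 with
#'    annotated terminus U or UA — polyadenylation completes it to UAA:
#'    `polyA_completed`;
#' 4. otherwise `not_terminable`.
#'
#' Exactly one class per gene.  Sequences are stored as DNA (T) and
#' reported as RNA (U).
#'
#' @param gene A `mito_gene` (from [read_mitogenome()]) or any list
#'   with `name` and spliced coding sequence `cds`; the coding sequence
#'   must be at least 4 nucleotides so the base preceding the terminal
#'   codon is readable.
#' @param polyA_completion Apply rule 3 (default TRUE; turn off for
#'   strict annotated-terminus mode).
#' @return A list of class `termination_call`: `gene`, `strand`,
#'   `terminal_codon` (RNA), `preceding_base` (RNA), `class`, `note`.
#' @export
classify_termination <- function(gene, polyA_completion = TRUE) {
  cds <- toupper(gene$cds)
  n <- nchar(cds)
  if (n < 4L)
    stop_mitorf(sprintf("coding sequence of '%s' too short to read terminus",
                        gene$name %||% "?"), "format_error")
  if (grepl("[^ACGT]", cds))
    stop_mitorf(sprintf("terminus of '%s' unreadable (non-ACGT)",
                        gene$name %||% "?"), "format_error")
  phase <- n %% 3L
  terminal <- substr(cds, n - 2L, n)
  preceding <- substr(cds, n - 3L, n - 3L)
  term_rna <- dna_to_rna(terminal)
  prec_rna <- dna_to_rna(preceding)

  if (phase == 0L && terminal %in% c("TAA", "TAG")) {
    cls <- "standard"; note <- "standard mitochondrial stop codon"
  } else if (phase == 0L && terminal %in% c("AGA", "AGG") &&
             preceding == "T") {
    cls <- "frameshift_terminable"
    note <- sprintf("-1 frameshift presents UAG (U + %s)", term_rna)
  } else if (polyA_completion && phase %in% c(1L, 2L) &&
             ((phase == 1L && substr(cds, n, n) == "T") ||
              (phase == 2L && substr(cds, n - 1L, n) == "TA"))) {
    stub <- dna_to_rna(substr(cds, n - phase + 1L, n))
    cls <- "polyA_completed"
    note <- sprintf("incomplete stop %s completed to UAA by polyadenylation",
                    stub)
    term_rna <- "UAA"
    prec_rna <- dna_to_rna(substr(cds, n - phase, n - phase))
  } else {
    cls <- "not_terminable"
    note <- "terminus not recognizable by mtRF1a"
  }
  structure(list(gene = gene$name %||% NA_character_,
                 strand = gene$strand %||% NA_character_,
                 terminal_codon = term_rna, preceding_base = prec_rna,
                 class = cls, note = note),
            class = "termination_call")
}

#' Scan a mitogenome for mtRF1a terminability
#'
#' Classifies every protein-coding gene with [classify_termination()]
#' and reports whether translation of all of them can be terminated by
#' mtRF1a (directly, via a -1 frameshift, or after polyadenylation
#' completion): the genome verdict is the AND over genes of
#' `class != "not_terminable"`.
#'
#' @param genome A `mitogenome` from [read_mitogenome()].
#' @param polyA_completion Passed to [classify_termination()].
#' @return List of class `termination_scan`: `calls` (one data-frame
#'   row per gene: gene, strand, terminal_codon, preceding_base, class,
#'   note), `all_terminable` (logical verdict), `n_genes`.
#' @export
scan_genome <- function(genome, polyA_completion = TRUE) {
  if (length(genome$genes) == 0L)
    stop_mitorf("genome has no CDS features", "precondition_error")
  calls <- lapply(genome$genes, classify_termination,
                  polyA_completion = polyA_completion)
  df <- do.call(rbind, lapply(calls, function(cl)
    data.frame(gene = cl$gene, strand = cl$strand,
               terminal_codon = cl$terminal_codon,
               preceding_base = cl$preceding_base,
               class = cl$class, note = cl$note,
               stringsAsFactors = FALSE)))
  structure(list(calls = df,
                 all_terminable = all(df$class != "not_terminable"),
                 n_genes = nrow(df)),
            class = "termination_scan")
}

#' @export
print.termination_scan <- function(x, ...) {
  cat(sprintf("Termination scan: %d CDS, %s\n", x$n_genes,
              if (x$all_terminable) "all terminable by mtRF1a"
              else "NOT all terminable by mtRF1a"))
  tab <- table(x$calls$class)
  for (cl in names(tab)) cat(sprintf("  %-22s %d\n", cl, tab[[cl]]))
  invisible(x)
}
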