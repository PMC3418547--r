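#!/usr/bin/env Rscript

# Helper to retrieve the external inputs needed by the published-number
# checks in tests/testthat/test-acceptance.R.  Requires network access;
# nothing in the package fetches implicitly.  Files land in
# inst/extdata/fetched/ (never committed: they are third-party data).
#
# Inputs assembled here:
#
#   mtrf_family.aln.fasta / mtrf_family_labels.tsv
#     mtRF1 and mtRF1a orthologs from the 17 vertebrate species
#     (Tetraodon nigroviridis, Platichthys flesus, Danio rerio, Gallus
#     gallus, Taeniopygia guttata, Ornithorhynchus anatinus, Monodelphis
#     domestica, Mus musculus, Rattus norvegicus, Homo sapiens, Pan
#     troglodytes, Macaca mulatta, Ailuropoda melanoleuca, Bos taurus,
#     Canis familiaris, Equus caballus, Sus scrofa), collected from
#     RefSeq starting from the human seeds below, aligned together with
#     the T. thermophilus RF1 reference using mafft
#     (mafft --auto in.fasta > mtrf_family.aln.fasta, FASTA output via
#     --anysymbol; label file: two-column TSV id<TAB>subfamily with
#     subfamily mtRF1 or mtRF1a, reference id TthRF1 unlabeled).
#
#   identity_trio.aln.fasta / identity_trio_labels.tsv
#     human mtRF1 (UniProt O75570), human mtRF1a (UniProt Q9UGC7) and
#     T. thermophilus RF1, aligned with mafft; the label file assigns
#     the two human paralogs to their subfamilies (plus two padding
#     orthologs per family if strict two-member subfamilies are
#     enforced) and leaves TthRF1 as reference.
#
#   3MR8.pdb
#     https://files.rcsb.org/download/3MR8.pdb (T. thermophilus 70S
#     ribosome termination complex with RF1).
#
#   human_mito.gb
#     https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=nuccore
#     &id=NC_012920.1&rettype=gb&retmode=text (human reference
#     mitochondrial genome, GenBank flat file).
#
#   table_s1_positions.tsv
#     Manual export of the article supplement's Table S1 (the 24
#     subfamily-discriminating positions in T. thermophilus RF1
#     numbering) as a TSV with columns ref_position, residue_a,
#     residue_b.

dest <- file.path("inst", "extdata", "fetched")
dir.create(dest, recursive = TRUE, showWarnings = FALSE)

fetch <- function(url, file) {
  out <- file.path(dest, file)
  if (file.exists(out)) {
    message("already present: ", out)
    return(invisible(out))
  }
  message("fetching ", url)
  ok <- tryCatch(utils::download.file(url, out, quiet = TRUE) == 0,
                 error = function(e) FALSE)
  if (!ok) message("  FAILED (offline?): ", file)
  invisible(out)
}

fetch("https://files.rcsb.org/download/3MR8.pdb", "3MR8.pdb")
fetch(paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
             "?db=nuccore&id=NC_012920.1&rettype=gb&retmode=text"),
      "human_mito.gb")
fetch("https://rest.uniprot.org/uniprotkb/O75570.fasta", "human_mtRF1.fasta")
fetch("https://rest.uniprot.org/uniprotkb/Q9UGC7.fasta", "human_mtRF1a.fasta")

message("\nRemaining manual steps (see header): ortholog collection and ",
        "mafft alignments for mtrf_family.aln.fasta / identity_trio.aln.fasta, ",
        "and the Table S1 export.")
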