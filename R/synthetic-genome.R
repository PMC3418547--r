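# Deterministic synthetic annotated mitogenomes with controlled CDS
# termini and preceding bases.

#' Recipe for a synthetic annotated mitogenome
#'
#' Each gene is specified by its terminal codon (a DNA triplet, or the
#' incomplete stop `"T"` / `"TA"`) and the base immediately 5' of that
#' terminus; the generator lays the genes out non-overlapping with
#' intergenic spacers, inserting minus-strand genes reverse-complemented
#' with `complement(...)` locations, and can rotate a circular genome so
#' the first gene spans the origin.
#'
#' @param genes List of gene specs, each
#'   `list(name = , strand = "+"|"-", terminal = , preceding = )`;
#'   `terminal` a DNA triplet or `"T"`/`"TA"`, `preceding` one of
#'   A/C/G/T.
#' @param circular Circular topology flag.
#' @param origin_span Rotate the genome so the first gene spans the
#'   origin (requires `circular`).
#' @param seed Integer seed (gene lengths, spacers, filler codons).
#' @return Object of class `genome_recipe`.
#' @export
genome_recipe <- function(genes, circular = TRUE, origin_span = FALSE,
                          seed = 1) {
  errs <- character()
  if (length(genes) == 0L) errs <- c(errs, "at least one gene required")
  for (g in genes) {
    if (is.null(g$name)) errs <- c(errs, "gene without name")
    if (!(g$strand %||% "+") %in% c("+", "-"))
      errs <- c(errs, sprintf("gene %s: strand must be + or -",
                              g$name %||% "?"))
    term <- toupper(g$terminal %||% "")
    ok_term <- (nchar(term) == 3L && !grepl("[^ACGT]", term)) ||
      term %in% c("T", "TA")
    if (!ok_term)
      errs <- c(errs, sprintf("gene %s: terminal '%s' not a DNA triplet or T/TA",
                              g$name %||% "?", term))
    if (!toupper(g$preceding %||% "") %in% c("A", "C", "G", "T"))
      errs <- c(errs, sprintf("gene %s: preceding base must be A/C/G/T",
                              g$name %||% "?"))
  }
  if (origin_span && !circular)
    errs <- c(errs, "origin_span requires a circular genome")
  if (length(errs) > 0L)
    stop_mitorf(paste(errs, collapse = "; "), "validation_error")
  structure(list(genes = genes, circular = circular,
                 origin_span = origin_span, seed = as.integer(seed)),
            class = "genome_recipe")
}

#' Recipe emulating a human-like 13-gene mitochondrial genome
#'
#' Thirteen protein-coding genes with the human-style terminus mix:
#' eight complete standard stops (UAA/UAG), three incomplete stops
#' (U or UA, completed to UAA by polyadenylation), and two genes ending
#' AGA/AGG with a preceding U (CO1 on the plus strand, ND6 on the minus
#' strand), so that every gene is terminable by mtRF1a once -1
#' frameshifts and polyadenylation are taken into account.
#'
#' @param seed Integer seed.
#' @return A `genome_recipe`.
#' @export
study_mitogenome_recipe <- function(seed = 1) {
  spec <- list(
    list(name = "ND1",  strand = "+", terminal = "TAA", preceding = "C"),
    list(name = "ND2",  strand = "+", terminal = "TAA", preceding = "A"),
    list(name = "CO1",  strand = "+", terminal = "AGA", preceding = "T"),
    list(name = "CO2",  strand = "+", terminal = "TAG", preceding = "G"),
    list(name = "ATP8", strand = "+", terminal = "TAA", preceding = "C"),
    list(name = "ATP6", strand = "+", terminal = "TAA", preceding = "A"),
    list(name = "CO3",  strand = "+", terminal = "T",   preceding = "C"),
    list(name = "ND3",  strand = "+", terminal = "TA",  preceding = "A"),
    list(name = "ND4L", strand = "+", terminal = "TAA", preceding = "G"),
    list(name = "ND4",  strand = "+", terminal = "T",   preceding = "A"),
    list(name = "ND5",  strand = "+", terminal = "TAA", preceding = "C"),
    list(name = "ND6",  strand = "-", terminal = "AGG", preceding = "T"),
    list(name = "CYB",  strand = "+", terminal = "TAG", preceding = "A"))
  genome_recipe(spec, circular = TRUE, origin_span = FALSE, seed = seed)
}

# Sense-ish filler codons: never create in-frame stops or AGA/AGG.
FILLER_CODONS <- c("GCC", "ATC", "CTA", "ACC", "GGA", "TCC", "AAC", "GAA")

#' Generate a synthetic annotated mitogenome with planted termini
#'
#' Builds the genome described by a [genome_recipe()]: every CDS ends
#' with exactly the requested terminus and penultimate base, the
#' annotation round-trips through [read_mitogenome()], and identical
#' recipe and seed give byte-identical files.
#'
#' @param recipe A `genome_recipe`.
#' @param path Optional output GenBank path; the manifest is written
#'   next to it as `<path>.manifest.json`.
#' @return List with `genome` (a `mitogenome`) and `manifest` (per-gene
#'   planted terminal codon, preceding base, strand and coordinates,
#'   plus seed and topology).
#' @export
gen_mitogenome <- function(recipe, path = NULL) {
  stopifnot(inherits(recipe, "genome_recipe"))
  with_seed(recipe$seed, {
    pieces <- character()
    pos <- 0L
    genes <- list()
    spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
    pieces <- c(pieces, spacer(60L)); pos <- pos + 60L
    for (g in recipe$genes) {
      term <- toupper(g$terminal)
      prec <- toupper(g$preceding)
      n_fill <- sample(20:60, 1L)
      cds <- paste0("ATG",
                    paste(sample(FILLER_CODONS, n_fill, replace = TRUE),
                          collapse = ""),
                    "GC", prec, term)
      insert <- if (g$strand == "-") revcomp(cds) else cds
      start <- pos + 1L
      end <- pos + nchar(insert)
      pieces <- c(pieces, insert)
      pos <- end
      sp <- sample(40:120, 1L)
      pieces <- c(pieces, spacer(sp)); pos <- pos + sp
      genes[[length(genes) + 1L]] <- structure(
        list(name = g$name, strand = g$strand,
             segments = data.frame(start = start, end = end),
             cds = cds),
        class = "mito_gene")
    }
    sequence <- paste(pieces, collapse = "")
    L <- nchar(sequence)

    if (recipe$origin_span) {
      # rotate so the first gene wraps around the origin
      g1 <- genes[[1L]]
      off <- g1$segments$start + (g1$segments$end - g1$segments$start) %/% 2L
      sequence <- paste0(substr(sequence, off + 1L, L),
                         substr(sequence, 1L, off))
      shift <- function(p) ((p - off - 1L) %% L) + 1L
      genes <- lapply(genes, function(g) {
        s <- shift(g$segments$start); e <- shift(g$segments$end)
        g$segments <- if (s <= e) data.frame(start = s, end = e)
          else data.frame(start = c(s, 1L), end = c(L, e))
        g
      })
    }

    genome <- structure(list(name = "SYNMT", sequence = sequence,
                             circular = recipe$circular, genes = genes),
                        class = "mitogenome")
    manifest <- list(
      generator = "gen_mitogenome", seed = recipe$seed,
      circular = recipe$circular, origin_span = recipe$origin_span,
      length = L,
      genes = do.call(rbind, lapply(seq_along(recipe$genes), function(i) {
        g <- recipe$genes[[i]]
        data.frame(name = g$name, strand = g$strand %||% "+",
                   terminal = toupper(g$terminal),
                   preceding = toupper(g$preceding),
                   start = genes[[i]]$segments$start[1],
                   end = genes[[i]]$segments$end[nrow(genes[[i]]$segments)],
                   stringsAsFactors = FALSE)
      })))
    if (!is.null(path)) {
      write_genbank(genome, path)
      write_json_file(manifest, paste0(path, ".manifest.json"))
    }
    list(genome = genome, manifest = manifest)
  })
}
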