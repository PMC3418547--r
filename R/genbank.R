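# Minimal GenBank flat-file reader/writer for annotated mitochondrial
# genomes.  No installed R package parses GenBank flat files offline,
# so the subset needed here (LOCUS topology, CDS features with
# join/complement locations, ORIGIN sequence) is implemented directly.

#' Read an annotated mitochondrial genome from a GenBank flat file
#'
#' Parses the LOCUS topology (circular/linear), the ORIGIN sequence and
#' all CDS features.  Locations support `join(...)`, `complement(...)`
#' (also nested) and origin-spanning segments on circular genomes;
#' coding sequences are returned spliced and strand-corrected.
#' Features flagged `/pseudo` are excluded.
#'
#' @param path Path to a GenBank flat file.
#' @return Object of class `mitogenome`: `name`, `sequence` (DNA, T
#'   alphabet), `circular`, `genes` (list of `mito_gene` objects, each
#'   with `name`, `strand`, `segments` data frame (1-based inclusive)
#'   and `cds`, the spliced coding sequence).
#' @export
read_mitogenome <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L)
    stop_mitorf("no LOCUS line", "format_error")
  circular <- grepl("\\bcircular\\b", locus[1], ignore.case = TRUE)
  name <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L)
    stop_mitorf("missing ORIGIN sequence block", "format_error")
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[end_at > origin_at[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_at[1] + 1L):(end_at - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L)
    stop_mitorf("empty ORIGIN sequence block", "format_error")
  L <- nchar(sequence)

  feat_at <- grep("^FEATURES", lines)
  genes <- list()
  if (length(feat_at) > 0L) {
    feat_lines <- lines[(feat_at[1] + 1L):(origin_at[1] - 1L)]
    is_key <- grepl("^ {5}\\S", feat_lines)
    key_idx <- which(is_key)
    for (k in seq_along(key_idx)) {
      i <- key_idx[k]
      key <- sub("^\\s+", "", substr(feat_lines[i], 1, 20))
      key <- strsplit(key, "\\s+")[[1]][1]
      if (key != "CDS") next
      block_end <- if (k < length(key_idx)) key_idx[k + 1L] - 1L
                   else length(feat_lines)
      block <- feat_lines[i:block_end]
      # location: feature line remainder plus continuation lines that
      # are not qualifiers
      loc <- trimws(substr(block[1], 21, nchar(block[1])))
      j <- 2L
      while (j <= length(block) && !grepl("^\\s*/", block[j])) {
        loc <- paste0(loc, trimws(block[j])); j <- j + 1L
      }
      quals <- block[grepl("^\\s*/", block)]
      if (any(grepl("^\\s*/pseudo\\b", quals))) next
      gene_m <- regmatches(quals, regexec('/gene="([^"]*)"', quals))
      gname <- unlist(lapply(gene_m, function(m) if (length(m) > 1) m[2]))
      if (length(gname) == 0L) {
        prod_m <- regmatches(quals, regexec('/product="([^"]*)"', quals))
        gname <- unlist(lapply(prod_m, function(m) if (length(m) > 1) m[2]))
      }
      gname <- if (length(gname) > 0L) gname[1] else sprintf("CDS_%d", k)
      parsed <- parse_gb_location(loc)
      if (any(parsed$segments$start < 1L) || any(parsed$segments$end > L))
        stop_mitorf(sprintf("feature '%s' coordinates beyond sequence length %d",
                            gname, L), "bounds_error")
      cds <- splice_segments(sequence, parsed$segments, parsed$strand)
      genes[[length(genes) + 1L]] <- structure(
        list(name = gname, strand = parsed$strand,
             segments = parsed$segments, cds = cds),
        class = "mito_gene")
    }
  }
  structure(list(name = name, sequence = sequence, circular = circular,
                 genes = genes),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("Mitogenome %s: %d bp, %s, %d CDS\n", x$name,
              nchar(x$sequence), if (x$circular) "circular" else "linear",
              length(x$genes)))
  invisible(x)
}

# Recursive GenBank location grammar: range | join(...) | complement(...)
parse_gb_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  if (grepl("^complement\\(", loc)) {
    inner <- parse_gb_location(sub("^complement\\((.*)\\)$", "\\1", loc))
    inner$strand <- if (inner$strand == "+") "-" else "+"
    return(inner)
  }
  if (grepl("^join\\(", loc)) {
    body <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- split_top_level(body)
    pieces <- lapply(parts, parse_gb_location)
    strands <- unique(vapply(pieces, function(p) p$strand, character(1)))
    segs <- do.call(rbind, lapply(pieces, function(p) p$segments))
    return(list(segments = segs,
                strand = if (length(strands) == 1L) strands else "+"))
  }
  m <- regexec("^([0-9]+)(\\.\\.([0-9]+))?$", loc)[[1]]
  g <- regmatches(loc, list(m))[[1]]
  if (length(g) == 0L)
    stop_mitorf(sprintf("unparseable location '%s'", loc), "format_error")
  start <- as.integer(g[2])
  end <- if (g[4] != "") as.integer(g[4]) else start
  list(segments = data.frame(start = start, end = end), strand = "+")
}

split_top_level <- function(s) {
  depth <- 0L; parts <- character(); cur <- ""
  for (ch in split1(s)) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) { parts <- c(parts, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  c(parts, cur)
}

splice_segments <- function(sequence, segments, strand) {
  parts <- vapply(seq_len(nrow(segments)), function(i)
    substr(sequence, segments$start[i], segments$end[i]), character(1))
  cds <- paste(parts, collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  unname(cds)
}

format_gb_location <- function(segments, strand) {
  ranges <- sprintf("%d..%d", segments$start, segments$end)
  loc <- if (length(ranges) > 1L)
    sprintf("join(%s)", paste(ranges, collapse = ",")) else ranges
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a mitogenome as a GenBank flat file
#'
#' Deterministic output (fixed date stamp) so identical genomes give
#' byte-identical files.
#'
#' @param genome A `mitogenome` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- nchar(genome$sequence)
  topo <- if (genome$circular) "circular" else "linear"
  lines <- c(
    sprintf("LOCUS       %-16s %6d bp    DNA     %-8s SYN 01-JAN-2000",
            genome$name, L, topo),
    "DEFINITION  Synthetic mitochondrial genome fixture.",
    sprintf("ACCESSION   %s", genome$name),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    "                     /organism=\"synthetic construct\"")
  for (g in genome$genes) {
    lines <- c(lines,
               sprintf("     CDS             %s",
                       format_gb_location(g$segments, g$strand)),
               sprintf("                     /gene=\"%s\"", g$name))
  }
  lines <- c(lines, "ORIGIN")
  seq_lc <- tolower(genome$sequence)
  for (start in seq(1L, L, by = 60L)) {
    chunk <- substr(seq_lc, start, min(start + 59L, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", start, paste(groups, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}
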