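# Shared constants and small helpers.

# The twenty standard amino-acid one-letter codes; ambiguity codes
# (X, B, Z, J) deliberately excluded so they never count as "perfectly
# conserved".
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHARS <- c("-", ".")

is_gap <- function(x) x %in% GAP_CHARS

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards.  All generator randomness goes through this, so
# fixture generation never perturbs (and is never perturbed by) the
# session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Reverse complement of a DNA string (T alphabet, IUPAC core only).
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1)))
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)

split1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mitorf <- function(msg, class) {
  stop(structure(class = c(class, "mitorf_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Write a data.frame as plain TSV (deterministic, no quoting surprises).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
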