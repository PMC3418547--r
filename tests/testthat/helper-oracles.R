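# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by the most direct route possible
# (explicit loops, exhaustive enumeration, alternative algorithms) so
# they stay independent of the package's implementation paths.

# Brute-force per-column scan for the strict discrimination criterion.
oracle_discriminating_columns <- function(aln) {
  standard <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  fams <- sort(unique(unname(aln$labels)))
  ids1 <- names(aln$labels)[aln$labels == fams[1]]
  ids2 <- names(aln$labels)[aln$labels == fams[2]]
  ncol_aln <- nchar(aln$seqs[[1]])
  hits <- integer()
  for (j in seq_len(ncol_aln)) {
    r1 <- unique(vapply(ids1, function(id) substr(aln$seqs[[id]], j, j),
                        character(1)))
    r2 <- unique(vapply(ids2, function(id) substr(aln$seqs[[id]], j, j),
                        character(1)))
    if (length(r1) == 1L && length(r2) == 1L &&
        r1 %in% standard && r2 %in% standard && r1 != r2)
      hits <- c(hits, j)
  }
  hits
}

# All-pairs hydrogen-bond oracle: double loop over every atom pair,
# role lookup via a locally rebuilt donor/acceptor test.
oracle_hbonds <- function(model, dist_min = 2.4, dist_max = 3.5) {
  a <- model$atoms
  chem <- mitorf:::hbond_chemistry
  role_of <- function(i) {
    hit <- chem$role[chem$resname == a$resname[i] & chem$atom == a$atom[i]]
    if (length(hit) == 0L) NA_character_ else hit[1]
  }
  roles <- vapply(seq_len(nrow(a)), role_of, character(1))
  ids <- paste0(a$chain, ":", a$resno, a$icode, ":", a$atom)
  res <- paste0(a$chain, ":", a$resno, a$icode)
  out <- NULL
  n <- nrow(a)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (res[i] == res[j]) next
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                     c(a$x[j], a$y[j], a$z[j]))^2))
      if (d < dist_min || d > dist_max) next
      i_d <- !is.na(roles[i]) && roles[i] %in% c("donor", "both")
      i_a <- !is.na(roles[i]) && roles[i] %in% c("acceptor", "both")
      j_d <- !is.na(roles[j]) && roles[j] %in% c("donor", "both")
      j_a <- !is.na(roles[j]) && roles[j] %in% c("acceptor", "both")
      if ((i_d && j_a) || (j_d && i_a))
        out <- rbind(out, data.frame(a = min(ids[i], ids[j]),
                                     b = max(ids[i], ids[j]),
                                     distance = d,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) out <- data.frame(a = character(), b = character(),
                                      distance = numeric())
  out[order(out$a, out$b), , drop = FALSE]
}

# All-pairs clash oracle.
oracle_clashes <- function(model, threshold = 0.4) {
  a <- model$atoms
  radii <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.10)
  ids <- paste0(a$chain, ":", a$resno, a$icode, ":", a$atom)
  res <- paste0(a$chain, ":", a$resno, a$icode)
  out <- NULL
  n <- nrow(a)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (res[i] == res[j]) next
      if (a$chain[i] == a$chain[j] && abs(a$resno[i] - a$resno[j]) == 1L) {
        lo <- if (a$resno[i] < a$resno[j]) i else j
        hi <- if (lo == i) j else i
        if ((a$atom[lo] == "C" && a$atom[hi] == "N") ||
            (a$atom[lo] == "O3'" && a$atom[hi] == "P")) next
      }
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                     c(a$x[j], a$y[j], a$z[j]))^2))
      ov <- radii[[a$element[i]]] + radii[[a$element[j]]] - d
      if (ov > threshold)
        out <- rbind(out, data.frame(a = min(ids[i], ids[j]),
                                     b = max(ids[i], ids[j]),
                                     overlap = ov,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) out <- data.frame(a = character(), b = character(),
                                      overlap = numeric())
  out[order(out$a, out$b), , drop = FALSE]
}

# Horn's closed-form quaternion absolute-orientation fit: an
# independent superposition algorithm returning the optimal rmsd.
oracle_quaternion_rmsd <- function(mobile, reference) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R0 <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(M, R0)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda <- max(eigen(N, symmetric = TRUE)$values)
  ss <- sum(M^2) + sum(R0^2) - 2 * lambda
  sqrt(max(ss, 0) / nrow(M))
}

# Exhaustive decision-table oracle for terminability of an in-frame
# terminus given (preceding base, terminal codon), DNA alphabet.
oracle_termination_class <- function(preceding, codon) {
  if (codon %in% c("TAA", "TAG")) return("standard")
  if (codon %in% c("AGA", "AGG") && preceding == "T")
    return("frameshift_terminable")
  "not_terminable"
}

# A gene-like object with an in-frame CDS ending `preceding` + `codon`.
toy_gene <- function(preceding, codon, name = "toy", strand = "+") {
  list(name = name, strand = strand,
       cds = paste0("ATGGCCATCACC", "GC", preceding, codon))
}

random_rigid_transform <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  structure(list(rotation = R, translation = stats::runif(3, -10, 10),
                 rmsd = 0), class = "rigid_transform")
}

# Small random protein-like model for property tests: a scatter of
# residues with polar and apolar atoms.
random_toy_model <- function(n_res = 20, seed = 1, spread = 12) {
  set.seed(seed)
  resnames <- sample(c("GLY", "SER", "ALA", "ASN", "GLU", "LYS"), n_res,
                     replace = TRUE)
  rows <- list()
  for (i in seq_len(n_res)) {
    base <- stats::runif(3, 0, spread)
    add <- function(atom, off) rows[[length(rows) + 1L]] <<- data.frame(
      chain = "A", resno = i, resname = resnames[i], atom = atom,
      x = base[1] + off[1], y = base[2] + off[2], z = base[3] + off[3],
      stringsAsFactors = FALSE)
    add("N", c(0, 0, 0)); add("CA", c(1.45, 0, 0)); add("C", c(2.0, 1.2, 0))
    add("O", c(2.0, 1.2, 1.23))
    if (resnames[i] == "SER") add("OG", c(1.45, 1.4, 0))
    if (resnames[i] == "ASN") { add("OD1", c(1.2, 2.4, 0.5)); add("ND2", c(0.4, 2.8, 0.2)) }
    if (resnames[i] == "GLU") { add("OE1", c(1.5, 2.9, 0.8)); add("OE2", c(2.6, 2.6, 0.3)) }
    if (resnames[i] == "LYS") add("NZ", c(0.8, 3.4, 1.1))
  }
  structure_model(do.call(rbind, rows))
}

# Reverse-complement an entire mitogenome, flipping every feature, to
# test strand invariance of the termination scan.
revcomp_genome <- function(genome) {
  L <- nchar(genome$sequence)
  genome$sequence <- mitorf:::revcomp(genome$sequence)
  genome$genes <- lapply(genome$genes, function(g) {
    segs <- g$segments
    new <- data.frame(start = L - segs$end + 1L, end = L - segs$start + 1L)
    g$segments <- new[rev(seq_len(nrow(new))), , drop = FALSE]
    rownames(g$segments) <- NULL
    g$strand <- if (g$strand == "+") "-" else "+"
    g$cds <- mitorf:::splice_segments(genome$sequence, g$segments, g$strand)
    g
  })
  genome
}
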