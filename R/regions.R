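# Release-factor region tables, region assignment, divergence reports
# and spatial-clustering significance.

#' Region table of the class I release-factor fold
#'
#' Named intervals over reference numbering (*T. thermophilus* RF1
#' convention).  The switch loop is fixed at residues 286--301; the
#' domain boundaries are editorial defaults derived from the
#' four-domain RF1 fold (domain 2 carries the codon-recognition
#' elements: the helix alpha-5 tip around Gly-116/Glu-119 and the
#' recognition loop with the PXT motif at Pro-184/Thr-186; domain 3
#' carries the catalytic GGQ; the switch loop links domains 3 and 4)
#' and can be overridden.  Intervals may overlap: a position can belong
#' to a domain and to a loop within it.
#'
#' @param domain1,domain2,domain3,domain4,switch_loop,recognition_loop,helix_alpha5_tip,helix_alpha7
#'   Integer length-2 vectors `c(start, end)` in reference numbering.
#' @param motifs Named list of motif positions (defaults: GGQ at
#'   229--231, PXT at 184--186).
#' @return An object of class `region_table`.
#' @export
region_table <- function(domain1 = c(1, 108),
                         domain2 = c(109, 205),
                         domain3 = c(206, 285),
                         domain4 = c(302, 360),
                         switch_loop = c(286, 301),
                         recognition_loop = c(178, 197),
                         helix_alpha5_tip = c(113, 121),
                         helix_alpha7 = c(296, 330),
                         motifs = list(GGQ = c(229, 231),
                                       PXT = c(184, 186))) {
  intervals <- data.frame(
    region = c("domain1", "domain2", "domain3", "domain4", "switch_loop",
               "recognition_loop", "helix_alpha5_tip", "helix_alpha7"),
    start = c(domain1[1], domain2[1], domain3[1], domain4[1],
              switch_loop[1], recognition_loop[1], helix_alpha5_tip[1],
              helix_alpha7[1]),
    end = c(domain1[2], domain2[2], domain3[2], domain4[2],
            switch_loop[2], recognition_loop[2], helix_alpha5_tip[2],
            helix_alpha7[2]),
    stringsAsFactors = FALSE)
  if (any(intervals$end < intervals$start))
    stop_mitorf("region interval with end < start", "validation_error")
  for (m in names(motifs)) {
    pos <- motifs[[m]]
    inside <- any(intervals$start <= min(pos) & intervals$end >= max(pos))
    if (!inside)
      stop_mitorf(sprintf("motif %s falls outside every declared region", m),
                  "validation_error")
  }
  structure(list(intervals = intervals, motifs = motifs),
            class = "region_table")
}

#' Regions containing a reference position
#'
#' @param position Integer reference position(s).
#' @param table A [region_table()].
#' @return For a single position, a character vector of all region
#'   labels containing it (possibly empty = unassigned); for several
#'   positions, a list of such vectors.
#' @export
assign_region <- function(position, table = region_table()) {
  stopifnot(inherits(table, "region_table"))
  one <- function(p) {
    iv <- table$intervals
    iv$region[iv$start <= p & iv$end >= p]
  }
  if (length(position) == 1L) one(position) else lapply(position, one)
}

# Single primary region per position for counting: the switch loop
# takes precedence over its flanking domains (reproducing the
# "20 in domain 2, 2 in the switch loop" partition style); annotation
# loops (recognition loop, helix tips) do not, since the codon
# recognition elements count with their parent domain 2.
primary_region <- function(position, table = region_table(),
                           precedence = c("switch_loop", "domain1",
                                          "domain2", "domain3", "domain4")) {
  vapply(position, function(p) {
    labs <- assign_region(p, table)
    hit <- precedence[precedence %in% labs]
    if (length(hit) > 0L) return(hit[1])
    if (length(labs) > 0L) return(labs[1])
    "unassigned"
  }, character(1))
}

#' Regional divergence report for discriminating positions
#'
#' Summarises where the subfamily-discriminating positions fall on the
#' release-factor fold: per-region counts under a disjoint
#' primary-region assignment (switch loop taking precedence over its
#' flanking domains, all other labels still reported per position) and,
#' when a structure is supplied, whether each mapped residue is present
#' in the model chain.  Counts over the primary assignment always sum
#' to the number of input positions.
#'
#' @param positions A `discriminating_positions` data frame from
#'   [detect_discriminating_positions()] (needs `ref_position`).
#' @param insertions Optional insertion table from [detect_insertions()]
#'   (reported alongside, anchored to their reference positions).
#' @param table A [region_table()].
#' @param model Optional [structure_model()] for structural context.
#' @param chain Chain id of the release factor in `model`.
#' @return List of class `divergence_report`: `counts` (named integer
#'   vector by primary region, including `unassigned`), `positions`
#'   (per-position rows with all region labels, primary region and —
#'   with a model — residue presence), `insertions`, `n_positions`.
#' @export
divergence_report <- function(positions, insertions = NULL,
                              table = region_table(), model = NULL,
                              chain = NULL) {
  ref_num <- suppressWarnings(as.integer(sub("\\+.*$", "", positions$ref_position)))
  unmappable <- is.na(ref_num)
  prim <- rep("unmappable", nrow(positions))
  prim[!unmappable] <- primary_region(ref_num[!unmappable], table)
  all_labels <- vapply(seq_len(nrow(positions)), function(i) {
    if (unmappable[i]) return("")
    paste(assign_region(ref_num[i], table), collapse = ",")
  }, character(1))
  in_model <- rep(NA, nrow(positions))
  if (!is.null(model)) {
    if (is.null(chain))
      stop_mitorf("chain required when a model is supplied",
                  "precondition_error")
    have <- unique(model$atoms$resno[model$atoms$chain == chain])
    in_model <- !unmappable & ref_num %in% have
  }
  per_pos <- data.frame(positions,
                        primary_region = prim, regions = all_labels,
                        in_model = in_model, stringsAsFactors = FALSE)
  lev <- unique(c(table$intervals$region, "unassigned", "unmappable"))
  counts <- table(factor(prim, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  structure(list(counts = counts, positions = per_pos,
                 insertions = insertions, n_positions = nrow(positions)),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("Divergence report:", x$n_positions, "discriminating position(s)\n")
  nz <- x$counts[x$counts > 0]
  for (r in names(nz)) cat(sprintf("  %-18s %d\n", r, nz[[r]]))
  if (!is.null(x$insertions) && nrow(x$insertions) > 0)
    cat("  insertions:",
        paste(sprintf("%s (len %d @ %d)", x$insertions$consensus,
                      x$insertions$length, x$insertions$anchor_ref_position),
              collapse = ", "), "\n")
  invisible(x)
}

#' Permutation p-value for spatial clustering of a residue set
#'
#' Tests whether a set of residues clusters in space more tightly than
#' same-size random residue subsets of the same chain.  The statistic
#' is the mean pairwise C-alpha distance; the null is uniform sampling
#' of residue subsets; the p-value uses the add-one estimator
#' `p = (1 + #\{null <= observed\}) / (1 + n_permutations)`, so it lies
#' in (0, 1].
#'
#' @param model A [structure_model()].
#' @param chain Chain id.
#' @param residues Integer vector (>= 3) of residue numbers with
#'   C-alpha atoms in the chain.
#' @param n_permutations Number of null draws (>= 100).
#' @param seed Integer seed.
#' @return Numeric p-value in (0, 1].
#' @export
clustering_pvalue <- function(model, chain, residues,
                              n_permutations = 1000, seed = 1) {
  if (length(residues) < 3L)
    stop_mitorf("need at least 3 residues", "precondition_error")
  if (n_permutations < 100L)
    stop_mitorf("need at least 100 permutations", "precondition_error")
  a <- model$atoms
  ca <- a[a$chain == chain & a$atom == "CA", , drop = FALSE]
  if (anyDuplicated(ca$resno))
    ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  pool <- ca$resno
  if (!all(residues %in% pool))
    stop_mitorf("residue(s) without C-alpha in chain", "precondition_error")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  rownames(xyz) <- as.character(ca$resno)
  stat <- function(set) mean(stats::dist(xyz[as.character(set), , drop = FALSE]))
  observed <- stat(residues)
  k <- length(residues)
  with_seed(seed, {
    null <- vapply(seq_len(n_permutations),
                   function(i) stat(sample(pool, k)), numeric(1))
    (1 + sum(null <= observed)) / (1 + n_permutations)
  })
}
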