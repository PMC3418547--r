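# Geometric primitives: distances, hydrogen bonds, steric clashes,
# least-squares rigid superposition.

# Donor/acceptor chemistry for protein residues and RNA/DNA nucleotides,
# keyed by (residue name, atom name).  Backbone amide N is a donor
# (except proline), carbonyl O and OXT are acceptors.  Used when no
# hydrogens are present, which is the normal case for crystal structures
# and models at this resolution.
hbond_chemistry <- local({
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  rows <- list()
  add <- function(res, atom, role) rows[[length(rows) + 1L]] <<-
    data.frame(resname = res, atom = atom, role = role,
               stringsAsFactors = FALSE)
  for (r in aa) {
    if (r != "PRO") add(r, "N", "donor")
    add(r, "O", "acceptor")
    add(r, "OXT", "acceptor")
  }
  add("SER", "OG", "both");   add("THR", "OG1", "both")
  add("TYR", "OH", "both");   add("CYS", "SG", "both")
  add("ASN", "OD1", "acceptor"); add("ASN", "ND2", "donor")
  add("GLN", "OE1", "acceptor"); add("GLN", "NE2", "donor")
  add("ASP", "OD1", "acceptor"); add("ASP", "OD2", "acceptor")
  add("GLU", "OE1", "acceptor"); add("GLU", "OE2", "acceptor")
  add("LYS", "NZ", "donor")
  add("ARG", "NE", "donor"); add("ARG", "NH1", "donor"); add("ARG", "NH2", "donor")
  add("HIS", "ND1", "both"); add("HIS", "NE2", "both")
  add("TRP", "NE1", "donor")
  add("MET", "SD", "acceptor")
  nts <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT")
  for (r in nts) {
    for (at in c("OP1", "OP2", "OP3", "O5'", "O4'", "O3'"))
      add(r, at, "acceptor")
    add(r, "O2'", "both")
  }
  for (r in c("A", "DA")) {
    add(r, "N1", "acceptor"); add(r, "N3", "acceptor")
    add(r, "N7", "acceptor"); add(r, "N6", "donor")
  }
  for (r in c("G", "DG")) {
    add(r, "N1", "donor"); add(r, "N2", "donor")
    add(r, "N3", "acceptor"); add(r, "N7", "acceptor"); add(r, "O6", "acceptor")
  }
  for (r in c("C", "DC")) {
    add(r, "N3", "acceptor"); add(r, "N4", "donor"); add(r, "O2", "acceptor")
  }
  for (r in c("U", "DT")) {
    add(r, "N3", "donor"); add(r, "O2", "acceptor"); add(r, "O4", "acceptor")
  }
  do.call(rbind, rows)
})

# Van der Waals radii (Angstrom) used for steric-clash overlap.
#' Default van der Waals radii
#'
#' Named vector of radii (Angstrom) used by [detect_clashes()]:
#' C 1.70, N 1.55, O 1.52, P 1.80, S 1.80, H 1.10.
#' @export
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.10)

cross_distances <- function(A, B) {
  # |a_i - b_j| for all pairs; A, B are n x 3 matrices
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Minimum distance between two atom selections
#'
#' Minimum Euclidean distance over the atom-pair cross product;
#' symmetric in its selection arguments.
#'
#' @param model A [structure_model()].
#' @param sel_a,sel_b Selections (see [select_atoms()]).
#' @return Distance in Angstrom.
#' @export
min_distance <- function(model, sel_a, sel_b) {
  ia <- select_atoms(model, sel_a)
  ib <- select_atoms(model, sel_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop_mitorf("empty selection", "selection_error")
  A <- model_coords(model, ia)
  B <- model_coords(model, ib)
  min(cross_distances(A, B))
}

atom_roles <- function(atoms) {
  # donor/acceptor role per atom from the chemistry table; warns once
  # about residue types absent from the table.
  key <- paste(atoms$resname, atoms$atom)
  tab_key <- paste(hbond_chemistry$resname, hbond_chemistry$atom)
  role <- hbond_chemistry$role[match(key, tab_key)]
  unknown <- setdiff(unique(atoms$resname),
                     unique(hbond_chemistry$resname))
  unknown <- setdiff(unknown, c("HOH"))
  polar <- atoms$element %in% c("N", "O", "S")
  if (length(unknown) > 0L && any(polar & atoms$resname %in% unknown))
    warning("no hydrogen-bond chemistry for residue type(s): ",
            paste(unknown, collapse = ", "), "; atoms skipped",
            call. = FALSE)
  role
}

#' Detect hydrogen bonds between two atom selections
#'
#' Reports all donor/acceptor pairs with one atom from each selection
#' (either direction) whose heavy-atom distance lies inside the
#' configured window (default 2.4--3.5 Angstrom).  When hydrogens are
#' present on the donor the D--H...A angle must additionally reach the
#' angular cutoff (default 120 degrees); without hydrogens the angle is
#' reported as `NA` and not tested.  Pairs within a single residue are
#' excluded.  Output is deterministically ordered by (donor, acceptor).
#'
#' @param model A [structure_model()].
#' @param sel_a,sel_b Selections (see [select_atoms()]).
#' @param dist_min,dist_max Heavy-atom donor--acceptor window, Angstrom.
#' @param angle_min D--H...A cutoff in degrees, applied only when the
#'   donor carries hydrogens.
#' @return Data frame: `donor`, `acceptor` (atom ids), `distance`,
#'   `angle` (`NA` without hydrogens).
#' @export
detect_hbonds <- function(model, sel_a, sel_b,
                          dist_min = 2.4, dist_max = 3.5,
                          angle_min = 120) {
  ia <- select_atoms(model, sel_a)
  ib <- select_atoms(model, sel_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop_mitorf("empty selection", "selection_error")
  a <- model$atoms
  role <- atom_roles(a)
  ids <- atom_key(a)
  res_of <- paste0(a$chain, ":", a$resno, a$icode)

  candidates <- function(idx_d, idx_a) {
    d <- idx_d[!is.na(role[idx_d]) & role[idx_d] %in% c("donor", "both")]
    ac <- idx_a[!is.na(role[idx_a]) & role[idx_a] %in% c("acceptor", "both")]
    if (length(d) == 0L || length(ac) == 0L) return(NULL)
    expand.grid(donor = d, acceptor = ac, KEEP.OUT.ATTRS = FALSE)
  }
  cand <- rbind(candidates(ia, ib), candidates(ib, ia))
  if (is.null(cand) || nrow(cand) == 0L)
    return(empty_hbonds())
  cand <- cand[cand$donor != cand$acceptor, , drop = FALSE]
  cand <- cand[res_of[cand$donor] != res_of[cand$acceptor], , drop = FALSE]
  # one record per unordered pair
  unordered <- paste(pmin(cand$donor, cand$acceptor),
                     pmax(cand$donor, cand$acceptor))
  cand <- cand[!duplicated(unordered), , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_hbonds())

  xyz <- as.matrix(a[, c("x", "y", "z")])
  dvec <- xyz[cand$donor, , drop = FALSE] - xyz[cand$acceptor, , drop = FALSE]
  cand$distance <- sqrt(rowSums(dvec^2))
  cand <- cand[cand$distance >= dist_min & cand$distance <= dist_max, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(empty_hbonds())

  cand$angle <- NA_real_
  keep <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    dn <- cand$donor[k]
    hyd <- which(a$element == "H" & res_of == res_of[dn])
    if (length(hyd) == 0L) next
    dh <- sqrt(rowSums((xyz[hyd, , drop = FALSE] -
                        matrix(xyz[dn, ], length(hyd), 3, byrow = TRUE))^2))
    hyd <- hyd[dh < 1.25]
    if (length(hyd) == 0L) next
    ang <- vapply(hyd, function(h) {
      v1 <- xyz[dn, ] - xyz[h, ]
      v2 <- xyz[cand$acceptor[k], ] - xyz[h, ]
      cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }, numeric(1))
    cand$angle[k] <- max(ang)
    keep[k] <- max(ang) >= angle_min
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(donor = ids[cand$donor], acceptor = ids[cand$acceptor],
                    distance = cand$distance, angle = cand$angle,
                    stringsAsFactors = FALSE)
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

empty_hbonds <- function() {
  data.frame(donor = character(), acceptor = character(),
             distance = numeric(), angle = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect steric clashes between two atom selections
#'
#' A pair clashes when its van der Waals overlap
#' `r_a + r_b - distance` exceeds the severe-overlap threshold
#' (default 0.4 Angstrom).  Pairs within the same residue and
#' covalently bonded inter-residue neighbours (peptide C--N, nucleic
#' O3'--P of consecutive residues in one chain) are excluded.
#'
#' @inheritParams detect_hbonds
#' @param overlap_threshold Severe-overlap threshold, Angstrom.
#' @param radii Named vector of van der Waals radii by element; an
#'   element missing from it raises a lookup error naming the element.
#' @return Data frame: `atom_a`, `atom_b` (ids), `distance`, `overlap`,
#'   ordered by (atom_a, atom_b).
#' @export
detect_clashes <- function(model, sel_a, sel_b, overlap_threshold = 0.4,
                           radii = vdw_radii) {
  ia <- select_atoms(model, sel_a)
  ib <- select_atoms(model, sel_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop_mitorf("empty selection", "selection_error")
  a <- model$atoms
  elems <- unique(a$element[c(ia, ib)])
  missing <- setdiff(elems, names(radii))
  if (length(missing) > 0L)
    stop_mitorf(paste("no van der Waals radius for element(s):",
                      paste(missing, collapse = ", ")), "lookup_error")
  ids <- atom_key(a)
  res_of <- paste0(a$chain, ":", a$resno, a$icode)
  cand <- expand.grid(i = ia, j = ib, KEEP.OUT.ATTRS = FALSE)
  cand <- cand[cand$i != cand$j, , drop = FALSE]
  unordered <- paste(pmin(cand$i, cand$j), pmax(cand$i, cand$j))
  cand <- cand[!duplicated(unordered), , drop = FALSE]
  cand <- cand[res_of[cand$i] != res_of[cand$j], , drop = FALSE]
  if (nrow(cand) > 0L) {
    bonded <- mapply(function(i, j) is_covalent_neighbour(a, i, j),
                     cand$i, cand$j)
    cand <- cand[!bonded, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(empty_clashes())
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- sqrt(rowSums((xyz[cand$i, , drop = FALSE] -
                     xyz[cand$j, , drop = FALSE])^2))
  ov <- radii[a$element[cand$i]] + radii[a$element[cand$j]] - d
  hit <- ov > overlap_threshold
  out <- data.frame(atom_a = ids[cand$i[hit]], atom_b = ids[cand$j[hit]],
                    distance = d[hit], overlap = unname(ov[hit]),
                    stringsAsFactors = FALSE)
  out[order(out$atom_a, out$atom_b), , drop = FALSE]
}

empty_clashes <- function() {
  data.frame(atom_a = character(), atom_b = character(),
             distance = numeric(), overlap = numeric(),
             stringsAsFactors = FALSE)
}

is_covalent_neighbour <- function(atoms, i, j) {
  if (atoms$chain[i] != atoms$chain[j]) return(FALSE)
  if (abs(atoms$resno[i] - atoms$resno[j]) != 1L) return(FALSE)
  first <- if (atoms$resno[i] < atoms$resno[j]) i else j
  second <- if (first == i) j else i
  (atoms$atom[first] == "C" && atoms$atom[second] == "N") ||
    (atoms$atom[first] == "O3'" && atoms$atom[second] == "P")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1, never a reflection) and
#' translation minimising the RMSD between corresponding points.
#'
#' @param mobile,reference Numeric n x 3 matrices of corresponding
#'   coordinates (1:1, n >= 3, non-collinear).
#' @return An object of class `rigid_transform`: `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` such that
#'   `mobile %*% t(rotation) + translation` best fits `reference`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L ||
      ncol(reference) != 3L)
    stop_mitorf("correspondence must be two equal n x 3 matrices",
                "degeneracy_error")
  n <- nrow(mobile)
  if (n < 3L)
    stop_mitorf("need at least 3 corresponding atom pairs",
                "degeneracy_error")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2L, cm); R0 <- sweep(reference, 2L, cr)
  sv_ref <- svd(R0)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1))
    stop_mitorf("reference points are collinear", "degeneracy_error")
  H <- crossprod(M, R0)                       # 3 x 3
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- as.numeric(cr - R %*% cm)
  fitted <- M %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - R0)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform, rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

#' Apply a rigid transform
#'
#' @param x An n x 3 coordinate matrix or a [structure_model()].
#' @param transform A `rigid_transform` from [superpose()].
#' @return Object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "structure_model")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    new <- xyz %*% t(transform$rotation) +
      matrix(transform$translation, nrow(xyz), 3, byrow = TRUE)
    x$atoms[, c("x", "y", "z")] <- new
    return(x)
  }
  as.matrix(x) %*% t(transform$rotation) +
    matrix(transform$translation, nrow(x), 3, byrow = TRUE)
}
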