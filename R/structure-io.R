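# Atomic coordinate models: container, PDB reader/writer, selections.

#' Construct a structure model from an atom table
#'
#' The container used by all geometric analyses.  Each row is one atom;
#' after alternate-location resolution the key (chain, residue number +
#' insertion code, atom name) is unique.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `x`, `y`, `z` and optionally `icode` (default `""`),
#'   `element` (derived from the atom name when missing), `occ`
#'   (default 1), `altloc` (default `""`), `type` (`"ATOM"` or
#'   `"HETATM"`, default `"ATOM"`).
#' @return An object of class `structure_model`.
#' @seealso [read_structure()], [select_atoms()]
#' @export
structure_model <- function(atoms) {
  req <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0L)
    stop_mitorf(paste("atom table missing column(s):",
                      paste(miss, collapse = ", ")), "format_error")
  n <- nrow(atoms)
  atoms$icode <- as.character(atoms$icode %||% rep("", n))
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$element <- as.character(atoms$element %||% guess_element(atoms$atom))
  blank <- is.na(atoms$element) | atoms$element == ""
  atoms$element[blank] <- guess_element(atoms$atom[blank])
  atoms$occ <- as.numeric(atoms$occ %||% rep(1, n))
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$altloc <- as.character(atoms$altloc %||% rep("", n))
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$type <- as.character(atoms$type %||% rep("ATOM", n))
  atoms$resno <- as.integer(atoms$resno)
  for (cc in c("x", "y", "z")) atoms[[cc]] <- as.numeric(atoms[[cc]])
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_mitorf("non-finite atom coordinates", "format_error")
  atoms <- resolve_altlocs(atoms)
  key <- atom_key(atoms)
  if (anyDuplicated(key))
    stop_mitorf(sprintf("duplicate atom(s) after altloc resolution: %s",
                        paste(unique(key[duplicated(key)]), collapse = ", ")),
                "format_error")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_model")
}

atom_key <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resno, atoms$icode, ":", atoms$atom)
}

#' Atom identifiers of a model
#'
#' @param model A `structure_model`.
#' @param sel Optional selection (see [select_atoms()]).
#' @return Character vector `"chain:resno[icode]:atomname"`.
#' @export
atom_ids <- function(model, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(nrow(model$atoms)) else select_atoms(model, sel)
  atom_key(model$atoms)[idx]
}

# Keep the highest-occupancy alternate location; ties go to altloc 'A'
# (then alphabetically), so parsing is deterministic.
resolve_altlocs <- function(atoms) {
  key <- paste0(atoms$chain, ":", atoms$resno, atoms$icode, ":", atoms$atom)
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    o <- atoms$occ[idx]
    cand <- idx[o == max(o)]
    cand[order(atoms$altloc[cand])][1]
  }), use.names = FALSE)
  out <- atoms[sort(keep), , drop = FALSE]
  out$altloc <- ""
  out
}

guess_element <- function(atom_name) {
  two_letter <- c("FE", "MG", "ZN", "MN", "NA", "CL", "BR", "CA")
  vapply(atom_name, function(a) {
    a <- gsub("[0-9'*\"]", "", toupper(a))
    if (a %in% two_letter && !a %in% c("CA", "NA")) return(a)
    substr(a, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("Structure model:", nrow(a), "atoms,",
      length(unique(paste0(a$chain, ":", a$resno, a$icode))), "residues,",
      length(unique(a$chain)), "chain(s)\n")
  invisible(x)
}

#' Read a fixed-column PDB coordinate file
#'
#' Retains both ATOM and HETATM records.  Alternate locations are
#' resolved to the highest-occupancy conformer (ties to altloc `A`);
#' insertion codes are kept as part of the residue identity.  Residue
#' numbering follows the file's author numbering.
#'
#' @param path Path to a PDB file.
#' @return A [structure_model()].
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  is_coord <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  for (i in which(is_coord)) {
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(lines[i], fld[1], fld[2])))
      if (is.na(v))
        stop_mitorf(sprintf("malformed coordinate field at line %d: '%s'",
                            i, lines[i]), "format_error")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(chain = ifelse(is.na(a$chain), "", a$chain),
                      resno = a$resno,
                      icode = ifelse(is.na(a$insert), "", a$insert),
                      resname = a$resid,
                      atom = a$elety,
                      element = ifelse(is.na(a$elesy), "", a$elesy),
                      x = a$x, y = a$y, z = a$z,
                      occ = a$o,
                      altloc = ifelse(is.na(a$alt), "", a$alt),
                      type = a$type,
                      stringsAsFactors = FALSE)
  structure_model(atoms)
}

#' Write a model as a fixed-column PDB file
#'
#' Deterministic output: same model, byte-identical file.
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  name_field <- ifelse(nchar(a$atom) >= 4L, substr(a$atom, 1L, 4L),
                       sprintf(" %-3s", a$atom))
  lines <- sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$type, seq_len(nrow(a)), name_field, " ",
                   substr(sprintf("%3s", a$resname), 1L, 3L),
                   substr(paste0(a$chain, " "), 1L, 1L),
                   a$resno, substr(paste0(a$icode, " "), 1L, 1L),
                   a$x, a$y, a$z, a$occ, 0,
                   sprintf("%2s", a$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---- selections -----------------------------------------------------------

#' Select atoms by pattern
#'
#' Selections address atoms as `"chain:resno[icode]:atomname"`.  Each of
#' the three fields accepts `*` (any), comma-separated alternatives, and
#' — for the residue field — ranges (`286-301`).  Atom names may use
#' glob wildcards (`O*`).  A residue token may carry an insertion-code
#' suffix (`115A`).  Alternatively `sel` may be a list with any of
#' `chain`, `resno`, `icode`, `resname`, `atom`, or an integer vector of
#' row indices.
#'
#' @param model A [structure_model()].
#' @param sel Selection pattern, list, or integer indices.
#' @return Integer vector of atom row indices (possibly empty).
#' @examples
#' m <- decoding_center_template("stacked")
#' length(select_atoms(m, "A:1492-1493:*"))
#' @export
select_atoms <- function(model, sel) {
  a <- model$atoms
  if (is.numeric(sel)) return(as.integer(sel))
  if (is.list(sel)) {
    keep <- rep(TRUE, nrow(a))
    if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
    if (!is.null(sel$resno)) keep <- keep & a$resno %in% sel$resno
    if (!is.null(sel$icode)) keep <- keep & a$icode %in% sel$icode
    if (!is.null(sel$resname)) keep <- keep & a$resname %in% sel$resname
    if (!is.null(sel$atom)) keep <- keep & a$atom %in% sel$atom
    return(which(keep))
  }
  parts <- strsplit(as.character(sel), ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop_mitorf(sprintf("selection '%s' must have 3 ':'-separated fields", sel),
                "selection_error")
  keep_chain <- field_match(a$chain, parts[1], glob = FALSE)
  keep_res <- res_field_match(a$resno, a$icode, parts[2])
  keep_atom <- field_match(a$atom, parts[3], glob = TRUE)
  which(keep_chain & keep_res & keep_atom)
}

field_match <- function(values, token, glob = FALSE) {
  if (token == "*") return(rep(TRUE, length(values)))
  alts <- strsplit(token, ",", fixed = TRUE)[[1]]
  hit <- rep(FALSE, length(values))
  for (t in alts) {
    hit <- hit | if (glob && grepl("[*?]", t))
      grepl(utils::glob2rx(t), values) else values == t
  }
  hit
}

res_field_match <- function(resno, icode, token) {
  if (token == "*") return(rep(TRUE, length(resno)))
  hit <- rep(FALSE, length(resno))
  for (t in strsplit(token, ",", fixed = TRUE)[[1]]) {
    if (grepl("^-?[0-9]+--?[0-9]+$", t)) {
      m <- regmatches(t, regexec("^(-?[0-9]+)-(-?[0-9]+)$", t))[[1]]
      lo <- as.integer(m[2]); hi <- as.integer(m[3])
      hit <- hit | (resno >= lo & resno <= hi)
    } else if (grepl("^-?[0-9]+[A-Za-z]$", t)) {
      n <- as.integer(sub("[A-Za-z]$", "", t))
      ic <- toupper(sub("^-?[0-9]+", "", t))
      hit <- hit | (resno == n & toupper(icode) == ic)
    } else if (grepl("^-?[0-9]+$", t)) {
      hit <- hit | (resno == as.integer(t) & icode == "")
    } else {
      stop_mitorf(sprintf("bad residue token '%s'", t), "selection_error")
    }
  }
  hit
}

#' Coordinates of selected atoms
#'
#' @inheritParams select_atoms
#' @param sel Optional selection; all atoms when `NULL`.
#' @return Numeric matrix (n x 3) with atom-id rownames.
#' @export
model_coords <- function(model, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(nrow(model$atoms))
         else select_atoms(model, sel)
  m <- as.matrix(model$atoms[idx, c("x", "y", "z"), drop = FALSE])
  rownames(m) <- atom_key(model$atoms)[idx]
  m
}
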