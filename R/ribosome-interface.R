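# Decoding-center state classification, binding-compatibility verdicts
# and switch-loop interaction inventories.

#' Decoding-center specification
#'
#' Identifies the decoding nucleotides A-1492 and A-1493, the helix-69
#' partner A-1914, and the local rRNA frame atoms used for
#' superposition (defaults match the synthetic templates of
#' [decoding_center_template()]; for experimental structures set the
#' chains and frame selection to the file's numbering).
#'
#' @param chain Chain id of the small-subunit rRNA.
#' @param a1492,a1493 Residue numbers of the decoding adenosines.
#' @param h69_chain Chain id holding the helix-69 partner.
#' @param a1914 Residue number of the helix-69 adenosine.
#' @param frame Selection (see [select_atoms()]) of invariant rRNA
#'   frame atoms flanking the decoding bases.
#' @return Object of class `decoding_center_spec`.
#' @export
decoding_center_spec <- function(chain = "A", a1492 = 1492, a1493 = 1493,
                                 h69_chain = "B", a1914 = 1914,
                                 frame = "A:1491,1494:*") {
  structure(list(chain = chain, a1492 = a1492, a1493 = a1493,
                 h69_chain = h69_chain, a1914 = a1914, frame = frame),
            class = "decoding_center_spec")
}

dc_nucleotide_sel <- function(spec, which = c("all", "bases")) {
  which <- match.arg(which)
  list(sprintf("%s:%d,%d:*", spec$chain, spec$a1492, spec$a1493),
       sprintf("%s:%d:*", spec$h69_chain, spec$a1914))
}

resolve_dc <- function(model, spec) {
  for (res in c(spec$a1492, spec$a1493)) {
    if (length(select_atoms(model, sprintf("%s:%d:*", spec$chain, res))) == 0L)
      stop_mitorf(sprintf("decoding nucleotide %s:%d not resolvable in model",
                          spec$chain, res), "resolution_error")
  }
  invisible(TRUE)
}

# key-matched coordinate correspondence between two models
matched_coords <- function(model_a, model_b, sel) {
  ca <- model_coords(model_a, sel)
  cb <- model_coords(model_b, sel)
  common <- intersect(rownames(ca), rownames(cb))
  list(a = ca[common, , drop = FALSE], b = cb[common, , drop = FALSE])
}

#' Classify the decoding-center conformational state
#'
#' Superposes the local rRNA frame of the model onto each labeled
#' template, computes the RMSD over the A-1492/A-1493 base ring atoms,
#' and returns the label of the least-RMSD template.  Ties break in the
#' order stacked < unstacked < recognized.
#'
#' @param model A [structure_model()] containing the decoding center.
#' @param spec A [decoding_center_spec()].
#' @param templates Named list of labeled template models (default: the
#'   three synthetic idealized templates).
#' @return `"stacked"`, `"unstacked"` or `"recognized"`, with the
#'   per-template RMSDs in attribute `rmsd`.
#' @export
classify_decoding_state <- function(model, spec = decoding_center_spec(),
                                    templates = decoding_center_templates()) {
  resolve_dc(model, spec)
  base_sel <- sprintf("%s:%d,%d:%s", spec$chain, spec$a1492, spec$a1493,
                      paste(BASE_RING_ATOMS, collapse = ","))
  order_pref <- c("stacked", "unstacked", "recognized")
  labels <- intersect(order_pref, names(templates))
  rmsds <- vapply(labels, function(lab) {
    tmpl <- templates[[lab]]
    fr <- matched_coords(model, tmpl, spec$frame)
    if (nrow(fr$a) < 3L)
      stop_mitorf("fewer than 3 shared frame atoms with template",
                  "resolution_error")
    tr <- superpose(fr$a, fr$b)
    ba <- matched_coords(model, tmpl, base_sel)
    if (nrow(ba$a) == 0L)
      stop_mitorf("no shared base atoms with template", "resolution_error")
    moved <- apply_transform(ba$a, tr)
    sqrt(mean(rowSums((moved - ba$b)^2)))
  }, numeric(1))
  out <- labels[which.min(rmsds)]   # which.min takes the first = preference order
  attr(out, "rmsd") <- rmsds
  out
}

#' Binding compatibility of a release factor with a decoding-center state
#'
#' Given a release-factor model posed in the ribosome frame, reports
#' whether that pose is sterically compatible with the decoding center:
#' the verdict is `compatible` iff there is no severe clash between any
#' release-factor atom and the decoding nucleotides (A-1492, A-1493 and
#' the helix-69 A-1914).  This is the computable core of the
#' observation that the RT-insert arginine of mtRF1 occupies the
#' position of the stop-codon-recognized A-1493, so mtRF1 can bind only
#' when both bases are stacked (empty A-site).
#'
#' @param rf_model Release-factor [structure_model()] in the ribosome
#'   frame.
#' @param ribosome_model Ribosome (decoding-center) model in the same
#'   frame.
#' @param spec A [decoding_center_spec()] resolvable in
#'   `ribosome_model`.
#' @param state Optional state label to record in the verdict; when
#'   `NULL` it is computed with [classify_decoding_state()].
#' @param overlap_threshold Severe-clash overlap threshold, Angstrom.
#' @return Object of class `compatibility_verdict`: `state`, `clashes`
#'   (data frame as from [detect_clashes()], release-factor atoms vs
#'   decoding nucleotides only), `compatible` (TRUE iff no clashes).
#' @export
binding_compatibility <- function(rf_model, ribosome_model,
                                  spec = decoding_center_spec(),
                                  state = NULL, overlap_threshold = 0.4) {
  resolve_dc(ribosome_model, spec)
  if (is.null(state))
    state <- as.character(classify_decoding_state(ribosome_model, spec))
  combined <- merge_models(rf_model, ribosome_model)
  rf_sel <- list(chain = unique(rf_model$atoms$chain))
  clashes <- empty_clashes()
  for (sel in dc_nucleotide_sel(spec)) {
    if (length(select_atoms(combined, sel)) == 0L) next
    clashes <- rbind(clashes,
                     detect_clashes(combined, rf_sel, sel,
                                    overlap_threshold = overlap_threshold))
  }
  structure(list(state = state, clashes = clashes,
                 compatible = nrow(clashes) == 0L),
            class = "compatibility_verdict")
}

#' @export
print.compatibility_verdict <- function(x, ...) {
  cat(sprintf("Decoding center %s: %s (%d severe clash(es))\n", x$state,
              if (x$compatible) "compatible" else "incompatible",
              nrow(x$clashes)))
  invisible(x)
}

#' Switch-loop interaction inventory
#'
#' All hydrogen bonds between the release-factor switch loop (reference
#' residues 286--301) and its partners, each labeled by partner class:
#' `decoding_center` (A-1492/A-1493/A-1914), `insert` (residues named
#' in `insert_residues`, e.g. the RT-insert arginine), `helix_capping`
#' (partners at the helix alpha-7 capping positions 298/301) or
#' `intramolecular` (anything else in the release-factor chain).
#'
#' @param model [structure_model()] containing the release factor and
#'   (optionally) the decoding center in one frame.
#' @param table A [region_table()] supplying the switch-loop interval.
#' @param spec A [decoding_center_spec()] naming the decoding
#'   nucleotides (used for partner classification only; absent
#'   nucleotides simply yield no such partners).
#' @param rf_chain Chain id of the release factor.
#' @param insert_residues Optional character vector of insert residue
#'   keys `"resno[icode]"` in `rf_chain` (e.g. `"115A"` for R-RTi).
#' @param ... Geometry parameters passed to [detect_hbonds()].
#' @return Data frame of class `switch_loop_inventory`: `loop_position`
#'   (switch-loop residue number), `loop_atom`, `partner` (atom id),
#'   `partner_class`, `distance`, `angle`.
#' @export
switch_loop_interactions <- function(model, table = region_table(),
                                     spec = decoding_center_spec(),
                                     rf_chain = "R",
                                     insert_residues = NULL, ...) {
  iv <- table$intervals
  sw <- iv[iv$region == "switch_loop", ]
  loop_sel <- sprintf("%s:%d-%d:*", rf_chain, sw$start, sw$end)
  loop_idx <- select_atoms(model, loop_sel)
  if (length(loop_idx) == 0L)
    stop_mitorf("switch-loop residues not resolvable", "resolution_error")
  hb <- detect_hbonds(model, loop_idx, seq_len(nrow(model$atoms)), ...)
  if (nrow(hb) == 0L) return(empty_inventory())

  ids <- atom_ids(model)
  loop_ids <- ids[loop_idx]
  capping <- c(298L, 301L)
  parse_id <- function(id) {
    parts <- strsplit(id, ":", fixed = TRUE)[[1]]
    list(chain = parts[1], res = parts[2], atom = parts[3],
         resno = as.integer(sub("[A-Za-z]+$", "", parts[2])))
  }
  rows <- lapply(seq_len(nrow(hb)), function(i) {
    d <- hb$donor[i]; a <- hb$acceptor[i]
    d_in <- d %in% loop_ids; a_in <- a %in% loop_ids
    dp <- parse_id(d); ap <- parse_id(a)
    if (d_in && a_in) {
      # loop-internal bond: inventoried only when exactly one side is a
      # helix alpha-7 capping position (298/301)
      d_cap <- dp$resno %in% capping; a_cap <- ap$resno %in% capping
      if (xor(d_cap, a_cap)) {
        lp <- if (d_cap) ap else dp
        partner_id <- if (d_cap) d else a
        return(data.frame(loop_position = lp$resno, loop_atom = lp$atom,
                          partner = partner_id,
                          partner_class = "helix_capping",
                          distance = hb$distance[i], angle = hb$angle[i],
                          stringsAsFactors = FALSE))
      }
      return(NULL)
    }
    lp <- if (d_in) dp else ap
    partner_id <- if (d_in) a else d
    pp <- if (d_in) ap else dp
    dc_keys <- c(paste0(spec$chain, ":", spec$a1492),
                 paste0(spec$chain, ":", spec$a1493),
                 paste0(spec$h69_chain, ":", spec$a1914))
    partner_key <- paste0(pp$chain, ":", pp$res)
    cls <- if (partner_key %in% dc_keys) "decoding_center"
      else if (pp$chain == rf_chain && !is.null(insert_residues) &&
               pp$res %in% insert_residues) "insert"
      else "intramolecular"
    data.frame(loop_position = lp$resno, loop_atom = lp$atom,
               partner = partner_id, partner_class = cls,
               distance = hb$distance[i], angle = hb$angle[i],
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty_inventory())
  out <- do.call(rbind, rows)
  out <- out[order(out$loop_position, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("switch_loop_inventory", "data.frame")
  out
}

empty_inventory <- function() {
  out <- data.frame(loop_position = integer(), loop_atom = character(),
                    partner = character(), partner_class = character(),
                    distance = numeric(), angle = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("switch_loop_inventory", "data.frame")
  out
}

#' Compare two switch-loop interaction inventories
#'
#' For each switch-loop position bonded in one inventory, reports
#' whether the other inventory bonds the same position (matched, with
#' the partner identities) or not; the symmetric difference is reported
#' both ways.  Used to show functional replacement of an interaction —
#' e.g. the A-1493 contact at position 295 in the RF1/ribosome complex
#' being taken over by the RT-insert arginine in mtRF1.
#'
#' @param inventory_a,inventory_b `switch_loop_inventory` data frames.
#' @return Data frame: `loop_position`, `in_a`, `in_b`, `matched`,
#'   `partners_a`, `partners_b`, `same_partner`.
#' @export
interaction_replacement <- function(inventory_a, inventory_b) {
  pos <- sort(union(inventory_a$loop_position, inventory_b$loop_position))
  rows <- lapply(pos, function(p) {
    pa <- sort(unique(inventory_a$partner[inventory_a$loop_position == p]))
    pb <- sort(unique(inventory_b$partner[inventory_b$loop_position == p]))
    data.frame(loop_position = p,
               in_a = length(pa) > 0L, in_b = length(pb) > 0L,
               matched = length(pa) > 0L && length(pb) > 0L,
               partners_a = paste(pa, collapse = ";"),
               partners_b = paste(pb, collapse = ";"),
               same_partner = identical(pa, pb),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
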