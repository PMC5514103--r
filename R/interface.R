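#' @title Interface analysis: buried area and typed contacts
#' @description Buried solvent-accessible area, interface residue sets,
#'   per-chain contributions and the typed atomic contact inventory
#'   (hydrogen bonds, salt bridges, van der Waals contacts, water-mediated
#'   bridges) for one antigen-binder pair. All criteria are heavy-atom,
#'   distance-based: crystal structures at typical antibody-complex
#'   resolutions carry no reliable hydrogens, so no angle terms are used by
#'   default.
#' @name interface_analysis
NULL

#' Contact criteria bundle
#'
#' Distance cutoffs (Angstrom) and SASA parameters used by the interface
#' detectors; every report records the criteria that produced it.
#' Category precedence is salt_bridge > hydrogen_bond > vdw: an atom pair
#' is reported under exactly one category.
#'
#' @param hbond donor-acceptor heavy-atom cutoff (default 3.5)
#' @param salt_bridge charged-N to charged-O cutoff (default 4.0)
#' @param vdw any cross-side heavy-atom pair cutoff (default 4.0)
#' @param water_bridge water-O to polar-atom cutoff (default 3.5)
#' @param dsasa_min per-residue buried-area threshold for interface
#'   membership (default 0.1 A^2)
#' @param probe,n_points SASA parameters
#' @return named list of criteria
#' @export
contact_criteria <- function(hbond = 3.5, salt_bridge = 4.0, vdw = 4.0,
                             water_bridge = 3.5, dsasa_min = 0.1,
                             probe = 1.4, n_points = 960) {
  stopifnot(hbond > 0, salt_bridge > 0, vdw > 0, water_bridge > 0)
  list(hbond = hbond, salt_bridge = salt_bridge, vdw = vdw,
       water_bridge = water_bridge, dsasa_min = dsasa_min,
       probe = probe, n_points = n_points)
}

## ---- donor/acceptor and charged-group typing tables (heavy atoms) -------

.SC_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2",
  GLN = "NE2", HIS = c("ND1", "NE2"), LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), TRP = "NE1", HOH = "O")

.SC_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  MET = "SD", HOH = "O")

.SB_BASIC <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                  HIS = c("ND1", "NE2"))
.SB_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

in_typing_table <- function(resname, atom, table) {
  hit <- rep(FALSE, length(resname))
  idx <- match(resname, names(table))
  ok <- which(!is.na(idx))
  hit[ok] <- vapply(ok, function(k) atom[k] %in% table[[idx[k]]], logical(1))
  hit
}

is_hb_donor <- function(resname, atom) {
  (atom == "N" & resname != "PRO" & resname != "HOH") |
    in_typing_table(resname, atom, .SC_DONORS)
}

is_hb_acceptor <- function(resname, atom) {
  (atom %in% c("O", "OXT") & resname != "HOH") |
    in_typing_table(resname, atom, .SC_ACCEPTORS)
}

is_sb_basic <- function(resname, atom) in_typing_table(resname, atom, .SB_BASIC)

is_sb_acidic <- function(resname, atom) {
  atom == "OXT" | in_typing_table(resname, atom, .SB_ACIDIC)
}

## ---- side selection helpers ---------------------------------------------

## a "side" is a selection spec: a list of select_atoms() arguments,
## e.g. list(role = "antigen") or list(chain = c("H","L"))
side_model <- function(model, side, drop_water = TRUE) {
  sub <- do.call(select_atoms, c(list(model), side))
  if (drop_water) {
    keep <- sub$atoms$resname != "HOH"
    if (!any(keep)) stop("side selection contains only waters")
    sub$atoms <- sub$atoms[keep, , drop = FALSE]
  }
  sub
}

check_disjoint <- function(a, b) {
  ka <- paste(a$atoms$chain, a$atoms$serial)
  kb <- paste(b$atoms$chain, b$atoms$serial)
  if (length(intersect(ka, kb)))
    stop("side selections overlap (", length(intersect(ka, kb)),
         " shared atoms)")
}

## cross-side heavy-atom pairs within cutoff, with atom annotations
cross_pairs <- function(model, side_a, side_b, cutoff) {
  a <- side_model(model, side_a); b <- side_model(model, side_b)
  check_disjoint(a, b)
  na <- nrow(a$atoms)
  all_at <- rbind(a$atoms, b$atoms)
  np <- neighbor_pairs(as.matrix(all_at[, c("x", "y", "z")]), cutoff)
  cross <- (np$i <= na) != (np$j <= na)
  np <- np[cross, , drop = FALSE]
  ia <- ifelse(np$i <= na, np$i, np$j)
  ib <- ifelse(np$i <= na, np$j, np$i)
  data.frame(
    chain_a = all_at$chain[ia], resno_a = all_at$resno[ia],
    icode_a = all_at$icode[ia], resname_a = all_at$resname[ia],
    atom_a = all_at$atom[ia], role_a = all_at$role[ia],
    chain_b = all_at$chain[ib], resno_b = all_at$resno[ib],
    icode_b = all_at$icode[ib], resname_b = all_at$resname[ib],
    atom_b = all_at$atom[ib], role_b = all_at$role[ib],
    distance = np$distance, stringsAsFactors = FALSE)
}

contact_records <- function(pairs, category) {
  if (nrow(pairs) == 0)
    return(cbind(pairs[0, , drop = FALSE],
                 data.frame(category = character(), water = character())))
  pairs$category <- category
  pairs$water <- NA_character_
  pairs[order(pairs$chain_a, pairs$resno_a, pairs$chain_b, pairs$resno_b,
              pairs$atom_a, pairs$atom_b), , drop = FALSE]
}

pair_key <- function(p) {
  paste(p$chain_a, p$resno_a, p$icode_a, p$atom_a,
        p$chain_b, p$resno_b, p$icode_b, p$atom_b, sep = "|")
}

## ---- buried area ---------------------------------------------------------

#' Buried solvent-accessible area of an interface
#'
#' BSA = SASA(side a alone) + SASA(side b alone) - SASA(complex), i.e. the
#' total area buried over both partners (so a receptor-ligand interface of
#' ~1000 A^2 per side reports ~2000 A^2). Waters are always excluded.
#'
#' @param model structure_model with radii assigned
#' @param side_a,side_b selection specs (lists of [select_atoms()]
#'   arguments), e.g. `list(role = "antigen")`
#' @param criteria [contact_criteria()]
#' @return object of class `interface_summary`: bsa_total, per-side and
#'   per-chain buried areas, per-residue delta-SASA vectors, interface
#'   residue sets (at `criteria$dsasa_min`, unioned with residues having a
#'   cross-side contact within `criteria$vdw`), and the criteria snapshot
#' @export
buried_area <- function(model, side_a, side_b, criteria = contact_criteria()) {
  a <- side_model(model, side_a); b <- side_model(model, side_b)
  check_disjoint(a, b)
  sa <- shrake_rupley_sasa(a, criteria$probe, criteria$n_points)
  sb <- shrake_rupley_sasa(b, criteria$probe, criteria$n_points)
  ab <- combine_models(a, b, allow_shared_chains = FALSE)
  sab <- shrake_rupley_sasa(ab, criteria$probe, criteria$n_points)
  bsa_total <- sa$total + sb$total - sab$total
  dsasa_side <- function(s_alone) {
    d <- s_alone$per_residue - sab$per_residue[names(s_alone$per_residue)]
    d
  }
  da <- dsasa_side(sa); db <- dsasa_side(sb)
  ## per-chain buried area (sum of atom-level loss per chain)
  chain_of <- function(s) s$per_atom$chain
  atom_loss <- function(s_alone) {
    key_alone <- paste(s_alone$per_atom$uid, s_alone$per_atom$atom)
    key_cplx <- paste(sab$per_atom$uid, sab$per_atom$atom)
    s_alone$per_atom$area - sab$per_atom$area[match(key_alone, key_cplx)]
  }
  la <- atom_loss(sa); lb <- atom_loss(sb)
  per_chain_a <- tapply(la, chain_of(sa), sum)
  per_chain_b <- tapply(lb, chain_of(sb), sum)
  contact <- cross_pairs(model, side_a, side_b, criteria$vdw)
  uid_a_contact <- unique(paste(contact$chain_a, contact$resno_a,
                                contact$icode_a, sep = "|"))
  uid_b_contact <- unique(paste(contact$chain_b, contact$resno_b,
                                contact$icode_b, sep = "|"))
  residues_a <- union(names(da)[da > criteria$dsasa_min], uid_a_contact)
  residues_b <- union(names(db)[db > criteria$dsasa_min], uid_b_contact)
  keys <- residue_keys(ab)
  out <- list(
    bsa_total = bsa_total,
    sasa_a = sa$total, sasa_b = sb$total, sasa_complex = sab$total,
    buried_chain_a = stats::setNames(as.numeric(per_chain_a),
                                     names(per_chain_a)),
    buried_chain_b = stats::setNames(as.numeric(per_chain_b),
                                     names(per_chain_b)),
    dsasa_a = da, dsasa_b = db,
    residues_a = residues_a[order(match(residues_a, keys$uid))],
    residues_b = residues_b[order(match(residues_b, keys$uid))],
    residue_keys = keys,
    params = criteria)
  class(out) <- "interface_summary"
  out
}

#' @export
print.interface_summary <- function(x, ...) {
  cat(sprintf("interface_summary: BSA %.0f A^2 (%d + %d interface residues)\n",
              x$bsa_total, length(x$residues_a), length(x$residues_b)))
  invisible(x)
}

#' Per-chain contribution to one side's buried area
#'
#' fraction(chain) = buried(chain) / sum(buried over that side's chains).
#'
#' @param summary interface_summary from [buried_area()]
#' @param side "a" or "b"
#' @return named numeric vector of fractions summing to 1
#' @export
chain_contribution <- function(summary, side = c("b", "a")) {
  side <- match.arg(side)
  v <- if (side == "a") summary$buried_chain_a else summary$buried_chain_b
  tot <- sum(v)
  if (tot <= 0) stop("zero buried area: contribution undefined")
  v / tot
}

#' Interface residue sets
#'
#' Residues whose per-residue SASA loss on complexation exceeds
#' `dsasa_min`, unioned with residues having any cross-side heavy-atom
#' pair within the vdW cutoff (so contact-only residues are not missed).
#'
#' @param model structure_model with radii assigned
#' @param side_a,side_b selection specs
#' @param criteria [contact_criteria()]; `dsasa_min` is the SASA-loss
#'   threshold in A^2
#' @return list(residues_a, residues_b): residue uid vectors, plus
#'   `keys` data.frame to translate uids to labels
#' @export
interface_residues <- function(model, side_a, side_b,
                               criteria = contact_criteria()) {
  s <- buried_area(model, side_a, side_b, criteria)
  list(residues_a = s$residues_a, residues_b = s$residues_b,
       keys = s$residue_keys)
}

## ---- contact detectors ---------------------------------------------------

#' Detect cross-side hydrogen bonds
#'
#' Every cross-side donor-acceptor heavy-atom pair within `d_max`.
#' Distance-only criterion (no hydrogens in the input structures). Pairs
#' that also satisfy salt-bridge typing are reported by
#' [detect_salt_bridges()] instead, never here.
#'
#' @param model structure_model
#' @param side_a,side_b selection specs
#' @param d_max cutoff in Angstrom
#' @return data.frame of contact records (category "hydrogen_bond")
#' @export
detect_hbonds <- function(model, side_a, side_b, d_max = 3.5) {
  p <- cross_pairs(model, side_a, side_b, d_max)
  da <- (is_hb_donor(p$resname_a, p$atom_a) &
           is_hb_acceptor(p$resname_b, p$atom_b)) |
        (is_hb_acceptor(p$resname_a, p$atom_a) &
           is_hb_donor(p$resname_b, p$atom_b))
  sb <- (is_sb_basic(p$resname_a, p$atom_a) &
           is_sb_acidic(p$resname_b, p$atom_b)) |
        (is_sb_acidic(p$resname_a, p$atom_a) &
           is_sb_basic(p$resname_b, p$atom_b))
  contact_records(p[da & !sb, , drop = FALSE], "hydrogen_bond")
}

#' Detect cross-side salt bridges
#'
#' Charged side-chain nitrogen (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2) to
#' charged oxygen (Asp OD1/OD2, Glu OE1/OE2, C-terminal OXT) pairs within
#' `d_max`. Two or more pairs between one residue pair constitute a
#' bidentate salt bridge.
#'
#' @inheritParams detect_hbonds
#' @return data.frame of contact records (category "salt_bridge") with a
#'   `bidentate` logical column per record's residue pair
#' @export
detect_salt_bridges <- function(model, side_a, side_b, d_max = 4.0) {
  p <- cross_pairs(model, side_a, side_b, d_max)
  sb <- (is_sb_basic(p$resname_a, p$atom_a) &
           is_sb_acidic(p$resname_b, p$atom_b)) |
        (is_sb_acidic(p$resname_a, p$atom_a) &
           is_sb_basic(p$resname_b, p$atom_b))
  rec <- contact_records(p[sb, , drop = FALSE], "salt_bridge")
  if (nrow(rec)) {
    respair <- paste(rec$chain_a, rec$resno_a, rec$icode_a,
                     rec$chain_b, rec$resno_b, rec$icode_b)
    rec$bidentate <- respair %in% names(which(table(respair) >= 2))
  } else rec$bidentate <- logical(0)
  rec
}

#' Detect cross-side van der Waals contacts
#'
#' All cross-side heavy-atom pairs within `d_max` not already typed as
#' hydrogen bond or salt bridge (at cutoffs `criteria$hbond` /
#' `criteria$salt_bridge`).
#'
#' @inheritParams detect_hbonds
#' @param criteria [contact_criteria()] supplying the polar-contact cutoffs
#'   used for the exclusion
#' @return data.frame of contact records (category "vdw")
#' @export
detect_vdw_contacts <- function(model, side_a, side_b, d_max = 4.0,
                                criteria = contact_criteria()) {
  p <- cross_pairs(model, side_a, side_b, d_max)
  if (nrow(p) == 0) return(contact_records(p, "vdw"))
  hb <- detect_hbonds(model, side_a, side_b, criteria$hbond)
  sb <- detect_salt_bridges(model, side_a, side_b, criteria$salt_bridge)
  typed <- c(pair_key(hb), pair_key(sb))
  contact_records(p[!(pair_key(p) %in% typed), , drop = FALSE], "vdw")
}

#' Detect water-mediated hydrogen-bond bridges
#'
#' A water bridges the interface when its oxygen lies within `d_max` of at
#' least one polar (N/O) atom of side a AND one of side b. One record is
#' emitted per (water, a-atom, b-atom) triple; the number of distinct
#' bridging waters is attached as attribute `n_waters`.
#'
#' @inheritParams detect_hbonds
#' @return data.frame of contact records (category "water_bridge", `water`
#'   column = water residue uid), with attribute `n_waters`
#' @export
detect_water_bridges <- function(model, side_a, side_b, d_max = 3.5) {
  w <- select_atoms(model, role = "water", elety = "O", allow_empty = TRUE)
  a <- side_model(model, side_a); b <- side_model(model, side_b)
  empty <- contact_records(
    cross_pairs(model, side_a, side_b, 0.1)[0, , drop = FALSE],
    "water_bridge")
  if (nrow(w$atoms) == 0) {
    attr(empty, "n_waters") <- 0L
    return(empty)
  }
  polar <- function(m) m$atoms[m$atoms$element %in% c("N", "O"), , drop = FALSE]
  pa <- polar(a); pb <- polar(b)
  wat <- w$atoms
  out <- list(); n <- 0L
  for (k in seq_len(nrow(wat))) {
    dxa <- sqrt((pa$x - wat$x[k])^2 + (pa$y - wat$y[k])^2 + (pa$z - wat$z[k])^2)
    dxb <- sqrt((pb$x - wat$x[k])^2 + (pb$y - wat$y[k])^2 + (pb$z - wat$z[k])^2)
    ia <- which(dxa <= d_max); ib <- which(dxb <= d_max)
    if (!length(ia) || !length(ib)) next
    g <- expand.grid(ia = ia, ib = ib)
    n <- n + 1L
    out[[n]] <- data.frame(
      chain_a = pa$chain[g$ia], resno_a = pa$resno[g$ia],
      icode_a = pa$icode[g$ia], resname_a = pa$resname[g$ia],
      atom_a = pa$atom[g$ia], role_a = pa$role[g$ia],
      chain_b = pb$chain[g$ib], resno_b = pb$resno[g$ib],
      icode_b = pb$icode[g$ib], resname_b = pb$resname[g$ib],
      atom_b = pb$atom[g$ib], role_b = pb$role[g$ib],
      distance = pmax(dxa[g$ia], dxb[g$ib]),
      category = "water_bridge",
      water = paste(wat$chain[k], wat$resno[k], wat$icode[k], sep = "|"),
      stringsAsFactors = FALSE)
  }
  res <- if (n) do.call(rbind, out) else empty
  attr(res, "n_waters") <- n
  res
}

#' Full typed contact table for one interface
#'
#' Runs all detectors under one criteria bundle and returns one row per
#' contact with residue labels in the `role_X123` style (one-letter code,
#' author numbering), plus summary counts by category.
#'
#' @param model structure_model
#' @param side_a,side_b selection specs
#' @param criteria [contact_criteria()]
#' @return list(table = data.frame(residue_a, residue_b, atoms, distance_A,
#'   category, water_id), counts = named integer vector, n_bridging_waters)
#' @export
contact_table <- function(model, side_a, side_b,
                          criteria = contact_criteria()) {
  sb <- detect_salt_bridges(model, side_a, side_b, criteria$salt_bridge)
  sb$bidentate <- NULL
  hb <- detect_hbonds(model, side_a, side_b, criteria$hbond)
  vd <- detect_vdw_contacts(model, side_a, side_b, criteria$vdw, criteria)
  wb <- detect_water_bridges(model, side_a, side_b, criteria$water_bridge)
  all <- rbind(sb, hb, vd, wb)
  lab <- function(role, resname, resno)
    sprintf("%s_%s%d", role, aa_three_to_one(resname), resno)
  tab <- data.frame(
    residue_a = lab(all$role_a, all$resname_a, all$resno_a),
    residue_b = lab(all$role_b, all$resname_b, all$resno_b),
    atoms = paste(all$atom_a, all$atom_b, sep = "-"),
    distance_A = round(all$distance, 2),
    category = all$category,
    water_id = ifelse(is.na(all$water), "", all$water),
    stringsAsFactors = FALSE)
  counts <- c(hydrogen_bond = nrow(hb), salt_bridge = nrow(sb),
              vdw = nrow(vd), water_bridge = nrow(wb))
  list(table = tab, counts = counts,
       n_bridging_waters = attr(wb, "n_waters") %||% 0L,
       params = criteria)
}
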