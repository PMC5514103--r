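#' @title Hierarchical coordinate model
#' @description A `structure_model` holds the heavy-atom coordinates of one
#'   macromolecular model as a flat atom table plus a chain-level role map.
#'   Roles distinguish the antigen from the antibody heavy/light chains and
#'   solvent so that downstream interface operations can select sides by
#'   biological meaning rather than by chain letter.
#' @name structure_model
NULL

.ATOM_COLS <- c("serial", "atom", "resname", "chain", "resno", "icode",
                "x", "y", "z", "occ", "alt", "b", "element", "type")

.ROLES <- c("antigen", "heavy", "light", "water", "other")

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns serial, atom, resname, chain, resno,
#'   icode, x, y, z, occ, alt, b, element, type ("ATOM"/"HETATM"). A `radius`
#'   column is added by [assign_radii()].
#' @param source_id character scalar identifying the source (file/accession).
#' @param role_map named character vector chain_id -> role
#'   (antigen/heavy/light/water/other). Unlisted chains become "other";
#'   water residues (HOH) are always role "water".
#' @return object of class `structure_model`
#' @export
structure_model <- function(atoms, source_id = "unknown", role_map = NULL) {
  missing_cols <- setdiff(.ATOM_COLS, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  m <- list(atoms = atoms, source_id = source_id, role_map = character())
  class(m) <- "structure_model"
  assign_roles(m, role_map %||% character(), warn_unlisted = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.structure_model <- function(x, ...) {
  at <- x$atoms
  cat(sprintf("structure_model '%s': %d atoms, %d residues, %d chains\n",
              x$source_id, nrow(at), n_residues(x), length(unique(at$chain))))
  rm <- x$role_map
  if (length(rm))
    cat("  roles:", paste(sprintf("%s=%s", names(rm), rm), collapse = " "), "\n")
  invisible(x)
}

#' Number of residues in a model
#' @param model structure_model
#' @return integer count of distinct (chain, resno, icode) triples
#' @export
n_residues <- function(model) length(unique(residue_uid(model$atoms)))

## internal residue unique id "chain|resno|icode"
residue_uid <- function(atoms) paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")

#' Residue keys of a model
#'
#' One row per residue in file order: chain, resno, icode, resname and the
#' internal uid used to index per-residue results.
#' @param model structure_model
#' @return data.frame(chain, resno, icode, resname, uid)
#' @export
residue_keys <- function(model) {
  at <- model$atoms
  uid <- residue_uid(at)
  keep <- !duplicated(uid)
  data.frame(chain = at$chain[keep], resno = at$resno[keep],
             icode = at$icode[keep], resname = at$resname[keep],
             uid = uid[keep], stringsAsFactors = FALSE)
}

#' Assign chain roles
#'
#' Sets the chain -> role map. Chains absent from `role_spec` get role
#' "other" (with a warning); HOH residues are forced to role "water"
#' regardless of the chain's role.
#'
#' @param model structure_model
#' @param role_spec named character vector, names are chain ids, values in
#'   antigen/heavy/light/water/other
#' @param warn_unlisted warn about chains not covered by `role_spec`
#' @return model with role_map set and a per-atom `role` column
#' @export
assign_roles <- function(model, role_spec, warn_unlisted = TRUE) {
  at <- model$atoms
  chains <- unique(at$chain)
  if (length(role_spec)) {
    bad <- setdiff(names(role_spec), chains)
    if (length(bad))
      stop("role_spec names chain(s) absent from model: ",
           paste(bad, collapse = ", "))
    badrole <- setdiff(role_spec, .ROLES)
    if (length(badrole))
      stop("unknown role(s): ", paste(badrole, collapse = ", "))
  }
  role_map <- stats::setNames(rep("other", length(chains)), chains)
  role_map[names(role_spec)] <- unname(role_spec)
  unlisted <- setdiff(chains, names(role_spec))
  ## chains that are pure water get role water silently
  for (ch in unlisted) {
    if (all(at$resname[at$chain == ch] == "HOH")) role_map[ch] <- "water"
  }
  unlisted <- setdiff(unlisted, names(role_map)[role_map == "water"])
  if (warn_unlisted && length(role_spec) && length(unlisted))
    warning("chain(s) not in role_spec given role 'other': ",
            paste(unlisted, collapse = ", "))
  role <- unname(role_map[at$chain])
  role[at$resname == "HOH"] <- "water"
  model$atoms$role <- role
  model$role_map <- role_map
  model
}

#' Select a substructure
#'
#' Filter by role, chain and/or author residue-number range; filters combine
#' with AND. Residue keys, radii and roles are preserved in the sub-model.
#'
#' @param model structure_model
#' @param role roles to keep (e.g. "antigen", c("heavy","light"))
#' @param chain chain ids to keep
#' @param resno integer vector of author residue numbers to keep
#' @param elety atom names to keep (e.g. "CA")
#' @param allow_empty return an empty model instead of erroring
#' @return structure_model restricted to matching atoms
#' @export
select_atoms <- function(model, role = NULL, chain = NULL, resno = NULL,
                         elety = NULL, allow_empty = FALSE) {
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(role))  keep <- keep & at$role %in% role
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(elety)) keep <- keep & at$atom %in% elety
  if (!any(keep) && !allow_empty)
    stop("empty selection (role=", paste(role, collapse = ","),
         " chain=", paste(chain, collapse = ","), ")")
  out <- model
  out$atoms <- at[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$role_map <- model$role_map[names(model$role_map) %in% out$atoms$chain]
  out
}

#' Coordinates of a model as an n x 3 matrix
#' @param model structure_model
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Replace coordinates of a model
#' @param model structure_model
#' @param xyz n x 3 matrix in atom order
#' @return model with new coordinates
#' @export
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms), ncol(xyz) == 3)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

#' Combine two models into one
#'
#' Atom tables are concatenated; chain ids must not collide unless
#' `allow_shared_chains` (used when re-joining selections of one model).
#' @param a,b structure_model
#' @param allow_shared_chains logical
#' @return structure_model
#' @export
combine_models <- function(a, b, allow_shared_chains = FALSE) {
  shared <- intersect(unique(a$atoms$chain), unique(b$atoms$chain))
  if (length(shared) && !allow_shared_chains)
    stop("chain id collision: ", paste(shared, collapse = ", "))
  at <- rbind(a$atoms, b$atoms)
  m <- list(atoms = at, source_id = paste(a$source_id, b$source_id, sep = "+"),
            role_map = c(a$role_map, b$role_map[setdiff(names(b$role_map),
                                                        names(a$role_map))]))
  class(m) <- "structure_model"
  m
}

#' One-letter sequence of a chain
#' @param model structure_model
#' @param chain chain id
#' @return character scalar (unknown residues become "X"; waters dropped)
#' @export
chain_sequence <- function(model, chain) {
  rk <- residue_keys(select_atoms(model, chain = chain))
  rk <- rk[rk$resname != "HOH", , drop = FALSE]
  paste(aa_three_to_one(rk$resname), collapse = "")
}

AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

#' Convert three-letter residue codes to one-letter
#' @param x character vector of 3-letter codes
#' @return character vector of 1-letter codes ("X" if unknown)
#' @export
aa_three_to_one <- function(x) {
  i <- match(toupper(x), AA3)
  out <- AA1[i]
  out[is.na(i)] <- "X"
  out
}
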