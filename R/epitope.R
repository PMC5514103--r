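#' @title Epitope extraction and cross-complex comparison
#' @description Places several complexes of the same antigen in a common
#'   frame, extracts the antigen residues engaged by each binder, labels
#'   them by secondary-structure region, and quantifies loop plasticity and
#'   Fab elbow flexibility across crystallographically independent copies.
#' @name epitope_comparison
NULL

#' Load a region map
#'
#' A region map names residue ranges on the antigen (author numbering),
#' e.g. the strands and loops of an IgSF V-set beta-sandwich. The packaged
#' default covers the V-set domain of human PD-L1 (aa 18-134).
#'
#' @param file TSV with columns region, start, end; default: packaged
#'   PD-L1 map
#' @return data.frame of class `region_map`
#' @export
load_region_map <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "pdl1_regions.tsv", package = "abitope")
  rm <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("region", "start", "end") %in% names(rm)))
    stop("region map needs columns region, start, end")
  ## ranges must not overlap
  pos <- unlist(mapply(seq, rm$start, rm$end, SIMPLIFY = FALSE))
  if (anyDuplicated(pos)) stop("region ranges overlap")
  class(rm) <- c("region_map", "data.frame")
  rm
}

region_of <- function(resno, region_map) {
  out <- rep("unassigned", length(resno))
  for (i in seq_len(nrow(region_map))) {
    hit <- resno >= region_map$start[i] & resno <= region_map$end[i]
    out[hit] <- region_map$region[i]
  }
  out
}

#' Superpose complexes on their shared antigen
#'
#' Each complex is rigidly transformed so that its antigen CA (or backbone)
#' atoms best fit the reference complex's antigen over the residue numbers
#' common to all complexes (correspondence by author numbering).
#'
#' @param complexes list of structure_model, each with an antigen role
#' @param reference index of the reference complex
#' @param atom_set "CA" or "backbone" (N, CA, C, O)
#' @return list of list(model = transformed model, fit = superposition);
#'   the reference entry has identity transform and rmsd 0
#' @export
superpose_on_antigen <- function(complexes, reference = 1L,
                                 atom_set = c("CA", "backbone")) {
  atom_set <- match.arg(atom_set)
  elety <- if (atom_set == "CA") "CA" else c("N", "CA", "C", "O")
  cas <- lapply(complexes, function(m)
    select_atoms(m, role = "antigen", elety = elety))
  ## restrict antigens with several copies to their first chain
  cas <- lapply(cas, function(m)
    select_atoms(m, chain = m$atoms$chain[1]))
  keysets <- lapply(cas, function(m)
    paste(m$atoms$resno, m$atoms$icode, m$atoms$atom, sep = "|"))
  common <- Reduce(intersect, keysets)
  if (length(common) < 3)
    stop("fewer than 3 common antigen positions across complexes")
  ref_xyz <- NULL
  out <- vector("list", length(complexes))
  get_xyz <- function(i) {
    m <- cas[[i]]
    idx <- match(common, keysets[[i]])
    as.matrix(m$atoms[idx, c("x", "y", "z")])
  }
  ref_xyz <- get_xyz(reference)
  for (i in seq_along(complexes)) {
    fit <- kabsch(get_xyz(i), ref_xyz)
    out[[i]] <- list(model = apply_transform(complexes[[i]], fit), fit = fit)
  }
  out
}

#' Extract the epitope of one complex
#'
#' Antigen-side interface residues (see [interface_residues()]) with
#' region labels from a region map.
#'
#' @param model structure_model with roles and radii assigned
#' @param binder_id label for the binder (e.g. the antibody name)
#' @param criteria [contact_criteria()]
#' @param region_map [load_region_map()] result, or NULL (labels become
#'   "unassigned" with a warning)
#' @param side_antigen,side_binder selection specs
#' @return object of class `epitope_set`: binder_id, residues data.frame
#'   (chain, resno, icode, resname, label, region)
#' @export
epitope_set <- function(model, binder_id = "binder",
                        criteria = contact_criteria(),
                        region_map = load_region_map(),
                        side_antigen = list(role = "antigen"),
                        side_binder = list(role = c("heavy", "light"))) {
  ir <- interface_residues(model, side_antigen, side_binder, criteria)
  keys <- ir$keys
  res <- keys[match(ir$residues_a, keys$uid), , drop = FALSE]
  res$label <- sprintf("%s%d%s", aa_three_to_one(res$resname), res$resno,
                       ifelse(res$icode == "", "", res$icode))
  if (is.null(region_map)) {
    warning("no region map supplied; epitope regions set to 'unassigned'")
    res$region <- "unassigned"
  } else {
    res$region <- region_of(res$resno, region_map)
  }
  rownames(res) <- NULL
  out <- list(binder_id = binder_id, residues = res, params = criteria)
  class(out) <- "epitope_set"
  out
}

#' @export
print.epitope_set <- function(x, ...) {
  cat(sprintf("epitope_set '%s': %d residues (%s)\n", x$binder_id,
              nrow(x$residues),
              paste(unique(x$residues$region), collapse = ", ")))
  cat(" ", paste(x$residues$label, collapse = " "), "\n")
  invisible(x)
}

## position key used to compare epitopes across complexes: author numbering
epi_pos <- function(set) paste0(set$residues$resno,
                                ifelse(set$residues$icode == "", "",
                                       set$residues$icode))

#' Compare epitopes across binders
#'
#' Set algebra on antigen residues (matched by author numbering) engaged
#' by each binder: intersection, union and pairwise Jaccard indices.
#' Errors when the sets clearly come from different antigens (conflicting
#' residue identities at shared positions).
#'
#' @param sets list of [epitope_set()] objects
#' @return list(intersection, union: data.frames with label columns;
#'   jaccard: matrix)
#' @export
epitope_overlap <- function(sets) {
  if (length(sets) < 2) stop("need at least two epitope sets")
  ## consistency: a shared position must carry the same residue type
  allres <- do.call(rbind, lapply(sets, function(s)
    s$residues[, c("resno", "icode", "resname")]))
  pos <- paste(allres$resno, allres$icode)
  conflict <- tapply(allres$resname, pos, function(v) length(unique(v)) > 1)
  if (any(conflict))
    stop("epitope sets disagree on residue identity at position(s) ",
         paste(names(conflict)[conflict], collapse = ", "),
         "; are these the same antigen?")
  keys <- lapply(sets, epi_pos)
  inter <- Reduce(intersect, keys)
  uni <- Reduce(union, keys)
  n <- length(sets)
  jac <- matrix(1, n, n,
                dimnames = list(vapply(sets, `[[`, "", "binder_id"),
                                vapply(sets, `[[`, "", "binder_id")))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- union(keys[[i]], keys[[j]])
    jac[i, j] <- if (length(u) == 0) 1 else
      length(intersect(keys[[i]], keys[[j]])) / length(u)
  }
  pick <- function(poskeys) {
    r1 <- sets[[1]]$residues
    take <- do.call(rbind, lapply(sets, `[[`, "residues"))
    take <- take[!duplicated(paste0(take$resno, take$icode)), , drop = FALSE]
    out <- take[paste0(take$resno, take$icode) %in% poskeys, , drop = FALSE]
    out[order(out$resno, out$icode), , drop = FALSE]
  }
  list(intersection = pick(inter), union = pick(uni), jaccard = jac)
}

#' Loop deviation between two superposed copies of the antigen
#'
#' Superposes the two antigens on CA atoms of the core (everything except
#' the named region), then reports per-residue CA displacement over the
#' region. This isolates genuine loop plasticity from rigid-body
#' differences.
#'
#' @param model_a,model_b structure_model (antigen role assigned)
#' @param region region name in `region_map`
#' @param region_map [load_region_map()]
#' @return list(mean, max, per_residue named vector of CA displacements in
#'   Angstrom, core_rmsd)
#' @export
loop_deviation <- function(model_a, model_b, region,
                           region_map = load_region_map()) {
  rm_row <- region_map[region_map$region == region, , drop = FALSE]
  if (nrow(rm_row) != 1) stop("unknown region: ", region)
  span <- seq(rm_row$start, rm_row$end)
  ca <- function(m) {
    s <- select_atoms(m, role = "antigen", elety = "CA")
    select_atoms(s, chain = s$atoms$chain[1])
  }
  a <- ca(model_a); b <- ca(model_b)
  key <- function(m) paste(m$atoms$resno, m$atoms$icode, sep = "|")
  common <- intersect(key(a), key(b))
  core <- common[!(as.integer(sub("\\|.*", "", common)) %in% span)]
  loop <- common[as.integer(sub("\\|.*", "", common)) %in% span]
  if (length(loop) == 0)
    stop("region '", region, "' absent from the common residue set")
  if (length(core) < 3) stop("fewer than 3 core residues for superposition")
  xyz <- function(m, keys) {
    as.matrix(m$atoms[match(keys, key(m)), c("x", "y", "z")])
  }
  fit <- kabsch(xyz(a, core), xyz(b, core))
  la <- xyz(a, loop) %*% fit$rotation
  la <- sweep(la, 2, fit$translation, "+")
  disp <- sqrt(rowSums((la - xyz(b, loop))^2))
  names(disp) <- loop
  list(mean = mean(disp), max = max(disp), per_residue = disp,
       core_rmsd = fit$rmsd)
}

#' Fab elbow swing across crystallographically independent copies
#'
#' For each pair of Fab copies: superpose copy i onto copy j using
#' variable-region CA atoms, then fit the constant regions and report the
#' rotation angle of the residual transform. The elbow swing is the
#' maximum over all pairs. Invariant to any global rigid motion of a copy;
#' the sign/axis of the swing is not reported, only its magnitude.
#'
#' @param fab_copies list of structure_model, one per Fab copy; each must
#'   contain the same chains/numbering for the regions below
#' @param v_sel,c_sel selection specs for the variable and constant
#'   regions (e.g. `list(chain = "H", resno = 1:115)`); CA atoms are used
#' @return list(max_angle_deg, pairwise matrix of angles, v_rmsd matrix)
#' @export
elbow_swing <- function(fab_copies, v_sel, c_sel) {
  if (length(fab_copies) < 2) stop("need at least two Fab copies")
  if (missing(v_sel) || missing(c_sel))
    stop("variable/constant region selections are required")
  ca_of <- function(m, sel) {
    s <- do.call(select_atoms, c(list(m), sel))
    s <- select_atoms(s, elety = "CA")
    s
  }
  key <- function(m) paste(m$atoms$chain, m$atoms$resno, m$atoms$icode,
                           sep = "|")
  vs <- lapply(fab_copies, ca_of, v_sel)
  cs <- lapply(fab_copies, ca_of, c_sel)
  vcommon <- Reduce(intersect, lapply(vs, key))
  ccommon <- Reduce(intersect, lapply(cs, key))
  if (length(vcommon) < 3 || length(ccommon) < 3)
    stop("fewer than 3 common CA positions in the V or C region")
  xyz <- function(m, keys) as.matrix(m$atoms[match(keys, key(m)),
                                             c("x", "y", "z")])
  n <- length(fab_copies)
  ang <- matrix(0, n, n); vr <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    vfit <- kabsch(xyz(vs[[i]], vcommon), xyz(vs[[j]], vcommon))
    ci <- xyz(cs[[i]], ccommon) %*% vfit$rotation
    ci <- sweep(ci, 2, vfit$translation, "+")
    cfit <- kabsch(ci, xyz(cs[[j]], ccommon))
    ang[i, j] <- ang[j, i] <- rotation_angle(cfit$rotation)
    vr[i, j] <- vr[j, i] <- vfit$rmsd
  }
  list(max_angle_deg = max(ang), pairwise_deg = ang, v_rmsd = vr)
}

#' Count antigen copies in the asymmetric unit
#'
#' Number of antigen chain instances in the deposited asymmetric unit,
#' identified either by the role map (role "antigen") or by sequence
#' identity to a supplied entity sequence.
#'
#' @param model structure_model
#' @param antigen_entity NULL (use roles), a one-letter sequence, or a
#'   character vector of chain ids
#' @param min_identity sequence-identity threshold when matching by
#'   sequence (default 0.9)
#' @return integer count (0 with a warning when no antigen found)
#' @export
asu_copy_count <- function(model, antigen_entity = NULL, min_identity = 0.9) {
  chains <- setdiff(unique(model$atoms$chain),
                    unique(model$atoms$chain[model$atoms$role == "water"]))
  if (is.null(antigen_entity)) {
    hits <- names(model$role_map)[model$role_map == "antigen"]
  } else if (length(antigen_entity) == 1 && nchar(antigen_entity) > 5 &&
             !antigen_entity %in% chains) {
    hits <- chains[vapply(chains, function(ch) {
      s <- chain_sequence(model, ch)
      if (nchar(s) < 0.5 * nchar(antigen_entity)) return(FALSE)
      al <- needleman_wunsch(s, antigen_entity)
      ident <- attr(al, "identity")
      ident >= min_identity
    }, logical(1))]
  } else {
    hits <- intersect(chains, antigen_entity)
  }
  if (length(hits) == 0) warning("no antigen chains found")
  length(hits)
}
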