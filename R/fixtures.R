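#' @title Synthetic coordinate fixtures with known ground truth
#' @description Generators for geometric test instruments: random sphere
#'   clusters with analytically known SASA and exact pair lists, toy
#'   two-chain complexes with planted contact inventories, hinged
#'   two-domain chains with a known elbow rotation, and homolog pairs with
#'   a planted bulky-residue substitution that clashes with a partner
#'   chain. Fixtures use real residue/atom names so the typing tables are
#'   exercised, but the backbone geometry is idealized; they are
#'   instruments, not physically realistic folds. All generators are
#'   deterministic for a fixed seed.
#' @name fixtures_synthetic
NULL

## run code under a local RNG seed without touching the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(code)
}

atom_row <- function(serial, atom, resname, chain, resno, xyz, element,
                     type = "ATOM") {
  data.frame(serial = serial, atom = atom, resname = resname, chain = chain,
             resno = resno, icode = "", x = xyz[1], y = xyz[2], z = xyz[3],
             occ = 1, alt = "", b = 0, element = element, type = type,
             stringsAsFactors = FALSE)
}

finish_model <- function(rows, source_id, role_map) {
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  structure_model(at, source_id = source_id, role_map = role_map)
}

#' Random pseudo-atom cluster with exact pair ground truth
#'
#' `n` CA pseudo-atoms placed uniformly in a cubic box; the ground truth
#' is the full all-pairs distance list computed by brute force.
#'
#' @param n number of atoms
#' @param box box edge in Angstrom
#' @param seed RNG seed (fixed seed => identical output)
#' @return list(model, pairs = data.frame(i, j, distance) with i < j)
#' @export
make_sphere_cluster <- function(n = 100, box = 40, seed = 1) {
  stopifnot(n >= 1)
  xyz <- with_seed(seed, matrix(stats::runif(3 * n, 0, box), ncol = 3))
  rows <- lapply(seq_len(n), function(i)
    atom_row(i, "CA", "ALA", "A", i, xyz[i, ], "C"))
  model <- finish_model(rows, sprintf("sphere_cluster_n%d_seed%d", n, seed),
                        c(A = "other"))
  pairs <- if (n < 2) {
    data.frame(i = integer(), j = integer(), distance = numeric())
  } else {
    cmb <- utils::combn(n, 2)
    d <- sqrt(colSums((t(xyz[cmb[1, ], , drop = FALSE]) -
                         t(xyz[cmb[2, ], , drop = FALSE]))^2))
    data.frame(i = cmb[1, ], j = cmb[2, ], distance = d)
  }
  list(model = model, pairs = pairs)
}

## ---- toy complex with planted contacts ----------------------------------

## residue templates: local coordinates with the designated contact atom at
## the origin and the rest of the residue trailing along -x
.tpl_ser <- function() list(
  resname = "SER", contact = "OG",
  atoms = list(OG = c(0, 0, 0), CB = c(-1.4, 0, 0), CA = c(-2.9, 0.3, 0),
               N = c(-3.6, 1.5, 0.3), C = c(-3.7, -0.9, -0.2),
               O = c(-4.9, -1.1, -0.3)))
.tpl_arg <- function() list(
  resname = "ARG", contact = "NH1",
  atoms = list(NH1 = c(0, 1.16, 0), NH2 = c(0, -1.16, 0),
               CZ = c(-0.65, 0, 0), NE = c(-1.98, 0, 0),
               CD = c(-3.4, 0, 0), CG = c(-4.8, 0.4, 0),
               CB = c(-6.2, 0, 0), CA = c(-7.6, 0.3, 0),
               N = c(-8.3, 1.5, 0.3), C = c(-8.4, -0.9, -0.2),
               O = c(-9.6, -1.1, -0.3)))
.tpl_glu <- function() list(
  resname = "GLU", contact = "OE1",
  atoms = list(OE1 = c(0, 1.16, 0), OE2 = c(0, -1.16, 0),
               CD = c(-0.65, 0, 0), CG = c(-2.1, 0, 0),
               CB = c(-3.5, 0.4, 0), CA = c(-4.9, 0, 0),
               N = c(-5.6, 1.2, 0.3), C = c(-5.7, -1.2, -0.2),
               O = c(-6.9, -1.4, -0.3)))
.tpl_lys <- function() list(
  resname = "LYS", contact = "NZ",
  atoms = list(NZ = c(0, 0, 0), CE = c(-1.5, 0, 0), CD = c(-2.9, 0.4, 0),
               CG = c(-4.3, 0, 0), CB = c(-5.7, 0.4, 0),
               CA = c(-7.1, 0, 0), N = c(-7.8, 1.2, 0.3),
               C = c(-7.9, -1.2, -0.2), O = c(-9.1, -1.4, -0.3)))
.tpl_asp <- function() list(
  resname = "ASP", contact = "OD1",
  atoms = list(OD1 = c(0, 0, 0), OD2 = c(-1.6, 1.9, 0.4),
               CG = c(-1.0, 1.0, 0.2), CB = c(-2.4, 1.2, 0.2),
               CA = c(-3.1, 2.4, 0.5), N = c(-3.2, 3.6, -0.2),
               C = c(-4.5, 2.2, 0.8), O = c(-5.4, 3.0, 0.9)))
.tpl_ala <- function() list(
  resname = "ALA", contact = "CB",
  atoms = list(CB = c(0, 0, 0), CA = c(-1.5, 0, 0), N = c(-2.2, 1.2, 0.2),
               C = c(-2.2, -1.3, -0.2), O = c(-3.4, -1.5, -0.3)))
.tpl_gly_bbO <- function() list(
  resname = "GLY", contact = "O",
  atoms = list(O = c(0, 0, 0), C = c(-1.23, 0, 0), CA = c(-1.9, 1.3, 0.2),
               N = c(-3.2, 1.2, 0.4)))

place_residue <- function(tpl, origin, flip, rot) {
  xyz <- do.call(rbind, tpl$atoms)
  if (flip) xyz[, 1] <- -xyz[, 1]
  xyz <- xyz %*% rot
  sweep(xyz, 2, origin, "+")
}

#' Toy two-chain complex with a planted contact inventory
#'
#' Builds chains A and B from idealized residue templates so that each
#' requested contact is realized at its target distance (to well under
#' 0.05 A) and no unintended cross-chain atom pair comes within `audit`
#' (default 4.5 A). Stations are spread far apart and randomly oriented
#' per seed. The construction is audited and errors out if any stray
#' cross-chain pair violates the guarantee.
#'
#' @param spec list of planted contacts; each element is a list with
#'   `category` in hydrogen_bond/salt_bridge/vdw/water_bridge and
#'   `distance` (for water_bridge: `d_a`, `d_b`). A salt_bridge entry may
#'   set `bidentate = TRUE` (Arg/Glu twin pairs) or FALSE (Lys/Asp single
#'   pair).
#' @param seed RNG seed for station orientations
#' @param audit stray-contact audit distance (default 4.0 A, the widest
#'   default detection cutoff)
#' @return list(model (roles: A antigen, B heavy, W water; radii
#'   assigned), inventory = data.frame(category, atom_a, atom_b,
#'   distance), expected_counts named vector)
#' @export
make_toy_complex <- function(spec = list(
                               list(category = "hydrogen_bond", distance = 2.9),
                               list(category = "salt_bridge", distance = 3.5,
                                    bidentate = TRUE),
                               list(category = "vdw", distance = 3.8),
                               list(category = "water_bridge",
                                    d_a = 2.8, d_b = 2.9)),
                             seed = 1, audit = 4.0) {
  rows_a <- list(); rows_b <- list(); rows_w <- list()
  inv <- list()
  resno_a <- 0L; resno_b <- 100L; resno_w <- 500L
  with_seed(seed, {
    for (k in seq_along(spec)) {
      pc <- spec[[k]]
      dd <- c(pc$distance, pc$d_a, pc$d_b)
      if (length(dd) == 0 || any(!is.finite(dd)) || any(dd < 2.0))
        stop("geometrically unsatisfiable planted contact (need finite ",
             "target distances >= 2.0 A)")
      ## charged-group geometry admits stray sub-cutoff pairs below these
      if (pc$category == "salt_bridge" &&
          pc$distance < (if (isTRUE(pc$bidentate)) 3.4 else 2.9))
        stop("geometrically unsatisfiable planted salt bridge: flanking ",
             "group atoms would enter the cutoff shell at this distance")
      origin <- c(0, 30 * k, 0)
      rot <- rotation_matrix(stats::rnorm(3) + 1e-3, stats::runif(1, 0, 360))
      cat_k <- pc$category
      if (cat_k == "hydrogen_bond") {
        d <- pc$distance
        tpl <- .tpl_ser()
        xa <- place_residue(tpl, origin, flip = FALSE, rot)
        xb <- place_residue(tpl, origin + c(d, 0, 0) %*% rot, flip = TRUE, rot)
        resno_a <- resno_a + 1L; resno_b <- resno_b + 1L
        rows_a[[length(rows_a) + 1]] <- mapply_rows(xa, tpl, "A", resno_a)
        rows_b[[length(rows_b) + 1]] <- mapply_rows(xb, tpl, "B", resno_b)
        inv[[length(inv) + 1]] <- data.frame(category = cat_k, atom_a = "OG",
                                             atom_b = "OG", distance = d)
      } else if (cat_k == "salt_bridge") {
        d <- pc$distance
        bid <- isTRUE(pc$bidentate)
        ta <- if (bid) .tpl_arg() else .tpl_lys()
        tb <- if (bid) .tpl_glu() else .tpl_asp()
        xa <- place_residue(ta, origin, flip = FALSE, rot)
        xb <- place_residue(tb, origin + c(d, 0, 0) %*% rot, flip = TRUE, rot)
        resno_a <- resno_a + 1L; resno_b <- resno_b + 1L
        rows_a[[length(rows_a) + 1]] <- mapply_rows(xa, ta, "A", resno_a)
        rows_b[[length(rows_b) + 1]] <- mapply_rows(xb, tb, "B", resno_b)
        inv_k <- if (bid)
          data.frame(category = cat_k, atom_a = c("NH1", "NH2"),
                     atom_b = c("OE1", "OE2"), distance = d)
        else
          data.frame(category = cat_k, atom_a = "NZ", atom_b = "OD1",
                     distance = d)
        inv[[length(inv) + 1]] <- inv_k
      } else if (cat_k == "vdw") {
        d <- pc$distance
        tpl <- .tpl_ala()
        xa <- place_residue(tpl, origin, flip = FALSE, rot)
        xb <- place_residue(tpl, origin + c(d, 0, 0) %*% rot, flip = TRUE, rot)
        resno_a <- resno_a + 1L; resno_b <- resno_b + 1L
        rows_a[[length(rows_a) + 1]] <- mapply_rows(xa, tpl, "A", resno_a)
        rows_b[[length(rows_b) + 1]] <- mapply_rows(xb, tpl, "B", resno_b)
        inv[[length(inv) + 1]] <- data.frame(category = cat_k, atom_a = "CB",
                                             atom_b = "CB", distance = d)
      } else if (cat_k == "water_bridge") {
        da <- pc$d_a %||% 2.8; db <- pc$d_b %||% 2.9
        ta <- .tpl_ser(); tb <- .tpl_gly_bbO()
        xa <- place_residue(ta, origin, flip = FALSE, rot)
        xw <- origin + c(da, 0, 0) %*% rot
        xb <- place_residue(tb, origin + c(da + db, 0, 0) %*% rot,
                            flip = TRUE, rot)
        resno_a <- resno_a + 1L; resno_b <- resno_b + 1L
        resno_w <- resno_w + 1L
        rows_a[[length(rows_a) + 1]] <- mapply_rows(xa, ta, "A", resno_a)
        rows_b[[length(rows_b) + 1]] <- mapply_rows(xb, tb, "B", resno_b)
        rows_w[[length(rows_w) + 1]] <-
          atom_row(0L, "O", "HOH", "W", resno_w, as.numeric(xw), "O",
                   type = "HETATM")
        inv[[length(inv) + 1]] <- data.frame(category = cat_k, atom_a = "OG",
                                             atom_b = "O",
                                             distance = max(da, db))
      } else stop("unknown planted category: ", cat_k)
    }
  })
  if (length(rows_a) == 0) {
    ## empty spec: two far-apart single-residue chains
    ta <- .tpl_ala()
    rows_a <- list(mapply_rows(place_residue(ta, c(0, 0, 0), FALSE, diag(3)),
                               ta, "A", 1L))
    rows_b <- list(mapply_rows(place_residue(ta, c(50, 0, 0), TRUE, diag(3)),
                               ta, "B", 101L))
  }
  model <- finish_model(c(rows_a, rows_b, rows_w),
                        sprintf("toy_complex_seed%d", seed),
                        c(A = "antigen", B = "heavy"))
  model <- assign_radii(model)
  inventory <- if (length(inv)) do.call(rbind, inv) else
    data.frame(category = character(), atom_a = character(),
               atom_b = character(), distance = numeric())
  audit_toy_complex(model, inventory, audit)
  counts <- table(factor(inventory$category,
                         levels = c("hydrogen_bond", "salt_bridge", "vdw",
                                    "water_bridge")))
  list(model = model, inventory = inventory,
       expected_counts = stats::setNames(as.integer(counts), names(counts)))
}

mapply_rows <- function(xyz, tpl, chain, resno) {
  nm <- rownames(xyz)
  do.call(rbind, lapply(seq_len(nrow(xyz)), function(i)
    atom_row(0L, nm[i], tpl$resname, chain, resno, xyz[i, ],
             substr(nm[i], 1, 1))))
}

## construction guarantee: the only cross-chain pairs within `audit` are
## the designated contact-atom pairs (waters checked separately)
audit_toy_complex <- function(model, inventory, audit) {
  at <- model$atoms
  a <- at[at$chain == "A", , drop = FALSE]
  b <- at[at$chain == "B", , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) return(invisible(TRUE))
  d <- outer(rowSums(as.matrix(a[, c("x", "y", "z")])^2),
             rowSums(as.matrix(b[, c("x", "y", "z")])^2), "+") -
    2 * as.matrix(a[, c("x", "y", "z")]) %*%
      t(as.matrix(b[, c("x", "y", "z")]))
  d <- sqrt(pmax(d, 0))
  close <- which(d <= audit, arr.ind = TRUE)
  got <- paste(a$atom[close[, 1]], b$atom[close[, 2]])
  direct <- inventory[inventory$category != "water_bridge" &
                        inventory$distance <= audit, , drop = FALSE]
  want <- paste(direct$atom_a, direct$atom_b)
  if (!setequal(got, want) || length(got) != length(want))
    stop("toy-complex construction failed its audit: stray cross-chain ",
         "pair(s): ", paste(setdiff(got, want), collapse = ", "))
  invisible(TRUE)
}

#' Hinged two-domain chain pair with a known elbow rotation
#'
#' Two copies of an idealized CA-only two-domain chain (helical traces);
#' in the second copy the "constant" domain is rotated by `angle` about a
#' hinge axis through the inter-domain junction. Optionally the whole
#' second copy receives a random global rigid motion (the planted hinge
#' angle is invariant to it).
#'
#' @param angle hinge rotation in degrees (0-180)
#' @param seed RNG seed for the global motion
#' @param n_v,n_c residues per domain
#' @param global_motion apply a random rigid motion to copy 2
#' @return list(copy1, copy2, v_sel, c_sel, angle)
#' @export
make_hinged_fab <- function(angle = 30, seed = 1, n_v = 40, n_c = 40,
                            global_motion = TRUE) {
  stopifnot(angle >= 0, angle <= 180)
  helix <- function(n, z0) {
    t <- seq_len(n)
    cbind(5 * cos(t * 100 * pi / 180), 5 * sin(t * 100 * pi / 180),
          z0 + 1.5 * t)
  }
  v_xyz <- helix(n_v, 0)
  c_xyz <- helix(n_c, max(v_xyz[, 3]) + 3)
  hinge_point <- c(0, 0, max(v_xyz[, 3]) + 1.5)
  build <- function(vx, cx, id) {
    rows <- lapply(seq_len(n_v + n_c), function(i) {
      xyz <- if (i <= n_v) vx[i, ] else cx[i - n_v, ]
      atom_row(i, "CA", "GLY", "H", i, xyz, "C")
    })
    finish_model(rows, id, c(H = "heavy"))
  }
  copy1 <- build(v_xyz, c_xyz, sprintf("hinged_fab_ref_seed%d", seed))
  rot <- rotation_matrix(c(1, 0.3, 0.2), angle)
  c2 <- sweep(sweep(c_xyz, 2, hinge_point) %*% rot, 2, hinge_point, "+")
  copy2 <- build(v_xyz, c2, sprintf("hinged_fab_rot%g_seed%d", angle, seed))
  if (global_motion) {
    g <- with_seed(seed, list(r = rotation_matrix(stats::rnorm(3) + 1e-3,
                                                  stats::runif(1, 0, 360)),
                              t = stats::runif(3, -20, 20)))
    copy2 <- apply_transform(copy2, g$r, g$t)
  }
  list(copy1 = copy1, copy2 = copy2,
       v_sel = list(chain = "H", resno = seq_len(n_v)),
       c_sel = list(chain = "H", resno = n_v + seq_len(n_c)),
       angle = angle)
}

#' Homolog pair with a planted bulky substitution clashing with a partner
#'
#' An idealized antigen chain bound by a small partner chain, plus a
#' homolog identical to the antigen except that residue `p` is replaced by
#' tryptophan whose ring is positioned to overlap the nearest partner atom
#' by `margin` Angstrom (negative margin: no overlap). With
#' `substitute = FALSE` the homolog is an exact copy (self-graft control).
#' The homolog is returned under a random rigid motion so the
#' structural-alignment transform is exercised.
#'
#' @param margin planted vdW overlap in Angstrom
#' @param p substituted residue number
#' @param seed RNG seed (homolog pose)
#' @param substitute plant the Trp substitution?
#' @return list(complex (roles antigen/heavy, radii assigned), homolog
#'   (radii assigned), target_residue, expect_clash)
#' @export
make_homolog_pair <- function(margin = 1.0, p = 6, seed = 1,
                              substitute = TRUE) {
  n <- 12
  stopifnot(p >= 2, p <= n - 1)
  ## zig-zag backbone in the xz plane, side chains along +y
  res_xyz <- function(i) {
    base <- c(3.8 * i, 0, 2 * (i %% 2))
    list(N = base + c(-0.9, -0.8, 0.3), CA = base,
         C = base + c(0.9, -0.8, -0.3), O = base + c(0.9, -2.0, -0.3),
         CB = base + c(0, 1.5, 0))
  }
  mk_chain <- function(chain, resnames) {
    rows <- list()
    for (i in seq_along(resnames)) {
      ax <- res_xyz(i)
      for (nm in names(ax))
        rows[[length(rows) + 1]] <-
          atom_row(0L, nm, resnames[i], chain, i, ax[[nm]],
                   substr(nm, 1, 1))
    }
    rows
  }
  ant_rows <- mk_chain("A", rep("ALA", n))
  cb_p <- res_xyz(p)$CB
  ## partner: 3 residues floating above residue p, mirrored in y so its
  ## central CB points down toward the antigen at ~3.9 A (normal contact)
  prt_rows <- list()
  for (i in 1:3) {
    ax <- res_xyz(i)
    for (nm in names(ax)) {
      xyz <- ax[[nm]]
      xyz[2] <- -xyz[2]
      xyz <- xyz - res_xyz(i)$CA + cb_p + c(3.8 * (i - 2), 5.3, 1)
      prt_rows[[length(prt_rows) + 1]] <-
        atom_row(0L, nm, "ALA", "B", i, xyz, substr(nm, 1, 1))
    }
  }
  complex <- finish_model(c(ant_rows, prt_rows),
                          sprintf("homolog_complex_seed%d", seed),
                          c(A = "antigen", B = "heavy"))
  complex <- assign_radii(complex)
  ## nearest partner atom to the substitution site's CB
  bat <- complex$atoms[complex$atoms$chain == "B", , drop = FALSE]
  dcb <- sqrt((bat$x - cb_p[1])^2 + (bat$y - cb_p[2])^2 + (bat$z - cb_p[3])^2)
  tgt <- bat[which.min(dcb), ]
  tgt_pos <- c(tgt$x, tgt$y, tgt$z)
  hom_rows <- mk_chain("A", rep("ALA", n))
  if (substitute) {
    ## replace residue p by TRP: the ring tip (CH2, trigonal C, r 1.76 A)
    ## is placed at d = r_tip + r_partner - margin from the nearest
    ## partner atom; the rest of the ring is strung back toward CB so no
    ## other ring atom comes closer than the tip
    dirv <- tgt_pos - cb_p
    dirv <- dirv / sqrt(sum(dirv^2))
    perp <- c(dirv[2], -dirv[1], 0)
    perp <- 0.6 * perp / sqrt(sum(perp^2))
    tip_d <- 1.76 + tgt$radius - margin
    tip <- tgt_pos - dirv * tip_d
    ring <- list(CH2 = tip,
                 CZ3 = tip - 0.7 * dirv + perp,
                 CZ2 = tip - 0.7 * dirv - perp,
                 CE3 = tip - 1.4 * dirv + perp,
                 CE2 = tip - 1.4 * dirv - perp,
                 NE1 = tip - 2.1 * dirv - perp,
                 CD1 = tip - 2.1 * dirv + perp,
                 CD2 = tip - 2.4 * dirv,
                 CG = tip - 2.9 * dirv)
    idx_p <- which(vapply(hom_rows, function(r) r$resno == p, logical(1)))
    for (i in idx_p) hom_rows[[i]]$resname <- "TRP"
    for (nm in names(ring))
      hom_rows[[length(hom_rows) + 1]] <-
        atom_row(0L, nm, "TRP", "A", p, ring[[nm]], substr(nm, 1, 1))
    ord <- order(vapply(hom_rows, function(r) r$resno, numeric(1)))
    hom_rows <- hom_rows[ord]
  }
  homolog <- finish_model(hom_rows, sprintf("homolog_seed%d", seed),
                          c(A = "antigen"))
  homolog <- assign_radii(homolog)
  g <- with_seed(seed + 17, list(r = rotation_matrix(stats::rnorm(3) + 1e-3,
                                                     stats::runif(1, 0, 360)),
                                 t = stats::runif(3, -15, 15)))
  homolog <- apply_transform(homolog, g$r, g$t)
  list(complex = complex, homolog = homolog,
       target_residue = list(chain = "A", resno = p, icode = ""),
       expect_clash = substitute && margin > 0)
}

#' Write a fixture to disk (PDB + JSON ground-truth sidecar)
#'
#' @param fixture result of a `make_*` generator
#' @param dir output directory (created if needed)
#' @param name base file name
#' @return invisibly, the paths written
#' @export
write_fixture <- function(fixture, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  models <- Filter(function(x) inherits(x, "structure_model"), fixture)
  truth <- Filter(function(x) !inherits(x, "structure_model"), fixture)
  if (inherits(fixture$model, "structure_model")) {
    models <- list(model = fixture$model)
    truth <- fixture[setdiff(names(fixture), "model")]
  }
  for (nm in names(models)) {
    f <- file.path(dir, sprintf("%s_%s.pdb", name, nm))
    write_pdb_model(models[[nm]], f)
    paths <- c(paths, f)
  }
  jf <- file.path(dir, sprintf("%s_truth.json", name))
  ## named atomic vectors become JSON objects, not nameless arrays
  truth <- lapply(truth, function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(truth, jf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(paths, jf))
}
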