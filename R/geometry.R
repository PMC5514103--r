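#' Deterministic near-uniform points on the unit sphere
#'
#' Generalized golden-angle spiral lattice. Purely arithmetic (no RNG), so
#' SASA results are exactly reproducible for a given `n`.
#'
#' @param n number of points (>= 1)
#' @return n x 3 matrix of unit vectors
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' All heavy-atom pairs within a distance cutoff
#'
#' Cell-list (spatial binning) neighbor search: atoms are binned into cubic
#' cells of edge `cutoff` and only the 27-cell neighborhoods are examined,
#' so the cost is linear in the number of atoms for biomolecular densities.
#' Each unordered pair is reported once, indexed by row in `model$atoms`.
#'
#' @param model structure_model (or plain n x 3 coordinate matrix)
#' @param cutoff distance cutoff in Angstrom (> 0)
#' @return data.frame(i, j, distance) with i < j
#' @export
neighbor_pairs <- function(model, cutoff) {
  stopifnot(cutoff > 0)
  xyz <- if (is.matrix(model)) model else coords(model)
  n <- nrow(xyz)
  empty <- data.frame(i = integer(), j = integer(), distance = numeric())
  if (n < 2) return(empty)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  dims <- apply(cell, 2, max) + 1L
  cid <- cell[, 1] + dims[1] * (cell[, 2] + dims[2] * cell[, 3])
  by_cell <- split(seq_len(n), cid)
  ## half-shell of 13 neighbor offsets + self avoids double counting
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 |
                (offs$dy == 0 & offs$dx >= 0))), , drop = FALSE]
  keys <- as.numeric(names(by_cell))
  res_i <- list(); res_j <- list(); m <- 0L
  for (ci in seq_along(by_cell)) {
    ids_a <- by_cell[[ci]]
    key <- keys[ci]
    kz <- key %/% (dims[1] * dims[2])
    ky <- (key - kz * dims[1] * dims[2]) %/% dims[1]
    kx <- key - kz * dims[1] * dims[2] - ky * dims[1]
    for (oi in seq_len(nrow(offs))) {
      nx <- kx + offs$dx[oi]; ny <- ky + offs$dy[oi]; nz <- kz + offs$dz[oi]
      if (nx < 0 || ny < 0 || nz < 0 ||
          nx >= dims[1] || ny >= dims[2] || nz >= dims[3]) next
      self <- offs$dx[oi] == 0 && offs$dy[oi] == 0 && offs$dz[oi] == 0
      ids_b <- if (self) ids_a else
        by_cell[[as.character(nx + dims[1] * (ny + dims[2] * nz))]]
      if (is.null(ids_b)) next
      if (self) {
        if (length(ids_a) < 2) next
        cmb <- utils::combn(ids_a, 2)
        ii <- cmb[1, ]; jj <- cmb[2, ]
      } else {
        g <- expand.grid(ii = ids_a, jj = ids_b)
        ii <- g$ii; jj <- g$jj
      }
      m <- m + 1L
      res_i[[m]] <- ii; res_j[[m]] <- jj
    }
  }
  if (m == 0L) return(empty)
  ii <- unlist(res_i); jj <- unlist(res_j)
  d <- sqrt(rowSums((xyz[ii, , drop = FALSE] - xyz[jj, , drop = FALSE])^2))
  keep <- d <= cutoff
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
  swap <- ii > jj
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  ord <- order(ii, jj)
  data.frame(i = ii[ord], j = jj[ord], distance = d[ord])
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe of radius `probe` over the van der Waals surface by testing,
#' for every heavy atom, `n_points` lattice points on its solvent-expanded
#' sphere against all neighboring expanded spheres. Waters and HETATM
#' ligands are excluded unless `include_het = TRUE` (select them explicitly
#' to measure them).
#'
#' Each atom's spiral lattice is deterministically re-oriented so its pole
#' points at the nearest neighboring atom: the dominant occlusion boundary
#' then runs along the lattice's equal-area stratification, which cuts the
#' cap-area discretization error by an order of magnitude and makes the
#' result insensitive to rigid motions of the whole model. No randomness
#' is involved anywhere.
#'
#' @param model structure_model with radii assigned (see [assign_radii()])
#' @param probe probe radius in Angstrom (water: 1.4)
#' @param n_points points per atom on the test sphere (>= 100; default 960)
#' @param include_het include waters/HETATM records
#' @return object of class `sasa_result`: list(per_atom data.frame,
#'   per_residue named vector (by residue uid), total, params)
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960,
                               include_het = FALSE) {
  stopifnot(n_points >= 100, probe >= 0)
  at <- model$atoms
  if (is.null(at$radius) || anyNA(at$radius))
    stop("radii not assigned; call assign_radii() first")
  if (!include_het)
    at <- at[at$resname != "HOH" & at$type != "HETATM", , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms to measure")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rexp <- at$radius + probe
  n <- nrow(at)
  pts <- sphere_points(n_points)
  ## candidate neighbors: centers closer than the largest possible overlap
  nb <- neighbor_pairs(xyz, cutoff = 2 * max(rexp))
  keep <- nb$distance < rexp[nb$i] + rexp[nb$j]
  nb <- nb[keep, , drop = FALSE]
  adj <- vector("list", n)
  if (nrow(nb)) {
    adj_i <- split(nb$j, factor(nb$i, levels = seq_len(n)))
    adj_j <- split(nb$i, factor(nb$j, levels = seq_len(n)))
    for (i in seq_len(n)) adj[[i]] <- c(adj_i[[i]], adj_j[[i]])
  }
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    loc <- pts
    if (length(nb)) {
      ## orient the lattice pole toward the nearest neighbor (deterministic;
      ## ties resolved by atom order)
      dn <- sqrt(colSums((t(xyz[nb, , drop = FALSE]) - xyz[i, ])^2))
      u <- (xyz[nb[which.min(dn)], ] - xyz[i, ]) / min(dn)
      e <- diag(3)[, which.min(abs(u))]
      v <- c(u[2] * e[3] - u[3] * e[2], u[3] * e[1] - u[1] * e[3],
             u[1] * e[2] - u[2] * e[1])
      v <- v / sqrt(sum(v^2))
      w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
      loc <- pts %*% rbind(v, w, u)
    }
    p <- loc * rexp[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- p[acc, 1] - xyz[j, 1]
      dy <- p[acc, 2] - xyz[j, 2]
      dz <- p[acc, 3] - xyz[j, 3]
      acc[acc] <- dx * dx + dy * dy + dz * dz >= rexp[j]^2
    }
    area[i] <- sum(acc) / n_points * 4 * pi * rexp[i]^2
  }
  uid <- residue_uid(at)
  per_res <- tapply(area, uid, sum)
  per_res <- stats::setNames(as.numeric(per_res), names(per_res))
  out <- list(
    per_atom = data.frame(serial = at$serial, chain = at$chain,
                          resno = at$resno, icode = at$icode,
                          resname = at$resname, atom = at$atom,
                          uid = uid, area = area, stringsAsFactors = FALSE),
    per_residue = per_res,
    total = sum(area),
    params = list(probe = probe, n_points = n_points,
                  radii_table = model$radii_name %||% "unknown"))
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.1f A^2 over %d atoms (probe %.2f, %d points, radii '%s')\n",
              x$total, nrow(x$per_atom), x$params$probe, x$params$n_points,
              x$params$radii_table))
  invisible(x)
}

#' Closed-form SASA of two intersecting solvent-expanded spheres
#'
#' Exact spherical-cap solution used as the analytic oracle for the
#' Shrake-Rupley engine. For center distance d, expanded radii R1, R2:
#' the cap of sphere 1 buried inside sphere 2 has height
#' h1 = R1 - (d^2 + R1^2 - R2^2) / (2 d), giving accessible area
#' 4 pi R1^2 - 2 pi R1 h1. Full areas are returned when the expanded
#' spheres do not intersect; a contained sphere has area 0.
#'
#' @param r1,r2 van der Waals radii in Angstrom
#' @param d center-center distance (> 0)
#' @param probe probe radius
#' @return c(area1, area2) in Angstrom^2
#' @export
analytic_two_sphere_sasa <- function(r1, r2, d, probe = 1.4) {
  stopifnot(d > 0)
  R1 <- r1 + probe; R2 <- r2 + probe
  full <- function(R) 4 * pi * R^2
  if (d >= R1 + R2) return(c(full(R1), full(R2)))
  if (d <= abs(R1 - R2)) {
    ## one expanded sphere entirely inside the other
    if (R1 > R2) return(c(full(R1), 0)) else return(c(0, full(R2)))
  }
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  a1 <- 2 * pi * R1 * (R1 + x1)
  a2 <- 2 * pi * R2 * (R2 + x2)
  c(a1, a2)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid transform mapping `coords_a` onto `coords_b` over a
#' given one-to-one correspondence, with reflection corrected so the
#' rotation is proper. The transform acts on row vectors:
#' `transformed = coords_a %*% rotation + translation` (each row offset).
#'
#' @param coords_a,coords_b n x 3 matrices, n >= 3, matching rows
#' @return object of class `superposition`: list(rotation 3x3,
#'   translation length-3, n_pairs, rmsd)
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b) || ncol(coords_a) != 3)
    stop("coordinate sets must be matching n x 3 matrices")
  n <- nrow(coords_a)
  if (n < 3) stop("need at least 3 point pairs")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  a0 <- sweep(coords_a, 2, ca); b0 <- sweep(coords_b, 2, cb)
  sv_a <- svd(a0)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1))
    stop("ill-conditioned (collinear) point set")
  h <- crossprod(a0, b0)
  s <- svd(h)
  dsign <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, dsign)) %*% t(s$v)
  trans <- cb - as.numeric(ca %*% rot)
  fit <- a0 %*% rot
  rmsd <- sqrt(mean(rowSums((fit - b0)^2)))
  out <- list(rotation = rot, translation = trans, n_pairs = n, rmsd = rmsd)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d pairs, rmsd %.3f A, rotation %.1f deg\n",
              x$n_pairs, x$rmsd, rotation_angle(x$rotation)))
  invisible(x)
}

#' Apply a superposition (or explicit R, t) to a model
#' @param model structure_model
#' @param transform superposition object, or 3x3 rotation
#' @param translation length-3 vector when `transform` is a plain matrix
#' @return transformed model
#' @export
apply_transform <- function(model, transform, translation = c(0, 0, 0)) {
  if (inherits(transform, "superposition")) {
    rot <- transform$rotation; tr <- transform$translation
  } else {
    rot <- transform; tr <- translation
  }
  xyz <- coords(model) %*% rot
  xyz <- sweep(xyz, 2, tr, "+")
  set_coords(model, xyz)
}

#' Rotation angle of a proper rotation matrix
#'
#' Axis-agnostic magnitude in degrees: arccos((trace - 1) / 2), in
#' [0, 180].
#'
#' @param r 3x3 orthogonal matrix with det +1
#' @return angle in degrees
#' @export
rotation_angle <- function(r) {
  if (!is.matrix(r) || any(dim(r) != 3)) stop("need a 3x3 matrix")
  if (max(abs(crossprod(r) - diag(3))) > 1e-6 || det(r) < 0)
    stop("matrix is not a proper rotation")
  ct <- (sum(diag(r)) - 1) / 2
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Rotation matrix about an axis
#' @param axis length-3 vector (normalized internally)
#' @param angle_deg rotation angle in degrees
#' @return 3x3 rotation matrix (acts on row vectors: `xyz %*% R`)
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  k <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  rot <- diag(3) * ct + st * k + (1 - ct) * (u %o% u)
  ## transpose: our convention applies rotations to row vectors
  t(rot)
}
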