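test_that("neighbor_pairs handles cutoff boundaries", {
  m <- mini_model(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(nrow(neighbor_pairs(m, 3.5)), 1)
  expect_equal(nrow(neighbor_pairs(m, 2.9)), 0)
  expect_equal(nrow(neighbor_pairs(mini_model(c(0, 0, 0)), 5)), 0)
})

test_that("neighbor_pairs equals the all-pairs oracle on random clusters", {
  for (seed in 1:5) {
    sc <- make_sphere_cluster(n = 300, box = 40, seed = seed)
    xyz <- coords(sc$model)
    got <- neighbor_pairs(sc$model, 5)
    want <- brute_pairs(xyz, 5)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
  }
})

test_that("sphere point lattice is deterministic and unit-norm", {
  p1 <- sphere_points(960); p2 <- sphere_points(960)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1^2), rep(1, 960), tolerance = 1e-12)
})

test_that("SASA of isolated spheres matches the closed form", {
  m <- mini_model(c(0, 0, 0))
  m$atoms$radius <- 1.9; m$radii_name <- "test"
  s <- shrake_rupley_sasa(m, probe = 1.4, n_points = 960)
  expect_equal(s$total, 4 * pi * 3.3^2, tolerance = 0.005)
  ## two atoms far apart: each keeps its isolated area
  m2 <- mini_model(rbind(c(0, 0, 0), c(100, 0, 0)))
  m2$atoms$radius <- 1.9; m2$radii_name <- "test"
  s2 <- shrake_rupley_sasa(m2, 1.4, 960)
  expect_equal(s2$per_atom$area, rep(4 * pi * 3.3^2, 2), tolerance = 1e-9)
})

test_that("SASA matches the two-sphere spherical-cap closed form on a grid", {
  for (r in c(1.4, 1.65, 1.9)) for (d in c(2.0, 3.0, 3.3, 4.5, 6.0)) {
    m <- mini_model(rbind(c(0, 0, 0), c(d, 0, 0)))
    m$atoms$radius <- r; m$radii_name <- "test"
    s <- shrake_rupley_sasa(m, 1.4, 960)
    an <- analytic_two_sphere_sasa(r, r, d, 1.4)
    expect_equal(s$per_atom$area, an, tolerance = 0.005,
                 label = sprintf("r=%g d=%g", r, d))
  }
})

test_that("analytic two-sphere oracle limits are exact", {
  ## no intersection: full expanded-sphere areas
  expect_equal(analytic_two_sphere_sasa(1.9, 1.9, 10, 1.4),
               rep(4 * pi * 3.3^2, 2))
  ## containment: inner sphere fully buried
  expect_equal(analytic_two_sphere_sasa(0.6, 1.9, 0.5, 1.4)[1], 0)
  expect_equal(analytic_two_sphere_sasa(0.6, 1.9, 0.5, 1.4)[2],
               4 * pi * 3.3^2)
  ## equal spheres approaching coincidence: each tends to a half sphere
  a <- analytic_two_sphere_sasa(1.9, 1.9, 1e-9, 1.4)
  expect_equal(a, rep(2 * pi * 3.3^2, 2), tolerance = 1e-6)
  ## dense-sampling cross-check at one expanded-radius separation
  an <- analytic_two_sphere_sasa(1.9, 1.9, 3.3, 1.4)
  m <- mini_model(rbind(c(0, 0, 0), c(3.3, 0, 0)))
  m$atoms$radius <- 1.9; m$radii_name <- "test"
  s <- shrake_rupley_sasa(m, 1.4, 100000)
  expect_equal(s$per_atom$area, an, tolerance = 5e-4)
})

test_that("SASA result is internally consistent", {
  tc <- make_toy_complex(seed = 4)
  s <- shrake_rupley_sasa(tc$model)
  expect_equal(s$total, sum(s$per_atom$area), tolerance = 1e-6)
  agg <- tapply(s$per_atom$area, s$per_atom$uid, sum)
  expect_equal(s$per_residue[names(agg)], agg[names(agg)],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(s$per_atom$area >= 0))
  expect_equal(s$params$n_points, 960)
})

test_that("SASA is invariant under rigid-body motion", {
  tc <- make_toy_complex(seed = 6)
  s1 <- shrake_rupley_sasa(tc$model)
  m2 <- apply_transform(tc$model, rotation_matrix(c(1, 1, 0), 73),
                        c(10, -5, 3))
  s2 <- shrake_rupley_sasa(m2)
  expect_lt(abs(s2$total - s1$total) / s1$total, 0.001)
})

test_that("per-molecule SASA decreases monotonically on approach", {
  areas <- vapply(c(20, 10, 6, 4.5, 3.5, 2.5), function(d) {
    m <- mini_model(rbind(c(0, 0, 0), c(d, 0, 0)))
    m$atoms$radius <- 1.9; m$radii_name <- "test"
    shrake_rupley_sasa(m, 1.4, 960)$per_atom$area[1]
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("kabsch recovers exact and noisy rigid transforms", {
  set.seed(11)
  a <- matrix(rnorm(60, sd = 5), ncol = 3)
  ## identity
  k0 <- kabsch(a, a)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(k0$rmsd, 0, tolerance = 1e-9)
  ## known rotation + translation
  r <- rotation_matrix(c(2, -1, 0.5), 37)
  b <- sweep(a %*% r, 2, c(4, -2, 9), "+")
  k <- kabsch(a, b)
  expect_equal(rotation_angle(k$rotation), 37, tolerance = 1e-6)
  expect_lt(k$rmsd, 1e-9)
  ## proper rotation enforced
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(k$rotation), diag(3), tolerance = 1e-9)
  ## rmsd symmetric in argument order
  bn <- b + matrix(rnorm(60, sd = 0.5), ncol = 3)
  expect_equal(kabsch(a, bn)$rmsd, kabsch(bn, a)$rmsd, tolerance = 1e-9)
})

test_that("kabsch beats an exhaustive rotation-grid oracle on noisy data", {
  set.seed(21)
  a <- matrix(rnorm(150, sd = 6), ncol = 3)
  r <- rotation_matrix(c(1, 2, 3), 52)
  b <- sweep(a %*% r, 2, c(1, 2, 3), "+") + matrix(rnorm(150, sd = 0.5),
                                                   ncol = 3)
  k <- kabsch(a, b)
  ## rmsd should be near the noise scale for n=50 points
  expect_lt(k$rmsd, 1.0)
  ## coarse grid over Euler angles: no grid rotation does better
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  ang <- seq(0, 330, by = 30) * pi / 180
  grid_best <- Inf
  for (p in ang) for (t in ang[1:6]) for (s in ang) {
    rz1 <- matrix(c(cos(p), -sin(p), 0, sin(p), cos(p), 0, 0, 0, 1), 3, 3)
    ry <- matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, 3)
    rz2 <- matrix(c(cos(s), -sin(s), 0, sin(s), cos(s), 0, 0, 0, 1), 3, 3)
    rg <- rz1 %*% ry %*% rz2
    grid_best <- min(grid_best, sqrt(mean(rowSums((a0 %*% rg - b0)^2))))
  }
  expect_lte(k$rmsd, grid_best + 1e-9)
})

test_that("degenerate kabsch input errors", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch(line, line), "collinear")
})

test_that("rotation_angle convention and composition", {
  expect_equal(rotation_angle(diag(3)), 0)
  expect_equal(rotation_angle(rotation_matrix(c(0, 1, 0), 30)), 30,
               tolerance = 1e-9)
  r <- rotation_matrix(c(1, 1, 1), 20) %*% rotation_matrix(c(1, 1, 1), 15)
  expect_equal(rotation_angle(r), 35, tolerance = 1e-9)
  expect_error(rotation_angle(matrix(2 * diag(3), 3, 3)), "rotation")
})
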