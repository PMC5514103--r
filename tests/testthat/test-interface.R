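two_chain_spheres <- function(d, r = 1.87) {
  ## one CA pseudo-atom per chain, d apart (radius from the default table)
  at <- rbind(mini_model(c(0, 0, 0), chain = "A")$atoms,
              mini_model(c(d, 0, 0), chain = "B")$atoms)
  at$serial <- 1:2
  m <- structure_model(at, role_map = c(A = "antigen", B = "heavy"))
  assign_radii(m)
}

test_that("distant chains bury no area", {
  m <- two_chain_spheres(100)
  s <- buried_area(m, list(chain = "A"), list(chain = "B"))
  expect_equal(s$bsa_total, 0, tolerance = 1e-9)
  ir <- interface_residues(m, list(chain = "A"), list(chain = "B"))
  expect_length(ir$residues_a, 0)
  expect_length(ir$residues_b, 0)
})

test_that("planted two-sphere interface equals twice the analytic cap loss", {
  d <- 3.0
  m <- two_chain_spheres(d)
  s <- buried_area(m, list(chain = "A"), list(chain = "B"))
  full <- 4 * pi * (1.87 + 1.4)^2
  an <- analytic_two_sphere_sasa(1.87, 1.87, d, 1.4)
  expect_equal(s$bsa_total, 2 * (full - an[1]), tolerance = 0.01)
})

test_that("buried area is symmetric and rigid-motion invariant", {
  tc <- make_toy_complex(seed = 9)
  a <- list(role = "antigen"); b <- list(role = "heavy")
  s1 <- buried_area(tc$model, a, b)
  s2 <- buried_area(tc$model, b, a)
  expect_identical(s1$bsa_total, s2$bsa_total)
  m2 <- apply_transform(tc$model, rotation_matrix(c(0, 1, 2), 61),
                        c(-4, 8, 2))
  s3 <- buried_area(m2, a, b)
  ## BSA is a small difference of large SASA terms: bound the deviation by
  ## 0.1% of the complex SASA (the lattice-discretization scale)
  expect_lt(abs(s3$bsa_total - s1$bsa_total), 0.001 * s1$sasa_complex)
})

test_that("overlapping side selections are rejected", {
  tc <- make_toy_complex(seed = 1)
  expect_error(buried_area(tc$model, list(chain = "A"),
                           list(chain = c("A", "B"))), "overlap")
})

test_that("chain contribution fractions sum to one and respect symmetry", {
  tc <- make_toy_complex(seed = 1)
  s <- buried_area(tc$model, list(role = "antigen"), list(role = "heavy"))
  co <- chain_contribution(s, "b")
  expect_equal(unname(co), 1)   # single binder chain
  ## symmetric two-chain binder: one antigen atom, two flanking binder atoms
  at <- rbind(mini_model(c(0, 0, 0), chain = "A")$atoms,
              mini_model(c(3.2, 0, 0), chain = "H")$atoms,
              mini_model(c(-3.2, 0, 0), chain = "L")$atoms)
  at$serial <- 1:3
  m <- structure_model(at, role_map = c(A = "antigen", H = "heavy",
                                        L = "light"))
  m <- assign_radii(m)
  s2 <- buried_area(m, list(chain = "A"), list(chain = c("H", "L")))
  co2 <- chain_contribution(s2, "b")
  expect_equal(sum(co2), 1, tolerance = 1e-6)
  expect_equal(unname(co2["H"]), 0.5, tolerance = 0.01)
  ## zero interface -> undefined contribution
  s0 <- buried_area(two_chain_spheres(100), list(chain = "A"),
                    list(chain = "B"))
  expect_error(chain_contribution(s0, "b"), "undefined")
})

test_that("interface residues are exactly the planted contacting residues", {
  tc <- make_toy_complex(spec = list(
    list(category = "hydrogen_bond", distance = 2.9),
    list(category = "vdw", distance = 3.8),
    list(category = "salt_bridge", distance = 3.4, bidentate = FALSE)),
    seed = 12)
  ir <- interface_residues(tc$model, list(role = "antigen"),
                           list(role = "heavy"))
  expect_length(ir$residues_a, 3)
  expect_length(ir$residues_b, 3)
})

test_that("hydrogen-bond detector applies typing and distance rules", {
  mk <- function(d) make_toy_complex(spec = list(
    list(category = "hydrogen_bond", distance = d)), seed = 31)
  hb <- detect_hbonds(mk(2.8)$model, list(role = "antigen"),
                      list(role = "heavy"))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.8, tolerance = 1e-6)
  ## beyond cutoff: no H-bond, recovered as vdW only
  tc38 <- mk(3.8)
  expect_equal(nrow(detect_hbonds(tc38$model, list(role = "antigen"),
                                  list(role = "heavy"))), 0)
  vd <- detect_vdw_contacts(tc38$model, list(role = "antigen"),
                            list(role = "heavy"))
  expect_equal(nrow(vd), 1)
  ## apolar pair at H-bond distance is not an H-bond
  tcc <- make_toy_complex(spec = list(list(category = "vdw",
                                           distance = 2.8)), seed = 32)
  expect_equal(nrow(detect_hbonds(tcc$model, list(role = "antigen"),
                                  list(role = "heavy"))), 0)
  expect_equal(nrow(detect_vdw_contacts(tcc$model, list(role = "antigen"),
                                        list(role = "heavy"))), 1)
})

test_that("salt bridges: bidentate pairs, cutoff, and H-bond precedence", {
  tc <- make_toy_complex(spec = list(
    list(category = "salt_bridge", distance = 3.5, bidentate = TRUE)),
    seed = 33)
  sb <- detect_salt_bridges(tc$model, list(role = "antigen"),
                            list(role = "heavy"))
  expect_equal(nrow(sb), 2)
  expect_true(all(sb$bidentate))
  expect_setequal(sb$atom_a, c("NH1", "NH2"))
  ## the same charged pairs are not double-reported as H-bonds
  hb <- detect_hbonds(tc$model, list(role = "antigen"), list(role = "heavy"))
  expect_equal(nrow(hb), 0)
  ## beyond 4.0 A: nothing
  tc2 <- make_toy_complex(spec = list(
    list(category = "salt_bridge", distance = 4.5, bidentate = FALSE)),
    seed = 34)
  expect_equal(nrow(detect_salt_bridges(tc2$model, list(role = "antigen"),
                                        list(role = "heavy"))), 0)
})

test_that("vdW detector equals the typed brute-force oracle on random atoms", {
  set.seed(41)
  xyz <- matrix(runif(600, 0, 25), ncol = 3)
  at <- rbind(mini_model(xyz[1:100, ], chain = "A")$atoms,
              mini_model(xyz[101:200, ], chain = "B",
                         resno = 1:100)$atoms)
  at$serial <- seq_len(nrow(at))
  m <- assign_radii(structure_model(at, role_map = c(A = "antigen",
                                                     B = "heavy")))
  vd <- detect_vdw_contacts(m, list(chain = "A"), list(chain = "B"))
  ## oracle: all cross-chain pairs <= 4.0 (ALA CA atoms: no donors/acceptors)
  d <- as.matrix(dist(xyz[1:200, ]))
  want <- sum(d[1:100, 101:200] <= 4.0)
  expect_equal(nrow(vd), want)
  expect_equal(nrow(detect_hbonds(m, list(chain = "A"),
                                  list(chain = "B"))), 0)
})

test_that("water bridges require both sides within reach", {
  tc <- make_toy_complex(seed = 35)   # default spec has one bridge
  wb <- detect_water_bridges(tc$model, list(role = "antigen"),
                             list(role = "heavy"))
  expect_equal(attr(wb, "n_waters"), 1L)
  expect_equal(nrow(wb), 1)
  expect_match(wb$water, "^W\\|")
  ## water pulled away from side b: no bridge
  m2 <- tc$model
  wsel <- m2$atoms$chain == "W"
  ## move the water 3 A further from side b along the station axis
  m2$atoms$x[wsel] <- m2$atoms$x[wsel] + 30
  wb2 <- detect_water_bridges(m2, list(role = "antigen"),
                              list(role = "heavy"))
  expect_equal(attr(wb2, "n_waters"), 0L)
})

test_that("contact categories partition the contact set", {
  tc <- make_toy_complex(seed = 36)
  a <- list(role = "antigen"); b <- list(role = "heavy")
  hb <- detect_hbonds(tc$model, a, b)
  sb <- detect_salt_bridges(tc$model, a, b)
  vd <- detect_vdw_contacts(tc$model, a, b)
  keys <- c(paste(hb$atom_a, hb$resno_a, hb$atom_b, hb$resno_b),
            paste(sb$atom_a, sb$resno_a, sb$atom_b, sb$resno_b),
            paste(vd$atom_a, vd$resno_a, vd$atom_b, vd$resno_b))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("contact records reference interface residues", {
  tc <- make_toy_complex(seed = 37)
  a <- list(role = "antigen"); b <- list(role = "heavy")
  ir <- interface_residues(tc$model, a, b)
  direct <- rbind(detect_hbonds(tc$model, a, b)[, c("chain_a", "resno_a")],
                  detect_salt_bridges(tc$model, a, b)[, c("chain_a", "resno_a")],
                  detect_vdw_contacts(tc$model, a, b)[, c("chain_a", "resno_a")])
  uids <- paste(direct$chain_a, direct$resno_a, "", sep = "|")
  expect_true(all(uids %in% ir$residues_a))
})

test_that("contact_table aggregates one row per contact with counts", {
  tc <- make_toy_complex(spec = list(
    list(category = "hydrogen_bond", distance = 2.9),
    list(category = "salt_bridge", distance = 3.5, bidentate = FALSE),
    list(category = "vdw", distance = 3.8),
    list(category = "water_bridge", d_a = 2.8, d_b = 2.9)), seed = 38)
  ct <- contact_table(tc$model, list(role = "antigen"), list(role = "heavy"))
  expect_equal(unname(ct$counts), c(1L, 1L, 1L, 1L),
               ignore_attr = TRUE)
  expect_equal(nrow(ct$table), 4)
  expect_match(ct$table$residue_a[1], "^antigen_")
  ## empty interface -> empty table
  tc0 <- make_toy_complex(spec = list(), seed = 39)
  ct0 <- contact_table(tc0$model, list(role = "antigen"),
                       list(role = "heavy"))
  expect_equal(sum(ct0$counts), 0L)
  expect_equal(nrow(ct0$table), 0)
})

test_that("planted inventories are recovered exactly across seeds", {
  for (seed in 1:12) {
    spec <- random_contact_spec(seed)
    tc <- make_toy_complex(spec = spec, seed = seed)
    ct <- contact_table(tc$model, list(role = "antigen"),
                        list(role = "heavy"))
    expect_equal(unname(ct$counts), unname(spec_counts(spec)),
                 label = sprintf("seed %d", seed))
  }
})
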