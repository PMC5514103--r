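test_that("PDB round-trip preserves atoms, keys and coordinates", {
  for (seed in c(1, 5)) {
    tc <- make_toy_complex(seed = seed)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb_model(tc$model, f)
    m2 <- read_structure(f, role_spec = c(A = "antigen", B = "heavy"))
    expect_equal(nrow(m2$atoms), nrow(tc$model$atoms))
    expect_equal(residue_keys(m2)[, c("chain", "resno", "resname")],
                 residue_keys(tc$model)[, c("chain", "resno", "resname")])
    expect_lt(max(abs(coords(m2) - coords(tc$model))), 1e-3)
  }
})

test_that("waters are written as HETATM/HOH and kept with role water", {
  tc <- make_toy_complex(seed = 2)
  txt <- write_pdb_model(tc$model)
  wat <- grep("HOH", txt, value = TRUE)
  expect_true(length(wat) >= 1)
  expect_true(all(startsWith(wat, "HETATM")))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, f)
  m <- read_structure(f)
  expect_true(all(m$atoms$role[m$atoms$resname == "HOH"] == "water"))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   SER A   1      11.000   1.000   1.000  1.00  0.00           N",
    "ATOM      2  CA ASER A   1      12.000   1.000   1.000  0.60  0.00           C",
    "ATOM      3  CA BSER A   1      19.000   1.000   1.000  0.40  0.00           C",
    "ATOM      4  C   SER A   1      13.500   1.000   1.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3)              # one CA survives
  expect_equal(m$atoms$x[m$atoms$atom == "CA"], 12.0)
  expect_equal(n_residues(m), 1)              # altlocs never change residues
  ## tie in occupancy: altloc letter order wins
  lines[2] <- sub("0.60", "0.40", lines[2])
  writeLines(lines, f)
  m2 <- read_structure(f)
  expect_equal(m2$atoms$x[m2$atoms$atom == "CA"], 12.0)
})

test_that("hydrogens are dropped on parse", {
  lines <- c(
    "ATOM      1  N   GLY A   1       1.000   1.000   1.000  1.00  0.00           N",
    "ATOM      2  H   GLY A   1       1.500   1.800   1.000  1.00  0.00           H",
    "ATOM      3  CA  GLY A   1       2.400   1.000   1.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 2)
  expect_false("H" %in% m$atoms$element)
})

test_that("mmCIF parsing agrees with the PDB path", {
  tc <- make_toy_complex(seed = 3)
  at <- tc$model$atoms
  cif <- c("data_toy", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
             "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")),
    sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
            at$type, at$serial, at$element, at$atom, at$resname, at$chain,
            at$resno, at$x, at$y, at$z, at$occ, at$b, at$resno, at$resname,
            at$chain, at$atom))
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), nrow(at))
  expect_lt(max(abs(coords(m) - coords(tc$model))), 1e-3)
  expect_setequal(unique(m$atoms$chain), unique(at$chain))
})

test_that("parse errors are informative; empty files rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_structure(f), "empty coordinate|parse error")
  expect_error(read_structure("no/such/file.pdb"), "not found")
})

test_that("role assignment covers, warns and errors as specified", {
  tc <- make_toy_complex(seed = 1)
  m <- tc$model
  m2 <- assign_roles(m, c(A = "antigen", B = "heavy"))
  expect_equal(unname(m2$role_map[c("A", "B")]), c("antigen", "heavy"))
  expect_true(all(m2$atoms$role[m2$atoms$resname == "HOH"] == "water"))
  ## omitted chain -> other, with warning
  expect_warning(m3 <- assign_roles(m, c(A = "antigen")), "other")
  expect_equal(unname(m3$role_map["B"]), "other")
  ## absent chain -> error
  expect_error(assign_roles(m, c(Z = "antigen")), "absent")
})

test_that("selection by role, chain and residue range", {
  tc <- make_toy_complex(seed = 1)
  m <- tc$model
  ant <- select_atoms(m, role = "antigen")
  expect_setequal(unique(ant$atoms$chain), "A")
  sub <- select_atoms(m, chain = "A", resno = 1:2)
  expect_equal(sort(unique(sub$atoms$resno)), 1:2)
  wat <- select_atoms(m, role = "water")
  expect_true(all(wat$atoms$resname == "HOH"))
  expect_error(select_atoms(m, chain = "Q"), "empty selection")
  ## radii survive selection
  expect_false(anyNA(ant$atoms$radius))
})

test_that("radii assignment: default table values, fallback, idempotence", {
  tc <- make_toy_complex(seed = 1)
  m <- tc$model
  at <- m$atoms
  ## backbone carbonyl O -> 1.40 under the packaged table
  expect_equal(unique(at$radius[at$atom == "O" & at$resname != "HOH"]), 1.40)
  ## trigonal vs tetrahedral carbons
  expect_equal(unique(at$radius[at$atom == "C"]), 1.76)
  expect_equal(unique(at$radius[at$atom == "CB"]), 1.87)
  expect_equal(unique(at$radius[at$element == "N" & at$resname != "HOH"]),
               1.65)
  ## idempotent
  m2 <- assign_radii(m)
  expect_identical(m2$atoms$radius, m$atoms$radius)
  ## element-only fallback for a nonstandard residue
  lig <- mini_model(c(0, 0, 0), resname = "LIG", atom = "C1", element = "C")
  expect_equal(assign_radii(lig)$atoms$radius, 1.87)
  ## unknown element errors, naming the atom
  bad <- mini_model(c(0, 0, 0), atom = "XX", element = "X")
  expect_error(assign_radii(bad), "no radius rule")
})

test_that("1-char chain id is enforced on write", {
  m <- mini_model(c(0, 0, 0), chain = "AB")
  expect_error(write_pdb_model(m), "1-character")
})
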