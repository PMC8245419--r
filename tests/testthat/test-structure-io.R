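test_that("hand-written PDB text parses into the expected model", {
  pdb <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C",
    "ATOM      3  C   ALA A   1      12.714   7.124  -4.922  1.00 10.00           C",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  m <- read_structure(f)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(unique(m$atoms$chain), "A")
  expect_equal(unique(m$atoms$resno), 1L)
  expect_equal(m$atoms$x[2], 11.639, tolerance = 1e-6)
})

test_that("alternate locations collapse to the highest-occupancy conformer", {
  pdb <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40 10.00           N",
    "ATOM      2  N  BALA A   1       1.000   0.000   0.000  0.60 10.00           N",
    "ATOM      3  CA AALA A   1       2.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CA BALA A   1       3.000   0.000   0.000  0.50 10.00           C",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$elety == "N"], 1.0)   # occupancy 0.6 wins
  expect_equal(m$atoms$x[m$atoms$elety == "CA"], 2.0)  # tie -> altloc A
})

test_that("mmCIF and PDB readings of the same model agree", {
  b <- make_helical_bundle(n_helices = 2, residues_per_helix = 5)
  fp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(b, fp)
  cif_lines <- c(
    "data_synthetic", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . ALA A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA A %s 1",
            seq_len(nrow(b$atoms)), b$atoms$element, b$atoms$elety,
            b$atoms$resno, b$atoms$x, b$atoms$y, b$atoms$z,
            b$atoms$resno, b$atoms$elety),
    "#"
  )
  fc <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif_lines, fc)
  mp <- read_structure(fp)
  mc <- suppressWarnings(read_structure(fc))  # read.cif beta notice
  expect_equal(nrow(mc$atoms), nrow(mp$atoms))
  expect_equal(as.matrix(mc$atoms[, c("x", "y", "z")]),
               as.matrix(mp$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("write/read round-trip preserves structure to PDB precision", {
  b <- make_helical_bundle()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(b, f)
  b2 <- read_structure(f)
  expect_equal(nrow(b2$atoms), nrow(b$atoms))
  expect_equal(
    nrow(dplyr::distinct(b2$atoms, chain, resno, ins)),
    nrow(dplyr::distinct(b$atoms, chain, resno, ins)))
  expect_lt(max(abs(as.matrix(b2$atoms[, c("x", "y", "z")]) -
                    as.matrix(b$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("a conservation profile survives the B-factor round-trip", {
  b <- make_helical_bundle(n_helices = 3, residues_per_helix = 10)
  profile <- tibble::tibble(resno = seq_len(30),
                            value = round(runif(30, 0, 8), 2))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(b, f, bfactor_map = profile)
  b2 <- read_structure(f)
  got <- b2$atoms |>
    dplyr::filter(elety == "CA") |>
    dplyr::arrange(resno) |>
    dplyr::pull(b)
  expect_equal(got, profile$value, tolerance = 0.01)
})

test_that("out-of-range B-factors are refused", {
  b <- make_helical_bundle(n_helices = 1, residues_per_helix = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(
    write_structure(b, f, bfactor_map = tibble::tibble(resno = 1, value = 1e5)),
    "field width")
})

test_that("Calpha traces cover exactly the residues that have a CA", {
  b <- make_helical_bundle(n_helices = 2, residues_per_helix = 5)
  tr <- extract_ca_trace(b, "A")
  expect_equal(nrow(tr), 10)
  expect_equal(tr$aa, rep("A", 10))

  # hetero residues (waters, lipids) are excluded even with central atoms
  at <- b$atoms
  extra <- tibble::tibble(
    chain = "A", resno = c(101L, 102L), ins = "", resid = c("HOH", "OLC"),
    het = TRUE, elety = c("O", "C1"), element = c("O", "C"),
    x = 99, y = 99, z = 99, o = 1, b = 0)
  m <- structure_model(dplyr::bind_rows(at, extra), id = "withhet")
  expect_equal(nrow(extract_ca_trace(m, "A")), 10)

  expect_error(extract_ca_trace(b, "Z"), "not found")
})

test_that("residues lacking a CA are skipped with a warning", {
  b <- make_helical_bundle(n_helices = 1, residues_per_helix = 5)
  at <- dplyr::filter(b$atoms, !(resno == 3 & elety == "CA"))
  m <- structure_model(at, id = "gappy")
  expect_warning(tr <- extract_ca_trace(m, "A"), "lack a CA")
  expect_equal(nrow(tr), 4)
  expect_false(3 %in% tr$resno)
})

test_that("atom role counts partition the atom set", {
  empty <- structure_model(make_helical_bundle()$atoms[0, ], id = "empty")
  expect_equal(unlist(count_atoms_by_role(empty)),
               c(protein = 0, water = 0, retinal = 0, lipid = 0,
                 other = 0, total = 0))

  # 5 alanines at 5 heavy atoms each (N, CA, C, O, CB) + 3 waters
  ala <- do.call(rbind, lapply(seq_len(5), function(i) {
    tibble::tibble(chain = "A", resno = i, ins = "", resid = "ALA",
                   het = FALSE,
                   elety = c("N", "CA", "C", "O", "CB"),
                   element = c("N", "C", "C", "O", "C"),
                   x = i * 4 + c(0, 1, 2, 2, 1), y = c(0, 1, 0, -1, 2),
                   z = 0, o = 1, b = 0)
  }))
  wat <- tibble::tibble(chain = "W", resno = 1:3, ins = "", resid = "HOH",
                        het = TRUE, elety = "O", element = "O",
                        x = 50 + 1:3 * 5, y = 0, z = 0, o = 1, b = 0)
  ret <- tibble::tibble(chain = "A", resno = 500L, ins = "", resid = "RET",
                        het = TRUE, elety = "C15", element = "C",
                        x = -20, y = 0, z = 0, o = 1, b = 0)
  unk <- tibble::tibble(chain = "A", resno = 600L, ins = "", resid = "XYZ",
                        het = TRUE, elety = "C1", element = "C",
                        x = -30, y = 0, z = 0, o = 1, b = 0)
  m <- structure_model(rbind(ala, wat, ret, unk), id = "mixed")
  counts <- count_atoms_by_role(m)
  expect_equal(counts$protein, 25)
  expect_equal(counts$water, 3)
  expect_equal(counts$retinal, 1)
  expect_equal(counts$other, 1)
  expect_equal(counts$total, nrow(m$atoms))
  expect_equal(counts$protein + counts$water + counts$retinal +
                 counts$lipid + counts$other, counts$total)
})
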