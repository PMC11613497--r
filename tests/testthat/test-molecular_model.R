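test_that("a generated polyalanine PDB reads back with the expected content", {
  path <- withr::local_tempfile(fileext = ".pdb")
  p0 <- make_polypeptide("AAA", path = path)
  p <- read_pdb(path, role = "protein")
  expect_s3_class(p, "mfcc_protein")
  expect_equal(nresidues(p), 3L)
  expect_equal(nrow(p$atoms), 33L)
  expect_equal(sort(table(p$atoms$element)),
               sort(table(p0$atoms$element)))
  # residue ordering and coordinates survive the round trip
  expect_equal(p$atoms$name, p0$atoms$name)
  expect_equal(as.matrix(p$atoms[, c("x", "y", "z")]),
               as.matrix(p0$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("a single-atom HETATM file reads as a ligand with configured charge", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1 CL    CL A 401       1.000   2.000   3.000  1.00  0.00          CL",
    "END"), path)
  lig <- read_pdb(path, role = "ligand", ligand_charge = -1L)
  expect_s3_class(lig, "mfcc_ligand")
  expect_equal(natoms(lig$molecule), 1L)
  expect_equal(lig$molecule$element, "Cl")
  expect_equal(lig$charge, -1L)
  expect_equal(lig$molecule$xyz[1, ], c(1, 2, 3), ignore_attr = TRUE)
})

test_that("structural defects in PDB input surface as named errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  make_polypeptide("AAA", path = path)
  lines <- readLines(path)
  # remove the backbone C of residue 2
  drop <- grepl("^ATOM", lines) & substr(lines, 14, 16) == "C  " &
    substr(lines, 23, 26) == "   2"
  expect_true(any(drop))
  writeLines(lines[!drop], path)
  err <- expect_error(read_pdb(path, "protein"),
                      class = "mfcc_error_missing_backbone")
  expect_match(conditionMessage(err), "ALA A2")

  # multi-model file
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", lines, "ENDMDL", "MODEL     2", lines, "ENDMDL"),
             path2)
  expect_error(read_pdb(path2, "protein"), class = "mfcc_error_multi_model")

  # altloc duplicates error unless a policy is chosen
  path3 <- withr::local_tempfile(fileext = ".pdb")
  alt <- lines
  atom1 <- which(grepl("^ATOM", alt))[1]
  la <- alt[atom1]
  a_version <- paste0(substr(la, 1, 16), "A", substr(la, 18, nchar(la)))
  b_version <- paste0(substr(la, 1, 16), "B", substr(la, 18, nchar(la)))
  substr(b_version, 57, 60) <- "0.30"
  writeLines(c(alt[seq_len(atom1 - 1)], a_version, b_version,
               alt[-seq_len(atom1)]), path3)
  expect_error(read_pdb(path3, "protein"), class = "mfcc_error_altloc")
  p <- read_pdb(path3, "protein", altloc_policy = "occupancy")
  expect_equal(nrow(p$atoms), 33L)
})

test_that("min_distance matches elementary geometry and is symmetric", {
  a <- molecule("Ar", matrix(c(0, 0, 0), 1))
  b <- molecule("Ar", matrix(c(3, 4, 0), 1))
  expect_equal(min_distance(a, b), 5)
  expect_equal(min_distance(a, a), 0)
  m <- random_molecule(6, seed = 1)
  diam <- max(stats::dist(m$xyz))
  spanx <- max(m$xyz[, 1]) - min(m$xyz[, 1])
  d <- diam + 7
  m2 <- shifted(m, c(d, 0, 0))
  expect_gte(min_distance(m, m2), d - diam)
  expect_equal(min_distance(m, m2), min_distance(m2, m))
  expect_error(min_distance(a, list(xyz = NULL)), class = "mfcc_error_empty_molecule")
})

test_that("min_distance equals the exhaustive double-loop oracle", {
  for (s in 1:8) {
    a <- random_molecule(5 + s %% 4, seed = s)
    b <- shifted(random_molecule(4 + s %% 3, seed = s + 100), c(2, -1, 3))
    expect_equal(min_distance(a, b), oracle_min_distance(a, b), tolerance = 1e-12)
  }
})

test_that("XYZ output round-trips and rejects degenerate input", {
  w <- molecule(c("O", "H", "H"),
                rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.24, 0.9266, 0)),
                charge = 0L, label = "water")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(w, path)
  lines <- readLines(path)
  expect_equal(lines[1], "3")
  expect_length(lines, 5)
  w2 <- read_xyz(path)
  expect_identical(w2$element, w$element)
  expect_equal(w2$xyz, w$xyz, tolerance = 1e-6)
  expect_equal(w2$charge, 0L)
  expect_error(write_xyz(list(), path), class = "mfcc_error_empty_molecule")
  expect_error(molecule(character(0), matrix(numeric(0), ncol = 3)),
               class = "mfcc_error_empty_molecule")
})

test_that("molecule invariants are enforced", {
  expect_error(molecule("Xx", matrix(0, 1, 3)), class = "mfcc_error_bad_element")
  expect_error(molecule(c("C", "C"), matrix(c(0, 0, 0, Inf, 0, 0), 2, byrow = TRUE)),
               class = "mfcc_error_bad_coordinates")
  expect_error(molecule(c("C", "C"), matrix(rnorm(6), 2), serial = c(1, 1)),
               class = "mfcc_error_duplicate_serial")
})
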