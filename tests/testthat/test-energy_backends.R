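test_that("the pairwise backend reproduces the closed form on a dimer", {
  par <- pairwise_params()
  m <- molecule(c("Na", "Cl"), rbind(c(0, 0, 0), c(3, 0, 0)))
  be <- pairwise_backend(par)
  r <- 3
  s <- (par$sig[["Na"]] + par$sig[["Cl"]]) / 2
  e <- sqrt(par$eps[["Na"]] * par$eps[["Cl"]])
  u <- par$coulomb * par$q[["Na"]] * par$q[["Cl"]] / r +
    4 * e * ((s / r)^12 - (s / r)^6)
  expect_equal(compute_energy(m, be)$energy, u, tolerance = 1e-12)
})

test_that("pairwise energies are additive for far-separated subsystems", {
  be <- pairwise_backend()
  a <- random_molecule(5, seed = 2, elements = c("Ar"))
  b <- shifted(random_molecule(4, seed = 3, elements = c("Ar")), c(700, 0, 0))
  eu <- energy <- compute_energy(mfccmbe:::mol_concat(list(a, b)), be)$energy
  expect_equal(eu, compute_energy(a, be)$energy + compute_energy(b, be)$energy,
               tolerance = 1e-10)
})

test_that("the three-body backend equals an independent pair+triple summation", {
  par <- threebody_params()
  tb <- threebody_backend(par)
  for (s in 1:4) {
    m <- random_molecule(3 + s, seed = 10 + s, elements = c("Ar", "C", "O"))
    expect_equal(compute_energy(m, tb)$energy,
                 oracle_total_energy(m, par, nu = par$nu),
                 tolerance = 1e-9)
  }
})

test_that("dimer interaction energy equals the exhaustive cross-pair sum", {
  par <- pairwise_params()
  be <- pairwise_backend(par)
  for (s in 1:6) {
    a <- random_molecule(4 + s %% 3, seed = s)
    b <- shifted(random_molecule(5, seed = s + 50), c(6, 1, -2))
    expect_equal(pair_interaction(a, b, be), oracle_cross_pairs(a, b, par),
                 tolerance = 1e-8)
  }
})

test_that("the trimer interaction isolates exactly the mixed triples", {
  # E_ABC - E_AB - E_AC - E_BC + E_A + E_B + E_C under the three-body
  # potential must equal the sum of w over triples with one atom per body.
  par <- threebody_params()
  tb <- threebody_backend(par)
  cat2 <- function(...) mfccmbe:::mol_concat(list(...))
  for (s in 1:3) {
    a <- random_molecule(3, seed = s, elements = "Ar")
    b <- shifted(random_molecule(3, seed = s + 20, elements = "Ar"), c(5, 0, 0))
    c_ <- shifted(random_molecule(2, seed = s + 40, elements = "Ar"), c(2, 5, 0))
    e <- function(m) compute_energy(m, tb)$energy
    tri <- e(cat2(a, b, c_)) - e(cat2(a, b)) - e(cat2(a, c_)) - e(cat2(b, c_)) +
      e(a) + e(b) + e(c_)
    expect_equal(tri, oracle_mixed_triples(a, b, c_, par$nu), tolerance = 1e-9)
  }
})

test_that("the energy cache is transparent and keyed by geometry", {
  be <- pairwise_backend()
  m <- random_molecule(8, seed = 7)
  e1 <- compute_energy(m, be, use_cache = FALSE)$energy
  e2 <- compute_energy(m, be)$energy          # populates cache
  e3 <- compute_energy(m, be)$energy          # served from cache
  expect_identical(e1, e2)
  expect_identical(e2, e3)
  m2 <- shifted(m, c(1e-3, 0, 0))
  expect_false(isTRUE(all.equal(subsystem_key(m), subsystem_key(m2))))
})

test_that("manifest export enumerates the MFCC subsystem set and is reproducible", {
  cx <- make_complex("AAA", ligand = "point", seed = 2)
  plan <- fragment_protein(cx$protein)
  subs <- plan_subsystems(plan, cx$ligand, method = "mfcc")
  # 3 fragments + 2 caps + (3+2) ligand supermolecules + the ligand
  expect_length(subs, 11L)
  roles <- vapply(subs, function(m) attr(m, "role"), "")
  expect_equal(sum(roles == "fragment"), 3L)
  expect_equal(sum(roles == "cap"), 2L)
  expect_equal(sum(grepl("-lig$", roles)), 5L)
  expect_equal(sum(roles == "ligand"), 1L)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_manifest(subs, d1)
  export_manifest(subs, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  expect_error(export_manifest(list(), withr::local_tempdir()),
               class = "mfcc_error_empty_manifest")
  expect_error(export_manifest(c(subs, subs[1]), withr::local_tempdir()),
               class = "mfcc_error_key_collision")
})

test_that("imported energies round-trip and units convert to kJ/mol", {
  cx <- make_complex("AA", ligand = "point", seed = 9)
  plan <- fragment_protein(cx$protein)
  be <- pairwise_backend()
  subs <- plan_subsystems(plan, cx$ligand, method = "mfcc")
  dir <- withr::local_tempdir()
  idx <- export_manifest(subs, dir)
  keys <- vapply(subs, subsystem_key, "")
  en <- vapply(subs, function(m) compute_energy(m, be)$energy, numeric(1))

  hartree <- 2625.4996394799
  res <- file.path(dir, "results.tsv")
  writeLines(c("# unit: hartree",
               paste(keys, format(en / hartree, digits = 17), sep = "\t")), res)
  imported <- import_energies(idx, res)
  expect_equal(unname(imported[keys]), en, tolerance = 1e-9)

  # the imported table reproduces the in-process result through the ledger
  tb <- table_backend(imported)
  expect_equal(mfcc_pl_interaction(plan, cx$ligand, tb)$value,
               mfcc_pl_interaction(plan, cx$ligand, be)$value,
               tolerance = 1e-6)

  # missing entry errors and names the key
  writeLines(c("# unit: kJ/mol",
               paste(keys[-1], format(en[-1], digits = 17), sep = "\t")), res)
  err <- expect_error(import_energies(idx, res), class = "mfcc_error_missing_energy")
  expect_match(conditionMessage(err), keys[1], fixed = TRUE)

  # absent unit header errors
  writeLines(paste(keys, en, sep = "\t"), res)
  expect_error(import_energies(idx, res), class = "mfcc_error_missing_unit")
})

test_that("missing subsystem energies surface with the subsystem named", {
  plan <- fragment_protein(make_polypeptide("AA"))
  tb <- table_backend(c(dummy = 1))
  err <- expect_error(mfcc_total_energy(plan, tb),
                      class = "mfcc_error_missing_energy")
  expect_match(conditionMessage(err), "frag001")
})
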