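be <- pairwise_backend()
tb <- threebody_backend()

test_that("MFCC total energy of a single capped-free residue is its own energy", {
  plan <- fragment_protein(make_polypeptide("A"))
  expect_length(plan$caps, 0L)
  expect_equal(mfcc_total_energy(plan, be),
               compute_energy(plan$fragments[[1]], be)$energy)
})

test_that("the MFCC ledger carries the mandated signs", {
  plan <- fragment_protein(make_polypeptide("GGGGG"))
  led <- build_mfcc_ledger(plan)
  expect_equal(sort(led$coef), sort(c(rep(1, 5), rep(-1, 4))))
  expect_equal(led$coef[led$family == "frag"], rep(1, 5))
  expect_equal(led$coef[led$family == "cap"], rep(-1, 4))
})

test_that("pair_interaction matches closed forms and limits", {
  par <- pairwise_params()
  a <- molecule("Ar", matrix(c(0, 0, 0), 1))
  b <- molecule("Ar", matrix(c(2^(1 / 6) * par$sig[["Ar"]], 0, 0), 1))
  expect_equal(pair_interaction(a, b, be), -par$eps[["Ar"]], tolerance = 1e-12)
  far <- molecule("Ar", matrix(c(900, 0, 0), 1))
  expect_lt(abs(pair_interaction(a, far, be)), 1e-10)
})

test_that("MFCC-MBE(2) total energy is exact for pairwise potentials in idealized overlap mode", {
  for (s in 1:4) {
    plan <- make_bead_chain(9 + s, window = 4, overlap = 1, seed = s)
    etrue <- compute_energy(plan$parent, be)$energy
    expect_equal(mfcc_mbe2_total_energy(plan, be), etrue,
                 tolerance = 1e-10 * max(1, abs(etrue)))
    # MFCC alone is not exact here (the missing long-range pairs are real)
    expect_gt(abs(mfcc_total_energy(plan, be) - etrue), 1e-6)
  }
})

test_that("with no caps the assembly reduces termwise to the plain two-body expansion", {
  plan <- make_bead_chain(12, window = 3, overlap = 0, seed = 4)
  expect_length(plan$caps, 0L)
  terms <- mfccmbe:::mbe2_terms(plan)
  expect_true(all(terms$family == "ff"))
  # termwise: every pair term is the plain dimer interaction
  direct <- sum(vapply(seq_len(nrow(terms)), function(r)
    pair_interaction(plan$fragments[[terms$i[r]]],
                     plan$fragments[[terms$j[r]]], be), numeric(1)))
  mono <- sum(vapply(plan$fragments, function(m) compute_energy(m, be)$energy,
                     numeric(1)))
  etrue <- compute_energy(plan$parent, be)$energy
  expect_equal(mfcc_mbe2_total_energy(plan, be), mono + direct, tolerance = 1e-9)
  expect_equal(mono + direct, etrue, tolerance = 1e-9 * abs(etrue))
})

test_that("MFCC results are invariant to fragment enumeration order", {
  plan <- fragment_protein(make_polypeptide("AGSDA", seed = 1))
  v1 <- mfcc_total_energy(plan, pairwise_backend())
  perm <- c(3, 1, 5, 2, 4)
  plan2 <- plan
  plan2$fragments <- plan$fragments[perm]
  v2 <- mfcc_total_energy(plan2, pairwise_backend())
  expect_equal(v1, v2, tolerance = 1e-12 * abs(v1))
})

test_that("MFCC interaction energy is exact for pairwise potentials", {
  cx <- make_complex("AGSDK", ligand = "zwitterion", seed = 21)
  plan <- fragment_protein(cx$protein)
  est <- mfcc_pl_interaction(plan, cx$ligand, be)
  ref <- supermolecular_interaction(cx$protein, cx$ligand, be)
  expect_lt(abs(interaction_error(est, ref)), 1e-8 * max(1, abs(ref$value)))
  # also against the raw cross-pair oracle
  expect_equal(ref$value,
               oracle_cross_pairs(protein_molecule(cx$protein),
                                  cx$ligand$molecule, pairwise_params()),
               tolerance = 1e-8)
})

test_that("an N=1 protein has a single fragment-ligand term and no caps", {
  cx <- make_complex("A", ligand = "point", anchor_residue = 1, seed = 3)
  plan <- fragment_protein(cx$protein)
  est <- mfcc_pl_interaction(plan, cx$ligand, be)
  expect_equal(est$value,
               pair_interaction(plan$fragments[[1]], cx$ligand$molecule, be),
               tolerance = 1e-10)
  expect_equal(nrow(est$ledger), 1L)
})

test_that("a ligand at extreme separation interacts with nothing", {
  # a charge-neutral ligand: the Lennard-Jones tail vanishes as r^-6
  p <- make_polypeptide("AAA")
  plan <- fragment_protein(p)
  lig <- molecule("Ar", matrix(c(1000, 1000, 0), 1), label = "far")
  expect_lt(abs(mfcc_pl_interaction(plan, lig, be)$value), 1e-6)
  expect_lt(abs(mfcc_mbe2_pl_interaction(plan, lig, be, lambda = Inf)$value), 1e-6)
})

test_that("every three-body correction vanishes for a pairwise potential", {
  cx <- make_complex("CAASC", conformation = "helical",
                     ss_pairs = list(c(1, 5)), ligand = "point", seed = 11)
  plan <- fragment_protein(cx$protein)
  L <- cx$ligand$molecule
  terms <- mfccmbe:::mbe2_terms(plan)
  b <- pairwise_backend()
  for (r in seq_len(nrow(terms))) {
    te <- mfccmbe:::term_entries(plan, terms$family[r], terms$i[r], terms$j[r])
    expect_lt(abs(mfccmbe:::eval_entries_lig(te$entries, L, b)), 1e-8)
  }
  # hence the upgraded scheme coincides with MFCC for any cutoff
  mfcc <- mfcc_pl_interaction(plan, cx$ligand, b)
  for (lam in c(2, 4, Inf))
    expect_equal(mfcc_mbe2_pl_interaction(plan, cx$ligand, b, lam)$value,
                 mfcc$value, tolerance = 1e-8)
})

test_that("pair ledgers are atom-multiset balanced with integer coefficients", {
  cx <- make_complex("CAASC", conformation = "helical",
                     ss_pairs = list(c(1, 5)), ligand = "point", seed = 11)
  plan <- fragment_protein(cx$protein)
  L <- cx$ligand$molecule
  terms <- mfccmbe:::mbe2_terms(plan)
  for (r in seq_len(nrow(terms))) {
    te <- mfccmbe:::term_entries(plan, terms$family[r], terms$i[r], terms$j[r])
    coefs <- vapply(te$entries, `[[`, numeric(1), "coef")
    expect_true(all(coefs == round(coefs)))
    # pair ledger: the two bodies' atoms cancel exactly against the joined
    # subsystem(s); ligand-augmented ledger: everything cancels, ligand
    # included (this is what makes the term a pure three-body interaction)
    tally <- new.env(parent = emptyenv())
    for (e in mfccmbe:::entries_with_ligand(te$entries, L))
      for (k in mfccmbe:::atom_coord_key(e$mol))
        assign(k, (if (is.null(tally[[k]])) 0 else tally[[k]]) + e$coef,
               envir = tally)
    counts <- unlist(as.list(tally))
    expect_true(all(counts == 0),
                label = sprintf("multiset balance %s(%d,%d)",
                                terms$family[r], terms$i[r], terms$j[r]))
  }
})

test_that("MFCC-MBE(2) with the three-body backend is exact at lambda = Inf in idealized mode", {
  bc <- make_bead_complex(11, window = 4, overlap = 1, distance = 2.5, seed = 5)
  est <- mfcc_mbe2_pl_interaction(bc$plan, bc$ligand, tb, lambda = Inf)
  ref <- supermolecular_interaction(bc$plan, bc$ligand, tb)
  expect_lt(abs(interaction_error(est, ref)), 1e-8 * max(1, abs(ref$value)))
  # MFCC alone misses the genuine three-body contributions
  expect_gt(abs(interaction_error(mfcc_pl_interaction(bc$plan, bc$ligand, tb),
                                  ref)), 1e-4)
})

test_that("the trimer screen matches its definition and treats the boundary strictly", {
  bc <- make_bead_complex(11, window = 4, overlap = 1, distance = 2.5, seed = 42)
  st <- screen_trimers(bc$plan, bc$ligand, 3.5)
  oracle <- (st$d_al < 3.5) + (st$d_bl < 3.5) + (st$d_ab < 3.5) >= 2
  expect_equal(st$included, oracle)
  # exactly at the cutoff a distance does not count as below it
  lam <- sort(unique(c(st$d_al, st$d_bl)))[3]
  st2 <- screen_trimers(bc$plan, bc$ligand, lam)
  oracle2 <- (st2$d_al < lam) + (st2$d_bl < lam) + (st2$d_ab < lam) >= 2
  expect_equal(st2$included, oracle2)
  expect_error(screen_trimers(bc$plan, bc$ligand, -1), class = "mfcc_error_bad_lambda")
})

test_that("a cutoff below every intermolecular distance reproduces MFCC", {
  bc <- make_bead_complex(9, window = 4, overlap = 1, distance = 2.5, seed = 8)
  st <- screen_trimers(bc$plan, bc$ligand, 1)
  expect_equal(sum(st$included), 0L)
  est <- mfcc_mbe2_pl_interaction(bc$plan, bc$ligand, tb, lambda = 1)
  expect_equal(est$value, mfcc_pl_interaction(bc$plan, bc$ligand, tb)$value,
               tolerance = 1e-12)
})

test_that("ledger term counts follow the combinatorial formulas", {
  for (N in 1:8) {
    plan <- fragment_protein(make_polypeptide(strrep("G", N)))
    expect_equal(plan$n_fragments, N)
    expect_length(plan$caps, max(N - 1, 0))
    terms <- mfccmbe:::mbe2_terms(plan)
    expect_equal(sum(terms$family == "ff"), choose(N, 2))
    expect_equal(sum(terms$family == "cc"), choose(N - 1, 2))
    expect_equal(sum(terms$family == "fc"), (N - 1) * (N - 2))
  }
})

test_that("interaction_error is a signed difference and refuses mixed parameters", {
  expect_equal(interaction_error(5, 5), 0)
  expect_equal(interaction_error(3, 7), -interaction_error(7, 3))
  bc <- make_bead_complex(9, window = 4, overlap = 1, seed = 1)
  est <- mfcc_pl_interaction(bc$plan, bc$ligand, be)
  ref <- supermolecular_interaction(bc$plan, bc$ligand, tb)
  expect_error(interaction_error(est, ref), class = "mfcc_error_mixed_params")
})
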