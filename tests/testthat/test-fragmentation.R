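test_that("cut sites follow the chain and disulfide topology", {
  expect_equal(nrow(detect_cut_sites(make_polypeptide("AA"))), 1L)
  expect_equal(nrow(detect_cut_sites(make_polypeptide("A"))), 0L)
  p <- make_polypeptide(c("ACA", "AACA"), ss_pairs = list(c(2, 6)))
  sites <- detect_cut_sites(p)
  expect_equal(sum(sites$type == "peptide"), 5L)  # 2 + 3, none across chains
  expect_equal(sum(sites$type == "ss"), 1L)
})

test_that("capped fragments have the expected composition", {
  plan <- fragment_protein(make_polypeptide("AAA"))
  expect_equal(plan$n_fragments, 3L)
  expect_length(plan$caps, 2L)
  # middle fragment is N-acetyl-alanine-N'-methylamide (Ac-Ala-NHMe)
  expect_equal(mol_formula(plan$fragments[[2]]), "C6H12N2O2")
  # terminal fragments carry a cap only on the interior side
  expect_named(attr(plan$fragments[[1]], "groups"), "nme")
  expect_named(attr(plan$fragments[[3]], "groups"), "ace")
  expect_setequal(names(attr(plan$fragments[[2]], "groups")), c("ace", "nme"))
  # standalone builder agrees with the plan
  f2 <- build_capped_fragment(make_polypeptide("AAA"), 2)
  expect_identical(f2$element, plan$fragments[[2]]$element)
  expect_identical(f2$xyz, plan$fragments[[2]]$xyz)
})

test_that("cap molecules are N-methylacetamide with in-fragment coordinates", {
  p <- make_polypeptide("GGGGGGG")
  plan <- fragment_protein(p)
  expect_length(plan$caps, 6L)
  for (cap in plan$caps) {
    expect_equal(mol_formula(cap, heavy_only = TRUE), "C3NO")
    expect_equal(mol_formula(cap), "C3H7NO")
  }
  # bitwise coordinate identity with the copies inside adjacent fragments
  for (k in seq_along(plan$caps)) {
    ck <- mfccmbe:::atom_coord_key(plan$caps[[k]])
    fk <- c(mfccmbe:::atom_coord_key(plan$fragments[[k]]),
            mfccmbe:::atom_coord_key(plan$fragments[[k + 1]]))
    expect_true(all(ck %in% fk))
  }
  cap1 <- build_cap_molecule(p, 1)
  expect_identical(cap1$xyz, plan$caps[[1]]$xyz)
})

test_that("disulfides are cut and capped with methyl sulfide groups", {
  p <- make_polypeptide("CAAAC", conformation = "helical",
                        ss_pairs = list(c(1, 5)))
  plan <- fragment_protein(p)
  expect_equal(plan$n_fragments, 5L)
  expect_length(plan$caps, 5L)  # 4 peptide + 1 disulfide
  ss <- plan$caps[[which(plan$sites$type == "ss")]]
  expect_equal(mol_formula(ss), "C2H6S2")  # dimethyl disulfide analogue
  # each cysteine fragment carries an added S-CH3 unit on the partner side
  f1 <- plan$fragments[[1]]
  grp <- attr(f1, "groups")
  ss_idx <- grp[[grep("^ss", names(grp))]]
  expect_equal(sort(table(f1$element[ss_idx])),
               sort(table(c("S", "C", "H", "H", "H"))))
})

test_that("a 10-residue chain with one internal disulfide yields 10+9+1 subsystems", {
  p <- make_polypeptide("CAAAAAAAAC", conformation = "helical",
                        ss_pairs = list(c(1, 10)))
  plan <- fragment_protein(p)
  expect_equal(plan$n_fragments, 10L)
  expect_equal(sum(plan$sites$type == "peptide"), 9L)
  expect_equal(sum(plan$sites$type == "ss"), 1L)
})

test_that("overlap counting and link-hydrogen pairing hold on diverse fixtures", {
  fixtures <- list(
    fragment_protein(make_polypeptide("AAA")),
    fragment_protein(make_polypeptide("GDKSA", seed = 3)),
    fragment_protein(make_polypeptide("CAAAC", conformation = "helical",
                                      ss_pairs = list(c(1, 5)))),
    fragment_protein(make_polypeptide(c("ACA", "AACA"), ss_pairs = list(c(2, 6)))))
  parents <- list(
    protein_molecule(make_polypeptide("AAA")),
    protein_molecule(make_polypeptide("GDKSA", seed = 3)),
    protein_molecule(make_polypeptide("CAAAC", conformation = "helical",
                                      ss_pairs = list(c(1, 5)))),
    protein_molecule(make_polypeptide(c("ACA", "AACA"), ss_pairs = list(c(2, 6)))))
  for (f in seq_along(fixtures)) {
    plan <- fixtures[[f]]
    oc <- overlap_counts(plan, parents[[f]])
    # every parent heavy atom: fragments containing it minus caps = 1
    expect_true(all((oc$nf - oc$nc)[oc$heavy] == 1),
                label = sprintf("overlap identity, fixture %d", f))
    # constructed link hydrogens pair off between fragments and caps
    lh_frag <- unlist(lapply(plan$fragments, function(m)
      mfccmbe:::atom_coord_key(m)[is.na(m$source)]))
    lh_cap <- unlist(lapply(plan$caps, function(m)
      mfccmbe:::atom_coord_key(m)[is.na(m$source)]))
    expect_equal(sort(lh_frag), sort(lh_cap),
                 label = sprintf("link-H pairing, fixture %d", f))
  }
})

test_that("fragmentation is idempotent", {
  p <- make_polypeptide("AGSDA", seed = 5)
  p1 <- fragment_protein(p)
  p2 <- fragment_protein(p)
  expect_identical(lapply(p1$fragments, `[[`, "xyz"),
                   lapply(p2$fragments, `[[`, "xyz"))
  expect_identical(lapply(p1$caps, `[[`, "xyz"),
                   lapply(p2$caps, `[[`, "xyz"))
})

test_that("fragment charges come from the protonation table", {
  plan <- fragment_protein(make_polypeptide("ADKA"))
  expect_equal(vapply(plan$fragments, `[[`, integer(1), "charge"),
               c(0L, -1L, 1L, 0L))
  expect_true(all(vapply(plan$caps, `[[`, integer(1), "charge") == 0L))
})

test_that("proline at an N-side cut errors unless a policy is configured", {
  p <- make_polypeptide("APA")
  expect_error(fragment_protein(p), class = "mfcc_error_proline")
  plan <- fragment_protein(p, spec = cap_spec(proline_policy = "strip"))
  expect_equal(plan$n_fragments, 3L)
  # the stripped nitrogen gets a link hydrogen in place of the ring carbon
  expect_true(any(grepl("proline", plan$provenance$desc[!is.na(plan$provenance$desc)])))
})

test_that("degenerate inputs are rejected", {
  expect_error(fragment_protein(list()), class = "mfcc_error_empty_protein")
  expect_error(build_cap_molecule(make_polypeptide("AAA"), 7),
               class = "mfcc_error_bad_site")
})
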