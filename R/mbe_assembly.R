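# ---------------------------------------------------------------------------
# Signed subsystem ledgers for the MFCC and MFCC-MBE(2) energy expressions.
#
# MFCC total:        E  =  sum_i E_i^frag - sum_k E_k^cap
# MFCC-MBE(2) total: E  =  E^MFCC + sum dE^ff - sum dE^fc + sum dE^cc
# Interaction energies replace each term by its interaction with the ligand.
#
# Pair interactions between overlapping bodies need care:
#  * bodies connected by a cut site (peptide neighbours, disulfide partners)
#    are healed into the covalently bonded dimer; the exact atom-multiset
#    surplus (provably the cap molecule of the healed site) enters as a +1
#    correction subsystem, so every ledger is atom-multiset balanced;
#  * bodies that merely share constructed cap atoms (fragments i and i+2,
#    a fragment facing a cap one cut further, adjacent caps) drop the
#    clashing cap (sub)groups on both sides before forming the plain pair.
# Multiset balance is what makes all two-body ledgers exact for strictly
# pairwise potentials and all ligand-augmented three-body terms vanish there.
# ---------------------------------------------------------------------------

mol_rows <- function(m) {
  data.frame(element = m$element, name = m$name, serial = m$serial,
             x = m$xyz[, 1], y = m$xyz[, 2], z = m$xyz[, 3],
             source = m$source, source_desc = m$source_desc,
             stringsAsFactors = FALSE)
}

# Merge two overlapping bodies into their covalent dimer: duplicate atoms
# (bitwise coordinate copies) are kept once, and constructed link hydrogens
# that end up overlapping a retained heavy atom are removed.  The exact
# multiset difference (A + B) - dimer is returned as the correction molecule.
heal_union <- function(A, B, label, stray_radius = 0.8) {
  ra <- mol_rows(A); rb <- mol_rows(B)
  ka <- atom_coord_key(A); kb <- atom_coord_key(B)
  dup <- kb %in% ka
  un <- rbind(ra, rb[!dup, , drop = FALSE])
  heavy <- un$element != "H"
  cand <- which(un$element == "H" & is.na(un$source))
  stray <- logical(nrow(un))
  if (length(cand) > 0L && any(heavy)) {
    hxyz <- as.matrix(un[heavy, c("x", "y", "z")])
    for (i in cand) {
      d2 <- colSums((t(hxyz) - as.numeric(un[i, c("x", "y", "z")]))^2)
      if (min(d2) < stray_radius^2) stray[i] <- TRUE
    }
  }
  dimer <- un[!stray, , drop = FALSE]
  surplus <- rbind(rb[dup, , drop = FALSE], un[stray, , drop = FALSE])
  D <- rows_to_molecule(dimer, charge = A$charge + B$charge,
                        label = paste0("dimer", label))
  S <- rows_to_molecule(surplus, charge = 0L, label = paste0("healcap", label))
  list(dimer = D, surplus = S)
}

# Drop, from each of two bodies, the cap (sub)groups that contain atoms the
# bodies share -- either bitwise coordinate copies or constructed atoms
# overlapping an atom of the partner body (within `clash_radius`); returns
# modified disjoint bodies.  Genuine non-bonded contacts sit well above
# 1.5 A, while every cap-construction overlap sits below 0.7 A, so the
# radius separates the two regimes cleanly.
drop_shared_groups <- function(A, B, clash_radius = 0.8) {
  ka <- atom_coord_key(A); kb <- atom_coord_key(B)
  d2 <- outer(rowSums(A$xyz^2), rep(1, nrow(B$xyz))) +
    outer(rep(1, nrow(A$xyz)), rowSums(B$xyz^2)) - 2 * A$xyz %*% t(B$xyz)
  close <- d2 < clash_radius^2
  hitA <- which(ka %in% kb | apply(close, 1, any))
  hitB <- which(kb %in% ka | apply(close, 2, any))
  if (length(hitA) + length(hitB) == 0L)
    return(list(A = A, B = B, modified = FALSE))
  strip <- function(m, keys, hit) {
    groups <- attr(m, "groups")
    if (is.null(groups))
      mfcc_error(paste0("bodies '", m$label, "' share atoms but carry no cap groups"),
                 "mfcc_error_internal")
    drop <- integer(0)
    for (g in groups) if (any(hit %in% g)) drop <- c(drop, g)
    if (!all(hit %in% drop))
      mfcc_error(paste0("shared atoms of '", m$label,
                        "' are not confined to cap groups"),
                 "mfcc_error_internal")
    mol_subset(m, setdiff(seq_along(keys), drop),
               label = paste0(m$label, "*"))
  }
  A2 <- strip(A, ka, hitA); B2 <- strip(B, kb, hitB)
  if (length(intersect(atom_coord_key(A2), atom_coord_key(B2))) > 0L ||
      min_distance(A2, B2) < clash_radius)
    mfcc_error("clash resolution failed to disjoin the two bodies",
               "mfcc_error_internal")
  list(A = A2, B = B2, modified = TRUE)
}

# Sites whose two members are exactly {i, j}.
connecting_sites <- function(plan, i, j) {
  s <- plan$sites
  if (nrow(s) == 0L) return(integer(0))
  which((s$left == i & s$right == j) | (s$left == j & s$right == i))
}

# Signed subsystem list realizing one pair interaction dE(A, B).
# Returns NULL for ineligible combinations.
pair_entries <- function(plan, i, j) {
  A <- plan$fragments[[i]]; B <- plan$fragments[[j]]
  ifc <- connecting_sites(plan, i, j)
  lab <- sprintf("[%d+%d]", i, j)
  if (length(ifc) > 0L) {
    h <- heal_union(A, B, lab)
    expected <- sort(unlist(lapply(plan$caps[ifc], atom_coord_key)))
    if (!identical(sort(atom_coord_key(h$surplus)), expected))
      mfcc_error(paste0("internal assertion failure: heal surplus of pair ",
                        lab, " does not equal the cap molecule(s)"),
                 "mfcc_error_internal")
    return(list(case = "linked",
                entries = list(list(mol = h$dimer, coef = 1),
                               list(mol = h$surplus, coef = 1),
                               list(mol = A, coef = -1),
                               list(mol = B, coef = -1))))
  }
  r <- drop_shared_groups(A, B)
  AB <- mol_concat(list(r$A, r$B), label = paste0("pair", lab))
  list(case = if (r$modified) "clash" else "plain",
       entries = list(list(mol = AB, coef = 1),
                      list(mol = r$A, coef = -1),
                      list(mol = r$B, coef = -1)))
}

fc_entries <- function(plan, i, k) {
  if (i %in% cap_members(plan, k)) return(NULL)
  A <- plan$fragments[[i]]; B <- plan$caps[[k]]
  r <- drop_shared_groups(A, B)
  lab <- sprintf("[f%d+c%d]", i, k)
  AB <- mol_concat(list(r$A, r$B), label = paste0("pair", lab))
  list(case = if (r$modified) "clash" else "plain",
       entries = list(list(mol = AB, coef = 1),
                      list(mol = r$A, coef = -1),
                      list(mol = r$B, coef = -1)))
}

cc_entries <- function(plan, k, l) {
  A <- plan$caps[[k]]; B <- plan$caps[[l]]
  r <- drop_shared_groups(A, B)
  lab <- sprintf("[c%d+c%d]", k, l)
  AB <- mol_concat(list(r$A, r$B), label = paste0("pair", lab))
  list(case = if (r$modified) "clash" else "plain",
       entries = list(list(mol = AB, coef = 1),
                      list(mol = r$A, coef = -1),
                      list(mol = r$B, coef = -1)))
}

term_entries <- function(plan, family, i, j) {
  switch(family,
         ff = pair_entries(plan, i, j),
         fc = fc_entries(plan, i, j),
         cc = cc_entries(plan, i, j))
}

# Enumerate all MBE(2) pair terms: ff over fragment pairs, fc over eligible
# fragment x cap combinations, cc over distinct cap pairs.
mbe2_terms <- function(plan) {
  n <- plan$n_fragments
  m <- length(plan$caps)
  out <- list()
  if (n > 1L) {
    p <- utils::combn(n, 2L)
    out$ff <- data.frame(family = "ff", i = p[1, ], j = p[2, ])
  }
  if (m > 0L && n > 0L) {
    fc <- expand.grid(i = seq_len(n), j = seq_len(m))
    keep <- !mapply(function(i, k) i %in% cap_members(plan, k), fc$i, fc$j)
    fc <- fc[keep, , drop = FALSE]
    if (nrow(fc) > 0L)
      out$fc <- data.frame(family = "fc", i = fc$i, j = fc$j)
  }
  if (m > 1L) {
    p <- utils::combn(m, 2L)
    out$cc <- data.frame(family = "cc", i = p[1, ], j = p[2, ])
  }
  if (length(out) == 0L)
    return(data.frame(family = character(0), i = integer(0), j = integer(0)))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

family_sign <- c(ff = 1, fc = -1, cc = 1)

# Kahan-compensated sum for stable ledger evaluation.
ksum <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

eval_entries <- function(entries, backend) {
  ksum(vapply(entries, function(e) e$coef * energy_of(e$mol, backend),
              numeric(1)))
}

with_ligand <- function(m, L) {
  mol_concat(list(m, L), charge = m$charge + L$charge,
             label = paste0(m$label, "+lig"))
}

# Ligand-augmented pair term: sum_s coef_s [E(s+L) - E(s) - E(L)], i.e. the
# pair ledger with every subsystem replaced by its interaction with the
# ligand.  Expanded, each term has the form of a three-body interaction
# energy (for a disjoint pair: E_ABL - E_AB - E_AL - E_BL + E_A + E_B + E_L),
# and the full signed entry list, ligand included, is atom-multiset balanced.
entries_with_ligand <- function(entries, L) {
  out <- lapply(entries, function(e)
    list(list(mol = with_ligand(e$mol, L), coef = e$coef),
         list(mol = e$mol, coef = -e$coef)))
  out <- unlist(out, recursive = FALSE)
  csum <- sum(vapply(entries, `[[`, numeric(1), "coef"))
  if (csum != 0)
    out[[length(out) + 1L]] <- list(mol = L, coef = -csum)
  out
}

eval_entries_lig <- function(entries, L, backend) {
  ksum(vapply(entries_with_ligand(entries, L), function(e)
    e$coef * energy_of(e$mol, backend), numeric(1)))
}

as_ligand_molecule <- function(ligand) {
  if (inherits(ligand, "mfcc_ligand")) return(ligand$molecule)
  if (inherits(ligand, "mfcc_molecule")) return(ligand)
  mfcc_error("ligand must be an mfcc_ligand or mfcc_molecule",
             "mfcc_error_bad_ligand")
}

# ---------------------------------------------------------------------------
# Total energies
# ---------------------------------------------------------------------------

#' MFCC ledger of a fragmentation plan
#'
#' @param plan an `mfcc_plan`.
#' @return data.frame of (subsystem label, key, family, coefficient): +1 for
#'   every capped fragment, -1 for every cap molecule (disulfide caps
#'   included).
#' @export
build_mfcc_ledger <- function(plan) {
  rows <- c(lapply(seq_along(plan$fragments), function(i) {
    m <- plan$fragments[[i]]
    data.frame(family = "frag", i = i, j = NA_integer_, coef = 1,
               label = m$label, key = subsystem_key(m), stringsAsFactors = FALSE)
  }), lapply(seq_along(plan$caps), function(k) {
    m <- plan$caps[[k]]
    data.frame(family = "cap", i = k, j = NA_integer_, coef = -1,
               label = m$label, key = subsystem_key(m), stringsAsFactors = FALSE)
  }))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' MFCC total energy
#'
#' Sum of capped-fragment energies minus the sum of cap-molecule energies.
#'
#' @param plan an `mfcc_plan`.
#' @param backend an `mfcc_backend`.
#' @return total energy in kJ/mol.
#' @export
mfcc_total_energy <- function(plan, backend) {
  ksum(c(vapply(plan$fragments, energy_of, numeric(1), backend = backend),
         -vapply(plan$caps, energy_of, numeric(1), backend = backend)))
}

#' Pair interaction energy
#'
#' `E(ab) - E(a) - E(b)` for two disjoint molecules; symmetric under swap.
#'
#' @param a,b molecules.
#' @param backend an `mfcc_backend`.
#' @return interaction energy in kJ/mol.
#' @export
pair_interaction <- function(a, b, backend) {
  ab <- mol_concat(list(a, b), label = paste0(a$label, "+", b$label))
  energy_of(ab, backend) - energy_of(a, backend) - energy_of(b, backend)
}

#' MFCC-MBE(2) total energy
#'
#' The MFCC total energy plus all fragment-fragment pair interactions, minus
#' fragment-cap interactions, plus cap-cap interactions.  Covalently
#' connected fragment pairs are evaluated through the healed dimer plus cap
#' correction; pairs sharing constructed cap atoms drop the clashing groups.
#'
#' @inheritParams mfcc_total_energy
#' @return total energy in kJ/mol.
#' @export
mfcc_mbe2_total_energy <- function(plan, backend) {
  base <- mfcc_total_energy(plan, backend)
  terms <- mbe2_terms(plan)
  if (nrow(terms) == 0L) return(base)
  contrib <- vapply(seq_len(nrow(terms)), function(r) {
    te <- term_entries(plan, terms$family[r], terms$i[r], terms$j[r])
    family_sign[[terms$family[r]]] * eval_entries(te$entries, backend)
  }, numeric(1))
  base + ksum(contrib)
}

# ---------------------------------------------------------------------------
# Protein-ligand interaction energies
# ---------------------------------------------------------------------------

new_interaction <- function(value, method, ledger, lambda, n_inc, n_exc,
                            params_key) {
  structure(list(value = value, method = method, ledger = ledger,
                 lambda = lambda, n_trimers_included = n_inc,
                 n_trimers_excluded = n_exc, params_key = params_key),
            class = "mfcc_interaction")
}

#' @export
print.mfcc_interaction <- function(x, ...) {
  cat(sprintf("<%s interaction energy: %.6f kJ/mol (lambda = %s, %d/%d trimers)>\n",
              x$method, x$value, format(x$lambda),
              x$n_trimers_included,
              x$n_trimers_included + x$n_trimers_excluded))
  invisible(x)
}

#' Supermolecular reference interaction energy
#'
#' `E(complex) - E(protein) - E(ligand)` from full calculations; the
#' reference against which fragmentation errors are measured.
#'
#' @param protein an `mfcc_protein`, `mfcc_plan`, or `mfcc_molecule`.
#' @param ligand an `mfcc_ligand` or `mfcc_molecule`.
#' @param backend an `mfcc_backend`.
#' @return an `mfcc_interaction`.
#' @export
supermolecular_interaction <- function(protein, ligand, backend) {
  P <- if (inherits(protein, "mfcc_plan")) plan_parent(protein)
       else if (inherits(protein, "mfcc_protein")) protein_molecule(protein)
       else protein
  L <- as_ligand_molecule(ligand)
  value <- energy_of(with_ligand(P, L), backend) - energy_of(P, backend) -
    energy_of(L, backend)
  new_interaction(value, "supermolecular", NULL, Inf, 0L, 0L,
                  backend$params_key)
}

plan_parent <- function(plan) {
  if (!is.null(plan$parent)) return(plan$parent)
  protein_molecule(plan$protein)
}

#' MFCC protein-ligand interaction energy
#'
#' Sum over all capped-fragment-ligand interaction energies minus the sum
#' over all cap-molecule-ligand interaction energies.  No distance cutoff is
#' applied: every fragment and cap term is always included.
#'
#' @param plan an `mfcc_plan`.
#' @param ligand an `mfcc_ligand` or `mfcc_molecule`.
#' @param backend an `mfcc_backend`.
#' @return an `mfcc_interaction`.
#' @export
mfcc_pl_interaction <- function(plan, ligand, backend) {
  L <- as_ligand_molecule(ligand)
  eL <- energy_of(L, backend)
  dl <- function(m) energy_of(with_ligand(m, L), backend) -
    energy_of(m, backend) - eL
  vals <- c(vapply(plan$fragments, dl, numeric(1)),
            -vapply(plan$caps, dl, numeric(1)))
  ledger <- build_mfcc_ledger(plan)
  ledger$family <- paste0(ledger$family, "-lig")
  new_interaction(ksum(vals), "mfcc", ledger, Inf, 0L, 0L, backend$params_key)
}

#' Screen three-body terms with a distance cutoff
#'
#' A trimer (body A, body B, ligand) survives the screen if at least two of
#' the three intermolecular minimum atom-atom distances
#' `d(A,L), d(B,L), d(A,B)` are strictly below `lambda`.  The same condition
#' is applied to fragment-fragment, fragment-cap and cap-cap trimers, with
#' distances measured to the unmodified bodies (a cap's own atoms, not its
#' parent fragments); bodies sharing atoms have distance 0.
#'
#' @param plan an `mfcc_plan`.
#' @param ligand an `mfcc_ligand` or `mfcc_molecule`.
#' @param lambda cutoff in Angstrom (`Inf` keeps every trimer).
#' @return data.frame with one row per trimer: family, body indices, the
#'   three distances and the inclusion flag.
#' @export
screen_trimers <- function(plan, ligand, lambda = 4) {
  if (!(is.numeric(lambda) && (lambda > 0 || is.infinite(lambda))))
    mfcc_error("lambda must be a positive length or Inf", "mfcc_error_bad_lambda")
  L <- as_ligand_molecule(ligand)
  terms <- mbe2_terms(plan)
  if (nrow(terms) == 0L) {
    terms$d_al <- terms$d_bl <- terms$d_ab <- numeric(0)
    terms$included <- logical(0)
    return(terms)
  }
  dfragL <- vapply(plan$fragments, min_distance, numeric(1), b = L)
  dcapL <- vapply(plan$caps, min_distance, numeric(1), b = L)
  body <- function(family, side, idx) {
    if (family == "ff" || (family == "fc" && side == 1L))
      plan$fragments[[idx]] else plan$caps[[idx]]
  }
  terms$d_al <- ifelse(terms$family == "cc", dcapL[terms$i], dfragL[terms$i])
  terms$d_bl <- ifelse(terms$family == "ff", dfragL[terms$j], dcapL[terms$j])
  terms$d_ab <- vapply(seq_len(nrow(terms)), function(r)
    min_distance(body(terms$family[r], 1L, terms$i[r]),
                 body(terms$family[r], 2L, terms$j[r])), numeric(1))
  terms$included <- (terms$d_al < lambda) + (terms$d_bl < lambda) +
    (terms$d_ab < lambda) >= 2
  terms
}

#' MFCC-MBE(2) protein-ligand interaction energy
#'
#' The MFCC interaction energy plus screened three-body corrections: for
#' every surviving (body, body, ligand) trimer the corresponding pair ledger
#' is augmented with the ligand term by term, giving a three-body interaction
#' contribution that is added for fragment-fragment and cap-cap trimers and
#' subtracted for fragment-cap trimers.
#'
#' @inheritParams mfcc_pl_interaction
#' @param lambda distance cutoff in Angstrom applied to the three-body terms
#'   (default 4; `Inf` includes every trimer).  The two-body MFCC part is
#'   never screened.
#' @return an `mfcc_interaction` carrying the flattened ledger and the
#'   trimer inclusion counts.
#' @export
mfcc_mbe2_pl_interaction <- function(plan, ligand, backend, lambda = 4) {
  L <- as_ligand_molecule(ligand)
  base <- mfcc_pl_interaction(plan, ligand, backend)
  tri <- screen_trimers(plan, ligand, lambda)
  contrib <- 0
  rows <- list(base$ledger)
  if (any(tri$included)) {
    inc <- tri[tri$included, , drop = FALSE]
    contrib <- ksum(vapply(seq_len(nrow(inc)), function(r) {
      te <- term_entries(plan, inc$family[r], inc$i[r], inc$j[r])
      family_sign[[inc$family[r]]] * eval_entries_lig(te$entries, L, backend)
    }, numeric(1)))
    rows <- c(rows, lapply(seq_len(nrow(inc)), function(r) {
      te <- term_entries(plan, inc$family[r], inc$i[r], inc$j[r])
      sgn <- family_sign[[inc$family[r]]]
      do.call(rbind, lapply(entries_with_ligand(te$entries, L), function(e)
        data.frame(family = paste0(inc$family[r], "-lig"),
                   i = inc$i[r], j = inc$j[r], coef = sgn * e$coef,
                   label = e$mol$label, key = subsystem_key(e$mol),
                   stringsAsFactors = FALSE)))
    }))
  }
  ledger <- do.call(rbind, rows)
  rownames(ledger) <- NULL
  new_interaction(base$value + contrib, "mfcc-mbe2", ledger, lambda,
                  sum(tri$included), sum(!tri$included), backend$params_key)
}

#' Signed fragmentation error of an interaction-energy estimate
#'
#' `estimate - reference`, both in kJ/mol.  Estimates computed with
#' different backend parameter sets must never be compared; this is enforced
#' when both arguments carry their parameter fingerprint.
#'
#' @param estimate,reference `mfcc_interaction` objects or plain numbers.
#' @return signed error in kJ/mol.
#' @export
interaction_error <- function(estimate, reference) {
  pk <- function(x) if (inherits(x, "mfcc_interaction")) x$params_key else NULL
  v <- function(x) if (inherits(x, "mfcc_interaction")) x$value else as.numeric(x)
  k1 <- pk(estimate); k2 <- pk(reference)
  if (!is.null(k1) && !is.null(k2) && !identical(k1, k2))
    mfcc_error("estimate and reference were computed with different backend parameter sets",
               "mfcc_error_mixed_params")
  v(estimate) - v(reference)
}

# ---------------------------------------------------------------------------
# Subsystem enumeration for external-engine manifests
# ---------------------------------------------------------------------------

#' Enumerate the unique subsystems a calculation needs
#'
#' For the MFCC interaction energy: every capped fragment, cap molecule, the
#' ligand, and each fragment/cap plus ligand supermolecule.  For MFCC-MBE(2)
#' additionally the pair-ledger subsystems of every trimer surviving the
#' screen, with and without the ligand.  Duplicate subsystems (by identity
#' key) are listed once.
#'
#' @param plan an `mfcc_plan`.
#' @param ligand optional ligand; omit for total-energy manifests.
#' @param method `"mfcc"` or `"mfcc-mbe2"`.
#' @param lambda trimer screen cutoff for `"mfcc-mbe2"`.
#' @return list of `mfcc_molecule`s, each carrying a `role` attribute.
#' @export
plan_subsystems <- function(plan, ligand = NULL,
                            method = c("mfcc", "mfcc-mbe2"), lambda = 4) {
  method <- match.arg(method)
  out <- list()
  add <- function(m, role) {
    attr(m, "role") <- role
    out[[length(out) + 1L]] <<- m
  }
  for (m in plan$fragments) add(m, "fragment")
  for (m in plan$caps) add(m, "cap")
  if (method == "mfcc-mbe2") {
    tri <- if (is.null(ligand)) mbe2_terms(plan) else {
      s <- screen_trimers(plan, ligand, lambda)
      s[s$included, , drop = FALSE]
    }
    if (nrow(tri) > 0L) for (r in seq_len(nrow(tri))) {
      te <- term_entries(plan, tri$family[r], tri$i[r], tri$j[r])
      for (e in te$entries) add(e$mol, paste0(tri$family[r], "-body"))
    }
  }
  if (!is.null(ligand)) {
    L <- as_ligand_molecule(ligand)
    n0 <- length(out)
    for (i in seq_len(n0)) {
      m <- out[[i]]
      add(with_ligand(m, L), paste0(attr(m, "role"), "-lig"))
    }
    add(L, "ligand")
  }
  keys <- vapply(out, subsystem_key, "")
  out[!duplicated(keys)]
}
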