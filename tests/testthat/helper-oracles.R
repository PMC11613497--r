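# Independent brute-force oracles, deliberately written as plain double /
# triple loops so they share no code path with the package's vectorized
# potential evaluation or its ledger assembly.

oracle_pair_u <- function(el1, x1, el2, x2, par) {
  r <- sqrt(sum((x1 - x2)^2))
  q <- par$q; eps <- par$eps; sig <- par$sig
  s <- (sig[[el1]] + sig[[el2]]) / 2
  e <- sqrt(eps[[el1]] * eps[[el2]])
  par$coulomb * q[[el1]] * q[[el2]] / r + 4 * e * ((s / r)^12 - (s / r)^6)
}

oracle_triple_w <- function(x1, x2, x3, nu) {
  r12 <- sqrt(sum((x1 - x2)^2))
  r13 <- sqrt(sum((x1 - x3)^2))
  r23 <- sqrt(sum((x2 - x3)^2))
  c1 <- (r12^2 + r13^2 - r23^2) / (2 * r12 * r13)
  c2 <- (r12^2 + r23^2 - r13^2) / (2 * r12 * r23)
  c3 <- (r13^2 + r23^2 - r12^2) / (2 * r13 * r23)
  nu * (1 + 3 * c1 * c2 * c3) / (r12 * r13 * r23)^3
}

# Total energy of one molecule by exhaustive loops.
oracle_total_energy <- function(m, par, nu = 0) {
  n <- natoms(m)
  e <- 0
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
    e <- e + oracle_pair_u(m$element[i], m$xyz[i, ], m$element[j], m$xyz[j, ], par)
  if (nu != 0 && n >= 3)
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
      e <- e + oracle_triple_w(m$xyz[i, ], m$xyz[j, ], m$xyz[k, ], nu)
  e
}

# Cross-pair interaction sum between two disjoint molecules.
oracle_cross_pairs <- function(a, b, par) {
  e <- 0
  for (i in seq_len(natoms(a))) for (j in seq_len(natoms(b)))
    e <- e + oracle_pair_u(a$element[i], a$xyz[i, ], b$element[j], b$xyz[j, ], par)
  e
}

# Sum of triple terms with one atom in each of three disjoint molecules.
oracle_mixed_triples <- function(a, b, c, nu) {
  e <- 0
  for (i in seq_len(natoms(a))) for (j in seq_len(natoms(b)))
    for (k in seq_len(natoms(c)))
      e <- e + oracle_triple_w(a$xyz[i, ], b$xyz[j, ], c$xyz[k, ], nu)
  e
}

oracle_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(natoms(a))) for (j in seq_len(natoms(b)))
    best <- min(best, sqrt(sum((a$xyz[i, ] - b$xyz[j, ])^2)))
  best
}

# Per-parent-atom count of (fragments containing it) - (caps containing it),
# matching subsystem atoms to parent atoms by rounded coordinates.
overlap_counts <- function(plan, parent) {
  keys <- mfccmbe:::atom_coord_key(parent)
  nf <- rowSums(vapply(plan$fragments, function(f)
    keys %in% mfccmbe:::atom_coord_key(f), logical(length(keys))))
  nc <- if (length(plan$caps) > 0L)
    rowSums(vapply(plan$caps, function(f)
      keys %in% mfccmbe:::atom_coord_key(f), logical(length(keys))))
  else rep(0, length(keys))
  list(nf = nf, nc = nc, heavy = parent$element != "H")
}

random_molecule <- function(n, seed, elements = c("C", "N", "O", "H", "Ar")) {
  withr::with_seed(seed, {
    el <- sample(elements, n, replace = TRUE)
    molecule(el, matrix(stats::rnorm(3 * n, sd = 3), ncol = 3),
             label = paste0("rand", seed))
  })
}

# Shift a molecule rigidly.
shifted <- function(m, dx) {
  m$xyz <- sweep(m$xyz, 2, dx, "+")
  m
}
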