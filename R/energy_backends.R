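# ---------------------------------------------------------------------------
# Scalar-energy backends.  The fragmentation algebra is backend-agnostic: any
# function Molecule -> energy (kJ/mol) can stand behind it.  Two analytic toy
# potentials make the algebra exactly verifiable:
#   * pairwise: Coulomb (per-element point charges) + Lennard-Jones.  Strictly
#     pairwise additive, so every two-body expansion is exact and every
#     three-body correction term vanishes identically.
#   * threebody: pairwise + an Axilrod-Teller-Muto triple-dipole term, so
#     three-body corrections are nonzero and the trimer algebra is testable.
# A table backend serves energies imported from an external engine manifest.
# ---------------------------------------------------------------------------

COULOMB_KJ_A <- 1389.3545764438  # e^2/(4 pi eps0), kJ/mol * Angstrom
HARTREE_KJMOL <- 2625.4996394799 # CODATA hartree -> kJ/mol
EV_KJMOL <- 96.4853321233
KCAL_KJMOL <- 4.184

#' Toy pairwise potential parameters
#'
#' Per-element point charges (e), Lennard-Jones well depths (kJ/mol) and
#' diameters (Angstrom), combined with Lorentz-Berthelot rules.  The set is a
#' fixed, seed-free definition so that all tests are exactly reproducible; it
#' is not fitted to anything.
#'
#' @param charges,epsilon,sigma named per-element vectors overriding the
#'   defaults.
#' @param coulomb Coulomb constant in kJ/mol * Angstrom / e^2.
#' @return list of class `mfcc_pair_params`.
#' @export
pairwise_params <- function(charges = NULL, epsilon = NULL, sigma = NULL,
                            coulomb = COULOMB_KJ_A) {
  q <- c(H = 0.157, C = -0.08, N = -0.40, O = -0.35, S = -0.15, P = 0.40,
         Cl = -0.60, Na = 0.60, Ar = 0.00)
  eps <- c(H = 0.065, C = 0.35, N = 0.70, O = 0.65, S = 1.00, P = 0.80,
           Cl = 1.20, Na = 0.10, Ar = 0.996)
  sig <- c(H = 2.00, C = 3.40, N = 3.25, O = 3.00, S = 3.60, P = 3.70,
           Cl = 3.50, Na = 2.30, Ar = 3.40)
  if (!is.null(charges)) q[names(charges)] <- charges
  if (!is.null(epsilon)) eps[names(epsilon)] <- epsilon
  if (!is.null(sigma)) sig[names(sigma)] <- sigma
  structure(list(q = q, eps = eps, sig = sig, coulomb = coulomb),
            class = "mfcc_pair_params")
}

#' Toy three-body potential parameters
#'
#' Pairwise parameters plus a single Axilrod-Teller-Muto triple strength
#' `nu` (kJ/mol * Angstrom^9) applied to every atom triple:
#' `w = nu * (1 + 3 cos a cos b cos c) / (r12 r13 r23)^3`, symmetric under
#' any permutation of the three atoms.
#'
#' @param pair an [pairwise_params()] object.
#' @param nu triple-interaction strength.
#' @return list of class `mfcc_threebody_params`.
#' @export
threebody_params <- function(pair = pairwise_params(), nu = 5000) {
  structure(c(unclass(pair), list(nu = nu)), class = "mfcc_threebody_params")
}

param_lookup <- function(tab, el, what) {
  miss <- setdiff(unique(el), names(tab))
  if (length(miss) > 0L)
    mfcc_error(paste0("no ", what, " parameter for element(s): ",
                      paste(miss, collapse = ", ")),
               "mfcc_error_missing_parameter")
  unname(tab[el])
}

pair_sum <- function(el, xyz, par) {
  n <- length(el)
  if (n < 2L) return(0)
  D <- as.matrix(stats::dist(xyz))
  iu <- which(upper.tri(D))
  r <- D[iu]
  q <- param_lookup(par$q, el, "charge")
  eps <- param_lookup(par$eps, el, "epsilon")
  sig <- param_lookup(par$sig, el, "sigma")
  qq <- outer(q, q)[iu]
  e2 <- sqrt(outer(eps, eps))[iu]
  s2 <- (outer(sig, sig, "+") / 2)[iu]
  sr6 <- (s2 / r)^6
  sum(par$coulomb * qq / r + 4 * e2 * (sr6^2 - sr6))
}

triple_sum <- function(el, xyz, par) {
  n <- length(el)
  if (n < 3L || par$nu == 0) return(0)
  D <- as.matrix(stats::dist(xyz))
  tri <- utils::combn(n, 3L)
  i <- tri[1, ]; j <- tri[2, ]; k <- tri[3, ]
  rij <- D[cbind(i, j)]; rik <- D[cbind(i, k)]; rjk <- D[cbind(j, k)]
  ci <- (rij^2 + rik^2 - rjk^2) / (2 * rij * rik)
  cj <- (rij^2 + rjk^2 - rik^2) / (2 * rij * rjk)
  ck <- (rik^2 + rjk^2 - rij^2) / (2 * rik * rjk)
  sum(par$nu * (1 + 3 * ci * cj * ck) / (rij * rik * rjk)^3)
}

#' Analytic backends and the external-table backend
#'
#' `pairwise_backend()` and `threebody_backend()` evaluate the toy potentials
#' directly; `table_backend()` serves pre-computed energies (e.g. imported
#' from an external quantum-chemistry engine via [import_energies()]) keyed
#' by subsystem identity.  All backends memoise results by identity key.
#'
#' @param params parameter object for the potential.
#' @return an object of class `mfcc_backend`.
#' @export
pairwise_backend <- function(params = pairwise_params()) {
  new_backend("pairwise", params)
}

#' @rdname pairwise_backend
#' @export
threebody_backend <- function(params = threebody_params()) {
  new_backend("threebody", params)
}

#' @rdname pairwise_backend
#' @param energies named numeric vector (kJ/mol) keyed by subsystem identity
#'   key, as returned by [import_energies()].
#' @export
table_backend <- function(energies, params = NULL) {
  b <- new_backend("table", params)
  b$energies <- energies
  b
}

new_backend <- function(type, params) {
  structure(list(type = type, params = params,
                 params_key = rlang::hash(list(type, params)),
                 cache = new.env(parent = emptyenv())),
            class = "mfcc_backend")
}

#' @export
print.mfcc_backend <- function(x, ...) {
  cat(sprintf("<%s backend, %d cached energies>\n", x$type,
              length(ls(x$cache))))
  invisible(x)
}

#' Identity key of a subsystem
#'
#' Hash of the element sequence, coordinates rounded to 1e-6 Angstrom, and
#' the formal charge; used for energy caching, manifest indexing, and
#' duplicate detection.
#'
#' @param m an `mfcc_molecule`.
#' @return a character hash.
#' @export
subsystem_key <- function(m) {
  rlang::hash(list(m$element, round(m$xyz, 6) + 0, m$charge))
}

#' Compute the total energy of a subsystem
#'
#' Deterministic for fixed input and parameters; results are cached by
#' identity key so repeated subsystems are computed once.  Non-convergence
#' (for the table backend: a missing or non-finite entry) is surfaced as an
#' error or a `converged = FALSE` flag, never as a silent zero.
#'
#' @param m an `mfcc_molecule`.
#' @param backend an `mfcc_backend`.
#' @param use_cache memoise by identity key.
#' @return list of class `mfcc_backend_result` with `energy` (kJ/mol),
#'   `converged`, and `meta`.
#' @export
compute_energy <- function(m, backend, use_cache = TRUE) {
  key <- paste0(subsystem_key(m), "|", backend$params_key)
  if (use_cache && !is.null(backend$cache[[key]]))
    return(backend$cache[[key]])
  e <- switch(backend$type,
    pairwise = pair_sum(m$element, m$xyz, backend$params),
    threebody = pair_sum(m$element, m$xyz, backend$params) +
      triple_sum(m$element, m$xyz, backend$params),
    table = {
      k <- subsystem_key(m)
      if (!k %in% names(backend$energies))
        mfcc_error(paste0("no energy available for subsystem '", m$label,
                          "' (key ", k, ")"), "mfcc_error_missing_energy")
      backend$energies[[k]]
    },
    mfcc_error(paste0("unknown backend type ", backend$type),
               "mfcc_error_bad_backend"))
  res <- structure(list(energy = e, converged = is.finite(e),
                        meta = list(key = key, backend = backend$type)),
                   class = "mfcc_backend_result")
  if (!res$converged)
    mfcc_error(paste0("backend did not produce a finite energy for '",
                      m$label, "'"), "mfcc_error_not_converged")
  if (use_cache) backend$cache[[key]] <- res
  res
}

# Convenience: scalar energy.
energy_of <- function(m, backend) compute_energy(m, backend)$energy

# ---------------------------------------------------------------------------
# External-engine manifest: one XYZ file per subsystem plus a tab-separated
# index (key, role, charge, filename); results come back as a tab-separated
# file (key, energy) with a unit header line.
# ---------------------------------------------------------------------------

#' Export a subsystem manifest for an external engine
#'
#' @param subsystems list of `mfcc_molecule`; each may carry a `role`
#'   attribute (fragment, cap, frag-lig, ...).
#' @param dir output directory (created if needed).
#' @return path of the written index file, invisibly.
#' @export
export_manifest <- function(subsystems, dir) {
  if (length(subsystems) == 0L)
    mfcc_error("cannot export an empty subsystem list", "mfcc_error_empty_manifest")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- vapply(subsystems, subsystem_key, "")
  if (anyDuplicated(keys))
    mfcc_error(paste0("identity-key collision in manifest: ",
                      paste(keys[duplicated(keys)], collapse = ", ")),
               "mfcc_error_key_collision")
  roles <- vapply(subsystems, function(m) {
    r <- attr(m, "role"); if (is.null(r)) "subsystem" else r
  }, "")
  files <- sprintf("%04d_%s.xyz", seq_along(subsystems), substr(keys, 1, 10))
  for (i in seq_along(subsystems))
    write_xyz(subsystems[[i]], file.path(dir, files[i]))
  idx <- data.frame(key = keys, role = roles,
                    charge = vapply(subsystems, `[[`, integer(1), "charge"),
                    file = files, stringsAsFactors = FALSE)
  index_path <- file.path(dir, "index.tsv")
  utils::write.table(idx, index_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(index_path)
}

#' Import energies computed by an external engine
#'
#' The results file is tab-separated `key<TAB>energy` with a mandatory unit
#' header line `# unit: <hartree|kJ/mol|kcal/mol|eV>`; all values are
#' converted to kJ/mol.  Every manifest entry must be covered.
#'
#' @param index_path manifest index written by [export_manifest()].
#' @param results_path results file.
#' @return named numeric vector of energies (kJ/mol) keyed by identity key,
#'   suitable for [table_backend()].
#' @export
import_energies <- function(index_path, results_path) {
  idx <- utils::read.table(index_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  lines <- readLines(results_path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  unit_line <- grep("unit:", header, value = TRUE)
  if (length(unit_line) == 0L)
    mfcc_error("results file lacks a '# unit:' header line",
               "mfcc_error_missing_unit")
  unit <- trimws(sub(".*unit:", "", unit_line[1]))
  factor <- switch(unit,
                   "hartree" = HARTREE_KJMOL,
                   "kJ/mol" = 1,
                   "kcal/mol" = KCAL_KJMOL,
                   "eV" = EV_KJMOL,
                   mfcc_error(paste0("unknown energy unit '", unit, "'"),
                              "mfcc_error_bad_unit"))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(body, "\t")
  keys <- vapply(parts, `[[`, "", 1)
  vals <- as.numeric(vapply(parts, `[[`, "", 2)) * factor
  names(vals) <- keys
  absent <- setdiff(idx$key, keys)
  if (length(absent) > 0L)
    mfcc_error(paste0("results are missing energies for key(s): ",
                      paste(absent, collapse = ", ")),
               "mfcc_error_missing_energy")
  vals
}
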