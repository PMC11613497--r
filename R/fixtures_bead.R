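# ---------------------------------------------------------------------------
# Idealized overlap mode: bead-chain molecules partitioned into windows
# whose pairwise intersections define the caps as literal atom subsets (no
# constructed atoms).  In this mode the inclusion-exclusion identities of
# the energy assembly hold with zero geometric error, which is what the
# exactness test suite relies on.
# ---------------------------------------------------------------------------

#' Generate a bead-chain molecule with an overlap partition
#'
#' Beads (argon atoms by default) are placed along a gentle helix with fixed
#' spacing.  The chain is partitioned into fragment windows; consecutive
#' windows overlap by `overlap` beads and each overlap region becomes a cap
#' ("idealized overlap mode").  With `overlap = 0` the partition is a plain
#' non-overlapping fragmentation with no caps, reducing the assembly to the
#' ordinary two-body expansion.
#'
#' @param n_beads number of beads.
#' @param window window length in beads.
#' @param overlap overlap between consecutive windows in beads (>= 0).
#' @param spacing bead spacing in Angstrom.
#' @param element element symbol of the beads.
#' @param seed integer seed for jitter; `NULL` disables jitter.
#' @param jitter uniform jitter amplitude in Angstrom.
#' @param windows optional explicit list of integer index vectors overriding
#'   `window`/`overlap`; must cover all beads, with consecutive windows
#'   overlapping in single shared runs.
#' @return an `mfcc_plan` (mode `"bead"`) whose `parent` field holds the
#'   full chain molecule.
#' @export
make_bead_chain <- function(n_beads, window = 4L, overlap = 1L, spacing = 1.8,
                            element = "Ar", seed = NULL, jitter = 0.1,
                            windows = NULL) {
  i <- seq_len(n_beads)
  xyz <- cbind(i * spacing, 0.6 * sin(0.9 * i), 0.6 * cos(0.9 * i))
  if (!is.null(seed))
    xyz <- withr::with_seed(as.integer(seed),
      xyz + matrix(stats::runif(3 * n_beads, -jitter, jitter), ncol = 3))
  chain <- molecule(rep(element, n_beads), xyz,
                    name = rep(element, n_beads), label = "bead-chain")
  if (is.null(windows)) {
    if (overlap < 0L || overlap >= window)
      mfcc_error("overlap must satisfy 0 <= overlap < window",
                 "mfcc_error_bad_partition")
    windows <- list()
    start <- 1L
    repeat {
      end <- min(start + window - 1L, n_beads)
      windows[[length(windows) + 1L]] <- start:end
      if (end == n_beads) break
      start <- end - overlap + 1L
    }
  }
  validate_windows(windows, n_beads)
  nw <- length(windows)
  fragments <- lapply(seq_len(nw), function(w) {
    m <- mol_subset(chain, windows[[w]], label = sprintf("frag%03d", w))
    attr(m, "groups") <- list()
    m
  })
  caps <- list()
  sites <- data.frame(type = character(0), left = integer(0),
                      right = integer(0))
  for (w in seq_len(nw - 1L)) {
    ov <- intersect(windows[[w]], windows[[w + 1L]])
    if (length(ov) == 0L) next
    caps[[length(caps) + 1L]] <- mol_subset(chain, ov,
                                            label = sprintf("cap[%d,%d]", w, w + 1L))
    attr(caps[[length(caps)]], "groups") <- list()
    sites <- rbind(sites, data.frame(type = "overlap", left = w, right = w + 1L))
  }
  if (nrow(sites) > 0L) sites$site_id <- seq_len(nrow(sites))
  else sites <- data.frame(type = character(0), left = integer(0),
                           right = integer(0), site_id = integer(0))
  plan <- structure(list(n_fragments = nw, fragments = fragments, caps = caps,
                         sites = sites, mode = "bead", parent = chain,
                         windows = windows),
                    class = "mfcc_plan")
  plan$provenance <- plan_provenance(plan)
  plan
}

validate_windows <- function(windows, n_beads) {
  covered <- sort(unique(unlist(windows)))
  if (!identical(covered, seq_len(n_beads)))
    mfcc_error("fragment windows must cover every bead exactly",
               "mfcc_error_bad_partition")
  for (w in seq_along(windows)) {
    if (any(diff(windows[[w]]) != 1L))
      mfcc_error("each window must be a contiguous bead run",
                 "mfcc_error_bad_partition")
    for (v in seq_along(windows)) {
      if (v <= w) next
      ov <- intersect(windows[[w]], windows[[v]])
      if (v > w + 1L && length(ov) > 0L)
        mfcc_error("only consecutive windows may overlap",
                   "mfcc_error_bad_partition")
    }
  }
  # overlap regions must not touch each other (windows longer than the sum
  # of their two overlaps) so caps are disjoint
  for (w in seq_along(windows)) {
    if (w == 1L || w == length(windows)) next
    left <- intersect(windows[[w - 1L]], windows[[w]])
    right <- intersect(windows[[w]], windows[[w + 1L]])
    if (length(intersect(left, right)) > 0L)
      mfcc_error("overlap regions of consecutive cut sites must be disjoint",
                 "mfcc_error_bad_partition")
  }
  invisible(TRUE)
}

#' Generate a bead-chain complex with a point ligand
#'
#' Places a single-atom ligand at a requested minimum distance from a chosen
#' bead of a [make_bead_chain()] system, perpendicular to the chain axis.
#'
#' @inheritParams make_bead_chain
#' @param ligand_element element of the point ligand.
#' @param anchor_bead bead index the ligand sits next to (default: middle).
#' @param distance requested minimum bead-ligand distance in Angstrom.
#' @return list with elements `plan` (an `mfcc_plan`, mode `"bead"`) and
#'   `ligand` (an `mfcc_ligand`).
#' @export
make_bead_complex <- function(n_beads, window = 4L, overlap = 1L,
                              spacing = 1.8, element = "Ar",
                              ligand_element = "Ar", anchor_bead = NULL,
                              distance = 2.5, seed = NULL, jitter = 0.1) {
  plan <- make_bead_chain(n_beads, window = window, overlap = overlap,
                          spacing = spacing, element = element, seed = seed,
                          jitter = jitter)
  chain <- plan$parent
  if (is.null(anchor_bead)) anchor_bead <- max(1L, n_beads %/% 2L)
  anchor <- chain$xyz[anchor_bead, ]
  u <- c(0, unitv(anchor[2:3] + c(0.3, 0.4)))
  lig_at <- function(t) molecule(ligand_element, matrix(anchor + t * u, 1),
                                 serial = natoms(chain) + 1L,
                                 label = "bead-ligand")
  f <- function(t) min_distance(chain, lig_at(t)) - distance
  t0 <- stats::uniroot(f, c(0.05, distance + 30))$root
  list(plan = plan, ligand = ligand_structure(lig_at(t0), 0L))
}
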