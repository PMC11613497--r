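# ---------------------------------------------------------------------------
# MFCC fragmentation: cut peptide bonds (and declared/detected disulfides),
# cap the severed valences with ACE / NME groups (methyl sulfide for S-S),
# and join the capping groups of neighbouring fragments into cap molecules.
#
# All retained cap atoms reuse parent-atom coordinates; link hydrogens are
# placed on the original bond vector from the retained atom toward the
# removed atom at a fixed per-element length.  Cap-group atoms are built once
# per cut site and shared between fragments and cap molecules, so the
# coordinate-coincidence invariants hold bitwise.
# ---------------------------------------------------------------------------

#' Capping specification
#'
#' @param link_lengths named lengths (Angstrom) of constructed link hydrogens,
#'   keyed by the element of the atom that retains the hydrogen.
#' @param proline_policy what to do when an N-side cut hits a proline, whose
#'   backbone nitrogen is tertiary: `"error"` (default) aborts; `"strip"`
#'   replaces the ring CD carbon by a link hydrogen and flags the fragment.
#' @return a list of class `mfcc_cap_spec`.
#' @export
cap_spec <- function(link_lengths = c(C = 1.09, N = 1.01, S = 1.34),
                     proline_policy = c("error", "strip")) {
  structure(list(link_lengths = link_lengths,
                 proline_policy = match.arg(proline_policy)),
            class = "mfcc_cap_spec")
}

#' Default residue protonation table
#'
#' Fragment formal charges are assigned from this table (configuration input,
#' never inferred from geometry): aspartate/glutamate carboxylates are
#' deprotonated, lysine/arginine are protonated, histidine is neutral.
#' Termini are neutral by default.
#'
#' @return named integer vector of side-chain charges.
#' @export
default_protonation <- function() {
  c(ASP = -1L, GLU = -1L, LYS = 1L, ARG = 1L, HIS = 0L)
}

# -- bonded-neighbour detection within one residue ---------------------------

res_adjacency <- function(a) {
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  isH <- a$element == "H"
  isS <- a$element == "S"
  thr <- matrix(1.75, n, n)
  thr[isS, ] <- 1.95; thr[, isS] <- 1.95
  thr[isH, ] <- 1.25; thr[, isH] <- 1.25
  thr[isH, isS] <- 1.45; thr[isS, isH] <- 1.45
  adj <- d < thr
  diag(adj) <- FALSE
  adj
}

constructed_serial <- local({
  function(site_id, slot) 1000000L + site_id * 1000L + slot
})

link_h_row <- function(center, removed, length_tab, serial, desc) {
  cpos <- c(center$x, center$y, center$z)
  rpos <- c(removed$x, removed$y, removed$z)
  L <- unname(length_tab[[center$element]])
  if (is.null(L) || is.na(L)) L <- 1.09
  pos <- cpos + L * unitv(rpos - cpos)
  data.frame(element = "H", name = "HL", serial = serial,
             x = pos[1], y = pos[2], z = pos[3],
             source = NA_integer_, source_desc = desc,
             stringsAsFactors = FALSE)
}

copy_row <- function(a, j) {
  data.frame(element = a$element[j], name = a$name[j], serial = a$serial[j],
             x = a$x[j], y = a$y[j], z = a$z[j], source = a$serial[j],
             source_desc = NA_character_, stringsAsFactors = FALSE)
}

# Convert atom `center_name` of residue `i` into a methyl (or generic
# H-completed) group: keep the atom, its hydrogens, and the bond toward
# `retain_name`; replace every other heavy neighbour by a link hydrogen.
methyl_group <- function(p, i, center_name, retain_name, spec, site_id,
                         slot0, tag) {
  a <- p$atoms[p$res_atoms[[i]], , drop = FALSE]
  adj <- res_adjacency(a)
  ci <- which(a$name == center_name)
  if (length(ci) != 1L)
    mfcc_error(sprintf("residue %d has no unique atom %s", i, center_name),
               "mfcc_error_missing_backbone")
  nb <- which(adj[ci, ])
  rows <- list(copy_row(a, ci))
  slot <- slot0
  for (j in nb) {
    if (a$name[j] == retain_name) next
    if (a$element[j] == "H") {
      rows[[length(rows) + 1L]] <- copy_row(a, j)
    } else {
      slot <- slot + 1L
      rows[[length(rows) + 1L]] <- link_h_row(
        a[ci, ], a[j, ], spec$link_lengths,
        constructed_serial(site_id, slot),
        sprintf("linkH(%s->%s)@res%d/%s", center_name, a$name[j], i, tag))
    }
  }
  do.call(rbind, rows)
}

# ACE group for the cut after residue `left`: carbonyl C and O of `left`
# plus its CA converted to a methyl.
ace_group <- function(p, left, spec, site_id) {
  a <- p$atoms[p$res_atoms[[left]], , drop = FALSE]
  co <- do.call(rbind, lapply(which(a$name %in% c("C", "O")), function(j) copy_row(a, j)))
  me <- methyl_group(p, left, "CA", "C", spec, site_id, slot0 = 0L, tag = "ace")
  g <- rbind(co, me)
  attr(g, "subgroups") <- list(carbonyl = seq_len(nrow(co)),
                               methyl = nrow(co) + seq_len(nrow(me)))
  g
}

# NME group for the cut before residue `right`: amide N and H of `right`
# plus its CA converted to a methyl.
nme_group <- function(p, right, spec, site_id) {
  a <- p$atoms[p$res_atoms[[right]], , drop = FALSE]
  adj <- res_adjacency(a)
  ni <- which(a$name == "N")
  rows <- list(copy_row(a, ni))
  slot <- 50L
  if (p$residues$resname[right] == "PRO") {
    if (spec$proline_policy == "error")
      mfcc_error(sprintf(
        "N-side cut at proline residue %d: backbone N is tertiary; set proline_policy = 'strip' to cap it with a link hydrogen", right),
        "mfcc_error_proline")
    cd <- which(a$name == "CD")
    if (length(cd) == 1L) {
      slot <- slot + 1L
      rows[[length(rows) + 1L]] <- link_h_row(
        a[ni, ], a[cd, ], spec$link_lengths, constructed_serial(site_id, slot),
        sprintf("linkH(N->CD)@res%d/nme[proline]", right))
    }
  } else {
    hn <- which(adj[ni, ] & a$element == "H")
    for (j in hn) rows[[length(rows) + 1L]] <- copy_row(a, j)
  }
  am <- do.call(rbind, rows)
  me <- methyl_group(p, right, "CA", "N", spec, site_id, slot0 = 60L, tag = "nme")
  g <- rbind(am, me)
  attr(g, "subgroups") <- list(amide = seq_len(nrow(am)),
                               methyl = nrow(am) + seq_len(nrow(me)))
  g
}

# Methyl-sulfide group capping the severed S-S bond: keep the partner's SG
# and convert the partner's CB into a methyl.
ss_group <- function(p, partner, spec, site_id, side) {
  a <- p$atoms[p$res_atoms[[partner]], , drop = FALSE]
  sg <- which(a$name == "SG")
  if (length(sg) != 1L)
    mfcc_error(sprintf("CYS residue %d has no SG atom", partner),
               "mfcc_error_bad_disulfide")
  rows <- list(copy_row(a, sg))
  me <- methyl_group(p, partner, "CB", "SG", spec, site_id,
                     slot0 = if (side == 1L) 0L else 30L, tag = "ssme")
  g <- rbind(do.call(rbind, rows), me)
  attr(g, "subgroups") <- list(all = seq_len(nrow(g)))
  g
}

#' Detect cut sites of a protein
#'
#' One peptide cut per bonded consecutive residue pair within a chain
#' (between the carbonyl C of residue k and the amide N of residue k+1), plus
#' one cut per declared or detected disulfide bridge.  No cuts are placed
#' across chain breaks.
#'
#' @param p an `mfcc_protein`.
#' @return data.frame with columns `type` (`"peptide"` or `"ss"`), `left`,
#'   `right` (residue indices) and `site_id`.
#' @export
detect_cut_sites <- function(p) {
  n <- nresidues(p)
  sites <- list()
  if (n > 1L) for (i in seq_len(n - 1L)) {
    if (p$residues$chain[i] != p$residues$chain[i + 1L]) next
    ai <- p$atoms[p$res_atoms[[i]], ]
    aj <- p$atoms[p$res_atoms[[i + 1L]], ]
    cpos <- ai[ai$name == "C", c("x", "y", "z")]
    npos <- aj[aj$name == "N", c("x", "y", "z")]
    d <- vnorm(as.numeric(cpos) - as.numeric(npos))
    if (d <= 1.8) {
      sites[[length(sites) + 1L]] <- data.frame(
        type = "peptide", left = i, right = i + 1L, stringsAsFactors = FALSE)
    } else if (d <= 2.5) {
      mfcc_error(sprintf(
        "unresolvable peptide bond geometry between residues %d and %d (C-N distance %.2f A)",
        i, i + 1L, d), "mfcc_error_bad_geometry")
    } # else: chain break, no cut
  }
  if (nrow(p$disulfide) > 0L) for (r in seq_len(nrow(p$disulfide)))
    sites[[length(sites) + 1L]] <- data.frame(
      type = "ss", left = p$disulfide[r, 1], right = p$disulfide[r, 2],
      stringsAsFactors = FALSE)
  out <- if (length(sites) > 0L) do.call(rbind, sites) else
    data.frame(type = character(0), left = integer(0), right = integer(0))
  out$site_id <- seq_len(nrow(out))
  out
}

rows_to_molecule <- function(rows, charge = 0L, label = "") {
  molecule(rows$element, as.matrix(rows[, c("x", "y", "z")]), name = rows$name,
           serial = rows$serial, source = rows$source,
           source_desc = rows$source_desc, charge = charge, label = label)
}

# Build all cap groups once per site; everything downstream reuses them.
build_site_groups <- function(p, sites, spec) {
  lapply(seq_len(nrow(sites)), function(s) {
    if (sites$type[s] == "peptide") {
      list(ace = ace_group(p, sites$left[s], spec, sites$site_id[s]),
           nme = nme_group(p, sites$right[s], spec, sites$site_id[s]))
    } else {
      list(g_left = ss_group(p, sites$right[s], spec, sites$site_id[s], 1L),
           g_right = ss_group(p, sites$left[s], spec, sites$site_id[s], 2L))
    }
  })
}

fragment_rows <- function(p, i, sites, groups) {
  a <- p$atoms[p$res_atoms[[i]], , drop = FALSE]
  rows <- do.call(rbind, lapply(seq_len(nrow(a)), function(j) copy_row(a, j)))
  grp <- list()
  for (s in seq_len(nrow(sites))) {
    if (sites$type[s] == "peptide") {
      if (sites$right[s] == i) {          # N-side cut: ACE cap from residue i-1
        g <- groups[[s]]$ace
        grp$ace <- nrow(rows) + seq_len(nrow(g))
        rows <- rbind(rows, g)
      }
      if (sites$left[s] == i) {           # C-side cut: NME cap from residue i+1
        g <- groups[[s]]$nme
        grp$nme <- nrow(rows) + seq_len(nrow(g))
        rows <- rbind(rows, g)
      }
    } else {
      if (sites$left[s] == i) {
        g <- groups[[s]]$g_left
        grp[[paste0("ss", sites$site_id[s])]] <- nrow(rows) + seq_len(nrow(g))
        rows <- rbind(rows, g)
      }
      if (sites$right[s] == i) {
        g <- groups[[s]]$g_right
        grp[[paste0("ss", sites$site_id[s])]] <- nrow(rows) + seq_len(nrow(g))
        rows <- rbind(rows, g)
      }
    }
  }
  list(rows = rows, groups = grp)
}

#' Build one capped amino acid fragment
#'
#' The fragment contains residue `i`'s atoms; at an N-side cut an ACE
#' (acetyl) cap built from residue i-1's carbonyl C, O and its CA converted
#' to a methyl; at a C-side cut an NME (N-methylamide) cap built from residue
#' i+1's N, amide H and its CA converted to a methyl.  Cysteines with a cut
#' disulfide get a methyl-sulfide cap on SG.  Terminal fragments carry caps
#' only on their interior side; true termini are left intact.
#'
#' @param p an `mfcc_protein`.
#' @param i fragment (residue) index, 1-based.
#' @param spec an [cap_spec()].
#' @param protonation named side-chain charge table (see
#'   [default_protonation()]).
#' @return an `mfcc_molecule` with a `groups` attribute marking cap-group
#'   atom indices.
#' @export
build_capped_fragment <- function(p, i, spec = cap_spec(),
                                  protonation = default_protonation()) {
  sites <- detect_cut_sites(p)
  groups <- build_site_groups(p, sites, spec)
  fr <- fragment_rows(p, i, sites, groups)
  ch <- fragment_charge(p, i, protonation)
  m <- rows_to_molecule(fr$rows, charge = ch,
                        label = sprintf("frag%03d:%s", i, p$residues$resname[i]))
  attr(m, "groups") <- fr$groups
  m
}

fragment_charge <- function(p, i, protonation) {
  rn <- p$residues$resname[i]
  ch <- if (rn %in% names(protonation)) protonation[[rn]] else 0L
  as.integer(ch)
}

#' Build the cap molecule of a cut site
#'
#' For a peptide cut the ACE group of the following fragment and the NME
#' group of the preceding fragment are joined into one molecule
#' (N-methylacetamide); for a disulfide cut the two methyl-sulfide groups are
#' joined (dimethyl disulfide).  Atom coordinates are identical, bitwise, to
#' the same cap-group atoms inside the two adjacent capped fragments.
#'
#' @param p an `mfcc_protein`.
#' @param k cut-site index as returned by [detect_cut_sites()].
#' @param spec a [cap_spec()].
#' @return an `mfcc_molecule`; cap molecules are always neutral.
#' @export
build_cap_molecule <- function(p, k, spec = cap_spec()) {
  sites <- detect_cut_sites(p)
  if (k < 1L || k > nrow(sites))
    mfcc_error(sprintf("no cut site %d", k), "mfcc_error_bad_site")
  groups <- build_site_groups(p, sites, spec)
  cap_molecule_from_groups(sites, groups, k)
}

cap_molecule_from_groups <- function(sites, groups, k) {
  g <- groups[[k]]
  if (sites$type[k] == "peptide") {
    rows <- rbind(g$ace, g$nme)
    sub <- list(ace_carbonyl = attr(g$ace, "subgroups")$carbonyl,
                ace_methyl = attr(g$ace, "subgroups")$methyl,
                nme_amide = nrow(g$ace) + attr(g$nme, "subgroups")$amide,
                nme_methyl = nrow(g$ace) + attr(g$nme, "subgroups")$methyl)
    lab <- sprintf("cap[%d,%d]", sites$left[k], sites$right[k])
  } else {
    rows <- rbind(g$g_left, g$g_right)
    sub <- list(g_left = seq_len(nrow(g$g_left)),
                g_right = nrow(g$g_left) + seq_len(nrow(g$g_right)))
    lab <- sprintf("sscap[%d,%d]", sites$left[k], sites$right[k])
  }
  m <- rows_to_molecule(rows, charge = 0L, label = lab)
  attr(m, "groups") <- sub
  m
}

#' Fragment a protein into capped fragments and cap molecules
#'
#' Produces the complete fragmentation plan: N capped single amino acid
#' fragments, one cap molecule per peptide cut (N-1 for a single unbroken
#' chain) and per cut disulfide, and a provenance map from every subsystem
#' atom back to its parent atom (or its constructed-link-hydrogen
#' descriptor).
#'
#' @inheritParams build_capped_fragment
#' @return an object of class `mfcc_plan` with fields `n_fragments`,
#'   `fragments`, `caps`, `sites`, `mode`, `provenance`.
#' @export
fragment_protein <- function(p, spec = cap_spec(),
                             protonation = default_protonation()) {
  if (!inherits(p, "mfcc_protein") || nresidues(p) == 0L)
    mfcc_error("fragment_protein requires a non-empty protein structure",
               "mfcc_error_empty_protein")
  sites <- detect_cut_sites(p)
  groups <- build_site_groups(p, sites, spec)
  n <- nresidues(p)
  fragments <- lapply(seq_len(n), function(i) {
    fr <- fragment_rows(p, i, sites, groups)
    m <- rows_to_molecule(fr$rows, charge = fragment_charge(p, i, protonation),
                          label = sprintf("frag%03d:%s", i, p$residues$resname[i]))
    attr(m, "groups") <- fr$groups
    m
  })
  caps <- lapply(seq_len(nrow(sites)), function(k)
    cap_molecule_from_groups(sites, groups, k))
  plan <- structure(list(n_fragments = n, fragments = fragments, caps = caps,
                         sites = sites, mode = "peptide",
                         protein = p),
                    class = "mfcc_plan")
  plan$provenance <- plan_provenance(plan)
  check_plan_invariants(plan)
  plan
}

plan_provenance <- function(plan) {
  one <- function(m) data.frame(subsystem = m$label, serial = m$serial,
                                parent = m$source, desc = m$source_desc,
                                stringsAsFactors = FALSE)
  do.call(rbind, c(lapply(plan$fragments, one), lapply(plan$caps, one)))
}

# Internal assertion: cap-molecule atoms coincide bitwise with their copies
# inside the adjacent fragments.
check_plan_invariants <- function(plan) {
  for (k in seq_along(plan$caps)) {
    cap <- plan$caps[[k]]
    ck <- atom_coord_key(cap)
    members <- unlist(plan$sites[k, c("left", "right")])
    fk <- unlist(lapply(members, function(i) atom_coord_key(plan$fragments[[i]])))
    if (!all(ck %in% fk))
      mfcc_error(sprintf(
        "internal assertion failure: cap %s atoms do not coincide with their in-fragment copies",
        cap$label), "mfcc_error_internal")
  }
  invisible(TRUE)
}

#' @export
print.mfcc_plan <- function(x, ...) {
  cat(sprintf("<fragmentation plan: %d fragments, %d caps (%s mode)>\n",
              x$n_fragments, length(x$caps), x$mode))
  invisible(x)
}

# Fragment indices a cap's cut site connects (used for pair eligibility).
cap_members <- function(plan, k) {
  as.integer(unlist(plan$sites[k, c("left", "right")]))
}
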