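# ---------------------------------------------------------------------------
# Domain types: Atom / Molecule / ProteinStructure / LigandStructure
#
# A Molecule is a light-weight S3 record holding parallel vectors plus an
# n x 3 coordinate matrix (Angstrom).  `source` carries the serial of the
# parent-structure atom a subsystem atom copies; constructed link hydrogens
# have NA there and a human-readable descriptor in `source_desc`.
# ---------------------------------------------------------------------------

PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe")

mfcc_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "mfcc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)))
}

#' Construct a molecule
#'
#' The basic container for any subsystem sent to an energy backend: an ordered
#' set of atoms with element symbols, Cartesian coordinates in Angstrom, PDB
#' style atom names, integer serials, and provenance links back to the parent
#' structure.
#'
#' @param element character vector of element symbols.
#' @param xyz numeric matrix (n x 3) of coordinates in Angstrom.
#' @param name atom name labels (PDB convention); defaults to the elements.
#' @param serial integer atom serials, unique within the molecule.
#' @param source integer serial of the parent-structure atom each atom copies,
#'   or `NA` for constructed link hydrogens.
#' @param source_desc character descriptor for constructed atoms.
#' @param charge integer total formal charge.
#' @param label human-readable identity.
#' @return An object of class `mfcc_molecule`.
#' @export
molecule <- function(element, xyz, name = element, serial = seq_along(element),
                     source = serial, source_desc = rep(NA_character_, length(element)),
                     charge = 0L, label = "") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- length(element)
  if (n < 1L)
    mfcc_error("a molecule must contain at least one atom", "mfcc_error_empty_molecule")
  if (nrow(xyz) != n)
    mfcc_error("element vector and coordinate matrix disagree in length",
               "mfcc_error_bad_molecule")
  if (!all(element %in% PERIODIC_SYMBOLS))
    mfcc_error(paste0("unknown element symbol(s): ",
                      paste(setdiff(element, PERIODIC_SYMBOLS), collapse = ", ")),
               "mfcc_error_bad_element")
  if (!all(is.finite(xyz)))
    mfcc_error("non-finite coordinates", "mfcc_error_bad_coordinates")
  serial <- as.integer(serial)
  if (anyDuplicated(serial))
    mfcc_error("atom serials must be unique within a molecule",
               "mfcc_error_duplicate_serial")
  structure(list(element = as.character(element), xyz = xyz,
                 name = as.character(name), serial = serial,
                 source = as.integer(source), source_desc = source_desc,
                 charge = as.integer(charge), label = as.character(label)),
            class = "mfcc_molecule")
}

#' Number of atoms in a molecule
#' @param m an `mfcc_molecule`.
#' @return integer atom count.
#' @export
natoms <- function(m) length(m$element)

#' @export
print.mfcc_molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s': %d atoms, charge %+d, formula %s>\n",
              x$label, natoms(x), x$charge, mol_formula(x)))
  invisible(x)
}

#' Hill-order molecular formula
#'
#' @param m an `mfcc_molecule`.
#' @param heavy_only drop hydrogens first if `TRUE`.
#' @return a formula string such as `"C3H7NO"`.
#' @export
mol_formula <- function(m, heavy_only = FALSE) {
  el <- m$element
  if (heavy_only) el <- el[el != "H"]
  if (length(el) == 0L) return("")
  tab <- table(el)
  ord <- c(intersect(c("C", "H"), names(tab)),
           sort(setdiff(names(tab), c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (tab[[e]] == 1L) e else paste0(e, tab[[e]])
  }, ""), collapse = "")
}

# Subset a molecule by atom indices, preserving metadata.
mol_subset <- function(m, idx, label = m$label) {
  out <- m
  out$element <- m$element[idx]
  out$xyz <- m$xyz[idx, , drop = FALSE]
  out$name <- m$name[idx]
  out$serial <- m$serial[idx]
  out$source <- m$source[idx]
  out$source_desc <- m$source_desc[idx]
  out$label <- label
  attr(out, "groups") <- NULL
  out
}

# Concatenate molecules without any deduplication; serials are kept if
# globally unique, otherwise renumbered.
mol_concat <- function(mols, charge = NULL, label = "") {
  stopifnot(length(mols) >= 1L)
  el <- unlist(lapply(mols, `[[`, "element"), use.names = FALSE)
  xyz <- do.call(rbind, lapply(mols, `[[`, "xyz"))
  nm <- unlist(lapply(mols, `[[`, "name"), use.names = FALSE)
  sr <- unlist(lapply(mols, `[[`, "serial"), use.names = FALSE)
  so <- unlist(lapply(mols, `[[`, "source"), use.names = FALSE)
  sd <- unlist(lapply(mols, `[[`, "source_desc"), use.names = FALSE)
  if (anyDuplicated(sr)) sr <- seq_along(el)
  if (is.null(charge)) charge <- sum(vapply(mols, `[[`, integer(1), "charge"))
  molecule(el, xyz, name = nm, serial = sr, source = so, source_desc = sd,
           charge = charge, label = label)
}

# Stable textual key for one atom (element + coordinates rounded to 1e-6 A);
# used for deduplication and multiset difference between subsystems.
atom_coord_key <- function(m) {
  paste(m$element, sprintf("%.6f,%.6f,%.6f",
                           round(m$xyz[, 1], 6) + 0,
                           round(m$xyz[, 2], 6) + 0,
                           round(m$xyz[, 3], 6) + 0))
}

#' Minimum intermolecular distance
#'
#' The distance between two molecules is the shortest Euclidean distance
#' between any atom of the first and any atom of the second; this is the
#' metric used by the trimer distance screen.
#'
#' @param a,b molecules.
#' @return length in Angstrom (0 if the molecules share an atom position).
#' @export
min_distance <- function(a, b) {
  if (is.null(a$xyz) || is.null(b$xyz) || nrow(a$xyz) == 0L || nrow(b$xyz) == 0L)
    mfcc_error("min_distance requires two non-empty molecules",
               "mfcc_error_empty_molecule")
  A <- a$xyz; B <- b$xyz
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

# ---------------------------------------------------------------------------
# Geometry primitives
# ---------------------------------------------------------------------------

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

# Place atom D given reference positions A (bond), B (angle), C (dihedral):
# |DA| = r, angle(D,A,B) = ang, dihedral(D,A,B,C) = dih (degrees). NeRF-style.
place_atom <- function(a, b, c, r, ang, dih) {
  ang <- ang * pi / 180
  dih <- -dih * pi / 180
  ab <- unitv(a - b)
  n <- unitv(pracma_cross(b - c, ab))
  m <- pracma_cross(n, ab)
  d <- c(-r * cos(ang), r * sin(ang) * cos(dih), r * sin(ang) * sin(dih))
  a + d[1] * ab + d[2] * m + d[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Dihedral angle between four points
#' @param p1,p2,p3,p4 numeric xyz triples.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  ang * 180 / pi
}

# ---------------------------------------------------------------------------
# Protein / ligand structures
# ---------------------------------------------------------------------------

#' Assemble a protein structure from an atom table
#'
#' @param atoms data.frame with columns chain, resno, icode, resname, name,
#'   element, serial, x, y, z.
#' @param disulfide_pairs two-column matrix of residue indices (into the
#'   residue ordering) declared as disulfide-bonded, or `NULL` to detect
#'   SG-SG pairs geometrically.
#' @param ss_threshold SG-SG bond detection threshold in Angstrom.
#' @return object of class `mfcc_protein` with residues ordered by
#'   (chain, residue number, insertion code).
#' @export
protein_structure <- function(atoms, disulfide_pairs = NULL, ss_threshold = 2.3) {
  stopifnot(is.data.frame(atoms))
  atoms$icode[is.na(atoms$icode)] <- ""
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
  ukey <- unique(key)
  # residues in file order within chain; order chains as encountered, then
  # resno + insertion code
  meta <- do.call(rbind, lapply(ukey, function(k) {
    i <- which(key == k)[1]
    data.frame(chain = atoms$chain[i], resno = atoms$resno[i],
               icode = atoms$icode[i], resname = atoms$resname[i],
               stringsAsFactors = FALSE)
  }))
  ord <- order(match(meta$chain, unique(meta$chain)), meta$resno,
               match(meta$icode, c("", LETTERS)))
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  res_atoms <- lapply(paste(meta$chain, meta$resno, meta$icode, sep = "|"),
                      function(k) which(key == k))
  p <- structure(list(atoms = atoms, residues = meta, res_atoms = res_atoms),
                 class = "mfcc_protein")
  # backbone sanity
  std <- !(meta$resname %in% c("UNK", "HOH"))
  for (i in which(std)) {
    nm <- atoms$name[res_atoms[[i]]]
    missing <- setdiff(c("N", "CA", "C", "O"), nm)
    if (length(missing) > 0L)
      mfcc_error(sprintf("residue %s %s%d%s is missing backbone atom(s) %s",
                         meta$resname[i], meta$chain[i], meta$resno[i],
                         meta$icode[i], paste(missing, collapse = ", ")),
                 "mfcc_error_missing_backbone")
  }
  p$disulfide <- resolve_disulfides(p, disulfide_pairs, ss_threshold)
  p
}

resolve_disulfides <- function(p, declared, threshold) {
  if (!is.null(declared)) {
    declared <- matrix(as.integer(declared), ncol = 2)
    for (r in seq_len(nrow(declared))) {
      rn <- p$residues$resname[declared[r, ]]
      if (!all(rn == "CYS"))
        mfcc_error("declared disulfide pair must reference CYS residues",
                   "mfcc_error_bad_disulfide")
    }
    return(declared)
  }
  cys <- which(p$residues$resname == "CYS")
  if (length(cys) < 2L) return(matrix(integer(0), ncol = 2))
  sg <- lapply(cys, function(i) {
    j <- p$res_atoms[[i]][p$atoms$name[p$res_atoms[[i]]] == "SG"]
    if (length(j) == 1L) as.numeric(p$atoms[j, c("x", "y", "z")]) else NULL
  })
  pairs <- list()
  for (a in seq_along(cys)) for (b in seq_along(cys)) {
    if (b <= a || is.null(sg[[a]]) || is.null(sg[[b]])) next
    if (vnorm(sg[[a]] - sg[[b]]) <= threshold)
      pairs[[length(pairs) + 1L]] <- c(cys[a], cys[b])
  }
  if (length(pairs) == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

#' @export
print.mfcc_protein <- function(x, ...) {
  cat(sprintf("<protein: %d residues, %d atoms, %d chain(s), %d disulfide(s)>\n",
              nrow(x$residues), nrow(x$atoms),
              length(unique(x$residues$chain)), nrow(x$disulfide)))
  invisible(x)
}

#' Number of residues
#' @param p an `mfcc_protein`.
#' @return integer residue count.
#' @export
nresidues <- function(p) nrow(p$residues)

# Molecule view of one residue (atoms exactly as stored).
residue_molecule <- function(p, i, label = NULL) {
  idx <- p$res_atoms[[i]]
  a <- p$atoms[idx, , drop = FALSE]
  if (is.null(label))
    label <- sprintf("res%d:%s", i, p$residues$resname[i])
  molecule(a$element, as.matrix(a[, c("x", "y", "z")]), name = a$name,
           serial = a$serial, source = a$serial, charge = 0L, label = label)
}

#' Whole protein as a single molecule
#'
#' Used for supermolecular reference energies.
#'
#' @param p an `mfcc_protein`.
#' @param charge total formal charge to record (metadata only).
#' @return an `mfcc_molecule` containing every protein atom.
#' @export
protein_molecule <- function(p, charge = 0L) {
  a <- p$atoms
  molecule(a$element, as.matrix(a[, c("x", "y", "z")]), name = a$name,
           serial = a$serial, source = a$serial, charge = as.integer(charge),
           label = "protein")
}

#' Wrap a molecule as a ligand
#'
#' Ligand formal charge is always an input (taken from configuration), never
#' inferred from the structure.
#'
#' @param m an `mfcc_molecule`.
#' @param charge integer formal charge.
#' @return an object of class `mfcc_ligand`.
#' @export
ligand_structure <- function(m, charge = 0L) {
  m$charge <- as.integer(charge)
  m$label <- if (nzchar(m$label)) m$label else "ligand"
  structure(list(molecule = m, charge = as.integer(charge)),
            class = "mfcc_ligand")
}

#' @export
print.mfcc_ligand <- function(x, ...) {
  cat(sprintf("<ligand: %d atoms, charge %+d>\n", natoms(x$molecule), x$charge))
  invisible(x)
}

# ---------------------------------------------------------------------------
# PDB input (via bio3d), XYZ input/output
# ---------------------------------------------------------------------------

#' Read a PDB file as protein or ligand
#'
#' Column layout follows wwPDB v3.3 as parsed by [bio3d::read.pdb()].  For
#' `role = "protein"`, ATOM records are used and residues are ordered by
#' (chain, residue number, insertion code); every standard residue must have a
#' resolvable backbone (N, CA, C, O).  For `role = "ligand"`, HETATM records
#' are used and the formal charge is taken from `ligand_charge`.
#'
#' @param path PDB file path (single model).
#' @param role `"protein"` or `"ligand"`.
#' @param ligand_charge integer formal charge for the ligand (configuration
#'   input, never inferred).
#' @param altloc_policy `"error"` (default) refuses alternate locations;
#'   `"occupancy"` keeps the highest-occupancy (ties: lexicographically first)
#'   alternate.
#' @param disulfide_pairs optional declared CYS pairs (residue indices).
#' @param ss_threshold SG-SG detection threshold in Angstrom.
#' @param include_het for `role = "protein"`: `"exclude"` (default) drops
#'   HETATM records; `"include"` keeps them as extra residues.
#' @return `mfcc_protein` or `mfcc_ligand`.
#' @export
read_pdb <- function(path, role = c("protein", "ligand"), ligand_charge = 0L,
                     altloc_policy = c("error", "occupancy"),
                     disulfide_pairs = NULL, ss_threshold = 2.3,
                     include_het = c("exclude", "include")) {
  role <- match.arg(role)
  altloc_policy <- match.arg(altloc_policy)
  include_het <- match.arg(include_het)
  if (!file.exists(path))
    mfcc_error(paste0("PDB file not found: ", path), "mfcc_error_io")
  if (pdb_model_count(path) > 1L)
    mfcc_error(paste0("multi-model PDB file: ", path,
                      "; extract a single MODEL before reading"),
               "mfcc_error_multi_model")
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  # altloc handling
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    if (altloc_policy == "error")
      mfcc_error(paste0("alternate locations present in ", path,
                        "; set altloc_policy = 'occupancy' to resolve them"),
                 "mfcc_error_altloc")
    keep <- rep(TRUE, nrow(at))
    grp <- paste(at$chain, at$resno, at$insert, at$elety)
    for (g in unique(grp[nzchar(alt)])) {
      i <- which(grp == g)
      if (length(i) > 1L) {
        o <- at$o[i]; o[is.na(o)] <- 0
        best <- i[order(-o, alt[i])][1]
        keep[setdiff(i, best)] <- FALSE
      }
    }
    at <- at[keep, , drop = FALSE]
  }
  el <- pdb_element(at)
  tab <- data.frame(chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
                    resno = at$resno,
                    icode = ifelse(is.na(at$insert), "", at$insert),
                    resname = at$resid, name = at$elety, element = el,
                    serial = at$eleno, x = at$x, y = at$y, z = at$z,
                    stringsAsFactors = FALSE)
  if (role == "ligand") {
    lig <- tab[at$type == "HETATM", , drop = FALSE]
    if (nrow(lig) == 0L) lig <- tab
    m <- molecule(lig$element, as.matrix(lig[, c("x", "y", "z")]),
                  name = lig$name, serial = lig$serial, source = lig$serial,
                  charge = as.integer(ligand_charge), label = "ligand")
    return(ligand_structure(m, ligand_charge))
  }
  keep <- at$type == "ATOM"
  if (include_het == "include") keep <- keep | at$type == "HETATM"
  tab <- tab[keep & !(tab$resname %in% "HOH"), , drop = FALSE]
  if (nrow(tab) == 0L)
    mfcc_error(paste0("no protein ATOM records in ", path), "mfcc_error_io")
  protein_structure(tab, disulfide_pairs = disulfide_pairs,
                    ss_threshold = ss_threshold)
}

pdb_model_count <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sum(startsWith(lines, "MODEL "))
}

pdb_element <- function(at) {
  el <- trimws(at$elesy)
  bad <- is.na(el) | !nzchar(el) | !(el %in% PERIODIC_SYMBOLS)
  if (any(bad)) {
    # fall back to the atom-name convention: strip digits, first letter(s)
    guess <- gsub("[0-9']", "", trimws(at$elety[bad]))
    two <- substr(guess, 1, 2)
    two <- paste0(substr(two, 1, 1), tolower(substr(two, 2, 2)))
    one <- substr(guess, 1, 1)
    el[bad] <- ifelse(two %in% PERIODIC_SYMBOLS & nchar(guess) > 1 &
                        two %in% c("Cl", "Br", "Fe", "Zn", "Mg", "Na", "Se"),
                      two, one)
  }
  el
}

#' Write a molecule in XYZ format
#'
#' Standard XYZ: atom-count line, a comment line carrying the label and total
#' charge, then one `element x y z` line per atom at fixed precision.
#'
#' @param m an `mfcc_molecule`.
#' @param path output file path.
#' @param digits printed coordinate precision.
#' @return `invisible(path)`.
#' @export
write_xyz <- function(m, path, digits = 6) {
  if (!inherits(m, "mfcc_molecule") || natoms(m) == 0L)
    mfcc_error("write_xyz requires a non-empty molecule", "mfcc_error_empty_molecule")
  fmt <- sprintf("%%-2s %%14.%df %%14.%df %%14.%df", digits, digits, digits)
  lines <- c(as.character(natoms(m)),
             sprintf("label=%s charge=%d", m$label, m$charge),
             sprintf(fmt, m$element, m$xyz[, 1], m$xyz[, 2], m$xyz[, 3]))
  tryCatch(writeLines(lines, path),
           error = function(e) mfcc_error(
             paste0("failed writing XYZ to ", path, ": ", conditionMessage(e)),
             "mfcc_error_io"))
  invisible(path)
}

#' Read an XYZ file written by [write_xyz()]
#'
#' @param path XYZ file path.
#' @return an `mfcc_molecule`; label and charge are recovered from the
#'   comment line when present.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path))
    mfcc_error(paste0("XYZ file not found: ", path), "mfcc_error_io")
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(lines[1])
  comment <- lines[2]
  body <- lines[2 + seq_len(n)]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  el <- vapply(parts, `[[`, "", 1)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  charge <- 0L
  label <- ""
  if (grepl("charge=", comment))
    charge <- as.integer(sub(".*charge=(-?[0-9]+).*", "\\1", comment))
  if (grepl("label=", comment))
    label <- sub("^.*label=([^ ]*).*$", "\\1", comment)
  molecule(el, xyz, charge = charge, label = label)
}
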