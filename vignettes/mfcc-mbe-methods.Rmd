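---
title: "Fragment-based protein-ligand interaction energies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based protein-ligand interaction energies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfccmbe)
```

## The problem

Supermolecular quantum-chemical calculations on whole proteins are rarely
feasible, yet protein-ligand interaction energies are exactly the kind of
quantity one wants from quantum chemistry.  Fragmentation methods divide the
protein into pieces small enough to compute, then reassemble the total from
per-piece energies.  `mfccmbe` implements one family of such schemes built on
chemically meaningful single amino acid fragments:

* **MFCC** (molecular fractionation with conjugate caps): cut every peptide
  bond, cap the severed valences of each residue with an acetyl (ACE) group
  on the N side and an N-methylamide (NME) group on the C side, and subtract
  the energies of the *cap molecules* — the joined ACE+NME units
  (N-methylacetamide for a peptide cut) — to correct the double counting:

  $$E \approx \sum_{i=1}^{N} E_i^{\mathrm{frag}} \;-\; \sum_{k=1}^{N-1} E_{[k,k+1]}^{\mathrm{cap}}.$$

  Disulfide bridges are cut at the S-S bond and capped with methyl-sulfide
  groups; the joined disulfide cap is the dimethyl-disulfide analogue and
  enters the sum exactly like a peptide cap.

* **MFCC-MBE(2)**: MFCC neglects all interactions *between* fragments.  The
  two-body upgrade adds every fragment-fragment pair interaction
  $\Delta E^{\mathrm{ff}}_{ij}$ and corrects the double counting that the
  overlapping caps introduce by subtracting fragment-cap interactions
  $\Delta E^{\mathrm{fc}}$ and adding back cap-cap interactions
  $\Delta E^{\mathrm{cc}}$:

  $$E \approx E^{\mathrm{MFCC}} + \sum_{i<j}\Delta E^{\mathrm{ff}}_{ij}
    - \sum_{i,k}\Delta E^{\mathrm{fc}}_{i,[k,k+1]}
    + \sum_{k<l}\Delta E^{\mathrm{cc}}_{[k,k+1],[l,l+1]}.$$

* **Interaction energies**: the protein-ligand interaction energy is
  $E_{\mathrm{int}} = E^{\mathrm{P-L}} - E^{\mathrm{P}} - E^{\mathrm{L}}$.
  Replacing every term of the MFCC sum by its interaction with the ligand
  gives the MFCC interaction energy (a two-body approximation); replacing
  every term of the MFCC-MBE(2) sum likewise gives a three-body scheme whose
  correction terms are (body, body, ligand) trimer interactions.  The
  two-body MFCC part is never distance-screened; the trimer corrections can
  be screened with a cutoff $\lambda$: a trimer enters only if **at least two
  of its three intermolecular minimum atom-atom distances are below
  $\lambda$** (strictly below — a distance equal to $\lambda$ does not
  count; the boundary rule is a package decision since only the inequality
  direction matters in practice).

## Pair terms between overlapping bodies

Adjacent capped fragments are not disjoint: fragment $i$ contains cap atoms
copied from residues $i\pm1$.  The package distinguishes three cases, chosen
so that every pair ledger is *atom-multiset balanced* — the signed sum of
atom multisets over the ledger's subsystems vanishes exactly:

1. **Covalently connected bodies** ($j=i+1$, or a disulfide pair).  The two
   fragments are healed into the proper covalent dimer $D$ (deduplicating
   bitwise-identical atoms and removing constructed link hydrogens that
   would overlap a retained heavy atom).  The exact multiset surplus
   $F_i \uplus F_j \setminus D$ is provably the cap molecule of the healed
   cut, and the interaction is
   $\Delta E = E(D) + E(\mathrm{cap}) - E(F_i) - E(F_j)$.
   An internal assertion verifies the surplus-equals-cap identity on every
   call.

2. **Clashing bodies** ($j=i+2$; a fragment facing a cap one cut further;
   adjacent caps).  Here the two bodies share constructed cap atoms, or
   carry constructed atoms that overlap atoms of the partner (closer than
   0.8 Å — every genuine cap-construction overlap sits below 0.7 Å while
   real non-bonded contacts stay above 1.5 Å).  The offending cap
   (sub)groups are dropped from both bodies before forming the plain pair.
   For $j=i+2$ this is precisely "omit the clashing inner cap groups".

3. **Disjoint bodies**: the ordinary
   $\Delta E = E(A \cup B) - E(A) - E(B)$.

Each ligand-augmented trimer term applies
$E(X) \mapsto E(X{\cup}L) - E(X) - E(L)$ to every subsystem of the pair
ledger.  Because the ledger is multiset balanced, each such term expands to a
pure three-body interaction (for a disjoint pair:
$E_{ABL} - E_{AB} - E_{AL} - E_{BL} + E_A + E_B + E_L$).

Two consequences make the whole construction *exactly testable*:

* under a **strictly pairwise potential** every three-body term is
  identically zero, the MFCC interaction energy equals the supermolecular
  one exactly (each parent atom's ligand cross terms are counted net once by
  the overlap identity, and constructed link hydrogens cancel pairwise
  between fragments and caps), and MFCC-MBE(2) coincides with MFCC at every
  cutoff;
* in **idealized overlap mode** (bead chains whose caps are literal atom
  subsets) and with a potential containing genuine triple terms,
  MFCC-MBE(2) with $\lambda=\infty$ reproduces the supermolecular
  interaction energy exactly.

The test suite asserts both at $10^{-8}$ relative tolerance; they are the
arbiter for every construction choice above.

## Capping geometry

Retained cap atoms reuse the parent coordinates bitwise.  A severed bond is
completed by a link hydrogen placed on the original bond vector from the
retained atom toward the removed atom, at 1.09 Å from carbon, 1.01 Å from
nitrogen, and 1.34 Å from sulfur.  Converting a C$\alpha$ to a cap methyl
keeps its hydrogens, keeps the bond to the cap carbonyl/amide, and replaces
the remaining heavy substituents by link hydrogens (for glycine this is a
no-op on one substituent).  Because cap groups are built once per cut site
and shared by the two adjacent fragments and the cap molecule, the
coordinate-coincidence invariants hold exactly, which is what makes the
cancellation identities above hold to machine precision rather than to a
geometric tolerance.

Proline's backbone nitrogen is tertiary, so the NME recipe is ambiguous at
an N-side cut.  The package refuses by default
(`cap_spec(proline_policy = "error")`); the explicit `"strip"` policy
replaces the ring CD carbon by a link hydrogen and records the decision in
the provenance table.

## Energy backends

The scheme is backend-agnostic: any function from a geometry to a scalar
energy (kJ/mol) can stand behind it.  The quantum-chemical level, solvation
model and dispersion treatment belong to the backend, not to the assembly.
Three backends ship with the package:

* `pairwise_backend()` — Coulomb (fixed per-element point charges, Coulomb
  constant 1389.3545764 kJ mol$^{-1}$ Å) plus Lennard-Jones with
  Lorentz-Berthelot combination.  Strictly pairwise additive by
  construction; its parameters are a fixed, seed-free set chosen to give
  interaction energies of order 10-100 kJ/mol at vdW contact, not fitted to
  anything.
* `threebody_backend()` — the pairwise potential plus an
  Axilrod-Teller-Muto triple term
  $w = \nu (1 + 3\cos\alpha\cos\beta\cos\gamma)/(r_{12}r_{13}r_{23})^3$
  with $\nu = 5000$ kJ mol$^{-1}$ Å$^9$, sized so triple contributions are a
  few percent of pair terms at bead spacing — large enough to measure, small
  enough not to dominate.
* `table_backend()` — scalar energies imported from an external engine via
  the plain-text manifest (`export_manifest()` / `import_energies()`; one
  XYZ per subsystem plus a tab-separated index).  Results files declare
  their unit; hartree values convert at 2625.4996394799 kJ/mol.  A missing
  entry is an error naming the key — a failed external calculation must
  never silently contribute zero.

Energies are memoised by an identity key (hash of element sequence,
coordinates rounded to $10^{-6}$ Å, and formal charge), so subsystems shared
between terms are computed once.  Ledger sums use Kahan compensation in a
fixed construction order.  Estimates carry a fingerprint of their backend
parameters, and `interaction_error()` refuses to compare estimates computed
with different parameter sets (mirroring the rule that energies from
different dielectric settings must never be mixed in one ledger).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 4 Å | trimer screen cutoff; the interaction energy typically stabilizes around 4 Å, which balances accuracy against the cubic growth in trimer count |
| `ss_threshold` | 2.3 Å | SG-SG distance below which a cysteine pair is treated as disulfide-bonded (explicit declaration overrides) |
| link H lengths | 1.09 / 1.01 / 1.34 Å | C-H / N-H / S-H completion distances |
| `proline_policy` | `"error"` | N-side proline handling (see above) |
| protonation table | ASP/GLU $-1$, LYS/ARG $+1$, HIS 0 | fragment formal charges; configuration input, never inferred |
| ligand charge | required input | likewise never inferred from the structure |

## The synthetic fixtures

`make_polypeptide()` builds polypeptides by internal-coordinate chain growth
(NeRF) with standard bond lengths and angles, all hydrogens, neutral termini
(NH$_2$/COOH) and named backbone presets (extended $\varphi,\psi = -139,
135$; helical $-57, -47$) or per-residue angles.  Optional uniform jitter
(default amplitude 0.05 Å, applied only when a seed is given) breaks
accidental symmetry in property tests; identical (spec, seed) inputs yield
bitwise-identical structures.  Declared single-chain disulfides are realized
by a deterministic grid search over the two cysteine $\chi_1$ angles
followed by symmetric closure of the S-S distance to 2.05 Å — this stretches
the fixture's CB-SG bonds, which the assembly never consumes; inter-chain
disulfides are realized by rigid placement of the second chain.
`make_complex()` places a point-charge, zwitterion-like or water ligand at a
requested minimum distance along the clearest direction orthogonal to the
chain axis.

`make_bead_chain()` provides the idealized overlap mode: argon beads on a
gentle helix, partitioned into windows whose pairwise intersections are the
caps (with `overlap = 0`, a partition with no caps at all, under which the
assembly demonstrably reduces to the plain two-body expansion).  Bead
spacing (1.8 Å) and ligand distance (2.5 Å) are chosen so that cutoff values
between 1 and 8 Å sweep the trimer set from empty to complete.

What the fixtures deliberately do **not** emulate: realistic conformational
ensembles, solvent, crystallographic disorder, or force-field-minimized
geometries.  Passing tests therefore certify the *algebra* of the
fragmentation — counting, cancellation, screening, convergence — under
controlled potentials, not the chemical accuracy of any particular quantum
chemistry backend on real proteins, which is governed by the backend and the
structures supplied by the user.

## Problem sizes and numerical choices

The exactness suites run on 5-12-residue peptides (20 randomized complexes),
9-13-bead chains (10 systems for three-body exactness, 8 for the cutoff
scan), and term-count checks for chains of 1-8 residues; these sizes
exercise every term family and adjacency case while keeping the whole suite
in tens of seconds.  "Exact" identities are asserted at $10^{-8}$ relative
tolerance; the dominant numerical noise is cancellation between large
intramolecular Lennard-Jones sums, which stays near $10^{-12}$ relative in
practice.  Strict inequality at the screen boundary, highest-occupancy
(then lexicographic) altloc resolution, and exclusion of non-ligand HETATM
records (with an opt-in) are the remaining tie-break decisions.

## Known limitations

* Fragment sizes are fixed at one amino acid; larger fragments and
  alternative capping chemistries are out of scope.
* Four-body and higher corrections, density-based corrections, and
  basis-set superposition handling are not implemented.
* The clash-resolution rule for fragment-cap and cap-cap pairs around
  shared methyls (and around disulfide caps) is a package decision validated
  by the exactness suite; other resolutions exist that satisfy the same
  identities.
* `run_from_config()` computes supermolecular references with the analytic
  backends only; for external engines the reference must be supplied through
  the manifest workflow.

## A worked example

```{r example}
cx <- make_complex("AGSDKA", ligand = "zwitterion", distance = 3, seed = 1)
plan <- fragment_protein(cx$protein)
plan
backend <- pairwise_backend()
scan <- run_lambda_scan(plan, cx$ligand, backend, lambdas = c(1, 4, Inf))
scan
```

Under the pairwise backend the error column is zero to numerical precision
for both methods at every cutoff — the package's central exactness property.
The same scan with `threebody_backend()` on a bead-chain complex shows the
cutoff convergence: a finite error at small $\lambda$ that shrinks to zero
at $\lambda = \infty$.
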