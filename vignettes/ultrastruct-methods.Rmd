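---
title: "Methods: geometric analysis of ultra-high-resolution structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric analysis of ultra-high-resolution structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultrastruct)
```

## Scope and model of the data

Sub-Angstrom protein crystal structures resolve features that routine
structures blur: individual side chains split over two occupied
conformations with refined occupancies summing to one, refined hydrogen
positions, well-ordered solvent networks, and unexpected solvates. This
package treats such a structure as a flat table of atom records — one row
per deposited record, so alternate conformers are separate rows carrying
their altloc label and occupancy — plus the crystal cell and space group,
and optional additional coordinate models for trajectories. Blank-altloc
atoms are shared by every conformer of their residue; analyses only ever
pair atoms whose labels are equal or blank, and every derived interaction
carries the limiting occupancy of its partners.

Record parsing and fixed-column output are delegated to bio3d; this
package adds the unit-cell record, validation (occupancy ranges, altloc
uniqueness, per-group occupancy sums), residue categorisation (polymer /
water / metal / ligand) and the analysis layers described below. Atom
names are normalised across dialects (`OT2` ≡ `OXT`, `H0C` ≡ `H3`,
guanidinium `HH1` ≡ `HH11`), because interaction tables in the
literature frequently use modelling-suite names while deposited files
use PDB v3.

## Torsions, chirality and internal coordinates

Dihedrals follow the IUPAC sign convention (positive = clockwise
rotation of the far bond viewed from the second atom towards the third;
trans = +180°, reported range (−180°, 180°]). The convention matters
because disulphide chirality is read directly off the sign of
χ³ = Cβ–Sγ–Sγ′–Cβ′: positive torsions near +100° are right-handed
bridges, negative near −80° left-handed. An exactly zero torsion raises
an error rather than guessing.

Internal-coordinate construction is the standard sequential (NeRF)
placement: atom *i* is positioned at its stated bond length, angle and
torsion relative to atoms *i−1, i−2, i−3*, with the first three atoms in
a canonical frame. Bond angles of 0° or 180° (|sin θ| < 1e−10) are
rejected as degenerate frames. The builder and the measurement routine
are exact inverses to well below 1e−6 (torsions in degrees), which the
suite verifies on a thousand random chains; this round trip is also how
printed bridge geometry is turned back into coordinates for end-to-end
checks. Only the torsions *printed* for a bridge constrain the re-measured
χ³; the one flanking torsion of the 5-atom chain is free and provably
irrelevant, so the acceptance script draws it from the seed.

Superposition uses the Kabsch SVD solution with the determinant
correction that excludes reflections; the quaternion (Horn) eigenvalue
method serves as an independent oracle in the tests, never as the
implementation.

## Hydrogen bonds, the water census and salt bridges

No pre-installed R package provides geometric hydrogen-bond detection,
so it is implemented here. Donors are polar atoms carrying a refined
hydrogen; when a polar oxygen's hydrogens are absent from the model
(waters are typically refined without them) the heavy-atom distance
alone decides, and when a structure has no hydrogens at all the detector
falls back entirely to the donor–acceptor distance with a warning.
Defaults — D···A ≤ 3.4 Å, H···A ≤ 2.5 Å, ∠DHA ≥ 120° — are common
geometric practice; the tool-specific criteria behind published solvent
censuses are generally unstated, so `calibrate_hbond_criteria()` sweeps
the cutoffs against target bond totals and reports the full discrepancy
table, including both conventions for whether main-chain–water bonds are
merged into the side-chain total. The calibration is demonstrated on
synthetic solvent networks; applying it to a deposited structure
requires that structure's coordinate file, which is deliberately not
shipped.

Each water is typed by its counts of side-chain–water and unique
water–water bonds; "side chain" includes the charged terminal amine and
carboxylate groups, since interaction tables treat them as side-chain
groups. The census obeys three conservation identities (Σ n_SC·N equals
the SC–W total; Σ n_WW·N equals twice the unique W–W total; typed waters
plus bond-less waters equal the water count), asserted on every fixture.

Salt bridges are recorded at atom-contact level: a donor with refined
hydrogens contributes one record per hydrogen within 3.2 Å of an
acceptor oxygen (so a guanidinium reaching one oxygen with both NH
groups yields two records), and a donor without hydrogens is tested at
N···O ≤ 4.0 Å. This granularity matches how published contact tables are
printed.

## Secondary structure

The assigner is deliberately rule-based and auditable rather than a
re-implementation of the full 8-state DSSP. Helices are driven by
main-chain CO(i)···HN(i+k) bonds with k ∈ {3, 4, 5} and by torsion
regions; the regions are declared configuration
(helical φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°]; strand φ ∈ [−180°, −45°],
ψ ∈ [90°, 180°] ∪ [−180°, −170°]) because the cutoffs behind published
per-chain descriptions are never stated; per-residue (φ, ψ) are always
attached to the result so any assignment can be audited. A run is a
helix when it has two supporting bonds, or one bond over at least four
uniformly helical residues; its kind follows the dominant offset, with
all offsets kept as sub-annotations so one turn of π-helix inside an
α-run is reported, not split. A chain-terminal residue with one
undefined torsion joins a helix only if spanned by a helical bond and
its defined torsion is helical — this is what lets an N-terminal residue
with indeterminate φ belong to the first helix without letting boundary
bonds drag coil residues in.

Strands record two extents: the torsion-based run and the (possibly
shorter) range actually engaged in cross-strand bonds; they are never
silently merged. Antiparallel sheets are strand pairs joined by at least
one cross-strand main-chain bond. A lone i→i+3 bond whose two central
residues match the canonical type-I torsions ((−60°, −30°) and
(−90°, 0°)) within a ±30° tolerance is a type I turn; a lone i→i+4 bond
with both endpoints outside a helix or exactly at a helix boundary is an
open α-turn — the boundary condition distinguishes the genuine
helix-terminus open turn from helical capping bonds.

## Crystal symmetry and metal sites

Only the identity group and space group 146 in its hexagonal setting are
needed for this family of structures; the nine operators (three-fold
rotation × rhombohedral centering) are written out explicitly and tested
for closure against literal textbook formulas. Neighbour searches
enumerate lattice shifts in a bounded box (−2..2 per axis by default) —
at desk scale no spatial index is warranted, and a brute-force oracle
checks equivalence. The Matthews coefficient uses the defining ratio
V_M = V_cell/(n_ops·M) with the conventional 1.23 Å³/Da constant for the
solvent fraction; the protein mass per asymmetric unit is an explicit
input, never inferred, because published V_M values are frequently not
reproducible from a nominal monomer mass.

A metal on the three-fold axis acquires its complete coordination sphere
from one ligand copy per asymmetric unit; symmetry-equivalent ligands
are collapsed to one representative with multiplicity, and
special-position self-images of the metal are excluded inside 0.2 Å. The
2.8 Å default cutoff covers reported Zn–N/O distances (2.0–2.4 Å) with
margin.

## Disorder ledgers

Published per-residue order/disorder assessments are made by inspecting
electron density; maps are out of scope here, so the ledger uses
coordinate-file proxies: two or more altlocs on a side-chain atom →
`double_conformer`; missing expected heavy atoms or a maximum side-chain
B-factor above a threshold → `problematic`; otherwise `single_ordered`.
The altloc test takes precedence, since a modelled split is direct
evidence of two conformations regardless of displacement parameters.
The B threshold is relative (2× the structure's median B) so structures
refined on different displacement scales are treated alike. Agreement
with density-based calls is therefore qualitative: the ledger is exact
about what the coordinate file asserts, not about what the density
shows. Correspondence between chain pairs is a 3×3 contingency over
position-matched labels plus the discordant-position list;
self-correspondence is always 100%.

The activity annotation is a static summary of insulin positions
repeatedly implicated in receptor binding across mutagenesis,
conservation and structural studies, ranked by how often each position
recurs (α most, δ least, the invariant disulphide cysteines rated α);
C/D-chain positions map onto their sequence-identical A/B equivalents.

## Trajectory analysis

The analysis layer is engine-agnostic: multi-MODEL coordinate files (or
generator schedules) in, per-frame series out. Torsion series agree with
the dihedral routine frame by frame; angular differences are always
circular, and an optional unwrapping makes series crossing the ±180°
seam continuous. Because no published definition exists for
"torsion-RMSD kinetics" plots, the package's operationalisation is
declared: the root-mean-square circular deviation from the circular mean
in a sliding window (10 frames by default). Endpoint RMSD is the
final-frame-vs-first Kabsch-superposed RMSD per chain grouping, on Cα
atoms by default. Published trajectory values themselves are stochastic
and engine-dependent and are not reproduction targets; what the suite
guarantees instead is exact recovery of scheduled kinematics
(torsion drives to 1e−6 degrees, rigid motions to zero RMSD).

## The synthetic generators and what passing tests mean

Every analysis stage is tested by generate → analyse → compare-to-plan.
The generators use ideal backbone geometry (N–Cα 1.458, Cα–C 1.525,
C–N 1.329 Å, ω = 180°) with canonical torsions per motif: α (−57°, −47°),
3₁₀ (−49°, −26°), π (−60°, −64°), strand (−150°, 140°), coil
(−150°, 60°) — the π values chosen so a uniform run yields i→i+5 bonds
without i→i+4 contamination, and the hairpin's reversal torsions
((−45°, −35°), (−115°, −5°)) chosen inside the type-I tolerance such
that the turn bond and at least two cross-strand bonds exist by
construction. Water networks realise declarative plans (forest edges at
2.8 Å, serine-hydroxyl contacts at 2.7 Å, everything else kept beyond
3.6 Å), erroring on geometrically unrealisable plans rather than
emitting a wrong ground truth.

The benchmark asymmetric unit (`synthetic_insulin_benchmark()`) is a
stand-in assembled entirely in code from published numbers: the three
internal-bridge conformers rebuilt from their printed internal
coordinates, the six salt-bridge contacts placed at their printed
distances, and a Zn site on the three-fold axis. Passing its tests shows
the analysis path recovers those numbers from raw coordinates; it does
not substitute for analysing the deposited entries, which requires their
coordinate files.

What the fixtures do not emulate: real rotamer distributions, solvent
disorder, lattice contacts between neighbouring molecules, coordinate
noise, and density-level evidence. Tests passing on fixtures therefore
demonstrate correctness of the geometric logic under clean conditions,
not field performance on noisy deposits; the criteria-calibration
machinery exists precisely because real-data cutoffs need tuning.

## Problem sizes and numerical choices

The shipped suite runs 10⁴ random torsion quadruples against an
independent half-plane oracle (±1e−9°), 10³ internal-coordinate round
trips (±1e−6), several hundred Kabsch-vs-quaternion comparisons
(±1e−9 Å), 50 randomised helix fixtures with exact span/kind recovery,
and brute-force symmetry-neighbour equivalence on multi-ligand sites —
sizes chosen to exercise the properties densely while keeping the whole
suite under a couple of minutes on one CPU. Degenerate inputs
(collinear torsion frames, rank-deficient superpositions, zero-length
vectors, 0° chirality) raise informative errors rather than returning
numbers.

## Known limitations

* No electron-density input: order classes are coordinate-file proxies.
* Acceptor geometry is distance/angle only; no orbital or energy terms,
  no π-interactions, and nitrogen acceptors are ignored.
* Space-group support is limited to the two groups this structure family
  needs; others raise an error listing what is supported.
* The secondary-structure assigner targets the motifs described for this
  fold (helices, one sheet topology, type I turns, open α-turns), not
  the full DSSP state set; bends and polyproline II are out of scope.
* mmCIF support is read-only and limited to the atom-site loop that
  bio3d exposes.
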