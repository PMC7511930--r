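---
title: "Ensemble repacking: the models and numerical choices behind ensrepack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble repacking: the models and numerical choices behind ensrepack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensrepack)
```

## The problem

Computational enzyme design places a model of a reaction's transition state
(TS) into a protein scaffold and searches for a set of side-chain rotamers
that stabilizes it. The classical protocol operates on a single fixed
backbone template, which makes its predictions brittle: sub-Angstrom backbone
differences between the template and the conformation the designed sequence
actually adopts can flip which rotamers and TS poses score well. `ensrepack`
implements the full desk-side protocol — targeted TS placement, a
physics-based pairwise scoring function, and simulated-annealing repacking —
over either a single template or an *ensemble* of backbone templates
(ensemble-refinement members or MD snapshots), so that design scores can be
read across a conformational ensemble rather than a point estimate. It also
provides the companion analyses used when comparing designed variants to
crystal structures: within-crystal B-factor Z-scores as a conformational
heterogeneity measure, mutation-set bookkeeping, and catalytic-efficiency
estimation from sub-saturating kinetics.

## Structures and conformer policy

Structures are parsed from fixed-column PDB text into a `structure_model`
holding protein atoms, HETATM ligands (kept in a separate table, never merged
into protein chains), and optionally waters (dropped by default: the design
protocol uses protein heavy atoms only). Residue numbering follows the
deposited file so that positions keep their literature labels.

Alternate conformers are resolved by a `conformer_policy`. The default mirrors
standard design practice: per residue, keep the single conformer with the
highest summed occupancy; break occupancy ties toward the lexicographically
smallest altloc tag; treat blank-altloc atoms as one full-occupancy conformer
and always keep them. The tie-break and the blank-altloc convention are
package conventions — deposition practice does not dictate them — and are
therefore exercised explicitly in the tests. Multi-MODEL files map to one
`structure_model` per MODEL record; members that do not share residue keys
trigger a warning rather than an error, since trimmed ensemble members are
common in practice.

## Rotamers

Side-chain conformations come from a backbone-independent rotamer library in
a documented TSV dialect (`res_type`, `prob`, four chi means, four chi
standard deviations). The package ships only a small generic library for
tests and demos (`make_toy_rotamer_library()`); a user-supplied file in the
same dialect — e.g. a conversion of the Dunbrack 2002 backbone-independent
library — drops in without code changes. Sampling is densified by expanding
chi1 and chi2 to mean ± 1 standard deviation (`expansion_policy()`), the
expansion used in the design lineage this package follows; a record with k
expandable chis yields 3^k variants before duplicate collapse. Expansion
carries the parent rotamer probability unchanged onto every variant — the
library's probabilities are bookkeeping here, not energy terms, so no
re-weighting is applied.

Side chains are built by internal-coordinate (NERF) construction from a
single packaged ideal-geometry table (bond lengths and angles per atom, with
branch atoms at fixed torsion offsets). The table is a constant of the
artifact: building a side chain and re-measuring its chi dihedrals is the
identity to better than 1e-6 degrees, which is the property the repacker
relies on. Angles follow the IUPAC dihedral sign convention and are wrapped
into (-180, 180].

## The scoring function

All energies are kcal/mol. The pairwise terms, their defaults, and the
reasons for them:

* **Lennard-Jones 12-6** with Dreiding-style combining rules (arithmetic mean
  for the equilibrium diameter, geometric mean for the well depth) and atomic
  radii scaled by **0.9**. The scale softens the hard-sphere penalty for the
  discrete rotamer approximation; the minimum of the pair potential sits
  exactly at the scaled combined radius, which the tests verify by a
  golden-section search oracle.
* **Directional hydrogen bonds**: a hybrid 12-10 radial form with well depth
  **8.0 kcal/mol** at an equilibrium donor-acceptor distance of **2.8 Å**,
  scaled by an angular factor `F ∈ [0, 1]` built from squared cosines — 1 for
  a linear donor-H-acceptor arrangement at the hybridization-appropriate
  approach angle at the acceptor (120° sp2 by default, 109.5° sp3), 0 at 90°.
  When no explicit hydrogen is present (the package works on heavy atoms),
  the donor-H factor is taken at its ideal value of 1 — a deliberate,
  documented simplification rather than a geometric hydrogen builder.
* **Electrostatics**: Coulomb's law with a distance-dependent dielectric of
  **10**, i.e. `ε(r) = 10·r`, so energies fall off as `1/r²`. This is the
  standard reading of a "distance-dependent dielectric of n" in this family
  of scoring functions; a constant-dielectric mode is a config switch.
* **Occlusion solvation**: per heavy atom, neighbours within **5 Å**
  contribute a weight `(1 − r/cutoff)²`; the summed weight is divided by a
  saturation constant (**3.0**) and clamped to `[0, 1]` to give an occlusion
  fraction `f`. Nonpolar atoms gain `−0.05·f·A_ref·c` on burial and pay
  `2.5·(1−f)·A_ref·c` for exposure; polar atoms pay `1.0·f·A_ref·c` for
  burial, with `A_ref = 25 Å²` per heavy atom and `c = 0.02 kcal/mol/Å²`.
  The scale factors (0.05 / 2.5 / 1.0) are the published constants of the
  scoring lineage; the reference area, the unit constant and the occlusion
  functional itself are this package's own — chosen for O(n·k) cost and a
  testable saturation limit — and are versioned as such. No claim of
  numerical agreement with any proprietary implementation is made.
* **Secondary-structure propensity**: residues are classed helix / strand /
  other by fixed φ/ψ boxes (helix: φ ∈ [−100, −30], ψ ∈ [−80, −5]; strand:
  φ ∈ [−180, −45] with ψ near the extended region), then a per-(residue,
  class) table value is added; absent pairs contribute zero. The shipped
  table is small and conventional; it is config-replaceable.
* **Contact-geometry bias**: catalytic contact specs (distance, angles,
  dihedrals with tolerances) grant an additive bonus (default **−100
  kcal/mol**, config-exposed) whenever satisfied. A bias, not a constraint:
  unsatisfied poses survive, they just score worse.

Pair terms use a hard **12 Å** cutoff without switching — simplicity over
continuity, and exactly decomposable; oracle tests disable the cutoff
(`pair_cutoff = Inf`). Atom pairs closer than 0.01 Å raise a clash flag and
every pair energy is capped at **+1000 kcal/mol** to keep Monte Carlo
numerics finite. Intra-residue pairs and peptide-adjacent backbone pairs are
excluded from the non-bonded sums (covalent context, constant across
rotamers).

## Targeted ligand placement

TS poses are *constructed*, not docked: from three ordered protein anchor
atoms, the ligand contact atom is placed by internal coordinates at the
spec's distance/angle/dihedral, two further ligand anchors fix the
orientation, and the whole rigid ligand is mapped onto this frame (exact
three-point superposition). Discretizing the contact DOFs gives the pose
library; poses with any protein-ligand heavy-atom distance below 2.0 Å
(anchor pairs exempt; the threshold is a package choice) are discarded, and
survivors are scored as protein-ligand interaction energy plus the bias of
every satisfied spec.

The rigid-body refinement grid translates the TS by ±0.4 Å per Cartesian
axis in 0.2 Å steps and rotates ±10° about each axis in 5° steps, about the
TS geometric center — 5 values per axis over 6 axes, 15,625 poses. The
rotation span is fixed by that printed count: five values per rotation axis
force ±10°, not 0-10°. Rotation composition is fixed as Rz·Ry·Rx; at these
small angles the ordering effect is slight, but determinism requires fixing
it.

## Repacking

The search space is decomposed into an interaction matrix: one-body energies
(choice vs. the fixed background, plus solvation and the background-anchored
contact bias) and two-body energies (choice pairs, including TS-side-chain
terms with the bias applied where a spec anchors a designable position).
When a TS pose set is given it is treated as one super-position searched
jointly with the rotamers (`ts_as_position`); a nested per-pose mode is the
`FALSE` branch of the same flag.

One modelling decision makes the matrix exact rather than approximate: the
solvation occlusion environment is frozen to the all-Gly background during
matrix construction, and `total_energy()` accepts the same frozen-background
context. Under that convention the matrix energy of *any* assignment equals
the directly recomputed structure energy to 1e-6 (a tested invariant), at the
cost of ignoring choice-choice occlusion — the standard trade in
matrix-based design codes.

Optimization is Metropolis Monte Carlo with geometric simulated annealing:
single-position uniform resampling moves, temperature from 100 down to 0.1
kcal/mol at a cooling factor of 0.95 per stage. The default
`moves_per_stage` is 50 × (total choices); at desk-scale problem sizes this
already saturates agreement with the exhaustive oracle, and the stage count
is config-exposed for larger problems. The move loop is compiled (C++) and
draws from a self-contained xoshiro256++ generator seeded by splitmix64 —
the annealing trajectory is bit-reproducible for a given 64-bit seed on any
platform, independent of R's RNG state. The best assignment ever visited is
returned; the per-stage best-so-far trace never increases. An exhaustive
`brute_force()` oracle (guarded at 1e6 combinations, lexicographic
tie-break) backs the property tests.

Design energies are reported as the difference to the **all-Gly reference**:
the same template with every designable position truncated to glycine, plus
the placed TS pose, scored under the identical frozen-background context.
Differencing removes the large template-dependent constant and makes scores
comparable across backbone templates. Final selection ties break by (energy,
pose index, lexicographic assignment).

## Ensemble design

`design_over_ensemble()` runs placement → pose selection → repacking per
member (one starting pose per member by default, matching how individual
ensemble members are treated in the protocol this package implements, versus
ten starting poses for single crystal-structure templates) and ranks members
by their all-Gly delta. Per-member seeds are derived as
`xor(seed, member_index − 1)`, so ensembles are reproducible, members are
decorrelated, and a single-member ensemble reproduces `repack_sequence()`
bit-for-bit. A failing member (e.g. a truncated model missing a design
position) is flagged and skipped, not fatal — long ensembles should not die
on one bad model. Supporting utilities: trajectory subsampling at a fixed
time interval (nearest-frame selection; the count obeys
`floor((span − start)/interval) + 1`) and least-squares (Kabsch)
superposition RMSD over a C-alpha selection by default, which is how
ensemble-to-reference deviations are usually quoted.

## Heterogeneity and kinetics analyses

**B-factor Z-scores.** Raw B-factors mix conformational heterogeneity with
crystal-to-crystal disorder; standardizing within a structure
(`z = (B − mean)/sd`, population standard deviation) removes the affine
component, which is exactly the property (tested) that justifies comparing
Z-scores across different crystals. The default population is the side-chain
heavy atoms (CB included) of standard residues — the side-chain flexibility
question is what the analysis answers — with an all-heavy-atom mode
available since the choice is not dictated; only the highest-occupancy
conformer enters the statistics (an occupancy-weighted variant would be a
flag-level extension). Per-residue scores are means over side-chain heavy
atoms; glycines and side-chain-less residues are excluded rather than
zero-filled, and two-chain crystals are summarized by the cross-chain mean
with single-chain residues flagged.

**Mutation bookkeeping.** Tokens of the `K50Q` form parse into sets with
unique positions, support exact-token set difference and annotation counts
(e.g. how many mutations fall at previously design-optimized sites), and
round-trip through formatting. The published variant table this package uses
in its tests ships as a plain TSV (`hg_series_mutations()`).

**Catalytic efficiency.** When saturation is unreachable, the
Michaelis-Menten model reduces to `v0 = (kcat/KM)·[E0]·[S]`; `fit_efficiency()`
estimates kcat/KM as the least-squares slope of `v0` against `[E0][S]`,
constrained through the origin because the model has no intercept (an
unconstrained mode exists as a flag for diagnostics). The regression
standard error of the slope is the reported uncertainty.

## What the synthetic fixtures do and do not show

All test inputs are generated in code. The toy scaffold is a poly-Ala ring
with a guaranteed-clear central pocket — it exercises parsing, geometry,
placement and repacking plumbing, but it is not a protein fold: no secondary
structure to speak of, no tertiary packing, no realistic φ/ψ distribution.
The toy ligand is a generic planar 9-atom ring with one donor and one
acceptor; it is deliberately *not* a model of any real transition state, and
no parameterization of real TS chemistry is claimed. Synthetic B-factor
profiles (multiplicative loop inflation + Gaussian noise) and kinetics
(linear model + fractional noise) have known ground truth by construction.
Passing tests therefore demonstrate that the algorithms are implemented
correctly and self-consistently — not that the energy function reproduces
experimental design outcomes; real applications require user-supplied
structures, a full rotamer library, TS charges, and calibrated contact
geometries.

Problem sizes in the test suite are deliberately small: scaffolds of 12-16
residues, 1-3 design positions, pose libraries of 1-6, random interaction
matrices up to 1e5 combinations, 10-20 annealing seeds per property. These
sizes already make the combinatorial properties (grid counts, oracle
equivalence, matrix consistency) fully informative, and keep the default
suite fast.

## Known limitations

* No explicit hydrogens: the donor-H angular factor defaults to ideal; a
  geometric hydrogen builder would sharpen hydrogen-bond discrimination.
* Solvation is a one-body/frozen-background approximation during
  combinatorial search; choice-choice occlusion is ignored by design.
* No post-repack Cartesian minimization and no backbone flexibility within a
  member — backbone variation enters only through the ensemble.
* No dead-end elimination or belief-propagation search; simulated annealing
  plus the exhaustive oracle covers the intended problem sizes.
* Isotropic B-factors only; no TLS decomposition or occupancy refinement.
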