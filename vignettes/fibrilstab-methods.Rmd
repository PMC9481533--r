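---
title: "Stability maps, ligand occupancy and interface metrics for amyloid fibrils"
author: "fibrilstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability maps, ligand occupancy and interface metrics for amyloid fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilstab)
```

# Scope

`fibrilstab` quantifies how a small-molecule disaggregant perturbs an amyloid
fibril, using the AD-tau paired helical filament (PHF) bound by the green-tea
polyphenol EGCG as its motivating system. Five analyses are covered:

1. **Solvation-energy stability maps** of fibril chains, and atom-wise
   difference maps between two structures.
2. **CryoEM ligand occupancy** from three masked map statistics, plus masked
   real-space model-map correlation.
3. **Ligand-interface metrics**: buried surface area, hydrogen-bond geometry,
   ring-stacking/curvature profiles, and multi-pose comparison.
4. **Per-residue inter-layer spacing profiles** for single models or
   coordinate ensembles (the typical MD readout).
5. **Virtual-screen bookkeeping**: docking-box emission, per-engine z-scores,
   consensus ranking and hit selection.

A synthetic-fixture generator builds fibrils, ligand columns and density maps
with known ground truth, so the full pipeline is testable without any
deposited data. Structure refinement, docking and MD themselves are out of
scope; the package consumes their coordinate, map and score outputs.

# The solvation stability model

For each atom of a *central* chain (median axial position per protofilament,
so both axial neighbours are present) the model computes

$$\Delta G_{\mathrm{atom}} = -\,\mathrm{ASP}(\mathrm{class})\times
\bigl(\mathrm{SASA}_{\mathrm{ref}}-\mathrm{SASA}_{\mathrm{fold}}\bigr)/1000
\quad [\mathrm{kcal\,mol^{-1}}],$$

where $\mathrm{SASA}_{\mathrm{fold}}$ is the atom's solvent-accessible
surface area in the full fibril context, $\mathrm{SASA}_{\mathrm{ref}}$ its
area in the reference state, and ASP an atomic solvation parameter in
cal mol^-1^ A^-2^. The output sign is flipped relative to the raw
transfer-energy convention (recorded in the metadata as
`signConvention = "negative = stabilizing"`) so that burying hydrophobic
surface is negative/stabilizing and burying charged surface is
positive/destabilizing — the direction that makes fibril-core residues red
and solvent-exposed ones blue in the usual map colouring. A per-residue
ordering-entropy penalty (kcal mol^-1^, always $\ge 0$) is added to each
scored residue; the chain total is *exactly* the sum of atom energies plus
entropy penalties, and the reported per-structure figure is the mean over
the two protofilament chains of a C2 fibril.

Assumptions worth stating plainly: the model is a surface-area model — no
electrostatics, no force field, no conformational sampling; energies are
only meaningful relative to the declared reference state and parameter
tables; and the entropy term is a per-residue constant, not a
rotatable-bond count.

## Parameter tables

* **ASP table** (`aspTable()`): five heavy-atom classes (C, neutral N/O,
  charged O^-^, charged N^+^, S) with the Eisenberg–McLachlan scale
  (+16, −6, −24, −50, +21 cal mol^-1^ A^-2^). The table ships as an editable
  TSV and its identity is stamped into every result.
* **Entropy table** (`entropyTable()`): per-residue side-chain ordering
  penalties on a conventional T·dS-at-300-K scale (Gly/Ala 0 up to Arg
  ~2.6 kcal mol^-1^), also an editable TSV, with an off-switch
  (`includeEntropy = FALSE`) to isolate the surface term.
* **Charge classes** (`classifyAtoms()`): a deterministic heavy-atom rule,
  no pKa calculation. Asp/Glu carboxylate oxygens and OXT are always O^-^.
  Lys NZ and Arg NH1/NH2/NE are N^+^ under the default
  `protonation = "lys-arg"` (physiological pH); His ND1/NE2 join only under
  `"all"`; `"none"` neutralizes everything. The rule is intentionally
  crude — it trades accuracy at unusual pH for bit-reproducibility.

## Reference state

`referenceSasa()` offers two conventions. The default, `extended-rebuild`,
re-poses the chain with ideal extended dihedrals
($\varphi=-120^\circ,\ \psi=120^\circ,\ \omega=180^\circ$), rebuilding the
backbone by NeRF chain extension and carrying each residue's side chain
rigidly on its local (N, CA, C) frame; carbonyl oxygens are idealized.
`isolated-chain` simply strips all other chains. The two differ whenever the
folded chain is compact; both are exposed because the printed per-chain
energies of the original analysis are sensitive to this unstated convention.
Residues that cannot be rebuilt (missing backbone atoms) fall back to
isolated-chain areas and are listed in the result.

## SASA engine

Shrake–Rupley with deterministic Fibonacci-lattice sphere points (no RNG, so
results are bit-reproducible), probe 1.4 A, 960 points per atom by default,
hydrogens ignored (parameter tables are heavy-atom-typed), one declared
Bondi-type radius set (`vdwRadii()`). Numerical accuracy: an isolated sphere
is exact by construction; against the analytic two-sphere cap formula the
engine is within 0.5% at 960 points on a half-Angstrom grid of separations,
while the worst case between grid points is ~0.8% — the quantization floor of
a 960-point indicator quadrature; at 3840 points the error drops below 0.3%.
Tests assert the declared-grid bound and the 960-vs-3840 convergence rather
than an unattainable uniform bound.

# Ligand occupancy from density maps

The estimator applies three masks to the map and computes

$$\mathrm{occupancy}=\frac{\max(\mathrm{site})-\overline{\mathrm{solvent}}}
{\max(\mathrm{reference})-\overline{\mathrm{solvent}}},$$

with site = voxels within 2 A of the ligand atoms, reference = within 2 A of
backbone atoms of a ligand-free segment (residues 345–352 of the tau core in
the original analysis), and solvent = a 6–12 A shell around the whole model.
"max" is the literal maximum voxel (a trimmed quantile maximum is available
for noisy maps, off by default). The estimate is unclamped, reported with its
three intermediate statistics, and invariant to affine rescaling of the map.
Two open conventions were decided here: the solvent mask is a *shell* (not
the whole non-model volume), keeping it clear of both model density and box
edges; and all four backbone atoms (N, CA, C, O) enter the reference mask.
Both are configurable, so their sensitivity is directly reportable.

`readMap()`/`writeMap()` implement MRC2014 mode-2 directly (axis-order
normalization, ORIGIN/nstart conventions, orthogonal cells only), since no
installed R package reads MRC. `realSpaceCC()` compares observed density to
a Gaussian-atom simulation (one isotropic Gaussian per heavy atom,
$\sigma=\mathrm{resolution}/3$, amplitude $\propto$ atomic number) over a
mask — the fit metric used in multi-pose comparison.

# Interface metrics

* **Buried area**: receptor-side by default (SASA of the receptor alone
  minus in-complex), matching the "area buried on the fibril surface"
  convention; ligand-side and the exact average are available. With a ligand
  column, passing one copy buries it against both fibril and axial ligand
  neighbours.
* **Hydrogen bonds**: N/O pairs across two selections, different residues,
  heavy-atom distance $\le$ 3.5 A; a D–H...A angle $\ge 120^\circ$ is
  enforced only when explicit hydrogens exist (deposited heavy-atom models
  have none). Roles are evaluated both ways, so the result is symmetric in
  the selections.
* **Stacking profiles**: ligand copies are ordered along the fibril axis;
  per adjacent pair the all-atom centroid separation, least-squares
  plane-plane tilt, and per-ring solvent-face vs fibril-face edge
  separations are reported. Edge atoms are picked by projection onto the
  solvent direction (axis -> column centroid, perpendicular to the axis)
  with a name-ordered tie-break, which makes the profile invariant under
  rigid transforms of the whole structure. A curved stack shows
  solvent-face < spacing < fibril-face.
* **Pose comparison**: per pose, masked correlation (when a map is given),
  buried area, H-bond count, clash count (heavy-atom pairs closer than
  0.6 x radius sum) and a *simplified* complementarity score — the fraction
  of the ligand's exposed vdW-surface points whose gap to the receptor
  surface lies in [0, 1] A. This is deliberately not the Lawrence–Colman Sc
  statistic and is labelled non-canonical. Ranking is lexicographic
  (correlation, buried area, H-bonds, clashes, complementarity) and the rule
  string is recorded in the output; a pose whose simulated density misses
  the mask entirely is ranked worst rather than erroring.

# Inter-layer spacing

`spacingProfile()` measures, per residue, the distance between equivalent
C-alpha atoms in adjacent layers of the same protofilament, aggregated over
layer pairs, protofilaments and frames (multi-model ensembles are lists of
structures; trajectory parsing is upstream). The default metric is the
Euclidean C-alpha–C-alpha distance — the physical separation between stacked
chains. Note a geometric subtlety: with a non-zero twist the Euclidean
distance exceeds the rise by the chord the twist sweeps at the residue's
radius, so only the `"axial"` projection mode recovers the rise exactly for
twisted fibrils; at the synthetic default (−1.2°/layer, compact chains) the
Euclidean profile stays within ~0.06 A of the rise. Both the per-residue
mean and the maximum are emitted because a hinge displacing a single layer
pair dilutes the mean over all pairs while the maximum keeps the full ~9 A
signature. `perturbationProfile()` differences two profiles, propagates
spreads in quadrature, and reports the argmax residue.

# Screen ranking

Scores are standardized per engine (z = (score − mean)/sd; lower = stronger
for both engines); the consensus is the unweighted mean of available engine
z-scores (the fusion rule was not stated by the original screen, so both
per-engine and consensus values are kept); ranking is ascending with
lexicographic compound-ID tie-break; hits are compounds at or below a
z-threshold (−2 by default, i.e. predicted to bind more than two standard
deviations stronger than the average compound), optionally truncated to a
top-N. Docking boxes derive from the bound-ligand centroid with shipped
default extents of 20 x 16 x 12 A (Vina-style) or a 7 A edge
(Rosetta-style); an explicit padding switches to a bounding-box rule.

# The synthetic generator: what it emulates and what it does not

`fixtureSpec()` fixes the study conditions: 5 layers x 2 C2-related
protofilaments (10 chains), rise 4.8 A, twist −1.2°/layer (a typical
PHF-scale fixture convention — the PHF twist is not printed in the source
analyses), chains of 11 residues numbered 338–348 around the
inter-protofilament cleft. Templates are poly-Ala, poly-Gly, a "cleft"
variant placing Glu338/Lys340/Ser341/Glu342/Lys343 (the charged residues
lining the EGCG site) or a user sequence; chains are ideal extended strands
built with the same NeRF machinery as the reference rebuild. The mock ligand
is a rigid planar tri-ring scaffold (A/C/D-analog hexagons plus exocyclic
hydroxyl oxygens) with no chemistry beyond geometry; its default anchor sits
in the cleft in polar contact with both protofilaments and clash-free.
Curved-stack fixtures place copies on a circular arc whose centre lies
beyond the solvent edge, hitting a requested solvent-face separation (3.5 A
reproduces the van-der-Waals-contact compression) while widening the
fibril face.

Maps are Gaussian-atom fields. The ligand's full-occupancy amplitude is
calibrated so its site peak equals the protein reference peak — exactly the
normalization the occupancy formula assumes — and is then scaled by
`ligandFraction`, which thereby *is* the ground-truth occupancy. Occupancy
recovery is tested with the column offset ~6 A from the protein: at the
tight cleft anchor, protein density inside the site mask inflates
low-occupancy estimates, which mirrors a real limitation of the estimator on
crowded sites rather than a generator defect. Map noise is i.i.d. Gaussian
per voxel; cryoEM noise correlation is deliberately not modelled (the
formula uses only max/mean statistics). The generator does **not** emulate
the real tau C-shape fold, atomic B-factors, or projection-image formation —
so passing tests demonstrate correctness of the *computations*, not that the
shipped parameter tables reproduce any particular deposited structure's
absolute energies.

The screen-score generator draws background compounds from a truncated
normal (|z| < 1.8 before planting) so the five planted strong binders at
z ≈ −3 are unambiguous ground truth for every seed; a positive-control
compound is placed 2.5 sd below the mean.

# Numerical choices and degenerate inputs

* All generator outputs are pure functions of the spec including its seed;
  the only RNG uses are map noise and screen scores, both drawn under
  `withr::with_seed`.
* Layer assignment estimates the axis as the direction minimizing each
  chain's own axial extent (chains lie in the layer plane), clusters axial
  centroids with a 1 A gap rule, and propagates protofilament labels by
  nearest-azimuth matching layer to layer (robust to small twist). A chain
  whose *backbone* spans more than 1.5 rises is an ambiguity error; side
  chains may legitimately reach neighbouring layers.
* Helical expansion mints single-character chain IDs deterministically in
  layer-major order, so PDB round-trips preserve identity.
* Degenerate cases error loudly: empty masks, site/reference overlap,
  reference max at or below the solvent mean, constant density in a
  correlation mask, zero score variance per engine, fewer than three layers
  for a stability map, fewer than two ligand copies for a stack.
* Problem sizes throughout the tests and the acceptance script (10-chain,
  11-residue fibrils; ~300k-voxel maps; 106-compound tables) were chosen so
  every quantity is exercised end-to-end in seconds while leaving the
  geometry large enough that burial, masking and clustering are non-trivial.

# Known limitations

* Absolute solvation energies depend on the unprinted ASP/entropy
  conventions of the original analysis; reproduction of its per-chain
  figures is therefore a tolerance question, and this package exposes every
  knob (tables, reference mode, protonation, entropy switch) rather than
  asserting one bit-exact path.
* The occupancy estimator inherits the formula's assumptions: a reference
  segment at full occupancy, comparable peak shapes at site and reference,
  and a solvent region representative of the noise floor.
* mmCIF writing is a minimal canonical-column `atom_site` loop; exotic
  categories are not preserved. Non-orthogonal map cells are rejected.
* The complementarity score is a documented stand-in, not Lawrence–Colman
  Sc; the EGCG ring-definition data file uses a generic flavan-3-ol-gallate
  naming convention that must be checked against the chemical component
  entry of the model in hand.
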