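---
title: "ligdyn: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ligdyn: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligdyn)
```

ligdyn characterises a protein–ligand complex from two kinds of input: a
docking ensemble (per-model scores and ligand RMSD to a reference pose)
and MD trajectory frames bound to an annotated topology. This vignette
explains the models behind each stage, the parameters that matter and
their defaults, what the synthetic-data generators emulate (and what they
deliberately do not), and the numerical choices that were genuinely open.

## Conventions

Coordinates are in Ångström throughout; energies carry whatever unit the
input score or decomposition column carries (Rosetta-style score units
for docking, kcal/mol for decomposition tables). Atom indices are
1-based, the natural convention in R; residue numbers are never renumbered
— an atom is matched by (chain, resid, name), so author numbering such as
"E226" survives round-trips. Trajectory interchange is multi-model PDB
(every MD engine can export it), with chemistry — donor/acceptor flags,
charged-group membership, nonpolar carbons, ring definitions, van der
Waals radii — supplied as a TSV sidecar rather than inferred from
force-field files. Unannotated atoms fall back to Bondi radii and carry
no flags; the package never infers protonation or chemistry from
geometry, so the flag assignments are the user's statement of the system
at their chosen pH.

## The docking funnel and Pnear

A well-behaved docking campaign concentrates its low-energy models near
the binding pose: plotted as energy vs RMSD-to-reference, the cloud forms
a funnel. Pnear summarises this in [0, 1]:

$$P_{near} = \frac{\sum_i e^{-RMSD_i^2/\lambda^2}\, e^{-E_i/k_BT}}
                  {\sum_j e^{-E_j/k_BT}}$$

λ (default 1.5 Å) sets how far from the reference pose a model still
counts as "near-native"; k~B~T (default 0.62, in the units of the energy
column) sets how quickly high-energy models lose weight. Both defaults
are the values conventional for Rosetta-style docking funnels. Pnear is
invariant to adding a constant to all energies; the implementation shifts
energies by their minimum before exponentiation so that deeply negative
scores cannot overflow, and the test suite checks the shifted evaluation
against plain unshifted summation to 1e-10. Two-stage model selection
(default: 1,000 lowest total scores, then 10 lowest interface scores)
breaks ties by score then model id, so the output is independent of input
row order. The reference pose is the lowest-interface-score model.

The energy entering Pnear is the interface (binding) score by default —
the quantity plotted against ligand RMSD in a docking-funnel figure —
with the total score available as an option. The RMSD is the
*unsuperimposed* ligand RMSD: the complex frames are already in a common
receptor frame after docking, and superimposing the ligand would erase
the binding-mode displacement being measured.

## Interaction fingerprints

Detectors are purely geometric, per frame, with cpptraj-style cutoffs:

* hydrogen bond: donor–acceptor heavy-atom distance ≤ 3.0 Å **and**
  D–H···A angle (vertex at the hydrogen) ≥ 135° for at least one
  hydrogen bonded to the donor. Explicit hydrogens are required; a donor
  without a bonded hydrogen is skipped with a warning rather than
  guessed.
* salt bridge: any cation-group atom within 4.0 Å of an anion-group
  atom, reported at residue/moiety granularity. When reproducing a
  specific complex, restrict the selections to the charged residues of
  interest; the detector itself places no restriction beyond the flags.
* hydrophobic contact: any nonpolar protein atom of a residue within
  4.0 Å of a ligand nonpolar carbon.
* π-stacking over ring systems (rings sharing two or more atoms are
  fused, so an indole counts as one 9-atom system): face-to-face needs
  minimum heavy-atom distance < 4 Å, centroid distance < 5 Å and a
  ring-normal angle in [0°, 45°] ∪ [135°, 180°]; edge-to-face needs the
  distance criterion and a normal angle in (45°, 135°). Because a plane
  normal has no preferred sign, the implementation folds the angle to
  [0°, 90°] and tests ≤ 45° vs > 45°, which is equivalent and makes the
  two classes mutually exclusive by construction.

Boundary conventions follow the wording of each criterion: the hydrogen
bond, salt bridge and hydrophobic distances are inclusive (≤), the
π-stacking distances strict (<). The ring "centre of mass" is implemented
as the unweighted centroid — ring atoms (C, N, O) have near-equal masses,
so the difference is well below the 1 Å scale of the criteria — and the
ring normal is the least-squares plane normal via SVD, which remains
well-defined for puckered rings such as riboses.

Persistence is the fraction of frames in which an interaction is
present, exactly `mean(occupancy)`. Reporting filters are *strict*
inequalities: hydrogen bonds and salt bridges are kept above 25% of the
simulation time, π-stacks above 20%; an interaction at exactly the
threshold is dropped. Replicate averaging matches interactions by (kind,
partner, partner) and zero-fills replicates where an interaction was
never seen, flagging the row. Whether the persistence threshold should
apply per replicate before averaging or after is genuinely open; the
package applies it after averaging by default (a contact seen at 30%,
20%, 28% across replicates averages to 26% and is reported), and
`persistence_filter()` can equally be applied per replicate first.

## Pocket volume

The grid algorithm mirrors the POVME family: an axis-aligned lattice
covering user-supplied inclusion spheres (anchored at the bounding-box
minimum corner, so the grid is deterministic), seed points inside seed
spheres or within one grid spacing of a ligand atom, growth of the seed
set by points within 3.0 Å of the current region iterated to closure,
then removal of every point closer to a protein heavy atom than that
atom's van der Waals radius + 1.09 Å (a hydrogen-bond length). Volume =
retained points × spacing³.

The default spacing is 1.0 Å. A 0.1 Å grid — the spacing sometimes
quoted for this algorithm — costs 1,000× more points for the same site
and is only worthwhile for publication-grade absolute volumes; it is
accepted via `grid_spacing` but not the default. What matters is that
the estimate converges: on a synthetic spherical cavity of radius 4 Å
(analytic volume 268.1 Å³) the relative error falls from 4.4% at 1.0 Å
through 1.7% at 0.5 Å to under 0.5% at 0.25–0.2 Å, and the test suite
asserts this convergence. Growth is iterated to closure because a single
"up to 3 Å" dilation is ambiguous when the seed region is small;
`single_expansion = TRUE` reproduces the one-shot dilation. Hydrogens
are excluded from the exclusion test by default (the algorithm's
convention operates on heavy atoms). The convex-hull option — clipping
grown points to the hull of the seed set, membership tested by Gilbert's
projection algorithm so no external hull library is needed — is
implemented but off by default, the conventional setting when comparing
bound and unbound systems with identical spheres.

## Essential dynamics

Frames from one or more ensembles are concatenated, each frame is
least-squares fitted (Kabsch, proper rotations only) onto the **first
frame of the concatenation** over the Cα selection, and the 3N×3N
covariance of positional fluctuations about the concatenated mean is
diagonalised. Projections are computed per source ensemble onto the
shared eigenbasis, so unbound and bound states can be compared in one
essential subspace. No mass weighting is applied — on a Cα-only
selection it is immaterial. The first-frame fit reference is the
documented default (with `reference = "mean"` as an option); eigenvector
signs are fixed by making each column's largest-magnitude element
positive, since the sign is mathematically arbitrary but determinism is
needed for reproducible output.

The KDE basin map evaluates a 2D Gaussian kernel density over the
(PC1, PC2) projections per ensemble and pooled (both are emitted, since
either convention is defensible), with the normal-reference (Scott-type)
bandwidth and a 128×128 grid padded by three bandwidths. Local density
maxima below 10% of the global maximum are suppressed: they are
sampling-tail bumps, not populated conformational basins. Motion
reconstruction along a component interpolates mean + t·eigenvector
between the two extreme projection values; porcupine vectors are the
per-atom eigenvector pattern scaled by the projection sweep.

## Conformational states

DBSCAN runs on the all-to-all superposed-RMSD matrix with eps = 1.0 Å
and minPts = 42 as defaults. The implementation is the classic
algorithm: a frame is core when at least minPts frames (itself included,
the scikit-learn counting convention) lie within eps; clusters grow from
core points in frame order, and a border point reachable from several
clusters joins the first discovered — implementations differ here, so
the tie-break is documented and the equivalence test against an
independent core-graph reference only requires border points to join
*some* adjacent cluster. Medoids (minimum summed within-cluster RMSD)
represent clusters.

Sugar pucker uses Altona–Sundaralingam pseudorotation. For the
five-membered ring O4′-C1′-C2′-C3′-C4′ the endocyclic torsions are
indexed so that ν₀ is the C1′-C2′-C3′-C4′ torsion; the pucker model is
then ν_j = τ_m·cos(P + 144°·j), giving ν₀ = τ_m·cos P — the classical
relation placing C3′-endo near P = 18° and C2′-endo near P = 162°. P and
τ_m are recovered by the discrete Fourier inversion of the five
torsions, which is exact for torsion sets that follow the model and
least-squares for real (slightly off-model) rings. The wheel is split
into twenty 18° windows paired into the ten envelope/twist families;
rings with τ_m below 5° are reported "planar/undefined" because the
phase of a flat ring is numerically meaningless. Cremer–Pople puckering
coordinates would be the natural alternative; pseudorotation was chosen
because it is the standard furanose convention and its phase windows map
directly onto the conformer names used for nucleotides.

## Energy-decomposition aggregation

The package aggregates per-residue binding free energy decompositions
(e.g. MM/GBSA per-residue tables) across replicate trajectories: mean
and SD per residue, residues present in only some replicates kept with a
warning, and the report filtered to |mean| > kT with kT = 0.6 kcal/mol
(thermal energy at 300 K) — contributions below thermal noise are not
meaningful. At the complex level, `check_decomposition_components()`
enforces the bookkeeping identities ΔG_gas = ΔE_ele + ΔE_vdw,
ΔG_sol = ΔG_pol + ΔG_np and ΔG_bind = ΔG_gas + ΔG_sol within
0.2 kcal/mol. Computing the underlying GB energies is explicitly out of
scope: the inputs are tables, not structures.

## What the synthetic generators emulate

Each generator produces data *plus the exact quantity its consumer
estimates*, so recovery is testable end to end:

* `gen_two_domain_protein`: two rigid Cα-bead domains displacing along
  one or two planted collective modes (an inter-domain clamping pattern
  along the separation axis and a transverse shear) with prescribed
  variances — 9 and 4 Å² by default, a dominant-plus-secondary mode
  structure typical of hinge motions — plus isotropic Gaussian jitter.
  The planted modes are projected orthogonal to the six rigid-body
  modes, so superposition cannot absorb them. The jitter default is
  σ = 0.02 Å per coordinate: its total variance 3Nσ² (0.072 Å² over 60
  beads) must remain a negligible perturbation next to the smallest
  planted variance, or it would visibly dilute the variance fractions
  the analysis is supposed to recover.
* `gen_interaction_system`: one pair per interaction kind, placed inside
  its geometric criteria with per-frame probability equal to the
  scheduled occupancy and far beyond the cutoff otherwise, in spatial
  zones 60 Å apart so pairs cannot cross-talk; the realised Bernoulli
  fractions are returned, so detector persistence must match them
  *exactly*.
* `gen_cavity_system`: a spherical shell of carbon pseudo-atoms at
  radius r + 2.79 Å, so the vdW + 1.09 Å exclusion carves the reachable
  region down to exactly the cavity radius r. The shell surface spacing
  (default 0.45 Å) comes from the coverage bound ε₀ = (d/2)²/(2·2.79 Å):
  a grid point just outside the cavity escapes removal only if it slips
  between shell atoms, and at d = 0.45 Å the leak band is ~0.009 Å —
  far below grid discretisation error. An optional two-state radius
  schedule emulates pocket breathing between a wide and a narrow state.
* `gen_funnel_scores`: near-native models (RMSD ~ |N(0, 0.2 Å)|,
  energies lowered by `funnel_depth`) mixed with decoys (RMSD
  2 + Exp(scale) Å); the ground-truth Pnear is evaluated directly from
  the sampled points by plain summation, independent of the pipeline
  code path.
* `gen_furanose`: ring coordinates are found by BFGS refinement of a
  planar-pentagon start against the five target torsions with soft
  bond-length (1.54 Å) and bond-angle restraints; the fit must close
  within 0.3° or it errors. The generator-analyzer round trip closes
  within 0.5° over the full 0–360° phase sweep.

What the generators do **not** emulate: force-field energetics, solvent,
correlated thermal motion, sequence realism, or anharmonic mode
coupling. Passing tests therefore demonstrate that the *analysis layer*
is correct — detectors match their definitions, estimators recover
planted parameters, volumes converge to analytic values — not that any
particular biological system behaves this way. Real trajectories bring
overlapping interactions, partial occupancies correlated in time, and
non-Gaussian mode amplitudes that these tests deliberately exclude.

## Numerical choices and degenerate inputs

Kabsch superposition rejects fit sets with fewer than three atoms or
with collinear geometry (second singular value below 1e-8 of the first)
instead of returning an arbitrary rotation; reflections are excluded by
the determinant correction. RMSF uses the trajectory mean structure as
reference (initial first-frame alignment, then one refit onto the mean)
— the standard convention where mean vs first-frame is not otherwise
specified. The pairwise-RMSD matrix is computed exactly once per
unordered pair and mirrored, so it is symmetric to machine precision
with an exactly zero diagonal. Score-table rows with non-numeric entries
are dropped with a counted warning, never silently. Grid configurations
that would exceed 10⁸ points are refused with advice to coarsen the
spacing. Zero-variance PCA components cannot be animated and
zero-variance projections cannot be KDE-mapped; both error explicitly.

## Problem sizes

The shipped analyses and tests run on deliberately modest sizes — 60-bead
proteins, 50–5,000 frames, 500–20,000 docking models, cavities of 3–4.5 Å
radius on 0.2–1.0 Å grids — chosen so every ground-truth recovery is
statistically decisive (e.g. 5,000 frames put the sampling error of a
variance estimate near 2%) while the whole suite stays desk-scale. All
stages accept arbitrarily larger inputs; the pairwise-RMSD and clustering
stages expose `stride` for trajectories where the quadratic frame-pair
cost bites.

## Known limitations

* Hydrogen-bond detection requires explicit hydrogens and topology
  bonds; there is no hydrogen placement or bond perception.
* The annotation sidecar is trusted as given: wrong flags produce wrong
  fingerprints, by design (engine-agnosticism over inference).
* Pnear's energy scale k~B~T = 0.62 is treated as dimensionless-compatible
  with whatever unit the score column carries; no unit conversion is
  attempted.
* The convex-hull pocket option clips to the hull of the seed set; with
  ligand-derived seeding the hull follows the ligand conformation of
  each frame.
* DBSCAN border-point assignment is order-dependent by construction
  (first-discovered cluster); partitions of core points and the noise
  set are order-invariant, and the tests assert exactly that.
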