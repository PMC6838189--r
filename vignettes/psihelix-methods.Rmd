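---
title: "Methods: geometry, hydration and stacking energetics of pseudouridine-modified RNA duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, hydration and stacking energetics of pseudouridine-modified RNA duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psihelix)
```

## Scope and scientific background

Pseudouridine (Ψ) is the most abundant post-transcriptional RNA
modification: an isomer of uridine in which the base is attached to the
ribose through a carbon–carbon bond (C1′–C5) rather than the usual
N-glycosidic bond (C1′–N1).  The Watson–Crick face is unchanged, but the
liberated N1 carries an extra imino proton (HN1) that points into the major
groove, where it can coordinate structural water.  In double helices the
modification stabilizes the duplex thermodynamically, by an amount that
depends on the identity of the flanking base pairs.

`psihelix` implements, as a reusable and fully tested pipeline, the three
analysis families used to dissect that sequence dependence on short RNA
duplexes with one internal Ψ–A pair:

* **conformational geometry** — superposition RMSD/RMSF, glycosidic
  torsions, sugar pseudorotation, rigid-body base-pair/step parameters,
  interatomic distance series, iRED order parameters, average-linkage
  clustering;
* **hydration statistics** — geometric hydrogen-bond detection, single- and
  two-water bridge occupancies and lifetimes, radial distribution
  functions, water occupancy grids;
* **stacking energetics** — pairwise molecular-mechanics base–base
  energies, the four-base step decomposition, U→Ψ substitution deltas for
  the eight unique steps around a central Ψ–A pair, and the additive
  sixteen-motif trinucleotide predictor, plus export of capped tetramer
  geometries for external quantum-chemistry software.

Because production molecular-dynamics trajectories are neither
redistributable nor recomputable at desk scale, every input the analyses
need is generated by the synthetic-structure module: idealized A-form
duplexes for the eight studied sequences, Gaussian pseudo-trajectories, and
explicit water placements with the statistical structure the analyses are
designed to detect.  The generator and the detectors are deliberately
closed-loop: a bridge constructed at occupancy *f* must be recovered by the
occupancy machinery at exactly *f* when no jitter is added.

## The duplex set

Eight 9-mer duplexes are built in: the four modified ones with central
motifs 5′-GΨC, CΨG, AΨU and UΨA (Ψ always at strand-1 position 5, paired
with A14) and their unmodified counterparts.  Residues are numbered 1–9
along strand 1 and 10–18 along strand 2, each 5′→3′, so strand-1 residue
*i* pairs with residue 19 − *i*.

```{r}
topo <- duplex_preset("CPG")
topo
```

## A-form construction

Each base is an idealized planar geometry built from survey bond lengths
and angles, placed in the standard base-pair reference frame: C1′ at
(−2.479, 5.346, 0) so that the paired C1′–C1′ distance is 10.69 Å, with
the glycosidic bond at a fixed angle λ = 54.5° to the C1′–C1′ line.  A
small per-base in-plane rotation (≤ 5°), calibrated once against ideal
Watson–Crick donor–acceptor distances, compensates the idealized ring
geometry; the resulting hydrogen bonds fall at 2.84–2.94 Å.

The pairing partner is the template rotated 180° about the frame's x axis.
Pair *i* is then placed by the helical screw with twist 32.7°/bp and rise
2.81 Å/bp (classic A-RNA fiber values), displaced −4.4 Å along x.
Inclination defaults to 0°, i.e. the helix axis is normal to the base
planes.  This is a deliberate simplification: in this simple per-pair screw
model a non-zero inclination tilts successive pairs about rotated axes and
drives their edges into contact, whereas the untilted ladder keeps every
step's local geometry identical and lets the step-parameter machinery
recover the construction values exactly.  The cost is a perpendicular
stacking separation equal to the rise (2.81 Å), about 0.5 Å tighter than
real A-RNA — see *Limitations*.

Sugars are built at pseudorotation phase 11° and amplitude 42° (the values
typical of well-refined A-RNA solution ensembles) by a deterministic
least-squares closure of the five ring bonds and five endocyclic torsions.
Glycosidic torsions are anti: χ = 205° for the standard residues and 195°
for Ψ, the ~10° low-anti shift characteristic of the C-glycoside.
Pseudouridine is incorporated exactly as a rearrangement of the uridine
ring: the C1′ anchor is unchanged, the ring attaches through C5, HN1
appears on N1, and H5 disappears.  A consequence worth stating explicitly:
with the sugar on C5, ring connectivity forces the C2 carbonyl (O2) into
the Watson–Crick position that O4 occupies in uridine, while O4 faces the
minor groove and HN1 takes the major-groove corner that H5 occupies in U —
which is precisely why HN1 sits near its own backbone OP2.

The phosphodiester arm is first built per nucleotide from canonical A-form
internal coordinates (β 178°, γ 54°, δ 82°), then a deterministic
refinement re-places each O5′–P arm so the phosphate truly bridges C5′(i)
and O3′(i−1) at bond geometry without steric overlap; α/γ/ζ of the final
model are therefore emergent closure values.  In the default build the
imino proton ends up 4.2 Å from its own OP2 and 6.6 Å from the
5′-neighbouring OP2 — inside the ranges reported for Ψ-containing helices
(and too far, by > 1 Å, for a single water to bridge HN1 and OP2(5′)
directly, which is exactly the geometric situation the two-water chain
resolves).

```{r}
frame <- build_aform_duplex(topo)
c1c1_distances(frame, topo)$mean
glycosidic_chi(frame, 5)    # pseudouridine
pseudorotation(frame, 5)
```

## Pseudo-dynamics

Thermal motion is emulated by i.i.d. isotropic Gaussian displacements of
every atom (default σ = 0.15 Å, 10 ps frame spacing, 200 frames for the
desk-scale study).  This is *not* molecular dynamics, and it is chosen
deliberately: every downstream statistic validated against a closed form
(RMSD and RMSF → σ√3, order-parameter limits, occupancy counting) has an
exact expectation under this model.  What the model does **not** emulate:

* collective motions — there is no correlation between atoms, so
  bond-vector order parameters are *lower* than in a stable duplex (the
  C1′–H1′ S² comes out ≈ 0.8 at σ = 0.15 rather than the > 0.87 seen for
  internal residues in stable helices), and internal coordinates such as
  the sugar pucker fluctuate more than real ensembles do;
* sequence-dependent flexibility — all residues fluctuate identically, so
  modified-vs-unmodified RMSF differences are not reproduced;
* thermodynamics of any kind.

Passing tests therefore demonstrate correctness of the estimators, not
realism of the motions.

## Hydrogen bonds, bridges and hydration

A donor–H···acceptor triple is a hydrogen bond when the donor–acceptor
distance is ≤ 3.0 Å and the donor–H–acceptor angle is ≥ 135° (both
parameters adjustable via `hbond_criteria()`).  Water oxygen accepts, water
hydrogens donate, phosphate OP1/OP2 only accept, and HN1 donates through
N1.  A single-water bridge between two sites exists in a frame when one
water is simultaneously hydrogen-bonded to both; a two-water chain requires
water₁ bonded to site A, water₂ to site B, and water₁–water₂ bonded.
Occupancy is the percentage of bridged frames (water identity free to
change); lifetimes are mean maximal runs of consecutive bonded frames times
the frame spacing, with zero gap tolerance.

The generator places the intra-residue bridge (W accepting from HN1 and
donating to OP2 of Ψ5) and optionally the second water hydrogen-bonded to
OP2 of residue 4, in an exact fraction of frames — the default study
fraction is 0.28, the observed occupancy of that bridge in the reference
simulations.  RDF profiles use 0.05 Å bins by default with exact shell
volumes, normalized by the box density when a box is present and
self-normalized by the far-shell mean otherwise (the mode is recorded in
the result).  Water occupancy grids (default 0.5 Å voxels) report the
per-voxel fraction of frames containing a water oxygen and support
modified-minus-reference difference maps, written as OpenDX text.

```{r}
wt <- place_bridge_waters(frame, "two_water_chain", residue = 5,
                          n_frames = 100, occupancy_fraction = 0.28,
                          seed = 1)
bridge_occupancy(wt, c(5, "HN1"), c(5, "OP2"))
bridge_occupancy(wt, c(5, "HN1"), c(4, "OP2"), chain_order = 2)
```

## Geometry conventions

* **Superposition** is the Kabsch SVD solution; the test suite checks it
  against an independent quaternion (Horn) implementation to 10⁻⁸.
* **Ensemble RMSD**: for multi-model ensembles the summary is the maximum
  over models of the RMSD to the iterated ensemble-average structure
  (heavy atoms).  Other conventions exist (e.g. maximum pairwise RMSD);
  this one is fixed and stated here because deposited-ensemble statistics
  depend on it.
* **Base-pair/step parameters** use least-squares fits of the standard base
  templates to the observed ring atoms, a symmetric hinge onto the common
  z axis and the mid-frame construction (the CEHS-style scheme).  Buckle /
  propeller / opening are the rotations about the pair mid-frame x / y / z
  axes; tilt / roll / twist the analogous step rotations.  Published tools
  differ by small systematic offsets in these parameters; within-package
  comparisons are exact, and cross-tool agreement should be judged on
  trends, not digits.  Fits with RMSD > 0.5 Å flag the base as distorted.
* **Pseudorotation** follows Altona–Sundaralingam, with the quadrant
  resolved through `atan2` so C3′-endo means P ∈ [0°, 36°); when ν₂ ≈ 0
  the amplitude is recovered from ν₀ and flagged.  Ensemble summaries
  average the phase on the circle.  Note that a mirror-image sugar maps
  P → P + 180° (C3′-endo ↔ C3′-exo).
* **χ** is reported in [0°, 360°) so the anti region reads ~170–280°; for
  Ψ the torsion is O4′–C1′–C5–C4, the C-glycoside analogue of the
  standard definition.
* **iRED order parameters** diagonalize M = ⟨P₂(û·û)⟩ accumulated through
  a rank-2 tensor embedding; S² discards exactly the five largest
  eigenmodes (collective reorientation).  With n vectors the discarded
  subspace leaks ~5/n of the internal amplitude into S², so cone-model
  validations use ≥ 100 well-spread vectors; with fewer than six vectors
  iRED is undefined and the direct ⟨P₂⟩ plateau estimator is used, flagged.
* **Clustering** is `stats::hclust` average linkage on the pairwise
  heavy-atom RMSD matrix; the representative structure is the re-superposed
  mean of the most populated cluster, ties broken towards the lowest
  cluster index.

## Stacking energies

Base–base energies are strict nonbonded sums over base atoms only
(fragments severed at the glycosidic bond): Coulomb kqᵢqⱼ/r with
k = 332.0637 kcal·Å·mol⁻¹·e⁻², dielectric 1, no cutoff, plus 12-6
Lennard-Jones with Lorentz–Berthelot combining.  For a step with strand-1
bases A (5′) and B and partners D, C:

dE(step) = E(ADBC) − E(AD) − E(BC),

which under pairwise-additive mechanics equals
E(AB) + E(CD) + E(AC) + E(BD) — an identity the package verifies to 10⁻⁹
by computing the tetramer energy through an independent flat summation.
The U→Ψ delta ddE = dE(modified) − dE(unmodified) is computed per step on
representative structures (cluster representative by default), and the
sixteen trinucleotide motifs X-Ψ-Z are predicted additively from the two
constituent steps.

The bundled charge set uses the classic AMBER (Cornell-type) nucleobase
charges with parm99 Lennard-Jones classes.  The pseudouridine entries are
a clearly flagged **surrogate** (the published Ψ set is not
redistributable): uridine charges with the glycosidic role moved from N1
to C5 and HN1 shifted so the fragment's net charge matches uridine's.
Every report derived from them carries `psu_charges = "surrogate"`; a real
parameter set can be supplied via `default_forcefield(path)`.

Two consequences, stated plainly.  First, absolute stacking energies on the
untilted 2.81 Å ladder are vdW-repulsive — only differences are
meaningful, and the machinery is validated through its algebraic and oracle
properties, not through absolute values.  Second, the *ordering* of the
eight MM ddE values on these synthetic geometries does **not** reproduce
the ordering established by quantum-chemical calculations on
simulation-derived geometries (where Ψ stabilizes Ψ–purine steps by up to
−1.59 kcal/mol, most strongly 5′ΨG, and the GΨG trinucleotide most of
all).  Reproducing that ordering requires both the published Ψ charges and
realistic stacked geometries; the supported path for quantitative work is
`import_qm_energies()`, which feeds externally computed step energies into
the identical delta/trinucleotide machinery, with
`prepare_tetramer_geometry()` + `export_qm_geometry()` producing the capped
(N–H / C–H at the glycosidic position) monomer-superposed tetramers those
calculations need.

```{r}
ff <- default_forcefield()
e <- step_stacking_energy(frame, topo, 5, ff)
e
enumerate_unique_steps()$label
head(enumerate_trinucleotide_motifs())
```

## Numerical choices and degenerate inputs

* Ring closure and phosphate refinement are small deterministic
  least-squares problems (fixed multi-starts, BFGS); identical inputs give
  identical structures, and every stochastic generator derives its stream
  from one integer seed.
* Superposition rejects collinear selections; torsions reject coincident
  atoms; energies reject interatomic distances below 0.5 Å and any
  unparameterized atom, listing it.
* RDF self-normalization falls back to raw counts (mode
  `"unnormalized-counts"`) when no far-shell population exists.
* 5′-terminal residues carry no phosphate: backbone RMSF uses the available
  subset and flags the row `"partial"`.
* Water placement retries are bounded; an infeasible solvation request
  fails rather than looping.

## Desk-scale study sizes

The default `analysis_config()` uses 200 frames per duplex at σ = 0.15 Å,
0.28 constructed bridge occupancy, 0.05 Å RDF bins and single-cluster
representatives; `run_study()` over all four duplex pairs completes in
well under a minute, and the validation suite's largest constructions
(10⁴ bulk waters × 100 frames for RDF flatness; 250 bond vectors × 10⁴
frames for the cone model; 1000-frame bridge recovery) were sized to keep
each check comfortably within interactive runtimes while leaving the
sampling error several times smaller than the tolerance being asserted.

## Known limitations

* The untilted screw places base planes 2.81 Å apart — tighter than real
  A-RNA stacking (≈ 3.3 Å); absolute vdW stacking terms are repulsive.
* Uncorrelated Gaussian noise exaggerates internal-coordinate spread
  (pucker, bond vectors) relative to real ensembles of the same RMSD; the
  synthetic solution-ensemble stand-in therefore uses a small σ (0.03 Å).
* The surrogate Ψ charges reproduce uridine's fragment charge but not the
  published charge distribution; MM ddE *orderings* on synthetic geometry
  are not meaningful (see above).
* A handful of idealized contacts are tighter than reality (e.g.
  H2′(i)···O5′(i+1) ≈ 1.6 Å); no analysis in the package consumes those
  atoms.
* Sequence-dependent roll/opening differences are not emulated: the
  generator's local geometry is sequence-independent by construction.
* RDFs use no periodic imaging; boxes are metadata for density
  normalization only.
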