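# psihelix

Structure, hydration and stacking-energy analysis of RNA duplexes carrying
an internal pseudouridine–adenosine base pair.

Pseudouridine (Ψ) is the most abundant RNA modification: uridine
re-attached to its ribose through a C1′–C5 carbon–carbon bond. Its
Watson–Crick face is unchanged, but the liberated N1–H imino proton points
into the major groove, coordinates structural water, and the modification
stabilizes double helices by an amount that depends on the flanking base
pairs. `psihelix` is for structural bioinformaticians who want to quantify
that context dependence on short duplexes: it builds all-atom idealized
A-form models of 9-mer duplexes with a central Ψ–A (or U–A) pair,
generates pseudo-trajectories and explicit bridging-water placements, and
computes the standard observables:

* **geometry** — Kabsch superposition RMSD/RMSF, glycosidic χ
  (O4′–C1′–C5–C4 for the C-glycoside), Altona–Sundaralingam sugar
  pseudorotation, CEHS-style base-pair and step parameters
  (buckle/propeller/opening, tilt/roll/twist…), C1′–C1′ and P–P distance
  series, iRED order parameters S² of the C1′–H1′ vectors (all but the
  five largest eigenmodes of M = ⟨P₂(ûᵢ·ûⱼ)⟩ discarded), average-linkage
  clustering;
* **hydration** — hydrogen bonds by the geometric criterion (donor–acceptor
  ≤ 3.0 Å and donor–H–acceptor ≥ 135°), single-water and two-water bridge
  occupancies and lifetimes (e.g. the intra-residue OP2(5)–W–HN1(5) bridge
  and the two-water chain to OP2 of the preceding residue), radial
  distribution functions with exact-shell normalization, water occupancy
  grids (OpenDX text output);
* **stacking energetics** — pairwise nonbonded base–base energies
  (Coulomb + 12-6 Lennard-Jones, Lorentz–Berthelot, base atoms only) and
  the four-base step decomposition
  ΔE<sub>AC,BD</sub> = E<sub>ADBC</sub> − E<sub>AD</sub> − E<sub>BC</sub>
  (= E<sub>AB</sub>+E<sub>CD</sub>+E<sub>AC</sub>+E<sub>BD</sub> under
  pairwise-additive mechanics), U→Ψ substitution deltas for the eight
  unique steps around the central pair, the additive sixteen-motif
  trinucleotide predictor, import of externally computed (quantum-chemical)
  step energies, and export of capped tetramer geometries for
  counterpoise-style calculations.

Multi-model PDB ensembles and a plain XYZ frame-list dialect are read and
written natively; pseudouridine is recognized as residue `PSU` with its
imino proton normalized to `HN1`.

## Worked example

```r
library(psihelix)

topo <- duplex_preset("CPG")      # 5'-UCACΨGAGU / 3'-AGUGACUCA
topo
#> RNA duplex topology, 9 base pairs
#>   5'-UCACΨGAGU-3'
#>   3'-AGUGACUCA-5'
#>   pseudouridine at strand-1 position(s): 5

frame <- build_aform_duplex(topo)
c1c1_distances(frame, topo)$mean        # paired C1'-C1' separation
#> [1] 10.692
glycosidic_chi(frame, 5)                # anti, low-anti for the C-glycoside
#> [1] 195
pseudorotation(frame, 5)
#> sugar pucker: P = 11.0 deg, tau_m = 42.0 deg

wt <- place_bridge_waters(frame, "two_water_chain", residue = 5,
                          n_frames = 200, occupancy_fraction = 0.28, seed = 1)
bridge_occupancy(wt, c(5, "HN1"), c(5, "OP2"))
#> OP2(5)-W-HN1(5): occupancy 28.0% over 200 frames, mean lifetime 0.016 ns (chain order 1)
bridge_occupancy(wt, c(5, "HN1"), c(4, "OP2"), chain_order = 2)
#> OP2(4)-W-HN1(5): occupancy 28.0% over 200 frames, mean lifetime 0.016 ns (chain order 2)
```

The first result is the construction's paired C1′–C1′ distance (10.69 Å,
the A-form value fixed by the standard base reference frame); χ = 195°
shows the ~10° low-anti shift of Ψ relative to its unmodified counterpart
(205°); the sugar is C3′-endo at the configured phase/amplitude. The two
bridge reports recover, at exactly the constructed 28% of frames, the
hydration signature of pseudouridine in a helix: one water bridging HN1
and OP2 within the Ψ residue, chained through a second water to the
5′-neighbouring phosphate (HN1 sits 6.6 Å from OP2(4) here — too far for a
single water).

`run_study(analysis_config())` runs the whole desk-scale study (four
modified duplexes plus references, geometry + hydration + stacking) and
returns the consolidated tables; `validate_against_ensemble()` recomputes
ensemble statistics (mean C1′–C1′, circular-mean pucker phase, maximum
RMSD to the ensemble average, HN1–OP2 distances) for any multi-model PDB
file against configured intervals.

The bundled force-field table ships classic AMBER-type nucleobase charges;
the pseudouridine charges are a documented surrogate derived from uridine
and every energy report carries a `psu_charges = "surrogate"` flag — see
`?default_forcefield` and the methods vignette
(`vignettes/psihelix-methods.Rmd`) for what that implies and for the
imported-QM pathway used for quantitative orderings.

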