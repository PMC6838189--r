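Package: psihelix
Title: Structure, Hydration and Stacking-Energy Analysis of
    Pseudouridine-Modified RNA Duplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse short RNA double helices carrying an internal
    pseudouridine (PSU) - adenosine base pair.  The package builds idealized
    A-form duplexes with the modification incorporated as a C-glycoside,
    generates fluctuating pseudo-trajectories and explicit bridging-water
    placements, and computes the standard conformational observables
    (superposition RMSD/RMSF, glycosidic torsions, sugar pseudorotation,
    rigid-body base-pair and step parameters, iRED order parameters,
    average-linkage clustering), hydration statistics (radial distribution
    functions, hydrogen-bond detection, single- and two-water bridge
    occupancies and lifetimes, water occupancy grids), and molecular-mechanics
    base-stacking energies with the four-base step decomposition, including
    the U-to-PSU modification deltas for the eight unique steps and the
    additive sixteen-motif trinucleotide predictor.  Multi-model PDB ensembles
    and plain XYZ frame lists are read and written, and stacked tetramer
    geometries can be exported for external quantum-chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
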