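Package: oligolens
Title: Geometric Trajectory Analysis of Peptide Oligomer Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of conformational ensembles of small peptide
    oligomers (multi-model PDB trajectories) with or without bound small
    molecules. Implements geometric interaction detectors (heavy-atom
    contacts, donor-hydrogen-acceptor hydrogen bonds, aromatic pi-pi and
    CH-pi stacking geometry), Kabsch-Sander secondary-structure assignment
    mapped to six categories, Shrake-Rupley solvent-accessible surface
    area, ensemble statistics (probability densities, two-dimensional
    potentials of mean force, Daura conformational clustering,
    convergence diagnostics), and a deterministic synthetic conformer
    generator for amyloidogenic peptide octamers such as hIAPP(20-29)
    with melatonin-like ligands, so every pipeline stage is testable
    without a molecular-dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, graphics, bio3d, Rcpp, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
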