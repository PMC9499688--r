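---
title: "Geometric ensemble analysis of peptide oligomers with oligolens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric ensemble analysis of peptide oligomers with oligolens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`oligolens` analyses conformational ensembles of small peptide oligomers —
the motivating system is the octamer of the amyloidogenic core of human
islet amyloid polypeptide, hIAPP(20–29) (sequence SNNFGAILSS, acetyl- and
amide-capped), with or without melatonin-like small molecules at a 1:4
peptide:ligand molar ratio. The trajectory interchange format is
multi-model PDB; internally all lengths are nm and all free energies
kcal/mol.

Every analysis is geometric, operating on coordinates alone:

* **Contacts.** Two residues are in contact when any pair of their heavy
  (non-hydrogen) atoms comes within 0.54 nm (minimum-image convention
  under an orthorhombic box). Inter-peptide contact probability maps
  average the indicator over frames and ordered chain pairs, which
  symmetrises the (i, j)/(j, i) contributions of each unordered pair of
  identical chains.
* **Hydrogen bonds.** A donor–hydrogen–acceptor triple is a hydrogen
  bond when the donor–acceptor distance is below 0.35 nm and the D–H–A
  angle exceeds 150°. Donor/acceptor roles come from per-residue
  templates (backbone amides, Ser hydroxyl, Asn amide, the ligand's
  indole and amide N–H, carbonyl and methoxy oxygens).
* **Secondary structure.** A self-contained implementation of the
  Kabsch–Sander rules: backbone hydrogen bonds by the electrostatic
  energy model `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)`
  kcal/mol (bond when `E < −0.5`), n-turns giving G/H/I (two consecutive
  turns) or T, parallel/antiparallel bridge patterns giving B with
  ladders of length ≥ 2 giving E, bends S where the Cα(i−2)–Cα(i)–Cα(i+2)
  angle exceeds 70°, and the priority H > E > B > G > I > T > S > C.
  The eight-state code pools into the six reported categories (H, G, I →
  helix; E → β-sheet; B → β-bridge; T → turn; S → bend; else coil).
  Helix is taken to pool H/G/I since population summaries report a single
  helix class.
* **SASA.** Shrake–Rupley with a 0.14 nm water probe, Bondi radii on
  heavy atoms (C 0.170, N 0.155, O 0.152, S 0.180 nm), and a
  deterministic golden-spiral point lattice (default 960 points) so
  results are bit-reproducible. Hydrogens carry no surface. The total
  used for the free-energy landscape covers peptide heavy atoms only, so
  the axis reflects the compactness of the oligomer, not of the ligand
  shell.
* **Ensemble statistics.** 1D PDFs (Freedman–Diaconis binning, 50-bin
  fallback), 2D potentials of mean force `F = −RT ln H(x, y)` at 310 K
  (`R = 0.0019872 kcal/(mol·K)`), shifted so the minimum over populated
  bins is zero with empty bins masked (never zero-filled); Daura
  (gromos) greedy clustering on the pairwise post-fit Cα RMSD matrix at
  a 0.45 nm cutoff; and a Jensen–Shannon convergence diagnostic (base 2)
  over three observables: secondary-structure composition, end-to-end
  distance PDF and the per-frame inter-peptide main-chain H-bond count
  PDF, with a 0.05-bit default threshold.
* **Aromatic geometry.** Ring centroids and least-squares plane normals
  (smallest principal direction, sign-canonicalised to non-negative z,
  ties towards y then x, so stored normals are reproducible); interplane
  angles folded into [0°, 90°]; closest-ring pairing for stacking events
  with classification parallel ≤ 30°, herringbone ≥ 50° (common aromatic
  conventions; both thresholds configurable); CH–π distances as methyl
  carbon to ring centroid (Ile CG2/CD1, Leu CD1/CD2; the minimum is
  reported; a ring-atom variant is available via `mode = "ringatoms"`).

## Key parameters

| parameter | default | unit | role |
|---|---|---|---|
| contact cutoff | 0.54 | nm | heavy-atom contact definition |
| H-bond distance / angle | 0.35 / 150 | nm / deg | geometric H-bond |
| cluster cutoff | 0.45 | nm | Daura Cα-RMSD neighbourhood |
| SASA probe / points | 0.14 / 960 | nm / – | rolling probe, sphere lattice |
| temperature | 310 | K | PMF scale, RT = 0.61603 kcal/mol |
| stacking thresholds | 30 / 50 | deg | parallel / herringbone split |
| convergence threshold | 0.05 | bits | JSD pass criterion |

All of these are surfaced through `validateConfig()`, which applies the
defaults, rejects unknown keys with a closest-match suggestion, and
aggregates range errors.

## The synthetic-ensemble generator

Replica-exchange ensembles of this system are not reproducible at desk
scale, so `generateEnsemble()` provides a *conformer-mixture* stand-in
that the whole pipeline can be validated against. Per frame, each of the
(default 8) chains is a β-sheet-pair member, an α-helix, or a
random-coil conformer:

* sheet pairs are two in-register parallel strands at (φ, ψ) = (−125°,
  120°) separated by 0.48 nm along the sheet's hydrogen-bond direction —
  geometry tuned once so interior residues satisfy both the
  Kabsch–Sander criterion and the geometric H-bond criterion with no
  steric overlap;
* coil chains are rebuilt every frame by sampling φ ∈ (−160°, −50°), ψ ∈
  (−180°, 180°) with heavy-atom self-clash rejection (0.2 nm);
* units are packed into a cubic box (edge three times the largest unit
  extent) with a 0.45 nm inter-unit clearance, which also guarantees no
  spurious inter-unit hydrogen bonds; the box travels with every frame
  so periodic code paths are exercised;
* ligands are placed either randomly at ≥ 2 nm from every peptide atom
  (the study's initial condition) or rigidly stacked on the
  phenylalanine rings at a prescribed (angle, centroid distance);
* isotropic Gaussian noise (default σ = 0.005 nm, a realistic
  sub-Ångström thermal jitter) is added last.

**Calibration.** The state probabilities are not free parameters: the
generator measures the per-cell category yields of its own conformers
(the sheet dimer and helix under the same coordinate noise, and 200
noisy coil draws) and solves a small linear system so that the
*pipeline-measured* β-sheet and coil fractions match the requested
composition targets, e.g. 16 %/52 % for the apo octamer and 2 %/60 %
for the ligand-present conditions. Calibrating under noise matters:
edge hydrogen bonds of the sheet dimer are marginal, and noiseless
yields would overestimate the realised β fraction by several points.

**What passing tests show — and what they do not.** Target-recovery
tests demonstrate that the assignment, detection and population
machinery is self-consistent and unbiased on ensembles whose ground
truth is known by construction. They do not validate force-field
physics, sampling convergence of real simulations, or the thermodynamic
meaning of the generated mixtures; real trajectories have correlated
frames, partial secondary structure within single chains, and
side-chain rotamer diversity that the generator does not emulate.

## Numerical conventions and edge cases

* Dihedrals follow the IUPAC sign convention (verified against the
  major trajectory toolkits); built residues are L-amino acids
  (C–N–CA–CB ≈ −120°).
* Two amide-hydrogen conventions coexist deliberately. The *builder*
  places H in the sp2 amide plane (≈120° to both C(prev) and CA, trans
  to the carbonyl oxygen), the standard peptide geometry. The
  *reconstruction* operation for structures lacking hydrogens places H
  0.10 nm from N along the normalised sum of the unit vectors
  N→(away from C_prev) and N→(away from O_prev); this bisector rule is
  adequate for the distance-based Kabsch–Sander energy but tilts the H
  out of the amide plane, so geometric D–H–A angles computed from
  reconstructed hydrogens are systematically low. Explicit hydrogens are
  always preferred when present.
* Kabsch superposition excludes reflections via the determinant
  correction; collinear point sets are an error. Daura tie-breaks go to
  the lowest frame index; neighbour counts include the frame itself;
  the chain-permutation degeneracy of identical peptides is *not*
  minimised over (fixed chain order, as in the common gromos tool).
* PMF bins default to 50×50 over the sampled range padded by half a
  bin; the minimum over defined bins is exactly zero by construction.
* Zero-variance PDF input collapses to a single point-mass bin. Chains
  shorter than three residues are assigned coil throughout. Glycine has
  an empty side-chain heavy set, so its SC–SC contact rows are
  structurally zero.
* Population error bars are standard errors over five equal trajectory
  blocks (a package convention; block count configurable).
* Analyses assume pre-imaged, molecule-whole coordinates; minimum-image
  wrapping is applied to inter-molecular distance tests, not to bonded
  geometry.
* The joint Cα set of all chains (fixed order) defines both the RMSD
  time series and the clustering metric; RMSD "to the initial
  structure" uses frame 1 of the input.

## Design decisions

* Bioconductor-style S4 classes (`Topology`, `Trajectory`,
  `SecondaryStructure`, `ContactMap`, `PMFSurface`, `ClusterResult`)
  with validity methods and accessors; frames are lightweight lists, as
  in the major trajectory toolkits.
* PDB record parsing is delegated to `bio3d`; the wrapper adds the
  per-model atom-count contract (a structured error naming the model),
  CRYST1 box handling and template-driven role annotation. The writer
  is a small fixed-width emitter because `bio3d` does not emit CRYST1
  records.
* Residue templates (plain text, `inst/extdata/residue_templates.txt`)
  cover the residues of the study system (S, N, F, G, A, I, L, the
  ACE/NH2 caps, and the melatonin ligand as two annotated rings plus
  donors/acceptors/methyls). `readTemplates()` accepts the same format
  for anything else; unknown residues are rejected by name.
* The Shrake–Rupley point test and the grouped minimum-distance kernels
  are the only compiled code (Rcpp), mirroring where the field's
  packages use C.
* Cap atoms (CH3CO, NH2) are classified main chain: they extend the
  backbone amide chain.
* Test problem sizes are chosen so the whole suite runs comfortably on
  one core: 400-frame octamer ensembles for target recovery, 15-frame
  clustering oracles, 100 random superposition point sets.

## Known limitations

* Templates ship for the study system's residues only (plus user
  extension); no protonation-state logic, no bond-order perception.
* DSSP-lite implements the classic rule set; π-helix bulge edge cases
  and PPII extensions are out of scope, and cross-validation against a
  reference DSSP implementation is enforced at ≥ 95 % agreement on
  generated fixtures, not 100 % (the reference reconstructs hydrogens
  with its own convention).
* The generator's coil model is dihedral sampling with clash rejection,
  not a physical model; its turn/bend byproducts are whatever the
  assignment rules find in such chains.
* Single default rotamer per side chain; XTC/DCD/GRO readers are not
  provided (the `Trajectory` contract accommodates them).
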