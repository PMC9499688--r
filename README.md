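# oligolens

Geometric trajectory analysis for small peptide-oligomer ensembles, built
around the system in which melatonin suppresses β-sheet formation in
octamers of the amyloidogenic core of human islet amyloid polypeptide,
hIAPP(20–29) (SNNFGAILSS, acetyl/amide capped, 1:4 peptide:ligand ratio).
It is aimed at structural-bioinformatics users who have conformational
ensembles as multi-model PDB files and want the standard aggregation
observables without a simulation engine in the loop.

The package implements, from coordinates alone:

* heavy-atom **contacts** (cutoff 0.54 nm, minimum image) and
  inter-peptide residue **contact probability maps** (MC–MC / SC–SC);
* geometric **hydrogen bonds** (d(D···A) < 0.35 nm, ∠D–H–A > 150°) and
  per-frame count PDFs;
* **secondary structure** by the Kabsch–Sander rules
  (E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol, bond when
  E < −0.5), mapped to helix / β-sheet / β-bridge / turn / bend / coil;
* **Shrake–Rupley SASA** (0.14 nm probe, Bondi radii, deterministic
  golden-spiral lattice);
* ensemble statistics: PDFs, **2D potentials of mean force**
  F(x, y) = −RT ln H(x, y) at 310 K, **Daura (gromos) clustering** at a
  0.45 nm Cα-RMSD cutoff, and a Jensen–Shannon **convergence check**;
* **π–π and CH–π stacking geometry** (ring centroids, plane normals,
  closest-ring pairing, herringbone/parallel classification);
* a deterministic **synthetic-ensemble generator** (peptide builder from
  backbone dihedrals, β-sheet oligomer assembly, idealized melatonin,
  prescribed stacking placements, and calibrated conformer mixtures) so
  every stage is testable without molecular dynamics.

## Worked example

```r
library(oligolens)

## a 100-frame octamer ensemble at the apo composition conditions
## (16% beta-sheet, 52% coil), no ligand
spec <- scenarioSpec(nPeptides = 8, nLigands = 0,
                     composition = c(`beta-sheet` = 0.16, coil = 0.52),
                     nFrames = 100, seed = 11)
traj <- generateEnsemble(spec)

ss <- assignSecondaryStructure(traj)
ssPopulation(ss)
#>      category fraction           se
#> 1       helix  0.14125 0.0088366248
#> 2  beta-sheet  0.13800 0.0115758369
#> 3 beta-bridge  0.00025 0.0002500000
#> 4        turn  0.02225 0.0007015608
#> 5        bend  0.15450 0.0047326988
#> 6        coil  0.54375 0.0115565863
```

The β-sheet and coil fractions recover the generator's composition
targets (0.16 / 0.52) to within sampling error at this short length —
that recovery, at 400 frames and ±3 percentage points, is one of the
package's acceptance checks. Downstream, the same trajectory feeds
`interpeptideContactMap()`, `detectHBonds()`, `shrakeRupleySasa()`,
`pmf2d()`, `dauraCluster()` and `convergenceCheck()`; with ligands
present, `ligandBindingProbability()`, `ligandHbondProfile()`,
`stackingEvents()` and `chpiMinDistance()` are added.
`runFullPipeline(traj, outDir = "out")` writes the full table set as TSV
with provenance headers, and `exec/oligolens` exposes
`generate | analyze | converge | cluster | pipeline` as a shell command.

## Documentation

The methods vignette (`vignettes/oligomer-analysis.Rmd`) describes the
model and its assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, the numerical conventions
(dihedral signs, hydrogen placement, tie-breaks, binning) and known
limitations.
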