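# haruspex

Voxel-wise annotation of cryo-EM reconstruction maps: a 3D U-Net segments a
density map into **α-helix**, **β-sheet**, **nucleotide** and **unassigned**
density, and the package provides every stage around the network — MRC2014
map I/O with σ-normalization and voxel-size rescaling, atomic-model parsing
(PDB / PDBML / mmCIF) with hydrogen-bond secondary-structure assignment and
torsion-angle extension, density-gated ground-truth voxel labeling,
training-segment extraction with rotation/translation augmentation, tiled
whole-map inference that partitions the input map into four MRC files, and
per-residue recall/precision/F1 evaluation. A synthetic phantom generator
(ideal helices, antiparallel sheets, oligonucleotide chains with
Gaussian-atom density) makes the whole pipeline trainable and testable at
desk scale with no downloads.

## Who this is for

Structural biologists interpreting maps at ~4 Å or better (domain
placement, de novo main-chain tracing, model validation) and method
developers who need a complete, reproducible reference pipeline for
volumetric map annotation.

## The method in brief

Ground truth: residues are labeled helix/sheet by author annotations plus a
Kabsch–Sander hydrogen-bond analysis (energy
`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol, bond when
`E < −0.5`; i→i+4 turn pairs for helices, bridge membership for sheets with
strand direction deliberately ignored), extended along the chain by
Ramachandran-profile matching; nucleotides are always their own class. On a
σ-normalized map (σ = r.m.s.d. of the density), voxels within 3 Å of a
residue's backbone get its class when the backbone density exceeds 2 σ, are
excluded from training between 1–2 σ, and far-from-model density ≥ 1 σ is
excluded as unmodelled. Annotated maps are cut into 70³ segments (kept if
≥ 100 atoms ≥ 1 σ, backbone mean ≥ 3 σ, ≥ 5 % annotated), augmented by the
24 proper cube rotations and random 40³ crops, and fed to an encoder–decoder
network that predicts the central 20³ voxels as four softmax channels,
trained with weighted cross-entropy (structured voxels ×16, excluded voxels
×0). Inference tiles the map so every voxel is predicted exactly once, and
the four output maps receive each voxel's full density at its argmax class,
so they sum voxel-for-voxel to the input map. Per-residue scoring:
`recall = 100·tp/(tp+fn)`, `precision = 100·tp/(tp+fp)`, F1 = harmonic mean.

See the vignette (`vignettes/cryoem-map-segmentation.Rmd`) for the full
model description, parameter table and design rationale.

## Worked example

```r
library(haruspex)
set.seed(1)

ds  <- makePhantomDataset(randomPhantomSpecs(12))   # 12 simulated maps
sp  <- splitSegments(ds$segments, 0.1)
net <- buildNetwork(tinyNetworkConfig())            # 2 levels, 8 channels
fit <- trainNetwork(net, sp$train, sp$eval)
tail(fit$history, 1)
#>   step trainLoss  evalLoss evalAccuracy
#> 5  200 0.5653117 0.5797485       0.8906

ph <- ds$phantoms[[1]]
pv <- predictMap(fit$net, ph$map)
evaluateResidues(pv, ph$model, ph$labels, ph$map)[c("recall", "precision")]
#> $recall
#> [1] 100
#> $precision
#> [1] 51.19363
```

`trainNetwork` reports the weighted cross-entropy and the fraction of
trainable voxels whose argmax class is correct on held-out segments (here
0.89 from a small 12-phantom demo corpus; the package's own acceptance
study trains on ~50 segments and reaches about 0.92-0.93). `evaluateResidues`
reports the per-residue percentages over residues with backbone density
≥ 1 σ whose truth or prediction is structured: every structured residue of
this phantom is recovered (recall 100 %) while boundary residues drag the
precision down — the same recall-rich, precision-poor profile that
per-map evaluation shows on real reconstructions.

The command-line interface wraps the same functions:

```sh
haruspex train --phantoms 12 --out weights.ckpt --seed 1
haruspex predict map.mrc --weights weights.ckpt       # four MRC outputs
haruspex annotate map.mrc model.pdb                   # ground-truth labels
haruspex evaluate map.mrc model.pdb weights.ckpt      # JSON summary
```

(the `haruspex` script lives in `inst/cli/`; after installation find it via
`system.file("cli", "haruspex", package = "haruspex")`).

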