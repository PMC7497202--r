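---
title: "Voxel-wise secondary-structure annotation of cryo-EM maps"
author: "haruspex package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise secondary-structure annotation of cryo-EM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Reconstruction maps from single-particle cryo-EM at resolutions of about
4 Å or better show secondary-structure elements — α-helices as cylindrical
tubes, β-sheets as flat striated slabs, RNA/DNA as wide, high-contrast
helical ridges — but assigning them by eye is slow and error-prone,
especially when the composition of the complex is unknown. This package
segments a map voxel by voxel into four classes (**helix**, **sheet**,
**nucleotide**, **unassigned**) with a small 3D U-Net, and ships the entire
surrounding pipeline: ground-truth generation from deposited atomic models,
training-segment extraction and augmentation, tiled whole-map inference
that partitions the input density into four MRC maps, and per-residue
recall/precision/F1 evaluation.

Everything is testable offline: a synthetic phantom generator builds ideal
helices, antiparallel sheets and oligonucleotide chains with
Gaussian-atom density, so each stage — and a scaled-down training run — is
exercised end to end without downloading a single experimental map.

## Map handling and normalization

Maps are MRC2014 mode-2 volumes. On reading, the grid is reordered to
X, Y, Z axis order whatever the file's `MAPC/MAPR/MAPS` permutation says,
and the origin combines the `ORIGIN` record with `NXSTART`-style voxel
offsets (both conventions occur in the wild; when both are present they
are summed, which is the behaviour of common viewers for volumes that use
only one of the two).

All density thresholds operate in **σ units**, where σ is the
root-mean-square spread of the density about the grid mean (the
EM-community map "r.m.s.d.", computed with the population 1/N
normalization). `sigmaNormalize()` subtracts the mean and divides by σ, so
a normalized map has mean 0 and σ exactly 1, and the value 0 is the mean
density level — which is also the fill value used for out-of-map padding
during resampling and tiled inference. Whether the community "r.m.s.d." is
taken about zero or about the mean is convention-dependent; this package
uses the spread about the mean throughout and recomputes it from the grid
(header statistics are never trusted after a grid is modified). For
experimentally solvent-flattened maps with near-zero mean the two
conventions coincide.

The network accepts voxel sizes in the window **[1.0, 1.2] Å**. Maps
outside the window are resampled by trilinear interpolation onto a grid
with voxel size exactly **1.1 Å**, preserving the Cartesian origin and
extent; the new dimension per axis is `round(oldDim · oldVoxel / 1.1)`
with round-half-away-from-zero (the choice of rounding rule is ours; it
changes the grid by at most one voxel). Anisotropic voxel sizes are
rejected explicitly rather than silently averaged. Trilinear interpolation
is exact for affine fields, which the test suite exploits as an oracle.

## Ground-truth labels from atomic models

Per-residue classes come from three sources, merged in a fixed order of
precedence:

1. **Nucleotide residues** are always class `nucleotide`.
2. **Author annotations** (HELIX/SHEET records, `struct_conf`/
   `struct_sheet_range`) are applied to their residue ranges; they
   represent the depositors' judgement and win over detected labels on
   conflict.
3. **Hydrogen-bond detection**: a variant of the classic backbone
   H-bond analysis. The bond energy is the Kabsch–Sander electrostatic
   model `E = 0.084·332·(1/rON + 1/rCH − 1/rOH − 1/rCN)` kcal/mol with
   the amide hydrogen placed 1 Å from N along the preceding residue's
   C=O direction; `E < −0.5` kcal/mol counts as a bond. α-helix: two
   consecutive i→i+4 turns label the four covered residues. Sheet: a
   residue joins if it participates in at least one bridge, with the
   parallel and antiparallel bond patterns accepted identically and only
   *membership* recorded — no ladder direction or sheet topology
   (strand direction is deliberately omitted; the network has a single
   sheet class). 3₁₀ and π helices are not separately detected: the
   network has one helix class, and i→i+4 patterns dominate at the
   target resolutions.
4. **Torsion-angle extension**: labels grow outward along the chain into
   unassigned residues whose (φ, ψ) falls into the matching Ramachandran
   basin — helix φ ∈ (−100°, −30°), ψ ∈ (−80°, −5°); sheet
   φ ∈ (−180°, −45°), ψ ∈ (90°, 180°] ∪ [−180°, −150°) — iterated to a
   fixed point. The windows are fixed constants chosen from standard
   STRIDE/Richardson-style regions and are exposed as configuration
   (`ramachandranWindows()`), since the exact windows of torsion-based
   assigners are not standardized. The extension is monotone (it only
   converts unassigned residues) and terminates in at most chain-length
   iterations. Chain termini lacking φ or ψ are never extended.

Alternate locations resolve to the highest-occupancy conformer (ties to
the first in file order).

## From residue labels to voxel labels

`annotateVoxels()` turns (map, model, labels) into a per-voxel class grid
plus a train/exclude mask, with the density gates applied per residue on
the mean trilinearly-interpolated density at the backbone atoms (amino
acids: N, CA, C, O; nucleotides: P, O5′, C5′, C4′, C3′, O3′ — sugar-ring
atoms beyond the backbone chain are not counted, a choice documented here
because conventions differ):

* backbone density **> 2 σ** → all voxels whose *centers* lie within
  **3 Å** of the residue's backbone atoms get the residue class;
* backbone density **in [1, 2] σ** → those voxels are *excluded* from
  training (visible but unreliable density);
* voxels farther than **5 Å** from every model atom but with density
  **≥ 1 σ** → excluded (high density that was never modelled);
* everything else → unassigned, trainable.

Using the voxel center for membership (rather than any part of the voxel
cube) keeps the rule unambiguous. When two residues of different classes
both reach a voxel, the nearest backbone atom wins; exact ties resolve by
the fixed priority nucleotide > helix > sheet, which makes the output
deterministic (the conflict rule is our choice; nothing in the gate
definitions forces one). A voxel that receives a class is never masked —
with the annotate gate strictly above the mask gate a single residue can
never do both, and across residues annotation wins. Residues below 1 σ
contribute nothing at all. The fast implementation visits only the local
voxel box around each atom; the test suite holds it bit-identical to an
O(voxels × atoms) brute-force scan on ≤ 32³ maps.

## Training segments and augmentation

Annotated maps are tiled into non-overlapping **70³** blocks anchored at
multiples of 70 (partial edge blocks are zero-padded; padded voxels are
unassigned and excluded). Non-overlapping tiling is a deliberate choice:
it cannot leak the same voxels into both training and evaluation splits.
A block is kept only if it passes three gates: at least **100 model
atoms** with interpolated density ≥ 1 σ (all atoms count, not only
backbone), a **mean backbone density ≥ 3 σ**, and at least **5 %** of its
voxels annotated.

A training sample is one of the **24** proper axis-aligned cube rotations
(enumerated deterministically as permutation+flip pairs with positive
determinant) applied to the segment, followed by a uniformly random
**40³** crop; the target is the center-aligned **20³** label block.
Loss weights are **16** for structured voxels, **1** for unassigned, **0**
for excluded — the 16 is a fixed constant derived from the roughly 95 %
unassigned prevalence in annotated experimental maps, not re-estimated per
dataset, so runs are comparable. The evaluation split is by segment
(`splitSegments()`, 5 % by default, at least one segment).

## The network

A compact 3D U-Net maps a 40³ single-channel density block to 20³ × 4
softmax probabilities (the center of the input volume; the 10-voxel rim is
context). Encoder: `levels` blocks of two same-padded 3³ convolutions
followed by 2× max pooling; a two-convolution bottleneck; decoder:
nearest-neighbor upsampling, skip concatenation with the encoder block of
the same resolution, and two more convolutions; finally a 1³ convolution
to 4 channels, a center crop, and a per-voxel softmax.

Design choices that the architecture sketch leaves open, fixed here:

* **Normalization**: per-channel *instance normalization* of each
  convolution response (statistics over the spatial grid of the single
  sample). It is group-size-free, needs no running statistics, works at
  any input size, adds no parameters (the existing conv bias acts as the
  shift), and in our experiments it is the difference between
  convergence in hundreds versus many thousands of steps on one CPU.
* **Optimizer**: Adam; the full-scale default learning rate is 1e-4, the
  scaled-down phantom configuration uses a larger rate (see below)
  because instance-normalized small networks tolerate it.
* **Loss**: weighted masked cross-entropy
  `Σ w·(−log p[true]) / Σ w`, defined as 0 when all weights vanish.
  Excluded voxels have weight 0 and provably cannot influence gradients
  (asserted bit-exactly in the tests).
* Arithmetic is float32 in compiled code (GEMM-based convolutions);
  runs are bit-reproducible on a given machine under a fixed seed, with
  no stochastic kernels.

The full-scale training protocol (40 000 steps with 100 segments per
step) is expressed by the `NetworkConfig()` defaults but is far outside a
desktop CPU budget and is **not** what the package's own checks run.

## Scaled-down phantom study

The package's own end-to-end check trains the tiny configuration
(`tinyNetworkConfig()`: 2 levels, 8 base channels) on segments cut from
**55 synthetic phantoms** — each a 70³ box at 1.1 Å/voxel packed with
twelve posed elements (four 36-residue helices, four 5×10-residue
antiparallel sheets, four 16-residue nucleic chains), Gaussian-atom
density of width 1 Å, and 5 % additive noise — about 50 segments for
training with 10 % held out. Elements are placed clash-free (inter-element
atom distances ≥ 3.5 Å, atoms ≥ 5 Å from the box faces), so the density is
that of a packed but physically possible assembly. The tiny run uses 200 Adam steps at
batch 5, learning rate 1e-2 with cosine decay to a tenth, and returns the
Polyak-averaged weights; it is sized to fit in minutes on one CPU and must
reach ≥ 0.90 held-out voxel accuracy over trainable voxels, where accuracy
is scored on five deterministic crops per held-out segment (the centered
crop and four offset crops covering distinct regions).

One training-head detail matters for interpreting the outputs: the
16-fold voxel weighting is applied both as the loss weights and as a
matching logit offset on the training softmax (`log w` added per class).
The two are equivalent up to a shift of the output bias, so the training
objective is exactly the weighted cross-entropy above — but with the
offset in place the *emitted* probabilities are calibrated posteriors
rather than weighted ones, so the argmax used by the map partition and
the per-residue evaluation is the accuracy-optimal decision rule instead
of a rule biased 16:1 towards structure.

What passing this proves: the whole chain — geometry builders, density
simulation, hydrogen-bond labeling, voxel gates, augmentation, the
network's forward/backward, the optimizer — is wired correctly and can
fit real structure-to-density relationships. What it does **not** prove:
performance on experimental maps. The phantoms have no solvent, no CTF or
alignment artifacts, no B-factor variation, no map sharpening, and their
error structure is nothing like a real reconstruction; training on
simulated density is explicitly *not* a substitute for curated
experimental training data, and no claim of map realism is made.

## Inference and the four output maps

`predictMap()` normalizes, rescales into the voxel window if needed,
tiles the map into 20³ output tiles at stride 20 (each read from a 40³
window dilated 10 voxels per side, zero-padded at the map faces), runs
the network per tile, and stitches. Every voxel is predicted by exactly
one tile, so stitching equals per-tile prediction by construction; with
instance normalization the network is not exactly
translation-equivariant across tile boundaries, which is documented here
rather than asserted away. If the map was rescaled, probabilities are
resampled back onto the *original* grid and renormalized per voxel, so
outputs always overlay the user's map in Coot or ChimeraX.

The four output MRC maps assign each voxel's full input density to the
argmax class (ties to the lowest channel index: helix, sheet, nucleotide,
unassigned). This is the only rule under which the four maps sum
*exactly*, value for value, to the input map — the conservation property
the integration tests assert bit-for-bit on written float32 files. An
optional flag exposes the raw probability maps.

## Per-residue evaluation

A residue's predicted class is the majority argmax class over voxels
within 3 Å of its backbone atoms (mirroring the annotation radius; ties
to the lowest channel). The evaluation set is all residues with mean
backbone density ≥ 1 σ whose truth *or* prediction is structured — true
negatives (unassigned residues predicted unassigned) are excluded from
the denominator, which is why tp + fp + fn sums to 100 % here. Within the
set: correct structured prediction → tp; structured truth predicted
unassigned → fn; everything else (wrong structured class, or structure
predicted on unassigned truth) → fp, counted once, never double-counted
as fn. Then `recall = 100·tp/(tp+fn)`, `precision = 100·tp/(tp+fp)`, and
F1 is their harmonic mean; multi-map summaries report medians.

## Known limitations

* Polyproline-II helices, β-turns and membrane/detergent density have no
  class of their own; PII in particular is a known α-helix confounder.
* Single helix class: 3₁₀/π helices are folded into "helix" by the
  torsion extension at best.
* The evaluation-set convention (true negatives excluded) must be kept in
  mind when comparing percentages across tools.
* Phantom training accuracy does not transfer to experimental maps; the
  full-scale protocol requires a curated experimental corpus and GPU
  time.
* Checkpoints are R serializations of parameter tensors plus the
  configuration (format-versioned); they are runtime artifacts, not
  shipped data.

## A minimal session

```{r example}
library(haruspex)
set.seed(1)

# build a phantom study, train the tiny network
ds <- makePhantomDataset(randomPhantomSpecs(12))
sp <- splitSegments(ds$segments, 0.1)
net <- buildNetwork(tinyNetworkConfig())
fit <- trainNetwork(net, sp$train, sp$eval)
tail(fit$history)

# predict a map and write the four-class partition
ph <- ds$phantoms[[1]]
writeMRC(ph$map, "phantom.mrc")
predictToFiles(fit$net, "phantom.mrc")

# evaluate per residue against the generating model
pv <- predictMap(fit$net, ph$map)
evaluateResidues(pv, ph$model, ph$labels, ph$map)[c("recall", "precision", "f1")]
```
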