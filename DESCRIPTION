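Package: haruspex
Title: Secondary-Structure Segmentation of Cryo-EM Density Maps with a 3D U-Net
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates cryo-EM reconstruction maps by voxel-wise classification
    into alpha-helix, beta-sheet, nucleotide and unassigned density. Provides
    MRC2014 map input/output with sigma normalization and voxel-size rescaling,
    atomic-model parsing (PDB, PDBML, mmCIF) with a hydrogen-bond based
    secondary-structure assignment and torsion-angle extension, ground-truth
    voxel labeling with density gates and training masks, segment extraction
    and augmentation for network training, a compact 3D U-Net encoder-decoder
    (40^3 voxel input, 20^3 voxel four-class output) with weighted masked
    cross-entropy loss, tiled whole-map inference that partitions the input
    density into four MRC maps, per-residue recall/precision/F1 evaluation,
    and a synthetic phantom generator (ideal helices, antiparallel sheets,
    oligonucleotide chains, Gaussian-atom density) for end-to-end testing and
    scaled-down training.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    bio3d,
    xml2,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
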