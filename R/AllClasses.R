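#' @import methods
#' @importFrom stats rnorm runif median sd
#' @importFrom utils head tail
NULL

#' Voxel class codes
#'
#' The four annotation classes used throughout the package, in fixed channel
#' order. Ties in argmax operations are broken towards the lowest channel
#' index, so the order is part of the contract.
#'
#' @format Character vector of length 4: `helix`, `sheet`, `nucleotide`,
#'   `unassigned`.
#' @export
VOXEL_CLASSES <- c("helix", "sheet", "nucleotide", "unassigned")

#' DensityMap: a 3D cryo-EM density grid
#'
#' Holds a single-channel scalar density volume together with its voxel size
#' (Angstrom per voxel, isotropic), the Cartesian origin of voxel
#' `(0, 0, 0)`, and the map sigma (root-mean-square spread of the density
#' values, the EM-community "r.m.s.d."). The grid is always stored in X, Y, Z
#' axis order: array index 1 runs along Cartesian X. The Cartesian position of
#' 0-based voxel index `(i, j, k)` is `origin + c(i, j, k) * voxelSize`.
#'
#' @slot grid 3D numeric array of density values.
#' @slot voxelSize numeric(1), Angstrom per voxel along every axis.
#' @slot origin numeric(3), Cartesian Angstrom position of voxel (0,0,0).
#' @slot sigma numeric(1), map r.m.s.d. in the grid's density units;
#'   `NA_real_` until computed or read from the file header.
#' @slot normalized logical(1), TRUE after [sigmaNormalize()].
#' @export
setClass("DensityMap",
  representation(
    grid = "array",
    voxelSize = "numeric",
    origin = "numeric",
    sigma = "numeric",
    normalized = "logical"
  ),
  prototype(
    voxelSize = 1.0,
    origin = c(0, 0, 0),
    sigma = NA_real_,
    normalized = FALSE
  )
)

setValidity("DensityMap", function(object) {
  d <- dim(object@grid)
  if (length(d) != 3L) {
    return("grid must be a 3D array")
  }
  if (any(d < 1L)) {
    return("all three grid dimensions must be >= 1")
  }
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
    object@voxelSize <= 0) {
    return("voxelSize must be a single positive number")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    return("origin must be a finite numeric vector of length 3")
  }
  TRUE
})

#' StructuralModel: polymer chains of an atomic model
#'
#' Atoms are stored as one data.frame row per atom, ordered by chain, residue
#' sequence number and insertion code; author secondary-structure records
#' (HELIX/SHEET or their PDBML/mmCIF equivalents) are kept separately.
#'
#' @slot atoms data.frame with columns `chain`, `resno` (integer), `insert`
#'   (character, "" when absent), `resid` (residue name), `elety` (atom name,
#'   PDB convention; primes as in O5'), `x`, `y`, `z` (Angstrom), `kind`
#'   (one of "amino", "nucleotide", "other").
#' @slot authorSS data.frame with columns `chain`, `start`, `end` (residue
#'   sequence numbers) and `class` ("helix" or "sheet").
#' @export
setClass("StructuralModel",
  representation(atoms = "data.frame", authorSS = "data.frame")
)

setValidity("StructuralModel", function(object) {
  need <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z", "kind")
  if (!all(need %in% names(object@atoms))) {
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(object@atoms) > 0 &&
    !all(object@atoms$kind %in% c("amino", "nucleotide", "other"))) {
    return("atom kind must be amino, nucleotide or other")
  }
  TRUE
})

#' AnnotationConfig: thresholds for ground-truth voxel labeling
#'
#' @slot labelRadius Angstrom; voxels whose centers lie within this distance
#'   of a qualifying residue's backbone atoms receive the residue class
#'   (default 3.0).
#' @slot farRadius Angstrom; voxels farther than this from every model atom
#'   but with density >= `densityFloor` are excluded from training
#'   (default 5.0).
#' @slot annotateGate sigma units; a residue annotates voxels only if its mean
#'   backbone density exceeds this (default 2.0).
#' @slot maskGate sigma units; residues with backbone density in
#'   `[maskGate, annotateGate]` mask their voxels instead (default 1.0).
#' @slot densityFloor sigma units; density threshold for the far-from-model
#'   exclusion rule (default 1.0).
#' @export
setClass("AnnotationConfig",
  representation(
    labelRadius = "numeric", farRadius = "numeric",
    annotateGate = "numeric", maskGate = "numeric", densityFloor = "numeric"
  ),
  prototype(
    labelRadius = 3.0, farRadius = 5.0,
    annotateGate = 2.0, maskGate = 1.0, densityFloor = 1.0
  )
)

setValidity("AnnotationConfig", function(object) {
  if (object@labelRadius >= object@farRadius) {
    return("labelRadius must be < farRadius")
  }
  if (object@maskGate > object@annotateGate) {
    return("maskGate must be <= annotateGate")
  }
  if (any(c(
    object@labelRadius, object@farRadius, object@annotateGate,
    object@maskGate, object@densityFloor
  ) <= 0)) {
    return("all thresholds must be positive")
  }
  TRUE
})

#' LabelVolume: per-voxel ground-truth classes and training mask
#'
#' Co-registered with the DensityMap it was derived from (same shape, voxel
#' size and origin). Classes are stored as integer codes 1..4 indexing
#' [VOXEL_CLASSES]; the mask is TRUE where a voxel may contribute to the
#' training loss and FALSE where it is excluded.
#'
#' @slot classes 3D integer array, values in 1..4.
#' @slot mask 3D logical array, TRUE = train, FALSE = exclude.
#' @slot voxelSize numeric(1), Angstrom.
#' @slot origin numeric(3), Angstrom.
#' @export
setClass("LabelVolume",
  representation(
    classes = "array", mask = "array",
    voxelSize = "numeric", origin = "numeric"
  )
)

setValidity("LabelVolume", function(object) {
  if (!identical(dim(object@classes), dim(object@mask))) {
    return("classes and mask must share dimensions")
  }
  if (length(dim(object@classes)) != 3L) {
    return("classes must be a 3D array")
  }
  cl <- object@classes
  if (any(cl < 1L | cl > 4L)) {
    return("class codes must lie in 1..4")
  }
  TRUE
})

#' SegmentFilter: the three acceptance gates for 70^3 training segments
#'
#' A segment is kept only if it contains at least `minAtoms` model atoms whose
#' interpolated density is >= 1 sigma, its backbone atoms average at least
#' `minBackboneMean` sigma, and at least `minAnnotatedFraction` of its voxels
#' carry a non-unassigned class.
#'
#' @slot minAtoms integer, default 100.
#' @slot minBackboneMean sigma units, default 3.0.
#' @slot minAnnotatedFraction fraction in (0,1), default 0.05.
#' @export
setClass("SegmentFilter",
  representation(
    minAtoms = "numeric", minBackboneMean = "numeric",
    minAnnotatedFraction = "numeric"
  ),
  prototype(minAtoms = 100, minBackboneMean = 3.0, minAnnotatedFraction = 0.05)
)

setValidity("SegmentFilter", function(object) {
  if (any(c(
    object@minAtoms, object@minBackboneMean,
    object@minAnnotatedFraction
  ) <= 0)) {
    return("all thresholds must be positive")
  }
  TRUE
})

#' NetworkConfig: architecture and training hyperparameters of the 3D U-Net
#'
#' @slot inputSize voxels per edge of the input cube (default 40).
#' @slot outputSize voxels per edge of the predicted center cube (default 20).
#' @slot levels encoder depth, i.e. number of down-sampling stages
#'   (default 3).
#' @slot baseChannels channels of the first encoder block, doubling per level
#'   (default 32).
#' @slot nClasses output channels (fixed at 4).
#' @slot steps optimizer steps for [trainNetwork()] (default 40000).
#' @slot batchSegments segments sampled per step (default 100).
#' @slot weightPositive loss weight of non-unassigned voxels relative to
#'   unassigned ones (default 16).
#' @slot learningRate Adam step size (default 1e-4).
#' @export
setClass("NetworkConfig",
  representation(
    inputSize = "numeric", outputSize = "numeric", levels = "numeric",
    baseChannels = "numeric", nClasses = "numeric", steps = "numeric",
    batchSegments = "numeric", weightPositive = "numeric",
    learningRate = "numeric"
  ),
  prototype(
    inputSize = 40, outputSize = 20, levels = 3, baseChannels = 32,
    nClasses = 4, steps = 40000, batchSegments = 100, weightPositive = 16,
    learningRate = 1e-4
  )
)

setValidity("NetworkConfig", function(object) {
  if (object@outputSize != object@inputSize - 20) {
    return("outputSize must equal inputSize - 20 (center crop of 10 per side)")
  }
  if (object@nClasses != 4) {
    return("the network predicts exactly 4 classes")
  }
  if (object@inputSize %% 2^object@levels != 0) {
    return("inputSize must be divisible by 2^levels for pooling")
  }
  if (object@levels < 1 || object@baseChannels < 1) {
    return("levels and baseChannels must be >= 1")
  }
  TRUE
})

#' UNet3D: a 3D encoder-decoder segmentation network
#'
#' Parameters are stored as a flat named list of numeric arrays; the
#' architecture is fully determined by the [NetworkConfig-class].
#'
#' @slot config a [NetworkConfig-class].
#' @slot params named list of parameter arrays (convolution kernels and
#'   biases).
#' @export
setClass("UNet3D", representation(config = "NetworkConfig", params = "list"))

#' PredictionVolume: whole-map four-class probabilities
#'
#' Four co-registered probability grids (channel order [VOXEL_CLASSES]) that
#' sum to 1 at every voxel, registered to the grid of the map that was
#' predicted.
#'
#' @slot probs 4D numeric array, dim = c(nx, ny, nz, 4).
#' @slot voxelSize numeric(1), Angstrom.
#' @slot origin numeric(3), Angstrom.
#' @export
setClass("PredictionVolume",
  representation(probs = "array", voxelSize = "numeric", origin = "numeric")
)

setValidity("PredictionVolume", function(object) {
  d <- dim(object@probs)
  if (length(d) != 4L || d[4] != 4L) {
    return("probs must be a 4D array with 4 channels")
  }
  TRUE
})
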