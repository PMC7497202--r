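#' Segment: one 70^3 training block cut from an annotated map
#'
#' @slot density 3D array, sigma-normalized density.
#' @slot labels 3D integer array of class codes 1..4.
#' @slot mask 3D logical array, TRUE = train.
#' @slot mapId character, provenance map identifier.
#' @slot corner integer(3), 0-based voxel corner of the block in its map.
#' @export
setClass("Segment",
  representation(
    density = "array", labels = "array", mask = "array",
    mapId = "character", corner = "integer"
  )
)

#' Segment filter constructor
#'
#' @param minAtoms minimum number of model atoms at >= 1 sigma inside the
#'   block (default 100).
#' @param minBackboneMean minimum mean backbone density in sigma (default 3).
#' @param minAnnotatedFraction minimum fraction of non-unassigned voxels
#'   (default 0.05).
#' @return A [SegmentFilter-class].
#' @export
SegmentFilter <- function(minAtoms = 100, minBackboneMean = 3.0,
                          minAnnotatedFraction = 0.05) {
  new("SegmentFilter",
    minAtoms = minAtoms, minBackboneMean = minBackboneMean,
    minAnnotatedFraction = minAnnotatedFraction
  )
}

# zero-padded sub-block [corner, corner + size) of a 3D array (0-based corner)
.padded_block <- function(a, corner, size, fill) {
  d <- dim(a)
  out <- array(fill, dim = c(size, size, size))
  lo <- corner + 1L
  hi <- pmin(corner + size, d)
  if (any(lo > hi)) {
    return(out)
  }
  n <- hi - lo + 1L
  out[1:n[1], 1:n[2], 1:n[3]] <-
    a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  out
}

#' Cut an annotated map into filtered 70^3 training segments
#'
#' Tiles the map with non-overlapping blocks of `segSize` voxels anchored at
#' multiples of `segSize` (partial edge blocks are zero-padded; their padded
#' labels are unassigned and their padded mask voxels are excluded). A block
#' is kept only if it passes all three gates of the [SegmentFilter-class]:
#' at least `minAtoms` model atoms inside it with interpolated density
#' >= 1 sigma, mean interpolated density over the backbone atoms inside it of
#' at least `minBackboneMean` sigma, and at least `minAnnotatedFraction` of
#' its voxels carrying a non-unassigned class.
#'
#' @param map a sigma-normalized [DensityMap-class].
#' @param model the co-registered [StructuralModel-class].
#' @param lv the [LabelVolume-class] for the map.
#' @param filter a [SegmentFilter-class].
#' @param segSize block edge in voxels (default 70).
#' @param mapId provenance string stored in each segment.
#' @return List of [Segment-class] objects (possibly empty).
#' @export
extractSegments <- function(map, model, lv, filter = SegmentFilter(),
                            segSize = 70L, mapId = "map") {
  stopifnot(is(map, "DensityMap"), is(lv, "LabelVolume"))
  validObject(filter)
  d <- dim(map@grid)
  v <- map@voxelSize
  o <- map@origin
  at <- model@atoms
  if (nrow(at) == 0) {
    return(list())
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  dens_at <- interpolateDensity(map, xyz)
  is_bb <- mapply(function(e, k) e %in% .backbone_names(k),
    at$elety, at$kind,
    USE.NAMES = FALSE
  )
  frac <- sweep(xyz, 2, o) / v # 0-based fractional voxel index per atom
  corners <- expand.grid(
    x = seq(0L, d[1] - 1L, by = segSize),
    y = seq(0L, d[2] - 1L, by = segSize),
    z = seq(0L, d[3] - 1L, by = segSize)
  )
  out <- list()
  for (ci in seq_len(nrow(corners))) {
    corner <- as.integer(corners[ci, ])
    inside <- frac[, 1] >= corner[1] & frac[, 1] < corner[1] + segSize &
      frac[, 2] >= corner[2] & frac[, 2] < corner[2] + segSize &
      frac[, 3] >= corner[3] & frac[, 3] < corner[3] + segSize
    if (sum(inside & dens_at >= 1.0) < filter@minAtoms) next
    bb <- inside & is_bb
    if (!any(bb)) next
    if (mean(dens_at[bb]) < filter@minBackboneMean) next
    labs <- .padded_block(lv@classes, corner, segSize, 4L)
    if (mean(labs != 4L) < filter@minAnnotatedFraction) next
    out[[length(out) + 1L]] <- new("Segment",
      density = .padded_block(map@grid, corner, segSize, 0),
      labels = labs,
      mask = array(.padded_block(lv@mask, corner, segSize, FALSE) > 0,
        dim = c(segSize, segSize, segSize)
      ),
      mapId = mapId, corner = corner
    )
  }
  out
}

#' The 24 orientation-preserving axis-aligned cube rotations
#'
#' Enumerates, in a fixed deterministic order, all rotations of a cubic
#' volume that map grid axes onto grid axes: each is an axis permutation
#' combined with axis flips, restricted to positive determinant (proper
#' rotations, no mirror images). The identity is element 1.
#'
#' @return List of 24 transforms, each a list with `perm` (integer(3)) and
#'   `flip` (logical(3)). Apply with [applyRotation()].
#' @export
enumerateRotations <- function() {
  perms <- list(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
  sign_perm <- c(1, -1, -1, 1, 1, -1)
  out <- vector("list", 24)
  k <- 0L
  for (p in seq_along(perms)) {
    for (f in 0:7) {
      flip <- c(
        bitwAnd(f, 1L) > 0L, bitwAnd(f, 2L) > 0L,
        bitwAnd(f, 4L) > 0L
      )
      if (sign_perm[p] * (-1)^sum(flip) != 1) next
      k <- k + 1L
      out[[k]] <- list(perm = perms[[p]], flip = flip)
    }
  }
  out
}

#' Apply a cube rotation to a 3D volume
#'
#' @param vol cubic 3D array.
#' @param rot one element of [enumerateRotations()].
#' @return The rotated array (same dimensions).
#' @export
applyRotation <- function(vol, rot) {
  d <- dim(vol)
  idx <- lapply(1:3, function(a) if (rot$flip[a]) rev(seq_len(d[a])) else seq_len(d[a]))
  aperm(vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], rot$perm)
}

#' Per-voxel training loss weights
#'
#' Structured (non-unassigned) voxels weigh `weightPositive` (default 16)
#' relative to unassigned ones, compensating the roughly 95 % unassigned
#' class prevalence; excluded voxels get weight 0 and never contribute to
#' the loss.
#'
#' @param target 3D integer array of class codes 1..4.
#' @param mask 3D logical array, TRUE = train.
#' @param weightPositive relative weight of structured voxels.
#' @return 3D numeric weight array of the same shape.
#' @export
voxelLossWeights <- function(target, mask, weightPositive = 16) {
  w <- array(1, dim = dim(target))
  w[target != 4L] <- weightPositive
  w[!mask] <- 0
  w
}

#' Draw one augmented training sample from a segment
#'
#' Picks one of the 24 cube rotations and a uniform corner offset in
#' `{0..segSize-cropSize}^3` (translational augmentation), rotates the
#' segment, crops a `cropSize^3` density block and the center-aligned
#' `outSize^3` label/mask block, and attaches loss weights. Randomness comes
#' from R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param seg a [Segment-class].
#' @param cropSize input cube edge (default 40).
#' @param outSize output cube edge (default 20).
#' @param weightPositive passed to [voxelLossWeights()].
#' @param rotation,offset fix the rotation index (1..24) and 0-based corner
#'   offset instead of drawing them; intended for deterministic slicing.
#' @return List with `input` (cropSize^3 array), `target` (outSize^3 integer
#'   codes), `mask`, `weight` (outSize^3), `rotation` and `offset`.
#' @export
sampleTrainingExample <- function(seg, cropSize = 40L, outSize = 20L,
                                  weightPositive = 16, rotation = NULL,
                                  offset = NULL) {
  segSize <- dim(seg@density)[1]
  stopifnot(cropSize <= segSize, outSize <= cropSize)
  rots <- enumerateRotations()
  ri <- if (is.null(rotation)) sample.int(24L, 1L) else as.integer(rotation)
  off <- if (is.null(offset)) {
    sample.int(segSize - cropSize + 1L, 3L, replace = TRUE) - 1L
  } else {
    as.integer(rep_len(offset, 3L))
  }
  dens <- applyRotation(seg@density, rots[[ri]])
  labs <- applyRotation(seg@labels, rots[[ri]])
  msk <- applyRotation(seg@mask, rots[[ri]])
  margin <- (cropSize - outSize) %/% 2L
  ix <- (off[1] + 1L):(off[1] + cropSize)
  iy <- (off[2] + 1L):(off[2] + cropSize)
  iz <- (off[3] + 1L):(off[3] + cropSize)
  ox <- (off[1] + margin + 1L):(off[1] + margin + outSize)
  oy <- (off[2] + margin + 1L):(off[2] + margin + outSize)
  oz <- (off[3] + margin + 1L):(off[3] + margin + outSize)
  target <- labs[ox, oy, oz]
  mask <- msk[ox, oy, oz]
  list(
    input = dens[ix, iy, iz],
    target = target, mask = mask,
    weight = voxelLossWeights(target, mask, weightPositive),
    rotation = ri, offset = off
  )
}

#' Split segments into training and evaluation sets
#'
#' Uniformly random disjoint split; the evaluation set holds
#' `max(1, round(evalFraction * N))` segments. Deterministic under a fixed
#' seed.
#'
#' @param segs list of [Segment-class] objects (at least 2).
#' @param evalFraction fraction set aside for evaluation (default 0.05).
#' @return List with elements `train` and `eval`.
#' @export
splitSegments <- function(segs, evalFraction = 0.05) {
  n <- length(segs)
  if (n < 2) stop("need at least 2 segments to split")
  ne <- max(1L, as.integer(.round_half_away(evalFraction * n)))
  ei <- sample.int(n, ne)
  list(train = segs[-ei], eval = segs[ei])
}

#' @export
setMethod("show", "Segment", function(object) {
  d <- dim(object@density)
  cat(sprintf(
    "Segment %s@(%d,%d,%d): %d^3 voxels, %.1f%% annotated, %.1f%% excluded\n",
    object@mapId, object@corner[1], object@corner[2], object@corner[3],
    d[1], 100 * mean(object@labels != 4L), 100 * mean(!object@mask)
  ))
})
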