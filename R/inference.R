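# zero-padded block of arbitrary (possibly negative / overhanging) corner
.padded_block_any <- function(a, corner, size, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = rep(size, 3L))
  lo <- pmax(corner, 0L)
  hi <- pmin(corner + size, d) - 1L
  if (any(lo > hi)) {
    return(out)
  }
  dst <- lo - corner
  out[
    (dst[1] + 1):(dst[1] + hi[1] - lo[1] + 1),
    (dst[2] + 1):(dst[2] + hi[2] - lo[2] + 1),
    (dst[3] + 1):(dst[3] + hi[3] - lo[3] + 1)
  ] <-
    a[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1), (lo[3] + 1):(hi[3] + 1)]
  out
}

#' Tile a map into network input windows
#'
#' Output tiles of `outputSize^3` voxels at stride `outputSize` cover every
#' voxel of the map exactly once; each input window is its tile dilated by
#' the network margin on every side, with voxels outside the map padded with
#' 0 (the mean level of a sigma-normalized map).
#'
#' @param map a sigma-normalized [DensityMap-class].
#' @param inputSize network input edge (default 40).
#' @param outputSize network output edge (default 20).
#' @return List of tiles, each a list with `window` (inputSize^3 array) and
#'   `corner` (0-based voxel index of the tile's output corner).
#' @export
tileMap <- function(map, inputSize = 40L, outputSize = 20L) {
  d <- dim(map@grid)
  margin <- (inputSize - outputSize) %/% 2L
  corners <- expand.grid(
    x = seq(0L, d[1] - 1L, by = outputSize),
    y = seq(0L, d[2] - 1L, by = outputSize),
    z = seq(0L, d[3] - 1L, by = outputSize)
  )
  lapply(seq_len(nrow(corners)), function(i) {
    corner <- as.integer(corners[i, ])
    list(
      window = .padded_block_any(map@grid, corner - margin, inputSize, 0),
      corner = corner
    )
  })
}

#' Predict whole-map class probabilities
#'
#' Runs the full inference pipeline: sigma-normalize, rescale the voxel size
#' into the accepted window when necessary, tile the map into input windows,
#' run the network on every window, and stitch the per-tile predictions into
#' a whole-map probability volume. When the map was rescaled, the
#' probabilities are resampled back onto the original input grid by trilinear
#' interpolation and renormalized per voxel, so the result always overlays
#' the user's map.
#'
#' @param net a trained [UNet3D-class].
#' @param map a [DensityMap-class] (raw; normalization is applied
#'   internally).
#' @param window voxel-size acceptance window in Angstrom.
#' @param target rescale target in Angstrom.
#' @return A [PredictionVolume-class] registered to `map`.
#' @export
predictMap <- function(net, map, window = c(1.0, 1.2), target = 1.1) {
  stopifnot(is(net, "UNet3D"), is(map, "DensityMap"))
  cfg <- net@config
  norm <- if (.is_normalized(map)) map else sigmaNormalize(map)
  work <- rescaleVoxelSize(norm, target = target, window = window)
  rescaled <- !identical(dim(work@grid), dim(norm@grid)) ||
    work@voxelSize != norm@voxelSize
  d <- dim(work@grid)
  probs <- array(0, dim = c(d, 4))
  outSize <- as.integer(cfg@outputSize)
  tiles <- tileMap(work, as.integer(cfg@inputSize), outSize)
  for (tl in tiles) {
    p <- netForward(net, tl$window)
    co <- tl$corner
    n <- pmin(co + outSize, d) - co
    probs[
      (co[1] + 1):(co[1] + n[1]), (co[2] + 1):(co[2] + n[2]),
      (co[3] + 1):(co[3] + n[3]),
    ] <- p[1:n[1], 1:n[2], 1:n[3], , drop = FALSE]
  }
  if (rescaled) {
    dd <- dim(norm@grid)
    ax <- lapply(1:3, function(a) {
      (seq_len(dd[a]) - 1) * norm@voxelSize / work@voxelSize
    })
    pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
    back <- array(0, dim = c(dd, 4))
    for (k in 1:4) {
      back[, , , k] <- array(.trilinear_index(probs[, , , k], pts), dim = dd)
    }
    s <- back[, , , 1] + back[, , , 2] + back[, , , 3] + back[, , , 4]
    zero <- s <= 0
    s[zero] <- 1
    for (k in 1:4) back[, , , k] <- back[, , , k] / s
    if (any(zero)) {
      u <- back[, , , 4]
      u[zero] <- 1
      back[, , , 4] <- u
      for (k in 1:3) {
        b <- back[, , , k]
        b[zero] <- 0
        back[, , , k] <- b
      }
    }
    probs <- back
  }
  new("PredictionVolume",
    probs = probs, voxelSize = map@voxelSize,
    origin = map@origin
  )
}

#' @describeIn predictMap probability array accessor (nx x ny x nz x 4)
#' @param pv a [PredictionVolume-class]
#' @export
predictionProbs <- function(pv) pv@probs

#' @export
setMethod("show", "PredictionVolume", function(object) {
  d <- dim(object@probs)
  am <- .argmax4(object@probs)
  tab <- tabulate(am, nbins = 4)
  cat(sprintf(
    "PredictionVolume: %d x %d x %d voxels; argmax: helix %d, sheet %d, nucleotide %d, unassigned %d\n",
    d[1], d[2], d[3], tab[1], tab[2], tab[3], tab[4]
  ))
})

#' Partition the input density into four class maps
#'
#' At every voxel the argmax class (ties to the lowest channel index)
#' receives the full input density value and the other three maps receive 0,
#' so the four output maps sum voxelwise to the input map exactly and
#' together represent the entire input density.
#'
#' @param map the input [DensityMap-class].
#' @param pv the co-registered [PredictionVolume-class].
#' @return Named list of four [DensityMap-class] objects
#'   (helix, sheet, nucleotide, unassigned).
#' @export
partitionDensity <- function(map, pv) {
  stopifnot(identical(dim(map@grid), dim(pv@probs)[1:3]))
  am <- .argmax4(pv@probs)
  out <- lapply(1:4, function(k) {
    g <- map@grid
    g[am != k] <- 0
    DensityMap(g, voxelSize = map@voxelSize, origin = map@origin)
  })
  names(out) <- VOXEL_CLASSES
  out
}

#' Run prediction and write the four output MRC maps
#'
#' Convenience wrapper used by the command-line interface: predicts a map,
#' partitions the density and writes `<stem>_helix.mrc`, `<stem>_sheet.mrc`,
#' `<stem>_nucleotide.mrc` and `<stem>_unassigned.mrc` (plus, optionally,
#' the four raw probability maps).
#'
#' @param net a trained [UNet3D-class].
#' @param mapPath input MRC file.
#' @param outdir output directory (default: directory of `mapPath`).
#' @param probabilities also write raw probability maps.
#' @return Invisibly, the paths written.
#' @export
predictToFiles <- function(net, mapPath, outdir = dirname(mapPath),
                           probabilities = FALSE) {
  map <- readMRC(mapPath)
  pv <- predictMap(net, map)
  parts <- partitionDensity(map, pv)
  stem <- file.path(outdir, sub("\\.[^.]*$", "", basename(mapPath)))
  paths <- character(0)
  for (k in seq_along(VOXEL_CLASSES)) {
    p <- paste0(stem, "_", VOXEL_CLASSES[k], ".mrc")
    writeMRC(parts[[k]], p)
    paths <- c(paths, p)
  }
  if (probabilities) {
    for (k in seq_along(VOXEL_CLASSES)) {
      p <- paste0(stem, "_prob_", VOXEL_CLASSES[k], ".mrc")
      writeMRC(DensityMap(pv@probs[, , , k],
        voxelSize = map@voxelSize,
        origin = map@origin
      ), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
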