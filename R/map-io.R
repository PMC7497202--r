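#' Construct a DensityMap
#'
#' @param grid 3D numeric array of density values (X, Y, Z axis order).
#' @param voxelSize Angstrom per voxel (isotropic).
#' @param origin Cartesian Angstrom position of voxel (0,0,0).
#' @param sigma map r.m.s.d. if already known, else NA.
#' @return A [DensityMap-class].
#' @examples
#' m <- DensityMap(array(rnorm(8^3), c(8, 8, 8)), voxelSize = 1.1)
#' @export
DensityMap <- function(grid, voxelSize = 1.0, origin = c(0, 0, 0),
                       sigma = NA_real_) {
  new("DensityMap",
    grid = grid, voxelSize = as.numeric(voxelSize),
    origin = as.numeric(origin), sigma = as.numeric(sigma),
    normalized = FALSE
  )
}

#' @describeIn DensityMap density grid accessor
#' @param x,object a DensityMap
#' @export
mapGrid <- function(x) x@grid

#' @describeIn DensityMap voxel size accessor (Angstrom)
#' @export
voxelSize <- function(x) x@voxelSize

#' @describeIn DensityMap origin accessor (Angstrom)
#' @export
mapOrigin <- function(x) x@origin

#' @describeIn DensityMap stored map sigma (NA until computed or read)
#' @export
mapSigma <- function(x) x@sigma

#' @export
setMethod("show", "DensityMap", function(object) {
  d <- dim(object@grid)
  cat(sprintf(
    "DensityMap: %d x %d x %d voxels, %.3f A/voxel\n", d[1], d[2], d[3],
    object@voxelSize
  ))
  cat(sprintf(
    "  origin: (%.2f, %.2f, %.2f) A; sigma: %s%s\n",
    object@origin[1], object@origin[2], object@origin[3],
    ifelse(is.na(object@sigma), "unset", sprintf("%.4g", object@sigma)),
    ifelse(object@normalized, " (sigma-normalized)", "")
  ))
})

# MRC2014 header layout: 256 little-endian 4-byte words, then optional
# extended header (NSYMBT bytes), then the data section.
.mrc_read_header <- function(con) {
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  extra <- readBin(con, "raw", n = 100)
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  magic_raw <- readBin(con, "raw", n = 4)
  magic <- rawToChar(magic_raw[magic_raw != as.raw(0)])
  machst <- readBin(con, "raw", n = 4)
  rms <- readBin(con, "numeric", n = 1, size = 4, endian = "little")
  nlabl <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  labels <- readBin(con, "raw", n = 800)
  list(
    n = ints[1:3], mode = ints[4], nstart = ints[5:7], m = ints[8:10],
    cella = cella, cellb = cellb, mapcrs = mapcrs, dstats = dstats,
    ispg = ispg, nsymbt = nsymbt, origin = origin, magic = magic,
    machst = machst, rms = rms, nlabl = nlabl
  )
}

#' Read an MRC2014 density map
#'
#' Reads a mode-2 (32-bit float) MRC volume. Whatever the file's axis order
#' (MAPC/MAPR/MAPS), the grid is reordered so that array index 1 runs along
#' Cartesian X. The origin combines the ORIGIN header record with any
#' NXSTART-style voxel offsets. The RMS header field is kept as the map sigma
#' when positive, otherwise sigma is left unset.
#'
#' @param path path to an MRC file.
#' @return A [DensityMap-class].
#' @seealso [writeMRC()], [sigmaNormalize()]
#' @export
readMRC <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .mrc_read_header(con)
  if (!h$magic %in% c("MAP ", "MAP")) {
    # Old-style files may omit the magic; insist on sane dimensions instead.
    if (any(h$n <= 0) || any(h$n > 1e5)) {
      stop("malformed MRC header: bad MAP magic and implausible NX/NY/NZ")
    }
  }
  if (h$mode != 2L) {
    stop("unsupported MRC MODE ", h$mode, " (only mode 2, float32)")
  }
  if (any(h$n < 1L)) stop("malformed MRC header: non-positive NX/NY/NZ")
  if (any(h$m < 1L) || any(h$cella <= 0)) {
    stop("malformed MRC header: non-positive MX/MY/MZ or CELLA")
  }
  if (!all(sort(h$mapcrs) == 1:3)) {
    stop("malformed MRC header: MAPC/MAPR/MAPS must be a permutation of 1:3")
  }
  if (h$nsymbt > 0) invisible(readBin(con, "raw", n = h$nsymbt))
  nvox <- prod(h$n)
  dat <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(dat) < nvox) stop("malformed MRC file: truncated data section")
  raw <- array(dat, dim = h$n)
  # raw dims run along Cartesian axes (mapc, mapr, maps); reorder to X,Y,Z
  grid <- aperm(raw, match(1:3, h$mapcrs))

  vox <- h$cella / h$m
  if (diff(range(vox)) > 1e-4 * mean(vox)) {
    stop(
      "anisotropic voxel size not supported: ",
      paste(sprintf("%.4f", vox), collapse = " x "), " A"
    )
  }
  vox <- mean(vox)
  if (vox <= 0) stop("malformed MRC header: non-positive voxel size")

  nstart_xyz <- h$nstart[match(1:3, h$mapcrs)]
  origin <- h$origin + nstart_xyz * vox
  sigma <- if (is.finite(h$rms) && h$rms > 0) h$rms else NA_real_
  DensityMap(grid, voxelSize = vox, origin = origin, sigma = sigma)
}

#' Write a DensityMap as an MRC2014 file
#'
#' Writes a mode-2 (float32) volume in X, Y, Z axis order with correct cell,
#' grid and origin headers. The RMS header field is always set to the r.m.s.d.
#' recomputed from the grid, and DMIN/DMAX/DMEAN are filled in, so the file
#' displays correctly in Coot/Chimera-style viewers.
#'
#' @param map a [DensityMap-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeMRC <- function(map, path) {
  stopifnot(is(map, "DensityMap"))
  validObject(map)
  g <- map@grid
  d <- dim(g)
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  rms <- sqrt(mean((g - mean(g))^2))
  wint(d) # NX NY NZ
  wint(2) # MODE 2
  wint(c(0, 0, 0)) # NXSTART..
  wint(d) # MX MY MZ
  wflt(d * map@voxelSize) # CELLA
  wflt(c(90, 90, 90)) # CELLB
  wint(1:3) # MAPC MAPR MAPS = X,Y,Z
  wflt(c(min(g), max(g), mean(g))) # DMIN DMAX DMEAN
  wint(1) # ISPG (3D volume)
  wint(0) # NSYMBT
  extra <- raw(100)
  nver <- writeBin(20140L, raw(), size = 4, endian = "little")
  extra[9:12] <- nver # NVERSION, word 28
  writeBin(extra, con)
  wflt(map@origin) # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # MACHST little-endian
  wflt(rms) # RMS
  wint(1) # NLABL
  lab <- charToRaw(formatC("haruspex density map", width = -80))
  writeBin(c(lab, raw(800 - length(lab))), con)
  writeBin(as.numeric(g), con, size = 4, endian = "little")
  invisible(path)
}

#' Map sigma: r.m.s.d. of the density distribution
#'
#' Computes the root-mean-square spread of all voxel values about the grid
#' mean (the EM-community map "r.m.s.d.", with the population 1/N
#' normalization). All density thresholds in this package are expressed in
#' multiples of this value.
#'
#' @param map a [DensityMap-class] with a non-constant grid.
#' @return The sigma value (density units). Use [sigmaNormalize()] to store
#'   it and rescale the grid.
#' @export
computeSigma <- function(map) {
  stopifnot(is(map, "DensityMap"))
  g <- map@grid
  s <- sqrt(mean((g - mean(g))^2))
  if (s == 0) stop("degenerate map: constant density grid has no sigma")
  s
}

#' Normalize a map to sigma units
#'
#' Subtracts the grid mean and divides by the map r.m.s.d., so that the
#' normalized grid has mean 0 and r.m.s.d. exactly 1. Density gates such as
#' "annotate above 2 sigma" are applied to normalized maps.
#'
#' @param map a [DensityMap-class].
#' @return A normalized DensityMap with `sigma = 1`.
#' @export
sigmaNormalize <- function(map) {
  s <- computeSigma(map)
  g <- (map@grid - mean(map@grid)) / s
  out <- DensityMap(g, voxelSize = map@voxelSize, origin = map@origin,
    sigma = 1)
  out@normalized <- TRUE
  out
}

.is_normalized <- function(map, tol = 1e-3) {
  g <- map@grid
  abs(mean(g)) < tol && abs(sqrt(mean((g - mean(g))^2)) - 1) < tol
}

# round half away from zero (R's round() rounds half to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Rescale a map's voxel size into the accepted window
#'
#' The segmentation network accepts voxel sizes in a fixed window
#' (default 1.0-1.2 Angstrom). Maps inside the window are returned unchanged;
#' maps outside are resampled by trilinear interpolation onto a grid with
#' voxel size exactly `target` (default 1.1 Angstrom), preserving the
#' Cartesian origin and extent. The new dimension along each axis is
#' `round(oldDim * oldVoxel / target)` (half away from zero). Samples falling
#' outside the original grid take value 0 (the mean level of a
#' sigma-normalized map).
#'
#' @param map a [DensityMap-class].
#' @param target target voxel size in Angstrom.
#' @param window acceptance window c(lo, hi) in Angstrom.
#' @return A [DensityMap-class]; the input object itself when no resampling
#'   is needed.
#' @export
rescaleVoxelSize <- function(map, target = 1.1, window = c(1.0, 1.2)) {
  stopifnot(is(map, "DensityMap"))
  validObject(map)
  v <- map@voxelSize
  if (v >= window[1] && v <= window[2]) {
    return(map)
  }
  d <- dim(map@grid)
  nd <- pmax(1L, as.integer(.round_half_away(d * v / target)))
  # fractional indices (0-based) into the old grid for each new axis position
  ax <- lapply(1:3, function(a) (seq_len(nd[a]) - 1) * target / v)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  vals <- .trilinear_index(map@grid, pts)
  out <- DensityMap(array(vals, dim = nd),
    voxelSize = target,
    origin = map@origin, sigma = NA_real_
  )
  out@normalized <- map@normalized
  out
}

# Trilinear interpolation at fractional 0-based voxel indices.
# pts: n x 3 matrix. Out-of-bounds contributions are 0.
.trilinear_index <- function(grid, pts) {
  d <- dim(grid)
  i0 <- floor(pts)
  f <- pts - i0
  acc <- numeric(nrow(pts))
  for (dx in 0:1) {
    wx <- if (dx == 0) 1 - f[, 1] else f[, 1]
    ix <- i0[, 1] + dx
    for (dy in 0:1) {
      wy <- if (dy == 0) 1 - f[, 2] else f[, 2]
      iy <- i0[, 2] + dy
      for (dz in 0:1) {
        wz <- if (dz == 0) 1 - f[, 3] else f[, 3]
        iz <- i0[, 3] + dz
        w <- wx * wy * wz
        ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3] &
          w > 0
        if (any(ok)) {
          lin <- ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok]) + 1
          acc[ok] <- acc[ok] + w[ok] * grid[lin]
        }
      }
    }
  }
  acc
}

#' Sample a map at Cartesian points by trilinear interpolation
#'
#' @param map a [DensityMap-class].
#' @param xyz n x 3 matrix of Cartesian Angstrom coordinates.
#' @return numeric vector of interpolated density values; points outside the
#'   grid contribute 0 from out-of-bounds corners.
#' @export
interpolateDensity <- function(map, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  pts <- sweep(xyz, 2, map@origin) / map@voxelSize
  .trilinear_index(map@grid, pts)
}
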