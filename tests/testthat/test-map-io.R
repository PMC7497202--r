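test_that("MRC round trip preserves grid, voxel size and origin", {
  m <- toy_map(d = c(8, 10, 12), voxel = 1.37, origin = c(-3.5, 2, 11))
  f <- tempfile(fileext = ".mrc")
  writeMRC(m, f)
  m2 <- readMRC(f)
  # float32 quantization on the way out
  expect_equal(mapGrid(m2), mapGrid(m), tolerance = 1e-6)
  expect_equal(voxelSize(m2), 1.37, tolerance = 1e-6)
  expect_equal(mapOrigin(m2), c(-3.5, 2, 11), tolerance = 1e-5)
  # header voxel size echoes back for an unusual value too
  m3 <- toy_map(voxel = 1.4)
  f3 <- tempfile(fileext = ".mrc")
  writeMRC(m3, f3)
  expect_equal(voxelSize(readMRC(f3)), 1.4, tolerance = 1e-6)
  # a second read of the re-written file is identical (fixpoint)
  f4 <- tempfile(fileext = ".mrc")
  writeMRC(m2, f4)
  expect_identical(mapGrid(readMRC(f4)), mapGrid(m2))
})

test_that("constant-zero 8^3 map writes 512 zero floats after the header", {
  f <- tempfile(fileext = ".mrc")
  writeMRC(DensityMap(array(0, c(8, 8, 8)), voxelSize = 1), f)
  expect_equal(file.size(f), 1024 + 512 * 4)
  con <- file(f, "rb")
  invisible(readBin(con, "raw", n = 1024))
  dat <- readBin(con, "numeric", n = 512, size = 4)
  close(con)
  expect_identical(dat, rep(0, 512))
})

test_that("files with non-XYZ axis order are reordered on read", {
  # hand-write a ZYX-ordered MRC file and compare against the explicit
  # index-permutation oracle
  d_file <- c(5L, 6L, 7L) # file order: columns=Z, rows=Y, sections=X
  set.seed(3)
  raw <- array(rnorm(prod(d_file)), dim = d_file)
  f <- tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d_file) # NX NY NZ (per file axis)
  wi(2)
  wi(c(0, 0, 0))
  wi(c(7, 6, 5)) # MX MY MZ along cell X,Y,Z
  wf(c(7, 6, 5) * 2.0) # CELLA: voxel 2 A
  wf(c(90, 90, 90))
  wi(c(3, 2, 1)) # MAPC=Z MAPR=Y MAPS=X
  wf(c(min(raw), max(raw), mean(raw)))
  wi(1)
  wi(0)
  writeBin(raw(100), con)
  wf(c(0, 0, 0))
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(stats::sd(raw))
  wi(0)
  writeBin(raw(800), con)
  wf(as.numeric(raw))
  close(con)

  m <- readMRC(f)
  expect_equal(dim(mapGrid(m)), c(7L, 6L, 5L))
  # oracle: file dims run along (Z, Y, X), so XYZ = transpose 3,2,1
  expect_equal(mapGrid(m), aperm(raw, c(3, 2, 1)), tolerance = 1e-6)
  expect_equal(voxelSize(m), 2.0, tolerance = 1e-6)
})

test_that("malformed MRC headers are rejected with a named field", {
  f <- tempfile(fileext = ".mrc")
  m <- toy_map(d = c(4, 4, 4))
  writeMRC(m, f)
  # corrupt MODE (word 4) to 1
  con <- file(f, "r+b")
  seek(con, 12, rw = "write")
  writeBin(1L, con, size = 4, endian = "little")
  close(con)
  expect_error(readMRC(f), "MODE")
  expect_error(readMRC(tempfile()), "not found")
})

test_that("the writer is readable by an independent MRC parser", {
  skip_if_not(nzchar(Sys.which("python")), "python not on PATH")
  m <- toy_map(d = c(6, 5, 4), voxel = 1.25, origin = c(1, -2, 3))
  f <- tempfile(fileext = ".mrc")
  writeMRC(m, f)
  out <- tempfile(fileext = ".txt")
  code <- sprintf(paste0(
    "import gemmi, numpy as np\n",
    "m = gemmi.read_ccp4_map(r'%s')\n",
    "a = np.array(m.grid, copy=False)\n",
    "print(a.shape)\n",
    "print(round(float(a.sum()), 4))\n",
    "print(round(m.grid.spacing[0], 6))\n"
  ), f)
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  res <- system2("python", script, stdout = TRUE)
  expect_equal(res[1], "(6, 5, 4)")
  expect_equal(as.numeric(res[2]), round(sum(mapGrid(m)), 4),
    tolerance = 1e-3)
  expect_equal(as.numeric(res[3]), 1.25, tolerance = 1e-5)
})

test_that("computeSigma matches hand-computed r.m.s.d. values", {
  # symmetric two-point distribution {-1, +1}
  g <- array(rep(c(-1, 1), 32), c(4, 4, 4))
  expect_equal(computeSigma(DensityMap(g)), 1)
  # {0,0,0,4}: mean 1, sigma = sqrt((1+1+1+9)/4) = sqrt(3)
  g2 <- array(c(0, 0, 0, 4), c(4, 1, 1))
  expect_equal(computeSigma(DensityMap(g2)), sqrt(3))
  # scaling: sigma(a*g) = a * sigma(g)
  m <- toy_map()
  expect_equal(computeSigma(DensityMap(3.7 * mapGrid(m))),
    3.7 * computeSigma(m))
  # constant grid is degenerate
  expect_error(computeSigma(DensityMap(array(2, c(3, 3, 3)))), "constant")
})

test_that("computeSigma is invariant under permutation and origin shifts", {
  m <- toy_map(d = c(6, 6, 6))
  s0 <- computeSigma(m)
  g <- mapGrid(m)
  expect_equal(computeSigma(DensityMap(aperm(g, c(2, 3, 1)))), s0)
  expect_equal(computeSigma(DensityMap(g, origin = c(100, -5, 2))), s0)
})

test_that("sigma normalization yields r.m.s.d. 1 and mean 0", {
  m <- toy_map(d = c(10, 10, 10))
  n <- sigmaNormalize(m)
  g <- mapGrid(n)
  expect_equal(sqrt(mean((g - mean(g))^2)), 1, tolerance = 1e-6)
  expect_equal(mean(g), 0, tolerance = 1e-9)
  expect_equal(mapSigma(n), 1)
})

test_that("voxel sizes inside the window are returned unchanged", {
  for (v in c(1.0, 1.05, 1.1, 1.2)) {
    m <- toy_map(voxel = v)
    expect_identical(rescaleVoxelSize(m), m)
  }
})

test_that("rescaling resizes grids by the round-half-away rule", {
  # 70 voxels at 1.4 A -> round(70 * 1.4 / 1.1) = round(89.09) = 89
  g <- array(rnorm(70 * 4 * 4), c(70, 4, 4))
  m <- DensityMap(g, voxelSize = 1.4)
  r <- rescaleVoxelSize(m)
  expect_equal(dim(mapGrid(r))[1], 89)
  expect_equal(voxelSize(r), 1.1)
  expect_equal(mapOrigin(r), mapOrigin(m))
  # a constant map stays constant under interpolation (interior value)
  mc <- DensityMap(array(5, c(12, 12, 12)), voxelSize = 1.5)
  rc <- rescaleVoxelSize(mc)
  inner <- mapGrid(rc)[2:15, 2:15, 2:15]
  expect_equal(max(abs(inner - 5)), 0, tolerance = 1e-9)
})

test_that("trilinear rescaling reproduces an affine ramp at interior points", {
  d <- c(16, 16, 16)
  idx <- expand.grid(x = 0:15, y = 0:15, z = 0:15)
  ramp <- array(2 + 0.5 * idx$x + 0.25 * idx$y - 0.125 * idx$z, dim = d)
  m <- DensityMap(ramp, voxelSize = 1.4) # outside window -> resample
  r <- rescaleVoxelSize(m)
  dn <- dim(mapGrid(r))
  # expected ramp at new fractional positions (1.1/1.4 of a voxel step)
  s <- 1.1 / 1.4
  idx2 <- expand.grid(x = seq_len(dn[1]) - 1, y = seq_len(dn[2]) - 1,
    z = seq_len(dn[3]) - 1)
  expected <- 2 + 0.5 * idx2$x * s + 0.25 * idx2$y * s - 0.125 * idx2$z * s
  got <- as.vector(mapGrid(r))
  interior <- idx2$x * s <= 15 & idx2$y * s <= 15 & idx2$z * s <= 15
  expect_equal(got[interior], expected[interior], tolerance = 1e-10)
})

test_that("interpolateDensity agrees with exact values at nodes and midpoints", {
  g <- array(0, c(5, 5, 5))
  g[3, 3, 3] <- 3
  g[4, 3, 3] <- 4
  m <- DensityMap(g, voxelSize = 2, origin = c(10, 0, 0))
  # at the node itself
  expect_equal(interpolateDensity(m, c(10 + 2 * 2, 4, 4)), 3)
  # midpoint between the 3-valued and 4-valued nodes: (3+4)/2
  expect_equal(interpolateDensity(m, c(10 + 2 * 2.5, 4, 4)), 3.5)
  # far outside the grid: zero
  expect_equal(interpolateDensity(m, c(1000, 0, 0)), 0)
})
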