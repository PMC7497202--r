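test_that("ideal helices have canonical backbone geometry", {
  h <- buildIdealHelix(10)
  at <- modelAtoms(h)
  ca <- as.matrix(at[at$elety == "CA", c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(steps - 3.8) < 0.1))
  # a 10-residue helix spans about 15 Angstrom
  expect_equal(sqrt(sum((ca[10, ] - ca[1, ])^2)), 15, tolerance = 0.1)
  # the hydrogen-bond detector recognizes the interior as helical
  lab <- assignSecondaryStructure(h)
  rt <- residueTable(h)
  expect_true(all(lab[rt$key[rt$resno %in% 3:8]] == "helix"))
  expect_error(buildIdealHelix(3), "at least 4")
})

test_that("antiparallel sheets pair at hydrogen-bond geometry", {
  s <- buildAntiparallelSheet(2, 8)
  at <- modelAtoms(s)
  NA_ <- as.matrix(at[at$chain == "A" & at$elety == "N", c("x", "y", "z")])
  OB <- as.matrix(at[at$chain == "B" & at$elety == "O", c("x", "y", "z")])
  dmin <- apply(NA_, 1, function(p) min(sqrt(colSums((t(OB) - p)^2))))
  bonded <- dmin[dmin < 3.2]
  expect_gte(length(bonded), 3)
  expect_true(all(abs(bonded - 2.9) < 0.3))
  # inter-strand spacing ~4.8 A between CA traces
  caA <- as.matrix(at[at$chain == "A" & at$elety == "CA", c("x", "y", "z")])
  caB <- as.matrix(at[at$chain == "B" & at$elety == "CA", c("x", "y", "z")])
  gap <- min(apply(caA, 1, function(p) min(sqrt(colSums((t(caB) - p)^2)))))
  expect_true(gap > 3.9 && gap < 5.7)
  expect_error(buildAntiparallelSheet(1, 8), "at least 2")
  # the detector labels bridge residues sheet
  lab <- assignSecondaryStructure(s)
  expect_gte(sum(lab == "sheet"), 8)
})

test_that("nucleic chains follow A-form-like geometry", {
  nc <- buildNucleicChain(12)
  at <- modelAtoms(nc)
  P <- as.matrix(at[at$elety == "P", c("x", "y", "z")])
  pp <- sqrt(rowSums(diff(P)^2))
  expect_true(all(abs(pp - 5.9) < 0.5))
  lab <- assignSecondaryStructure(nc)
  expect_true(all(lab == "nucleotide"))
  expect_error(buildNucleicChain(1), "at least 2")
  # posed chain fits its declared bounding box
  p <- pose(randomRotation(), c(20, 20, 20))
  nc2 <- buildNucleicChain(8, p)
  xyz <- as.matrix(modelAtoms(nc2)[, c("x", "y", "z")])
  expect_true(all(abs(xyz - 20) < 24))
})

test_that("geometry builders are rigid-motion covariant", {
  set.seed(41)
  R <- randomRotation()
  t <- c(7, -3, 12)
  h0 <- modelAtoms(buildIdealHelix(8))
  h1 <- modelAtoms(buildIdealHelix(8, pose(R, t)))
  xyz0 <- unname(as.matrix(h0[, c("x", "y", "z")]))
  xyz1 <- unname(as.matrix(h1[, c("x", "y", "z")]))
  expect_equal(xyz1, sweep(xyz0 %*% t(R), 2, -t), tolerance = 1e-10)
  # pairwise distances preserved
  expect_equal(as.numeric(dist(xyz1)), as.numeric(dist(xyz0)),
    tolerance = 1e-10)
})

test_that("simulated density peaks at atoms and is reproducible", {
  m <- buildIdealHelix(6, pose(t = c(10, 10, 10)))
  map <- simulateDensity(m, dim = 20, voxelSize = 1.1)
  g <- mapGrid(map)
  # the global maximum voxel lies within one voxel of some atom
  imax <- arrayInd(which.max(g), dim(g))
  center <- (imax - 1) * 1.1
  xyz <- as.matrix(modelAtoms(m)[, c("x", "y", "z")])
  dmin <- min(sqrt(colSums((t(xyz) - as.numeric(center))^2)))
  expect_lt(dmin, 1.1 * sqrt(3))
  # sigma-normalized output
  expect_equal(sqrt(mean((g - mean(g))^2)), 1, tolerance = 1e-6)
  # deterministic with noise off
  map2 <- simulateDensity(m, dim = 20, voxelSize = 1.1)
  expect_identical(mapGrid(map2), g)
  # and under a fixed seed with noise on
  set.seed(50)
  n1 <- simulateDensity(m, dim = 20, voxelSize = 1.1, noiseSigma = 0.1)
  set.seed(50)
  n2 <- simulateDensity(m, dim = 20, voxelSize = 1.1, noiseSigma = 0.1)
  expect_identical(mapGrid(n1), mapGrid(n2))
})

test_that("raw Gaussian-atom density is additive over atoms", {
  m1 <- buildIdealHelix(6, pose(t = c(8, 8, 8)))
  m2 <- buildIdealHelix(6, pose(t = c(30, 30, 8)))
  both <- mergeModels(m1, m2)
  d <- c(40, 40, 20)
  r1 <- haruspex:::.splat_density(m1, d, 1.1, c(0, 0, 0), 1.0)
  r2 <- haruspex:::.splat_density(m2, d, 1.1, c(0, 0, 0), 1.0)
  rb <- haruspex:::.splat_density(both, d, 1.1, c(0, 0, 0), 1.0)
  expect_equal(rb, r1 + r2, tolerance = 1e-12)
  expect_equal(sum(rb), sum(r1) + sum(r2), tolerance = 1e-9)
})

test_that("phantom ground truth is recoverable by the annotation pipeline", {
  set.seed(52)
  for (kind in c("helix", "nucleotide")) {
    model <- switch(kind,
      helix = buildIdealHelix(10, pose(t = c(14, 14, 14))),
      nucleotide = buildNucleicChain(8, pose(t = c(16, 16, 8)))
    )
    map <- simulateDensity(model, dim = 32, voxelSize = 1.1)
    labels <- assignSecondaryStructure(model)
    lv <- annotateVoxels(map, model, labels)
    # voxels within 3 A of backbone atoms of labeled residues carry the
    # generating class
    at <- modelAtoms(model)
    rt <- residueTable(model)
    keep <- rt$key[labels[rt$key] == kind]
    bbn <- if (kind == "nucleotide") {
      c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
    } else {
      c("N", "CA", "C", "O")
    }
    sel <- paste(at$chain, at$resno, at$insert, sep = "\r") %in% keep &
      at$elety %in% bbn
    bb <- as.matrix(at[sel, c("x", "y", "z")])
    d <- dim(mapGrid(map))
    centers <- as.matrix(expand.grid(
      x = (seq_len(d[1]) - 1) * 1.1, y = (seq_len(d[2]) - 1) * 1.1,
      z = (seq_len(d[3]) - 1) * 1.1
    ))
    dmin <- rep(Inf, nrow(centers))
    for (ai in seq_len(nrow(bb))) {
      dmin <- pmin(dmin, sqrt(colSums((t(centers) - bb[ai, ])^2)))
    }
    near <- array(dmin <= 3, dim = d)
    code <- match(kind, VOXEL_CLASSES)
    expect_gte(mean(labelClasses(lv)[near] == code), 0.95)
  }
})

test_that("phantom datasets pass the segment gates and noise-only ones fail", {
  set.seed(53)
  ds <- makePhantomDataset(randomPhantomSpecs(2))
  expect_gte(length(ds$segments), 2)
  # each phantom contributes at least one segment and all four classes
  cl <- labelClasses(ds$phantoms[[1]]$lv)
  expect_setequal(unique(as.vector(cl)), 1:4)
  # an all-noise phantom (no model) yields no segments
  noise_spec <- phantomSpec(list(), dim = 70, noiseSigma = 1.0)
  expect_warning(
    ds0 <- makePhantomDataset(list(noise_spec)),
    "no segment"
  )
  expect_length(ds0$segments, 0)
  # fixed seed reproduces the dataset exactly
  set.seed(54)
  a <- makePhantomDataset(randomPhantomSpecs(1))
  set.seed(54)
  b <- makePhantomDataset(randomPhantomSpecs(1))
  expect_identical(a$segments[[1]]@density, b$segments[[1]]@density)
  expect_identical(a$segments[[1]]@labels, b$segments[[1]]@labels)
})

test_that("phantom labels are pose-invariant", {
  set.seed(55)
  lab0 <- unname(assignSecondaryStructure(buildNucleicChain(6)))
  for (i in 1:2) {
    p <- pose(randomRotation(), runif(3, -10, 30))
    expect_equal(unname(assignSecondaryStructure(buildNucleicChain(6, p))),
      lab0)
  }
})
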