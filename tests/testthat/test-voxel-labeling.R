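test_that("residue backbone density interpolates the map correctly", {
  # constant map: any residue inside reads the constant
  m <- DensityMap(array(2.5, c(8, 8, 8)), voxelSize = 1)
  bb <- rbind(N = c(3, 3, 3), CA = c(4, 4, 4), C = c(5, 5, 5),
    O = c(3.5, 4, 4.5))
  expect_equal(residueBackboneDensity(m, bb), 2.5)
  # single atom exactly at a voxel center picks the node value
  g <- array(0, c(8, 8, 8))
  g[4, 4, 4] <- 3
  m2 <- DensityMap(g, voxelSize = 1)
  expect_equal(residueBackboneDensity(m2, rbind(CA = c(3, 3, 3))), 3)
  # atom at the midpoint of two voxel centers valued 0 and 4
  g3 <- array(0, c(8, 8, 8))
  g3[4, 4, 4] <- 4
  m3 <- DensityMap(g3, voxelSize = 1)
  expect_equal(residueBackboneDensity(m3, rbind(CA = c(2.5, 3, 3))), 2)
  # all atoms outside the map: sentinel
  expect_true(is.na(residueBackboneDensity(m, rbind(CA = c(100, 0, 0)))))
})

test_that("annotateVoxels requires a sigma-normalized map", {
  ph <- toy_phantom(dim = 24, nres = 6)
  raw <- DensityMap(mapGrid(ph$map) * 3, voxelSize = 1.1)
  expect_error(annotateVoxels(raw, ph$model, ph$labels), "normalized")
})

test_that("annotation equals the brute-force oracle on randomized phantoms", {
  set.seed(101)
  cfg <- AnnotationConfig()
  for (i in 1:6) {
    kind <- c("helix", "sheet", "nucleotide")[(i - 1) %% 3 + 1]
    p <- pose(randomRotation(), runif(3, 10, 18))
    model <- switch(kind,
      helix = buildIdealHelix(8, p),
      sheet = buildAntiparallelSheet(2, 6, p),
      nucleotide = buildNucleicChain(6, p)
    )
    map <- simulateDensity(model, dim = 28, voxelSize = 1.1,
      noiseSigma = 0.05)
    labels <- assignSecondaryStructure(model)
    lv <- annotateVoxels(map, model, labels, cfg)
    or <- oracle_annotate(map, model, labels, cfg)
    expect_identical(labelClasses(lv), or$classes)
    expect_identical(labelMask(lv), or$mask)
  }
})

test_that("residues between 1 and 2 sigma mask instead of annotate", {
  # raise the map r.m.s.d. with off-model noise until the helix backbone
  # reads between the mask gate (1 sigma) and the annotate gate (2 sigma)
  model <- buildIdealHelix(8, pose(t = c(13, 13, 13)))
  at <- modelAtoms(model)
  bb <- as.matrix(at[at$elety %in% c("N", "CA", "C", "O"), c("x", "y", "z")])
  labels <- assignSecondaryStructure(model)
  scaled <- NULL
  set.seed(33)
  for (noise in c(0.2, 0.35, 0.5, 0.8, 1.2)) {
    map <- simulateDensity(model, dim = 24, voxelSize = 1.1,
      noiseSigma = noise)
    dens <- mean(interpolateDensity(map, bb))
    if (dens > 1 && dens < 2) {
      scaled <- map
      break
    }
  }
  expect_false(is.null(scaled))
  lv <- annotateVoxels(scaled, model, labels)
  # the gate applies per residue: find the residues whose own backbone mean
  # sits in [1, 2) sigma and check their neighborhoods
  rt <- residueTable(model)
  gated <- list()
  annotated <- FALSE
  for (r in seq_len(nrow(rt))) {
    if (labels[[rt$key[r]]] == "unassigned") next # never gated
    sel <- at$resno == rt$resno[r] & at$elety %in% c("N", "CA", "C", "O")
    rb <- as.matrix(at[sel, c("x", "y", "z")])
    dr <- mean(interpolateDensity(scaled, rb))
    if (dr >= 1 && dr < 2) gated[[length(gated) + 1]] <- rb
    if (dr > 2) annotated <- TRUE
  }
  expect_gt(length(gated), 0)
  if (!annotated) expect_true(all(labelClasses(lv) == 4L))
  d <- dim(mapGrid(scaled))
  centers <- as.matrix(expand.grid(
    x = (seq_len(d[1]) - 1) * 1.1, y = (seq_len(d[2]) - 1) * 1.1,
    z = (seq_len(d[3]) - 1) * 1.1
  ))
  for (rb in gated) {
    dmin <- rep(Inf, nrow(centers))
    for (ai in seq_len(nrow(rb))) {
      dmin <- pmin(dmin, sqrt(colSums((t(centers) - rb[ai, ])^2)))
    }
    near <- array(dmin <= 3, dim = d) & labelClasses(lv) == 4L
    expect_true(all(!labelMask(lv)[near]))
  }
})

test_that("unmodelled density far from atoms is excluded from training", {
  model <- buildIdealHelix(10, pose(t = c(8, 14, 14)))
  raw <- haruspex:::.splat_density(model, c(28, 28, 28), 1.1, c(0, 0, 0), 1.0)
  # a synthetic blob >5 A from every atom, and a sub-floor ripple
  blob_center <- c(26, 26, 26) # voxel indices; far corner
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    raw[blob_center[1] + dx, blob_center[2] + dy, blob_center[3] + dz] <-
      raw[blob_center[1] + dx, blob_center[2] + dy, blob_center[3] + dz] + 2
  }
  ripple <- c(2, 26, 2)
  raw[ripple[1], ripple[2], ripple[3]] <- 0.05
  map <- sigmaNormalize(DensityMap(raw, voxelSize = 1.1))
  labels <- assignSecondaryStructure(model)
  lv <- annotateVoxels(map, model, labels)
  g <- mapGrid(map)
  # blob voxels above 1 sigma are excluded
  expect_gt(g[26, 26, 26], 1)
  expect_false(labelMask(lv)[26, 26, 26])
  # the ripple stays below 1 sigma and remains trainable
  expect_lt(g[2, 26, 2], 1)
  expect_true(labelMask(lv)[2, 26, 2])
  expect_equal(labelClasses(lv)[2, 26, 2], 4L)
})

test_that("no voxel is both class-labeled and excluded", {
  ph <- toy_phantom(dim = 28, nres = 10, noise = 0.05)
  lv <- annotateVoxels(ph$map, ph$model, ph$labels)
  labeled <- labelClasses(lv) != 4L
  expect_true(all(labelMask(lv)[labeled]))
})

test_that("annotation is equivariant under integer-voxel translation", {
  shift_vox <- c(2L, 3L, 1L)
  v <- 1.1
  base <- toy_phantom(dim = 26, nres = 8)
  moved_model <- new("StructuralModel",
    atoms = within(modelAtoms(base$model), {
      x <- x + shift_vox[1] * v
      y <- y + shift_vox[2] * v
      z <- z + shift_vox[3] * v
    }),
    authorSS = authorSS(base$model)
  )
  moved_map <- simulateDensity(moved_model, dim = 26 + max(shift_vox),
    voxelSize = v)
  lv1 <- annotateVoxels(base$map, base$model, base$labels)
  lv2 <- annotateVoxels(moved_map, moved_model,
    assignSecondaryStructure(moved_model))
  d <- dim(labelClasses(lv1))
  inner <- lapply(1:3, function(a) 1:(d[a] - max(shift_vox)))
  a1 <- labelClasses(lv1)[inner[[1]], inner[[2]], inner[[3]]]
  a2 <- labelClasses(lv2)[
    inner[[1]] + shift_vox[1], inner[[2]] + shift_vox[2],
    inner[[3]] + shift_vox[3]
  ]
  # identical class pattern where both volumes are defined; small border
  # effects from the map's own normalization are tolerated
  expect_gt(mean(a1 == a2), 0.995)
  expect_identical(sort(unique(as.vector(a1))), sort(unique(as.vector(a2))))
})

test_that("one-hot encoding sums to one and serialization round-trips", {
  ph <- toy_phantom(dim = 20, nres = 6)
  lv <- annotateVoxels(ph$map, ph$model, ph$labels)
  oh <- labelOneHot(lv)
  expect_true(all(apply(oh, 1:3, sum) == 1))
  pre <- tempfile()
  paths <- writeLabelVolume(lv, pre)
  cl <- readMRC(paste0(pre, "_classes.mrc"))
  mk <- readMRC(paste0(pre, "_mask.mrc"))
  expect_identical(array(as.integer(mapGrid(cl)), dim(labelClasses(lv))),
    labelClasses(lv))
  expect_identical(array(mapGrid(mk) > 0, dim(labelMask(lv))),
    labelMask(lv))
})
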