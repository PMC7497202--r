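# --- ideal backbone geometry -------------------------------------------------
# Natural-extension-reference-frame placement: position D given A, B, C and
# the internal coordinates r(C-D), angle(B-C-D) and torsion(A-B-C-D).
.place_atom <- function(a, b, c, r, theta_deg, chi_deg) {
  th <- theta_deg * pi / 180
  ch <- chi_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n^2))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  # sign convention chosen so that a chain built with torsion chi measures
  # chi under the IUPAC dihedral rule (right-handed helices from negative phi)
  d2 <- r * c(-cos(th), sin(th) * cos(ch), -sin(th) * sin(ch))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# standard peptide bond lengths (A) and angles (deg)
.PEP <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8
)

# backbone (N, CA, C, O) of an n-residue chain with per-residue phi/psi and
# omega = 180; returns an atom data.frame in local coordinates
.build_backbone <- function(n, phi, psi, chain = "A", startRes = 1L,
                            resid = "ALA") {
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  g <- .PEP
  N <- matrix(0, n, 3)
  CA <- matrix(0, n, 3)
  C <- matrix(0, n, 3)
  O <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  aa <- (180 - g$ang_n_ca_c) * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(cos(aa), sin(aa), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .place_atom(
        N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$c_n,
        g$ang_ca_c_n, psi[i - 1]
      )
      CA[i, ] <- .place_atom(
        CA[i - 1, ], C[i - 1, ], N[i, ], g$n_ca,
        g$ang_c_n_ca, 180
      )
      C[i, ] <- .place_atom(
        C[i - 1, ], N[i, ], CA[i, ], g$ca_c,
        g$ang_n_ca_c, phi[i]
      )
    }
    O[i, ] <- .place_atom(
      N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o,
      psi[i] + 180
    )
  }
  xyz <- rbind(N, CA, C, O)[rep(seq_len(n), each = 4) + c(0, n, 2 * n, 3 * n), ]
  data.frame(
    chain = chain, resno = startRes + rep(seq_len(n) - 1L, each = 4L),
    insert = "", resid = resid,
    elety = rep(c("N", "CA", "C", "O"), n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], kind = "amino",
    stringsAsFactors = FALSE
  )
}

.apply_pose <- function(at, pose) {
  if (is.null(pose)) {
    return(at)
  }
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(pose$R)
  at$x <- xyz[, 1] + pose$t[1]
  at$y <- xyz[, 2] + pose$t[2]
  at$z <- xyz[, 3] + pose$t[3]
  at
}

.as_model <- function(at) {
  new("StructuralModel", atoms = at, authorSS = data.frame(
    chain = character(), start = integer(), end = integer(),
    class = character(), stringsAsFactors = FALSE
  ))
}

#' Identity pose
#'
#' @param R 3x3 rotation matrix.
#' @param t translation vector (Angstrom).
#' @return Pose list for the geometry builders.
#' @export
pose <- function(R = diag(3), t = c(0, 0, 0)) list(R = R, t = t)

#' Uniform random rotation matrix
#'
#' Drawn from R's RNG (QR decomposition of a Gaussian matrix, determinant
#' fixed to +1), so deterministic under `set.seed()`.
#'
#' @return 3x3 rotation matrix.
#' @export
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Build an ideal alpha-helix backbone
#'
#' Full backbone (N, CA, C, O) from ideal internal coordinates
#' (phi = -57, psi = -47, omega = 180, standard bond lengths and angles),
#' rigid-transformed by `pose`. A 10-residue helix is about 15 Angstrom long
#' (1.5 Angstrom rise per residue).
#'
#' @param n number of residues (>= 4).
#' @param pose rigid transform from [pose()].
#' @param chain chain identifier.
#' @return A [StructuralModel-class] fragment.
#' @export
buildIdealHelix <- function(n, pose = NULL, chain = "A") {
  if (n < 4) stop("an alpha-helix fixture needs at least 4 residues")
  .as_model(.apply_pose(.build_backbone(n, -57, -47, chain = chain), pose))
}

#' Build an extended single beta-strand backbone
#'
#' An isolated strand in the beta basin (phi = -135, psi = 135) with no
#' hydrogen-bonding partner; useful as a negative control for bridge
#' detection.
#'
#' @param n number of residues (>= 2).
#' @param pose rigid transform.
#' @param chain chain identifier.
#' @return A [StructuralModel-class] fragment.
#' @export
buildExtendedStrand <- function(n, pose = NULL, chain = "A") {
  if (n < 2) stop("a strand needs at least 2 residues")
  .as_model(.apply_pose(.build_backbone(n, -135, 135, chain = chain), pose))
}

# Antiparallel pairing geometry, calibrated once against the package's own
# hydrogen-bond detector and frozen. The strand is first rotated into a
# canonical frame (screw axis along x, mean carbonyl direction along y),
# then the partner strand is the 180-degree rotation about y, translated by
# .SHEET_T; every further strand repeats with period .SHEET_PERIOD.
.SHEET_RF <- matrix(c(
  0.843559, 0.536312, -0.027892,
  -0.453734, 0.739530, 0.497213,
  0.287288, -0.406773, 0.867180
), 3, 3, byrow = TRUE)
.SHEET_FLIP <- diag(c(-1, 1, -1))
.SHEET_T <- c(24.6, 4.0, -0.6)
.SHEET_PERIOD <- c(-4.1, 8.05, 0)

#' Build an idealized antiparallel beta-sheet backbone
#'
#' Extended strands (phi = -135, psi = 135) paired antiparallel at about
#' 4.8 Angstrom inter-strand spacing with a canonical hydrogen-bond registry
#' (inter-strand N...O close to 2.9 Angstrom at the bonded positions). Each
#' strand is its own chain (A, B, C, ...).
#'
#' @param nStrands number of strands (>= 2).
#' @param strandLen residues per strand.
#' @param pose rigid transform applied to the whole sheet.
#' @return A [StructuralModel-class] fragment.
#' @export
buildAntiparallelSheet <- function(nStrands, strandLen = 8, pose = NULL) {
  if (nStrands < 2) stop("an antiparallel sheet needs at least 2 strands")
  base <- .build_backbone(strandLen, -135, 135)
  xyz1 <- as.matrix(base[, c("x", "y", "z")]) %*% t(.SHEET_RF)
  at <- NULL
  for (s in seq_len(nStrands)) {
    shift <- ((s - 1) %/% 2) * .SHEET_PERIOD
    if (s %% 2 == 1) {
      xyz <- sweep(xyz1, 2, shift, "+")
    } else {
      xyz <- sweep(xyz1 %*% t(.SHEET_FLIP), 2, .SHEET_T + shift, "+")
    }
    a <- base
    a$chain <- LETTERS[s]
    a$x <- xyz[, 1]
    a$y <- xyz[, 2]
    a$z <- xyz[, 3]
    at <- rbind(at, a)
  }
  .as_model(.apply_pose(at, pose))
}

# approximate A-form backbone template: cylindrical (radius A, phase deg,
# rise A) per atom relative to the residue's P phosphorus
.NUC_TEMPLATE <- data.frame(
  elety = c("P", "O5'", "C5'", "C4'", "C3'", "O3'"),
  r = c(8.71, 8.39, 8.63, 8.18, 8.48, 8.28),
  phase = c(0, 5.8, 11.9, 18.0, 23.7, 29.1),
  z = c(0, 0.88, 1.66, 2.26, 2.88, 2.66),
  stringsAsFactors = FALSE
)
.NUC_TWIST <- 32.7 # degrees per residue
.NUC_RISE <- 2.81 # Angstrom per residue

#' Build a simplified single-stranded nucleic-acid backbone
#'
#' Places the six backbone atoms (P, O5', C5', C4', C3', O3') of each
#' residue on an A-form-like helix (32.7 degrees twist, 2.81 Angstrom rise),
#' giving consecutive P-P distances near 5.9 Angstrom. Bases and sugars
#' beyond the backbone are not modelled.
#'
#' @param n number of residues (>= 2).
#' @param pose rigid transform.
#' @param chain chain identifier.
#' @return A [StructuralModel-class] fragment with residues of kind
#'   nucleotide.
#' @export
buildNucleicChain <- function(n, pose = NULL, chain = "A") {
  if (n < 2) stop("a nucleic-acid fixture needs at least 2 residues")
  tpl <- .NUC_TEMPLATE
  rows <- lapply(seq_len(n), function(i) {
    ph <- (tpl$phase + (i - 1) * .NUC_TWIST) * pi / 180
    data.frame(
      chain = chain, resno = i, insert = "", resid = "U",
      elety = tpl$elety,
      x = tpl$r * cos(ph), y = tpl$r * sin(ph),
      z = tpl$z + (i - 1) * .NUC_RISE,
      kind = "nucleotide", stringsAsFactors = FALSE
    )
  })
  .as_model(.apply_pose(do.call(rbind, rows), pose))
}

#' Merge several model fragments
#'
#' Chains are relabeled (A, B, C, ...) to stay unique.
#'
#' @param ... [StructuralModel-class] fragments.
#' @return A combined [StructuralModel-class].
#' @export
mergeModels <- function(...) {
  frags <- list(...)
  if (length(frags) == 1 && is.list(frags[[1]]) &&
    !is(frags[[1]], "StructuralModel")) {
    frags <- frags[[1]]
  }
  if (length(frags) == 0) {
    return(.as_model(data.frame(
      chain = character(), resno = integer(), insert = character(),
      resid = character(), elety = character(), x = numeric(),
      y = numeric(), z = numeric(), kind = character(),
      stringsAsFactors = FALSE
    )))
  }
  at <- NULL
  ci <- 0L
  for (fr in frags) {
    a <- fr@atoms
    for (ch in unique(a$chain)) {
      ci <- ci + 1L
      a$chain[a$chain == ch] <- sprintf("%s", c(LETTERS, letters)[ci])
    }
    at <- rbind(at, a)
  }
  .as_model(at)
}

# electron counts of the elements occurring in the fixtures; Gaussian
# amplitudes scale with them so that phosphate groups are brighter than
# carbon/nitrogen/oxygen, as in experimental maps
.ELECTRONS <- c(C = 6, N = 7, O = 8, P = 15, S = 16)

.atom_weight <- function(elety) {
  el <- substr(sub("^[0-9']+", "", elety), 1, 1)
  z <- .ELECTRONS[el]
  z[is.na(z)] <- 6
  unname(z / 6)
}

# raw (un-normalized) Gaussian-atom density accumulation
.splat_density <- function(model, d, voxelSize, origin, atomSigma) {
  g <- array(0, dim = d)
  xyz <- as.matrix(model@atoms[, c("x", "y", "z")])
  amp <- .atom_weight(model@atoms$elety)
  reach <- 4 * atomSigma
  for (i in seq_len(nrow(xyz))) {
    nb <- .voxels_near(xyz[i, ], reach, d, voxelSize, origin)
    if (length(nb$lin) == 0) next
    g[nb$lin] <- g[nb$lin] + amp[i] * exp(-nb$d2 / (2 * atomSigma^2))
  }
  g
}

#' Simulate a density map from a model
#'
#' Places an isotropic Gaussian of width `atomSigma` at every atom center,
#' with an amplitude proportional to the element's electron count (so
#' phosphorus-rich nucleic-acid backbones are brighter than protein, as in
#' experimental maps), adds optional Gaussian pixel noise, and
#' sigma-normalizes the result.
#' This is a testing phantom: it has none of the error structure or
#' processing artifacts of experimentally reconstructed maps.
#'
#' @param model a [StructuralModel-class].
#' @param dim grid dimensions (voxels), scalar or length 3.
#' @param voxelSize Angstrom per voxel.
#' @param origin Cartesian origin of voxel (0,0,0).
#' @param atomSigma Gaussian atom width in Angstrom (default 1.0).
#' @param noiseSigma additive noise level, in units of the noise-free
#'   Gaussian peak amplitude (default 0).
#' @return A sigma-normalized [DensityMap-class].
#' @export
simulateDensity <- function(model, dim = 70L, voxelSize = 1.1,
                            origin = c(0, 0, 0), atomSigma = 1.0,
                            noiseSigma = 0) {
  d <- as.integer(rep_len(dim, 3L))
  g <- .splat_density(model, d, voxelSize, origin, atomSigma)
  if (noiseSigma > 0) {
    g <- g + array(rnorm(prod(d), sd = noiseSigma), dim = d)
  }
  sigmaNormalize(DensityMap(g, voxelSize = voxelSize, origin = origin))
}

#' Specification of one synthetic phantom
#'
#' @param elements list of element descriptors, each a list with `kind`
#'   ("helix", "sheet" or "nucleotide"), `n` (residues, or residues per
#'   strand for sheets), optional `nStrands`, and `pose`.
#' @param dim grid dimensions in voxels (default 70).
#' @param voxelSize Angstrom per voxel (default 1.1).
#' @param atomSigma Gaussian atom width (default 1.0 Angstrom).
#' @param noiseSigma additive noise level (default 0.05).
#' @return A phantom specification list.
#' @export
phantomSpec <- function(elements, dim = 70L, voxelSize = 1.1,
                        atomSigma = 1.0, noiseSigma = 0.05) {
  list(
    elements = elements, dim = as.integer(rep_len(dim, 3L)),
    voxelSize = voxelSize, atomSigma = atomSigma, noiseSigma = noiseSigma
  )
}

.build_element <- function(el) {
  m <- switch(el$kind,
    helix = buildIdealHelix(el$n),
    sheet = buildAntiparallelSheet(el$nStrands %||% 4L, el$n),
    nucleotide = buildNucleicChain(el$n),
    stop("unknown element kind: ", el$kind)
  )
  at <- m@atoms
  if (isTRUE(el$center)) {
    # pose acts about the element centroid
    ctr <- colMeans(as.matrix(at[, c("x", "y", "z")]))
    at$x <- at$x - ctr[1]
    at$y <- at$y - ctr[2]
    at$z <- at$z - ctr[3]
  }
  .as_model(.apply_pose(at, el$pose))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build one phantom: model, simulated map, labels and label volume
#'
#' @param spec a [phantomSpec()].
#' @param cfg an [AnnotationConfig-class].
#' @return List with `model`, `map` (sigma-normalized), `labels`
#'   (per-residue) and `lv` ([LabelVolume-class]).
#' @export
buildPhantom <- function(spec, cfg = AnnotationConfig()) {
  model <- mergeModels(lapply(spec$elements, .build_element))
  map <- simulateDensity(model,
    dim = spec$dim, voxelSize = spec$voxelSize,
    atomSigma = spec$atomSigma, noiseSigma = spec$noiseSigma
  )
  labels <- assignSecondaryStructure(model)
  lv <- annotateVoxels(map, model, labels, cfg)
  list(model = model, map = map, labels = labels, lv = lv)
}

# place an element without steric clashes: draw a random orientation, then
# a translation uniform over all positions that keep every atom at least
# `margin` Angstrom from the box faces; keep the first pose whose atoms
# stay >= minDist from all already-placed atoms (after `tries` attempts,
# the pose with the largest clearance wins). Elements can touch at
# van-der-Waals-like distances, as in a real assembly, but never
# interpenetrate.
.place_clash_free <- function(local_xyz, placed_xyz, extent,
                              margin = 5, minDist = 3.5, tries = 40) {
  centroid <- colMeans(local_xyz)
  centered <- sweep(local_xyz, 2, centroid)
  best <- NULL
  for (k in seq_len(tries)) {
    R <- randomRotation()
    xyz0 <- centered %*% t(R)
    t_lo <- margin - apply(xyz0, 2, min)
    t_hi <- (extent - margin) - apply(xyz0, 2, max)
    if (any(t_hi < t_lo)) next # does not fit at this orientation
    tr <- t_lo + runif(3) * (t_hi - t_lo)
    xyz <- sweep(xyz0, 2, tr, "+")
    p <- list(R = R, t = tr)
    if (is.null(placed_xyz) || nrow(placed_xyz) == 0) {
      return(list(pose = p, xyz = xyz, clearance = Inf))
    }
    cross <- xyz %*% t(placed_xyz)
    d2 <- outer(rowSums(xyz^2), rowSums(placed_xyz^2), "+") - 2 * cross
    dmin <- sqrt(max(min(d2), 0))
    if (dmin >= minDist) {
      return(list(pose = p, xyz = xyz, clearance = dmin))
    }
    if (is.null(best) || dmin > best$clearance) {
      best <- list(pose = p, xyz = xyz, clearance = dmin)
    }
  }
  if (is.null(best)) stop("element does not fit inside the phantom box")
  best
}

#' Random phantom specifications
#'
#' Each phantom packs twelve structural elements (four helices, four
#' antiparallel sheets, four nucleic chains) at random poses inside the
#' box, leaving at least 5 Angstrom margin, emulating the dense packing of
#' a macromolecular assembly so that the default segment filter (at least
#' 5 % annotated volume) is satisfiable. Element sizes: 36-residue helices,
#' 5 x 10-residue antiparallel sheets, 16-residue nucleic chains.
#'
#' @param n number of phantoms.
#' @param dim box edge in voxels (default 70).
#' @param voxelSize Angstrom per voxel (default 1.1).
#' @param noiseSigma additive noise level (default 0.05).
#' @return List of [phantomSpec()] objects.
#' @export
randomPhantomSpecs <- function(n, dim = 70L, voxelSize = 1.1,
                               noiseSigma = 0.05) {
  extent <- rep_len(dim, 3) * voxelSize
  lapply(seq_len(n), function(i) {
    kinds <- sample(rep(c("helix", "sheet", "nucleotide"), each = 4L))
    placed <- NULL
    elements <- lapply(kinds, function(k) {
      el <- list(kind = k)
      el$n <- switch(k, helix = 36L, sheet = 10L, nucleotide = 16L)
      if (k == "sheet") el$nStrands <- 5L
      local <- as.matrix(modelAtoms(.build_element(c(el, list(pose = NULL))))[
        , c("x", "y", "z")])
      # local builder coordinates are not centered; recenter before posing
      pl <- .place_clash_free(local, placed, extent)
      placed <<- rbind(placed, pl$xyz)
      el$pose <- pl$pose
      el$center <- TRUE
      el
    })
    phantomSpec(elements,
      dim = dim, voxelSize = voxelSize,
      noiseSigma = noiseSigma
    )
  })
}

#' Build a phantom training dataset
#'
#' For each specification: build the model, simulate its density, assign
#' residue labels, annotate voxels, and cut filtered training segments.
#' Specifications yielding no segment that passes the [SegmentFilter-class]
#' are skipped with a warning.
#'
#' @param specs list of [phantomSpec()] objects.
#' @param cfg an [AnnotationConfig-class].
#' @param filter a [SegmentFilter-class].
#' @return List with `segments` (list of [Segment-class]) and `phantoms`
#'   (list of [buildPhantom()] results, one per spec).
#' @export
makePhantomDataset <- function(specs, cfg = AnnotationConfig(),
                               filter = SegmentFilter()) {
  segments <- list()
  phantoms <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    ph <- buildPhantom(specs[[i]], cfg)
    segs <- extractSegments(ph$map, ph$model, ph$lv, filter,
      segSize = min(specs[[i]]$dim),
      mapId = sprintf("phantom%03d", i)
    )
    if (length(segs) == 0) {
      warning("phantom ", i, " produced no segment passing the filter; skipped")
    }
    segments <- c(segments, segs)
    phantoms[[i]] <- ph
  }
  list(segments = segments, phantoms = phantoms)
}
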