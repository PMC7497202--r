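#' Annotation configuration constructor
#'
#' @param labelRadius,farRadius,annotateGate,maskGate,densityFloor see
#'   [AnnotationConfig-class]; defaults 3 A, 5 A, 2 sigma, 1 sigma, 1 sigma.
#' @return An [AnnotationConfig-class].
#' @export
AnnotationConfig <- function(labelRadius = 3.0, farRadius = 5.0,
                             annotateGate = 2.0, maskGate = 1.0,
                             densityFloor = 1.0) {
  new("AnnotationConfig",
    labelRadius = labelRadius, farRadius = farRadius,
    annotateGate = annotateGate, maskGate = maskGate,
    densityFloor = densityFloor
  )
}

.BACKBONE_AMINO <- c("N", "CA", "C", "O")
.BACKBONE_NUC <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

.backbone_names <- function(kind) {
  if (kind == "nucleotide") .BACKBONE_NUC else .BACKBONE_AMINO
}

# backbone atom coordinates of one residue (those present), n x 3
.backbone_coords <- function(coords, kind) {
  sel <- rownames(coords) %in% .backbone_names(kind)
  coords[sel, , drop = FALSE]
}

#' Mean backbone density of a residue
#'
#' Trilinearly interpolates a sigma-normalized map at the residue's backbone
#' atom positions (amino acids: N, CA, C, O; nucleotides: P, O5', C5', C4',
#' C3', O3', whichever are present) and averages over the atoms that lie
#' inside the map extent.
#'
#' @param map a sigma-normalized [DensityMap-class].
#' @param backbone n x 3 matrix of backbone atom coordinates (Angstrom), as
#'   returned for one residue by the model accessors.
#' @return Mean density in sigma units, or `NA` (the out-of-map sentinel)
#'   when every backbone atom lies outside the map extent.
#' @export
residueBackboneDensity <- function(map, backbone) {
  if (nrow(backbone) == 0) {
    return(NA_real_)
  }
  d <- dim(map@grid)
  idx <- sweep(backbone, 2, map@origin) / map@voxelSize
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
    idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
    idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  if (!any(inside)) {
    return(NA_real_)
  }
  mean(.trilinear_index(map@grid, idx[inside, , drop = FALSE]))
}

# linear voxel indices (1-based) and squared distances of all voxel centers
# within radius r of point p
.voxels_near <- function(p, r, d, v, o) {
  lo <- pmax(ceiling((p - r - o) / v), 0)
  hi <- pmin(floor((p + r - o) / v), d - 1)
  if (any(lo > hi)) {
    return(list(lin = integer(0), d2 = numeric(0)))
  }
  ii <- lo[1]:hi[1]
  jj <- lo[2]:hi[2]
  kk <- lo[3]:hi[3]
  dx2 <- (o[1] + ii * v - p[1])^2
  dy2 <- (o[2] + jj * v - p[2])^2
  dz2 <- (o[3] + kk * v - p[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  sel <- which(d2 <= r * r)
  if (length(sel) == 0) {
    return(list(lin = integer(0), d2 = numeric(0)))
  }
  ni <- length(ii)
  nj <- length(jj)
  a <- arrayInd(sel, c(ni, nj, length(kk)))
  lin <- (ii[a[, 1]]) + d[1] * (jj[a[, 2]]) + d[1] * d[2] * (kk[a[, 3]]) + 1
  list(lin = lin, d2 = d2[sel])
}

#' Ground-truth voxel annotation of a map from a labeled model
#'
#' Applies the density-gated distance rules that turn per-residue labels into
#' a per-voxel [LabelVolume-class]:
#' for every helix/sheet/nucleotide residue whose mean backbone density
#' exceeds `annotateGate` (2 sigma), all voxels whose centers lie within
#' `labelRadius` (3 A) of its backbone atoms receive the residue class; when
#' the backbone density falls in `[maskGate, annotateGate)` (1-2 sigma) those
#' voxels are excluded from training instead; voxels farther than `farRadius`
#' (5 A) from every model atom but with density at least `densityFloor`
#' (1 sigma) are also excluded (high density that was never modelled); all
#' remaining voxels are unassigned and trainable. When a voxel lies within
#' `labelRadius` of residues with different classes, the nearest backbone
#' atom wins; exact distance ties are resolved by the fixed priority
#' nucleotide > helix > sheet. Voxels that receive a class are never masked.
#'
#' @param map a sigma-normalized [DensityMap-class].
#' @param model the co-registered [StructuralModel-class].
#' @param labels per-residue classes from [assignSecondaryStructure()].
#' @param cfg an [AnnotationConfig-class].
#' @return A [LabelVolume-class] co-registered with `map`.
#' @export
annotateVoxels <- function(map, model, labels, cfg = AnnotationConfig()) {
  stopifnot(is(map, "DensityMap"), is(model, "StructuralModel"))
  validObject(cfg)
  if (!.is_normalized(map)) {
    stop("annotateVoxels requires a sigma-normalized map; see sigmaNormalize()")
  }
  d <- dim(map@grid)
  v <- map@voxelSize
  o <- map@origin
  nvox <- prod(d)

  rt <- residueTable(model)
  ridx <- .residue_index(model)
  at <- model@atoms

  # class priority for exact-tie resolution: nucleotide > helix > sheet
  tie_rank <- c(helix = 2, sheet = 3, nucleotide = 1)
  class_code <- c(helix = 1L, sheet = 2L, nucleotide = 3L)

  best_d2 <- rep(Inf, nvox)
  best_rank <- rep(99L, nvox)
  best_class <- integer(nvox) # 0 = none
  mask_excl <- logical(nvox) # residue-gate exclusions

  for (r in seq_len(nrow(rt))) {
    cls <- labels[[rt$key[r]]]
    if (is.na(cls) || cls == "unassigned") next
    coords <- .residue_coords(at, ridx[[r]])
    bb <- .backbone_coords(coords, rt$kind[r])
    dens <- residueBackboneDensity(map, bb)
    if (is.na(dens) || dens < cfg@maskGate) next
    annotate <- dens > cfg@annotateGate
    for (ai in seq_len(nrow(bb))) {
      nb <- .voxels_near(bb[ai, ], cfg@labelRadius, d, v, o)
      if (length(nb$lin) == 0) next
      if (annotate) {
        rk <- tie_rank[[cls]]
        cc <- class_code[[cls]]
        closer <- nb$d2 < best_d2[nb$lin] - 1e-9
        tied <- abs(nb$d2 - best_d2[nb$lin]) <= 1e-9 &
          rk < best_rank[nb$lin]
        upd <- closer | tied
        if (any(upd)) {
          lin <- nb$lin[upd]
          best_d2[lin] <- nb$d2[upd]
          best_rank[lin] <- rk
          best_class[lin] <- cc
        }
      } else {
        mask_excl[nb$lin] <- TRUE
      }
    }
  }

  # voxels within farRadius of any model atom (all atoms, not just backbone)
  near_any <- logical(nvox)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  for (ai in seq_len(nrow(xyz))) {
    nb <- .voxels_near(xyz[ai, ], cfg@farRadius, d, v, o)
    near_any[nb$lin] <- TRUE
  }

  classes <- rep(4L, nvox)
  classes[best_class > 0L] <- best_class[best_class > 0L]
  mask <- rep(TRUE, nvox)
  unlabeled <- best_class == 0L
  mask[mask_excl & unlabeled] <- FALSE
  mask[!near_any & as.vector(map@grid) >= cfg@densityFloor & unlabeled] <- FALSE

  new("LabelVolume",
    classes = array(classes, dim = d), mask = array(mask, dim = d),
    voxelSize = v, origin = o
  )
}

#' @describeIn annotateVoxels class-code grid accessor (1..4, see
#'   [VOXEL_CLASSES])
#' @param lv a [LabelVolume-class]
#' @export
labelClasses <- function(lv) lv@classes

#' @describeIn annotateVoxels training-mask grid accessor (TRUE = train)
#' @export
labelMask <- function(lv) lv@mask

#' @export
setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@classes)
  tab <- tabulate(object@classes, nbins = 4)
  cat(sprintf("LabelVolume: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf(
    "  helix %d | sheet %d | nucleotide %d | unassigned %d; excluded %d\n",
    tab[1], tab[2], tab[3], tab[4], sum(!object@mask)
  ))
})

#' One-hot encoding of a LabelVolume
#'
#' @param lv a [LabelVolume-class].
#' @return 4D numeric array dim c(nx, ny, nz, 4); channels sum to 1 at every
#'   voxel.
#' @export
labelOneHot <- function(lv) {
  d <- dim(lv@classes)
  oh <- array(0, dim = c(d, 4))
  for (k in 1:4) oh[, , , k] <- as.numeric(lv@classes == k)
  oh
}

#' Serialize a LabelVolume as MRC files
#'
#' Writes `<prefix>_classes.mrc` (integer class codes 1..4 stored as float)
#' and `<prefix>_mask.mrc` (1 = train, 0 = exclude), each carrying the
#' volume's registration.
#'
#' @param lv a [LabelVolume-class].
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
writeLabelVolume <- function(lv, prefix) {
  pc <- paste0(prefix, "_classes.mrc")
  pm <- paste0(prefix, "_mask.mrc")
  writeMRC(DensityMap(array(as.numeric(lv@classes), dim(lv@classes)),
    voxelSize = lv@voxelSize, origin = lv@origin
  ), pc)
  writeMRC(DensityMap(array(as.numeric(lv@mask), dim(lv@mask)),
    voxelSize = lv@voxelSize, origin = lv@origin
  ), pm)
  invisible(c(pc, pm))
}
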