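# Shared fixtures, built in code at test time.

# a small reproducible density map with a known grid
toy_map <- function(d = c(8, 10, 12), voxel = 1.1, origin = c(0, 0, 0),
                    seed = 1) {
  set.seed(seed)
  DensityMap(array(rnorm(prod(d)), dim = d), voxelSize = voxel,
    origin = origin)
}

# one small phantom (single helix) on a compact grid, normalized
toy_phantom <- function(dim = 32, seed = 1, noise = 0, nres = 12,
                        poseR = diag(3), poset = NULL) {
  set.seed(seed)
  if (is.null(poset)) poset <- rep(dim * 1.1 / 2 - 9, 3)
  model <- buildIdealHelix(nres, pose = pose(poseR, poset))
  map <- simulateDensity(model, dim = dim, voxelSize = 1.1,
    noiseSigma = noise)
  labels <- assignSecondaryStructure(model)
  list(model = model, map = map, labels = labels)
}

# Independent brute-force voxel-annotation oracle: O(voxels x atoms) scan
# implementing the 3 A / 5 A / 1 sigma / 2 sigma rules directly.
oracle_annotate <- function(map, model, labels, cfg = AnnotationConfig()) {
  g <- mapGrid(map)
  d <- dim(g)
  v <- voxelSize(map)
  o <- mapOrigin(map)
  at <- modelAtoms(model)
  rt <- residueTable(model)

  centers <- as.matrix(expand.grid(
    x = o[1] + (seq_len(d[1]) - 1) * v,
    y = o[2] + (seq_len(d[2]) - 1) * v,
    z = o[3] + (seq_len(d[3]) - 1) * v
  ))
  nvox <- nrow(centers)

  bb_names <- function(kind) {
    if (kind == "nucleotide") {
      c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
    } else {
      c("N", "CA", "C", "O")
    }
  }
  # per-residue backbone density by independent trilinear interpolation
  interp1 <- function(p) {
    f <- (p - o) / v
    i0 <- floor(f)
    acc <- 0
    for (dx in 0:1) {
      for (dy in 0:1) {
        for (dz in 0:1) {
          ii <- i0 + c(dx, dy, dz)
          w <- prod(ifelse(c(dx, dy, dz) == 1, f - i0, 1 - (f - i0)))
          if (all(ii >= 0) && all(ii < d) && w > 0) {
            acc <- acc + w * g[ii[1] + 1, ii[2] + 1, ii[3] + 1]
          }
        }
      }
    }
    acc
  }

  best_d <- rep(Inf, nvox)
  best_class <- integer(nvox)
  best_rank <- rep(99L, nvox)
  mask_excl <- logical(nvox)
  rank_of <- c(helix = 2L, sheet = 3L, nucleotide = 1L)
  code_of <- c(helix = 1L, sheet = 2L, nucleotide = 3L)

  for (r in seq_len(nrow(rt))) {
    cls <- labels[[rt$key[r]]]
    if (cls == "unassigned") next
    sel <- at$chain == rt$chain[r] & at$resno == rt$resno[r] &
      at$insert == rt$insert[r] & at$elety %in% bb_names(rt$kind[r])
    bb <- as.matrix(at[sel, c("x", "y", "z"), drop = FALSE])
    if (nrow(bb) == 0) next
    f <- sweep(bb, 2, o) / v
    inside <- f[, 1] >= 0 & f[, 1] <= d[1] - 1 & f[, 2] >= 0 &
      f[, 2] <= d[2] - 1 & f[, 3] >= 0 & f[, 3] <= d[3] - 1
    if (!any(inside)) next
    dens <- mean(apply(bb[inside, , drop = FALSE], 1, interp1))
    if (dens < cfg@maskGate) next
    dmin <- rep(Inf, nvox)
    for (ai in seq_len(nrow(bb))) {
      dd <- sqrt(colSums((t(centers) - bb[ai, ])^2))
      dmin <- pmin(dmin, dd)
    }
    inr <- dmin <= cfg@labelRadius
    if (dens > cfg@annotateGate) {
      upd <- inr & (dmin < best_d - 1e-9 |
        (abs(dmin - best_d) <= 1e-9 & rank_of[[cls]] < best_rank))
      best_d[upd] <- dmin[upd]
      best_class[upd] <- code_of[[cls]]
      best_rank[upd] <- rank_of[[cls]]
    } else {
      mask_excl[inr] <- TRUE
    }
  }

  dall <- rep(Inf, nvox)
  if (nrow(at) > 0) {
    xyz <- as.matrix(at[, c("x", "y", "z")])
    for (ai in seq_len(nrow(xyz))) {
      dall <- pmin(dall, sqrt(colSums((t(centers) - xyz[ai, ])^2)))
    }
  }

  classes <- rep(4L, nvox)
  classes[best_class > 0] <- best_class[best_class > 0]
  mask <- rep(TRUE, nvox)
  unl <- best_class == 0
  mask[mask_excl & unl] <- FALSE
  mask[dall > cfg@farRadius & as.vector(g) >= cfg@densityFloor & unl] <- FALSE
  list(classes = array(classes, d), mask = array(mask, d))
}

# write a minimal single-model PDB text fixture
write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1.0, altloc = " ", element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9']", "", name), 1, 1)
  nmf <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf(
    "ATOM  %5d %s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, nmf, altloc, resid, chain, resno, x, y, z, occ, 0.0, element
  )
}
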