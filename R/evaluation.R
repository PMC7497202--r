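#' Recall, precision and F1 from classification counts
#'
#' Computes the per-residue performance numbers from true-positive,
#' false-positive and false-negative counts (or percentages):
#' `recall = 100 * tp / (tp + fn)`, `precision = 100 * tp / (tp + fp)`, and
#' F1 as their harmonic mean `2 / (recall^-1 + precision^-1)`.
#'
#' @param tp,fp,fn counts or percentages of evaluated residues.
#' @return List with `tp`, `fp`, `fn`, `recall`, `precision`, `f1`
#'   (percent).
#' @examples
#' # a typical single-map outcome
#' evaluationFromCounts(tp = 70.5, fp = 18.8, fn = 10.7)
#' @export
evaluationFromCounts <- function(tp, fp, fn) {
  # a ratio with an empty denominator (no positives predicted, or none in
  # the reference) is reported as 0 rather than undefined
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  f1 <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else {
    0
  }
  list(tp = tp, fp = fp, fn = fn, recall = recall, precision = precision,
    f1 = f1)
}

#' Per-residue predicted class
#'
#' Aggregates a [PredictionVolume-class] to one class per residue: the
#' majority argmax class over all voxels whose centers lie within `radius`
#' (default 3 A, mirroring the annotation radius) of the residue's backbone
#' atoms. Ties, both in the per-voxel argmax and in the majority vote, go to
#' the lowest channel index. A residue with no voxels in range gets the
#' `unassigned` sentinel.
#'
#' @param pv a [PredictionVolume-class].
#' @param backbone n x 3 matrix of the residue's backbone atom coordinates.
#' @param radius aggregation radius in Angstrom.
#' @return One of [VOXEL_CLASSES].
#' @export
residuePredictedClass <- function(pv, backbone, radius = 3.0) {
  d <- dim(pv@probs)[1:3]
  v <- pv@voxelSize
  o <- pv@origin
  lin <- integer(0)
  for (i in seq_len(nrow(backbone))) {
    nb <- .voxels_near(backbone[i, ], radius, d, v, o)
    lin <- c(lin, nb$lin)
  }
  lin <- unique(lin)
  if (length(lin) == 0) {
    return("unassigned")
  }
  am <- .argmax4(pv@probs)
  counts <- tabulate(am[lin], nbins = 4)
  VOXEL_CLASSES[which.max(counts)]
}

#' Per-residue evaluation of a prediction against reference labels
#'
#' The evaluation set consists of residues with mean backbone density of at
#' least `minDensity` (1 sigma) whose truth or prediction is a structured
#' class (true negatives are excluded from the denominator). Within that
#' set: a true positive is a structured residue predicted with its true
#' class; a false negative is a structured residue predicted unassigned; all
#' other evaluated residues (wrong structured class, or a structured
#' prediction on unassigned truth) count as false positives. tp/fp/fn are
#' reported as percentages of the evaluation set, together with recall,
#' precision and F1 via [evaluationFromCounts()].
#'
#' @param pv a [PredictionVolume-class].
#' @param model the co-registered [StructuralModel-class].
#' @param truth per-residue reference classes
#'   (from [assignSecondaryStructure()]).
#' @param map the sigma-normalized [DensityMap-class] used for the density
#'   gate.
#' @param minDensity backbone density gate in sigma units.
#' @param radius per-residue aggregation radius in Angstrom.
#' @return List as [evaluationFromCounts()], plus `nEvaluated` and a
#'   per-residue data.frame `residues` (chain, resno, truth, predicted,
#'   backbone density).
#' @export
evaluateResidues <- function(pv, model, truth, map, minDensity = 1.0,
                             radius = 3.0) {
  if (!.is_normalized(map)) {
    stop("evaluateResidues requires a sigma-normalized map")
  }
  rt <- residueTable(model)
  ridx <- .residue_index(model)
  at <- model@atoms
  rows <- list()
  for (r in seq_len(nrow(rt))) {
    coords <- .residue_coords(at, ridx[[r]])
    bb <- .backbone_coords(coords, rt$kind[r])
    dens <- residueBackboneDensity(map, bb)
    if (is.na(dens) || dens < minDensity) next
    tr <- truth[[rt$key[r]]]
    pr <- residuePredictedClass(pv, bb, radius)
    rows[[length(rows) + 1]] <- data.frame(
      chain = rt$chain[r], resno = rt$resno[r], truth = tr, predicted = pr,
      density = dens, stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) stop("empty evaluation set: no residue passed the density gate")
  evalset <- df$truth != "unassigned" | df$predicted != "unassigned"
  df <- df[evalset, , drop = FALSE]
  if (nrow(df) == 0) stop("empty evaluation set: no structured truth or prediction")
  n <- nrow(df)
  tp <- sum(df$truth != "unassigned" & df$predicted == df$truth)
  fn <- sum(df$truth != "unassigned" & df$predicted == "unassigned")
  fp <- n - tp - fn
  out <- evaluationFromCounts(100 * tp / n, 100 * fp / n, 100 * fn / n)
  out$nEvaluated <- n
  out$residues <- df
  out
}

#' Summary report over several evaluated maps
#'
#' @param counts list of results from [evaluateResidues()] (or
#'   [evaluationFromCounts()]), one per map.
#' @return List with `perMap` (data.frame of tp/fp/fn/recall/precision/f1
#'   per map) and `medianRecall` / `medianPrecision` across maps.
#' @export
perMapReport <- function(counts) {
  stopifnot(length(counts) >= 1)
  perMap <- do.call(rbind, lapply(seq_along(counts), function(i) {
    ct <- counts[[i]]
    data.frame(
      map = i, tp = ct$tp, fp = ct$fp, fn = ct$fn, recall = ct$recall,
      precision = ct$precision, f1 = ct$f1
    )
  }))
  list(
    perMap = perMap,
    medianRecall = median(perMap$recall),
    medianPrecision = median(perMap$precision)
  )
}

#' Per-residue labels derived from a LabelVolume
#'
#' Aggregates a ground-truth [LabelVolume-class] to one class per residue by
#' the same majority rule used for predictions
#' ([residuePredictedClass()]): the most frequent voxel class within
#' `radius` of the residue's backbone atoms, ties to the lowest channel.
#' Evaluating a label volume against residue labels derived this way from
#' the same volume is the package's self-consistency identity (100 % recall
#' and precision).
#'
#' @param lv a [LabelVolume-class].
#' @param model the co-registered [StructuralModel-class].
#' @param radius aggregation radius in Angstrom.
#' @return Named character vector of per-residue classes (names are residue
#'   keys).
#' @export
residueLabelsFromVolume <- function(lv, model, radius = 3.0) {
  pv <- predictionFromLabels(lv)
  rt <- residueTable(model)
  ridx <- .residue_index(model)
  at <- model@atoms
  out <- stats::setNames(rep("unassigned", nrow(rt)), rt$key)
  for (r in seq_len(nrow(rt))) {
    coords <- .residue_coords(at, ridx[[r]])
    bb <- .backbone_coords(coords, rt$kind[r])
    out[[rt$key[r]]] <- residuePredictedClass(pv, bb, radius)
  }
  out
}

#' Build a PredictionVolume from ground-truth labels
#'
#' One-hot encodes a [LabelVolume-class] as class probabilities; useful for
#' self-evaluation checks and for testing the evaluation path without a
#' trained network.
#'
#' @param lv a [LabelVolume-class].
#' @return A [PredictionVolume-class].
#' @export
predictionFromLabels <- function(lv) {
  new("PredictionVolume",
    probs = labelOneHot(lv), voxelSize = lv@voxelSize, origin = lv@origin
  )
}
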