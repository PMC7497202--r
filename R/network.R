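#' Network configuration constructor
#'
#' @param inputSize,outputSize,levels,baseChannels,steps,batchSegments,weightPositive,learningRate
#'   see [NetworkConfig-class]. The full-scale defaults follow the published
#'   training protocol (40^3 input, 20^3 output, 40000 steps of 100
#'   segments, 16-fold positive weighting); `tinyNetworkConfig()` gives the
#'   scaled-down configuration used for phantom training.
#' @return A [NetworkConfig-class].
#' @export
NetworkConfig <- function(inputSize = 40, outputSize = 20, levels = 3,
                          baseChannels = 32, steps = 40000,
                          batchSegments = 100, weightPositive = 16,
                          learningRate = 1e-4) {
  new("NetworkConfig",
    inputSize = inputSize, outputSize = outputSize, levels = levels,
    baseChannels = baseChannels, nClasses = 4, steps = steps,
    batchSegments = batchSegments, weightPositive = weightPositive,
    learningRate = learningRate
  )
}

#' @describeIn NetworkConfig scaled-down configuration (2 levels, 8 base
#'   channels) for CPU phantom training.
#' @param steps,batchSegments,learningRate overrides for the tiny run.
#' @export
tinyNetworkConfig <- function(steps = 200, batchSegments = 5,
                              learningRate = 1e-2) {
  NetworkConfig(
    levels = 2, baseChannels = 8, steps = steps,
    batchSegments = batchSegments, learningRate = learningRate
  )
}

# conv layers of the architecture: name, in-channels, out-channels.
# Encoder blocks double the width per level; the decoder mirrors them with
# skip concatenations; a final 1^3 conv maps to the 4 class channels.
.layer_spec <- function(cfg) {
  L <- cfg@levels
  B <- cfg@baseChannels
  ch <- B * 2^(seq_len(L) - 1)
  spec <- list()
  inc <- 1
  for (l in seq_len(L)) {
    spec[[paste0("enc", l, "_1")]] <- c(inc, ch[l])
    spec[[paste0("enc", l, "_2")]] <- c(ch[l], ch[l])
    inc <- ch[l]
  }
  cb <- B * 2^L
  spec[["bot_1"]] <- c(inc, cb)
  spec[["bot_2"]] <- c(cb, cb)
  upc <- cb
  for (l in rev(seq_len(L))) {
    spec[[paste0("dec", l, "_1")]] <- c(upc + ch[l], ch[l])
    spec[[paste0("dec", l, "_2")]] <- c(ch[l], ch[l])
    upc <- ch[l]
  }
  spec
}

#' Number of trainable parameters of a configuration
#'
#' Closed-form count over all 3^3 convolution kernels, biases and the final
#' 1^3 class projection.
#'
#' @param cfg a [NetworkConfig-class].
#' @return integer parameter count.
#' @export
countParameters <- function(cfg) {
  spec <- .layer_spec(cfg)
  n <- sum(vapply(spec, function(s) s[2] * (s[1] * 27 + 1), 0))
  n + 4 * (cfg@baseChannels + 1) # 1^3 output conv
}

#' Build a randomly initialized 3D U-Net
#'
#' Encoder of `levels` blocks (two same-padded 3^3 convolutions, each
#' followed by per-channel instance normalization, bias and ReLU, then 2x
#' max pooling), a two-convolution bottleneck, and a mirrored decoder with
#' nearest-neighbor upsampling and skip concatenations; a final 1^3
#' convolution maps to the four class channels, followed by a center crop to
#' the output cube and a per-voxel softmax. Instance normalization computes
#' statistics per sample over the spatial grid (no batch or group
#' dependence), which stabilizes optimization without adding parameters.
#' Kernels use He-normal initialization from R's RNG, so the build is
#' deterministic under `set.seed()`.
#'
#' @param cfg a [NetworkConfig-class].
#' @return A [UNet3D-class].
#' @export
buildNetwork <- function(cfg = NetworkConfig()) {
  validObject(cfg)
  spec <- .layer_spec(cfg)
  params <- list()
  for (nm in names(spec)) {
    ci <- spec[[nm]][1]
    co <- spec[[nm]][2]
    params[[paste0(nm, "_W")]] <-
      matrix(rnorm(co * ci * 27, sd = sqrt(2 / (ci * 27))), co, ci * 27)
    params[[paste0(nm, "_b")]] <- numeric(co)
  }
  params[["out_W"]] <- matrix(
    rnorm(4 * cfg@baseChannels, sd = sqrt(2 / cfg@baseChannels)),
    4, cfg@baseChannels
  )
  params[["out_b"]] <- numeric(4)
  new("UNet3D", config = cfg, params = params)
}

#' @export
setMethod("show", "UNet3D", function(object) {
  cfg <- object@config
  cat(sprintf(
    "UNet3D: %d^3 -> %d^3 x 4, %d level(s), %d base channels, %d parameters\n",
    cfg@inputSize, cfg@outputSize, cfg@levels, cfg@baseChannels,
    countParameters(cfg)
  ))
})

# integer architecture descriptor passed to the compiled kernels
.net_cfg <- function(cfg) {
  as.integer(c(cfg@levels, cfg@inputSize, cfg@outputSize, cfg@baseChannels))
}

#' Forward pass of the segmentation network
#'
#' Maps one (or a list of) `inputSize^3` density block(s) to
#' `outputSize^3 x 4` per-voxel class probabilities (channel order
#' [VOXEL_CLASSES]); the probabilities sum to 1 at every voxel.
#'
#' @param net a [UNet3D-class].
#' @param input a 3D array, or a list of 3D arrays.
#' @return A 4D probability array, or a list of them.
#' @export
netForward <- function(net, input) {
  if (is.list(input)) {
    return(lapply(input, netForward, net = net))
  }
  cfg <- net@config
  if (!identical(dim(input), rep(as.integer(cfg@inputSize), 3L))) {
    stop(
      "input must be a ", cfg@inputSize, "^3 array, got ",
      paste(dim(input), collapse = "x")
    )
  }
  .cpp_unet_fw(net@params, .net_cfg(cfg), as.numeric(input))
}

#' @describeIn netForward `predict` method for UNet3D objects
#' @param object a [UNet3D-class]
#' @param ... ignored
#' @export
setMethod("predict", "UNet3D", function(object, input, ...) {
  netForward(object, input)
})

#' Weighted masked cross-entropy loss
#'
#' `sum(w * -log p[true]) / sum(w)`; voxels with zero weight (training
#' exclusions) never influence the value, and an all-zero weight block has
#' loss 0 by definition. Invariant under rescaling of all weights.
#'
#' @param pred 4D probability array (out^3 x 4) from [netForward()].
#' @param target 3D integer array of true class codes 1..4.
#' @param weights 3D non-negative weight array.
#' @return Non-negative scalar loss.
#' @export
netLoss <- function(pred, target, weights) {
  sw <- sum(weights)
  if (sw == 0) {
    return(0)
  }
  d <- dim(target)
  lin <- seq_len(prod(d))
  ptrue <- pred[cbind(arrayInd(lin, d), as.vector(target))]
  sum(as.vector(weights) * -log(pmax(ptrue, 1e-12))) / sw
}

# the weight EMA is seeded with the random initialization; for very short
# runs, where that seed still dominates, fall back to the last iterate
.ema_corrected <- function(ema, params, decay, t) {
  if (decay^t > 0.5) {
    return(params)
  }
  ema
}

.adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0), t = 0
  )
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Voxel accuracy of predictions over trainable voxels
#'
#' @param pred 4D probability array from [netForward()].
#' @param target 3D integer class codes.
#' @param mask 3D logical, only TRUE voxels are scored.
#' @return Fraction of trainable voxels whose argmax class (ties to the
#'   lowest channel) matches the target.
#' @export
voxelAccuracy <- function(pred, target, mask) {
  am <- .argmax4(pred)
  mean(am[mask] == target[mask])
}

# argmax over the 4th dim with ties to the lowest channel index
.argmax4 <- function(p4) {
  d <- dim(p4)
  m <- matrix(p4, prod(d[1:3]), 4)
  am <- max.col(m, ties.method = "first")
  array(am, dim = d[1:3])
}

# deterministic evaluation crops: the centered crop plus four offset crops
# whose output windows tile distinct regions of the segment
.eval_offsets <- function(segSize, cropSize) {
  m <- segSize - cropSize
  h <- m %/% 2L
  unique(list(
    c(h, h, h), c(0L, 0L, 0L), c(m, m, 0L), c(m, 0L, m), c(0L, m, m)
  ))
}

# map calibrated output probabilities to the weighted training head
# (per-voxel renormalized w_c * p_c), used to report training-comparable
# losses
.training_probs <- function(pred, weightPositive) {
  w <- c(rep(weightPositive, 3), 1)
  for (k in 1:4) pred[, , , k] <- pred[, , , k] * w[k]
  s <- pred[, , , 1] + pred[, , , 2] + pred[, , , 3] + pred[, , , 4]
  for (k in 1:4) pred[, , , k] <- pred[, , , k] / s
  pred
}

#' Evaluate a network on a list of segments
#'
#' Scores a deterministic set of five crops per segment (the centered crop
#' plus four offset crops whose output windows cover distinct regions) and
#' reports the training-head loss and the voxel accuracy (argmax of the
#' calibrated probabilities) over trainable voxels.
#'
#' @param net a [UNet3D-class].
#' @param segs list of [Segment-class].
#' @return list with `loss` and `accuracy`.
#' @export
evaluateNetwork <- function(net, segs) {
  cfg <- net@config
  losses <- numeric(0)
  ok <- 0
  tot <- 0
  for (seg in segs) {
    segSize <- dim(seg@density)[1]
    for (off in .eval_offsets(segSize, as.integer(cfg@inputSize))) {
      s <- sampleTrainingExample(seg, cfg@inputSize, cfg@outputSize,
        cfg@weightPositive,
        rotation = 1L, offset = off
      )
      pr <- netForward(net, s$input)
      losses <- c(losses, netLoss(.training_probs(pr, cfg@weightPositive),
        s$target, s$weight))
      am <- .argmax4(pr)
      ok <- ok + sum(am[s$mask] == s$target[s$mask])
      tot <- tot + sum(s$mask)
    }
  }
  list(loss = mean(losses), accuracy = if (tot > 0) ok / tot else NA_real_)
}

#' Train the segmentation network on annotated segments
#'
#' Per step, draws `batchSegments` augmented samples via
#' [sampleTrainingExample()] (each from a uniformly chosen training segment),
#' accumulates the weighted cross-entropy gradient over the batch and applies
#' one Adam update. The learning rate follows a cosine decay from the
#' configured value to a tenth of it over the run, and the returned network
#' carries a Polyak (exponential moving) average of the weights rather than
#' the last iterate, both of which damp the end-of-training oscillation of
#' small-batch Adam. The evaluation segments are scored periodically (with
#' the current iterate; the final entry uses the averaged weights). The
#' whole run is reproducible under `set.seed()` on one machine.
#'
#' @param net a freshly built (or partially trained) [UNet3D-class].
#' @param trainSegs non-empty list of training [Segment-class] objects.
#' @param evalSegs list of held-out segments (may be empty).
#' @param evalEvery evaluate every this many steps (default: 5 times per
#'   run).
#' @param checkpointPath if non-NULL, the trained network is written there
#'   via [saveCheckpoint()].
#' @param verbose print progress lines.
#' @return list with `net` (trained [UNet3D-class]) and `history`
#'   (data.frame of step, trainLoss, evalLoss, evalAccuracy).
#' @export
trainNetwork <- function(net, trainSegs, evalSegs = list(),
                         evalEvery = NULL, checkpointPath = NULL,
                         verbose = FALSE) {
  cfg <- net@config
  if (length(trainSegs) == 0) stop("empty training set")
  steps <- cfg@steps
  batch <- cfg@batchSegments
  if (is.null(evalEvery)) evalEvery <- max(1L, as.integer(steps / 5))
  params <- net@params
  st <- .adam_init(params)
  ema <- params
  ema_decay <- 0.98
  hist <- list()
  for (step in seq_len(steps)) {
    grads <- NULL
    lsum <- 0
    for (bi in seq_len(batch)) {
      seg <- trainSegs[[sample.int(length(trainSegs), 1L)]]
      s <- sampleTrainingExample(
        seg, cfg@inputSize, cfg@outputSize,
        cfg@weightPositive
      )
      fb <- .cpp_unet_fwbw(
        params, .net_cfg(cfg), as.numeric(s$input),
        as.integer(s$target), as.numeric(s$weight),
        log(c(rep(cfg@weightPositive, 3), 1))
      )
      lsum <- lsum + fb$loss
      g <- fb$grads
      if (is.null(grads)) {
        grads <- g
      } else {
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + g[[nm]]
      }
    }
    for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / batch
    lr_t <- cfg@learningRate *
      (0.1 + 0.45 * (1 + cos(pi * (step - 1) / steps)))
    up <- .adam_step(params, grads, st, lr_t)
    params <- up$params
    st <- up$state
    # bias-corrected exponential moving average of the weights
    for (nm in names(ema)) {
      ema[[nm]] <- ema_decay * ema[[nm]] + (1 - ema_decay) * params[[nm]]
    }
    if (step %% evalEvery == 0 || step == steps) {
      net@params <- if (step == steps) .ema_corrected(ema, params, ema_decay, step) else params
      ev <- if (length(evalSegs) > 0) {
        evaluateNetwork(net, evalSegs)
      } else {
        list(loss = NA_real_, accuracy = NA_real_)
      }
      hist[[length(hist) + 1]] <- data.frame(
        step = step, trainLoss = lsum / batch, evalLoss = ev$loss,
        evalAccuracy = ev$accuracy
      )
      if (verbose) {
        message(sprintf(
          "step %d: train loss %.4f, eval loss %.4f, eval acc %.4f",
          step, lsum / batch, ev$loss, ev$accuracy
        ))
      }
    }
  }
  net@params <- .ema_corrected(ema, params, ema_decay, steps)
  if (!is.null(checkpointPath)) saveCheckpoint(net, checkpointPath)
  list(net = net, history = do.call(rbind, hist))
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a single-file R serialization of the named parameter
#' tensors, the [NetworkConfig-class] fields, and a format version tag.
#'
#' @param net a [UNet3D-class].
#' @param path checkpoint file path.
#' @return `saveCheckpoint` invisibly returns `path`; `loadCheckpoint`
#'   returns a [UNet3D-class].
#' @export
saveCheckpoint <- function(net, path) {
  cfg <- net@config
  obj <- list(
    format = "haruspex-checkpoint", version = 1L,
    config = list(
      inputSize = cfg@inputSize, outputSize = cfg@outputSize,
      levels = cfg@levels, baseChannels = cfg@baseChannels,
      steps = cfg@steps, batchSegments = cfg@batchSegments,
      weightPositive = cfg@weightPositive, learningRate = cfg@learningRate
    ),
    params = net@params
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "haruspex-checkpoint")) {
    stop("not a haruspex checkpoint: ", path)
  }
  cfg <- do.call(NetworkConfig, obj$config)
  new("UNet3D", config = cfg, params = obj$params)
}
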