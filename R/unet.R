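#' Segmentation training configuration
#'
#' Training protocol for the larva segmenter: fifty epochs of Adam on soft
#' Dice loss, learning rate starting at 5e-4 and dropping tenfold at the
#' fifteenth and fortieth epochs. One model is trained per working
#' resolution; supported resolutions are 64, 128, 256, 512 and 1024 px.
#'
#' @param resolution working resolution (square), one of 64, 128, 256, 512,
#'   1024.
#' @param epochs number of training epochs.
#' @param initialLr initial Adam learning rate.
#' @param lrDropEpochs epochs at which the learning rate divides by
#'   `lrDropFactor`.
#' @param lrDropFactor learning-rate drop factor.
#' @param batchSize gradient-accumulation batch size.
#' @param diceEps smoothing constant added to the Dice numerator and
#'   denominator.
#' @param baseChannels feature channels at the finest level; widths double
#'   at each coarser level.
#' @param depth number of resolution levels (including the bottleneck).
#' @param warmupSteps optimizer steps over which the learning rate ramps
#'   linearly from zero. Adam's bias-corrected first steps are full-sized
#'   sign steps before its moment estimates carry information; the short
#'   ramp makes (re)starts stable, which matters most when training
#'   resumes from another model's weights.
#' @param seed RNG seed controlling weight initialization and shuffling.
#' @return a validated config list.
#' @export
trainConfig <- function(resolution = 256L, epochs = 50L, initialLr = 5e-4,
                        lrDropEpochs = c(15L, 40L), lrDropFactor = 10,
                        batchSize = 4L, diceEps = 1.0, baseChannels = 16L,
                        depth = 4L, warmupSteps = 5L, seed = 1L) {
  resolution <- as.integer(resolution)
  if (!resolution %in% c(64L, 128L, 256L, 512L, 1024L))
    stop("resolution must be one of 64, 128, 256, 512, 1024")
  if (!.isCount(epochs) || epochs < 1L) stop("epochs must be >= 1")
  if (!.isCount(depth) || depth < 2L) stop("depth must be >= 2")
  if (2L^depth > resolution) stop("depth too large for resolution")
  list(resolution = resolution, epochs = as.integer(epochs),
       initialLr = initialLr, lrDropEpochs = as.integer(lrDropEpochs),
       lrDropFactor = lrDropFactor, batchSize = as.integer(batchSize),
       diceEps = diceEps, baseChannels = as.integer(baseChannels),
       depth = as.integer(depth), warmupSteps = as.integer(warmupSteps),
       seed = as.integer(seed))
}

# He-style initialization of the flat weight list in the order the forward
# pass consumes it: encoder levels 1..L (two 3x3 convs each), decoder
# levels L-1..1 (two 3x3 convs each), then the 1x1 sigmoid head.
.unetInit <- function(channels, inChannels = 3L) {
  L <- length(channels)
  w <- list()
  conv <- function(cin, cout) {
    sd <- sqrt(2 / (cin * 9))
    list(W = matrix(stats::rnorm(cout * cin * 9, sd = sd), cout, cin * 9),
         b = rep(0, cout))
  }
  cins <- c(inChannels, channels[-L])
  for (lev in seq_len(L)) {
    w <- c(w, conv(cins[lev], channels[lev]),
           conv(channels[lev], channels[lev]))
  }
  for (lev in seq(L - 1L, 1L)) {
    w <- c(w, conv(channels[lev + 1L] + channels[lev], channels[lev]),
           conv(channels[lev], channels[lev]))
  }
  sdh <- sqrt(2 / channels[1L])
  w <- c(w, list(W = matrix(stats::rnorm(channels[1L], sd = sdh), 1L,
                            channels[1L]),
                 b = 0))
  # flatten to W1, b1, W2, b2, ...
  out <- vector("list", length(w))
  for (i in seq_along(w)) out[[i]] <- w[[i]]
  out
}

.unetForward <- function(model, img) {
  .unetPredict(img, model@weights, model@channels)
}

#' Train a larva segmentation network
#'
#' Trains a small fully-convolutional U-Net to separate the larva from the
#' well background at the configured working resolution. Images are
#' downsampled with area/bilinear interpolation and scaled to \[0, 1\];
#' label masks are downsampled with nearest-neighbor interpolation so
#' labels never bleed. Optimization is Adam on soft Dice loss with the
#' stepped learning-rate schedule in [trainConfig()]. The final-epoch
#' weights are returned (no checkpoint selection).
#'
#' Because the network is fully convolutional, a model trained at one
#' resolution can seed training at another: passing `init` starts from
#' that model's weights instead of random initialization (progressive
#' refinement). This is how the expensive high-resolution models are
#' trained in minutes: the coarse model already solves the task and the
#' fine-tuning epochs adapt it to the larger structure scale.
#'
#' @param annotations an [AnnotationSet-class] with a nonempty train split.
#' @param config a [trainConfig()] list.
#' @param init optional [UNetModel-class] whose weights initialize the
#'   network; its architecture (depth, channel widths) must match
#'   `config`.
#' @param verbose print per-epoch losses.
#' @return a [UNetModel-class]; `@history` holds per-epoch train and
#'   validation Dice loss.
#' @export
trainSegmenter <- function(annotations, config = trainConfig(),
                           init = NULL, verbose = FALSE) {
  stopifnot(is(annotations, "AnnotationSet"))
  res <- config$resolution
  idxTrain <- which(annotations@split == "train")
  idxVal <- which(annotations@split == "val")
  if (length(idxTrain) == 0L) stop("empty training split")

  prep <- function(i) {
    it <- annotations@items[[i]]
    img <- .resizeArray(.normalizeFrame(it$image), res, res, "bilinear")
    msk <- .resizeMatrix(it$mask + 0, res, res, "nearest")
    list(img = img, mask = msk)
  }
  train <- lapply(idxTrain, prep)
  val <- lapply(idxVal, prep)

  set.seed(config$seed)
  channels <- as.integer(config$baseChannels * 2^(seq_len(config$depth) - 1L))
  if (is.null(init)) {
    weights <- .unetInit(channels)
  } else {
    stopifnot(is(init, "UNetModel"))
    if (!identical(init@channels, channels))
      stop("init model architecture does not match config")
    weights <- init@weights
  }
  mAdam <- lapply(weights, function(w) w * 0)
  vAdam <- lapply(weights, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8
  tAdam <- 0L

  history <- data.frame(epoch = integer(), lr = numeric(),
                        trainDice = numeric(), valDice = numeric())
  for (epoch in seq_len(config$epochs)) {
    lr <- config$initialLr /
      config$lrDropFactor^sum(epoch >= config$lrDropEpochs)
    ord <- sample(length(train))
    losses <- numeric(0)
    for (start in seq(1L, length(ord), by = config$batchSize)) {
      batch <- ord[start:min(start + config$batchSize - 1L, length(ord))]
      acc <- NULL
      for (i in batch) {
        g <- .unetGrad(train[[i]]$img, train[[i]]$mask, weights, channels,
                       config$diceEps)
        losses <- c(losses, g$loss)
        if (is.null(acc)) acc <- g$grads
        else for (k in seq_along(acc)) acc[[k]] <- acc[[k]] + g$grads[[k]]
      }
      tAdam <- tAdam + 1L
      lrStep <- lr * min(1, tAdam / max(1L, config$warmupSteps))
      for (k in seq_along(weights)) {
        gk <- acc[[k]] / length(batch)
        mAdam[[k]] <- beta1 * mAdam[[k]] + (1 - beta1) * gk
        vAdam[[k]] <- beta2 * vAdam[[k]] + (1 - beta2) * gk^2
        mhat <- mAdam[[k]] / (1 - beta1^tAdam)
        vhat <- vAdam[[k]] / (1 - beta2^tAdam)
        weights[[k]] <- weights[[k]] -
          lrStep * mhat / (sqrt(vhat) + adamEps)
      }
    }
    valDice <- NA_real_
    if (length(val)) {
      valDice <- mean(vapply(val, function(it) {
        p <- .unetPredict(it$img, weights, channels)
        diceLoss(p, it$mask, eps = config$diceEps)
      }, 0))
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                trainDice = mean(losses),
                                valDice = valDice))
    if (verbose)
      message(sprintf("epoch %3d  lr %.1e  train %.4f  val %.4f", epoch,
                      lr, mean(losses), valDice))
  }
  new("UNetModel", weights = weights, channels = channels,
      inChannels = 3L, resolution = res, history = history,
      config = config)
}

#' Apply a segmentation model to one native frame
#'
#' The frame is downsampled to the model's working resolution, passed
#' through the network, and the probability map is binarized at 0.5. The
#' mask is kept at the working resolution; [upsampleMask()] maps it back to
#' the native frame shape by nearest-neighbor interpolation.
#'
#' @param frame integer/numeric array (H, W, 3) with values 0..255.
#' @param model a trained [UNetModel-class].
#' @param resolution working resolution; must equal the model's training
#'   resolution.
#' @return a [SegMask-class].
#' @export
inferMask <- function(frame, model, resolution = model@resolution) {
  if (as.integer(resolution) != model@resolution)
    stop(sprintf("model was trained at resolution %d, not %d",
                 model@resolution, as.integer(resolution)))
  native <- dim(frame)[1:2]
  img <- .resizeArray(.normalizeFrame(frame), resolution, resolution,
                      "bilinear")
  p <- .unetPredict(img, model@weights, model@channels)
  SegMask((p >= 0.5) + 0L, native)
}

#' Upsample a mask to its native frame shape
#'
#' Nearest-neighbor interpolation, so the mask stays strictly binary.
#'
#' @param segmask a [SegMask-class].
#' @return 0/1 integer matrix with the native frame shape.
#' @export
upsampleMask <- function(segmask) {
  out <- .resizeMatrix(segmask@mask, segmask@nativeShape[1L],
                       segmask@nativeShape[2L], "nearest")
  storage.mode(out) <- "integer"
  out
}

#' Evaluate a segmentation model on a labeled split
#'
#' Masks are inferred at the model's working resolution, upsampled to the
#' native frame shape, and scored by IoU against the labeled truth masks.
#' Per-frame inference time is reported for information only.
#'
#' @param model a [UNetModel-class].
#' @param annotations an [AnnotationSet-class].
#' @param split which split to evaluate (default "test").
#' @return list with `iou` (per-image), `meanIou`, and `timePerFrame`
#'   (seconds).
#' @export
evaluateSegmenter <- function(model, annotations, split = "test") {
  idx <- which(annotations@split == split)
  if (length(idx) == 0L) stop("empty evaluation split")
  ious <- numeric(length(idx))
  tstart <- proc.time()[["elapsed"]]
  for (k in seq_along(idx)) {
    it <- annotations@items[[idx[k]]]
    sm <- inferMask(it$image, model)
    ious[k] <- iou(upsampleMask(sm), it$mask)
  }
  elapsed <- proc.time()[["elapsed"]] - tstart
  list(iou = ious, meanIou = mean(ious),
       timePerFrame = elapsed / length(idx))
}

#' Save / load a segmentation model
#'
#' The model is serialized with `saveRDS`; a JSON sidecar (`<path>.json`)
#' records the training configuration for provenance.
#'
#' @param model a [UNetModel-class].
#' @param path checkpoint file path.
#' @return `loadModel` returns the [UNetModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model@config, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "UNetModel"))
  model
}
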