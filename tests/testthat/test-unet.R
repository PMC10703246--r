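test_that("backpropagation matches central finite differences", {
  set.seed(7)
  channels <- c(2L, 4L)
  w <- larvacount:::.unetInit(channels, 3L)
  # nonzero biases keep activations off the ReLU kink where the loss is
  # nondifferentiable and finite differences are ill-defined
  for (i in seq_along(w))
    if (is.null(dim(w[[i]])))
      w[[i]] <- w[[i]] + rnorm(length(w[[i]]), sd = 0.05)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  truth <- matrix(rbinom(64, 1, 0.4), 8, 8)
  g <- larvacount:::.unetGrad(img, truth, w, channels, 1.0)
  expect_gte(g$loss, 0); expect_lte(g$loss, 1)
  for (li in seq_along(w)) {
    for (ii in sample(length(w[[li]]), min(3L, length(w[[li]])))) {
      eps <- 1e-6
      wp <- w; wp[[li]][ii] <- wp[[li]][ii] + eps
      wm <- w; wm[[li]][ii] <- wm[[li]][ii] - eps
      fd <- (larvacount:::.unetGrad(img, truth, wp, channels, 1.0)$loss -
             larvacount:::.unetGrad(img, truth, wm, channels, 1.0)$loss) /
        (2 * eps)
      expect_equal(g$grads[[li]][ii], fd, tolerance = 1e-4)
    }
  }
})

test_that("training improves validation Dice and is reproducible", {
  ann <- fixtureAnnotations()
  cfg <- trainConfig(64L, epochs = 8L, baseChannels = 4L, seed = 5L)
  m1 <- trainSegmenter(ann, cfg)
  expect_lt(m1@history$valDice[8L], m1@history$valDice[1L])
  m2 <- trainSegmenter(ann, cfg)
  expect_identical(m1@history$valDice, m2@history$valDice)
  expect_identical(m1@weights, m2@weights)

  # stepped learning-rate schedule is recorded in the history
  sched <- trainSegmenter(ann, trainConfig(64L, epochs = 5L,
                                           lrDropEpochs = c(2L, 4L),
                                           baseChannels = 4L, seed = 5L))
  expect_equal(sched@history$lr, c(5e-4, 5e-5, 5e-5, 5e-6, 5e-6))

  expect_error(trainConfig(64L, epochs = 0L), "epochs")
  expect_error(trainConfig(100L), "resolution")
  empty <- annotationSet(ann@items, rep("test", length(ann@items)))
  expect_error(trainSegmenter(empty, cfg), "empty training split")
})

test_that("mask inference binarizes, upsamples and validates resolution", {
  m64 <- fixtureModel64()
  ann <- fixtureAnnotations()
  idxTest <- which(ann@split == "test")
  fishIdx <- idxTest[vapply(ann@items[idxTest],
                            function(it) sum(it$mask) > 0, TRUE)]
  it <- ann@items[[fishIdx[1L]]]
  sm <- inferMask(it$image, m64)
  expect_s4_class(sm, "SegMask")
  expect_identical(sm@workingResolution, 64L)
  up <- upsampleMask(sm)
  expect_identical(dim(up), dim(it$mask))      # native frame shape
  expect_true(all(up %in% c(0L, 1L)))
  expect_gte(iou(up, it$mask), 0.7)

  # an all-background frame yields (almost) nothing
  bg <- array(12L, c(256L, 256L, 3L))
  expect_lt(maskAreaFraction(inferMask(bg, m64)), 0.001)

  expect_error(inferMask(it$image, m64, resolution = 128L),
               "trained at resolution 64")
})

test_that("evaluation scores IoU at native scale after upsampling", {
  m64 <- fixtureModel64()
  ann <- fixtureAnnotations()
  ev <- evaluateSegmenter(m64, ann, "test")
  expect_length(ev$iou, sum(ann@split == "test"))
  expect_equal(ev$meanIou, mean(ev$iou))
  expect_true(ev$timePerFrame > 0)

  # scoring a model against its own binarized output is perfect
  items <- lapply(ann@items[ann@split == "test"], function(it) {
    list(name = it$name, image = it$image,
         mask = upsampleMask(inferMask(it$image, m64)), polygon = NULL)
  })
  self <- annotationSet(items, rep("test", length(items)))
  expect_equal(evaluateSegmenter(m64, self, "test")$meanIou, 1.0)

  expect_error(evaluateSegmenter(m64, ann, "nosuch"), "empty")
})

test_that("model checkpoints round-trip with a config sidecar", {
  m <- fixtureModel64()
  p <- tempfile(fileext = ".rds")
  saveModel(m, p)
  expect_true(file.exists(paste0(p, ".json")))
  side <- jsonlite::fromJSON(paste0(p, ".json"))
  expect_identical(as.integer(side$resolution), 64L)
  back <- loadModel(p)
  expect_identical(back@weights, m@weights)
  expect_identical(back@resolution, m@resolution)
  unlink(c(p, paste0(p, ".json")))
})
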