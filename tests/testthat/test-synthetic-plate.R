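test_that("generation is deterministic and honors fish probability", {
  cfg <- simConfig(frameSize = 64L, nSlices = 3L, plateRows = 2L,
                   plateCols = 3L, fishProb = 0.5, seed = 9L)
  a <- generatePlate(cfg)
  b <- generatePlate(cfg)
  expect_identical(scanImages(a$scan), scanImages(b$scan))
  expect_identical(truthCounts(a$truth), truthCounts(b$truth))

  empty <- generatePlate(simConfig(frameSize = 64L, nSlices = 2L,
                                   plateRows = 2L, plateCols = 2L,
                                   fishProb = 0, seed = 9L))
  expect_true(all(vapply(empty$truth@wells,
                         function(w) !w$fishPresent && w$nSpots == 0L,
                         TRUE)))
  expect_true(all(vapply(empty$truth@wells,
                         function(w) sum(w$fishMask) == 0L, TRUE)))
})

test_that("spot placement honors count and pairwise separation", {
  # feasible geometry: 6 spots at separation 13 fit the eroded silhouette
  cfg <- simConfig(frameSize = 256L, nSlices = 1L, plateRows = 2L,
                   plateCols = 3L, fishProb = 1,
                   spotsPerFish = c(6L, 6L), minSpotSeparationPx = 13,
                   seed = 41L)
  sim <- generatePlate(cfg)
  for (w in sim$truth@wells) {
    expect_identical(w$nSpots, nrow(w$spotCenters))
    expect_identical(w$nSpots, 6L)
    expect_true(all(w$fishMask[w$spotCenters + 1L]))   # inside the mask
    if (w$nSpots > 1L) {
      d <- stats::dist(w$spotCenters)
      expect_gte(min(d), 13)
    }
  }
})

test_that("infeasible spot targets are reduced and recorded in truth", {
  cfg <- simConfig(frameSize = 128L, nSlices = 1L, plateRows = 1L,
                   plateCols = 2L, fishProb = 1,
                   spotsPerFish = c(40L, 40L), seed = 6L)
  sim <- generatePlate(cfg)
  for (w in sim$truth@wells) {
    expect_lt(w$nSpots, 40L)                  # cannot fit at separation 20
    expect_identical(w$nSpots, nrow(w$spotCenters))
    expect_gte(min(stats::dist(w$spotCenters)), 20)
  }
})

test_that("rendered spot fields match the Gaussian model", {
  expect_true(all(renderSpotField(matrix(numeric(0), 0, 2), 3, 1, 32) == 0L))

  one <- renderSpotField(cbind(16, 16), 3, 200, 33)
  expect_identical(max(one), 200L)
  expect_identical(one[17L, 17L], 200L)       # 0-based (16,16)

  # overlapping pair: values are the sum of the two Gaussians
  two <- renderSpotField(rbind(c(16, 14), c(16, 22)), 3, 100, 33)
  gauss <- function(r, c, r0, c0) 100 * exp(-((r - r0)^2 + (c - c0)^2) / 18)
  for (pt in list(c(16, 18), c(16, 14), c(14, 20))) {
    expected <- round(gauss(pt[1], pt[2], 16, 14) + gauss(pt[1], pt[2], 16, 22))
    expect_equal(two[pt[1] + 1L, pt[2] + 1L], expected, tolerance = 0)
  }
  expect_error(renderSpotField(cbind(40, 2), 3, 100, 33), "within the frame")
})

test_that("defocus blur decreases total variation away from the true slice", {
  cfg <- simConfig(frameSize = 128L, nSlices = 7L, plateRows = 1L,
                   plateCols = 2L, fishProb = 1, backgroundNoiseSd = 0,
                   seed = 14L)
  sim <- generatePlate(cfg)
  tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  for (w in seq_along(sim$truth@wells)) {
    zt <- sim$truth@wells[[w]]$zTrue
    tvs <- vapply(0:6, function(z) {
      g <- wellFrame(sim$scan, w, z)[, , 2L]
      storage.mode(g) <- "double"
      tv(g)
    }, 0)
    d <- abs(0:6 - zt)
    expect_true(all(diff(tvs[order(d)]) <= 1e-9))
  }
})

test_that("true-focus slice maximizes masked variance of Laplacian", {
  cfg <- simConfig(frameSize = 128L, nSlices = 7L, plateRows = 1L,
                   plateCols = 3L, fishProb = 1, seed = 3L)
  sim <- generatePlate(cfg)
  for (w in seq_along(sim$truth@wells)) {
    tw <- sim$truth@wells[[w]]
    scores <- vapply(0:6, function(z)
      varianceOfLaplacian(wellFrame(sim$scan, w, z), tw$fishMask + 0L), 0)
    expect_identical(which.max(scores) - 1L, tw$zTrue)
  }
})

test_that("truth serializes to JSON and back without loss", {
  cfg <- simConfig(frameSize = 64L, nSlices = 3L, plateRows = 2L,
                   plateCols = 2L, fishProb = 0.7, melanophoreProb = 1,
                   seed = 12L)
  sim <- generatePlate(cfg)
  p <- tempfile(fileext = ".json")
  writeTruth(sim$truth, p)
  back <- readTruth(p)
  for (i in seq_along(sim$truth@wells)) {
    w1 <- sim$truth@wells[[i]]; w2 <- back@wells[[i]]
    expect_identical(w1$fishPresent, w2$fishPresent)
    expect_identical(as.integer(w1$zTrue), w2$zTrue)
    expect_identical(w1$nSpots, w2$nSpots)
    expect_equal(unname(w1$spotCenters), unname(w2$spotCenters))
    expect_equal(unname(w1$melanophoreCenters),
                 unname(w2$melanophoreCenters))
    expect_identical(w1$fishMask, w2$fishMask)
    expect_identical(w1$orientation, w2$orientation)
  }
  unlink(p)
})
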