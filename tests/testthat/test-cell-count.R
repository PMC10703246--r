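test_that("to-zero thresholding keeps values at or above t and is
           idempotent", {
  img <- matrix(c(54, 55, 200, 10), 2, 2)
  out <- thresholdToZero(img, 55)
  expect_equal(sort(as.vector(out)), c(0, 0, 55, 200))
  expect_equal(thresholdToZero(out, 55), out)
  expect_true(all(thresholdToZero(matrix(1:50, 5, 10), 55) == 0))
})

test_that("single and paired Gaussian spots are detected at their centers", {
  expect_identical(nrow(detectBlobs(matrix(0, 64, 64), countParams())), 0L)

  one <- 255 * exp(-(outer((0:63 - 32)^2, (0:63 - 32)^2, `+`)) / (2 * 9))
  b1 <- detectBlobs(one, countParams())
  expect_identical(nrow(b1), 1L)
  expect_lt(max(abs(b1[1, c("row", "col")] - 32)), 1)

  two <- spotImage(rbind(c(22, 32), c(42, 32)), 3, 255, 64)
  b2 <- detectBlobs(two + 0, countParams())
  expect_identical(nrow(b2), 2L)

  # a dumbbell with separation > 4 * maxSigma is never one blob
  db <- spotImage(rbind(c(20, 32), c(44, 32)), 4, 220, 64)
  expect_gte(nrow(detectBlobs(db + 0, countParams())), 2L)
})

test_that("scale-space maxima match the brute-force volume scan", {
  set.seed(23)
  params <- countParams(countingResolution = 128L)
  for (k in 1:20) {
    size <- sample(48:128, 1)
    n <- sample(0:6, 1)
    centers <- if (n > 0)
      cbind(sample(8:(size - 9), n, replace = TRUE),
            sample(8:(size - 9), n, replace = TRUE)) else
      matrix(numeric(0), 0, 2)
    img <- larvacount:::.spotField(centers, runif(1, 2, 4),
                                   runif(max(1, n), 80, 255), size) +
      matrix(rnorm(size^2, 0, 2), size, size)
    img[img < 0] <- 0
    sp <- larvacount:::.dogSpace(img / 255, params)
    fast <- larvacount:::.localMaxima3(sp$dog, params$blobThreshold)
    slow <- oracleLocalMaxima(sp$dog, params$blobThreshold)
    expect_identical(nrow(fast), nrow(slow))
    if (nrow(fast) > 0) {
      ord1 <- order(fast[, 1], fast[, 2], fast[, 3])
      ord2 <- order(slow[, 1], slow[, 2], slow[, 3])
      expect_equal(unname(fast[ord1, , drop = FALSE]),
                   unname(slow[ord2, , drop = FALSE]))
    }
  }
})

test_that("lowering the blob threshold never decreases the count", {
  set.seed(5)
  img <- larvacount:::.spotField(rbind(c(20, 20), c(50, 60), c(80, 30)),
                                 3, c(90, 150, 250), 100) +
    matrix(abs(rnorm(1e4, 0, 3)), 100, 100)
  counts <- vapply(c(0.3, 0.15, 0.05, 0.02, 0.01), function(th)
    nrow(detectBlobs(img, countParams(blobThreshold = th))), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("well counting recovers planted spots and flags empty wells", {
  m64 <- fixtureModel64(); m128 <- fixtureModel128()
  sim <- generatePlate(simConfig(frameSize = 256L, nSlices = 5L,
                                 plateRows = 1L, plateCols = 3L,
                                 fishProb = 1, seed = 27L))
  params <- fixtureCountParams()
  for (w in 1:3) {
    zs <- scanImages(sim$scan)[w, , , , ]
    fr <- selectBestFrame(zs, m64, wellId = wellIds(sim$scan)[w])
    wc <- countWell(zs, fr, m128, params)
    expect_true(wc$fishPresent)
    expect_identical(wc$count, sim$truth@wells[[w]]$nSpots)
    expect_identical(wc$count, nrow(wc$blobs))
  }

  # fish with zero spots counts zero
  zero <- generatePlate(simConfig(frameSize = 256L, nSlices = 3L,
                                  plateRows = 1L, plateCols = 1L,
                                  fishProb = 1, spotsPerFish = c(0L, 0L),
                                  seed = 2L))
  zs <- scanImages(zero$scan)[1L, , , , ]
  fr <- selectBestFrame(zs, m64)
  expect_identical(countWell(zs, fr, m128, params)$count, 0L)

  # empty well: fishless outcome, never an error
  fishless <- new("FocusResult", wellId = "A9", scores = rep(NA_real_, 3),
                  bestZ = NA_integer_, fishFound = FALSE)
  wc <- countWell(zs, fishless, m128, params)
  expect_false(wc$fishPresent)
  expect_true(is.na(wc$count))
})

test_that("plate counting discards empties and is deterministic", {
  m64 <- fixtureModel64(); m128 <- fixtureModel128()
  sim <- generatePlate(simConfig(frameSize = 256L, nSlices = 3L,
                                 plateRows = 2L, plateCols = 3L,
                                 fishProb = 0.5, seed = 44L))
  out1 <- countPlate(sim$scan, m64, m128, fixtureCountParams())
  out2 <- countPlate(sim$scan, m64, m128, fixtureCountParams())
  expect_identical(out1$table, out2$table)
  nFish <- sum(vapply(sim$truth@wells, `[[`, TRUE, "fishPresent"))
  expect_identical(nrow(out1$table), nFish)
  expect_true(all(out1$table$count >= 0))

  allEmpty <- generatePlate(simConfig(frameSize = 256L, nSlices = 2L,
                                      plateRows = 1L, plateCols = 2L,
                                      fishProb = 0, seed = 1L))
  expect_identical(nrow(countPlate(allEmpty$scan, m64, m128,
                                   fixtureCountParams())$table), 0L)
})

test_that("overlay images mark every detected blob", {
  m64 <- fixtureModel64(); m128 <- fixtureModel128()
  sim <- generatePlate(simConfig(frameSize = 256L, nSlices = 3L,
                                 plateRows = 1L, plateCols = 1L,
                                 fishProb = 1, seed = 50L))
  zs <- scanImages(sim$scan)[1L, , , , ]
  fr <- selectBestFrame(zs, m64)
  wc <- countWell(zs, fr, m128, fixtureCountParams())
  p <- tempfile(fileext = ".png")
  writeOverlay(zs, wc, p)
  img <- png::readPNG(p)
  expect_identical(dim(img)[1:2], c(128L, 128L))
  for (k in seq_len(nrow(wc$blobs))) {
    r <- round(wc$blobs[k, "row"]) + 1L
    c <- round(wc$blobs[k, "col"]) + 1L
    expect_equal(img[r, c, 1], 1)
    expect_equal(img[r, c, 2], 0)
  }
  unlink(p)
})
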