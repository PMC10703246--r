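# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# 24-well single-slice training plate (balanced with background-only
# wells so the segmenter learns to reject empty frames) + split set
fixtureAnnotations <- function() {
  cached("annotations", function() {
    sim <- generatePlate(simConfig(frameSize = 256L, nSlices = 1L,
                                   plateRows = 4L, plateCols = 6L,
                                   fishProb = 0.6, seed = 11L))
    splitAnnotations(annotationsFromTruth(sim$scan, sim$truth),
                     c(0.6, 0.2, 0.2), seed = 2L)
  })
}

# the two fixture segmentation models of the scaled two-stage protocol
fixtureModel64 <- function() {
  cached("m64", function()
    trainSegmenter(fixtureAnnotations(),
                   trainConfig(64L, epochs = 40L, baseChannels = 8L,
                               seed = 5L)))
}

fixtureModel128 <- function() {
  cached("m128", function()
    trainSegmenter(fixtureAnnotations(),
                   trainConfig(128L, epochs = 40L, baseChannels = 8L,
                               seed = 5L)))
}

# counting parameters for the 256-px fixture scale (counting at 128,
# mirroring the native 3072 -> 1024 protocol)
fixtureCountParams <- function(...) {
  countParams(countingResolution = 128L, ...)
}

# a single 0..255 image with gaussian spots at given 0-based centers
spotImage <- function(centers, sigma, amplitude, size) {
  renderSpotField(centers, sigma, rep(amplitude, NROW(centers)), size)
}

# Full-plate study under the default (easy) conditions: 96 wells, 31
# slices, 256-px frames, counted with the scaled two-stage protocol.
# Generated and counted in streaming mode so the 2.3 GB volume never
# resides in memory; only the small outputs are cached.
acceptanceStudy <- function() {
  cached("study", function() {
    scanPath <- tempfile(fileext = ".h5")
    truth <- generatePlateStream(simConfig(seed = 7L), scanPath)
    out <- countPlateFile(scanPath, fixtureModel64(), fixtureModel128(),
                          fixtureCountParams())
    unlink(scanPath); gc(verbose = FALSE)
    fish <- vapply(truth@wells, `[[`, TRUE, "fishPresent")
    list(ids = defaultWellIds(),
         fish = fish,
         truthCounts = truthCounts(truth),
         zTrue = vapply(truth@wells, function(w)
           if (w$fishPresent) w$zTrue else NA_integer_, 1L),
         nSlices = truth@nSlices,
         table = out$table,
         bestZ = vapply(out$focus, function(f)
           if (f@fishFound) f@bestZ else NA_integer_, 1L))
  })
}

# ---- independent oracles -------------------------------------------------

# brute-force 26-neighborhood maxima scan of a DoG volume (plain R loops)
oracleLocalMaxima <- function(vol, threshold) {
  d <- dim(vol)
  hits <- NULL
  for (s in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    v <- vol[i, j, s]
    if (v <= threshold) next
    nb <- vol[max(1, i - 1):min(d[1], i + 1),
              max(1, j - 1):min(d[2], j + 1),
              max(1, s - 1):min(d[3], s + 1)]
    if (v >= max(nb)) hits <- rbind(hits, c(i, j, s, v))
  }
  if (is.null(hits)) matrix(numeric(0), 0L, 4L) else hits
}

# the same scan vectorized with array shifts (fast enough for many large
# volumes; validated against the loop version on small cases)
oracleLocalMaximaShift <- function(vol, threshold) {
  d <- dim(vol)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- vol
  ok <- vol > threshold
  for (di in -1:1) for (dj in -1:1) for (ds in -1:1) {
    if (di == 0 && dj == 0 && ds == 0) next
    nb <- pad[2:(d[1] + 1L) + di, 2:(d[2] + 1L) + dj,
              2:(d[3] + 1L) + ds, drop = FALSE]
    ok <- ok & (vol >= nb)
  }
  idx <- which(ok, arr.ind = TRUE)
  cbind(idx, vol[ok])
}

# random spot image for oracle-equivalence checks: spots far enough apart
# that no overlap pruning is involved
randomSpotImage <- function(size, maxSpots = 6L, minSep = 14) {
  n <- sample(0:maxSpots, 1L)
  centers <- matrix(numeric(0), 0L, 2L)
  tries <- 0L
  while (nrow(centers) < n && tries < 200L) {
    tries <- tries + 1L
    cand <- c(sample(8:(size - 9L), 1L), sample(8:(size - 9L), 1L))
    if (nrow(centers) == 0L ||
        min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >=
        minSep^2)
      centers <- rbind(centers, cand)
  }
  img <- larvacount:::.spotField(centers, runif(1, 2, 4),
                                 runif(max(1, nrow(centers)), 80, 255),
                                 size) +
    matrix(abs(rnorm(size^2, 0, 1.5)), size, size)
  list(image = pmin(img, 255), centers = centers)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracleMannWhitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  Uobs <- min(uOf(seq_len(na)), na * nb - uOf(seq_len(na)))
  combs <- utils::combn(na + nb, na)
  Us <- apply(combs, 2L, uOf)
  # the min-statistic's tail already covers both sides of the U_a tail
  Us <- pmin(Us, na * nb - Us)
  list(U = Uobs, p = min(1, mean(Us <= Uobs)))
}

# OLS by explicit normal equations (2x2 solve)
oracleOls <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sxx <- sum(x^2); sy <- sum(y); sxy <- sum(x * y)
  det <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  pred <- intercept + slope * x
  list(slope = slope, intercept = intercept,
       r_squared = 1 - sum((y - pred)^2) / sum((y - mean(y))^2))
}
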