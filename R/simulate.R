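#' Synthetic plate simulation configuration
#'
#' Defines the scene statistics of a simulated 96-well acquisition: one
#' larva per well (or an empty well), green-channel fluorescent spots of
#' known count and position inside the larva, defocus blur growing linearly
#' with distance from a true-focus slice, optional mesh-insert background
#' texture, and rare dim autofluorescent confounder spots (melanophores).
#' The defaults mirror the square-well study conditions: 87 of 96 wells
#' occupied, 2.6 percent of fish in a non-lateral orientation (31.7 percent
#' with mesh inserts), 31 slices at a 100 micrometer step.
#'
#' @param frameSize square frame side in pixels (256 default; 3072 native).
#' @param nSlices number of Z-slices.
#' @param zStepUm axial step, micrometers.
#' @param plateRows,plateCols plate grid.
#' @param fishProb probability a well contains a fish.
#' @param spotsPerFish inclusive integer range of target spot counts.
#' @param spotSigmaPx Gaussian radius of a rendered spot, pixels.
#' @param spotAmplitude inclusive 8-bit amplitude range of spots; the lower
#'   bound must exceed the default counting threshold (55).
#' @param minSpotSeparationPx minimum center-to-center spot distance;
#'   must exceed `4 * spotSigmaPx` so easy configurations stay resolvable.
#' @param defocusBlurPerSlice blur-sigma increment (pixels) per slice of
#'   distance from the true-focus slice.
#' @param backgroundLevel mean background intensity (8-bit).
#' @param backgroundNoiseSd per-pixel Gaussian read-noise sd (8-bit units).
#' @param meshMode add a periodic mesh-insert grid texture to the
#'   background and, attenuated, under the fish.
#' @param meshPeriodPx,meshAmplitude mesh texture period and amplitude.
#' @param melanophoreProb probability a fish carries confounder spots.
#' @param melanophoresPerFish inclusive range of confounder counts.
#' @param melanophoreAmplitude confounder amplitude; dim relative to real
#'   spots (between the mesh-mode threshold 30 and the default 55).
#' @param melanophoreSigmaPx confounder Gaussian radius.
#' @param nonLateralProb probability a fish lies in a non-lateral
#'   orientation; defaults to 0.026, or 0.317 when `meshMode = TRUE`.
#' @param seed RNG seed; per-well substreams are derived from it so the
#'   result does not depend on generation order.
#' @return validated config list.
#' @export
simConfig <- function(frameSize = 256L, nSlices = 31L, zStepUm = 100,
                      plateRows = 8L, plateCols = 12L, fishProb = 87 / 96,
                      spotsPerFish = c(5L, 60L), spotSigmaPx = 3,
                      spotAmplitude = c(120, 255),
                      minSpotSeparationPx = 20,
                      defocusBlurPerSlice = 1.5, backgroundLevel = 12,
                      backgroundNoiseSd = 3, meshMode = FALSE,
                      meshPeriodPx = 24L, meshAmplitude = 8,
                      melanophoreProb = 0.05,
                      melanophoresPerFish = c(1L, 3L),
                      melanophoreAmplitude = 42,
                      melanophoreSigmaPx = 2.5,
                      nonLateralProb = NULL, seed = 1L) {
  if (is.null(nonLateralProb)) nonLateralProb <- if (meshMode) 0.317 else 0.026
  cfg <- list(frameSize = as.integer(frameSize),
              nSlices = as.integer(nSlices), zStepUm = zStepUm,
              plateRows = as.integer(plateRows),
              plateCols = as.integer(plateCols), fishProb = fishProb,
              spotsPerFish = as.integer(spotsPerFish),
              spotSigmaPx = spotSigmaPx, spotAmplitude = spotAmplitude,
              minSpotSeparationPx = minSpotSeparationPx,
              defocusBlurPerSlice = defocusBlurPerSlice,
              backgroundLevel = backgroundLevel,
              backgroundNoiseSd = backgroundNoiseSd, meshMode = meshMode,
              meshPeriodPx = as.integer(meshPeriodPx),
              meshAmplitude = meshAmplitude,
              melanophoreProb = melanophoreProb,
              melanophoresPerFish = as.integer(melanophoresPerFish),
              melanophoreAmplitude = melanophoreAmplitude,
              melanophoreSigmaPx = melanophoreSigmaPx,
              nonLateralProb = nonLateralProb, seed = as.integer(seed))
  probs <- c(cfg$fishProb, cfg$melanophoreProb, cfg$nonLateralProb)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$frameSize < 32L) stop("frameSize too small")
  if (cfg$nSlices < 1L) stop("nSlices must be >= 1")
  if (cfg$spotAmplitude[1L] <= 55)
    stop("spotAmplitude lower bound must exceed the counting threshold (55)")
  if (cfg$minSpotSeparationPx <= 4 * cfg$spotSigmaPx)
    stop("minSpotSeparationPx must exceed 4 * spotSigmaPx")
  cfg
}

# unclipped sum of isotropic 2-D Gaussians on a frameSize^2 canvas;
# centers are 0-based (row, col)
.spotField <- function(centers, sigma, amplitudes, frameSize) {
  out <- matrix(0, frameSize, frameSize)
  if (is.null(centers) || NROW(centers) == 0L) return(out)
  win <- ceiling(4 * sigma)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1L]; c0 <- centers[k, 2L]
    rr <- max(0L, floor(r0 - win)):min(frameSize - 1L, ceiling(r0 + win))
    cc <- max(0L, floor(c0 - win)):min(frameSize - 1L, ceiling(c0 + win))
    g <- amplitudes[k] *
      exp(-outer((rr - r0)^2, (cc - c0)^2, `+`) / (2 * sigma^2))
    out[rr + 1L, cc + 1L] <- out[rr + 1L, cc + 1L] + g
  }
  out
}

#' Render a field of Gaussian spots
#'
#' Sum of isotropic 2-D Gaussians, rounded and clipped to the 8-bit range.
#'
#' @param centers n x 2 matrix of 0-based (row, col) centers inside the
#'   frame.
#' @param sigma Gaussian radius in pixels.
#' @param amplitudes peak amplitude per center (recycled).
#' @param frameSize square canvas side.
#' @return integer matrix (frameSize x frameSize), values 0..255.
#' @export
renderSpotField <- function(centers, sigma, amplitudes, frameSize) {
  if (NROW(centers) > 0L) {
    centers <- as.matrix(centers)
    if (any(centers < 0 | centers > frameSize - 1L))
      stop("spot centers must lie within the frame")
    amplitudes <- rep_len(amplitudes, nrow(centers))
  }
  out <- round(.clip8(.spotField(centers, sigma, amplitudes, frameSize)))
  storage.mode(out) <- "integer"
  out
}

# rotated superellipse fish silhouette; returns logical mask and the
# normalized radial coordinate (for shading)
.fishSilhouette <- function(frameSize, cx, cy, a, b, theta, expo = 2.5) {
  idx <- seq_len(frameSize) - 1L
  cc <- matrix(idx, frameSize, frameSize, byrow = TRUE)
  rr <- matrix(idx, frameSize, frameSize)
  u <- (cc - cx) * cos(theta) + (rr - cy) * sin(theta)
  v <- -(cc - cx) * sin(theta) + (rr - cy) * cos(theta)
  rad <- (abs(u) / a)^expo + (abs(v) / b)^expo
  list(mask = rad <= 1, rad = rad, u = u, v = v)
}

# greedy placement of points inside a mask honoring a minimum separation;
# returns 0-based (row, col) matrix with <= n rows
.placePoints <- function(maskIdx, n, minSep, frameSize, avoid = NULL) {
  placed <- matrix(numeric(0), 0L, 2L)
  if (length(maskIdx) == 0L || n == 0L) return(placed)
  budget <- 200L + 60L * n
  attempts <- 0L
  while (nrow(placed) < n && attempts < budget) {
    attempts <- attempts + 1L
    pix <- maskIdx[sample.int(length(maskIdx), 1L)]
    r <- (pix - 1L) %% frameSize
    c <- (pix - 1L) %/% frameSize
    cand <- c(r, c)
    others <- rbind(placed, avoid)
    if (NROW(others) > 0L) {
      d2 <- (others[, 1L] - r)^2 + (others[, 2L] - c)^2
      if (min(d2) < minSep^2) next
    }
    placed <- rbind(placed, cand, deparse.level = 0L)
  }
  placed
}

#' Generate a ground-truthed synthetic plate scan
#'
#' Renders each well as an in-focus RGB scene -- a shaded superellipse
#' larva silhouette (with yolk and eye features; shorter and rounder when
#' non-lateral) over a noisy background, green-channel Gaussian spots at
#' known positions inside the larva -- then produces each Z-slice by
#' blurring the scene with Gaussian sigma `defocusBlurPerSlice * |z -
#' zTrue|` and adding independent read noise. Spot placement is rejection
#' sampling inside the eroded fish mask honoring the minimum separation;
#' if the target count does not fit, the count is reduced and the truth
#' records what was actually rendered.
#'
#' @param config a [simConfig()] list.
#' @return `list(scan = PlateScan, truth = PlateTruth)`.
#' @export
generatePlate <- function(config = simConfig()) {
  fs <- config$frameSize
  nz <- config$nSlices
  nW <- config$plateRows * config$plateCols
  md <- plateMetadata(plateRows = config$plateRows,
                      plateCols = config$plateCols,
                      pixelSizeUm = 3 * 3072 / fs,
                      zStepUm = config$zStepUm, nSlices = nz)
  images <- array(0L, c(nW, nz, fs, fs, 3L))
  wells <- vector("list", nW)

  meshTex <- NULL
  if (config$meshMode) {
    idx <- seq_len(fs) - 1L
    lines <- (idx %% config$meshPeriodPx) < 2L
    grid <- outer(lines, lines, `|`)
    meshTex <- config$meshAmplitude *
      .gblur(grid + 0, sigma = 1.0)
  }

  # plate composition drawn once: round(fishProb * wells) occupied wells,
  # so the canonical 87-of-96 plate is reproduced exactly
  set.seed(config$seed)
  nFish <- round(config$fishProb * nW)
  fishWells <- sort(sample.int(nW, nFish))

  for (w in seq_len(nW)) {
    # bound the per-well rendering garbage (blur buffers, slice lists)
    if (w %% 8L == 0L) gc(verbose = FALSE)
    rendered <- .renderWell(config, w, fishWells, meshTex)
    for (z in seq_len(nz)) images[w, z, , , ] <- rendered$stack[z, , , ]
    wells[[w]] <- rendered$truth
  }

  scan <- PlateScan(images, md)
  truth <- new("PlateTruth", wells = wells, frameSize = fs,
               nSlices = nz, config = config)
  gc(verbose = FALSE)
  list(scan = scan, truth = truth)
}

# deterministic plate composition shared by the in-memory and streaming
# generators: exactly round(fishProb * wells) occupied wells
.plateLayout <- function(config) {
  nW <- config$plateRows * config$plateCols
  set.seed(config$seed)
  sort(sample.int(nW, round(config$fishProb * nW)))
}

.meshTexture <- function(config) {
  if (!config$meshMode) return(NULL)
  fs <- config$frameSize
  idx <- seq_len(fs) - 1L
  lines <- (idx %% config$meshPeriodPx) < 2L
  config$meshAmplitude * .gblur(outer(lines, lines, `|`) + 0, sigma = 1.0)
}

# render one well: (nz, fs, fs, 3) uint8 stack plus its truth record;
# driven entirely by the well's own RNG substream
.renderWell <- function(config, w, fishWells, meshTex) {
  fs <- config$frameSize
  nz <- config$nSlices
  set.seed((config$seed * 1000003L + w) %% 2147483647L)
  scene <- array(config$backgroundLevel, c(fs, fs, 3L))
    if (config$meshMode)
      for (k in 1:3) scene[, , k] <- scene[, , k] + meshTex

    fish <- w %in% fishWells
    truthWell <- list(fishPresent = FALSE, zTrue = NA_integer_,
                      spotCenters = matrix(numeric(0), 0L, 2L),
                      nSpots = 0L, orientation = "unknown",
                      melanophoreCenters = matrix(numeric(0), 0L, 2L),
                      fishMask = matrix(FALSE, fs, fs))
    if (fish) {
      nonLateral <- stats::runif(1) < config$nonLateralProb
      cx <- fs / 2 + stats::runif(1, -0.08, 0.08) * fs
      cy <- fs / 2 + stats::runif(1, -0.08, 0.08) * fs
      theta <- stats::runif(1, 0, pi)
      if (nonLateral) { a <- 0.20 * fs; b <- 0.12 * fs }
      else { a <- 0.36 * fs; b <- 0.085 * fs }
      sil <- .fishSilhouette(fs, cx, cy, a, b, theta)
      mask <- sil$mask
      shade <- pmax(0, 1 - 0.30 * sil$rad)
      # green body intensity stays far enough below the counting threshold
      # (55; 30 with mesh) that read noise cannot cross it: only spots (and
      # configured confounders) exceed the threshold inside the fish
      bodyG <- if (config$meshMode) 14 else 32
      yolkAdd <- if (config$meshMode) c(10, 4, 5) else c(12, 6, 6)
      body <- list(R = 70, G = bodyG, B = 55)
      # yolk: brighter disc toward the head end of the long axis
      yolk <- (sil$u - 0.45 * a)^2 + sil$v^2 <= (0.28 * b * 2)^2
      # eye: dark spot at the far head end
      eye <- (sil$u - 0.8 * a)^2 + sil$v^2 <= (0.12 * b * 2)^2
      for (k in 1:3) {
        base <- c(body$R, body$G, body$B)[k]
        layer <- scene[, , k]
        if (config$meshMode)
          layer[mask] <- config$backgroundLevel + 0.3 * meshTex[mask]
        else layer[mask] <- config$backgroundLevel
        add <- base * shade
        add[yolk & mask] <- add[yolk & mask] + yolkAdd[k]
        add[eye & mask] <- add[eye & mask] * 0.25
        layer[mask] <- layer[mask] + add[mask]
        scene[, , k] <- layer
      }

      # spots inside the eroded mask so coarse working-resolution masks
      # still cover every spot
      margin <- ceiling(max(3 * config$spotSigmaPx, 0.05 * fs))
      brush <- EBImage::makeBrush(2L * as.integer(margin) + 1L, "disc")
      eroded <- EBImage::erode(mask + 0, brush) > 0
      maskIdx <- which(eroded)
      # index-sample the range: sample(x, 1) on a scalar draws from 1:x
      spotRange <- config$spotsPerFish[1L]:config$spotsPerFish[2L]
      nTarget <- spotRange[sample.int(length(spotRange), 1L)]
      centers <- .placePoints(maskIdx, nTarget,
                              config$minSpotSeparationPx, fs)
      amps <- stats::runif(NROW(centers), config$spotAmplitude[1L],
                           config$spotAmplitude[2L])
      mel <- matrix(numeric(0), 0L, 2L)
      if (stats::runif(1) < config$melanophoreProb) {
        melRange <- config$melanophoresPerFish[1L]:
          config$melanophoresPerFish[2L]
        nMel <- melRange[sample.int(length(melRange), 1L)]
        # confounders only need to stay resolvable, not honor the full
        # spot spacing: half the separation suffices at these scales
        mel <- .placePoints(maskIdx, nMel,
                            max(8, config$minSpotSeparationPx / 2),
                            fs, avoid = centers)
      }
      scene[, , 2L] <- scene[, , 2L] +
        .spotField(centers, config$spotSigmaPx, amps, fs)
      if (NROW(mel) > 0L) {
        # confounders replace (not add to) the local body intensity, so
        # their total peak equals melanophoreAmplitude: invisible at the
        # default threshold 55, detectable at the mesh-mode threshold 30
        melField <- .spotField(mel, config$melanophoreSigmaPx,
                               rep(config$melanophoreAmplitude,
                                   NROW(mel)), fs)
        scene[, , 2L] <- pmax(scene[, , 2L], melField)
      }

      zlo <- floor(nz / 3); zhi <- max(zlo, ceiling(2 * nz / 3) - 1L)
      zTrue <- if (nz == 1L) 0L else sample(zlo:zhi, 1L)
      truthWell <- list(fishPresent = TRUE, zTrue = as.integer(zTrue),
                        spotCenters = centers, nSpots = NROW(centers),
                        orientation = if (nonLateral) "non_lateral"
                                      else "lateral",
                        melanophoreCenters = mel, fishMask = mask)
    }
    scene <- .clip8(scene)

    zTrue <- if (truthWell$fishPresent) truthWell$zTrue else (nz - 1L) %/% 2L
    # blur by distance: Gaussian semigroup lets slice d+1 reuse slice d
    slices <- vector("list", nz)
    maxd <- max(zTrue, nz - 1L - zTrue)
    blurred <- scene
    for (d in 0:maxd) {
      if (d > 0L) {
        inc <- config$defocusBlurPerSlice * sqrt(2 * d - 1)
        blurred <- .gblur(blurred, sigma = inc)
      }
      for (z in c(zTrue - d, zTrue + d)) {
        if (z >= 0L && z < nz && is.null(slices[[z + 1L]]))
          slices[[z + 1L]] <- blurred
      }
    }
    stack <- array(0L, c(nz, fs, fs, 3L))
    for (z in seq_len(nz)) {
      sl <- slices[[z]]
      if (config$backgroundNoiseSd > 0)
        sl <- sl + stats::rnorm(length(sl), sd = config$backgroundNoiseSd)
      stack[z, , , ] <- as.integer(round(.clip8(sl)))
    }
    list(stack = stack, truth = truthWell)
}

#' Generate a synthetic plate directly into an HDF5 scan file
#'
#' Streaming counterpart of [generatePlate()]: wells are rendered one at a
#' time and written straight into the (well, slice)-chunked HDF5 layout,
#' so the full image volume never resides in memory. Per-well RNG
#' substreams make the result identical to the in-memory generator under
#' the same configuration.
#'
#' @param config a [simConfig()] list.
#' @param scanPath output HDF5 path (overwritten).
#' @param truthPath optional path for the ground-truth JSON sidecar.
#' @param level gzip compression level for the image dataset.
#' @return invisibly, the [PlateTruth-class].
#' @export
generatePlateStream <- function(config = simConfig(), scanPath,
                                truthPath = NULL, level = 1L) {
  fs <- config$frameSize
  nz <- config$nSlices
  nW <- config$plateRows * config$plateCols
  md <- plateMetadata(plateRows = config$plateRows,
                      plateCols = config$plateCols,
                      pixelSizeUm = 3 * 3072 / fs,
                      zStepUm = config$zStepUm, nSlices = nz)
  meshTex <- .meshTexture(config)
  fishWells <- .plateLayout(config)

  if (file.exists(scanPath)) unlink(scanPath)
  ok <- rhdf5::h5createFile(scanPath)
  if (!isTRUE(ok)) stop(sprintf("cannot create HDF5 file '%s'", scanPath))
  rhdf5::h5createGroup(scanPath, "scan")
  rhdf5::h5createDataset(scanPath, "scan/images",
                         dims = c(nW, nz, fs, fs, 3L),
                         H5type = "H5T_STD_U8LE",
                         chunk = c(1L, 1L, fs, fs, 3L),
                         level = as.integer(level))
  rhdf5::h5write(defaultWellIds(config$plateRows, config$plateCols),
                 scanPath, "scan/well_ids")
  fid <- rhdf5::H5Fopen(scanPath)
  gid <- rhdf5::H5Gopen(fid, "scan")
  for (key in .metadataFields) rhdf5::h5writeAttribute(md[[key]], gid, key)
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)

  wells <- vector("list", nW)
  for (w in seq_len(nW)) {
    if (w %% 8L == 0L) gc(verbose = FALSE)
    rendered <- .renderWell(config, w, fishWells, meshTex)
    stack <- rendered$stack
    dim(stack) <- c(1L, nz, fs, fs, 3L)
    rhdf5::h5write(stack, scanPath, "scan/images",
                   index = list(w, NULL, NULL, NULL, NULL))
    wells[[w]] <- rendered$truth
  }
  rhdf5::h5closeAll()
  truth <- new("PlateTruth", wells = wells, frameSize = fs,
               nSlices = nz, config = config)
  if (!is.null(truthPath)) writeTruth(truth, truthPath)
  invisible(truth)
}

#' @describeIn generatePlate per-well true spot counts (NA for empty wells).
#' @param truth a [PlateTruth-class].
#' @export
truthCounts <- function(truth) {
  vapply(truth@wells, function(w)
    if (w$fishPresent) w$nSpots else NA_integer_, 1L)
}

# run-length encode a logical matrix (column-major) for the JSON sidecar
.rleEncode <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), first = r$values[1L], lengths = r$lengths)
}

.rleDecode <- function(enc) {
  n <- length(enc$lengths)
  vals <- rep(c(enc$first, !enc$first), length.out = n)
  matrix(inverse.rle(structure(list(lengths = enc$lengths, values = vals),
                               class = "rle")),
         enc$dim[1L], enc$dim[2L])
}

#' Write / read simulator ground truth as JSON
#'
#' The fish mask is stored run-length encoded; everything else verbatim.
#' Round-trips exactly.
#'
#' @param truth a [PlateTruth-class].
#' @param path output JSON path.
#' @return `readTruth` returns the [PlateTruth-class].
#' @export
writeTruth <- function(truth, path) {
  obj <- list(frameSize = truth@frameSize, nSlices = truth@nSlices,
              config = truth@config,
              wells = lapply(truth@wells, function(w) {
                list(fishPresent = w$fishPresent, zTrue = w$zTrue,
                     nSpots = w$nSpots, orientation = w$orientation,
                     spotCenters = w$spotCenters,
                     melanophoreCenters = w$melanophoreCenters,
                     fishMask = .rleEncode(w$fishMask))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  asMat <- function(m) {
    if (is.null(m) || length(m) == 0L) return(matrix(numeric(0), 0L, 2L))
    do.call(rbind, lapply(m, function(r) as.numeric(unlist(r))))
  }
  wells <- lapply(obj$wells, function(w) {
    list(fishPresent = isTRUE(w$fishPresent),
         zTrue = if (is.null(w$zTrue)) NA_integer_
                 else as.integer(w$zTrue),
         spotCenters = asMat(w$spotCenters),
         nSpots = as.integer(w$nSpots), orientation = w$orientation,
         melanophoreCenters = asMat(w$melanophoreCenters),
         fishMask = .rleDecode(list(
           dim = as.integer(unlist(w$fishMask$dim)),
           first = isTRUE(w$fishMask$first),
           lengths = as.integer(unlist(w$fishMask$lengths)))))
  })
  new("PlateTruth", wells = wells, frameSize = as.integer(obj$frameSize),
      nSlices = as.integer(obj$nSlices),
      config = lapply(obj$config, function(x)
        if (is.list(x)) unlist(x) else x))
}
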