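#' Counting parameters
#'
#' The three parameters that required calibration on real acquisitions:
#' the 8-bit pixel intensity threshold (55; 30 for mesh-insert plates,
#' whose background texture shifts the intensity distribution inside the
#' fish), the maximum blob sigma (5 px, matched to neutrophil size so
#' clusters are split rather than merged), and the scale-space blob
#' intensity threshold (0.05 on images normalized to \[0, 1\]). The
#' difference-of-Gaussian internals (minimum sigma, sigma ratio, overlap
#' pruning) are exposed here as well.
#'
#' @param intensityThreshold 8-bit to-zero threshold (values >= threshold
#'   are kept unmodified).
#' @param blobMaxSigma largest blob scale, pixels.
#' @param blobThreshold minimum scale-space peak intensity (normalized).
#' @param blobMinSigma smallest blob scale, pixels.
#' @param sigmaRatio ratio between successive scale-space sigmas.
#' @param overlap fraction above which the weaker of two overlapping blobs
#'   is pruned.
#' @param countingResolution working resolution for the counting-stage
#'   segmentation and blob detection (1024 native protocol; scaled
#'   fixtures use the synthetic frame size).
#' @param meshMode convenience switch: `TRUE` selects the mesh-insert
#'   default threshold 30 unless `intensityThreshold` is given explicitly.
#' @return validated parameter list.
#' @export
countParams <- function(intensityThreshold = NULL, blobMaxSigma = 5,
                        blobThreshold = 0.05, blobMinSigma = 1,
                        sigmaRatio = 1.6, overlap = 0.5,
                        countingResolution = 1024L, meshMode = FALSE) {
  if (is.null(intensityThreshold))
    intensityThreshold <- if (meshMode) 30 else 55
  p <- list(intensityThreshold = intensityThreshold,
            blobMaxSigma = blobMaxSigma, blobThreshold = blobThreshold,
            blobMinSigma = blobMinSigma, sigmaRatio = sigmaRatio,
            overlap = overlap,
            countingResolution = as.integer(countingResolution),
            meshMode = meshMode)
  if (!(p$blobMinSigma > 0 && p$blobMinSigma < p$blobMaxSigma))
    stop("need 0 < blobMinSigma < blobMaxSigma")
  if (p$intensityThreshold <= 0 || p$blobThreshold <= 0)
    stop("thresholds must be > 0")
  if (p$sigmaRatio <= 1) stop("sigmaRatio must exceed 1")
  p
}

#' To-zero intensity thresholding
#'
#' Pixels below the threshold are set to zero; pixels at or above it are
#' kept unmodified (so the dimmer rim of a cell keeps its gradient toward
#' the centroid, unlike binary thresholding). Idempotent.
#'
#' @param image single-channel numeric matrix.
#' @param t threshold (8-bit scale).
#' @return matrix of the same shape.
#' @export
thresholdToZero <- function(image, t) {
  stopifnot(is.matrix(image))
  out <- image
  out[out < t] <- 0
  out
}

# DoG scale-space shared by detectBlobs and the brute-force oracle used in
# the tests: list(dog = (H, W, nScales) array, sigmas)
.dogSpace <- function(image, params) {
  stopifnot(is.matrix(image))
  k <- ceiling(log(params$blobMaxSigma / params$blobMinSigma) /
                 log(params$sigmaRatio))
  sigmas <- params$blobMinSigma * params$sigmaRatio^(0:(k + 1L))
  blurred <- lapply(sigmas, function(s) .gblur(image, s))
  dog <- array(0, c(dim(image), length(sigmas) - 1L))
  for (i in seq_len(length(sigmas) - 1L)) {
    # normalize so the response scale is comparable across sigmas
    sf <- sigmas[i] / (sigmas[i + 1L] - sigmas[i])
    dog[, , i] <- (blurred[[i]] - blurred[[i + 1L]]) * sf
  }
  list(dog = dog, sigmas = sigmas[seq_len(length(sigmas) - 1L)])
}

# greedy overlap pruning: keep the stronger of two blobs whose circles
# (radius sqrt(2) * sigma) overlap by more than `overlap`
.pruneBlobs <- function(blobs, overlap) {
  if (nrow(blobs) <= 1L) return(blobs)
  ord <- order(-blobs[, "value"])
  blobs <- blobs[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(blobs))
  r <- sqrt(2) * blobs[, "sigma"]
  for (i in seq_len(nrow(blobs) - 1L)) {
    if (!keep[i]) next
    for (j in seq(i + 1L, nrow(blobs))) {
      if (!keep[j]) next
      d <- sqrt((blobs[i, "row"] - blobs[j, "row"])^2 +
                  (blobs[i, "col"] - blobs[j, "col"])^2)
      if (d > r[i] + r[j]) next
      # overlap fraction of the smaller disc
      rs <- min(r[i], r[j]); rl <- max(r[i], r[j])
      frac <- if (d <= rl - rs) 1 else {
        # circle-circle intersection area / area of the smaller circle
        d2 <- d^2
        a1 <- rs^2 * acos(pmin(1, pmax(-1, (d2 + rs^2 - rl^2) / (2 * d * rs))))
        a2 <- rl^2 * acos(pmin(1, pmax(-1, (d2 + rl^2 - rs^2) / (2 * d * rl))))
        a3 <- 0.5 * sqrt(pmax(0, (-d + rs + rl) * (d + rs - rl) *
                                (d - rs + rl) * (d + rs + rl)))
        (a1 + a2 - a3) / (pi * rs^2)
      }
      if (frac > overlap) keep[j] <- FALSE
    }
  }
  blobs[keep, , drop = FALSE]
}

#' Difference-of-Gaussian blob detection
#'
#' The image is normalized to \[0, 1\], a difference-of-Gaussian scale
#' space is built between `blobMinSigma` and `blobMaxSigma` (successive
#' sigmas in ratio `sigmaRatio`), and local maxima of the (row, col,
#' scale) volume exceeding `blobThreshold` are returned; of two detections
#' whose discs overlap by more than the `overlap` fraction, only the
#' stronger is kept.
#'
#' @param image single-channel matrix, 8-bit scale (0..255).
#' @param params a [countParams()] list.
#' @return matrix with columns `row`, `col` (0-based pixel coordinates),
#'   `sigma`, `value`; zero rows when nothing is detected.
#' @export
detectBlobs <- function(image, params = countParams()) {
  norm <- image / 255
  storage.mode(norm) <- "double"
  sp <- .dogSpace(norm, params)
  peaks <- .localMaxima3(sp$dog, params$blobThreshold)
  if (nrow(peaks) == 0L)
    return(matrix(numeric(0), 0L, 4L,
                  dimnames = list(NULL, c("row", "col", "sigma", "value"))))
  blobs <- cbind(row = peaks[, "row"] - 1, col = peaks[, "col"] - 1,
                 sigma = sp$sigmas[peaks[, "scale"]],
                 value = peaks[, "value"])
  .pruneBlobs(blobs, params$overlap)
}

#' Count cells in one well
#'
#' Takes the best-focus slice, segments the larva at the counting working
#' resolution, extracts the green channel, zeroes everything outside the
#' mask (so background can never contribute blobs), applies the to-zero
#' intensity threshold, and counts difference-of-Gaussian blobs.
#'
#' @param zstack (nz, H, W, 3) array for the well.
#' @param focus the well's [FocusResult-class].
#' @param modelHi counting-resolution [UNetModel-class] (its mask is
#'   upsampled to the counting resolution if they differ).
#' @param params a [countParams()] list.
#' @param wellId label carried through.
#' @return list (`wellId`, `fishPresent`, `bestZ`, `count`, `blobs`,
#'   `params`); a fishless well returns `fishPresent = FALSE` with an NA
#'   count rather than an error.
#' @export
countWell <- function(zstack, focus, modelHi, params = countParams(),
                      wellId = focus@wellId) {
  if (!focus@fishFound)
    return(list(wellId = wellId, fishPresent = FALSE, bestZ = NA_integer_,
                count = NA_integer_, blobs = NULL, params = params))
  frame <- zstack[focus@bestZ + 1L, , , , drop = FALSE]
  dim(frame) <- dim(zstack)[2:4]
  res <- params$countingResolution
  sm <- inferMask(frame, modelHi)
  mask <- .resizeMatrix(sm@mask, res, res, "nearest")
  green <- .resizeMatrix(.normalizeFrame(frame)[, , 2L] * 255, res, res,
                         "bilinear")
  green[mask == 0L] <- 0
  green <- thresholdToZero(green, params$intensityThreshold)
  blobs <- detectBlobs(green, params)
  list(wellId = wellId, fishPresent = TRUE, bestZ = focus@bestZ,
       count = nrow(blobs), blobs = blobs, params = params)
}

#' Count cells across a whole plate
#'
#' Per well: best-focus selection with the focus-resolution model, then
#' masked thresholding and blob counting on the selected slice with the
#' counting-resolution model. Empty wells (no fish found) are discarded
#' from the output table.
#'
#' @param scan a [PlateScan-class].
#' @param modelFocus focus-stage [UNetModel-class] (256-px protocol).
#' @param modelCount counting-stage [UNetModel-class] (1024-px protocol).
#' @param params a [countParams()] list.
#' @param minAreaFraction fish-presence mask-area fraction, see
#'   [selectBestFrame()].
#' @param groupLabel group label written to every row.
#' @param overlayDir if non-NULL, write per-well overlay PNGs with blob
#'   pins into this directory.
#' @param verbose print one log line per well.
#' @return list with `table` (the CountTable data.frame of fish-present
#'   wells), `focus` (per-well FocusResult list) and `wells` (per-well
#'   countWell results).
#' @export
countPlate <- function(scan, modelFocus, modelCount,
                       params = countParams(), minAreaFraction = 0.01,
                       groupLabel = "", overlayDir = NULL,
                       verbose = FALSE) {
  nW <- nWells(scan)
  ids <- wellIds(scan)
  focusList <- vector("list", nW)
  wellsOut <- vector("list", nW)
  rows <- list()
  for (w in seq_len(nW)) {
    # per-slice resize/normalize churn adds up over a 96-well plate;
    # collect periodically so the peak stays near the scan itself
    if (w %% 8L == 0L) gc(verbose = FALSE)
    zs <- scan@images[w, , , , , drop = FALSE]
    dim(zs) <- dim(scan@images)[2:5]
    fr <- selectBestFrame(zs, modelFocus, wellId = ids[w],
                          minAreaFraction = minAreaFraction)
    focusList[[w]] <- fr
    wc <- countWell(zs, fr, modelCount, params)
    wellsOut[[w]] <- wc
    if (verbose)
      message(sprintf("well %-3s fish=%-5s best_z=%-3s count=%s", ids[w],
                      fr@fishFound,
                      if (fr@fishFound) fr@bestZ else "-",
                      if (fr@fishFound) wc$count else "-"))
    if (wc$fishPresent) {
      rows[[length(rows) + 1L]] <-
        data.frame(well_id = ids[w], fish_present = TRUE,
                   best_z = wc$bestZ, count = wc$count,
                   orientation = "unknown", group_label = groupLabel,
                   stringsAsFactors = FALSE)
      if (!is.null(overlayDir))
        writeOverlay(zs, wc, file.path(overlayDir,
                                       paste0(ids[w], ".png")))
    }
  }
  table <- if (length(rows)) do.call(rbind, rows)
           else data.frame(well_id = character(), fish_present = logical(),
                           best_z = integer(), count = integer(),
                           orientation = character(),
                           group_label = character(),
                           stringsAsFactors = FALSE)
  if (verbose)
    message(sprintf("plate done: %d wells counted, %d discarded",
                    nrow(table), nW - nrow(table)))
  list(table = table, focus = focusList, wells = wellsOut)
}

#' Count cells across a plate, streaming wells from an HDF5 scan
#'
#' Identical pipeline to [countPlate()], but wells are read one at a time
#' from the (well, slice)-chunked container, so memory use is independent
#' of plate size.
#'
#' @param scanPath HDF5 scan path ([writeScan()] /
#'   [generatePlateStream()] layout).
#' @inheritParams countPlate
#' @return as [countPlate()].
#' @export
countPlateFile <- function(scanPath, modelFocus, modelCount,
                           params = countParams(),
                           minAreaFraction = 0.01, groupLabel = "",
                           overlayDir = NULL, verbose = FALSE) {
  contents <- rhdf5::h5ls(scanPath)
  if (!"/scan/images" %in% file.path(contents$group, contents$name))
    stop("HDF5 format error: missing dataset '/scan/images'")
  ids <- as.character(rhdf5::h5read(scanPath, "scan/well_ids"))
  nW <- length(ids)
  focusList <- vector("list", nW)
  wellsOut <- vector("list", nW)
  rows <- list()
  for (w in seq_len(nW)) {
    if (w %% 8L == 0L) gc(verbose = FALSE)
    zs <- readWellStack(scanPath, w)
    fr <- selectBestFrame(zs, modelFocus, wellId = ids[w],
                          minAreaFraction = minAreaFraction)
    focusList[[w]] <- fr
    wc <- countWell(zs, fr, modelCount, params)
    wellsOut[[w]] <- wc
    if (verbose)
      message(sprintf("well %-3s fish=%-5s best_z=%-3s count=%s", ids[w],
                      fr@fishFound,
                      if (fr@fishFound) fr@bestZ else "-",
                      if (fr@fishFound) wc$count else "-"))
    if (wc$fishPresent) {
      rows[[length(rows) + 1L]] <-
        data.frame(well_id = ids[w], fish_present = TRUE,
                   best_z = wc$bestZ, count = wc$count,
                   orientation = "unknown", group_label = groupLabel,
                   stringsAsFactors = FALSE)
      if (!is.null(overlayDir))
        writeOverlay(zs, wc, file.path(overlayDir, paste0(ids[w], ".png")))
    }
  }
  rhdf5::h5closeAll()
  table <- if (length(rows)) do.call(rbind, rows)
           else data.frame(well_id = character(), fish_present = logical(),
                           best_z = integer(), count = integer(),
                           orientation = character(),
                           group_label = character(),
                           stringsAsFactors = FALSE)
  if (verbose)
    message(sprintf("plate done: %d wells counted, %d discarded",
                    nrow(table), nW - nrow(table)))
  list(table = table, focus = focusList, wells = wellsOut)
}

#' Write an overlay PNG with blob pins
#'
#' The best-focus frame at counting resolution with a red cross over each
#' detected blob centroid.
#'
#' @param zstack (nz, H, W, 3) array for the well.
#' @param wellCount result of [countWell()].
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
writeOverlay <- function(zstack, wellCount, path) {
  stopifnot(isTRUE(wellCount$fishPresent))
  frame <- zstack[wellCount$bestZ + 1L, , , , drop = FALSE]
  dim(frame) <- dim(zstack)[2:4]
  res <- wellCount$params$countingResolution
  img <- .resizeArray(.normalizeFrame(frame), res, res, "bilinear")
  blobs <- wellCount$blobs
  arm <- max(2L, res %/% 100L)
  if (!is.null(blobs) && nrow(blobs)) {
    for (k in seq_len(nrow(blobs))) {
      r <- round(blobs[k, "row"]) + 1L
      c <- round(blobs[k, "col"]) + 1L
      rr <- pmax(1L, pmin(res, (r - arm):(r + arm)))
      cc <- pmax(1L, pmin(res, (c - arm):(c + arm)))
      img[rr, c, 1L] <- 1; img[rr, c, 2:3] <- 0
      img[r, cc, 1L] <- 1; img[r, cc, 2:3] <- 0
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
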