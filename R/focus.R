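#' Variance-of-Laplacian focus score of a masked region
#'
#' The frame is reduced to the focus channel (green by default, the
#' fluorescence channel), convolved with the 3x3 Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` using replicate padding, and scored by the
#' population variance of the response over the pixels where the mask is
#' set. Sharper regions score higher; a constant region scores zero, and
#' adding a constant to the image leaves the score unchanged.
#'
#' @param frame (H, W, 3) array at the working resolution, values 0..255.
#' @param mask a [SegMask-class] or 0/1 matrix at the same resolution.
#' @param channel "green", "red", "blue" or "gray" (luminance mean).
#' @return nonnegative focus score.
#' @export
varianceOfLaplacian <- function(frame, mask, channel = "green") {
  m <- if (is(mask, "SegMask")) mask@mask else mask
  if (sum(m) == 0L) stop("empty mask: treat well as fishless")
  ch <- switch(channel,
               red = frame[, , 1L], green = frame[, , 2L],
               blue = frame[, , 3L],
               gray = (frame[, , 1L] + frame[, , 2L] + frame[, , 3L]) / 3,
               stop("unknown focus channel"))
  if (!all(dim(ch) == dim(m))) stop("frame and mask shapes differ")
  storage.mode(ch) <- "double"
  lap <- .laplacian3(ch)
  v <- lap[m > 0]
  mean(v^2) - mean(v)^2            # population variance
}

#' Select the best-focus slice of a well Z-stack
#'
#' Each slice is segmented at the focus working resolution (256 px by
#' default); slices whose mask covers less than `minAreaFraction` of the
#' frame are scored as fishless. Among the remaining slices the
#' variance-of-Laplacian score is maximized; exact ties resolve to the
#' lowest slice index. A well with no scoring slice is a valid fishless
#' outcome, not an error.
#'
#' @param zstack (nz, H, W, 3) array, or a [PlateScan-class] plus `well`.
#' @param model focus-resolution [UNetModel-class].
#' @param wellId label carried into the result.
#' @param minAreaFraction minimum mask area as a fraction of frame area to
#'   accept a fish. The default 0.01 sits an order of magnitude below the
#'   smallest plausible larva silhouette at any working resolution (a
#'   non-lateral fish covers about 7 percent of the frame) and well above
#'   stray single-pixel activations.
#' @param channel focus channel, see [varianceOfLaplacian()].
#' @return a [FocusResult-class].
#' @export
selectBestFrame <- function(zstack, model, wellId = "?",
                            minAreaFraction = 0.01, channel = "green") {
  stopifnot(length(dim(zstack)) == 4L)
  nz <- dim(zstack)[1L]
  res <- model@resolution
  scores <- rep(NA_real_, nz)
  for (z in seq_len(nz)) {
    frame <- zstack[z, , , , drop = FALSE]
    dim(frame) <- dim(zstack)[2:4]
    sm <- inferMask(frame, model)
    if (maskAreaFraction(sm) < minAreaFraction) next
    chIdx <- switch(channel, red = 1L, green = 2L, blue = 3L, 0L)
    small <- array(0, c(res, res, 3L))
    if (chIdx > 0L) {
      ch <- frame[, , chIdx]
      storage.mode(ch) <- "double"
      small[, , chIdx] <- .resizeMatrix(ch, res, res, "bilinear")
    } else {
      small <- .resizeArray(frame, res, res, "bilinear")
    }
    scores[z] <- varianceOfLaplacian(small, sm@mask, channel = channel)
  }
  if (all(is.na(scores)))
    return(new("FocusResult", wellId = wellId, scores = scores,
               bestZ = NA_integer_, fishFound = FALSE))
  best <- which.max(scores)        # first maximum: lowest-index tie-break
  new("FocusResult", wellId = wellId, scores = scores,
      bestZ = as.integer(best - 1L), fishFound = TRUE)
}

#' Frame-selection agreement between manual and algorithmic choices
#'
#' Builds the confusion matrix over slice indices and the two headline
#' agreement rates: the percentage of exact matches (diagonal) and the
#' percentage of selections within one slice of each other.
#'
#' @param manual,algo named integer vectors of 0-based best-slice indices;
#'   names are well ids and must match as sets.
#' @param nSlices number of slices (matrix dimension).
#' @return list with `matrix` (manual in rows, algorithmic in columns),
#'   `pctExact` and `pctWithinOne` (percent).
#' @export
frameSelectionConfusion <- function(manual, algo, nSlices) {
  if (is.null(names(manual)) || is.null(names(algo)))
    stop("manual and algo must be named by well id")
  if (!setequal(names(manual), names(algo)))
    stop("manual and algo cover different well sets")
  algo <- algo[names(manual)]
  nSlices <- as.integer(nSlices)
  mat <- matrix(0L, nSlices, nSlices,
                dimnames = list(manual = as.character(seq_len(nSlices) - 1L),
                                algo = as.character(seq_len(nSlices) - 1L)))
  for (i in seq_along(manual))
    mat[manual[i] + 1L, algo[i] + 1L] <- mat[manual[i] + 1L, algo[i] + 1L] + 1L
  n <- length(manual)
  list(matrix = mat,
       pctExact = 100 * sum(diag(mat)) / n,
       pctWithinOne = 100 * sum(abs(manual - algo) <= 1L) / n)
}
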