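#' @useDynLib larvacount, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Plate acquisition metadata
#'
#' Constructs the metadata record attached to a [PlateScan-class]: plate
#' geometry and the acquisition settings that must stay constant for counts
#' to be comparable between scans.
#'
#' @param plateRows,plateCols plate grid (default 8 x 12, a 96-well plate).
#' @param pixelSizeUm lateral pixel size in micrometers per pixel.
#' @param zStepUm axial step between consecutive Z-slices, micrometers.
#' @param nSlices number of Z-slices per well.
#' @param exposureMs exposure time, milliseconds.
#' @param gainDigital,gainAnalog camera gains (unitless).
#' @param brightnessPct illumination brightness, percent.
#' @return a named list with validated fields.
#' @export
plateMetadata <- function(plateRows = 8L, plateCols = 12L,
                          pixelSizeUm = 3, zStepUm = 100, nSlices = 31L,
                          exposureMs = 200, gainDigital = 2.4,
                          gainAnalog = 1.0, brightnessPct = 50) {
  md <- list(plateRows = as.integer(plateRows),
             plateCols = as.integer(plateCols),
             pixelSizeUm = as.numeric(pixelSizeUm),
             zStepUm = as.numeric(zStepUm),
             nSlices = as.integer(nSlices),
             exposureMs = as.numeric(exposureMs),
             gainDigital = as.numeric(gainDigital),
             gainAnalog = as.numeric(gainAnalog),
             brightnessPct = as.numeric(brightnessPct))
  stopifnot(md$plateRows >= 1L, md$plateCols >= 1L, md$nSlices >= 1L)
  phys <- c(md$pixelSizeUm, md$zStepUm, md$exposureMs, md$gainDigital,
            md$gainAnalog, md$brightnessPct)
  if (any(!is.finite(phys)) || any(phys <= 0))
    stop("all physical acquisition quantities must be > 0")
  md
}

.metadataFields <- c("plateRows", "plateCols", "pixelSizeUm", "zStepUm",
                     "nSlices", "exposureMs", "gainDigital", "gainAnalog",
                     "brightnessPct")

#' Default row-major well labels
#'
#' Row-major labels "A1".."A12", "B1", ... matching plate-reader convention.
#'
#' @param plateRows,plateCols plate grid size.
#' @return character vector of length `plateRows * plateCols`.
#' @export
defaultWellIds <- function(plateRows = 8L, plateCols = 12L) {
  as.vector(t(outer(LETTERS[seq_len(plateRows)], seq_len(plateCols),
                    paste0)))
}

#' PlateScan: a multi-well volumetric plate scan
#'
#' The pipeline's sole raw input: a 5-axis unsigned 8-bit image volume with
#' axes (well, z, row-pixel, col-pixel, channel), stored in R as an integer
#' array with values in 0..255 and channel order R, G, B. Wells are ordered
#' row-major ("A1".."A12", "B1", ...). Pixel indices are 0-based (row, col)
#' with origin at the top-left throughout the package.
#'
#' @slot images integer array (wells, z, H, W, 3), values 0..255.
#' @slot metadata acquisition metadata list, see [plateMetadata()].
#' @slot wellIds character vector of unique well labels in row-major order.
#' @export
setClass("PlateScan",
         representation(images = "array", metadata = "list",
                        wellIds = "character"))

setValidity("PlateScan", function(object) {
  d <- dim(object@images)
  md <- object@metadata
  msgs <- character()
  if (length(d) != 5L)
    return("images must be a 5-axis array (well, z, H, W, channel)")
  if (!all(.metadataFields %in% names(md)))
    msgs <- c(msgs, paste("metadata missing:",
                          paste(setdiff(.metadataFields, names(md)),
                                collapse = ", ")))
  else {
    if (d[1L] != md$plateRows * md$plateCols)
      msgs <- c(msgs, "well axis length != plateRows * plateCols")
    if (d[2L] != md$nSlices)
      msgs <- c(msgs, "z axis length != metadata nSlices")
  }
  if (d[5L] != 3L) msgs <- c(msgs, "channel axis length must be exactly 3")
  if (length(object@wellIds) != d[1L])
    msgs <- c(msgs, "wellIds length != number of wells")
  if (anyDuplicated(object@wellIds))
    msgs <- c(msgs, "wellIds must be unique")
  # min/max (not range(), which duplicates large integer arrays)
  if (min(object@images) < 0 || max(object@images) > 255)
    msgs <- c(msgs, "image values must lie in 0..255")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PlateScan
#'
#' @param images integer array (wells, z, H, W, 3), values 0..255.
#' @param metadata list from [plateMetadata()].
#' @param wellIds optional well labels; defaults to row-major "A1".."H12".
#' @return a [PlateScan-class] object.
#' @export
PlateScan <- function(images, metadata = plateMetadata(),
                      wellIds = NULL) {
  if (is.null(wellIds))
    wellIds <- defaultWellIds(metadata$plateRows, metadata$plateCols)
  new("PlateScan", images = images, metadata = metadata,
      wellIds = wellIds)
}

#' SegMask: a binary foreground mask at a working resolution
#'
#' Carries the resolution the mask was inferred at and the native frame
#' shape it maps back to (by nearest-neighbor upsampling, which keeps the
#' mask binary).
#'
#' @slot mask integer matrix of 0/1 at the working resolution.
#' @slot nativeShape integer (H, W) of the native frame.
#' @slot workingResolution integer, side length of `mask`.
#' @export
setClass("SegMask",
         representation(mask = "matrix", nativeShape = "integer",
                        workingResolution = "integer"))

setValidity("SegMask", function(object) {
  if (!all(object@mask %in% c(0L, 1L)))
    return("mask values must be 0/1")
  if (length(object@nativeShape) != 2L)
    return("nativeShape must have length 2")
  TRUE
})

#' Construct a SegMask
#' @param mask 0/1 matrix.
#' @param nativeShape integer (H, W) native frame shape.
#' @return a [SegMask-class] object.
#' @export
SegMask <- function(mask, nativeShape) {
  storage.mode(mask) <- "integer"
  new("SegMask", mask = mask, nativeShape = as.integer(nativeShape),
      workingResolution = as.integer(nrow(mask)))
}

#' FocusResult: per-well focus scores and selected best slice
#'
#' @slot wellId well label.
#' @slot scores numeric vector of focus scores over Z (NA where no fish
#'   mask was found in that slice).
#' @slot bestZ 0-based index of the selected slice (NA if no fish).
#' @slot fishFound logical; `FALSE` means the well is discarded downstream.
#' @export
setClass("FocusResult",
         representation(wellId = "character", scores = "numeric",
                        bestZ = "integer", fishFound = "logical"))

#' UNetModel: a trained fully-convolutional segmentation network
#'
#' @slot weights flat list of conv weights/biases.
#' @slot channels integer vector of feature widths per resolution level.
#' @slot inChannels number of input channels (3 for RGB).
#' @slot resolution working resolution the model was trained at.
#' @slot history data.frame of per-epoch train/validation Dice loss.
#' @slot config the training configuration used.
#' @export
setClass("UNetModel",
         representation(weights = "list", channels = "integer",
                        inChannels = "integer", resolution = "integer",
                        history = "data.frame", config = "list"))

#' PlateTruth: simulator ground truth for a synthetic plate
#'
#' @slot wells per-well list: `fishPresent`, `zTrue` (0-based), `spotCenters`
#'   (n x 2 matrix of 0-based row, col), `nSpots`, `orientation`,
#'   `melanophoreCenters`, `fishMask` (logical matrix at frame size).
#' @slot frameSize frame side length in pixels.
#' @slot nSlices number of Z-slices.
#' @slot config the simulation configuration used.
#' @export
setClass("PlateTruth",
         representation(wells = "list", frameSize = "integer",
                        nSlices = "integer", config = "list"))

setMethod("show", "PlateScan", function(object) {
  d <- dim(object@images)
  cat(sprintf("PlateScan: %d wells x %d slices, frames %d x %d x %d (uint8)\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  plate %d x %d, %.3g um/px, z-step %.3g um\n",
              object@metadata$plateRows, object@metadata$plateCols,
              object@metadata$pixelSizeUm, object@metadata$zStepUm))
})

setMethod("show", "SegMask", function(object) {
  cat(sprintf("SegMask %d x %d (native %d x %d), area %d px\n",
              nrow(object@mask), ncol(object@mask),
              object@nativeShape[1], object@nativeShape[2],
              sum(object@mask)))
})

setMethod("show", "FocusResult", function(object) {
  if (object@fishFound)
    cat(sprintf("FocusResult %s: best z = %d (score %.4g) over %d slices\n",
                object@wellId, object@bestZ,
                object@scores[object@bestZ + 1L], length(object@scores)))
  else
    cat(sprintf("FocusResult %s: no fish found\n", object@wellId))
})

setMethod("show", "UNetModel", function(object) {
  cat(sprintf("UNetModel: %d levels (%s channels), resolution %d, %d epochs\n",
              length(object@channels),
              paste(object@channels, collapse = "-"),
              object@resolution, nrow(object@history)))
})

setMethod("show", "PlateTruth", function(object) {
  fish <- sum(vapply(object@wells, `[[`, TRUE, "fishPresent"))
  cat(sprintf("PlateTruth: %d wells (%d with fish), frame %d, %d slices\n",
              length(object@wells), fish, object@frameSize,
              object@nSlices))
})

# --- accessors -------------------------------------------------------------

#' @describeIn PlateScan-class the raw 5-axis image array.
#' @param scan a PlateScan.
#' @export
scanImages <- function(scan) scan@images

#' @describeIn PlateScan-class the well labels.
#' @export
wellIds <- function(scan) scan@wellIds

#' @describeIn PlateScan-class the acquisition metadata list.
#' @export
scanMetadata <- function(scan) scan@metadata

#' @describeIn PlateScan-class number of wells.
#' @export
nWells <- function(scan) dim(scan@images)[1L]

#' @describeIn PlateScan-class number of Z-slices.
#' @export
nSlices <- function(scan) dim(scan@images)[2L]

#' Extract one frame from a scan
#'
#' @param scan a [PlateScan-class].
#' @param well 1-based well index or well label.
#' @param z 0-based slice index.
#' @return integer array (H, W, 3).
#' @export
wellFrame <- function(scan, well, z) {
  if (is.character(well)) well <- match(well, scan@wellIds)
  z <- as.integer(z)
  if (is.na(well) || well < 1L || well > nWells(scan))
    stop("well out of range")
  if (z < 0L || z >= nSlices(scan)) stop("z index out of range")
  arr <- scan@images[well, z + 1L, , , , drop = FALSE]
  dim(arr) <- dim(scan@images)[3:5]
  arr
}

#' @describeIn SegMask-class binary mask matrix.
#' @param x a SegMask.
#' @export
maskMatrix <- function(x) x@mask

#' @describeIn SegMask-class fraction of mask pixels that are foreground.
#' @export
maskAreaFraction <- function(x) mean(x@mask)

#' @describeIn FocusResult-class per-slice focus scores.
#' @export
focusScores <- function(x) x@scores

#' @describeIn FocusResult-class 0-based selected best slice.
#' @export
bestZ <- function(x) x@bestZ
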