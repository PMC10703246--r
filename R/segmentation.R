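#' AnnotationSet: labeled frames for segmentation training
#'
#' Items pair an RGB frame with a binary truth mask (rasterized from a
#' polygon outline when the set comes from VGG Image Annotator JSON, or
#' taken directly from simulator ground truth). Each item is assigned to
#' the train, validation or test split.
#'
#' @slot items list of `list(name, image, mask, polygon)`; `image` is an
#'   (H, W, 3) array with values 0..255, `mask` a 0/1 matrix, `polygon` an
#'   n x 2 (x, y) vertex matrix or `NULL`.
#' @slot split character vector ("train", "val", "test") per item.
#' @export
setClass("AnnotationSet",
         representation(items = "list", split = "character"))

setValidity("AnnotationSet", function(object) {
  if (length(object@split) != length(object@items))
    return("split length != number of items")
  if (!all(object@split %in% c("train", "val", "test")))
    return("split values must be train/val/test")
  TRUE
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d items (%d train / %d val / %d test)\n",
              length(object@items), sum(object@split == "train"),
              sum(object@split == "val"), sum(object@split == "test")))
})

#' Construct an AnnotationSet
#'
#' @param items list of `list(name, image, mask, polygon)`.
#' @param split optional split assignment; defaults to assigning everything
#'   to "train".
#' @return an [AnnotationSet-class].
#' @export
annotationSet <- function(items, split = NULL) {
  if (is.null(split)) split <- rep("train", length(items))
  new("AnnotationSet", items = items, split = split)
}

#' Randomly split an annotation set
#'
#' Random assignment without stratification in the proportions used for the
#' sixty-image larva training set (30/13/17, i.e. 50/22/28 percent).
#'
#' @param annotations an [AnnotationSet-class].
#' @param proportions train/val/test proportions (must sum to 1).
#' @param seed RNG seed for the shuffle.
#' @return the annotation set with `@split` reassigned.
#' @export
splitAnnotations <- function(annotations, proportions = c(0.50, 0.22, 0.28),
                             seed = 1L) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8)
  n <- length(annotations@items)
  set.seed(seed)
  ord <- sample(n)
  nTrain <- round(proportions[1L] * n)
  nVal <- round(proportions[2L] * n)
  split <- rep("test", n)
  split[ord[seq_len(nTrain)]] <- "train"
  if (nVal > 0L) split[ord[nTrain + seq_len(nVal)]] <- "val"
  annotations@split <- split
  annotations
}

#' Rasterize a polygon outline to a binary mask
#'
#' A pixel is foreground iff its center lies inside the polygon (even-odd
#' rule) or exactly on its boundary. Vertices are (x, y) = (column, row) in
#' 0-based pixel coordinates, the convention used by VGG Image Annotator.
#'
#' @param polygon n x 2 matrix of (x, y) vertices, n >= 3.
#' @param shape integer (H, W) of the target mask.
#' @return 0/1 integer matrix.
#' @export
polygonToMask <- function(polygon, shape) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  shape <- as.integer(shape)
  xs <- polygon[, 1L]; ys <- polygon[, 2L]
  # shoelace area
  area <- abs(sum(xs * c(ys[-1L], ys[1L]) - c(xs[-1L], xs[1L]) * ys)) / 2
  if (area == 0) stop("degenerate polygon (zero area)")
  if (any(xs < 0 | xs > shape[2L] - 1L | ys < 0 | ys > shape[1L] - 1L))
    stop("polygon vertices outside frame bounds")
  .polygonMask(xs, ys, shape[1L], shape[2L])
}

#' Read VGG Image Annotator polygon annotations
#'
#' Accepts the VIA region-export JSON (a dictionary of images, each with a
#' `regions` list whose `shape_attributes` carry `all_points_x` /
#' `all_points_y`), or a full VIA project file (the `_via_img_metadata`
#' element). Exactly one polygon region per image is expected.
#'
#' @param jsonPath path to the VIA JSON file.
#' @param imageDir directory holding the referenced images (PNG).
#' @return an [AnnotationSet-class] with masks rasterized at native
#'   resolution (all items assigned to "train"; see [splitAnnotations()]).
#' @export
loadViaAnnotations <- function(jsonPath, imageDir) {
  via <- jsonlite::fromJSON(jsonPath, simplifyVector = FALSE)
  if (!is.null(via[["_via_img_metadata"]])) via <- via[["_via_img_metadata"]]
  if (length(via) == 0L) stop("VIA file contains no images")
  items <- lapply(via, function(entry) {
    fn <- entry$filename
    if (is.null(fn)) stop("VIA entry lacks a filename")
    regions <- entry$regions
    if (is.null(regions) || length(regions) == 0L)
      stop(sprintf("VIA format error: no regions for image '%s'", fn))
    sa <- regions[[1L]]$shape_attributes
    if (is.null(sa$name) || sa$name != "polygon")
      stop(sprintf("VIA format error: region for '%s' is '%s', not polygon",
                   fn, if (is.null(sa$name)) "unknown" else sa$name))
    poly <- cbind(unlist(sa$all_points_x), unlist(sa$all_points_y))
    path <- file.path(imageDir, fn)
    if (!file.exists(path))
      stop(sprintf("image file not found: %s", path))
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
    img <- round(raw[, , 1:3] * 255)
    mask <- polygonToMask(poly, dim(img)[1:2])
    list(name = fn, image = img, mask = mask, polygon = poly)
  })
  names(items) <- NULL
  annotationSet(items)
}

#' Build an annotation set from simulator ground truth
#'
#' Extracts the in-focus frame of each fish-containing well together with
#' the true fish mask, giving a perfectly labeled training set without
#' manual outlining.
#'
#' @param scan a [PlateScan-class] from [generatePlate()].
#' @param truth the matching [PlateTruth-class].
#' @param wells optional well indices to include (default: all wells).
#' @param includeEmpty keep empty wells as background-only examples (with
#'   all-zero masks), which teaches the network to reject fishless frames.
#' @return an [AnnotationSet-class].
#' @export
annotationsFromTruth <- function(scan, truth, wells = NULL,
                                 includeEmpty = TRUE) {
  fish <- vapply(truth@wells, `[[`, TRUE, "fishPresent")
  if (is.null(wells))
    wells <- if (includeEmpty) seq_along(truth@wells) else which(fish)
  if (!includeEmpty) wells <- intersect(wells, which(fish))
  if (length(wells) == 0L) stop("no wells to annotate")
  if (!any(fish[wells])) stop("no fish-containing wells to annotate")
  items <- lapply(wells, function(w) {
    tw <- truth@wells[[w]]
    z <- if (tw$fishPresent) tw$zTrue else (truth@nSlices - 1L) %/% 2L
    list(name = wellIds(scan)[w],
         image = wellFrame(scan, w, z),
         mask = tw$fishMask + 0L,
         polygon = NULL)
  })
  annotationSet(items)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)`.
#' With binary inputs and `eps` tending to zero this is one minus the Dice
#' overlap coefficient.
#'
#' @param pred probability map in \[0, 1\].
#' @param truth binary mask of the same shape.
#' @param eps smoothing constant (default 1).
#' @return loss value in \[0, 1\].
#' @export
diceLoss <- function(pred, truth, eps = 1.0) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  if (any(pred < 0 | pred > 1)) stop("pred must lie in [0, 1]")
  1 - (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)
}

#' Intersection over union of two binary masks
#'
#' Defined as 1 when both masks are empty.
#'
#' @param maskA,maskB binary masks of the same shape.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(maskA, maskB) {
  if (!all(dim(maskA) == dim(maskB))) stop("shape mismatch")
  a <- maskA > 0; b <- maskB > 0
  union <- sum(a | b)
  if (union == 0L) return(1.0)
  sum(a & b) / union
}
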