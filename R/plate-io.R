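#' Write a plate scan to an HDF5 container
#'
#' Layout: one uint8 dataset `/scan/images` with axes (well, z, H, W,
#' channel), chunked per (1 well, 1 slice) so the pipeline can stream one
#' frame at a time; acquisition metadata as attributes on the `/scan`
#' group; well labels as a string dataset `/scan/well_ids`.
#'
#' @param scan a [PlateScan-class].
#' @param path output file path (overwritten).
#' @return invisibly, `path`.
#' @export
writeScan <- function(scan, path) {
  validObject(scan)
  d <- dim(scan@images)
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop(sprintf("cannot create HDF5 file '%s'", path))
  rhdf5::h5createGroup(path, "scan")
  rhdf5::h5createDataset(path, "scan/images", dims = d,
                         H5type = "H5T_STD_U8LE",
                         chunk = c(1L, 1L, d[3L], d[4L], d[5L]),
                         level = 4L)
  rhdf5::h5write(scan@images, path, "scan/images")
  rhdf5::h5write(scan@wellIds, path, "scan/well_ids")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "scan")
  for (key in .metadataFields)
    rhdf5::h5writeAttribute(scan@metadata[[key]], gid, key)
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a plate scan from an HDF5 container
#'
#' Inverse of [writeScan()]; `readScan(writeScan(s, p))` reproduces `s`
#' element-wise. Missing datasets or metadata attributes raise a format
#' error naming the missing key; inconsistent shapes raise an invariant
#' error through the [PlateScan-class] validity method.
#'
#' @param path HDF5 file written by [writeScan()].
#' @return a [PlateScan-class].
#' @export
readScan <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  contents <- rhdf5::h5ls(path)
  have <- file.path(contents$group, contents$name)
  for (need in c("/scan/images", "/scan/well_ids"))
    if (!need %in% have)
      stop(sprintf("HDF5 format error: missing dataset '%s'", need))
  images <- rhdf5::h5read(path, "scan/images")
  storage.mode(images) <- "integer"
  wellIdsV <- as.character(rhdf5::h5read(path, "scan/well_ids"))
  attrs <- rhdf5::h5readAttributes(path, "scan")
  missing <- setdiff(.metadataFields, names(attrs))
  if (length(missing))
    stop(sprintf("HDF5 format error: missing metadata attribute(s): %s",
                 paste(missing, collapse = ", ")))
  md <- plateMetadata(plateRows = attrs$plateRows,
                      plateCols = attrs$plateCols,
                      pixelSizeUm = attrs$pixelSizeUm,
                      zStepUm = attrs$zStepUm, nSlices = attrs$nSlices,
                      exposureMs = attrs$exposureMs,
                      gainDigital = attrs$gainDigital,
                      gainAnalog = attrs$gainAnalog,
                      brightnessPct = attrs$brightnessPct)
  PlateScan(images, md, wellIdsV)
}

#' Read a single well's Z-stack from an HDF5 scan
#'
#' The (well, slice) chunking of the container makes per-well access a
#' handful of chunk reads, so a plate can be processed without ever
#' loading the full volume.
#'
#' @param path HDF5 file written by [writeScan()] or
#'   [generatePlateStream()].
#' @param well 1-based well index.
#' @return integer array (nz, H, W, 3).
#' @export
readWellStack <- function(path, well) {
  stack <- rhdf5::h5read(path, "scan/images",
                         index = list(as.integer(well), NULL, NULL, NULL,
                                      NULL))
  d <- dim(stack)
  dim(stack) <- d[-1L]
  storage.mode(stack) <- "integer"
  stack
}

#' Composite plate-slice geometry
#'
#' Dimensions (height, width) of the composite image formed by tiling all
#' wells of one Z-slice into the plate grid, without materializing it.
#' At native scale (96 wells of 3072 x 3072 in an 8 x 12 grid) this is
#' 24,576 x 36,864 pixels, i.e. about 906 megapixels per slice.
#'
#' @param metadata a [plateMetadata()] list.
#' @param frameShape integer (H, W) of a single well frame.
#' @return integer (height, width) of the composite.
#' @export
compositeShape <- function(metadata, frameShape = c(3072L, 3072L)) {
  as.integer(c(metadata$plateRows * frameShape[1L],
               metadata$plateCols * frameShape[2L]))
}

#' Materialize one composite plate slice
#'
#' Tiles the wells of slice `z` row-major into the plate grid: composite
#' pixel `(r*H + i, c*W + j)` equals pixel `(i, j)` of the well in plate
#' row `r`, column `c`. Total intensity is conserved.
#'
#' @param scan a [PlateScan-class].
#' @param z 0-based slice index.
#' @return integer array (plateRows*H, plateCols*W, 3).
#' @export
compositeSlice <- function(scan, z) {
  z <- as.integer(z)
  if (z < 0L || z >= nSlices(scan)) stop("z index out of range")
  md <- scan@metadata
  d <- dim(scan@images)
  H <- d[3L]; W <- d[4L]
  out <- array(0L, c(md$plateRows * H, md$plateCols * W, 3L))
  for (r in seq_len(md$plateRows) - 1L) {
    for (c in seq_len(md$plateCols) - 1L) {
      wIdx <- r * md$plateCols + c + 1L
      out[r * H + seq_len(H), c * W + seq_len(W), ] <-
        wellFrame(scan, wIdx, z)
    }
  }
  out
}

#' Write a composite slice as a PNG for inspection
#'
#' @param scan a [PlateScan-class].
#' @param z 0-based slice index.
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
writeCompositePng <- function(scan, z, path) {
  comp <- compositeSlice(scan, z)
  png::writePNG(comp / 255, path)
  invisible(path)
}

.countTableCols <- c("well_id", "fish_present", "best_z", "count",
                     "orientation", "group_label")

#' Write / read per-well count tables as CSV
#'
#' Header `well_id,fish_present,best_z,count,orientation,group_label`,
#' one row per non-discarded well. `readManualCounts` validates every row
#' and reports the offending line number on a malformed one; it is also
#' how externally produced (manual) counts enter the pipeline.
#'
#' @param table data.frame with the columns above.
#' @param path CSV path.
#' @return `readManualCounts` returns the validated data.frame.
#' @export
writeCounts <- function(table, path) {
  stopifnot(all(.countTableCols %in% names(table)))
  utils::write.csv(table[, .countTableCols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCounts
#' @export
readManualCounts <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!identical(names(raw), .countTableCols))
    stop(sprintf("parse error: expected header %s",
                 paste(.countTableCols, collapse = ",")))
  n <- nrow(raw)
  out <- data.frame(well_id = character(n), fish_present = logical(n),
                    best_z = integer(n), count = integer(n),
                    orientation = character(n), group_label = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    line <- i + 1L            # header is line 1
    fp <- toupper(raw$fish_present[i])
    if (!fp %in% c("TRUE", "FALSE"))
      stop(sprintf("parse error at line %d: bad fish_present '%s'", line,
                   raw$fish_present[i]))
    bz <- suppressWarnings(as.integer(raw$best_z[i]))
    ct <- suppressWarnings(as.integer(raw$count[i]))
    if (is.na(bz) && raw$best_z[i] != "NA")
      stop(sprintf("parse error at line %d: bad best_z '%s'", line,
                   raw$best_z[i]))
    if (is.na(ct) || ct < 0L)
      stop(sprintf("parse error at line %d: bad count '%s'", line,
                   raw$count[i]))
    if (!raw$orientation[i] %in% c("lateral", "non_lateral", "unknown"))
      stop(sprintf("parse error at line %d: bad orientation '%s'", line,
                   raw$orientation[i]))
    out$well_id[i] <- raw$well_id[i]
    out$fish_present[i] <- fp == "TRUE"
    out$best_z[i] <- bz
    out$count[i] <- ct
    out$orientation[i] <- raw$orientation[i]
    out$group_label[i] <- raw$group_label[i]
  }
  out
}
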