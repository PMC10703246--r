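test_that("scan write/read round-trips exactly through HDF5", {
  sim <- generatePlate(simConfig(frameSize = 64L, nSlices = 3L,
                                 plateRows = 2L, plateCols = 2L,
                                 fishProb = 1, seed = 4L))
  p <- tempfile(fileext = ".h5")
  writeScan(sim$scan, p)
  back <- readScan(p)
  expect_identical(scanImages(back), scanImages(sim$scan))
  expect_identical(scanMetadata(back), scanMetadata(sim$scan))
  expect_identical(wellIds(back), wellIds(sim$scan))

  # rewriting the same scan yields an identical image dataset
  p2 <- tempfile(fileext = ".h5")
  writeScan(sim$scan, p2)
  expect_identical(rhdf5::h5read(p, "scan/images"),
                   rhdf5::h5read(p2, "scan/images"))
  unlink(c(p, p2))
})

test_that("missing metadata attributes are reported by name", {
  sim <- generatePlate(simConfig(frameSize = 64L, nSlices = 2L,
                                 plateRows = 1L, plateCols = 2L,
                                 fishProb = 0, seed = 1L))
  p <- tempfile(fileext = ".h5")
  writeScan(sim$scan, p)
  fid <- rhdf5::H5Fopen(p)
  gid <- rhdf5::H5Gopen(fid, "scan")
  rhdf5::H5Adelete(gid, "zStepUm")
  rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  expect_error(readScan(p), "zStepUm")
  unlink(p)
  expect_error(readScan(tempfile()), "no such file")
})

test_that("malformed scans are rejected before writing", {
  bad <- array(0L, c(4L, 2L, 8L, 8L, 4L))   # 4 channels
  expect_error(PlateScan(bad, plateMetadata(2L, 2L, nSlices = 2L)),
               "channel")
  short <- array(300L, c(4L, 2L, 8L, 8L, 3L))
  expect_error(PlateScan(short, plateMetadata(2L, 2L, nSlices = 2L)),
               "0..255")
})

test_that("composite tiling places wells row-major and conserves intensity", {
  # 4 wells of 8x8 with distinct constant values
  vals <- c(10L, 20L, 30L, 40L)
  images <- array(0L, c(4L, 1L, 8L, 8L, 3L))
  for (w in 1:4) images[w, 1L, , , ] <- vals[w]
  scan <- PlateScan(images, plateMetadata(2L, 2L, nSlices = 1L))
  comp <- compositeSlice(scan, 0L)
  expect_identical(dim(comp), c(16L, 16L, 3L))
  expect_true(all(comp[1:8, 1:8, ] == 10L))    # A1 top-left
  expect_true(all(comp[1:8, 9:16, ] == 20L))   # A2 top-right
  expect_true(all(comp[9:16, 1:8, ] == 30L))   # B1 bottom-left
  expect_true(all(comp[9:16, 9:16, ] == 40L))
  expect_identical(sum(comp), sum(images))
  expect_error(compositeSlice(scan, 1L), "out of range")

  # single-well composite is the identity
  oneImages <- images[1L, , , , , drop = FALSE]
  dim(oneImages) <- c(1L, 1L, 8L, 8L, 3L)
  one <- PlateScan(oneImages, plateMetadata(1L, 1L, nSlices = 1L))
  expect_identical(compositeSlice(one, 0L), wellFrame(one, 1L, 0L))

  # native-scale geometry without materializing
  shp <- compositeShape(plateMetadata())
  expect_identical(shp, c(24576L, 36864L))
})

test_that("count tables round-trip through CSV with validation", {
  tab <- data.frame(well_id = c("A1", "A2", "B5"),
                    fish_present = c(TRUE, TRUE, TRUE),
                    best_z = c(3L, 15L, 0L), count = c(12L, 0L, 40L),
                    orientation = c("lateral", "non_lateral", "unknown"),
                    group_label = c("ctrl", "ctrl", "mo"),
                    stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".csv")
  writeCounts(tab, p)
  expect_identical(length(readLines(p)), 4L)   # header + 3 rows
  expect_identical(readManualCounts(p), tab)

  # empty table -> header-only file that still round-trips
  writeCounts(tab[0L, ], p)
  expect_identical(length(readLines(p)), 1L)
  expect_identical(nrow(readManualCounts(p)), 0L)

  # malformed rows are rejected with their line number
  writeLines(c("well_id,fish_present,best_z,count,orientation,group_label",
               "A1,TRUE,3,5,lateral,x",
               "A2,TRUE,2,-4,lateral,x"), p)
  expect_error(readManualCounts(p), "line 3")
  writeLines(c("well_id,fish_present,best_z,count,orientation,group_label",
               "A1,maybe,3,5,lateral,x"), p)
  expect_error(readManualCounts(p), "line 2")
  unlink(p)
})

test_that("streamed generation and counting match the in-memory route", {
  cfg <- simConfig(frameSize = 64L, nSlices = 3L, plateRows = 2L,
                   plateCols = 3L, fishProb = 0.7, seed = 17L)
  mem <- generatePlate(cfg)
  p <- tempfile(fileext = ".h5")
  truth <- generatePlateStream(cfg, p)
  streamed <- readScan(p)
  expect_identical(scanImages(streamed), scanImages(mem$scan))
  expect_identical(scanMetadata(streamed), scanMetadata(mem$scan))
  expect_identical(truthCounts(truth), truthCounts(mem$truth))
  for (w in seq_len(nWells(mem$scan))) {
    zs <- readWellStack(p, w)
    ref <- scanImages(mem$scan)[w, , , , ]
    expect_identical(zs, ref)
  }
  unlink(p)
})
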