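test_that("polygon rasterization follows the inclusive pixel-center rule", {
  # axis-aligned square: inclusive bounds give 41 x 41 pixels
  sq <- rbind(c(10, 10), c(50, 10), c(50, 50), c(10, 50))
  m <- polygonToMask(sq, c(64L, 64L))
  expect_identical(sum(m), 1681L)
  expect_identical(m[11L, 11L], 1L)           # 0-based (10,10) corner
  expect_identical(m[10L, 10L], 0L)

  # right triangle (0,0),(0,4),(4,0): centers with r + c <= 4 -> 15 px
  tri <- rbind(c(0, 0), c(0, 4), c(4, 0))
  mt <- polygonToMask(tri, c(8L, 8L))
  expect_identical(sum(mt), 15L)
  # brute-force half-plane oracle over all pixel centers
  oracle <- outer(0:7, 0:7, function(r, c) (r + c <= 4) & r >= 0 & c >= 0)
  expect_identical(mt == 1L, oracle)

  # full-frame rectangle -> all ones
  full <- rbind(c(0, 0), c(7, 0), c(7, 7), c(0, 7))
  expect_true(all(polygonToMask(full, c(8L, 8L)) == 1L))

  expect_error(polygonToMask(rbind(c(0, 0), c(20, 0), c(20, 20)),
                             c(8L, 8L)), "outside")
  expect_error(polygonToMask(rbind(c(1, 1), c(3, 3), c(5, 5)),
                             c(8L, 8L)), "degenerate")
  expect_error(polygonToMask(rbind(c(1, 1), c(3, 3)), c(8L, 8L)),
               "3 vertices")
})

viaFixture <- function(dir, regions) {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  png::writePNG(img, file.path(dir, "well.png"))
  via <- list(`well.png32` = list(filename = "well.png", size = 32L,
                                  regions = regions))
  path <- file.path(dir, "via.json")
  jsonlite::write_json(via, path, auto_unbox = TRUE)
  path
}

test_that("VIA polygon annotations load and rasterize", {
  dir <- tempfile(); dir.create(dir)
  poly <- list(shape_attributes = list(
    name = "polygon", all_points_x = c(5L, 25L, 25L, 5L),
    all_points_y = c(8L, 8L, 20L, 20L)))
  ann <- loadViaAnnotations(viaFixture(dir, list(poly)), dir)
  expect_s4_class(ann, "AnnotationSet")
  expect_length(ann@items, 1L)
  expect_identical(ann@items[[1L]]$mask,
                   polygonToMask(cbind(c(5, 25, 25, 5), c(8, 8, 20, 20)),
                                 c(32L, 32L)))
  expect_identical(dim(ann@items[[1L]]$image), c(32L, 32L, 3L))

  expect_error(loadViaAnnotations(viaFixture(dir, list()), dir),
               "no regions")
  rect <- list(shape_attributes = list(name = "rect", x = 1, y = 1,
                                       width = 5, height = 5))
  expect_error(loadViaAnnotations(viaFixture(dir, list(rect)), dir),
               "not polygon")
  p <- viaFixture(dir, list(poly))
  file.remove(file.path(dir, "well.png"))
  expect_error(loadViaAnnotations(p, dir), "not found")
  unlink(dir, recursive = TRUE)
})

test_that("dice loss and IoU follow their closed forms", {
  a <- matrix(0, 8, 8); a[2:3, 2] <- 1
  b <- matrix(0, 8, 8); b[3:4, 2] <- 1      # |A|=|B|=2, overlap 1
  eps <- 1e-12
  expect_equal(diceLoss(a, a, eps = eps), 0)
  expect_equal(iou(a, a), 1.0)
  disj <- matrix(0, 8, 8); disj[6, 6] <- 1
  expect_equal(diceLoss(a, disj, eps = eps), 1, tolerance = 1e-9)
  expect_equal(iou(a, disj), 0)
  expect_equal(diceLoss(a, b, eps = eps), 0.5)
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(iou(matrix(0, 4, 4), matrix(0, 4, 4)), 1.0)

  expect_error(diceLoss(a, matrix(0, 4, 4)), "mismatch")
  expect_error(iou(a, matrix(0, 4, 4)), "mismatch")
  expect_error(diceLoss(a * 2, a), "0, 1")

  # symmetry and the Dice = 2 IoU / (1 + IoU) identity on random masks
  set.seed(31)
  for (k in 1:50) {
    x <- matrix(rbinom(64, 1, 0.4), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(diceLoss(x, y, eps = eps), diceLoss(y, x, eps = eps))
    expect_equal(iou(x, y), iou(y, x))
    d <- 1 - diceLoss(x, y, eps = eps)
    expect_equal(d, 2 * iou(x, y) / (1 + iou(x, y)), tolerance = 1e-9)
    expect_gte(diceLoss(x, y), 0); expect_lte(diceLoss(x, y), 1)
  }
})

test_that("annotation splitting reproduces the 30/13/17 proportions", {
  items <- replicate(60, list(name = "x",
                              image = array(0L, c(8, 8, 3)),
                              mask = matrix(0L, 8, 8), polygon = NULL),
                     simplify = FALSE)
  ann <- splitAnnotations(annotationSet(items), c(0.50, 0.22, 0.28),
                          seed = 3L)
  expect_identical(sum(ann@split == "train"), 30L)
  expect_identical(sum(ann@split == "val"), 13L)
  expect_identical(sum(ann@split == "test"), 17L)
})
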