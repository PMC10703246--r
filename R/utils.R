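# Internal image helpers shared across modules.

# Resize a single-channel matrix. Downsampling by an integer factor uses
# block averaging (area interpolation, inherently anti-aliased); anything
# else goes through EBImage's bilinear resampler. `filter = "nearest"`
# (used for label masks) picks the nearest source pixel so labels never
# bleed.
.resizeMatrix <- function(m, h, w = h, filter = c("bilinear", "nearest")) {
  filter <- match.arg(filter)
  H <- nrow(m); W <- ncol(m)
  if (H == h && W == w) return(m)
  if (filter == "nearest") {
    ri <- pmin(H, floor(((seq_len(h) - 0.5) / h) * H) + 1L)
    ci <- pmin(W, floor(((seq_len(w) - 0.5) / w) * W) + 1L)
    return(m[ri, ci, drop = FALSE])
  }
  if (H %% h == 0L && W %% w == 0L && H > h && W > w) {
    f1 <- H %/% h; f2 <- W %/% w
    dim(m) <- c(f1, H %/% f1, W)
    s <- colMeans(m)                      # (h, W)
    s <- t(s)
    dim(s) <- c(f2, W %/% f2, h)
    return(t(colMeans(s)))                # (h, w)
  }
  as.matrix(EBImage::resize(EBImage::Image(m), w = h, h = w,
                            filter = "bilinear"))
}

# Resize an (H, W, C) numeric array channel-wise.
.resizeArray <- function(a, h, w = h, filter = "bilinear") {
  C <- dim(a)[3L]
  out <- array(0, c(h, w, C))
  for (k in seq_len(C)) out[, , k] <- .resizeMatrix(a[, , k], h, w, filter)
  out
}

# 0..255 integer frame -> [0, 1] double array.
.normalizeFrame <- function(frame) {
  a <- frame
  storage.mode(a) <- "double"
  a / 255
}

.clip8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# 3x3 Laplacian [[0,1,0],[1,-4,1],[0,1,0]] with replicate padding.
.laplacian3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up    <- m[c(1L, seq_len(H - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(H - 1L) + 1L, H), , drop = FALSE]
  left  <- m[, c(1L, seq_len(W - 1L)), drop = FALSE]
  right <- m[, c(seq_len(W - 1L) + 1L, W), drop = FALSE]
  up + down + left + right - 4 * m
}

# Gaussian blur that preserves plain-matrix/array types. The kernel
# radius is capped at the image size (gblur's 3-sigma default otherwise
# overflows small frames at the largest scale-space sigmas).
.gblur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- min(2L * as.integer(ceiling(3 * sigma)) + 1L,
           2L * ((min(dim(x)[1:2]) - 1L) %/% 2L) + 1L)
  if (is.matrix(x)) {
    as.matrix(EBImage::gblur(EBImage::Image(x), sigma = sigma,
                             radius = r))
  } else {
    out <- x
    for (k in seq_len(dim(x)[3L]))
      out[, , k] <- as.matrix(EBImage::gblur(EBImage::Image(x[, , k]),
                                             sigma = sigma, radius = r))
    out
  }
}

.isCount <- function(x) length(x) == 1L && is.finite(x) && x == round(x)
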