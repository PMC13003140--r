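#' @useDynLib sisegment, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm sd
#' @importFrom utils modifyList packageVersion
NULL

# ---- raster helpers ---------------------------------------------------------
#
# A "raster" is a plain numeric matrix (H x W, single channel) or an
# H x W x 3 array (color), values in [0, 1] unless stated otherwise.
# Pixel coordinates exposed to users are (row, col), 0-based, origin at the
# top-left pixel; internal R indexing is 1-based and converted at the surface.

assert_raster <- function(image, arg = "image") {
  if (!is.numeric(image) || length(image) == 0L)
    stop("degenerate input: ", arg, " must be a non-empty numeric raster")
  d <- dim(image)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] %in% c(1L, 3L))))
    stop(arg, " must be an H x W matrix or H x W x {1,3} array")
  if (any(d[1:2] == 0L)) stop("degenerate input: empty ", arg)
  if (!all(is.finite(image))) stop(arg, " contains non-finite values")
  invisible(image)
}

n_channels <- function(image) {
  d <- dim(image)
  if (length(d) == 2L) 1L else d[3]
}

# drop a trailing unit channel; promote 8-bit ranges to [0, 1]
normalize_range <- function(image) {
  d <- dim(image)
  if (length(d) == 3L && d[3] == 1L) {
    image <- image[, , 1L]
  }
  if (max(image) > 1) image <- image / 255
  image
}

#' Read an image raster from PNG or TIFF
#'
#' Returns a numeric matrix (grayscale) or an H x W x 3 array (color) with
#' values in \[0, 1\]. Alpha channels are dropped; 8-bit files are scaled to
#' unit range.
#'
#' @param path File path; format is chosen by extension
#'   (`.png`, `.tif`/`.tiff`).
#' @return A raster (matrix or H x W x 3 array).
#' @export
load_raster <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("cannot read image: unsupported extension '", ext, "'")
    ),
    error = function(e) stop("cannot read image: ", conditionMessage(e), call. = FALSE)
  )
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  if (length(dim(img)) == 3L && dim(img)[3] == 2L) img <- img[, , 1L]
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1L]
  assert_raster(img, "loaded image")
  img
}

#' Write a binary mask as an 8-bit PNG with values {0, 255}
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param path Output PNG path.
#' @export
save_mask <- function(mask, path) {
  if (is.logical(mask)) mask <- mask * 1
  assert_raster(mask, "mask")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  png::writePNG(mask, path)
  invisible(path)
}

#' Read a {0, 255} PNG mask as a logical matrix
#' @param path PNG path.
#' @export
load_mask <- function(path) {
  m <- load_raster(path)
  if (n_channels(m) != 1L) m <- m[, , 1L]
  m >= 0.5
}

#' Write a score map as a 32-bit float single-channel TIFF
#' @param map A [score_map] or numeric matrix.
#' @param path Output TIFF path.
#' @export
save_scoremap <- function(map, path) {
  v <- if (inherits(map, "score_map")) map$values else map
  assert_raster(v, "score map")
  tiff::writeTIFF(v, path, bits.per.sample = 32L)
  invisible(path)
}

# ---- resampling -------------------------------------------------------------

# Bilinear interpolation weight matrix mapping n_in samples to n_out samples,
# aligned on pixel centers (output center i maps to input coordinate
# (i - 0.5) * n_in / n_out + 0.5, clamped). For n_in == n_out this is the
# identity, so resampling at the native size is exact.
bilinear_weights <- function(n_in, n_out) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  pos <- pmin(pmax(pos, 1), n_in)
  lo <- pmin(floor(pos), n_in - ifelse(n_in > 1, 1, 0))
  frac <- pos - lo
  w <- matrix(0, n_out, n_in)
  idx <- cbind(seq_len(n_out), lo)
  w[idx] <- w[idx] + (1 - frac)
  idx2 <- cbind(seq_len(n_out), pmin(lo + 1, n_in))
  w[idx2] <- w[idx2] + frac
  w
}

resize_bilinear <- function(image, out_h, out_w) {
  assert_raster(image)
  wr <- bilinear_weights(nrow2(image), out_h)
  wc <- bilinear_weights(ncol2(image), out_w)
  if (n_channels(image) == 1L) {
    wr %*% image %*% t(wc)
  } else {
    out <- array(0, c(out_h, out_w, dim(image)[3]))
    for (c in seq_len(dim(image)[3])) out[, , c] <- wr %*% image[, , c] %*% t(wc)
    out
  }
}

resize_nearest <- function(image, out_h, out_w) {
  assert_raster(image)
  ri <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * nrow2(image) / out_h), 1L), nrow2(image))
  ci <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * ncol2(image) / out_w), 1L), ncol2(image))
  if (n_channels(image) == 1L) image[ri, ci, drop = FALSE] else image[ri, ci, , drop = FALSE]
}

nrow2 <- function(x) dim(x)[1]
ncol2 <- function(x) dim(x)[2]

# Separable Gaussian blur with replicate or cyclic padding. Kernel radius
# ceiling(3 * sigma); the kernel is normalized to sum 1, so cyclic padding
# conserves total mass exactly.
gaussian_blur <- function(m, sigma, pad = c("replicate", "cyclic")) {
  pad <- match.arg(pad)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(m)
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_axis <- function(x, along_rows) {
    n <- if (along_rows) nrow(x) else ncol(x)
    out <- 0 * x
    for (t in seq(-r, r)) {
      idx <- seq_len(n) + t
      idx <- if (pad == "cyclic") ((idx - 1) %% n) + 1 else pmin(pmax(idx, 1L), n)
      out <- out + k[t + r + 1] * (if (along_rows) x[idx, , drop = FALSE] else x[, idx, drop = FALSE])
    }
    out
  }
  blur_axis(blur_axis(m, TRUE), FALSE)
}

# min-max rescale to [0, 1]; a constant map rescales to all zeros
rescale01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

# row-major argmax/argmin of a matrix, returned as 0-based (row, col)
argmax_rowmajor <- function(m, decreasing = TRUE) {
  v <- as.vector(t(m))
  i <- if (decreasing) which.max(v) else which.min(v)
  c(row = (i - 1L) %/% ncol(m), col = (i - 1L) %% ncol(m))
}

# run code under a temporary RNG state derived from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# ---- score maps -------------------------------------------------------------

#' Construct a score map
#'
#' A score map is a non-negative per-pixel raster tagged with its role in the
#' pipeline: the anomaly map A(I), the domain filter F(I), or the surgical
#' instrument map SI(I) = A(I) * F(I).
#'
#' @param values Numeric H x W matrix, finite and non-negative.
#' @param kind One of `"anomaly"`, `"filter"`, `"si"`.
#' @param normalized Logical; if `TRUE`, values must lie in \[0, 1\].
#' @return An object of class `score_map` (a list with `values`, `kind`,
#'   `normalized`).
#' @export
score_map <- function(values, kind = c("anomaly", "filter", "si"), normalized = FALSE) {
  kind <- match.arg(kind)
  assert_raster(values, "score map values")
  if (n_channels(values) != 1L) stop("score map must be single-channel")
  if (any(values < 0)) stop("score map values must be non-negative")
  if (normalized && any(values > 1 + 1e-12)) stop("normalized score map must lie in [0,1]")
  structure(list(values = values, kind = kind, normalized = normalized),
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("<score_map kind=%s %dx%d range=[%.4g, %.4g]%s>\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values),
              if (x$normalized) " normalized" else ""))
  invisible(x)
}

#' @export
plot.score_map <- function(x, ...) {
  v <- x$values
  graphics::image(t(v)[, nrow(v):1, drop = FALSE], asp = nrow(v) / ncol(v),
                  axes = FALSE, useRaster = TRUE, ...)
  invisible(x)
}
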