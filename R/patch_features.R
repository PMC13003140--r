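# ---- patch features ---------------------------------------------------------
#
# The pipeline never sees raw pixels: every image is reduced to a spatial grid
# of locally aggregated patch-feature vectors. The default extractor is a
# deterministic multi-scale descriptor (per-cell mean, standard deviation and
# a gradient-orientation histogram, per channel and per scale) and needs no
# pretrained weights; any callable mapping image -> grid can be registered
# under a name so that a CNN backbone can stand in the same slot.

.extractor_registry <- new.env(parent = emptyenv())

#' Register a custom patch-feature extractor
#'
#' @param name Extractor name referenced by [feature_spec()].
#' @param fun A function `(image, spec) -> PatchFeatureGrid` (see
#'   [extract_features()] for the grid contract).
#' @export
register_extractor <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .extractor_registry)
  invisible(name)
}

#' Specify a patch-feature extractor
#'
#' @param name Extractor name; `"multiscale_stats"` is built in.
#' @param scales Integer downsampling factors (each >= 1); the descriptor is
#'   computed on an s x s box-filtered copy of the image for each scale and
#'   concatenated.
#' @param window Odd neighborhood size, in grid cells, used by
#'   [aggregate_neighborhood()].
#' @param stride Pixels per feature-grid cell.
#' @param params Free-form extractor parameters. For the built-in extractor:
#'   `bins` (gradient-orientation bins, 0 disables the histogram; default 8).
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(name = "multiscale_stats", scales = c(1L, 2L),
                         window = 3L, stride = 4L, params = list(bins = 8L)) {
  scales <- as.integer(scales)
  window <- as.integer(window)
  stride <- as.integer(stride)
  if (length(scales) == 0L || any(scales < 1L)) stop("scales must be non-empty, each >= 1")
  if (window < 1L || window %% 2L == 0L) stop("window must be an odd integer >= 1")
  if (stride < 1L) stop("stride must be >= 1")
  structure(list(name = name, scales = scales, window = window,
                 stride = stride, params = params),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec %s scales={%s} window=%d stride=%d>\n",
              x$name, paste(x$scales, collapse = ","), x$window, x$stride))
  invisible(x)
}

# per-cell ids for an H x W image with given stride (column-major cell grid)
cell_index <- function(h, w, stride) {
  hg <- ceiling(h / stride)
  ci <- ceiling(seq_len(h) / stride)          # cell row per pixel row
  cj <- ceiling(seq_len(w) / stride)          # cell col per pixel col
  list(hg = hg, wg = ceiling(w / stride),
       id = outer(ci, cj, function(a, b) (b - 1L) * hg + a))
}

# sum of v per cell id (v an H x W matrix), returned as hg x wg matrix
cell_sum <- function(v, idx) {
  s <- rowsum(as.vector(v), as.vector(idx$id))
  out <- numeric(idx$hg * idx$wg)
  out[as.integer(rownames(s))] <- s
  matrix(out, idx$hg, idx$wg)
}

# s x s block mean, replicated back to the original resolution
box_downsample <- function(m, s) {
  if (s == 1L) return(m)
  idx <- cell_index(nrow(m), ncol(m), s)
  cnt <- cell_sum(matrix(1, nrow(m), ncol(m)), idx)
  mu <- cell_sum(m, idx) / cnt
  ri <- ceiling(seq_len(nrow(m)) / s)
  ci <- ceiling(seq_len(ncol(m)) / s)
  mu[ri, ci, drop = FALSE]
}

multiscale_stats_extractor <- function(image, spec) {
  h <- nrow2(image); w <- ncol2(image)
  stride <- spec$stride
  bins <- spec$params$bins %||% 8L
  idx <- cell_index(h, w, stride)
  cnt <- cell_sum(matrix(1, h, w), idx)
  channels <- if (n_channels(image) == 1L) list(image) else
    lapply(seq_len(dim(image)[3]), function(c) image[, , c])
  feats <- list()
  for (s in spec$scales) {
    for (ch in channels) {
      v <- box_downsample(ch, s)
      mu <- cell_sum(v, idx) / cnt
      ex2 <- cell_sum(v * v, idx) / cnt
      sdv <- sqrt(pmax(ex2 - mu^2, 0))
      feats <- c(feats, list(mu, sdv))
      if (bins > 0L) {
        # central differences with replicate edges on the scale-s image
        gx <- (v[, pmin(seq_len(w) + 1L, w), drop = FALSE] -
               v[, pmax(seq_len(w) - 1L, 1L), drop = FALSE]) / 2
        gy <- (v[pmin(seq_len(h) + 1L, h), , drop = FALSE] -
               v[pmax(seq_len(h) - 1L, 1L), , drop = FALSE]) / 2
        mag <- sqrt(gx^2 + gy^2)
        ang <- atan2(gy, gx) %% (2 * pi)
        bin <- pmin(floor(ang / (2 * pi / bins)), bins - 1)
        for (b in 0:(bins - 1L)) {
          feats <- c(feats, list(cell_sum(mag * (bin == b), idx) / cnt))
        }
      }
    }
  }
  arr <- array(unlist(feats, use.names = FALSE), c(idx$hg, idx$wg, length(feats)))
  patch_grid(arr, stride, c(h, w))
}

patch_grid <- function(features, stride, source_shape) {
  structure(list(features = features, stride = as.integer(stride),
                 source_shape = as.integer(source_shape)),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<patch_grid %dx%d cells, D=%d, stride=%d, source=%dx%d>\n",
              d[1], d[2], d[3], x$stride, x$source_shape[1], x$source_shape[2]))
  invisible(x)
}

#' Extract a grid of patch-feature vectors from an image
#'
#' The grid has `ceiling(H / stride)` x `ceiling(W / stride)` cells; each cell
#' carries a D-dimensional descriptor of its stride x stride pixel block.
#' Extraction is deterministic: identical inputs give bit-identical grids.
#'
#' @param image Raster (matrix or H x W x 3 array), finite values.
#' @param spec A [feature_spec()].
#' @return A `patch_grid`: list with `features` (H' x W' x D array), `stride`
#'   and `source_shape`.
#' @export
extract_features <- function(image, spec = feature_spec()) {
  assert_raster(image)
  stopifnot(inherits(spec, "feature_spec"))
  if (identical(spec$name, "multiscale_stats")) {
    multiscale_stats_extractor(image, spec)
  } else if (exists(spec$name, envir = .extractor_registry, inherits = FALSE)) {
    fn <- get(spec$name, envir = .extractor_registry)
    out <- fn(image, spec)
    stopifnot(inherits(out, "patch_grid"))
    out
  } else {
    stop("unknown extractor: '", spec$name, "'")
  }
}

#' Average each feature vector over its grid neighborhood
#'
#' PatchCore-style local pooling: every cell is replaced by the mean of the
#' `window` x `window` cells around it, so each patch feature summarizes its
#' neighborhood. In `"valid"` mode edge cells average over the truncated
#' sub-window; `"cyclic"` mode wraps around (which preserves the per-feature
#' global mean exactly).
#'
#' @param grid A `patch_grid`.
#' @param window Odd integer >= 1.
#' @param mode `"valid"` (default) or `"cyclic"` edge handling.
#' @return A `patch_grid` of the same shape.
#' @export
aggregate_neighborhood <- function(grid, window = 3L,
                                   mode = c("valid", "cyclic")) {
  stopifnot(inherits(grid, "patch_grid"))
  mode <- match.arg(mode)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be an odd integer >= 1")
  if (window == 1L) return(grid)
  r <- (window - 1L) %/% 2L
  d <- dim(grid$features)
  hg <- d[1]; wg <- d[2]
  out <- array(0, d)
  acc_cnt <- matrix(0, hg, wg)
  shifts <- expand.grid(dr = -r:r, dc = -r:r)
  # accumulate shifted copies; in valid mode out-of-range shifts contribute
  # nothing and the count matrix normalizes per-cell
  acc <- array(0, d)
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    ri <- seq_len(hg) + dr; ci <- seq_len(wg) + dc
    if (mode == "cyclic") {
      ri <- ((ri - 1L) %% hg) + 1L; ci <- ((ci - 1L) %% wg) + 1L
      acc <- acc + grid$features[ri, ci, , drop = FALSE]
      acc_cnt <- acc_cnt + 1
    } else {
      ok_r <- ri >= 1L & ri <= hg; ok_c <- ci >= 1L & ci <= wg
      if (!any(ok_r) || !any(ok_c)) next
      acc[ok_r, ok_c, ] <- acc[ok_r, ok_c, , drop = FALSE] +
        grid$features[ri[ok_r], ci[ok_c], , drop = FALSE]
      acc_cnt[ok_r, ok_c] <- acc_cnt[ok_r, ok_c] + 1
    }
  }
  for (f in seq_len(d[3])) out[, , f] <- acc[, , f] / acc_cnt
  patch_grid(out, grid$stride, grid$source_shape)
}

# flatten a patch grid to an (H'*W') x D matrix, cells in column-major order
grid_matrix <- function(grid) {
  d <- dim(grid$features)
  matrix(grid$features, d[1] * d[2], d[3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
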