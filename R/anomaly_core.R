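# ---- memory bank & anomaly scoring ------------------------------------------
#
# "Segmenting anything new": nominal images (no instrument present) define
# normal anatomy through their pooled patch features. A greedy k-center
# coreset keeps a representative fraction of them; at inference each query
# patch is scored by its distance to the nearest bank vector, and the score
# grid is upsampled and smoothed into the per-pixel anomaly map A(I).

#' Greedy k-center coreset subsampling
#'
#' Selects `max(1, round(ratio * M))` rows by farthest-point traversal: the
#' start row is a seeded uniform draw (or `start` if given) and every further
#' pick is the row with the largest Euclidean distance to the rows already
#' selected — the classical minimax facility-location greedy.
#'
#' @param features M x D numeric matrix.
#' @param ratio Sampling fraction in (0, 1].
#' @param seed Integer seed for the start draw.
#' @param start Optional fixed 1-based start index (overrides the seeded draw).
#' @return Integer vector of selected row indices (distinct).
#' @export
coreset_select <- function(features, ratio, seed = 0L, start = NULL) {
  features <- as.matrix(features)
  m <- nrow(features)
  if (m < 1L) stop("no features to subsample")
  if (!is.numeric(ratio) || ratio <= 0) stop("ratio must be positive")
  if (ratio > 1) stop("ratio must be <= 1")
  n_sel <- max(1L, as.integer(round(ratio * m)))
  if (is.null(start)) start <- with_seed(seed, sample.int(m, 1L))
  greedy_coreset_cpp(features, n_sel, as.integer(start))
}

#' Build a memory bank of nominal patch features
#'
#' Extracts and neighborhood-aggregates patch features from every nominal
#' (instrument-free) image, pools them, and keeps a greedy k-center coreset.
#' Score normalization bounds are unset until [calibrate_normalization()] is
#' run.
#'
#' @param nominal_images List of rasters without instruments.
#' @param spec A [feature_spec()].
#' @param ratio Coreset sampling ratio in (0, 1]; default 0.1.
#' @param seed Integer seed (coreset start draw); recorded in the bank.
#' @return An object of class `memory_bank`.
#' @export
build_memory_bank <- function(nominal_images, spec = feature_spec(),
                              ratio = 0.1, seed = 0L) {
  if (!is.list(nominal_images) || length(nominal_images) == 0L)
    stop("no nominal data")
  mats <- lapply(nominal_images, function(img) {
    g <- aggregate_neighborhood(extract_features(img, spec), spec$window)
    grid_matrix(g)
  })
  pooled <- do.call(rbind, mats)
  keep <- coreset_select(pooled, ratio, seed = seed)
  structure(list(vectors = pooled[keep, , drop = FALSE],
                 spec = spec, coreset_ratio = ratio,
                 norm_lo = NA_real_, norm_hi = NA_real_,
                 seed = as.integer(seed)),
            class = "memory_bank")
}

#' @export
print.memory_bank <- function(x, ...) {
  cat(sprintf("<memory_bank N=%d D=%d ratio=%.3g%s>\n",
              nrow(x$vectors), ncol(x$vectors), x$coreset_ratio,
              if (is.finite(x$norm_lo)) sprintf(" calib=[%.4g, %.4g]", x$norm_lo, x$norm_hi)
              else " (uncalibrated)"))
  invisible(x)
}

bank_calibrated <- function(bank) is.finite(bank$norm_lo) && is.finite(bank$norm_hi)

#' Score query patches against a memory bank
#'
#' Per-cell anomaly score: Euclidean distance to the nearest bank vector
#' (`k = 1`, the default). With `k > 1` the score is the mean distance to the
#' k nearest bank vectors, an optional smoothing of the pixel score.
#'
#' @param bank A `memory_bank`.
#' @param grid A `patch_grid` (already neighborhood-aggregated).
#' @param k Number of nearest neighbors; default 1.
#' @return H' x W' numeric score grid.
#' @export
score_patches <- function(bank, grid, k = 1L) {
  stopifnot(inherits(bank, "memory_bank"), inherits(grid, "patch_grid"))
  q <- grid_matrix(grid)
  if (ncol(q) != ncol(bank$vectors))
    stop("feature dimension mismatch between bank and query grid")
  d <- dim(grid$features)
  matrix(nn_scores_cpp(q, bank$vectors, as.integer(k)), d[1], d[2])
}

#' Turn a patch score grid into a per-pixel anomaly map
#'
#' Bilinear upsampling of the coarse score grid to the source image shape
#' followed by Gaussian smoothing. With `stride = 1` and `sigma = 0` the map
#' equals the score grid.
#'
#' @param score_grid H' x W' numeric matrix from [score_patches()].
#' @param source_shape `(H, W)` of the source image in pixels.
#' @param stride Pixels per grid cell.
#' @param smoothing_sigma Gaussian sigma in pixels (>= 0); default 4.
#' @param pad Blur padding, `"replicate"` (default) or `"cyclic"`.
#' @return A [score_map] of kind `"anomaly"` (unnormalized).
#' @export
anomaly_map <- function(score_grid, source_shape, stride,
                        smoothing_sigma = 4, pad = "replicate") {
  if (smoothing_sigma < 0) stop("sigma must be >= 0")
  up <- resize_bilinear(score_grid, source_shape[1], source_shape[2])
  sm <- gaussian_blur(up, smoothing_sigma, pad)
  score_map(pmax(sm, 0), kind = "anomaly", normalized = FALSE)
}

# raw (unnormalized) anomaly map for one image under bank settings
raw_anomaly <- function(bank, image, smoothing_sigma = 4, k = 1L) {
  g <- aggregate_neighborhood(extract_features(image, bank$spec), bank$spec$window)
  s <- score_patches(bank, g, k = k)
  anomaly_map(s, g$source_shape, g$stride, smoothing_sigma)
}

#' Calibrate score normalization from example images
#'
#' The raw nearest-neighbor distances have no canonical scale, but the fixed
#' prompt-binarization thresholds assume scores in \[0, 1\]. Calibration runs
#' the bank on a small set of example images (typically a few frames that do
#' contain instruments) and records the min/max raw anomaly value observed;
#' [normalize_map()] maps that range to \[0, 1\].
#'
#' @param bank A `memory_bank`.
#' @param calibration_images List of rasters.
#' @param smoothing_sigma Sigma used for the anomaly maps (match the pipeline
#'   setting).
#' @param k Neighbor count, as in [score_patches()].
#' @return The bank with `norm_lo`/`norm_hi` set (`norm_hi` widened by 1e-8
#'   if the observed range is degenerate).
#' @export
calibrate_normalization <- function(bank, calibration_images,
                                    smoothing_sigma = 4, k = 1L) {
  stopifnot(inherits(bank, "memory_bank"))
  if (!is.list(calibration_images) || length(calibration_images) == 0L)
    stop("need at least one calibration image")
  rng <- range(vapply(calibration_images, function(img)
    range(raw_anomaly(bank, img, smoothing_sigma, k)$values),
    numeric(2)))
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1e-8
  bank$norm_lo <- rng[1]
  bank$norm_hi <- rng[2]
  bank
}

#' Normalize an anomaly map with a calibrated bank
#'
#' Affine map `(v - norm_lo) / (norm_hi - norm_lo)`, clipped to \[0, 1\].
#'
#' @param map A [score_map].
#' @param bank A calibrated `memory_bank`.
#' @return A normalized [score_map] of the same kind.
#' @export
normalize_map <- function(map, bank) {
  stopifnot(inherits(map, "score_map"), inherits(bank, "memory_bank"))
  if (!bank_calibrated(bank)) stop("bank is not calibrated")
  v <- (map$values - bank$norm_lo) / (bank$norm_hi - bank$norm_lo)
  score_map(pmin(pmax(v, 0), 1), kind = map$kind, normalized = TRUE)
}

#' Save / load a memory bank archive
#'
#' @param bank A `memory_bank`.
#' @param path Archive path (single file).
#' @export
save_bank <- function(bank, path) {
  stopifnot(inherits(bank, "memory_bank"))
  saveRDS(bank, path)
  invisible(path)
}

#' @rdname save_bank
#' @export
load_bank <- function(path) {
  if (!file.exists(path)) stop("bank file not found: ", path)
  bank <- readRDS(path)
  if (!inherits(bank, "memory_bank")) stop("not a memory bank archive")
  bank
}
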