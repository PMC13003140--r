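# ---- domain filters and the SI map ------------------------------------------
#
# The anomaly map marks everything unseen, including shadows, reflections and
# unusual anatomy. A cheap domain prior narrows it to instrument-like pixels:
# in true-color scenes instruments are (dark) gray while tissue is red, so
# redness (CIELAB a*), brightness (HSV V) and saturation (HSV S) are
# down-weighted; in intensity modalities (OCT, ultrasound) instrument shadows
# are near-black, so the raw signal itself is the prior. The surgical
# instrument map is the pixel-wise product SI(I) = A(I) * F(I).

#' Decompose an RGB image into a*, value and saturation channels
#'
#' Input values are treated as nonlinear sRGB (D65); 8-bit ranges are
#' auto-scaled to \[0, 1\]. a* comes from the sRGB -> CIELAB conversion, V and
#' S from RGB -> HSV.
#'
#' @param image H x W x 3 raster.
#' @return An object of class `color_channels`: list with `astar`, `value`,
#'   `saturation` matrices (V, S in \[0, 1\]; a* may be negative).
#' @export
rgb_to_channels <- function(image) {
  assert_raster(image)
  if (n_channels(image) != 3L) stop("rgb_to_channels needs a 3-channel image")
  if (max(image) > 1) image <- image / 255
  h <- nrow2(image); w <- ncol2(image)
  flat <- matrix(image, h * w, 3)
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  hsv <- grDevices::rgb2hsv(t(flat), maxColorValue = 1)
  structure(list(astar = matrix(lab[, 2], h, w),
                 value = matrix(hsv[3, ], h, w),
                 saturation = matrix(hsv[2, ], h, w)),
            class = "color_channels")
}

#' True-color instrument filter
#'
#' Per pixel, `F = 1 - (a*/max(a*) + V/max(V) + S/max(S)) / 3`, clipped to
#' \[0, 1\]. Each term is normalized by its per-image maximum; a term whose
#' maximum is not positive contributes 0 (for a*, the maximum is taken over
#' pixels with a* > 0, since a negative maximum makes the ratio meaningless).
#' High values mark dark, achromatic, non-red pixels — the typical appearance
#' of metallic instruments against perfused tissue.
#'
#' @param image H x W x 3 raster.
#' @return A normalized [score_map] of kind `"filter"`.
#' @export
filter_rgb <- function(image) {
  ch <- rgb_to_channels(image)
  term <- function(v, mx) if (mx > 0) v / mx else v * 0
  max_a <- {
    pos <- ch$astar[ch$astar > 0]
    if (length(pos)) max(pos) else 0
  }
  f <- 1 - (term(ch$astar, max_a) + term(ch$value, max(ch$value)) +
              term(ch$saturation, max(ch$saturation))) / 3
  score_map(pmin(pmax(f, 0), 1), kind = "filter", normalized = TRUE)
}

#' Intensity-signal instrument filter
#'
#' `F = I / max(I)` with intensities normalized to \[0, 1\]. Zero-signal
#' pixels — in particular the shadow columns instruments cast in OCT and
#' ultrasound B-scans — get filter value exactly 0, so no prompt can land in a
#' shadow. An all-zero image yields an all-zero filter (declared degenerate
#' rule). Negative offsets are removed before normalization.
#'
#' @param image Single-channel raster.
#' @return A normalized [score_map] of kind `"filter"`.
#' @export
filter_intensity <- function(image) {
  assert_raster(image)
  if (n_channels(image) != 1L) stop("filter_intensity needs a single-channel image")
  v <- image
  mn <- min(v)
  if (mn < 0) v <- v - mn
  mx <- max(v)
  f <- if (mx > 0) v / mx else v * 0
  score_map(f, kind = "filter", normalized = TRUE)
}

#' Surgical-instrument score map
#'
#' Pixel-wise product `SI(I) = A(I) * F(I)` of the normalized anomaly map and
#' the domain filter. Since F is in \[0, 1\], SI never exceeds the anomaly
#' score and is annihilated wherever the filter is 0.
#'
#' @param anomaly Normalized [score_map] of kind `"anomaly"`.
#' @param filter [score_map] of kind `"filter"`.
#' @return A normalized [score_map] of kind `"si"`.
#' @export
si_map <- function(anomaly, filter) {
  stopifnot(inherits(anomaly, "score_map"), inherits(filter, "score_map"))
  if (!identical(dim(anomaly$values), dim(filter$values)))
    stop("anomaly and filter shapes differ")
  if (!anomaly$normalized) stop("anomaly map must be normalized before filtering")
  score_map(anomaly$values * filter$values, kind = "si", normalized = TRUE)
}
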