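# ---- point-prompt generation ------------------------------------------------
#
# The SI map is reduced to a handful of pixel coordinates for the promptable
# segmenter: binarize at a size-derived threshold, label connected
# components, and take each component's SI-argmax pixel as a positive prompt.
# All coordinates are (row, col), 0-based, origin top-left.

#' Binarize an SI map
#'
#' Pixel is foreground iff `si >= threshold`. The map must be normalized to
#' \[0, 1\]; the threshold reflects the expected instrument fraction of the
#' image (0.65 when instruments cover about 35% of the frame, 0.85 for about
#' 15%).
#'
#' @param si Normalized [score_map].
#' @param threshold Fraction strictly between 0 and 1.
#' @return Logical H x W matrix.
#' @export
binarize_si <- function(si, threshold) {
  stopifnot(inherits(si, "score_map"))
  if (!si$normalized) stop("si map must be normalized")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  si$values >= threshold
}

#' Label connected components of a binary mask
#'
#' @param binary Logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return List with `labels` (integer matrix, 0 = background) and `count`.
#' @export
connected_components <- function(binary, connectivity = 8L) {
  if (!is.logical(binary)) binary <- binary > 0
  lab <- label_components_cpp(binary, as.integer(connectivity))
  list(labels = lab, count = max(lab))
}

empty_prompt_set <- function(threshold, labels, no_instrument = FALSE) {
  structure(list(positives = matrix(integer(), 0L, 2L,
                                    dimnames = list(NULL, c("row", "col"))),
                 negative = NULL, threshold = threshold,
                 component_labels = labels,
                 no_instrument = no_instrument, fallback = FALSE),
            class = "prompt_set")
}

#' @export
print.prompt_set <- function(x, ...) {
  cat(sprintf("<prompt_set %d positive%s%s threshold=%.2f%s>\n",
              nrow(x$positives), if (nrow(x$positives) == 1L) "" else "s",
              if (!is.null(x$negative)) " +1 negative" else "",
              x$threshold,
              if (x$no_instrument) " [no instrument]" else if (x$fallback) " [fallback]" else ""))
  invisible(x)
}

#' Select point prompts from an SI map
#'
#' The SI map is min-max rescaled per image (so the fixed thresholds are
#' meaningful on every frame), binarized, and labeled. With `multi = FALSE` a
#' single prompt is placed at the global SI argmax; with `multi = TRUE` one
#' prompt is placed per connected component, at the component's SI-argmax
#' pixel. Ties resolve to the first pixel in row-major order. If no pixel
#' clears the threshold the single global argmax is used as fallback; an
#' all-zero SI map yields an empty prompt set flagged `no_instrument`.
#'
#' @param si Normalized [score_map] of kind `"si"`.
#' @param threshold Binarization threshold in (0, 1); default 0.65.
#' @param multi Place one prompt per component (default `TRUE`).
#' @param connectivity Component connectivity, 4 or 8.
#' @param rescale Min-max rescale SI per image before thresholding (default
#'   `TRUE`).
#' @return An object of class `prompt_set`: 0-based `positives` (n x 2
#'   matrix), optional `negative`, `threshold`, `component_labels`, and flags
#'   `no_instrument` / `fallback`.
#' @export
select_prompts <- function(si, threshold = 0.65, multi = TRUE,
                           connectivity = 8L, rescale = TRUE) {
  stopifnot(inherits(si, "score_map"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  v <- si$values
  zero_labels <- matrix(0L, nrow(v), ncol(v))
  if (all(v == 0))
    return(empty_prompt_set(threshold, zero_labels, no_instrument = TRUE))
  vn <- if (rescale) rescale01(v) else v
  if (all(vn == 0)) {
    # constant nonzero map: no structure survives rescaling; fall back to the
    # (tied) global argmax under the row-major rule
    ps <- empty_prompt_set(threshold, zero_labels)
    ps$positives <- matrix(argmax_rowmajor(v), 1L,
                           dimnames = list(NULL, c("row", "col")))
    ps$fallback <- TRUE
    return(ps)
  }
  if (!multi) {
    p <- argmax_rowmajor(vn)
    ps <- empty_prompt_set(threshold, zero_labels)
    ps$positives <- matrix(p, 1L, dimnames = list(NULL, c("row", "col")))
    return(ps)
  }
  mask <- vn >= threshold
  if (!any(mask)) {
    p <- argmax_rowmajor(vn)
    ps <- empty_prompt_set(threshold, zero_labels)
    ps$positives <- matrix(p, 1L, dimnames = list(NULL, c("row", "col")))
    ps$fallback <- TRUE
    return(ps)
  }
  cc <- connected_components(mask, connectivity)
  pts <- matrix(NA_integer_, cc$count, 2L,
                dimnames = list(NULL, c("row", "col")))
  for (lbl in seq_len(cc$count)) {
    masked <- vn
    masked[cc$labels != lbl] <- -Inf
    pts[lbl, ] <- argmax_rowmajor(masked)
  }
  ps <- empty_prompt_set(threshold, cc$labels)
  ps$positives <- pts
  ps
}

#' Select a negative prompt in the central image area
#'
#' Returns the SI-argmin pixel inside the centered window covering
#' `central_fraction` of each dimension (row-major tie-break). Used in
#' domains where the segmenter tends to grab the whole frame (e.g. ultrasound
#' scans with information borders): a background point with the lowest
#' instrument score anchors what the mask must exclude.
#'
#' @param si Normalized [score_map].
#' @param central_fraction Fraction of each dimension (0, 1\]; default 0.5.
#' @return 0-based `(row, col)` integer vector.
#' @export
select_negative_prompt <- function(si, central_fraction = 0.5) {
  stopifnot(inherits(si, "score_map"))
  if (central_fraction <= 0 || central_fraction > 1)
    stop("central_fraction must lie in (0, 1]")
  v <- si$values
  h <- nrow(v); w <- ncol(v)
  hh <- max(1L, floor(h * central_fraction))
  ww <- max(1L, floor(w * central_fraction))
  r0 <- (h - hh) %/% 2L
  c0 <- (w - ww) %/% 2L
  win <- v[(r0 + 1L):(r0 + hh), (c0 + 1L):(c0 + ww), drop = FALSE]
  p <- argmax_rowmajor(win, decreasing = FALSE)
  c(row = unname(p["row"]) + r0, col = unname(p["col"]) + c0)
}
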