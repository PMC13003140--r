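# ---- mask proposals and selection -------------------------------------------
#
# The promptable-segmenter contract: given an image and a prompt set, a
# backend returns exactly three candidate binary masks with its own
# confidence scores. The reference backend grows regions around each positive
# prompt at three increasing intensity tolerances (so M1 <= M2 <= M3); an
# external promptable segmenter can be registered under a name and used
# through the same contract. The final mask is the proposal with the highest
# SAM4SIS score — its IoU against the binarized SI map.

.backend_registry <- new.env(parent = emptyenv())

#' Register a mask-proposal backend
#'
#' @param name Backend name used by [propose_masks()].
#' @param fun A function `(image, prompts, params) -> mask_proposals`.
#' @export
register_backend <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .backend_registry)
  invisible(name)
}

mask_proposals <- function(masks, confidences, prompts, no_instrument = FALSE) {
  stopifnot(length(masks) == 3L, length(confidences) == 3L)
  structure(list(masks = masks, confidences = as.numeric(confidences),
                 prompts = prompts, no_instrument = no_instrument),
            class = "mask_proposals")
}

#' @export
print.mask_proposals <- function(x, ...) {
  cat(sprintf("<mask_proposals areas={%s} conf={%s}%s>\n",
              paste(vapply(x$masks, sum, numeric(1)), collapse = ","),
              paste(sprintf("%.2f", x$confidences), collapse = ","),
              if (x$no_instrument) " [no instrument]" else ""))
  invisible(x)
}

#' Reference backend: seeded region growing at three tolerances
#'
#' Proposal i is the union, over all positive prompts, of the 4-connected
#' region whose pixel values stay within `tolerances[i]` of the prompt's
#' value (Euclidean over channels for color images), minus any region
#' connected to the negative prompt at the same tolerance (positive prompt
#' pixels are always retained). Tolerances must be strictly increasing, so
#' the proposals are nested M1 <= M2 <= M3. Backend confidences are
#' `1 / (1 + tolerance)`, min-max rescaled to \[0, 1\] (tightest proposal
#' most confident).
#'
#' @param image Raster.
#' @param prompts A `prompt_set` with at least one positive prompt.
#' @param tolerances Three strictly increasing non-negative reals; default
#'   `{1, 2, 4} * base_tol * value range` of the image.
#' @param base_tol Base tolerance as a fraction of the image value range;
#'   default 0.08.
#' @return A `mask_proposals` object.
#' @export
region_grow_backend <- function(image, prompts, tolerances = NULL,
                                base_tol = 0.08) {
  assert_raster(image)
  stopifnot(inherits(prompts, "prompt_set"))
  if (nrow(prompts$positives) < 1L) stop("need at least one positive prompt")
  rng <- diff(range(image))
  if (is.null(tolerances)) tolerances <- c(1, 2, 4) * base_tol * rng
  if (length(tolerances) != 3L || any(diff(tolerances) <= 0))
    stop("tolerances must be three strictly increasing values")
  h <- nrow2(image); w <- ncol2(image); nc <- n_channels(image)
  flat <- as.numeric(image)
  grow <- function(pt, tol)
    region_grow_cpp(flat, h, w, nc, pt[1], pt[2], tol)
  masks <- lapply(tolerances, function(tol) {
    m <- matrix(FALSE, h, w)
    for (i in seq_len(nrow(prompts$positives)))
      m <- m | grow(prompts$positives[i, ], tol)
    if (!is.null(prompts$negative)) {
      m <- m & !grow(prompts$negative, tol)
      # contract: every positive prompt pixel is inside every proposal
      m[prompts$positives + 1L] <- TRUE
    }
    m
  })
  conf <- 1 / (1 + tolerances)
  conf <- (conf - min(conf)) / (max(conf) - min(conf))
  mask_proposals(masks, conf, prompts)
}

#' Propose three candidate masks for a prompt set
#'
#' Dispatches to the named backend (`"region_grow"` is built in; others via
#' [register_backend()]). An empty prompt set short-circuits to three empty
#' masks flagged `no_instrument`.
#'
#' @param image Raster.
#' @param prompts A `prompt_set`.
#' @param backend Backend name.
#' @param params List of backend parameters (for the reference backend:
#'   `tolerances`, `base_tol`).
#' @return A `mask_proposals` object.
#' @export
propose_masks <- function(image, prompts, backend = "region_grow",
                          params = list()) {
  assert_raster(image)
  stopifnot(inherits(prompts, "prompt_set"))
  if (nrow(prompts$positives) == 0L) {
    empty <- matrix(FALSE, nrow2(image), ncol2(image))
    return(mask_proposals(list(empty, empty, empty), c(0, 0, 0), prompts,
                          no_instrument = TRUE))
  }
  if (identical(backend, "region_grow")) {
    do.call(region_grow_backend, c(list(image = image, prompts = prompts), params))
  } else if (exists(backend, envir = .backend_registry, inherits = FALSE)) {
    out <- do.call(get(backend, envir = .backend_registry),
                   list(image, prompts, params))
    stopifnot(inherits(out, "mask_proposals"))
    out
  } else {
    stop("unknown backend: '", backend, "'")
  }
}

#' SAM4SIS score of a candidate mask
#'
#' IoU between a proposed mask and the binarized SI map. If both are empty
#' the score is 0 (an empty proposal never wins by vacuity; contrast the
#' evaluation convention in [iou()]).
#'
#' @param mask,si_bin Logical matrices of the same shape.
#' @return Score in \[0, 1\].
#' @export
sam4sis_score <- function(mask, si_bin) {
  if (!identical(dim(mask), dim(si_bin))) stop("shape mismatch")
  inter <- sum(mask & si_bin)
  uni <- sum(mask | si_bin)
  if (uni == 0) 0 else inter / uni
}

#' Select the final mask by SAM4SIS score
#'
#' Scores each of the three proposals against the binarized SI map and keeps
#' the argmax; ties break by higher backend confidence, then lower proposal
#' index.
#'
#' @param proposals A `mask_proposals` object.
#' @param si_bin Logical SI support mask (same shape as the proposals).
#' @return An object of class `segmentation_result`: `mask`,
#'   `selected_index` (1..3), `sam4sis_scores`, `confidences`, `prompts`,
#'   `no_instrument`.
#' @export
select_mask <- function(proposals, si_bin) {
  stopifnot(inherits(proposals, "mask_proposals"))
  scores <- vapply(proposals$masks, sam4sis_score, numeric(1), si_bin = si_bin)
  ord <- order(-scores, -proposals$confidences, seq_along(scores))
  best <- ord[1]
  structure(list(mask = proposals$masks[[best]],
                 selected_index = best,
                 sam4sis_scores = scores,
                 confidences = proposals$confidences,
                 prompts = proposals$prompts,
                 no_instrument = proposals$no_instrument),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result selected=%d scores={%s} area=%d%s>\n",
              x$selected_index,
              paste(sprintf("%.3f", x$sam4sis_scores), collapse = ","),
              sum(x$mask),
              if (x$no_instrument) " [no instrument]" else ""))
  invisible(x)
}
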