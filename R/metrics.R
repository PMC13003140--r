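# ---- evaluation metrics -----------------------------------------------------
#
# Overlap metrics (IoU, DICE) plus the boundary-based normalized surface
# distance, which credits predictions whose boundary stays within a tolerance
# tau of the reference boundary — more informative than overlap for thin
# structures like instruments. Prompt accuracy measures the upstream step:
# the fraction of frames whose point prompt lands inside the reference mask.

check_pair <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  list(a = a > 0, b = b > 0)
}

#' Intersection over union of two binary masks
#'
#' Two empty masks score 1: for evaluation, agreeing on the absence of an
#' instrument is a perfect prediction (the selection convention in
#' [sam4sis_score()] differs deliberately).
#'
#' @param a,b Logical matrices of the same shape.
#' @return Fraction in \[0, 1\].
#' @export
iou <- function(a, b) {
  p <- check_pair(a, b)
  uni <- sum(p$a | p$b)
  if (uni == 0) 1 else sum(p$a & p$b) / uni
}

#' DICE coefficient of two binary masks
#' @inheritParams iou
#' @return Fraction in \[0, 1\]; both-empty scores 1.
#' @export
dice <- function(a, b) {
  p <- check_pair(a, b)
  tot <- sum(p$a) + sum(p$b)
  if (tot == 0) 1 else 2 * sum(p$a & p$b) / tot
}

#' Boundary pixels of a binary mask
#'
#' A mask pixel is a boundary pixel if at least one of its 4-neighbors is
#' outside the mask; the image border counts as outside.
#'
#' @param mask Logical matrix.
#' @return n x 2 matrix of 0-based `(row, col)` coordinates.
#' @export
boundary_pixels <- function(mask) {
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L), drop = FALSE]
  interior <- pad[1:h, 2:(w + 1L), drop = FALSE] &  # up
    pad[3:(h + 2L), 2:(w + 1L), drop = FALSE] &     # down
    pad[2:(h + 1L), 1:w, drop = FALSE] &            # left
    pad[2:(h + 1L), 3:(w + 2L), drop = FALSE]       # right
  bnd <- core & !interior
  which(bnd, arr.ind = TRUE) - 1L
}

#' Normalized surface distance with tolerance tau
#'
#' `NSD = (|S_A in B_{B,tau}| + |S_B in B_{A,tau}|) / (|S_A| + |S_B|)`,
#' where S are the 4-neighbor boundary pixel sets and the border region
#' B_{X,tau} contains all pixels within Euclidean distance tau of S_X
#' (distances between pixel centers on the 0-based grid). Symmetric and
#' non-decreasing in tau. Both boundaries empty scores 1.
#'
#' @param a,b Logical matrices of the same shape.
#' @param tau Tolerance in pixels (>= 0).
#' @return Fraction in \[0, 1\].
#' @export
nsd <- function(a, b, tau) {
  if (!is.numeric(tau) || tau < 0) stop("tau must be >= 0")
  check_pair(a, b)
  sa <- boundary_pixels(a)
  sb <- boundary_pixels(b)
  na <- nrow(sa); nb <- nrow(sb)
  if (na == 0L && nb == 0L) return(1)
  if (na == 0L || nb == 0L) return(0)
  # min squared distance from each row of x to the point set y
  within_tau <- function(x, y) {
    d2 <- outer(x[, 1]^2 + x[, 2]^2, y[, 1]^2 + y[, 2]^2, "+") -
      2 * tcrossprod(x, y)
    sum(apply(d2, 1, min) <= tau^2 + 1e-9)
  }
  (within_tau(sa, sb) + within_tau(sb, sa)) / (na + nb)
}

#' Prompt accuracy over a set of frames
#'
#' A frame is a hit iff at least one positive prompt pixel lies inside the
#' reference mask; a frame with an empty prompt set and a nonempty reference
#' is a miss.
#'
#' @param prompt_sets List of `prompt_set` objects.
#' @param reference_masks List of logical matrices (same length).
#' @return Fraction hits / frames.
#' @export
prompt_accuracy <- function(prompt_sets, reference_masks) {
  if (length(prompt_sets) != length(reference_masks))
    stop("prompt and reference lists differ in length")
  hits <- mapply(prompt_hit, prompt_sets, reference_masks)
  mean(hits)
}

prompt_hit <- function(prompts, reference) {
  pos <- prompts$positives
  if (nrow(pos) == 0L) return(sum(reference) == 0)
  any(reference[pos + 1L])
}

#' Evaluate segmentation results against reference masks
#'
#' Computes per-frame IoU, DICE, NSD and prompt hits, then dataset means and
#' population standard deviations.
#'
#' @param predictions List of `segmentation_result` objects (or plain logical
#'   masks; then prompt accuracy is `NA`).
#' @param references List of logical reference masks.
#' @param tau NSD tolerance in pixels.
#' @return An object of class `eval_report`: `per_frame` data frame
#'   (`iou`, `dice`, `nsd`, `prompt_hit`), `summary` list (`mIoU`, `mDICE`,
#'   `mNSD`, `pAcc`, per-metric `sd`), and `tau`.
#' @export
evaluate_segmentation <- function(predictions, references, tau = 10) {
  if (length(predictions) != length(references))
    stop("prediction and reference lists differ in length")
  rows <- mapply(function(pred, ref) {
    mask <- if (inherits(pred, "segmentation_result")) pred$mask else pred
    hit <- if (inherits(pred, "segmentation_result"))
      prompt_hit(pred$prompts, ref) else NA
    c(iou = iou(mask, ref), dice = dice(mask, ref),
      nsd = nsd(mask, ref, tau), prompt_hit = hit)
  }, predictions, references)
  per_frame <- as.data.frame(t(rows))
  per_frame$prompt_hit <- as.logical(per_frame$prompt_hit)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(
    per_frame = per_frame,
    summary = list(
      mIoU = mean(per_frame$iou), mDICE = mean(per_frame$dice),
      mNSD = mean(per_frame$nsd),
      pAcc = if (all(is.na(per_frame$prompt_hit))) NA_real_
             else mean(per_frame$prompt_hit),
      sd = list(iou = pop_sd(per_frame$iou), dice = pop_sd(per_frame$dice),
                nsd = pop_sd(per_frame$nsd))),
    tau = tau), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<eval_report n=%d tau=%g ",
                     "mIoU=%.4f mDICE=%.4f mNSD=%.4f pAcc=%s>\n"),
              nrow(x$per_frame), x$tau, s$mIoU, s$mDICE, s$mNSD,
              if (is.na(s$pAcc)) "NA" else sprintf("%.4f", s$pAcc)))
  invisible(x)
}

#' Write / read an evaluation report as JSON
#' @param report An `eval_report`.
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_frame <- as.data.frame(x$per_frame)
  structure(x, class = "eval_report")
}
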