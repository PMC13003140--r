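test_that("overlap metrics match counting arguments and conventions", {
  a <- matrix(FALSE, 6, 6); a[2:3, 2:4] <- TRUE
  expect_equal(iou(a, a), 1)
  expect_equal(dice(a, a), 1)
  # |A| = |B| = 2n with overlap n -> IoU 1/3, DICE 1/2
  b <- matrix(FALSE, 4, 4); b[1, 1:2] <- TRUE
  c_ <- matrix(FALSE, 4, 4); c_[1, 2] <- c_[2, 2] <- TRUE
  expect_equal(iou(b, c_), 1 / 3)
  expect_equal(dice(b, c_), 1 / 2)
  empty <- matrix(FALSE, 4, 4)
  expect_equal(iou(empty, empty), 1)
  expect_equal(dice(empty, empty), 1)
  expect_error(iou(a, b), "shapes")
})

test_that("dice and iou satisfy their algebraic identity", {
  set.seed(90)
  for (i in 1:50) {
    a <- random_mask(); b <- random_mask()
    i_ <- iou(a, b); d <- dice(a, b)
    expect_equal(d, 2 * i_ / (1 + i_), tolerance = 1e-12)
    expect_gte(d, i_)
  }
})

test_that("boundary extraction treats the image border as outside", {
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  expect_equal(boundary_pixels(m), cbind(row = 1L, col = 1L),
               ignore_attr = TRUE)
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  bp <- boundary_pixels(sq)
  expect_identical(nrow(bp), 8L)        # ring of the 3x3 square
  expect_false(any(bp[, 1] == 2 & bp[, 2] == 2))  # center excluded
  expect_identical(nrow(boundary_pixels(matrix(FALSE, 4, 4))), 0L)
  expect_identical(nrow(boundary_pixels(matrix(TRUE, 3, 3))), 8L)
})

test_that("NSD rewards boundaries within tolerance and is symmetric", {
  a <- matrix(FALSE, 20, 20); a[5:8, 5:8] <- TRUE
  expect_equal(nsd(a, a, 0), 1)
  expect_equal(nsd(a, a, 7), 1)

  p1 <- matrix(FALSE, 15, 15); p1[3, 3] <- TRUE
  p2 <- matrix(FALSE, 15, 15); p2[13, 3] <- TRUE    # 10 pixels apart
  expect_equal(nsd(p1, p2, 1), 0)
  expect_equal(nsd(p1, p2, 10), 1)
  expect_error(nsd(p1, p2, -1), "tau")

  set.seed(33)
  for (i in 1:15) {
    x <- random_mask(12, 12); y <- random_mask(12, 12)
    taus <- c(0, 1, 2, 4, 8, 17)
    vals <- vapply(taus, function(t) nsd(x, y, t), numeric(1))
    expect_true(all(diff(vals) >= -1e-12))            # monotone in tau
    expect_equal(nsd(x, y, 3), nsd(y, x, 3))
    if (any(x) && any(y)) expect_equal(vals[length(taus)], 1)  # tau ~ diagonal
  }
})

test_that("prompt accuracy counts frames with any prompt inside the mask", {
  mk <- function(row, col) {
    ps <- sisegment:::empty_prompt_set(0.65, matrix(0L, 5, 5))
    if (!is.na(row))
      ps$positives <- matrix(c(row, col), 1,
                             dimnames = list(NULL, c("row", "col")))
    ps
  }
  inside <- matrix(FALSE, 5, 5); inside[2:3, 2:3] <- TRUE
  expect_equal(prompt_accuracy(list(mk(1, 1), mk(2, 2)),
                               list(inside, inside)), 1)
  expect_equal(prompt_accuracy(list(mk(1, 1), mk(0, 0), mk(2, 2), mk(4, 4)),
                               list(inside, inside, inside, inside)), 0.5)
  expect_equal(prompt_accuracy(list(mk(NA, NA)), list(inside)), 0)  # no prompt
  expect_error(prompt_accuracy(list(mk(1, 1)), list(inside, inside)), "length")
})

test_that("report aggregation matches per-frame recomputation", {
  ref <- matrix(FALSE, 8, 8); ref[2:5, 2:5] <- TRUE
  pred1 <- ref                            # iou 1
  pred2 <- matrix(FALSE, 8, 8); pred2[7, 7] <- TRUE  # iou 0
  rep1 <- evaluate_segmentation(list(pred1), list(ref), tau = 2)
  expect_equal(rep1$summary$mIoU, 1)
  expect_equal(rep1$summary$sd$iou, 0)

  rep2 <- evaluate_segmentation(list(pred1, pred2), list(ref, ref), tau = 2)
  expect_equal(rep2$summary$mIoU, 0.5)
  expect_equal(rep2$summary$mDICE, mean(c(dice(pred1, ref), dice(pred2, ref))))
  expect_equal(rep2$summary$mNSD,
               mean(c(nsd(pred1, ref, 2), nsd(pred2, ref, 2))))
  expect_equal(rep2$per_frame$iou, c(1, 0))
})

test_that("evaluation reports round-trip through JSON", {
  set.seed(61)
  preds <- lapply(1:3, function(i) random_mask(10, 10))
  refs <- lapply(1:3, function(i) random_mask(10, 10))
  rep <- evaluate_segmentation(preds, refs, tau = 3)
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$summary$mIoU, rep$summary$mIoU)
  expect_equal(back$per_frame$nsd, rep$per_frame$nsd)
  expect_equal(back$tau, rep$tau)
})
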