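prompt_at <- function(row, col, h = 8, w = 8) {
  ps <- sisegment:::empty_prompt_set(0.65, matrix(0L, h, w))
  ps$positives <- matrix(c(row, col), 1, dimnames = list(NULL, c("row", "col")))
  ps
}

test_that("empty prompt sets yield three empty flagged masks", {
  img <- matrix(runif(36), 6, 6)
  ps <- sisegment:::empty_prompt_set(0.65, matrix(0L, 6, 6),
                                     no_instrument = TRUE)
  out <- propose_masks(img, ps)
  expect_true(out$no_instrument)
  expect_length(out$masks, 3)
  for (m in out$masks) expect_false(any(m))
})

test_that("region growing saturates at a uniform blob's boundary", {
  img <- matrix(0, 9, 9)
  img[3:6, 3:6] <- 1
  out <- region_grow_backend(img, prompt_at(3, 3, 9, 9))  # seed inside blob
  blob <- img == 1
  for (m in out$masks) expect_identical(m, blob)
  expect_equal(out$confidences, c(1, (1 / 1.16 - 1 / 1.32) / (1 / 1.08 - 1 / 1.32), 0),
               tolerance = 1e-9)
})

test_that("a tolerance spanning the value range floods the image", {
  set.seed(6)
  img <- matrix(runif(64, 0.4, 0.6), 8, 8)
  out <- region_grow_backend(img, prompt_at(4, 4), tolerances = c(0.05, 0.1, 1))
  expect_true(all(out$masks[[3]]))
})

test_that("two-level steps are separated below the step height", {
  img <- matrix(0, 6, 10)
  img[, 6:10] <- 1
  out <- region_grow_backend(img, prompt_at(2, 7), tolerances = c(0.2, 0.4, 0.8))
  bright <- img == 1
  for (m in out$masks) expect_identical(m, bright)
  expect_error(region_grow_backend(img, prompt_at(2, 7),
                                   tolerances = c(0.4, 0.4, 0.8)),
               "increasing")
})

test_that("negative prompts carve out their region but keep positive seeds", {
  img <- matrix(0, 6, 10)
  img[, 6:10] <- 1
  ps <- prompt_at(2, 7)
  ps$negative <- c(row = 4, col = 8)
  out <- region_grow_backend(img, ps, tolerances = c(0.2, 0.4, 0.8))
  for (m in out$masks) {
    expect_true(m[3, 8])            # positive seed always retained
    expect_false(m[5, 9])           # negative region excluded
  }
})

test_that("proposals are nested under increasing tolerances", {
  set.seed(19)
  for (i in 1:10) {
    img <- sisegment:::gaussian_blur(matrix(runif(20 * 20), 20, 20), 1.5)
    ps <- prompt_at(sample(0:19, 1), sample(0:19, 1), 20, 20)
    out <- region_grow_backend(img, ps)
    expect_true(all(out$masks[[2]][out$masks[[1]]]))
    expect_true(all(out$masks[[3]][out$masks[[2]]]))
    expect_true(all(out$confidences >= 0 & out$confidences <= 1))
    p1 <- ps$positives[1, ] + 1
    for (m in out$masks) expect_true(m[p1[1], p1[2]])
  }
})

test_that("the SAM4SIS score is the IoU against the SI support", {
  a <- matrix(FALSE, 4, 4); a[1, 1] <- a[1, 2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[1, 2] <- b[2, 2] <- TRUE
  expect_equal(sam4sis_score(a, b), 1 / 3)
  expect_equal(sam4sis_score(a, a), 1)
  expect_equal(sam4sis_score(a, !a & cbind(a[, -1], a[, 1, drop = FALSE])), 0)
  expect_equal(sam4sis_score(a * 0 > 1, a * 0 > 1), 0)  # both empty
  expect_equal(sam4sis_score(a, b), sam4sis_score(b, a))
  expect_error(sam4sis_score(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("mask selection takes the score argmax with declared tie-breaks", {
  si_bin <- matrix(FALSE, 5, 5); si_bin[2:3, 2:3] <- TRUE
  m_exact <- si_bin
  m_half <- si_bin; m_half[3, ] <- FALSE
  m_big <- matrix(TRUE, 5, 5)
  mp <- sisegment:::mask_proposals(list(m_half, m_exact, m_big), c(0.9, 0.1, 0.5),
                                   prompt_at(1, 1, 5, 5))
  res <- select_mask(mp, si_bin)
  expect_identical(res$selected_index, 2L)
  expect_equal(res$sam4sis_scores[2], 1)
  expect_identical(res$mask, m_exact)

  # all scores equal -> highest backend confidence wins
  mp2 <- sisegment:::mask_proposals(list(m_exact, m_exact, m_exact),
                                    c(0.2, 0.9, 0.5), prompt_at(1, 1, 5, 5))
  expect_identical(select_mask(mp2, si_bin)$selected_index, 2L)
  # equal scores and confidences -> lowest index
  mp3 <- sisegment:::mask_proposals(list(m_exact, m_exact, m_exact),
                                    c(0.5, 0.5, 0.5), prompt_at(1, 1, 5, 5))
  expect_identical(select_mask(mp3, si_bin)$selected_index, 1L)
})

test_that("permuting proposals permutes scores and keeps the winner", {
  set.seed(55)
  for (i in 1:40) {
    masks <- lapply(1:3, function(j) random_mask(10, 10))
    conf <- runif(3)
    si_bin <- random_mask(10, 10)
    mp <- sisegment:::mask_proposals(masks, conf, prompt_at(0, 0, 10, 10))
    res <- select_mask(mp, si_bin)
    perm <- sample(3)
    mpp <- sisegment:::mask_proposals(masks[perm], conf[perm],
                                      prompt_at(0, 0, 10, 10))
    resp <- select_mask(mpp, si_bin)
    expect_equal(resp$sam4sis_scores, res$sam4sis_scores[perm])
    expect_identical(resp$mask, res$mask)
  }
})

test_that("custom backends dispatch by name and bad names error", {
  register_backend("always_full", function(image, prompts, params) {
    full <- matrix(TRUE, nrow(image), ncol(image))
    sisegment:::mask_proposals(list(full, full, full), c(1, 1, 1), prompts)
  })
  img <- matrix(0.5, 4, 4)
  out <- propose_masks(img, prompt_at(1, 1, 4, 4), backend = "always_full")
  expect_true(all(out$masks[[1]]))
  expect_error(propose_masks(img, prompt_at(1, 1, 4, 4), backend = "no_such_backend"),
               "unknown backend")
})
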