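test_that("coreset selection follows greedy farthest-point exactly", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  expect_setequal(coreset_select(x, 1), 1:3)
  expect_identical(sort(coreset_select(x, 2 / 3, start = 1)), c(1L, 3L))
  set.seed(42)
  y <- matrix(rnorm(50 * 3), 50, 3)
  expect_identical(coreset_select(y, 0.4, start = 7),
                   as.integer(bf_coreset(y, 20, 7)))
  expect_identical(coreset_select(y, 0.4, seed = 9),
                   coreset_select(y, 0.4, seed = 9))
  expect_error(coreset_select(y, 0), "positive")
})

test_that("memory bank pools aggregated features and subsamples", {
  img <- matrix(0.5, 16, 16)
  spec <- feature_spec(scales = 1, stride = 4, params = list(bins = 0))
  bank <- build_memory_bank(list(img), spec, ratio = 1)
  expect_identical(nrow(bank$vectors), 16L)  # 4x4 grid
  expect_true(all(bank$vectors == rep(bank$vectors[1, ],
                                      each = nrow(bank$vectors))))
  expect_error(build_memory_bank(list(), spec), "no nominal data")

  set.seed(8)
  imgs <- lapply(1:10, function(i) matrix(runif(16 * 16), 16, 16))
  b <- build_memory_bank(imgs, spec, ratio = 0.1)
  expect_identical(nrow(b$vectors), as.integer(max(1, round(0.1 * 10 * 16))))
})

test_that("images used to build a full-ratio bank score zero everywhere", {
  set.seed(21)
  imgs <- lapply(1:2, function(i) matrix(runif(12 * 12), 12, 12))
  spec <- feature_spec(scales = 1, stride = 4)
  bank <- build_memory_bank(imgs, spec, ratio = 1)
  for (img in imgs) {
    g <- aggregate_neighborhood(extract_features(img, spec), spec$window)
    expect_true(all(score_patches(bank, g) == 0))
  }
})

test_that("patch scores are exact nearest-neighbor distances", {
  bank <- structure(list(vectors = rbind(c(0, 0), c(1, 0)),
                         spec = feature_spec(), coreset_ratio = 1,
                         norm_lo = NA_real_, norm_hi = NA_real_, seed = 0L),
                    class = "memory_bank")
  g <- as_grid(array(c(3, 0), c(1, 1, 2)))
  expect_equal(as.vector(score_patches(bank, g)), 2)
  g0 <- as_grid(array(c(1, 0), c(1, 1, 2)))
  expect_equal(as.vector(score_patches(bank, g0)), 0)
  expect_error(score_patches(bank, as_grid(array(1, c(1, 1, 3)))), "dimension")
})

test_that("scores match the brute-force scan and shrink with larger banks", {
  set.seed(14)
  bankv <- matrix(rnorm(120 * 6), 120, 6)
  q <- matrix(rnorm(180 * 6), 180, 6)
  mk_bank <- function(v) structure(
    list(vectors = v, spec = feature_spec(), coreset_ratio = 1,
         norm_lo = NA_real_, norm_hi = NA_real_, seed = 0L),
    class = "memory_bank")
  grid <- as_grid(array(q, c(18, 10, 6)))
  expect_equal(as.vector(score_patches(mk_bank(bankv), grid)),
               unname(bf_nn_scores(q, bankv, 1)))
  expect_equal(as.vector(score_patches(mk_bank(bankv), grid, k = 5)),
               unname(bf_nn_scores(q, bankv, 5)))
  sub <- bankv[1:40, ]
  expect_true(all(score_patches(mk_bank(bankv), grid) <=
                    score_patches(mk_bank(sub), grid) + 1e-12))
})

test_that("anomaly maps upsample, smooth, and conserve mass cyclically", {
  s <- matrix(runif(25), 5, 5)
  m <- anomaly_map(s, c(5, 5), stride = 1, smoothing_sigma = 0)
  expect_equal(m$values, s)
  expect_identical(m$kind, "anomaly")

  const <- matrix(2, 4, 4)
  mc <- anomaly_map(const, c(16, 16), stride = 4, smoothing_sigma = 3)
  expect_equal(mc$values, matrix(2, 16, 16), tolerance = 1e-9)

  spike <- matrix(0, 16, 16); spike[7, 9] <- 5
  mm <- anomaly_map(spike, c(16, 16), stride = 1, smoothing_sigma = 2.5,
                    pad = "cyclic")
  expect_equal(sum(mm$values), 5, tolerance = 1e-6)
  expect_error(anomaly_map(spike, c(16, 16), 1, smoothing_sigma = -1), "sigma")
})

test_that("calibration brackets observed scores and normalization is affine", {
  img <- matrix(0.4, 16, 16)
  spec <- feature_spec(scales = 1, stride = 4)
  bank <- build_memory_bank(list(img), spec, ratio = 1)
  cal <- calibrate_normalization(bank, list(img))
  expect_identical(cal$norm_lo, 0)           # self-match distances
  expect_equal(cal$norm_hi, 1e-8)            # epsilon widening of a flat range

  bank$norm_lo <- 0.2; bank$norm_hi <- 5.0
  m <- score_map(matrix(c(0.2, 2.6, 5.0, 7.3), 2, 2), "anomaly")
  nm <- normalize_map(m, bank)
  expect_true(nm$normalized)
  expect_equal(nm$values, matrix(c(0, 0.5, 1, 1), 2, 2))
  bank$norm_lo <- NA_real_
  expect_error(normalize_map(m, bank), "calibrated")
})

test_that("normalized calibration maps span the unit interval", {
  set.seed(31)
  spec <- feature_spec(scales = 1, stride = 4)
  nominal <- lapply(1:4, function(i) matrix(runif(24 * 24), 24, 24))
  probe <- lapply(1:3, function(i) matrix(runif(24 * 24), 24, 24))
  bank <- calibrate_normalization(build_memory_bank(nominal, spec, 0.5), probe)
  vals <- unlist(lapply(probe, function(img)
    normalize_map(sisegment:::raw_anomaly(bank, img), bank)$values))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(min(vals), 0)
  expect_equal(max(vals), 1)
})

test_that("banks round-trip through their archive format", {
  set.seed(2)
  bank <- build_memory_bank(list(matrix(runif(64), 8, 8)),
                            feature_spec(scales = 1, stride = 4), ratio = 0.5)
  path <- tempfile(fileext = ".rds")
  save_bank(bank, path)
  expect_identical(load_bank(path), bank)
  expect_error(load_bank(tempfile()), "not found")
})
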