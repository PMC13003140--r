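# Independent brute-force oracles and tiny fixtures used across the suite.

# all-pairs nearest-neighbor scan (mean of the k smallest distances)
bf_nn_scores <- function(query, bank, k = 1) {
  apply(query, 1, function(q) {
    d <- sqrt(colSums((t(bank) - q)^2))
    mean(sort(d)[seq_len(k)])
  })
}

# straightforward greedy farthest-point selection with a fixed start
bf_coreset <- function(x, n_select, start) {
  sel <- start
  mind <- sqrt(colSums((t(x) - x[start, ])^2))
  while (length(sel) < n_select) {
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    mind <- pmin(mind, sqrt(colSums((t(x) - x[nxt, ])^2)))
  }
  sel
}

# wrap a matrix (or H' x W' x D array) as a patch grid
as_grid <- function(features, stride = 1L, source_shape = NULL) {
  if (length(dim(features)) == 2L)
    features <- array(features, c(dim(features), 1L))
  d <- dim(features)
  sisegment:::patch_grid(features, stride,
                         source_shape %||% c(d[1] * stride, d[2] * stride))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalized score map from plain values
sm <- function(values, kind = "si", normalized = TRUE) {
  score_map(values, kind = kind, normalized = normalized)
}

random_mask <- function(h = 16, w = 16, p = 0.3) matrix(runif(h * w) < p, h, w)

# 2x2 sRGB fixture with channel values and Eq.-1 filter frozen from an
# independent color-science implementation (scikit-image rgb2lab/rgb2hsv)
eq1_fixture <- function() {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(1, 0, 0)        # pure red: attains max a*, V and S
  img[1, 2, ] <- c(0.5, 0.5, 0.5)  # mid gray
  img[2, 1, ] <- c(0, 0, 0)        # black
  img[2, 2, ] <- c(0.2, 0.8, 0.4)  # saturated green (negative a*)
  list(img = img,
       astar = matrix(c(80.0923, 0, -0.0015, -60.8523), 2, 2),
       value = matrix(c(1, 0, 0.5, 0.8), 2, 2),
       saturation = matrix(c(1, 0, 0, 0.75), 2, 2),
       f = matrix(c(0, 1, 0.8333394, 0.7365923), 2, 2))
}
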