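# ---- synthetic surgical scenes ----------------------------------------------
#
# Seeded generators for the two image domains the pipeline serves, so the
# whole chain (bank -> anomaly -> filter -> prompt -> proposal -> metrics)
# can be exercised without external data. The color domain emulates
# endoscopy/microscopy: low-frequency reddish tissue texture, specular
# highlights, and gray elongated (capsule-shaped) instruments. The intensity
# domain emulates OCT B-scans: multiplicative speckle over a dark background,
# bright curved tissue bands, a short bright instrument cross-section above
# them, and an exactly-zero shadow column beneath the instrument (shadow
# pixels are NOT part of the truth mask — the instrument, not its artifact,
# is the segmentation target).

#' Specify a synthetic scene
#'
#' @param domain `"rgb"` or `"intensity"`.
#' @param shape `(H, W)` in pixels; defaults 128 x 128 (rgb) and 92 x 256
#'   (intensity), the pipeline's working resolutions.
#' @param n_instruments 0..3 instruments (0 gives a nominal scene).
#' @param instrument_width_frac Instrument width as a fraction of H.
#' @param instrument_length_frac Instrument length as a fraction of W.
#' @param noise List: `texture_scale` (px per texture knot),
#'   `speckle_sigma` (log-sd of multiplicative speckle; intensity domain),
#'   `highlight_count` (specular disks; rgb domain).
#' @param seed Default seed used when the generator is called without one.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(domain = c("rgb", "intensity"), shape = NULL,
                       n_instruments = 1L,
                       instrument_width_frac = NULL,
                       instrument_length_frac = NULL,
                       noise = list(), seed = 0L) {
  domain <- match.arg(domain)
  defaults <- if (domain == "rgb") {
    list(shape = c(128L, 128L), wf = 0.08, lf = 0.55,
         noise = list(texture_scale = 16, speckle_sigma = 0, highlight_count = 3))
  } else {
    list(shape = c(92L, 256L), wf = 0.05, lf = 0.15,
         noise = list(texture_scale = 16, speckle_sigma = 0.35, highlight_count = 0))
  }
  shape <- as.integer(shape %||% defaults$shape)
  wf <- instrument_width_frac %||% defaults$wf
  lf <- instrument_length_frac %||% defaults$lf
  noise <- modifyList(defaults$noise, noise)
  if (any(shape < 8L)) stop("invalid spec: shape too small")
  if (n_instruments < 0L || n_instruments > 3L) stop("invalid spec: n_instruments must be 0..3")
  if (wf <= 0 || wf >= 1 || lf <= 0 || lf >= 1) stop("invalid spec: fractions must lie in (0,1)")
  structure(list(domain = domain, shape = shape,
                 n_instruments = as.integer(n_instruments),
                 instrument_width_frac = wf, instrument_length_frac = lf,
                 noise = noise, seed = as.integer(seed)),
            class = "scene_spec")
}

# low-frequency random field in [lo, hi]: coarse uniform knots, bilinear up
smooth_field <- function(h, w, scale, lo, hi) {
  kh <- max(2L, ceiling(h / scale)); kw <- max(2L, ceiling(w / scale))
  knots <- matrix(runif(kh * kw), kh, kw)
  lo + (hi - lo) * resize_bilinear(knots, h, w)
}

# vectorized HSV -> RGB, all arguments/values in [0, 1]
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), c(dim(h), 3L))
}

# capsule (thick segment) mask: pixels within width/2 of the segment between
# two endpoints, placed fully inside the image
capsule_mask <- function(h, w, length_px, width_px, theta_range = c(0, pi)) {
  half <- width_px / 2
  margin <- half + 2
  theta <- runif(1, theta_range[1], theta_range[2])
  # center constrained so both endpoints stay inside
  dx <- abs(cos(theta)) * length_px / 2
  dy <- abs(sin(theta)) * length_px / 2
  cx <- runif(1, min(margin + dy, h / 2), max(h - margin - dy, h / 2))
  cy <- runif(1, min(margin + dx, w / 2), max(w - margin - dx, w / 2))
  p1 <- c(cx - sin(theta) * length_px / 2, cy - cos(theta) * length_px / 2)
  p2 <- c(cx + sin(theta) * length_px / 2, cy + cos(theta) * length_px / 2)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  t <- pmin(pmax(((rr - p1[1]) * vx + (cc - p1[2]) * vy) / len2, 0), 1)
  d2 <- (rr - (p1[1] + t * vx))^2 + (cc - (p1[2] + t * vy))^2
  d2 <= half^2
}

scene_pair <- function(image, truth, spec, shadow = NULL, instruments = list()) {
  structure(list(image = image, truth_mask = truth, spec = spec,
                 shadow_mask = shadow, instrument_masks = instruments),
            class = "scene_pair")
}

#' @export
print.scene_pair <- function(x, ...) {
  cat(sprintf("<scene_pair %s %dx%d instruments=%d truth_area=%d>\n",
              x$spec$domain, x$spec$shape[1], x$spec$shape[2],
              length(x$instrument_masks), sum(x$truth_mask)))
  invisible(x)
}

#' Generate a color (endoscopy-like) scene with ground truth
#'
#' Background: smooth reddish texture (hue within +-0.04 of red, saturation
#' 0.4-0.9, value 0.3-0.8) with optional white specular disks. Instruments:
#' capsule-shaped gray regions (saturation < 0.15, value 0.35-0.5 with a mild
#' axial gradient) at seeded random pose. Deterministic per `(spec, seed)`.
#'
#' @param spec A [scene_spec()] with `domain = "rgb"`.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A `scene_pair`: `image` (H x W x 3), `truth_mask`,
#'   `instrument_masks`, `spec`.
#' @export
generate_rgb_scene <- function(spec = scene_spec("rgb"), seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$domain != "rgb") stop("invalid spec: domain must be 'rgb'")
  h <- spec$shape[1]; w <- spec$shape[2]
  with_seed(seed, {
    ts <- spec$noise$texture_scale
    hue <- (0.98 + smooth_field(h, w, ts, -0.04, 0.04)) %% 1
    sat <- smooth_field(h, w, ts, 0.4, 0.9)
    val <- smooth_field(h, w, ts, 0.3, 0.8)
    # specular highlights: small saturated-to-white disks
    nh <- spec$noise$highlight_count
    if (nh > 0) {
      for (i in seq_len(nh)) {
        r0 <- runif(1, 1, h); c0 <- runif(1, 1, w); rad <- runif(1, 1.5, 3.5)
        rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
        disk <- (rr - r0)^2 + (cc - c0)^2 <= rad^2
        sat[disk] <- 0.03
        val[disk] <- 0.98
      }
    }
    truth <- matrix(FALSE, h, w)
    instruments <- list()
    for (i in seq_len(spec$n_instruments)) {
      cap <- capsule_mask(h, w, spec$instrument_length_frac * w,
                          spec$instrument_width_frac * h)
      v0 <- runif(1, 0.35, 0.5)
      grad <- smooth_field(h, w, ts, -0.05, 0.05)
      sat[cap] <- runif(1, 0.02, 0.12)
      val[cap] <- pmin(pmax(v0 + grad[cap], 0.2), 0.6)
      hue[cap] <- runif(1)
      truth <- truth | cap
      instruments[[i]] <- cap
    }
    img <- hsv_to_rgb(hue, sat, val)
    scene_pair(img, truth, spec, instruments = instruments)
  })
}

#' Generate an intensity (OCT B-scan-like) scene with ground truth
#'
#' Dark background with multiplicative log-normal speckle, 1-3 bright curved
#' tissue bands, a short bright instrument cross-section above the bands, and
#' an exactly-zero shadow column below each instrument pixel. The truth mask
#' contains the instrument pixels only (never the shadow). Deterministic per
#' `(spec, seed)`.
#'
#' @param spec A [scene_spec()] with `domain = "intensity"`.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A `scene_pair` with `shadow_mask` recording the shadow pixels.
#' @export
generate_intensity_scene <- function(spec = scene_spec("intensity"),
                                     seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$domain != "intensity") stop("invalid spec: domain must be 'intensity'")
  h <- spec$shape[1]; w <- spec$shape[2]
  with_seed(seed, {
    ts <- spec$noise$texture_scale
    img <- smooth_field(h, w, ts, 0.03, 0.1)
    # bright curved tissue bands in the lower part of the scan
    n_bands <- sample(1:3, 1)
    cols <- seq_len(w)
    rr <- matrix(seq_len(h), h, w)
    for (b in seq_len(n_bands)) {
      c0 <- runif(1, 0.45, 0.85) * h
      amp <- runif(1, 0.02, 0.06) * h
      freq <- runif(1, 0.5, 2)
      phase <- runif(1, 0, 2 * pi)
      thick <- runif(1, 0.03, 0.06) * h
      center <- c0 + amp * sin(2 * pi * freq * cols / w + phase)
      band <- abs(rr - matrix(center, h, w, byrow = TRUE)) <= thick / 2
      level <- runif(1, 0.6, 0.85)
      img[band] <- pmax(img[band], level)
    }
    # multiplicative speckle; the same normal draws are used at any sigma so
    # speckle_sigma is a pure difficulty dial
    z <- matrix(rnorm(h * w), h, w)
    img <- pmin(img * exp(spec$noise$speckle_sigma * z), 1)
    band_top <- max(min(h * 0.45 - 1, h), 8)
    truth <- matrix(FALSE, h, w)
    shadow <- matrix(FALSE, h, w)
    instruments <- list()
    for (i in seq_len(spec$n_instruments)) {
      width_px <- spec$instrument_width_frac * h
      # the instrument sits in the free vitreous space above the bands
      repeat {
        cap <- capsule_mask(h, w, spec$instrument_length_frac * w, width_px,
                            theta_range = c(-0.25, 0.25))  # near-horizontal arc
        rows <- which(rowSums(cap) > 0)
        if (length(rows) && max(rows) < band_top - 2) break
      }
      img[cap] <- 0.9 + runif(sum(cap), 0, 0.08)
      truth <- truth | cap
      instruments[[i]] <- cap
    }
    if (spec$n_instruments > 0) {
      # exact-zero shadow strictly below the instrument in each column
      for (cidx in which(colSums(truth) > 0)) {
        bot <- max(which(truth[, cidx]))
        if (bot < h) shadow[(bot + 1):h, cidx] <- TRUE
      }
      shadow <- shadow & !truth
      img[shadow] <- 0
    }
    scene_pair(img, truth, spec, shadow = shadow, instruments = instruments)
  })
}

#' Generate a scene in the spec's domain
#' @param spec A [scene_spec()].
#' @param seed Integer seed.
#' @export
generate_scene <- function(spec, seed = spec$seed) {
  if (spec$domain == "rgb") generate_rgb_scene(spec, seed)
  else generate_intensity_scene(spec, seed)
}

# instrument/background intensity-contrast statistic recorded in dataset
# manifests: mean instrument minus mean background intensity (background
# excludes instrument and shadow pixels). Multiplicative speckle raises the
# background mean while the instrument is rendered at a fixed level, so
# larger speckle_sigma strictly lowers this statistic.
scene_contrast <- function(pair) {
  gray <- if (n_channels(pair$image) == 3L)
    (pair$image[, , 1] + pair$image[, , 2] + pair$image[, , 3]) / 3
  else pair$image
  bg <- !pair$truth_mask
  if (!is.null(pair$shadow_mask)) bg <- bg & !pair$shadow_mask
  if (!any(pair$truth_mask)) return(NA_real_)
  mean(gray[pair$truth_mask]) - mean(gray[bg])
}

# stable per-image seed derived from a dataset seed and an index
derive_seed <- function(seed, index) {
  ((as.double(seed) %% 65011) * 31259 + as.double(index) * 7919 + 104729) %% 2147483629
}

#' Generate a synthetic dataset on disk
#'
#' Writes `nominal/` (instrument-free scenes), `anomalous/` (scenes with
#' instruments), `masks/` (their truth masks) and `manifest.json`. Per-image
#' seeds are derived from `(seed, index)`, so regeneration from the manifest
#' is byte-identical and appending images never reshuffles existing ones.
#'
#' @param spec A [scene_spec()]; its `n_instruments` applies to anomalous
#'   scenes (nominal scenes force 0).
#' @param n_nominal,n_anomalous Image counts.
#' @param seed Dataset seed.
#' @param out_dir Output directory (created).
#' @param format `"png"` (8-bit) or, for the intensity domain, `"tiff16"`.
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(spec, n_nominal, n_anomalous, seed, out_dir,
                             format = c("png", "tiff16")) {
  format <- match.arg(format)
  if (format == "tiff16" && spec$domain != "intensity")
    stop("tiff16 output is only supported for the intensity domain")
  for (d in file.path(out_dir, c("nominal", "anomalous", "masks")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "png") "png" else "tif"
  write_img <- function(img, path) {
    if (format == "png") png::writePNG(img, path)
    else tiff::writeTIFF(img, path, bits.per.sample = 16L)
  }
  entries <- list()
  for (i in seq_len(n_nominal + n_anomalous)) {
    nominal <- i <= n_nominal
    sp <- spec
    sp$n_instruments <- if (nominal) 0L else spec$n_instruments
    s <- derive_seed(seed, i)
    pair <- generate_scene(sp, s)
    stem <- sprintf("%s_%04d.%s", if (nominal) "nominal" else "anomalous", i, ext)
    rel <- file.path(if (nominal) "nominal" else "anomalous", stem)
    write_img(pair$image, file.path(out_dir, rel))
    entry <- list(file = rel, seed = s, role = if (nominal) "nominal" else "anomalous")
    if (!nominal) {
      mask_rel <- file.path("masks", sprintf("anomalous_%04d.png", i))
      save_mask(pair$truth_mask, file.path(out_dir, mask_rel))
      entry$mask <- mask_rel
      entry$contrast <- scene_contrast(pair)
    }
    entries[[i]] <- entry
  }
  manifest <- list(version = 1L, domain = spec$domain,
                   shape = spec$shape, seed = seed, format = format,
                   spec = unclass(spec), entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
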