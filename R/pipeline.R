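# ---- pipeline configuration and orchestration -------------------------------

#' Pipeline configuration
#'
#' Bundles every tunable of the segmentation chain. Defaults follow the
#' method's reference settings: coreset ratio 0.1, optional 9-neighbor score
#' mode (off by default; the pixel score is the 1-NN distance), smoothing
#' sigma 4 px, working resolutions 128 x 128 (rgb) / 92 x 256 (intensity),
#' binarization threshold 0.65 (rgb, instruments ~35% of the frame) / 0.85
#' (intensity, ~15%), NSD tolerance 10 px.
#'
#' @param features A [feature_spec()].
#' @param coreset_ratio Coreset sampling ratio in (0, 1].
#' @param k_neighbors Neighbor count for the optional k-mean score mode.
#' @param knn_mode If `FALSE` (default) the pixel score is the plain 1-NN
#'   distance.
#' @param smoothing_sigma Anomaly-map Gaussian sigma in pixels.
#' @param filter `"rgb"` or `"intensity"` — the single domain switch.
#' @param threshold SI binarization threshold; default depends on `filter`.
#' @param multi One prompt per connected component (default `TRUE`).
#' @param negative_prompt Add a central-area negative prompt (default
#'   `FALSE`).
#' @param central_fraction Central window fraction for the negative prompt.
#' @param backend Mask-proposal backend name.
#' @param backend_params Backend parameter list.
#' @param tau NSD tolerance in pixels.
#' @param working_shape `(H, W)` the image is resized to before feature
#'   extraction; default depends on `filter`.
#' @param seed Integer seed recorded in provenance.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(features = feature_spec(),
                            coreset_ratio = 0.1,
                            k_neighbors = 9L, knn_mode = FALSE,
                            smoothing_sigma = 4,
                            filter = c("rgb", "intensity"),
                            threshold = NULL,
                            multi = TRUE,
                            negative_prompt = FALSE,
                            central_fraction = 0.5,
                            backend = "region_grow",
                            backend_params = list(),
                            tau = 10,
                            working_shape = NULL,
                            seed = 0L) {
  filter <- match.arg(filter)
  threshold <- threshold %||% if (filter == "rgb") 0.65 else 0.85
  working_shape <- as.integer(working_shape %||%
    if (filter == "rgb") c(128L, 128L) else c(92L, 256L))
  if (coreset_ratio <= 0 || coreset_ratio > 1) stop("coreset_ratio must lie in (0, 1]")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  structure(list(features = features, coreset_ratio = coreset_ratio,
                 k_neighbors = as.integer(k_neighbors), knn_mode = knn_mode,
                 smoothing_sigma = smoothing_sigma, filter = filter,
                 threshold = threshold, multi = multi,
                 negative_prompt = negative_prompt,
                 central_fraction = central_fraction,
                 backend = backend, backend_params = backend_params,
                 tau = tau, working_shape = working_shape,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The on-disk layout mirrors the object: a `features` section plus flat
#' keys; `load_config(save_config(cfg))` restores an identical object.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$features <- unclass(x$features)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- yaml::read_yaml(path)
  fs <- x$features
  feats <- feature_spec(name = fs$name, scales = fs$scales,
                        window = fs$window, stride = fs$stride,
                        params = fs$params)
  pipeline_config(features = feats, coreset_ratio = x$coreset_ratio,
                  k_neighbors = x$k_neighbors, knn_mode = x$knn_mode,
                  smoothing_sigma = x$smoothing_sigma, filter = x$filter,
                  threshold = x$threshold, multi = x$multi,
                  negative_prompt = x$negative_prompt,
                  central_fraction = x$central_fraction,
                  backend = x$backend,
                  backend_params = x$backend_params %||% list(),
                  tau = x$tau, working_shape = x$working_shape,
                  seed = x$seed)
}

config_hash <- function(config) rlang::hash(unclass(config))
bank_hash <- function(bank) rlang::hash(unclass(bank))

specs_compatible <- function(a, b) {
  identical(a$name, b$name) && identical(a$scales, b$scales) &&
    identical(a$window, b$window) && identical(a$stride, b$stride) &&
    identical(a$params, b$params)
}

bank_error <- function() {
  structure(class = c("sisegment_bank_incompatible", "error", "condition"),
            list(message = "bank incompatible with pipeline configuration",
                 call = NULL))
}

#' Build a memory bank under a pipeline configuration
#'
#' Convenience wrapper: extracts features per the config, subsamples at the
#' config's coreset ratio, and (optionally) calibrates score normalization on
#' `calibration_images`.
#'
#' @param nominal_images List of instrument-free rasters (resized to the
#'   working shape internally).
#' @param config A `pipeline_config`.
#' @param calibration_images Optional list of rasters (typically frames with
#'   instruments) for score-range calibration; if `NULL`, the nominal images
#'   are used.
#' @return A calibrated `memory_bank`.
#' @export
build_bank <- function(nominal_images, config = pipeline_config(),
                       calibration_images = NULL) {
  resize_all <- function(imgs) lapply(imgs, function(im)
    resize_bilinear(im, config$working_shape[1], config$working_shape[2]))
  nominal_images <- resize_all(nominal_images)
  bank <- build_memory_bank(nominal_images, config$features,
                            ratio = config$coreset_ratio, seed = config$seed)
  calib <- if (is.null(calibration_images)) nominal_images
           else resize_all(calibration_images)
  calibrate_normalization(bank, calib,
                          smoothing_sigma = config$smoothing_sigma,
                          k = if (config$knn_mode) config$k_neighbors else 1L)
}

#' Segment one image in memory
#'
#' Runs the full chain at the working resolution: features -> bank scoring ->
#' anomaly map -> normalization -> domain filter -> SI map -> prompts ->
#' three mask proposals -> SAM4SIS selection. The final mask is resized back
#' to the input resolution with nearest-neighbor interpolation (stays
#' binary).
#'
#' @param image Raster (any resolution).
#' @param bank A calibrated `memory_bank` matching the config's feature spec.
#' @param config A `pipeline_config`.
#' @return List: `result` (the working-resolution `segmentation_result`),
#'   `mask` (binary, input resolution), `anomaly`, `filter`, `si` (score
#'   maps), `si_bin`, `prompts`.
#' @export
segment_image <- function(image, bank, config = pipeline_config()) {
  assert_raster(image)
  stopifnot(inherits(bank, "memory_bank"))
  if (!specs_compatible(bank$spec, config$features)) stop(bank_error())
  in_shape <- dim(image)[1:2]
  work <- resize_bilinear(image, config$working_shape[1], config$working_shape[2])
  k <- if (config$knn_mode) config$k_neighbors else 1L
  anomaly <- normalize_map(raw_anomaly(bank, work, config$smoothing_sigma, k), bank)
  filt <- if (config$filter == "rgb") filter_rgb(work) else filter_intensity(work)
  si <- si_map(anomaly, filt)
  prompts <- select_prompts(si, config$threshold, multi = config$multi)
  if (config$negative_prompt && nrow(prompts$positives) > 0L)
    prompts$negative <- select_negative_prompt(si, config$central_fraction)
  proposals <- propose_masks(work, prompts, config$backend, config$backend_params)
  si_bin <- binarize_si(score_map(rescale01(si$values), "si", normalized = TRUE),
                        config$threshold)
  result <- select_mask(proposals, si_bin)
  mask_full <- resize_nearest(result$mask * 1, in_shape[1], in_shape[2]) >= 0.5
  list(result = result, mask = mask_full, anomaly = anomaly, filter = filt,
       si = si, si_bin = si_bin, prompts = prompts)
}

#' Run the pipeline on an image file and write artifacts
#'
#' Writes `<stem>_mask.png` (binary mask at input resolution),
#' `<stem>_anomaly.tif` and `<stem>_si.tif` (32-bit float score maps at the
#' working resolution), and `<stem>_result.json` (prompts, the three SAM4SIS
#' scores, selected index, and a provenance record with config hash, bank
#' hash, seed and package version).
#'
#' @param image_path Input PNG/TIFF path.
#' @param bank_path Path to a bank archive from [save_bank()] (or a
#'   `memory_bank` object).
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created).
#' @return The [segment_image()] result, invisibly.
#' @export
run_pipeline <- function(image_path, bank_path, config = pipeline_config(),
                         out_dir = ".") {
  image <- load_raster(image_path)
  bank <- if (inherits(bank_path, "memory_bank")) bank_path else load_bank(bank_path)
  out <- segment_image(image, bank, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- tools::file_path_sans_ext(basename(image_path))
  save_mask(out$mask, file.path(out_dir, paste0(stem, "_mask.png")))
  save_scoremap(out$anomaly, file.path(out_dir, paste0(stem, "_anomaly.tif")))
  save_scoremap(out$si, file.path(out_dir, paste0(stem, "_si.tif")))
  res <- out$result
  payload <- list(
    image = basename(image_path),
    prompts = list(positives = unname(apply(res$prompts$positives, 1, as.list)),
                   negative = if (is.null(res$prompts$negative)) NULL
                              else as.list(unname(res$prompts$negative)),
                   threshold = res$prompts$threshold,
                   no_instrument = res$prompts$no_instrument,
                   fallback = res$prompts$fallback),
    sam4sis_scores = res$sam4sis_scores,
    confidences = res$confidences,
    selected_index = res$selected_index,
    provenance = list(config_hash = config_hash(config),
                      bank_hash = bank_hash(bank),
                      seed = config$seed,
                      package = as.character(packageVersion("sisegment")),
                      r_version = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(payload, file.path(out_dir, paste0(stem, "_result.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
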