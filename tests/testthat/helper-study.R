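# The benchmark study (50 nominal / 10 calibration / 200 evaluation scenes
# per domain, seed 0) is expensive, so it is computed once per test run and
# shared between the acceptance blocks that probe it.

.study_cache <- new.env(parent = emptyenv())

study <- function(domain) {
  if (is.null(.study_cache[[domain]]))
    .study_cache[[domain]] <- run_benchmark(domain, seed = 0)
  .study_cache[[domain]]
}

# a small calibrated bank + config for pipeline-level tests (fast)
.tiny_cache <- new.env(parent = emptyenv())

tiny_rgb_setup <- function() {
  if (is.null(.tiny_cache$rgb)) {
    cfg <- pipeline_config(filter = "rgb", working_shape = c(64L, 64L))
    nsp <- scene_spec("rgb", shape = c(64, 64), n_instruments = 0)
    isp <- scene_spec("rgb", shape = c(64, 64))
    nominal <- lapply(1:6, function(i) generate_rgb_scene(nsp, seed = i)$image)
    calib <- lapply(1:3, function(i) generate_rgb_scene(isp, seed = 100 + i)$image)
    .tiny_cache$rgb <- list(cfg = cfg, nominal = nominal, isp = isp,
                            bank = build_bank(nominal, cfg, calib))
  }
  .tiny_cache$rgb
}
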