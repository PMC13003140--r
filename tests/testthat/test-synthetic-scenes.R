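test_that("scene specs validate their fields", {
  expect_error(scene_spec("rgb", n_instruments = 4), "invalid spec")
  expect_error(scene_spec("rgb", shape = c(4, 4)), "invalid spec")
  expect_error(scene_spec("rgb", instrument_width_frac = 0), "invalid spec")
  expect_error(generate_rgb_scene(scene_spec("intensity")), "domain")
  expect_error(generate_intensity_scene(scene_spec("rgb")), "domain")
  expect_identical(scene_spec("intensity")$shape, c(92L, 256L))
  expect_identical(scene_spec("rgb")$shape, c(128L, 128L))
})

test_that("generators are pure functions of spec and seed", {
  for (domain in c("rgb", "intensity")) {
    sp <- scene_spec(domain)
    a <- generate_scene(sp, seed = 17)
    b <- generate_scene(sp, seed = 17)
    expect_identical(a, b)
    c_ <- generate_scene(sp, seed = 18)
    expect_false(identical(a$image, c_$image))
  }
})

test_that("nominal scenes carry no instrument, mask, or shadow", {
  rgb0 <- generate_rgb_scene(scene_spec("rgb", n_instruments = 0), seed = 3)
  expect_false(any(rgb0$truth_mask))
  oct0 <- generate_intensity_scene(scene_spec("intensity", n_instruments = 0),
                                   seed = 3)
  expect_false(any(oct0$truth_mask))
  expect_false(any(oct0$shadow_mask))
  expect_gt(min(oct0$image), 0)
})

test_that("rgb instruments are less saturated than the tissue background", {
  sp <- scene_spec("rgb")
  for (s in 1:50) {
    pair <- generate_rgb_scene(sp, seed = s)
    ch <- rgb_to_channels(pair$image)
    expect_lt(mean(ch$saturation[pair$truth_mask]),
              mean(ch$saturation[!pair$truth_mask]))
  }
})

test_that("intensity scenes have dark shadows and bright instruments", {
  sp <- scene_spec("intensity")
  for (s in 1:50) {
    pair <- generate_intensity_scene(sp, seed = s)
    img <- pair$image
    bg <- !pair$truth_mask & !pair$shadow_mask
    expect_lt(mean(img[pair$shadow_mask]), mean(img[bg]))
    expect_true(all(img[pair$shadow_mask] == 0))
    bands <- bg & img > 0.4
    expect_gt(mean(img[pair$truth_mask]), mean(img[bands]))
    # shadow sits strictly below instrument pixels, never above
    expect_true(all(which(pair$shadow_mask, arr.ind = TRUE)[, 1] >
                      min(which(pair$truth_mask, arr.ind = TRUE)[, 1])))
  }
})

test_that("truth masks are connected with the expected area", {
  for (domain in c("rgb", "intensity")) {
    sp <- scene_spec(domain)
    target <- sp$instrument_width_frac * sp$instrument_length_frac *
      prod(sp$shape)
    for (s in 1:20) {
      pair <- generate_scene(sp, seed = 100 + s)
      for (m in pair$instrument_masks) {
        expect_identical(connected_components(m)$count, 1L)
        expect_lt(abs(sum(m) - target) / target, 0.3)
      }
    }
  }
})

test_that("more speckle strictly lowers the recorded contrast statistic", {
  sigmas <- c(0.15, 0.3, 0.45, 0.6)
  for (s in 1:8) {
    contrasts <- vapply(sigmas, function(sg) {
      sp <- scene_spec("intensity", noise = list(speckle_sigma = sg))
      sisegment:::scene_contrast(generate_intensity_scene(sp, seed = s))
    }, numeric(1))
    expect_true(all(diff(contrasts) < 0))
  }
})

test_that("datasets regenerate byte-identically from their manifest", {
  dir1 <- file.path(tempdir(), "ds1"); dir2 <- file.path(tempdir(), "ds2")
  unlink(c(dir1, dir2), recursive = TRUE)
  sp <- scene_spec("rgb", shape = c(32, 32))
  man <- generate_dataset(sp, n_nominal = 5, n_anomalous = 3, seed = 7,
                          out_dir = dir1)
  expect_length(man$entries, 8)
  expect_length(list.files(file.path(dir1, "nominal")), 5L)
  expect_length(list.files(file.path(dir1, "anomalous")), 3L)
  expect_length(list.files(file.path(dir1, "masks")), 3L)
  generate_dataset(sp, n_nominal = 5, n_anomalous = 3, seed = 7,
                   out_dir = dir2)
  for (rel in vapply(man$entries, `[[`, "", "file")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, rel))),
                     unname(tools::md5sum(file.path(dir2, rel))))
  }
  empty <- file.path(tempdir(), "ds0"); unlink(empty, recursive = TRUE)
  generate_dataset(sp, n_nominal = 2, n_anomalous = 0, seed = 1,
                   out_dir = empty)
  expect_length(list.files(file.path(empty, "masks")), 0L)
})
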