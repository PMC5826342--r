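test_that("an empty field is blank background with empty ground truth", {
  f <- generate_field(const_spec(1), n_cells = 0, seed = 1)
  np <- noise_params()
  expect_equal(nrow(f$ground_truth), 0)
  expect_true(all(f$field$chl == np$bg_chl_gray))
  expect_true(all(f$field$elfa == np$bg_elfa_gray))
})

test_that("zero_fraction = 1 leaves the ELFA channel at background over all cells", {
  sp <- treatment_spec("I1", "inorganic", 858, activity_median_FU = 0.5,
                       zero_fraction = 1)
  f <- generate_field(sp, n_cells = 6, seed = 3)
  expect_true(all(f$ground_truth$true_FU == 0))
  expect_true(all(f$field$elfa == noise_params()$bg_elfa_gray))
  # chlorophyll still carries the cells
  expect_gt(sum(f$field$chl > noise_params()$bg_chl_gray), 0)
})

test_that("a noise-free single cell painted at 10 FU quantifies to 10 within 2%", {
  # oracle: hand arithmetic on painted gray levels. The generator paints
  # gray so that Area*(MGrey-Bg)/(Texp*Fcal) = true_FU; verify directly on
  # the raster, then through the full pipeline.
  f <- generate_field(const_spec(10), n_cells = 1, seed = 11,
                      exposure_ms = 500, calibration_factor = 1)
  img <- f$field
  mask <- img$chl > noise_params()$bg_chl_gray
  n_px <- sum(mask)
  area <- n_px * img$pixel_size_um^2
  mgrey <- mean(img$elfa[mask])
  bg <- median(img$elfa[!mask])
  fu_hand <- area * (mgrey - bg) / (500 * 1)
  expect_equal(fu_hand, 10, tolerance = 0.02)

  cells <- process_field(img)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$felfa_FU, 10, tolerance = 0.02)
})

test_that("fields are bit-identical under the same seed and differ under another", {
  sp <- default_treatments()[5, ]
  a <- generate_field(sp, n_cells = 8, seed = 99)
  b <- generate_field(sp, n_cells = 8, seed = 99)
  c <- generate_field(sp, n_cells = 8, seed = 100)
  expect_identical(a$field$chl, b$field$chl)
  expect_identical(a$field$elfa, b$field$elfa)
  expect_equal(a$ground_truth, b$ground_truth)
  expect_false(identical(a$field$elfa, c$field$elfa))
})

test_that("painted ELFA signal is linear in exposure time", {
  f1 <- generate_field(const_spec(5), n_cells = 3, seed = 21,
                       exposure_ms = 500)
  f2 <- generate_field(const_spec(5), n_cells = 3, seed = 21,
                       exposure_ms = 1000)
  bg <- noise_params()$bg_elfa_gray
  s1 <- sum(f1$field$elfa - bg)
  s2 <- sum(f2$field$elfa - bg)
  expect_equal(s2 / s1, 2, tolerance = 1e-4)  # gray-level quantization
})

test_that("overcrowded fields fail with an explicit error, not an infinite loop", {
  expect_error(
    generate_field(const_spec(1), n_cells = 40, image_shape = c(128L, 128L),
                   seed = 5),
    "too crowded"
  )
})

test_that("parameter sets that would saturate the raster are rejected", {
  expect_error(
    generate_field(const_spec(1e5), n_cells = 1, seed = 1,
                   exposure_ms = 5000),
    "saturation"
  )
})

test_that("read noise that would drive pixels negative is rejected, never clipped", {
  sp <- const_spec(1)
  expect_error(
    generate_field(sp, n_cells = 1, seed = 2,
                   noise = noise_params(read_noise_sd = 2000)),
    "never clipped"
  )
})

test_that("generate_slide assembles a manifest across fields deterministically", {
  sp <- default_treatments()[2, ]
  s1 <- generate_slide(sp, n_fields = 3, cells_per_field = 4, seed = 8)
  s2 <- generate_slide(sp, n_fields = 3, cells_per_field = 4, seed = 8)
  expect_length(s1$fields, 3)
  expect_equal(nrow(s1$ground_truth), 12)
  expect_equal(s1$ground_truth, s2$ground_truth)
  expect_identical(s1$fields[[2]]$elfa, s2$fields[[2]]$elfa)
  # width never exceeds length; cells inside bounds
  expect_true(all(s1$ground_truth$width_um <= s1$ground_truth$length_um))
  expect_true(all(s1$ground_truth$center_row_px > 0 &
                    s1$ground_truth$center_row_px <= 512))
})
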