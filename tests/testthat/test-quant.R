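test_that("F_ELFA follows Area*(MGrey-BgMGrey)/(Texp*Fcal)", {
  # hand arithmetic: 50 * 100 / 500 = 10
  expect_equal(compute_felfa(50, 200, 100, exposure_ms = 500), 10)
  # zero-signal identity
  expect_equal(compute_felfa(50, 150, 150, exposure_ms = 500), 0)
  # linearity: doubling area doubles F_ELFA
  expect_equal(compute_felfa(100, 200, 100, exposure_ms = 500), 20)
  # homogeneity of degree 1 in net gray
  expect_equal(compute_felfa(50, 300, 100, exposure_ms = 500),
               2 * compute_felfa(50, 200, 100, exposure_ms = 500))
  # calibration factor divides
  expect_equal(compute_felfa(50, 200, 100, exposure_ms = 500,
                             calibration_factor = 2), 5)
})

test_that("negative net gray is clamped to zero with a QC message", {
  expect_message(
    out <- compute_felfa(c(50, 50), c(90, 200), c(100, 100),
                         exposure_ms = 500),
    "1 cell"
  )
  expect_equal(out, c(0, 10))
})

test_that("nonpositive exposure or calibration are precondition errors", {
  expect_error(compute_felfa(50, 200, 100, exposure_ms = 0), "exposure")
  expect_error(compute_felfa(50, 200, 100, exposure_ms = 500,
                             calibration_factor = 0), "calibration")
})

test_that("incubation normalization divides by the incubation time when enabled", {
  cfg <- quant_config(normalize_by_incubation = TRUE, incubation_h = 3)
  expect_equal(compute_felfa(50, 200, 100, exposure_ms = 500, cfg = cfg),
               10 / 3)
})

test_that("FU to fmol conversion uses the 0.1 fmol/FU factor", {
  expect_equal(to_fmol(1.6), 0.16)
  expect_equal(to_fmol(0.4), 0.04)
  expect_equal(to_fmol(0), 0)
  expect_equal(to_fmol(2, quant_config(conversion_fmol_per_FU = 0.2)), 0.4)
})

test_that("prolate-spheroid volume matches its closed forms", {
  # sphere limit: L = 6, Area = pi*3^2 -> W = 6, V = (pi/6) L^3
  v <- cell_volume(6, pi * 9)
  expect_equal(v$width_um, 6)
  expect_equal(v$volume_um3, pi / 6 * 216, tolerance = 1e-12)
  # hand arithmetic: L = 9, A = 15.904 -> W = 2.25, V = 23.86
  v2 <- cell_volume(9, 15.904)
  expect_equal(v2$width_um, 2.25, tolerance = 1e-4)
  expect_equal(v2$volume_um3, 23.86, tolerance = 1e-3)
  # derived width > length: axes swapped with warning, volume unchanged
  # under relabeling of the same two axes
  expect_warning(v3 <- cell_volume(2, pi / 4 * 2 * 8), "swapped")
  expect_equal(v3$volume_um3, pi / 6 * 8 * 4)
  expect_error(cell_volume(-1, 5), "positive")
})

test_that("quantify_cells augments measurements and handles empty input", {
  f <- generate_field(const_spec(2), n_cells = 3, seed = 37)
  cells <- measure_cells(f$field, segment_cells(f$field))
  out <- quantify_cells(cells, f$field)
  expect_true(all(c("felfa_FU", "activity_fmol", "width_um", "volume_um3")
                  %in% names(out)))
  expect_equal(out$activity_fmol, out$felfa_FU * 0.1)
  expect_true(all(out$width_um <= out$length_um))
  empty <- quantify_cells(cells[0, ], f$field)
  expect_equal(nrow(empty), 0)
  expect_true("felfa_FU" %in% names(empty))
})

test_that("quantified F_ELFA is invariant to exposure doubling on simulator output", {
  f1 <- process_field(generate_field(const_spec(5), n_cells = 3, seed = 41,
                                     exposure_ms = 500)$field)
  f2 <- process_field(generate_field(const_spec(5), n_cells = 3, seed = 41,
                                     exposure_ms = 1000)$field)
  expect_equal(f1$felfa_FU, f2$felfa_FU, tolerance = 1e-3)
})

test_that("quantified F_ELFA is invariant to a uniform ELFA background offset", {
  f <- generate_field(const_spec(5), n_cells = 4, seed = 43)$field
  base <- process_field(f)
  f$elfa <- f$elfa + 321L
  shifted <- process_field(f)
  expect_equal(shifted$felfa_FU, base$felfa_FU)
})
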