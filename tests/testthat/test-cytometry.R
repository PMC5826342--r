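test_that("blank and flat fields segment to zero labels", {
  np <- noise_params()
  blank <- field_image(matrix(np$bg_chl_gray, 64, 64),
                       matrix(np$bg_elfa_gray, 64, 64),
                       exposure_ms_elfa = 500)
  expect_equal(max(segment_cells(blank)), 0)
  zero <- field_image(matrix(0L, 64, 64), matrix(0L, 64, 64),
                      exposure_ms_elfa = 500)
  expect_equal(max(segment_cells(zero)), 0)
})

test_that("noise-free fields segment to exactly the painted masks", {
  f <- generate_field(default_treatments()[3, ], n_cells = 5, seed = 17)
  labels <- segment_cells(f$field)
  expect_equal(max(labels), 5)
  # every labeled pixel is a painted pixel and vice versa
  painted <- f$field$chl > noise_params()$bg_chl_gray
  expect_identical(labels > 0, painted)
})

test_that("border-touching cells are excluded under the default policy", {
  np <- noise_params()
  chl <- matrix(np$bg_chl_gray, 128L, 128L)
  elfa <- matrix(np$bg_elfa_gray, 128L, 128L)
  # disc of radius 15 px centered on the border
  for (r in 1:128) for (c in 1:128) {
    if ((r - 1)^2 + (c - 64)^2 <= 15^2) chl[r, c] <- np$chl_cell_gray
  }
  f <- field_image(chl, elfa, exposure_ms_elfa = 500)
  expect_equal(max(segment_cells(f)), 0)
  expect_equal(max(segment_cells(f, exclude_border = FALSE)), 1)
})

test_that("objects below the minimum equivalent diameter are filtered", {
  np <- noise_params()
  chl <- matrix(np$bg_chl_gray, 128L, 128L)
  # a 3x3 blob: equivalent diameter ~0.37 um at 0.11 um/px, below 2 um
  chl[60:62, 60:62] <- np$chl_cell_gray
  f <- field_image(chl, matrix(np$bg_elfa_gray, 128L, 128L),
                   exposure_ms_elfa = 500)
  expect_equal(max(segment_cells(f)), 0)
  expect_equal(max(segment_cells(f, min_equiv_diameter_um = 0)), 1)
})

test_that("measurements recover painted geometry and gray statistics", {
  f <- generate_field(const_spec(2), n_cells = 4, seed = 23)
  labels <- segment_cells(f$field)
  cells <- measure_cells(f$field, labels)
  cells <- match_ground_truth(cells, f$ground_truth)
  expect_equal(nrow(cells), 4)
  # measured area equals painted-mask area exactly in pixels
  painted_px <- tabulate(labels[labels > 0])
  expect_identical(cells$n_px, as.integer(painted_px[cells$cell_id]))
  # major-axis length within one pixel of ground truth
  expect_true(all(abs(cells$length_um - cells$true_length_um) <=
                    f$field$pixel_size_um * 1.5))
  # background recovered exactly on noise-free fields
  expect_true(all(cells$bg_mean_gray_elfa == noise_params()$bg_elfa_gray))
})

test_that("a flat ELFA image yields zero net gray for every cell", {
  f <- generate_field(const_spec(1), n_cells = 3, seed = 29)
  img <- f$field
  img$elfa[] <- 500L
  cells <- measure_cells(img, segment_cells(img))
  expect_true(all(cells$mean_gray_elfa - cells$bg_mean_gray_elfa == 0))
})

test_that("uniform ELFA offsets cancel in background subtraction", {
  f <- generate_field(const_spec(4), n_cells = 5, seed = 31)
  labels <- segment_cells(f$field)
  base <- measure_cells(f$field, labels)
  shifted <- f$field
  shifted$elfa <- shifted$elfa + 123L
  offs <- measure_cells(shifted, labels)
  expect_equal(offs$mean_gray_elfa - offs$bg_mean_gray_elfa,
               base$mean_gray_elfa - base$bg_mean_gray_elfa)
})

test_that("tiny labels are skipped with a warning", {
  np <- noise_params()
  chl <- matrix(np$bg_chl_gray, 64L, 64L)
  chl[10:30, 10:20] <- np$chl_cell_gray  # a real object
  labels <- matrix(0L, 64, 64)
  labels[10:30, 10:20] <- 1L
  labels[50, 50] <- 2L                   # 1-px label
  f <- field_image(chl, matrix(np$bg_elfa_gray, 64L, 64L),
                   exposure_ms_elfa = 500)
  expect_warning(cells <- measure_cells(f, labels), "<4 pixels")
  expect_equal(nrow(cells), 1)
})

test_that("per-field subsampling reproduces the 3-6 cells/field protocol", {
  cells <- tibble::tibble(
    field_id = rep(sprintf("f%02d", 1:30), each = 10),
    cell_id = rep(1:10, 30)
  )
  sub <- subsample_cells(cells, k_range = c(3, 6), seed = 5)
  per_field <- table(sub$field_id)
  expect_true(all(per_field >= 3 & per_field <= 6))
  # 30 fields x 3-6 cells: 90-180 cells per slide
  expect_gte(nrow(sub), 90)
  expect_lte(nrow(sub), 180)
  # determinism and the identity case
  expect_equal(subsample_cells(cells, c(3, 6), seed = 5), sub)
  expect_equal(subsample_cells(cells, c(10, 10), seed = 1), cells)
})
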