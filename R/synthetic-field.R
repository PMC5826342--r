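#' Noise and rendering parameters for synthetic fields
#'
#' Controls background gray levels and the (off-by-default) noise model of the
#' synthetic field generator: Poisson shot noise on pixel signal and additive
#' Gaussian read noise.
#'
#' @param shot_noise Apply Poisson shot noise to both channels?
#' @param read_noise_sd Standard deviation of additive Gaussian read noise
#'   (gray levels); 0 disables it.
#' @param bg_chl_gray,bg_elfa_gray Uniform background gray level of the
#'   chlorophyll and ELFA channel.
#' @param chl_cell_gray Gray level of cell interiors on the chlorophyll
#'   channel (must exceed `bg_chl_gray`).
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(shot_noise = FALSE, read_noise_sd = 0,
                         bg_chl_gray = 100, bg_elfa_gray = 200,
                         chl_cell_gray = 20000) {
  stopifnot(read_noise_sd >= 0, bg_chl_gray >= 0, bg_elfa_gray >= 0,
            chl_cell_gray > bg_chl_gray)
  structure(
    list(shot_noise = isTRUE(shot_noise), read_noise_sd = read_noise_sd,
         bg_chl_gray = bg_chl_gray, bg_elfa_gray = bg_elfa_gray,
         chl_cell_gray = chl_cell_gray),
    class = "noise_params"
  )
}

MAX_GRAY <- 65535L  # 16-bit unsigned rasters

# Logical mask of a filled ellipse, restricted to its bounding box.
# a, b: semi-axes in px; theta: orientation (rad, from row axis).
# Returns list(rows, cols, mask) with mask a logical matrix over the box.
ellipse_box_mask <- function(center_rc, a, b, theta, shape) {
  half <- ceiling(max(a, b)) + 1L
  r0 <- center_rc[1]; c0 <- center_rc[2]
  rows <- max(1L, floor(r0) - half):min(shape[1], ceiling(r0) + half)
  cols <- max(1L, floor(c0) - half):min(shape[2], ceiling(c0) + half)
  dr <- rows - r0
  dc <- cols - c0
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dr, dc, function(x, y) x * ct + y * st)
  v <- outer(dr, dc, function(x, y) -x * st + y * ct)
  list(rows = rows, cols = cols, mask = (u / a)^2 + (v / b)^2 <= 1)
}

#' Generate one synthetic two-channel field with known per-cell ground truth
#'
#' Renders a microscope field as the acquisition system would record it:
#' cells are prolate spheroids seen in projection, drawn as filled ellipses on
#' the chlorophyll channel, and their phosphatase activity is painted on the
#' ELFA channel such that the cell-associated fluorescence
#' \eqn{F_{ELFA} = Area \times (MGrey - BgMGrey) / (T_{exp} \times F_{cal})}
#' recovers each cell's true activity exactly (up to gray-level quantization).
#' Cells never overlap and never touch the field border; placement failure
#' after bounded retries raises a "field too crowded" error.
#'
#' The painted ELFA signal is linear in `exposure_ms`, so downstream
#' quantification is exposure-invariant by construction. Pixel values are
#' 16-bit; a parameter set that would saturate (or, with read noise, drive a
#' pixel negative) is rejected rather than clipped.
#'
#' @param spec A one-row [treatment_spec()].
#' @param n_cells Number of cells to place (>= 0).
#' @param image_shape Integer `(rows, cols)` of the rasters.
#' @param exposure_ms ELFA channel exposure time (ms).
#' @param calibration_factor Fluorescence calibration factor F_cal.
#' @param pixel_size_um Pixel size (um/px); default 0.11 um/px, plausible for
#'   a 60x objective.
#' @param noise A [noise_params()] object; noise is off by default.
#' @param seed Integer seed; the same (spec, seed) yields bit-identical
#'   images.
#' @param field_id,slide_id Identifiers stored in the result.
#' @param max_tries Placement retries per cell before failing.
#' @return A list with elements `field` (a [field_image()]) and
#'   `ground_truth` (a tibble with one row per cell: `field_id`, `cell_id`,
#'   `center_row_px`, `center_col_px`, `length_um`, `width_um`,
#'   `orientation_rad`, `true_FU`).
#' @examples
#' spec <- default_treatments()[3, ]
#' f <- generate_field(spec, n_cells = 5, seed = 1)
#' f$ground_truth
#' @export
generate_field <- function(spec, n_cells, image_shape = c(512L, 512L),
                           exposure_ms = 500, calibration_factor = 1,
                           pixel_size_um = 0.11,
                           noise = noise_params(), seed,
                           field_id = "field_1", slide_id = "slide_1",
                           max_tries = 500L) {
  stopifnot(inherits(spec, "treatment_spec"), nrow(spec) == 1,
            n_cells >= 0, length(image_shape) == 2, all(image_shape >= 16),
            inherits(noise, "noise_params"))
  if (missing(seed)) stop("`seed` is required for reproducible fields",
                          call. = FALSE)
  shape <- as.integer(image_shape)

  withr::with_seed(seed, {
    chl <- matrix(noise$bg_chl_gray, shape[1], shape[2])
    elfa <- matrix(noise$bg_elfa_gray, shape[1], shape[2])

    truth <- tibble::tibble(
      field_id = character(0), cell_id = integer(0),
      center_row_px = numeric(0), center_col_px = numeric(0),
      length_um = numeric(0), width_um = numeric(0),
      orientation_rad = numeric(0), true_FU = numeric(0)
    )

    if (n_cells > 0) {
      lengths_um <- stats::runif(n_cells, spec$cell_length_um_min,
                                 spec$cell_length_um_max)
      aspect <- stats::runif(n_cells, spec$aspect_ratio_min,
                             spec$aspect_ratio_max)
      widths_um <- lengths_um / aspect
      thetas <- stats::runif(n_cells, 0, 2 * pi)
      true_FU <- draw_activities(spec, n_cells)

      a_px <- lengths_um / 2 / pixel_size_um   # semi-major, px
      b_px <- widths_um / 2 / pixel_size_um
      centers <- matrix(NA_real_, n_cells, 2)
      # non-overlap via bounding circles (semi-major + 2 px gap);
      # borders kept clear so border exclusion never triggers on truth cells
      margin <- ceiling(a_px) + 3
      for (i in seq_len(n_cells)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          r0 <- stats::runif(1, 1 + margin[i], shape[1] - margin[i])
          c0 <- stats::runif(1, 1 + margin[i], shape[2] - margin[i])
          if (i == 1) {
            ok <- TRUE
          } else {
            prev <- seq_len(i - 1)
            d <- sqrt((centers[prev, 1] - r0)^2 + (centers[prev, 2] - c0)^2)
            ok <- all(d > a_px[i] + a_px[prev] + 2)
          }
          if (ok) {
            centers[i, ] <- c(r0, c0)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("field too crowded: could not place cell ", i, " of ",
               n_cells, " after ", max_tries, " tries", call. = FALSE)
        }
      }

      texp_fcal <- exposure_ms * calibration_factor
      px_area_um2 <- pixel_size_um^2
      for (i in seq_len(n_cells)) {
        eb <- ellipse_box_mask(centers[i, ], a_px[i], b_px[i], thetas[i],
                               shape)
        n_px <- sum(eb$mask)
        # chlorophyll: filled ellipse at constant gray
        sub <- chl[eb$rows, eb$cols]
        sub[eb$mask] <- noise$chl_cell_gray
        chl[eb$rows, eb$cols] <- sub

        # ELFA: distribute the exact integer gray total that inverts the
        # F_ELFA equation, so quantization error is < 1 gray over the cell
        total_gray <- true_FU[i] * texp_fcal / px_area_um2
        base <- floor(total_gray / n_px)
        rem <- round(total_gray - base * n_px)
        add <- rep(base, n_px)
        if (rem > 0) add[seq_len(rem)] <- add[seq_len(rem)] + 1
        if (noise$bg_elfa_gray + base + 1 > MAX_GRAY) {
          stop("ELFA saturation: cell ", i, " requires gray ",
               noise$bg_elfa_gray + base + 1, " > ", MAX_GRAY,
               "; reduce activity, exposure or calibration factor",
               call. = FALSE)
        }
        sub <- elfa[eb$rows, eb$cols]
        sub[eb$mask] <- sub[eb$mask] + add
        elfa[eb$rows, eb$cols] <- sub
      }

      truth <- tibble::tibble(
        field_id = field_id, cell_id = seq_len(n_cells),
        center_row_px = centers[, 1], center_col_px = centers[, 2],
        length_um = lengths_um, width_um = widths_um,
        orientation_rad = thetas, true_FU = true_FU
      )
    }

    if (noise$shot_noise) {
      chl[] <- stats::rpois(length(chl), chl)
      elfa[] <- stats::rpois(length(elfa), elfa)
    }
    if (noise$read_noise_sd > 0) {
      chl[] <- chl + stats::rnorm(length(chl), 0, noise$read_noise_sd)
      elfa[] <- elfa + stats::rnorm(length(elfa), 0, noise$read_noise_sd)
      chl[] <- round(chl)
      elfa[] <- round(elfa)
      if (min(chl) < 0 || min(elfa) < 0) {
        stop("read noise drove pixels negative; negative intensities are ",
             "never clipped - lower `read_noise_sd` or raise the background",
             call. = FALSE)
      }
    }
    if (max(chl) > MAX_GRAY || max(elfa) > MAX_GRAY) {
      stop("raster saturation after noise; reduce signal or noise levels",
           call. = FALSE)
    }
    storage.mode(chl) <- "integer"
    storage.mode(elfa) <- "integer"

    list(
      field = field_image(chl, elfa, exposure_ms_elfa = exposure_ms,
                          calibration_factor = calibration_factor,
                          pixel_size_um = pixel_size_um,
                          field_id = field_id, slide_id = slide_id),
      ground_truth = truth
    )
  })
}

#' Generate a slide's worth of fields for one treatment
#'
#' Convenience wrapper around [generate_field()]: renders `n_fields` fields
#' with `cells_per_field` cells each (one seed per field, derived from
#' `seed`), returning the fields and the combined ground-truth manifest.
#'
#' @inheritParams generate_field
#' @param n_fields Number of fields (the acquisition protocol images 30
#'   randomly selected fields per slide).
#' @param cells_per_field Cells per field; either a single count or a
#'   length-2 range sampled uniformly per field.
#' @return List with `fields` (list of `field_image`) and `ground_truth`
#'   (tibble over all fields).
#' @export
generate_slide <- function(spec, n_fields = 30, cells_per_field = 12,
                           seed, slide_id = spec$code[1], ...) {
  stopifnot(n_fields >= 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  rng <- range(cells_per_field)
  field_seeds <- withr::with_seed(seed, {
    sample.int(.Machine$integer.max - 1L, n_fields + 1L)
  })
  n_cells <- withr::with_seed(field_seeds[n_fields + 1L], {
    if (rng[1] == rng[2]) rep(rng[1], n_fields)
    else sample(rng[1]:rng[2], n_fields, replace = TRUE)
  })
  out <- purrr::map(seq_len(n_fields), function(i) {
    generate_field(spec, n_cells = n_cells[i], seed = field_seeds[i],
                   field_id = sprintf("%s_field_%02d", slide_id, i),
                   slide_id = slide_id, ...)
  })
  list(
    fields = purrr::map(out, "field"),
    ground_truth = purrr::list_rbind(purrr::map(out, "ground_truth"))
  )
}
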