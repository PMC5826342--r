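#' Quantification configuration
#'
#' @param conversion_fmol_per_FU Conversion from relative fluorescence units
#'   to hydrolyzed substrate, fmol per FU; default 0.1 (calibrated against
#'   natural lake plankton in the original assay development).
#' @param incubation_h Substrate incubation time (h); the standard protocol
#'   is 3 h at room temperature.
#' @param normalize_by_incubation Divide F_ELFA additionally by
#'   `incubation_h`? Off by default: the standard F_ELFA formula contains no
#'   incubation term and its output is conventionally reported per hour
#'   under the fixed 3-h protocol. Enable for cross-protocol comparisons.
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(conversion_fmol_per_FU = 0.1, incubation_h = 3,
                         normalize_by_incubation = FALSE) {
  stopifnot(conversion_fmol_per_FU > 0, incubation_h > 0)
  structure(
    list(conversion_fmol_per_FU = conversion_fmol_per_FU,
         incubation_h = incubation_h,
         normalize_by_incubation = isTRUE(normalize_by_incubation)),
    class = "quant_config"
  )
}

#' Cell-associated ELFA fluorescence
#'
#' The central quantity of the assay:
#' \deqn{F_{ELFA} = \frac{Area \times (MGrey - BgMGrey)}{T_{exp} \times F_{cal}}}
#' in relative fluorescence units (FU) cell^-1 h^-1, where `Area` (um^2) is
#' the projected cell area, `MGrey` the mean ELFA gray level over the cell,
#' `BgMGrey` the background gray level, `Texp` (ms) the exposure time and
#' `Fcal` the dimensionless calibration factor. A cell cannot hydrolyze
#' substrate negatively: negative net gray is clamped to 0 and the number of
#' clamped cells is reported via a message (QC signal).
#'
#' @param area_um2 Projected cell area(s), um^2.
#' @param mean_gray,bg_gray Mean cell and background gray on the ELFA
#'   channel.
#' @param exposure_ms Exposure time (ms), > 0.
#' @param calibration_factor Calibration factor, > 0.
#' @param cfg A [quant_config()].
#' @return Numeric vector of F_ELFA values (FU cell^-1 h^-1).
#' @examples
#' compute_felfa(50, 200, 100, exposure_ms = 500)  # 10 FU
#' @export
compute_felfa <- function(area_um2, mean_gray, bg_gray, exposure_ms,
                          calibration_factor = 1, cfg = quant_config()) {
  if (any(exposure_ms <= 0)) stop("exposure must be positive", call. = FALSE)
  if (any(calibration_factor <= 0)) {
    stop("calibration factor must be positive", call. = FALSE)
  }
  stopifnot(all(area_um2 > 0))
  f <- area_um2 * (mean_gray - bg_gray) / (exposure_ms * calibration_factor)
  n_neg <- sum(f < 0)
  if (n_neg > 0) {
    message(n_neg, " cell(s) with MGrey < BgMGrey clamped to 0")
    f[f < 0] <- 0
  }
  if (cfg$normalize_by_incubation) f <- f / cfg$incubation_h
  f
}

#' Convert relative fluorescence to hydrolyzed phosphate
#'
#' @param felfa_FU F_ELFA value(s), FU cell^-1 h^-1, >= 0.
#' @param cfg A [quant_config()]; the conversion is
#'   `felfa_FU * conversion_fmol_per_FU`.
#' @return Activities in fmol cell^-1 h^-1.
#' @examples
#' to_fmol(1.6)  # 0.16
#' @export
to_fmol <- function(felfa_FU, cfg = quant_config()) {
  stopifnot(all(felfa_FU >= 0))
  felfa_FU * cfg$conversion_fmol_per_FU
}

#' Cell volume from length and projected area (prolate spheroid)
#'
#' Approximates the cell as a prolate spheroid with circular cross-section —
#' the only ellipsoid determined by major-axis length and projected area
#' alone. The projected ellipse has area `A = (pi/4) L W`, so the derived
#' width is `W = 4 A / (pi L)` and the volume `V = (pi/6) L W^2`. If the
#' derived width exceeds the length the axes are swapped with a warning
#' (the symmetry axis is always the longer one).
#'
#' @param length_um Major-axis length(s), um, > 0.
#' @param area_um2 Projected area(s), um^2, > 0.
#' @return A tibble with `width_um` and `volume_um3`.
#' @examples
#' cell_volume(6, pi * 9)    # sphere: V = (pi/6) 6^3 = 113.1 um^3
#' cell_volume(9, 15.904)    # W = 2.25, V = 23.86 um^3
#' @export
cell_volume <- function(length_um, area_um2) {
  if (any(length_um <= 0) || any(area_um2 <= 0)) {
    stop("length and area must be positive", call. = FALSE)
  }
  w <- 4 * area_um2 / (pi * length_um)
  l <- length_um
  swap <- w > l
  if (any(swap)) {
    warning(sum(swap), " cell(s) with derived width > length; axes swapped",
            call. = FALSE)
    tmp <- l[swap]
    l[swap] <- w[swap]
    w[swap] <- tmp
  }
  tibble::tibble(width_um = w, volume_um3 = pi / 6 * l * w^2)
}

#' Quantify measured cells: activity and volume
#'
#' Augments a per-cell measurement table with the FLEA results: `felfa_FU`
#' (FU cell^-1 h^-1), `activity_fmol` (fmol cell^-1 h^-1), `width_um` and
#' `volume_um3`.
#'
#' @param cells Measurement tibble from [measure_cells()].
#' @param field The [field_image()] the cells were measured on (supplies
#'   exposure and calibration).
#' @param cfg A [quant_config()].
#' @return The input tibble with the four result columns appended.
#' @export
quantify_cells <- function(cells, field, cfg = quant_config()) {
  stopifnot(is.data.frame(cells), inherits(field, "field_image"))
  if (nrow(cells) == 0) {
    return(dplyr::mutate(cells, felfa_FU = numeric(0),
                         activity_fmol = numeric(0), width_um = numeric(0),
                         volume_um3 = numeric(0)))
  }
  felfa <- compute_felfa(cells$area_um2, cells$mean_gray_elfa,
                         cells$bg_mean_gray_elfa,
                         exposure_ms = field$exposure_ms_elfa,
                         calibration_factor = field$calibration_factor,
                         cfg = cfg)
  vol <- cell_volume(cells$length_um, cells$area_um2)
  dplyr::mutate(cells, felfa_FU = felfa, activity_fmol = to_fmol(felfa, cfg),
                width_um = vol$width_um, volume_um3 = vol$volume_um3)
}

#' Run the full per-field pipeline: segment, measure, quantify
#'
#' @param field A [field_image()].
#' @param cfg A [quant_config()].
#' @param ... Passed to [segment_cells()].
#' @return Per-cell activity tibble (see [quantify_cells()]).
#' @export
process_field <- function(field, cfg = quant_config(), ...) {
  labels <- segment_cells(field, ...)
  cells <- measure_cells(field, labels)
  quantify_cells(cells, field, cfg)
}

#' Simulate and analyze one treatment end to end
#'
#' Generates a slide of synthetic fields for a treatment, runs the imaging
#' pipeline on every field, and joins the recovered per-cell activities to
#' the ground truth.
#'
#' @inheritParams generate_slide
#' @param cfg A [quant_config()].
#' @param ... Passed to [generate_slide()] (noise, exposure, ...).
#' @return Per-cell tibble with recovered (`felfa_FU`, `activity_fmol`,
#'   `volume_um3`, ...) and true (`true_FU`, ...) values.
#' @examples
#' \donttest{
#' spec <- default_treatments()[3, ]
#' cells <- simulate_treatment_cells(spec, n_fields = 5, seed = 1)
#' median(cells$activity_fmol)
#' }
#' @export
simulate_treatment_cells <- function(spec, n_fields = 30,
                                     cells_per_field = 12, seed,
                                     cfg = quant_config(), ...) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  slide <- generate_slide(spec, n_fields = n_fields,
                          cells_per_field = cells_per_field, seed = seed,
                          ...)
  cells <- purrr::list_rbind(
    purrr::map(slide$fields, process_field, cfg = cfg)
  )
  cells <- match_ground_truth(cells, slide$ground_truth)
  dplyr::mutate(cells, variant = spec$code[1], p_source = spec$p_source[1],
                .before = 1)
}
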