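#' Define a culture treatment for the synthetic-data generator
#'
#' A treatment describes one experimental variant of the semi-continuous
#' *Coccomyxa* cultures: its phosphorus source and concentration, the
#' distribution of single-cell phosphatase activity it induces, and the cell
#' size range. Cells in a treatment are inactive (activity exactly 0) with
#' probability `zero_fraction`; active cells draw their activity (relative
#' fluorescence units, FU cell^-1 h^-1) from a log-normal distribution.
#'
#' When `zero_fraction < 0.5`, `activity_median_FU` is the median of the whole
#' population (zeros included): the log-normal location is shifted so that the
#' mixture median equals the requested value. When `zero_fraction >= 0.5` the
#' population median is 0 by construction, so `activity_median_FU` is
#' interpreted as the median of the *active* subpopulation.
#'
#' @param code Treatment label, one of `"I1"`, `"I2"`, `"I3"`, `"O1"`, `"O2"`,
#'   `"O3"` (I = inorganic orthophosphate, O = organic beta-glycerol
#'   phosphate; 1 = P-replete, 2-3 = P-depleted).
#' @param p_source `"inorganic"` or `"organic"`.
#' @param p_conc_umol_L Phosphorus concentration of the medium (umol P / L).
#' @param activity_median_FU Median single-cell activity (FU cell^-1 h^-1);
#'   see Details for the zero-fraction convention.
#' @param activity_sigma_log Log-scale standard deviation of the active-cell
#'   activity distribution.
#' @param zero_fraction Proportion of cells with no detectable activity.
#' @param cell_length_um_range Length-2 numeric, uniform range of cell major
#'   axis length (um).
#' @param aspect_ratio_range Length-2 numeric >= 1, uniform range of
#'   length/width aspect ratio.
#' @return A one-row tibble of class `treatment_spec`.
#' @export
treatment_spec <- function(code,
                           p_source = c("inorganic", "organic"),
                           p_conc_umol_L,
                           activity_median_FU,
                           activity_sigma_log = 0.8,
                           zero_fraction = 0,
                           cell_length_um_range = c(5.3, 6.5),
                           aspect_ratio_range = c(1.9, 2.1)) {
  p_source <- match.arg(p_source)
  stopifnot(
    code %in% c("I1", "I2", "I3", "O1", "O2", "O3"),
    is.numeric(p_conc_umol_L), p_conc_umol_L > 0,
    activity_median_FU >= 0, activity_sigma_log >= 0,
    zero_fraction >= 0, zero_fraction <= 1,
    length(cell_length_um_range) == 2,
    all(cell_length_um_range > 0),
    cell_length_um_range[1] <= cell_length_um_range[2],
    length(aspect_ratio_range) == 2,
    all(aspect_ratio_range >= 1),
    aspect_ratio_range[1] <= aspect_ratio_range[2]
  )
  out <- tibble::tibble(
    code = code,
    p_source = p_source,
    p_conc_umol_L = p_conc_umol_L,
    activity_median_FU = activity_median_FU,
    activity_sigma_log = activity_sigma_log,
    zero_fraction = zero_fraction,
    cell_length_um_min = cell_length_um_range[1],
    cell_length_um_max = cell_length_um_range[2],
    aspect_ratio_min = aspect_ratio_range[1],
    aspect_ratio_max = aspect_ratio_range[2]
  )
  class(out) <- c("treatment_spec", class(out))
  out
}

#' Default treatment specifications for the six experimental variants
#'
#' Returns the six calibrated treatments (I1-I3, O1-O3) used throughout the
#' package as the reference study conditions. Activity medians are calibrated
#' so that, with the standard 0.1 fmol/FU conversion, the P-depleted variants
#' I3 and O3 have median activities of 0.04 and 0.16 fmol cell^-1 h^-1, the
#' organic:inorganic ratio of P-depleted medians (O2:I2) is 10-fold, and the
#' P-replete variants are dominated by inactive cells. Cell sizes are set so
#' the mean prolate-spheroid volume is ~27 um^3 in P-replete and ~45 um^3 in
#' P-depleted variants.
#'
#' @return A tibble with one row per treatment (class `treatment_spec`).
#' @examples
#' default_treatments()
#' @export
default_treatments <- function() {
  replete_len <- c(5.3, 6.5)
  depleted_len <- c(6.3, 7.7)
  specs <- list(
    treatment_spec("I1", "inorganic", 858, activity_median_FU = 0.01,
                   zero_fraction = 0.6, cell_length_um_range = replete_len),
    treatment_spec("I2", "inorganic", 16, activity_median_FU = 0.25,
                   zero_fraction = 0.05, cell_length_um_range = depleted_len),
    treatment_spec("I3", "inorganic", 10, activity_median_FU = 0.4,
                   zero_fraction = 0.05, cell_length_um_range = depleted_len),
    treatment_spec("O1", "organic", 858, activity_median_FU = 0.05,
                   zero_fraction = 0.8, cell_length_um_range = replete_len),
    treatment_spec("O2", "organic", 16, activity_median_FU = 2.5,
                   zero_fraction = 0.05, cell_length_um_range = depleted_len),
    treatment_spec("O3", "organic", 10, activity_median_FU = 1.6,
                   zero_fraction = 0.05, cell_length_um_range = depleted_len)
  )
  out <- dplyr::bind_rows(specs)
  class(out) <- c("treatment_spec", class(out))
  out
}

#' Draw per-cell ground-truth activities for a treatment
#'
#' Samples `n` single-cell activities from the zero-inflated log-normal model
#' of a treatment spec (see [treatment_spec()] for the median convention).
#'
#' @param spec A one-row `treatment_spec`.
#' @param n Number of cells.
#' @return Numeric vector of activities (FU cell^-1 h^-1), zeros included.
#' @keywords internal
draw_activities <- function(spec, n) {
  stopifnot(nrow(spec) == 1, n >= 0)
  if (n == 0) return(numeric(0))
  z <- spec$zero_fraction
  m <- spec$activity_median_FU
  s <- spec$activity_sigma_log
  act <- numeric(n)
  is_zero <- stats::runif(n) < z
  n_act <- sum(!is_zero)
  if (n_act > 0) {
    if (m <= 0) {
      act[!is_zero] <- 0
    } else {
      if (s == 0) {
        act[!is_zero] <- m
      } else {
        meanlog <- log(m)
        if (z < 0.5) {
          # shift so that the mixture median equals m
          meanlog <- meanlog - s * stats::qnorm((0.5 - z) / (1 - z))
        }
        act[!is_zero] <- stats::rlnorm(n_act, meanlog = meanlog, sdlog = s)
      }
    }
  }
  act
}
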