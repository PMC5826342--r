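#' Construct a two-channel microscope field image
#'
#' A field image holds the two co-registered grayscale rasters acquired from
#' one microscope field — the chlorophyll-autofluorescence channel used to
#' locate and size cells, and the ELFA channel carrying the phosphatase
#' activity signal — together with the acquisition metadata needed for
#' quantification: ELFA exposure time (ms), fluorescence calibration factor
#' (dimensionless) and pixel size (um/px).
#'
#' @param chl,elfa Integer matrices of identical dimensions (16-bit range,
#'   values in 0..65535). Rasters are indexed `[row, col]`, 1-based in R.
#' @param exposure_ms_elfa Exposure time of the ELFA channel (ms), > 0.
#' @param calibration_factor Fluorescence calibration factor, > 0.
#' @param pixel_size_um Side length of one pixel (um), > 0.
#' @param field_id,slide_id Identifiers (character).
#' @return An object of class `field_image`.
#' @export
field_image <- function(chl, elfa, exposure_ms_elfa, calibration_factor = 1,
                        pixel_size_um = 0.11, field_id = "field_1",
                        slide_id = "slide_1") {
  if (!is.matrix(chl) || !is.matrix(elfa)) {
    stop("`chl` and `elfa` must be matrices", call. = FALSE)
  }
  if (!identical(dim(chl), dim(elfa))) {
    stop("channel shape mismatch: chl is ", paste(dim(chl), collapse = "x"),
         ", elfa is ", paste(dim(elfa), collapse = "x"), call. = FALSE)
  }
  if (!is.numeric(exposure_ms_elfa) || exposure_ms_elfa <= 0) {
    stop("`exposure_ms_elfa` must be positive", call. = FALSE)
  }
  if (!is.numeric(calibration_factor) || calibration_factor <= 0) {
    stop("`calibration_factor` must be positive", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be positive", call. = FALSE)
  }
  if (min(chl) < 0 || min(elfa) < 0) {
    stop("rasters must be nonnegative", call. = FALSE)
  }
  structure(
    list(
      chl = chl, elfa = elfa,
      exposure_ms_elfa = as.numeric(exposure_ms_elfa),
      calibration_factor = as.numeric(calibration_factor),
      pixel_size_um = as.numeric(pixel_size_um),
      field_id = as.character(field_id),
      slide_id = as.character(slide_id)
    ),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  cat("<field_image> ", x$field_id, " (slide ", x$slide_id, ")\n", sep = "")
  cat("  rasters: ", nrow(x$chl), " x ", ncol(x$chl),
      " px  (", signif(nrow(x$chl) * x$pixel_size_um, 3), " x ",
      signif(ncol(x$chl) * x$pixel_size_um, 3), " um)\n", sep = "")
  cat("  ELFA exposure: ", x$exposure_ms_elfa, " ms;  F_cal: ",
      x$calibration_factor, ";  pixel size: ", x$pixel_size_um, " um/px\n",
      sep = "")
  invisible(x)
}

#' @export
dim.field_image <- function(x) dim(x$chl)
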