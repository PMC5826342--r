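#' Write a field image to paired TIFFs with a JSON metadata sidecar
#'
#' Writes `<field_id>_chl.tif` and `<field_id>_elfa.tif` (single-channel
#' grayscale, 16-bit) plus `<field_id>_meta.json` holding the acquisition
#' metadata. The on-disk representation round-trips losslessly through
#' [read_field()].
#'
#' @param field A [field_image()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_field <- function(field, dir) {
  stopifnot(inherits(field, "field_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    chl = file.path(dir, paste0(field$field_id, "_chl.tif")),
    elfa = file.path(dir, paste0(field$field_id, "_elfa.tif")),
    sidecar = file.path(dir, paste0(field$field_id, "_meta.json"))
  )
  tiff::writeTIFF(field$chl / 65535, paths[["chl"]], bits.per.sample = 16L)
  tiff::writeTIFF(field$elfa / 65535, paths[["elfa"]], bits.per.sample = 16L)
  meta <- list(
    field_id = field$field_id, slide_id = field$slide_id,
    exposure_ms_elfa = field$exposure_ms_elfa,
    calibration_factor = field$calibration_factor,
    pixel_size_um = field$pixel_size_um
  )
  jsonlite::write_json(meta, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

read_gray16 <- function(path) {
  if (!file.exists(path)) {
    stop("TIFF not found: ", path, call. = FALSE)
  }
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) {
                    stop("unreadable TIFF ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(dim(img)) != 2) {
    stop("expected single-channel grayscale TIFF: ", path, call. = FALSE)
  }
  storage.mode(img) <- "integer"
  img
}

#' Read a field image from paired channel TIFFs and a JSON sidecar
#'
#' @param chl_path,elfa_path Paths to the chlorophyll and ELFA channel TIFFs.
#' @param sidecar_path Path to the JSON metadata sidecar. A sidecar without
#'   `calibration_factor` defaults it to 1 with a warning.
#' @return A validated [field_image()].
#' @export
read_field <- function(chl_path, elfa_path, sidecar_path) {
  chl <- read_gray16(chl_path)
  elfa <- read_gray16(elfa_path)
  if (!identical(dim(chl), dim(elfa))) {
    stop("channel shape mismatch between ", chl_path, " (",
         paste(dim(chl), collapse = "x"), ") and ", elfa_path, " (",
         paste(dim(elfa), collapse = "x"), ")", call. = FALSE)
  }
  if (!file.exists(sidecar_path)) {
    stop("sidecar not found: ", sidecar_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$exposure_ms_elfa) || meta$exposure_ms_elfa <= 0) {
    stop("nonpositive or missing exposure_ms_elfa in ", sidecar_path,
         call. = FALSE)
  }
  if (is.null(meta$calibration_factor)) {
    warning("sidecar ", sidecar_path,
            " has no calibration_factor; defaulting to 1", call. = FALSE)
    meta$calibration_factor <- 1
  }
  field_image(
    chl, elfa,
    exposure_ms_elfa = meta$exposure_ms_elfa,
    calibration_factor = meta$calibration_factor,
    pixel_size_um = if (is.null(meta$pixel_size_um)) 0.11 else meta$pixel_size_um,
    field_id = if (is.null(meta$field_id)) "field_1" else meta$field_id,
    slide_id = if (is.null(meta$slide_id)) "slide_1" else meta$slide_id
  )
}

#' Write / read a per-cell table as CSV
#'
#' Persists any per-cell tibble (measurements, activities, ground truth) with
#' one row per cell and stable column order. Numeric values round-trip to at
#' least 1e-9 relative precision; integers round-trip exactly.
#'
#' @param cells A data frame with one row per cell.
#' @param path CSV path.
#' @return `write_cell_table()` returns `path` invisibly; `read_cell_table()`
#'   returns a tibble.
#' @export
write_cell_table <- function(cells, path) {
  stopifnot(is.data.frame(cells))
  readr::write_csv(cells, path)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read a growth series as CSV
#'
#' Layout: `time_days, chl_ug_L, event` with `event` either `"none"` or
#' `"dilution:<factor>"` on the first sample at/after each event.
#'
#' @param series A [growth_series()].
#' @param path CSV path.
#' @export
write_growth_series <- function(series, path) {
  stopifnot(inherits(series, "growth_series"))
  readr::write_csv(tidy.growth_series(series), path)
  invisible(path)
}

#' @rdname write_growth_series
#' @export
read_growth_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("time_days", "chl_ug_L", "event") %in% names(df)))
  is_dil <- startsWith(df$event, "dilution:")
  growth_series(
    df$time_days, df$chl_ug_L,
    dilution_times_days = df$time_days[is_dil],
    dilution_factors = as.numeric(sub("^dilution:", "", df$event[is_dil]))
  )
}

#' Write all fields of a slide into the standard directory layout
#'
#' Produces `dir/<slide_id>/` with paired TIFFs, sidecars, and a
#' `ground_truth.csv` manifest when ground truth is supplied.
#'
#' @param slide Result of [generate_slide()], or a list of `field_image`s.
#' @param dir Parent output directory.
#' @export
write_slide <- function(slide, dir) {
  fields <- if (!is.null(slide$fields)) slide$fields else slide
  slide_dir <- file.path(dir, fields[[1]]$slide_id)
  for (f in fields) write_field(f, slide_dir)
  if (!is.null(slide$ground_truth)) {
    write_cell_table(slide$ground_truth,
                     file.path(slide_dir, "ground_truth.csv"))
  }
  invisible(slide_dir)
}
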