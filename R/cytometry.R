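#' Segment cells on the chlorophyll channel
#'
#' Thresholds the chlorophyll-autofluorescence channel (Otsu by default, or a
#' fixed absolute gray level) and labels connected components. Objects whose
#' area-equivalent diameter is below `min_equiv_diameter_um` are removed —
#' the default 2 um mirrors the retention cutoff of the 2-um-pore filters the
#' samples are collected on — and objects touching the field border are
#' excluded by default, since their projected area is truncated.
#'
#' This replaces the manual cell demarcation of the original image-analysis
#' workflow with an automated scheme; on noise-free synthetic fields it
#' recovers the painted masks exactly (see the package tests).
#'
#' @param field A [field_image()].
#' @param min_equiv_diameter_um Minimum area-equivalent diameter (um);
#'   0 disables the filter.
#' @param exclude_border Drop objects touching the raster border?
#' @param threshold `"otsu"` or `"fixed"`.
#' @param threshold_value Absolute gray level for `threshold = "fixed"`.
#' @return An integer label matrix (0 = background, 1..n = cells), with
#'   labels renumbered consecutively.
#' @export
segment_cells <- function(field, min_equiv_diameter_um = 2,
                          exclude_border = TRUE,
                          threshold = c("otsu", "fixed"),
                          threshold_value = NULL) {
  stopifnot(inherits(field, "field_image"), min_equiv_diameter_um >= 0)
  threshold <- match.arg(threshold)
  chl <- field$chl
  if (length(chl) == 0) stop("empty chlorophyll raster", call. = FALSE)

  if (threshold == "fixed") {
    if (is.null(threshold_value)) {
      stop("`threshold_value` required for fixed thresholding", call. = FALSE)
    }
    thr <- threshold_value
  } else {
    if (diff(range(chl)) == 0) {
      # flat image: nothing to segment
      return(matrix(0L, nrow(chl), ncol(chl)))
    }
    thr <- 65535 * EBImage::otsu(EBImage::Image(chl / 65535),
                                 range = c(0, 1), levels = 65536L)
  }
  mask <- chl > thr
  if (!any(mask)) return(matrix(0L, nrow(chl), ncol(chl)))

  labels <- EBImage::bwlabel(mask)
  labels <- EBImage::imageData(labels)

  drop <- integer(0)
  if (exclude_border) {
    border_labels <- unique(c(labels[1, ], labels[nrow(labels), ],
                              labels[, 1], labels[, ncol(labels)]))
    drop <- setdiff(border_labels, 0L)
  }
  if (min_equiv_diameter_um > 0) {
    counts <- tabulate(labels[labels > 0])
    min_px <- pi * (min_equiv_diameter_um / 2)^2 / field$pixel_size_um^2
    drop <- union(drop, which(counts < min_px))
  }
  if (length(drop)) labels[labels %in% drop] <- 0L

  # renumber consecutively
  kept <- sort(unique(labels[labels > 0]))
  if (length(kept)) {
    remap <- integer(max(kept))
    remap[kept] <- seq_along(kept)
    pos <- labels > 0
    labels[pos] <- remap[labels[pos]]
  }
  storage.mode(labels) <- "integer"
  labels
}

#' Measure per-cell geometry and ELFA gray statistics
#'
#' For each labeled cell: projected area (pixel count x pixel size squared,
#' um^2), major-axis length of the best-fit ellipse from image moments (um),
#' mean gray level of the cell on the ELFA channel (MGrey), and the field's
#' background gray level on the ELFA channel (BgMGrey), estimated over all
#' pixels outside the union of cell masks dilated by 2 px. The background
#' statistic is the median by default (robust to stray ELFA precipitates);
#' `bg_stat = "mean"` reproduces a plain mean-gray background.
#'
#' Labels covering fewer than 4 pixels carry no usable shape information and
#' are skipped with a warning.
#'
#' @param field A [field_image()].
#' @param labels Label matrix from [segment_cells()], same shape as the
#'   rasters.
#' @param bg_stat Background statistic, `"median"` (default) or `"mean"`.
#' @return A tibble with one row per cell: `cell_id`, `field_id`,
#'   `area_um2`, `length_um`, `mean_gray_elfa`, `bg_mean_gray_elfa`,
#'   `centroid_row_px`, `centroid_col_px`, `n_px`.
#' @export
measure_cells <- function(field, labels, bg_stat = c("median", "mean")) {
  stopifnot(inherits(field, "field_image"),
            identical(dim(labels), dim(field$chl)))
  bg_stat <- match.arg(bg_stat)

  empty <- tibble::tibble(
    cell_id = integer(0), field_id = character(0), area_um2 = numeric(0),
    length_um = numeric(0), mean_gray_elfa = numeric(0),
    bg_mean_gray_elfa = numeric(0), centroid_row_px = numeric(0),
    centroid_col_px = numeric(0), n_px = integer(0)
  )
  n_lab <- max(labels)
  if (n_lab == 0) return(empty)

  counts <- tabulate(labels[labels > 0], nbins = n_lab)
  tiny <- which(counts > 0 & counts < 4)
  if (length(tiny)) {
    warning(length(tiny), " label(s) with <4 pixels skipped", call. = FALSE)
    labels[labels %in% tiny] <- 0L
  }
  if (!any(labels > 0)) return(empty)

  # background: outside all masks dilated by 2 px
  brush <- EBImage::makeBrush(5L, shape = "disc")
  dil <- EBImage::dilate(labels > 0, brush)
  bg_px <- field$elfa[!dil]
  if (length(bg_px) == 0) {
    stop("no background pixels left after dilation", call. = FALSE)
  }
  bg <- if (bg_stat == "median") stats::median(bg_px) else mean(bg_px)

  mom <- EBImage::computeFeatures.moment(labels)
  keep <- sort(unique(labels[labels > 0]))
  ps <- field$pixel_size_um

  elfa_sum <- rowsum(as.numeric(field$elfa[labels > 0]),
                     group = labels[labels > 0])
  npx <- counts[keep]

  tibble::tibble(
    cell_id = as.integer(keep),
    field_id = field$field_id,
    area_um2 = npx * ps^2,
    length_um = mom[keep, "m.majoraxis"] * ps,
    mean_gray_elfa = as.numeric(elfa_sum[, 1]) / npx,
    bg_mean_gray_elfa = bg,
    centroid_row_px = mom[keep, "m.cx"],
    centroid_col_px = mom[keep, "m.cy"],
    n_px = as.integer(npx)
  )
}

#' Randomly subsample measured cells per field
#'
#' Emulates the acquisition protocol of measuring 3-6 randomly chosen cells
#' per field (90-180 per 30-field slide): for each field an integer k is
#' drawn uniformly from `k_range` and k cells are sampled uniformly without
#' replacement (fields with fewer cells keep all of them).
#'
#' @param cells Per-cell tibble with a `field_id` column.
#' @param k_range Length-2 integer range of cells to keep per field.
#' @param seed Integer seed; the same seed reproduces the same subset.
#' @return The subsampled tibble, original row order preserved.
#' @export
subsample_cells <- function(cells, k_range = c(3L, 6L), seed) {
  stopifnot(is.data.frame(cells), "field_id" %in% names(cells),
            length(k_range) == 2, k_range[1] >= 1,
            k_range[1] <= k_range[2])
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr::with_seed(seed, {
    ks <- seq(k_range[1], k_range[2])
    idx <- unlist(lapply(split(seq_len(nrow(cells)), cells$field_id),
                         function(rows) {
      k <- min(ks[sample.int(length(ks), 1)], length(rows))
      sort(rows[sample.int(length(rows), k)])
    }), use.names = FALSE)
    cells[sort(idx), ]
  })
}

#' Match segmented cells to a ground-truth manifest
#'
#' Joins each measured cell to the nearest ground-truth cell of the same
#' field by centroid distance (used for simulator validation).
#'
#' @param cells Measured-cell tibble (with `field_id`, centroid columns).
#' @param truth Ground-truth tibble from [generate_field()].
#' @param max_dist_px Maximum allowed centroid distance (px).
#' @return `cells` with `true_FU`, `true_length_um`, `true_width_um` and
#'   `match_dist_px` columns appended.
#' @export
match_ground_truth <- function(cells, truth, max_dist_px = 5) {
  stopifnot(is.data.frame(cells), is.data.frame(truth))
  out <- dplyr::group_split(dplyr::group_by(cells, .data$field_id))
  res <- purrr::map(out, function(cc) {
    tt <- truth[truth$field_id == cc$field_id[1], ]
    if (nrow(tt) == 0) {
      return(dplyr::mutate(cc, true_FU = NA_real_,
                           true_length_um = NA_real_,
                           true_width_um = NA_real_,
                           match_dist_px = NA_real_))
    }
    d <- outer(cc$centroid_row_px, tt$center_row_px, "-")^2 +
      outer(cc$centroid_col_px, tt$center_col_px, "-")^2
    j <- apply(d, 1, which.min)
    dist <- sqrt(d[cbind(seq_len(nrow(cc)), j)])
    bad <- dist > max_dist_px
    dplyr::mutate(cc,
                  true_FU = ifelse(bad, NA_real_, tt$true_FU[j]),
                  true_length_um = ifelse(bad, NA_real_, tt$length_um[j]),
                  true_width_um = ifelse(bad, NA_real_, tt$width_um[j]),
                  match_dist_px = dist)
  })
  purrr::list_rbind(res)
}
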