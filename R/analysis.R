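#' Frequency distribution of single-cell activities with geometric bins
#'
#' Builds the per-treatment activity histogram: a separate zero class for
#' cells with no activity (F_ELFA exactly 0 after clamping), an underflow
#' class for cells active but below the first bin edge, and half-open bins
#' `(edge_k, edge_{k+1}]` whose edges follow a geometric progression
#' `edge_k = base * ratio^k`. The defaults (base 0.02 FU, ratio 2) give the
#' class boundaries 0.02, 0.04, ..., 0.32, 0.64, 1.28, ... used when
#' describing activity distributions across several orders of magnitude.
#' Percentages are relative to the total cell count and sum to 100.
#'
#' @param activities Per-cell tibble with a `felfa_FU` column (e.g. from
#'   [quantify_cells()]), or a numeric vector of FU values.
#' @param base_edge_FU First bin edge (FU), > 0.
#' @param ratio Geometric ratio between consecutive edges, > 1.
#' @param n_bins Number of geometric bins; default covers the data maximum.
#' @param variant,species Optional labels stored on the result.
#' @return An object of class `activity_distribution`: a tibble with columns
#'   `class` (`"zero"`, `"underflow"`, `"bin"`), `lower_FU`, `upper_FU`,
#'   `label`, `n`, `pct`; attributes `n_cells`, `base_edge_FU`, `ratio`,
#'   `variant`, `species`, `median_FU`, `median_fmol`, `q25_FU`, `q75_FU`.
#' @examples
#' build_distribution(c(0, 0, 0.5, 1.1), n_bins = 8)
#' @export
build_distribution <- function(activities, base_edge_FU = 0.02, ratio = 2,
                               n_bins = NULL, variant = NA_character_,
                               species = NA_character_) {
  fu <- if (is.data.frame(activities)) activities$felfa_FU else activities
  if (length(fu) == 0) stop("no cells to bin", call. = FALSE)
  stopifnot(base_edge_FU > 0, ratio > 1, all(fu >= 0))

  if (is.null(n_bins)) {
    mx <- max(fu)
    n_bins <- if (mx <= base_edge_FU) 1L
              else ceiling(log(mx / base_edge_FU) / log(ratio))
  }
  stopifnot(n_bins >= 1)
  edges <- base_edge_FU * ratio^(0:n_bins)

  n_zero <- sum(fu == 0)
  n_under <- sum(fu > 0 & fu <= base_edge_FU)
  pos <- fu[fu > base_edge_FU]
  if (length(pos) && max(pos) > edges[n_bins + 1]) {
    stop("activities exceed the last bin edge (", signif(edges[n_bins + 1], 4),
         " FU); increase `n_bins`", call. = FALSE)
  }
  counts <- if (length(pos)) {
    tabulate(findInterval(pos, edges, left.open = TRUE,
                          rightmost.closed = FALSE),
             nbins = n_bins)
  } else {
    rep(0L, n_bins)
  }

  fmt <- function(x) formatC(x, format = "fg", digits = 3)
  out <- tibble::tibble(
    class = c("zero", "underflow", rep("bin", n_bins)),
    lower_FU = c(NA, 0, edges[1:n_bins]),
    upper_FU = c(NA, base_edge_FU, edges[2:(n_bins + 1)]),
    label = c("0", paste0("<", fmt(base_edge_FU)),
              paste0("(", fmt(edges[1:n_bins]), ",",
                     fmt(edges[2:(n_bins + 1)]), "]")),
    n = c(n_zero, n_under, counts),
    pct = 100 * c(n_zero, n_under, counts) / length(fu)
  )
  structure(out,
            class = c("activity_distribution", class(out)),
            n_cells = length(fu), base_edge_FU = base_edge_FU, ratio = ratio,
            variant = variant, species = species,
            median_FU = stats::median(fu),
            median_fmol = stats::median(fu) * 0.1,
            q25_FU = unname(stats::quantile(fu, 0.25)),
            q75_FU = unname(stats::quantile(fu, 0.75)))
}

#' Average activity distributions over replicate cultures
#'
#' Treatments are run in triplicate; published distributions show the mean
#' percentage per class across replicates with its SD. All inputs must share
#' the same binning (pass explicit `n_bins` to [build_distribution()]).
#'
#' @param distributions List of `activity_distribution` objects with
#'   identical bin structure.
#' @return A tibble with `class`, `label`, `mean_pct`, `sd_pct`,
#'   `n_replicates`.
#' @export
average_distributions <- function(distributions) {
  stopifnot(length(distributions) >= 1,
            all(purrr::map_lgl(distributions,
                               inherits, "activity_distribution")))
  labs <- purrr::map(distributions, "label")
  if (length(unique(labs)) != 1) {
    stop("distributions have different bin structures; rebuild with a ",
         "common `n_bins`", call. = FALSE)
  }
  pcts <- do.call(cbind, purrr::map(distributions, "pct"))
  tibble::tibble(
    class = distributions[[1]]$class,
    label = distributions[[1]]$label,
    mean_pct = rowMeans(pcts),
    sd_pct = apply(pcts, 1, stats::sd),
    n_replicates = length(distributions)
  )
}

#' Order-statistic summary of per-cell activities
#'
#' Medians, quartiles and 10/90 percentiles of single-cell activity per
#' group — the statistics shown in box-and-whisker comparisons of
#' treatments. Quantiles use the standard linear-interpolation convention
#' (R type 7).
#'
#' @param activities Per-cell tibble with `felfa_FU` and `activity_fmol`
#'   columns.
#' @param ... Grouping columns (tidy-select), e.g. `variant`; default
#'   ungrouped.
#' @return A tibble of group keys plus `n_cells`, and for FU and fmol the
#'   median, 25/75 quartiles and 10/90 percentiles.
#' @export
summarize_activity <- function(activities, ...) {
  stopifnot(is.data.frame(activities), nrow(activities) > 0,
            "felfa_FU" %in% names(activities))
  if (!"activity_fmol" %in% names(activities)) {
    activities$activity_fmol <- to_fmol(activities$felfa_FU)
  }
  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  activities |>
    dplyr::group_by(...) |>
    dplyr::summarize(
      n_cells = dplyr::n(),
      median_FU = stats::median(.data$felfa_FU),
      q25_FU = q(.data$felfa_FU, 0.25),
      q75_FU = q(.data$felfa_FU, 0.75),
      p10_FU = q(.data$felfa_FU, 0.10),
      p90_FU = q(.data$felfa_FU, 0.90),
      median_fmol = stats::median(.data$activity_fmol),
      q25_fmol = q(.data$activity_fmol, 0.25),
      q75_fmol = q(.data$activity_fmol, 0.75),
      p10_fmol = q(.data$activity_fmol, 0.10),
      p90_fmol = q(.data$activity_fmol, 0.90),
      .groups = "drop"
    )
}

#' Three-way factorial comparison of treatment responses
#'
#' Tests the effects of species (2 levels), P-source medium (inorganic vs
#' organic) and P concentration level (3 levels) — and all their
#' interactions — on a per-replicate response (growth rate, mean cell
#' volume, or activity), following the standard design for these culture
#' experiments: responses are log(x+1)-transformed, analyzed by three-way
#' ANOVA, and treatment differences assessed post hoc with Tukey's HSD.
#' The degrees of freedom of the seven effects (S, M, P, SxM, SxP, MxP,
#' SxMxP) are (1, 1, 2, 1, 2, 2, 2).
#'
#' @param table Per-replicate tibble with factor columns `species`,
#'   `medium`, `p_level`, a `replicate` column, and the response.
#' @param response Name of the response column (string or bare name).
#' @param post_hoc Compute Tukey HSD contrasts and compact-letter groupings?
#'   Disable for large simulation studies that only need the ANOVA table.
#' @return An object of class `flea_anova` with [tidy()] and [glance()]
#'   methods; components: `fit` (the `aov` object), `anova_table`,
#'   `tukey` (pairwise Tukey HSD contrasts), `letters` (compact letter
#'   display of the medium x P-level treatment means).
#' @examples
#' \donttest{
#' d <- simulate_factorial(medium_effect = 0.5, seed = 1)
#' fit <- compare_treatments(d, response)
#' tidy(fit)
#' }
#' @export
compare_treatments <- function(table, response, post_hoc = TRUE) {
  stopifnot(is.data.frame(table))
  resp <- rlang::as_name(rlang::ensym(response))
  needed <- c("species", "medium", "p_level", resp)
  miss <- setdiff(needed, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)

  df <- table |>
    dplyr::mutate(species = factor(.data$species),
                  medium = factor(.data$medium),
                  p_level = factor(.data$p_level))
  cells <- tidyr::expand_grid(
    species = levels(df$species), medium = levels(df$medium),
    p_level = levels(df$p_level)
  )
  counts <- df |>
    dplyr::count(.data$species, .data$medium, .data$p_level) |>
    dplyr::right_join(cells, by = c("species", "medium", "p_level")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
  bad <- dplyr::filter(counts, .data$n < 2)
  if (nrow(bad) > 0) {
    stop("design cells with <2 replicates: ",
         paste(sprintf("%s/%s/%s (n=%d)", bad$species, bad$medium,
                       bad$p_level, bad$n), collapse = "; "),
         call. = FALSE)
  }
  if (any(df[[resp]] < 0)) {
    stop("response must be nonnegative for the log(x+1) transform",
         call. = FALSE)
  }
  df$.y <- log1p(df[[resp]])
  fit <- stats::aov(.y ~ species * medium * p_level, data = df)

  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  keep <- terms != "Residuals"
  anova_table <- tibble::tibble(
    term = terms[keep],
    df = sm$Df[keep],
    sumsq = sm$`Sum Sq`[keep],
    statistic = sm$`F value`[keep],
    p.value = sm$`Pr(>F)`[keep]
  )

  tukey <- NULL
  letters_tbl <- NULL
  if (post_hoc) {
  tk <- stats::TukeyHSD(fit)
  tukey <- purrr::list_rbind(purrr::imap(tk, function(m, term) {
    tibble::tibble(term = term, contrast = rownames(m),
                   estimate = m[, "diff"], conf.low = m[, "lwr"],
                   conf.high = m[, "upr"], adj.p.value = m[, "p adj"])
  }))

  # compact letter display over the 6 medium x P-level treatments (species
  # pooled, as in the published letter annotations): Tukey contrasts on a
  # one-way refit of the treatment factor
  df$.trt <- interaction(df$medium, df$p_level, sep = ":")
  fit1 <- stats::aov(.y ~ .trt, data = df)
  tuk1 <- multcomp::glht(fit1, linfct = multcomp::mcp(.trt = "Tukey"))
  cld <- multcomp::cld(tuk1)
  letters_tbl <- tibble::tibble(
    treatment = names(cld$mcletters$Letters),
    group = unname(cld$mcletters$Letters)
  )
  }

  structure(
    list(fit = fit, response = resp, anova_table = anova_table,
         tukey = tukey, letters = letters_tbl,
         n = nrow(df), residual_df = sm$Df[!keep]),
    class = "flea_anova"
  )
}

#' @export
print.flea_anova <- function(x, ...) {
  cat("<flea_anova> three-way ANOVA on log(", x$response, " + 1), n = ",
      x$n, "\n", sep = "")
  print(x$anova_table)
  invisible(x)
}

#' @rdname compare_treatments
#' @param x,... A `flea_anova` object; further arguments ignored.
#' @method tidy flea_anova
#' @export
tidy.flea_anova <- function(x, ...) x$anova_table

#' @rdname compare_treatments
#' @method glance flea_anova
#' @export
glance.flea_anova <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    residual_df = x$residual_df,
    r.squared = summary(stats::lm(x$fit))$r.squared
  )
}

#' Simulate a per-replicate factorial response table
#'
#' Generates the 2 (species) x 2 (medium) x 3 (P level) design with
#' `n_rep` replicates per cell. Effects are specified on the log(x+1) scale,
#' where the model is additive Gaussian — so the downstream ANOVA on
#' log(x+1)-transformed responses is exact and the null type-I error is
#' nominal. Used for null-calibration and planted-effect power checks.
#'
#' @param species_effect,medium_effect Log-scale shift added to the second
#'   level of the factor.
#' @param p_level_effects Length-3 numeric, log-scale shift per P level.
#' @param baseline Log-scale grand mean.
#' @param sigma Log-scale residual SD.
#' @param n_rep Replicates per design cell (the study design is
#'   triplicate).
#' @param seed Integer seed.
#' @return Tibble with `species`, `medium`, `p_level`, `replicate`,
#'   `response`.
#' @export
simulate_factorial <- function(species_effect = 0, medium_effect = 0,
                               p_level_effects = c(0, 0, 0), baseline = 1,
                               sigma = 0.2, n_rep = 3, seed) {
  stopifnot(length(p_level_effects) == 3, sigma >= 0, n_rep >= 2)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  design <- tidyr::expand_grid(
    species = c("C_elongata", "C_silvae_gabretae"),
    medium = c("inorganic", "organic"),
    p_level = c("1", "2", "3"),
    replicate = seq_len(n_rep)
  )
  withr::with_seed(seed, {
    eta <- baseline +
      ifelse(design$species == "C_silvae_gabretae", species_effect, 0) +
      ifelse(design$medium == "organic", medium_effect, 0) +
      p_level_effects[as.integer(design$p_level)] +
      stats::rnorm(nrow(design), 0, sigma)
    dplyr::mutate(design, response = expm1(eta))
  })
}
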