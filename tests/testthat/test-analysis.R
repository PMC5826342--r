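test_that("geometric binning assigns cells to the documented classes", {
  # all inactive -> zero class holds 100%
  d <- build_distribution(rep(0, 50), n_bins = 4)
  expect_equal(d$pct[d$class == "zero"], 100)
  expect_equal(sum(d$pct), 100)

  # a cell at 0.5 FU falls in (0.32, 0.64] with base 0.02 and ratio 2
  d2 <- build_distribution(0.5, n_bins = 8)
  hit <- d2[d2$n > 0 & d2$class == "bin", ]
  expect_equal(hit$lower_FU, 0.32)
  expect_equal(hit$upper_FU, 0.64)

  # sub-base but positive activity lands in the underflow class
  d3 <- build_distribution(c(0.01, 0.5), n_bins = 8)
  expect_equal(d3$n[d3$class == "underflow"], 1)

  # edges follow a strict geometric progression
  bins <- d2[d2$class == "bin", ]
  expect_equal(bins$upper_FU / bins$lower_FU, rep(2, nrow(bins)))
})

test_that("percentages always sum to 100 and binning preserves order", {
  withr::with_seed(19, {
    for (i in 1:20) {
      fu <- c(rep(0, rpois(1, 5)), rlnorm(rpois(1, 40), -1, 1.2))
      if (length(fu) == 0) fu <- 0
      d <- build_distribution(fu, n_bins = 16)
      expect_equal(sum(d$pct), 100, tolerance = 1e-9)
      expect_equal(sum(d$n), length(fu))
    }
  })
  # order preservation: a >= b implies bin(a) >= bin(b)
  fu <- sort(c(0, 0.01, 0.05, 0.3, 0.33, 0.64, 0.641, 10))
  d <- build_distribution(fu, n_bins = 12)
  idx <- findInterval(fu[fu > 0.02], 0.02 * 2^(0:12), left.open = TRUE)
  expect_true(all(diff(idx) >= 0))
})

test_that("out-of-range activities are an explicit error, not silent loss", {
  expect_error(build_distribution(100, n_bins = 3), "last bin edge")
  expect_error(build_distribution(numeric(0)), "no cells")
})

test_that("triplicate distributions average class-wise with SDs", {
  reps <- lapply(1:3, function(i) {
    withr::with_seed(i, build_distribution(rlnorm(100, -1, 1), n_bins = 12))
  })
  avg <- average_distributions(reps)
  expect_equal(sum(avg$mean_pct), 100, tolerance = 1e-9)
  expect_equal(avg$mean_pct,
               (reps[[1]]$pct + reps[[2]]$pct + reps[[3]]$pct) / 3)
  expect_true(all(avg$sd_pct >= 0))
  bad <- withr::with_seed(4, build_distribution(rlnorm(50, -1, 1),
                                                base_edge_FU = 0.05,
                                                n_bins = 12))
  expect_error(average_distributions(list(reps[[1]], bad)), "bin structure")
})

test_that("activity summaries report the box-and-whisker order statistics", {
  act <- tibble::tibble(felfa_FU = rep(2, 10), activity_fmol = rep(0.2, 10))
  s <- summarize_activity(act)
  expect_equal(s$median_FU, 2)
  expect_equal(s$q25_FU, 2)
  expect_equal(s$p90_FU, 2)
  s2 <- summarize_activity(tibble::tibble(felfa_FU = 1:100))
  expect_equal(s2$median_FU, 50.5)
  expect_equal(s2$q25_FU, 25.75)   # type-7 linear interpolation
  expect_equal(s2$median_fmol, 5.05)
})

test_that("the three-way ANOVA reproduces the factorial design df (1,1,2,1,2,2,2)", {
  d <- simulate_factorial(seed = 101)
  fit <- compare_treatments(d, response)
  tab <- tidy(fit)
  expect_equal(tab$term,
               c("species", "medium", "p_level", "species:medium",
                 "species:p_level", "medium:p_level",
                 "species:medium:p_level"))
  expect_equal(tab$df, c(1, 1, 2, 1, 2, 2, 2))
  expect_equal(glance(fit)$residual_df, 24)  # 36 obs - 12 parameters
  expect_s3_class(fit$tukey, "tbl_df")
  expect_equal(nrow(fit$letters), 6)  # medium x p_level treatment means
  expect_true(all(c("group") %in% names(fit$letters)))
})

test_that("a constant response produces no spurious effects", {
  d <- simulate_factorial(sigma = 0, seed = 1)
  d$response <- 1
  fit <- compare_treatments(d, response, post_hoc = FALSE)
  # all effect sums of squares vanish (F is 0/0 in a saturated-null fit)
  expect_true(all(tidy(fit)$sumsq < 1e-20))
})

test_that("a planted medium effect is detected while species stays null", {
  d <- simulate_factorial(medium_effect = 0.6, sigma = 0.1, seed = 7)
  fit <- compare_treatments(d, response, post_hoc = FALSE)
  tab <- tidy(fit)
  expect_lt(tab$p.value[tab$term == "medium"], 0.05)
  expect_gt(tab$p.value[tab$term == "species"], 0.05)
})

test_that("incomplete designs are rejected with the missing cells listed", {
  d <- simulate_factorial(seed = 3)
  d <- d[!(d$medium == "organic" & d$p_level == "3"), ]
  expect_error(compare_treatments(d, response), "organic/3|<2 replicates")
  d2 <- simulate_factorial(seed = 3)
  d2$response[1] <- -1
  expect_error(compare_treatments(d2, response), "nonnegative")
})
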