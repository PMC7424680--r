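test_that("daily summary takes the median leaf and mean area per day", {
  s <- tibble::tibble(
    plant_id = "p1",
    das = c(12L, 12L, 12L, 13L, 13L, 15L),
    time_of_day = c(480L, 600L, 720L, 480L, 600L, 480L),
    leaf_count = c(4, 5, 5, NA, 6, 7),
    area = c(10, 12, 14, 20, 22, 30)
  )
  d <- daily_summary(s)
  expect_identical(d$leaf[d$das == 12], 5)         # median of {4,5,5}
  expect_identical(d$area[d$das == 12], 12)        # mean of {10,12,14}
  expect_identical(d$leaf[d$das == 13], 6)         # NA dropped
  # the absent day 14 appears as a missing row, not a zero
  expect_true(d$missing[d$das == 14])
  expect_true(is.na(d$leaf[d$das == 14]))
})

test_that("imputation fills interior gaps only and reproduces exact curves", {
  # no missing data: identity on the measured columns
  d0 <- make_daily(12:20, leaf = 2:10, area = (2:10)^2)
  expect_identical(impute_series(d0)$leaf, d0$leaf)
  # linear series with one gap: spline restores the exact value
  d1 <- make_daily(12:20, leaf = c(2:5, NA, 7:10), area = 1)
  expect_equal(impute_series(d1, "spline")$leaf[5], 6, tolerance = 1e-9)
  expect_equal(impute_series(d1, "upsample")$leaf[5], 6, tolerance = 1e-9)
  # noise-free exponential with a gap: curve fit restores it to 1e-6
  y <- 2 * exp(0.2 * (12:22)); y[6] <- NA
  d2 <- make_daily(12:22, leaf = y, area = y)
  out <- impute_series(d2, "curve_fit")
  expect_equal(out$leaf[6], 2 * exp(0.2 * 17), tolerance = 1e-6)
  # observed values never altered; no extrapolation at the edges
  d3 <- make_daily(12:20, leaf = c(NA, 3:9, NA), area = 1)
  out3 <- impute_series(d3, "spline")
  expect_identical(out3$leaf[2:8], d3$leaf[2:8])
  expect_true(is.na(out3$leaf[1]) && is.na(out3$leaf[9]))
  expect_error(impute_series(make_daily(1:4, leaf = c(1, NA, NA, 2), area = 1)),
               "4 observed")
})

test_that("exponential trend fitting recovers exact and constant series", {
  t <- 0:10
  d <- make_daily(t, leaf = 2 * exp(0.25 * t))
  fit <- fit_leaf_trend(d, leaf_window = c(0, Inf))
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$b, 0.25, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-12)
  cst <- fit_leaf_trend(make_daily(1:6, leaf = rep(3, 6)),
                        leaf_window = c(0, Inf))
  expect_identical(c(cst$a, cst$b), c(3, 0))
  expect_error(fit_leaf_trend(make_daily(1:6, leaf = rep(0, 6))), ">= 3")
})

test_that("noisy trend fit matches a brute-force grid search", {
  set.seed(12)
  t <- 5:25
  y <- pmax(1, round(0.7 * exp(0.1 * t) * exp(rnorm(21, 0, 0.05))))
  d <- make_daily(t, leaf = y)
  fit <- fit_leaf_trend(d, leaf_window = c(0, Inf))
  # grid oracle on the log-scale objective that the fit minimizes
  obj <- function(a, b) sum((log(y) - log(a) - b * t)^2)
  grid_a <- seq(0.4, 1.2, length.out = 200)
  grid_b <- seq(0.05, 0.15, length.out = 200)
  vals <- outer(grid_a, grid_b, Vectorize(obj))
  best <- arrayInd(which.min(vals), dim(vals))
  # agreement to the oracle's grid resolution
  expect_lt(abs(fit$a - grid_a[best[1]]), 0.8 / 199)
  expect_lt(abs(fit$b - grid_b[best[2]]), 0.1 / 199)
  # broom-style accessors
  expect_identical(tidy(fit)$term, c("a", "b"))
  expect_identical(glance(fit)$n, fit$n)
})

test_that("population mean trend is the pointwise average of the curves", {
  mk <- function(a, b) structure(list(a = a, b = b), class = "leaf_trend")
  tl <- 10:20
  one <- population_mean_trend(list(mk(2, 0.1)), tl)
  expect_equal(one$values, 2 * exp(0.1 * tl))
  two <- population_mean_trend(list(mk(1, 0), mk(3, 0)), tl)
  expect_equal(two$values, rep(2, 11))
  set.seed(13)
  ms <- lapply(1:5, function(i) mk(runif(1, 0.5, 2), runif(1, 0, 0.2)))
  got <- population_mean_trend(ms, tl)$values
  oracle <- Reduce(`+`, lapply(ms, function(m) m$a * exp(m$b * tl))) / 5
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(population_mean_trend(list(), tl), "at least one")
})

test_that("MSD profile zeroes at the constructed delay and respects overlap", {
  tl <- 12:32
  trend <- population_mean_trend(
    list(structure(list(a = 0.68, b = 0.09), class = "leaf_trend")), tl
  )
  # a plant delayed by 3 days: leaf(t) = trend(t - 3) has its minimum at -3
  delayed <- make_daily(tl, leaf = 0.68 * exp(0.09 * (tl - 3)))
  prof <- msd_profile(delayed, trend, k_range = 5)
  expect_equal(prof$msd[prof$k == -3], 0, tolerance = 1e-20)
  expect_identical(select_shift(prof), -3L)
  # a series equal to the trend zeroes at k = 0
  same <- make_daily(tl, leaf = trend$values)
  expect_equal(msd_profile(same, trend)$msd[8], 0, tolerance = 1e-20)
  # candidates below the overlap floor are excluded
  short <- make_daily(12:18, leaf = 0.68 * exp(0.09 * (12:18)))
  prof2 <- msd_profile(short, trend, k_range = 7, min_overlap = 5)
  expect_true(all(prof2$n_overlap >= 5))
  # negative delays push the short series off the timeline start
  expect_gte(min(prof2$k), -2)
  expect_error(msd_profile(make_daily(12:14, leaf = 1:3), trend,
                           k_range = 2, min_overlap = 10), "admissible")
})

test_that("shift selection breaks ties toward zero, then the smaller delay", {
  p <- function(k, msd) {
    structure(tibble::tibble(k = as.integer(k), msd = msd,
                             n_overlap = 10L),
              class = c("msd_profile", "tbl_df", "tbl", "data.frame"))
  }
  expect_identical(select_shift(p(-2:4, c(9, 8, 7, 5, 3, 1, 2))), 3L)
  expect_identical(select_shift(p(-3:3, rep(4, 7))), 0L)        # flat profile
  expect_identical(select_shift(p(c(-2, 0, 2), c(1, 5, 1))), -2L)  # |k| tie
})

test_that("area adjustment zeroes when aligned and finds built-in offsets", {
  tl <- 12:32
  area_trend <- population_mean_trend(
    list(structure(list(a = 3, b = 0.16), class = "leaf_trend")), tl
  )
  s <- -2L
  # aligned after s: area(u) = trend(u + s) so delta 0 is exact
  aligned <- make_daily(tl, leaf = NA_real_, area = 3 * exp(0.16 * (tl + s)))
  expect_identical(area_adjustment(aligned, area_trend, s), 0L)
  # built-in one-day residual: area(t - s + 1) = trend(t)
  offset <- make_daily(tl, leaf = NA_real_, area = 3 * exp(0.16 * (tl + s - 1)))
  expect_identical(area_adjustment(offset, area_trend, s), 1L)
  # insufficient overlap falls back to 0 with a warning
  tiny <- make_daily(12:14, leaf = NA_real_, area = c(10, 12, 14))
  expect_warning(dt0 <- area_adjustment(tiny, area_trend, 20L), "overlap")
  expect_identical(dt0, 0L)
})

test_that("apply_shift re-indexes days without touching any value", {
  pop <- quick_pop(n_plants = 2, seed = 21)
  s1 <- dplyr::filter(pop$series, plant_id == "plant_001")
  expect_identical(
    dplyr::arrange(apply_shift(s1, 0L, 0L), day, time_of_day)$area,
    dplyr::arrange(s1, das, time_of_day)$area
  )
  sh <- apply_shift(s1, 2L, 0L, timeline = 12:32)
  # normalized day 14 holds the value measured on day 12
  v14 <- sh$leaf_count[sh$day == 14 & sh$time_of_day == 480]
  v12 <- s1$leaf_count[s1$das == 12 & s1$time_of_day == 480]
  expect_identical(v14, v12)
  # retained values are a sub-multiset of the originals
  expect_true(all(table(sh$leaf_count) <= table(s1$leaf_count)[names(table(sh$leaf_count))]))
  # area shifts by s - delta_t
  sh2 <- apply_shift(s1, 2L, 1L, timeline = 12:32)
  a13 <- sh2$area[sh2$day == 13 & sh2$time_of_day == 480]
  expect_identical(a13, s1$area[s1$das == 12 & s1$time_of_day == 480])
})

test_that("normalization leaves an already-aligned population unshifted", {
  sp <- population_spec(n_plants = 6, shift_dist = 0L, leaf_noise_cv = 0,
                        leaf_noise_sd = 0, area_noise_cv = 0, seed = 31)
  pop <- generate_population(sp)
  res <- normalize_population(pop$series)
  expect_true(all(tidy(res)$s == 0L))
  expect_true(all(tidy(res)$delta_t == 0L))
  # values survive the identity normalization
  norm_daily <- dispersion_curves(res$normalized)
  raw_daily <- dispersion_curves(pop$series)
  expect_equal(norm_daily$mean, raw_daily$mean, tolerance = 1e-12)
})

test_that("normalization recovers germination offsets and tightens spread", {
  sp <- population_spec(n_plants = 28, shift_dist = -3:3,
                        balanced_shifts = TRUE, seed = 32)
  pop <- generate_population(sp)
  res <- normalize_population(pop$series)
  j <- dplyr::inner_join(tidy(res), pop$true_shifts, by = "plant_id")
  expect_gte(mean(j$s == -j$shift), 0.95)
  g <- glance(res)
  expect_gt(g$sd_ratio_final_day, 1.3)
  expect_identical(g$n_flagged, 0L)
})
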