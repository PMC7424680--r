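test_that("confusion counts are exact pixel tallies", {
  t20 <- matrix(FALSE, 20, 20)
  pred <- t20; pred[1:10, 1:10] <- TRUE
  cc <- confusion_counts(pred, pred)
  expect_identical(unlist(cc), c(tp = 100L, fp = 0L, fn = 0L, tn = 300L))
  # hand-counted partial overlap: truth 4 px, pred 4 px, 2 shared
  truth <- t20; truth[1, 1:4] <- TRUE
  pred2 <- t20; pred2[1, 3:6] <- TRUE
  cc2 <- confusion_counts(pred2, truth)
  expect_identical(unlist(cc2[, 1:3]), c(tp = 2L, fp = 2L, fn = 2L))
  cc3 <- confusion_counts(t20, t20)
  expect_identical(unlist(cc3[, 1:3]), c(tp = 0L, fp = 0L, fn = 0L))
  expect_error(confusion_counts(pred, matrix(TRUE, 5, 5)), "shape")
})

test_that("metrics follow their formulas, including degenerate conventions", {
  perfect <- segmentation_metrics(tibble::tibble(tp = 50, fp = 0, fn = 0, tn = 50))
  expect_equal(unlist(perfect[, 1:4]),
               c(precision = 100, recall = 100, jaccard = 100, dice = 100))
  m <- segmentation_metrics(tibble::tibble(tp = 2, fp = 2, fn = 2, tn = 94))
  expect_equal(m$precision, 50)
  expect_equal(m$recall, 50)
  expect_equal(m$jaccard, 100 / 3, tolerance = 1e-9)
  expect_equal(m$dice, 50)
  # empty vs empty scores 100 across the board; empty pred vs non-empty
  # truth is flagged with precision 0
  e <- segmentation_metrics(tibble::tibble(tp = 0, fp = 0, fn = 0, tn = 100))
  expect_equal(unlist(e[, 1:4]), c(precision = 100, recall = 100,
                                   jaccard = 100, dice = 100))
  expect_false(e$degenerate)
  f <- segmentation_metrics(tibble::tibble(tp = 0, fp = 0, fn = 10, tn = 90))
  expect_equal(f$precision, 0)
  expect_true(f$degenerate)
})

test_that("Dice-Jaccard identity and bounds hold over random mask pairs", {
  set.seed(14)
  for (trial in 1:1000) {
    n <- 64
    counts <- as.vector(rmultinom(1, n, runif(4, 0.01, 1)))
    m <- segmentation_metrics(tibble::tibble(tp = counts[1], fp = counts[2],
                                             fn = counts[3], tn = counts[4]))
    expect_true(all(unlist(m[, 1:4]) >= 0 & unlist(m[, 1:4]) <= 100))
    D <- m$dice / 100; J <- m$jaccard / 100
    expect_equal(D, 2 * J / (1 + J), tolerance = 1e-12)
  }
})

test_that("aggregate_metrics appends the unweighted mean row", {
  tab <- tibble::tibble(
    dataset = c("A1", "A2", "A3", "A4", "ours"),
    precision = c(92.05, 90.90, 95.86, 94.89, 96.05),
    recall = c(96.87, 97.45, 93.88, 98.37, 98.57),
    jaccard = c(89.26, 88.83, 89.85, 92.56, 93.29),
    dice = c(94.26, 93.71, 93.86, 96.06, 96.58)
  )
  agg <- aggregate_metrics(tab)
  mean_row <- agg[agg$dataset == "Mean", ]
  expect_equal(mean_row$precision, round(mean(tab$precision), 2))
  expect_equal(mean_row$recall, round(mean(tab$recall), 2))
  single <- aggregate_metrics(tab[1, ])
  expect_equal(single$precision[single$dataset == "Mean"], 92.05)
})

test_that("dispersion curves and ratios have their closed forms", {
  s <- tibble::tibble(
    plant_id = rep(c("a", "b"), each = 3),
    das = rep(1:3, 2),
    leaf_count = 1,
    area = rep(c(10, 14), each = 3)
  )
  d <- dispersion_curves(s)
  expect_equal(d$mean, rep(12, 3))
  expect_equal(d$sd, rep(sqrt(8), 3))   # sample SD of {10, 14} = 2*sqrt(2)
  same <- dplyr::mutate(s, area = 10)
  expect_equal(dispersion_curves(same)$sd, rep(0, 3))
  expect_equal(dispersion_ratio(d, d, 2), 1)
  d2 <- dplyr::mutate(d, sd = sd / 2)
  expect_equal(dispersion_ratio(d, d2, 2), 2)
  expect_warning(r <- dispersion_ratio(d, dplyr::mutate(d, sd = 0), 2), "zero")
  expect_identical(r, Inf)
  expect_error(dispersion_ratio(d, d2, 99), "absent")
})

test_that("outlier detector flags a planted defect and nothing else", {
  sp <- population_spec(n_plants = 24, shift_dist = -1:1, seed = 41)
  pop <- generate_population(sp)
  series <- pop$series
  bad <- "plant_007"
  series$area[series$plant_id == bad & series$das >= 20] <-
    series$area[series$plant_id == bad & series$das >= 20] * 0.5
  res <- normalize_population(series)
  rep <- detect_outliers(res$normalized)
  expect_identical(rep$plant_id[rep$flagged], bad)
  expect_lte(rep$first_flag_day[rep$plant_id == bad], 22)
  # homogeneous population: no flags
  clean <- normalize_population(pop$series)
  expect_false(any(detect_outliers(clean$normalized)$flagged))
  expect_error(detect_outliers(dplyr::filter(series, plant_id < "plant_005")),
               "5 plants")
})

test_that("sd growth shape separates exponential from linear curves", {
  day <- 12:32
  exp_curve <- tibble::tibble(day = day, n = 10, mean = 1,
                              sd = 0.5 * exp(0.16 * day))
  lin_curve <- tibble::tibble(day = day, n = 10, mean = 1,
                              sd = 2 + 0.8 * day)
  expect_identical(sd_growth_shape(exp_curve)$better, "exponential")
  expect_identical(suppressWarnings(sd_growth_shape(lin_curve))$better, "linear")
})
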