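test_that("rosette generator handles empty, disjoint, and seeded cases", {
  # empty rosette
  fx0 <- generate_rosette_image(rosette_spec(n_leaves = 0), seed = 1)
  expect_identical(fx0$truth$true_leaf_number, 0L)
  expect_false(any(fx0$truth$mask))

  # disjoint leaves by construction
  sp <- rosette_spec(n_leaves = 4, overlap_fraction = 0,
                     leaf_length_px = 30, leaf_width_px = 12)
  fx <- generate_rosette_image(sp, seed = 2)
  expect_identical(fx$truth$occluded_leaf_count, 0L)
  expect_identical(max(fx$truth$leaf_labels), 4L)
  lab <- dapdr:::label_components(fx$truth$mask)
  expect_identical(max(lab), 4L)  # pixel-disjoint leaves

  # determinism: same spec and seed give bit-identical output
  fx2 <- generate_rosette_image(sp, seed = 2)
  expect_identical(fx$image, fx2$image)
  expect_identical(fx$truth, fx2$truth)
  fx3 <- generate_rosette_image(sp, seed = 3)
  expect_false(identical(fx$image, fx3$image))
})

test_that("ground truth is pixel-consistent with the rendered labels", {
  for (seed in 1:4) {
    fx <- generate_rosette_image(
      rosette_spec(n_leaves = 6, overlap_fraction = 0.25, background = "soil"),
      seed = seed
    )
    t <- fx$truth
    expect_identical(t$mask, t$leaf_labels > 0L)
    labs <- sort(unique(t$leaf_labels[t$leaf_labels > 0]))
    expect_identical(length(labs),
                     as.integer(t$true_leaf_number - t$occluded_leaf_count))
    expect_identical(labs, seq_along(labs))
  }
})

test_that("full-occlusion fixtures decompose the measured count", {
  sp <- rosette_spec(n_leaves = 3, overlap_fraction = 0.2)
  fx <- generate_rosette_image(sp, seed = 3, angles = c(10, 150, 10),
                               size_factors = c(1, 0.8, 1))
  expect_identical(fx$truth$occluded_leaf_count, 1L)
  expect_identical(max(fx$truth$leaf_labels), 2L)
})

test_that("rosette too large for the frame errors", {
  expect_error(
    generate_rosette_image(
      rosette_spec(n_leaves = 3, leaf_length_px = 80, image_size = c(80L, 80L)),
      seed = 1
    ),
    "too small"
  )
})

test_that("population generator: structure, shifts, and determinism", {
  sp <- population_spec(n_plants = 12, shift_dist = -2:2, seed = 5)
  pop <- generate_population(sp)
  expect_identical(nrow(pop$true_shifts), 12L)
  expect_true(all(pop$true_shifts$shift %in% -2:2))
  expect_setequal(unique(pop$series$plant_id), pop$true_shifts$plant_id)
  expect_true(all(pop$series$leaf_count >= 0, na.rm = TRUE))
  expect_true(all(pop$series$area >= 0, na.rm = TRUE))
  # seeded determinism
  pop2 <- generate_population(sp)
  expect_identical(pop$series, pop2$series)
  # identical world up to coefficient draws when noise and shifts are off
  sp0 <- population_spec(n_plants = 4, shift_dist = 0L, leaf_noise_cv = 0,
                         leaf_noise_sd = 0, area_noise_cv = 0, seed = 2)
  pop0 <- generate_population(sp0)
  expect_true(all(pop0$true_shifts$shift == 0L))
})

test_that("noise-free log leaf counts are affine in shifted time", {
  sp <- population_spec(n_plants = 6, shift_dist = -3:3, leaf_noise_cv = 0,
                        leaf_noise_sd = 0, area_noise_cv = 0, seed = 11)
  pop <- generate_population(sp)
  daily <- daily_summary(pop$series)
  for (id in unique(daily$plant_id)[1:3]) {
    d <- daily[daily$plant_id == id & daily$leaf > 0, ]
    fit <- lm(log(d$leaf) ~ d$das)
    # residuals only reflect integer rounding of the counts
    expect_lt(sd(residuals(fit)), 0.15)
    expect_equal(unname(fit$coefficients[2]), 0.09, tolerance = 0.12)
  }
})

test_that("inject_missing blanks a seeded subset at the requested rate", {
  pop <- quick_pop(n_plants = 6, seed = 9)
  s0 <- pop$series
  expect_identical(inject_missing(s0, 0), s0)
  all_gone <- inject_missing(s0, 1, seed = 1)
  expect_true(all(is.na(all_gone$leaf_count)))
  expect_true(all(is.na(all_gone$area)))
  # determinism and rate within the binomial envelope
  m1 <- inject_missing(s0, 0.15, seed = 4)
  m2 <- inject_missing(s0, 0.15, seed = 4)
  expect_identical(m1, m2)
  n <- nrow(s0)
  frac <- mean(is.na(m1$leaf_count))
  ci <- qbinom(c(0.0005, 0.9995), n, 0.15) / n
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
})
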