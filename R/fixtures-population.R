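#' Specify a synthetic plant population
#'
#' Describes a population of plants whose daily leaf number follows an
#' exponential early-development trend `a * exp(b * (t - shift))` with an
#' integer-day germination offset (`shift`) per plant, and whose projected
#' rosette area follows a matching exponential modulated by a within-day
#' (diurnal) sinusoid. Measurement noise is relative (coefficient of
#' variation) with an optional absolute component for leaf counts; missing
#' timepoints can be injected. The per-plant true offsets are returned so
#' that shift-recovery can be scored exactly.
#'
#' Default magnitudes emulate Arabidopsis Col-0 growth imaged from 12 to 32
#' days after sowing: about 2 leaves at day 12 growing to about 12 at day
#' 32, area growing ~25-fold over the window, a 10% relative diurnal area
#' oscillation, 5% relative measurement noise, and germination offsets
#' uniform on whole days -3..3. Between-plant trend-coefficient variation is
#' kept small relative to one day of growth so that developmental-timing
#' differences dominate, which is the situation the normalization addresses.
#'
#' @param n_plants Number of plants.
#' @param timeline Integer days-after-sowing grid (default `12:32`).
#' @param a_dist,b_dist `c(mean, sd)` of the leaf-trend coefficients.
#' @param area_a_dist,area_b_dist `c(mean, sd)` of the area-trend
#'   coefficients (area units, per-day rate).
#' @param shift_dist Integer vector of candidate germination offsets (days);
#'   each plant's offset is drawn uniformly from it.
#' @param balanced_shifts Draw shifts as a shuffled balanced design
#'   (`shift_dist` recycled over the plants) instead of independently, so
#'   the sample mean offset is (near) zero. Shift-recovery oracles need
#'   this: shifts are only identifiable relative to the population mean.
#' @param leaf_noise_sd Absolute additive SD of leaf-count noise (counts).
#' @param leaf_noise_cv Relative SD of leaf-count noise.
#' @param area_noise_cv Relative SD of area noise.
#' @param diurnal_amplitude Relative amplitude of the within-day area
#'   oscillation.
#' @param missing_rate Fraction of timepoints whose measurements are set to
#'   missing.
#' @param time_of_day Minutes-of-day sampling grid within the photoperiod.
#' @param seed Integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_plants = 50L,
                            timeline = 12:32,
                            a_dist = c(0.68, 0.005),
                            b_dist = c(0.09, 0.00022),
                            area_a_dist = c(3.0, 0.03),
                            area_b_dist = c(0.16, 0.0004),
                            shift_dist = -3:3,
                            leaf_noise_sd = 0,
                            leaf_noise_cv = 0.05,
                            area_noise_cv = 0.05,
                            diurnal_amplitude = 0.10,
                            missing_rate = 0,
                            balanced_shifts = FALSE,
                            time_of_day = seq(480L, 1080L, by = 60L),
                            seed = 1L) {
  if (length(timeline) < 3) rlang::abort("timeline must span at least 3 days")
  if (missing_rate < 0 || missing_rate > 1) {
    rlang::abort("`missing_rate` must be in [0, 1]")
  }
  sds <- c(a_dist[2], b_dist[2], area_a_dist[2], area_b_dist[2],
           leaf_noise_sd, leaf_noise_cv, area_noise_cv)
  if (any(sds < 0)) rlang::abort("all noise SDs must be >= 0")
  structure(
    list(
      n_plants = as.integer(n_plants), timeline = as.integer(timeline),
      a_dist = a_dist, b_dist = b_dist,
      area_a_dist = area_a_dist, area_b_dist = area_b_dist,
      shift_dist = as.integer(shift_dist),
      balanced_shifts = isTRUE(balanced_shifts),
      leaf_noise_sd = leaf_noise_sd, leaf_noise_cv = leaf_noise_cv,
      area_noise_cv = area_noise_cv,
      diurnal_amplitude = diurnal_amplitude,
      missing_rate = missing_rate,
      time_of_day = as.integer(time_of_day),
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

#' Generate a synthetic population of trait time-series
#'
#' @param spec A [population_spec()].
#' @return A list with `series` (tibble: `plant_id`, `das`, `time_of_day`,
#'   `leaf_count`, `area`) and `true_shifts` (tibble: `plant_id`, `shift` in
#'   days; positive = later germination).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_plants
  tl <- spec$timeline
  tod <- spec$time_of_day

  a <- stats::rnorm(n, spec$a_dist[1], spec$a_dist[2])
  b <- stats::rnorm(n, spec$b_dist[1], spec$b_dist[2])
  Aa <- stats::rnorm(n, spec$area_a_dist[1], spec$area_a_dist[2])
  Ab <- stats::rnorm(n, spec$area_b_dist[1], spec$area_b_dist[2])
  shift <- if (spec$balanced_shifts) {
    sample(rep(spec$shift_dist, length.out = n))
  } else {
    sample(spec$shift_dist, n, replace = TRUE)
  }

  # zero-mean diurnal modulation over the sampling grid
  frac <- (tod - min(tod)) / max(1L, diff(range(tod)))
  osc0 <- sin(pi * frac)
  osc <- osc0 - mean(osc0)

  grid <- tidyr::expand_grid(
    plant = seq_len(n), das = tl, time_of_day = tod
  )
  grid <- dplyr::mutate(
    grid,
    plant_id = sprintf("plant_%03d", .data$plant),
    t_dev = .data$das - shift[.data$plant],
    leaf_true = a[.data$plant] * exp(b[.data$plant] * .data$t_dev),
    area_true = Aa[.data$plant] * exp(Ab[.data$plant] * .data$t_dev) *
      (1 + spec$diurnal_amplitude * osc[match(.data$time_of_day, tod)])
  )
  nr <- nrow(grid)
  leaf_noise <- stats::rnorm(nr, 0,
                             spec$leaf_noise_sd + spec$leaf_noise_cv * grid$leaf_true)
  area_noise <- stats::rnorm(nr, 0, 1)
  grid <- dplyr::mutate(
    grid,
    leaf_count = pmax(0, round(.data$leaf_true + leaf_noise)),
    area = pmax(0, .data$area_true * (1 + spec$area_noise_cv * area_noise))
  )
  series <- dplyr::select(grid, "plant_id", "das", "time_of_day",
                          "leaf_count", "area")
  series <- tibble::as_tibble(series)
  if (spec$missing_rate > 0) {
    series <- inject_missing(series, spec$missing_rate,
                             seed = spec$seed + 1L)
  }
  list(
    series = series,
    true_shifts = tibble::tibble(
      plant_id = sprintf("plant_%03d", seq_len(n)),
      shift = as.integer(shift)
    )
  )
}

#' Set a random subset of timepoints to missing
#'
#' Emulates acquisition gaps (for instance power failures) by blanking the
#' measurements of a seeded pseudo-random subset of rows. Day/time indices
#' are retained; only the measured values become `NA`.
#'
#' @param series A series tibble (`plant_id`, `das`, `time_of_day`,
#'   `leaf_count`, `area`).
#' @param rate Fraction of rows to blank, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The series with `leaf_count`/`area` set to `NA` on the selected
#'   rows.
#' @export
inject_missing <- function(series, rate, seed = 1L) {
  if (rate < 0 || rate > 1) rlang::abort("`rate` must be in [0, 1]")
  if (rate == 0) return(series)
  set.seed(seed)
  nr <- nrow(series)
  drop <- stats::runif(nr) < rate
  series$leaf_count[drop] <- NA
  series$area[drop] <- NA
  series
}
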