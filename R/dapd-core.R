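#' Summarize sub-daily measurements into a daily series
#'
#' Collapses frame-level measurements to one row per plant and day: the
#' daily leaf number is the median of the daytime frames (robust to
#' occasional counting glitches) and the daily area is the mean. Days inside
#' a plant's observed range with no usable measurement are kept as missing
#' rows rather than dropped, so gaps remain visible to imputation.
#'
#' @param series Tibble with columns `plant_id`, `das`, optionally
#'   `time_of_day`, `leaf_count`, `area`.
#' @return Tibble with columns `plant_id`, `das`, `leaf`, `area`, `n_obs`,
#'   `missing`.
#' @export
daily_summary <- function(series) {
  check_series(series)
  daily <- series |>
    dplyr::group_by(.data$plant_id, .data$das) |>
    dplyr::summarise(
      leaf = if (all(is.na(.data$leaf_count))) NA_real_ else
        stats::median(.data$leaf_count, na.rm = TRUE),
      area = if (all(is.na(.data$area))) NA_real_ else
        mean(.data$area, na.rm = TRUE),
      n_obs = sum(!is.na(.data$leaf_count) | !is.na(.data$area)),
      .groups = "drop"
    )
  # complete each plant's day grid so interior gaps appear as missing rows
  daily <- daily |>
    dplyr::group_by(.data$plant_id) |>
    tidyr::complete(das = tidyr::full_seq(.data$das, 1)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      n_obs = dplyr::coalesce(.data$n_obs, 0L),
      missing = is.na(.data$leaf) & is.na(.data$area)
    ) |>
    dplyr::arrange(.data$plant_id, .data$das)
  daily
}

#' Fill missing interior days of a daily series
#'
#' Missing interior values are estimated by cubic spline interpolation,
#' exponential curve fitting, or linear resampling. Observed values are
#' never altered and values are never extrapolated beyond each plant's
#' observed range.
#'
#' @param daily A daily tibble from [daily_summary()] (may hold several
#'   plants).
#' @param method `"spline"`, `"curve_fit"` (log-linear exponential fit) or
#'   `"upsample"` (linear interpolation).
#' @return The daily tibble with interior `NA`s of `leaf` and `area` filled
#'   and a logical `imputed` column.
#' @export
impute_series <- function(daily, method = c("spline", "curve_fit", "upsample")) {
  method <- match.arg(method)
  fill_one <- function(x, t) {
    obs <- which(!is.na(x))
    if (length(obs) == length(x)) return(x)
    if (length(obs) < 4) rlang::abort("need at least 4 observed points to impute")
    lo <- min(obs); hi <- max(obs)
    gaps <- setdiff(seq(lo, hi), obs)
    if (!length(gaps)) return(x)
    if (method == "spline") {
      x[gaps] <- stats::spline(t[obs], x[obs], xout = t[gaps], method = "natural")$y
    } else if (method == "upsample") {
      x[gaps] <- stats::approx(t[obs], x[obs], xout = t[gaps])$y
    } else {
      pos <- obs[x[obs] > 0]
      if (length(pos) < 3) rlang::abort("curve_fit needs >= 3 positive values")
      fit <- stats::lm(log(x[pos]) ~ t[pos])
      x[gaps] <- exp(fit$coefficients[1] + fit$coefficients[2] * t[gaps])
    }
    x
  }
  out <- daily |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::arrange(.data$das, .by_group = TRUE) |>
    dplyr::mutate(
      was_na = is.na(.data$leaf) & is.na(.data$area),
      leaf = fill_one(.data$leaf, .data$das),
      area = fill_one(.data$area, .data$das),
      imputed = .data$was_na & !(is.na(.data$leaf) & is.na(.data$area))
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"was_na")
  out
}

#' Fit the early-development exponential leaf trend
#'
#' Fits `leaf(t) = a * exp(b * t)` to one plant's daily leaf numbers by
#' log-linear least squares over the early-development window, by default
#' the days on which the measured leaf number lies between 2 and 12 (the
#' paper-style "early developmental stages" are not a fixed day range, so
#' the window is defined on the developmental scale itself).
#'
#' @param daily Daily tibble for a single plant.
#' @param leaf_window `c(min, max)` leaf-count range defining the fit
#'   window.
#' @param day_window Optional `c(first, last)` day range intersected with
#'   the leaf window.
#' @param refine Refit on the count scale (nonlinear least squares started
#'   at the log-linear estimate). The log of a rounded count is biased
#'   upward where counts are small, which displaces log-scale fits; the
#'   count-scale refit is unbiased under symmetric rounding. Used by
#'   [normalize_population()].
#' @return Object of class `leaf_trend` with elements `a`, `b`,
#'   `fit_window`, `rss` (residual sum of squares on the count scale), `n`,
#'   `plant_id`. [generics::tidy()] and [generics::glance()] methods are
#'   provided.
#' @export
fit_leaf_trend <- function(daily, leaf_window = c(2, 12), day_window = NULL,
                           refine = FALSE) {
  one_plant(daily)
  value <- daily$leaf
  keep <- !is.na(value) & value >= max(1, leaf_window[1]) & value <= leaf_window[2]
  if (!is.null(day_window)) {
    keep <- keep & daily$das >= day_window[1] & daily$das <= day_window[2]
  }
  t <- daily$das[keep]; y <- value[keep]
  if (length(y) < 3) rlang::abort("need >= 3 in-window points with leaf >= 1")
  if (all(y == y[1])) {
    a <- y[1]; b <- 0
  } else {
    fit <- stats::lm(log(y) ~ t)
    a <- exp(unname(fit$coefficients[1]))
    b <- unname(fit$coefficients[2])
    if (refine) {
      nl <- tryCatch(
        stats::nls(y ~ a0 * exp(b0 * t), start = list(a0 = a, b0 = b),
                   control = stats::nls.control(warnOnly = TRUE)),
        error = function(e) NULL
      )
      if (!is.null(nl)) {
        cf <- stats::coef(nl)
        if (is.finite(cf[1]) && cf[1] > 0) { a <- unname(cf[1]); b <- unname(cf[2]) }
      }
    }
  }
  structure(
    list(
      a = a, b = b,
      fit_window = range(t),
      rss = sum((y - a * exp(b * t))^2),
      n = length(y),
      plant_id = daily$plant_id[1]
    ),
    class = "leaf_trend"
  )
}

#' Fit an exponential trend to daily areas
#'
#' Same model and fitting as [fit_leaf_trend()] but on the daily mean area,
#' using all days with positive area. Used to build the population mean
#' area trend for the whole-day area adjustment.
#'
#' @inheritParams fit_leaf_trend
#' @return A `leaf_trend` object (the class records an exponential trend,
#'   whichever trait it was fitted to).
#' @export
fit_area_trend <- function(daily, day_window = NULL) {
  one_plant(daily)
  keep <- !is.na(daily$area) & daily$area > 0
  if (!is.null(day_window)) {
    keep <- keep & daily$das >= day_window[1] & daily$das <= day_window[2]
  }
  t <- daily$das[keep]; y <- daily$area[keep]
  if (length(y) < 3) rlang::abort("need >= 3 positive area values")
  fit <- stats::lm(log(y) ~ t)
  a <- exp(unname(fit$coefficients[1]))
  b <- unname(fit$coefficients[2])
  structure(
    list(a = a, b = b, fit_window = range(t),
         rss = sum((y - a * exp(b * t))^2), n = length(y),
         plant_id = daily$plant_id[1]),
    class = "leaf_trend"
  )
}

#' @export
print.leaf_trend <- function(x, ...) {
  cat(sprintf("Exponential trend for %s: a = %.4g, b = %.4g per day (n = %d, rss = %.4g)\n",
              x$plant_id, x$a, x$b, x$n, x$rss))
  invisible(x)
}

#' Average the fitted trends across a population
#'
#' Computes the pointwise mean of the per-plant exponential trends
#' `a_i * exp(b_i * t)` over a common day grid, the population reference
#' curve against which each plant's shift is scored.
#'
#' @param models List of `leaf_trend` objects.
#' @param timeline Integer day grid.
#' @param bias_correct Deflate the curve by `exp(var(log(a_i)) / 2)`. The
#'   arithmetic mean of exponential curves (the defining average) exceeds
#'   the typical individual's curve by exactly this lognormal factor when
#'   amplitudes vary — here mostly through germination offsets — which
#'   would otherwise bias every shift estimate by a common fraction of a
#'   day. Used by [normalize_population()].
#' @return Object of class `population_trend`: tibble-backed list with
#'   `timeline`, `values`, `n_plants`.
#' @export
population_mean_trend <- function(models, timeline, bias_correct = FALSE) {
  if (!length(models)) rlang::abort("need at least one fitted trend")
  timeline <- as.integer(timeline)
  curves <- vapply(models, function(m) m$a * exp(m$b * timeline),
                   numeric(length(timeline)))
  values <- if (is.matrix(curves)) rowMeans(curves) else curves
  if (bias_correct && length(models) > 1) {
    la <- log(vapply(models, function(m) m$a, numeric(1)))
    values <- values / exp(stats::var(la) / 2)
  }
  structure(
    list(timeline = timeline, values = values, n_plants = length(models)),
    class = "population_trend"
  )
}

#' @export
print.population_trend <- function(x, ...) {
  cat(sprintf("Population mean trend over days %d..%d (N = %d plants)\n",
              min(x$timeline), max(x$timeline), x$n_plants))
  invisible(x)
}

#' Mean squared deviation profile over candidate day shifts
#'
#' For each candidate integer delay `k`, compares the plant's daily leaf
#' numbers re-indexed by `k` against the population mean trend:
#' `MSD(k) = mean over t of (leaf(t - k) - trend(t))^2`, where the mean runs
#' over the `n` days of overlap between the shifted series and the trend
#' timeline. Candidates with fewer than `min_overlap` overlapping days are
#' excluded.
#'
#' @param daily Daily tibble for a single plant (leaf values used).
#' @param trend A [population_mean_trend()] object.
#' @param k_range Half-width of the symmetric candidate window (days);
#'   candidates are `-k_range..k_range`.
#' @param min_overlap Minimum overlapping days for a candidate to be
#'   admissible.
#' @param score `"msd"` (primary) or `"cor"`: with `"cor"` the profile also
#'   carries a cross-correlation column `cor` (the shift is still selected
#'   on MSD unless [select_shift()] is told otherwise).
#' @return Object of class `msd_profile`: tibble with columns `k`, `msd`,
#'   `n_overlap` (and `cor` if requested), plus a `plant_id` attribute.
#' @export
msd_profile <- function(daily, trend, k_range = 7L, min_overlap = 5L,
                        score = c("msd", "cor")) {
  score <- match.arg(score)
  one_plant(daily)
  stopifnot(inherits(trend, "population_trend"))
  ks <- -as.integer(k_range):as.integer(k_range)
  obs_days <- daily$das[!is.na(daily$leaf)]
  leaf_at <- function(d) daily$leaf[match(d, daily$das)]
  rows <- lapply(ks, function(k) {
    t_ok <- trend$timeline[(trend$timeline - k) %in% obs_days]
    n <- length(t_ok)
    if (n < min_overlap) return(NULL)
    meas <- leaf_at(t_ok - k)
    ref <- trend$values[match(t_ok, trend$timeline)]
    out <- tibble::tibble(k = k, msd = mean((meas - ref)^2), n_overlap = n)
    if (score == "cor") {
      out$cor <- if (stats::sd(meas) > 0 && stats::sd(ref) > 0)
        stats::cor(meas, ref) else NA_real_
    }
    out
  })
  profile <- dplyr::bind_rows(rows)
  if (!nrow(profile)) {
    rlang::abort("no admissible shift candidate: overlap below `min_overlap` everywhere")
  }
  structure(profile, class = c("msd_profile", class(profile)),
            plant_id = daily$plant_id[1])
}

#' Select the shift minimizing the MSD profile
#'
#' Returns the candidate delay with the lowest MSD; ties are broken by the
#' smallest absolute delay, then by the smaller (more negative) delay, so
#' that a perfectly flat profile yields 0.
#'
#' @param profile An [msd_profile()].
#' @param on Column to minimize, `"msd"` (default) or `"cor"` (maximized).
#' @return Integer shift `s`.
#' @export
select_shift <- function(profile, on = "msd") {
  stopifnot(nrow(profile) > 0)
  val <- if (on == "cor") -profile$cor else profile[[on]]
  ord <- order(val, abs(profile$k), profile$k)
  as.integer(profile$k[ord[1]])
}

#' Whole-day area adjustment after the leaf-based shift
#'
#' Plants with the same leaf number can differ in rosette expansion, so the
#' leaf-derived shift `s` is refined for the area series: `delta_t` is the
#' whole-day offset in `-delta_range..delta_range` minimizing the MSD
#' between the log of the plant's s-shifted daily area and the log of the
#' population mean area trend. Ties break as in [select_shift()].
#'
#' @param daily Daily tibble for a single plant (area values used).
#' @param area_trend A [population_mean_trend()] built from per-plant area
#'   trend fits.
#' @param s Integer shift selected from the leaf series.
#' @param delta_range Half-width of the candidate window (days).
#' @param min_overlap Minimum overlapping days.
#' @return Integer `delta_t`; if no candidate has enough overlap, 0 with a
#'   warning.
#' @export
area_adjustment <- function(daily, area_trend, s, delta_range = 2L,
                            min_overlap = 5L) {
  one_plant(daily)
  deltas <- -as.integer(delta_range):as.integer(delta_range)
  obs_days <- daily$das[!is.na(daily$area) & daily$area > 0]
  area_at <- function(d) daily$area[match(d, daily$das)]
  rows <- lapply(deltas, function(dd) {
    src <- area_trend$timeline - s + dd
    t_ok <- area_trend$timeline[src %in% obs_days]
    n <- length(t_ok)
    if (n < min_overlap) return(NULL)
    meas <- log(area_at(t_ok - s + dd))
    ref <- log(area_trend$values[match(t_ok, area_trend$timeline)])
    tibble::tibble(k = dd, msd = mean((meas - ref)^2), n_overlap = n)
  })
  profile <- dplyr::bind_rows(rows)
  if (!nrow(profile)) {
    rlang::warn("insufficient overlap for area adjustment; using delta_t = 0")
    return(0L)
  }
  ord <- order(profile$msd, abs(profile$k), profile$k)
  as.integer(profile$k[ord[1]])
}

#' Re-index a series by a whole-day shift
#'
#' Applies the developmental shift without touching any measured value: the
#' leaf measurement taken on day `d` is re-indexed to normalized day
#' `d + s`, and the area measurement to `d + s - delta_t` (so the value at
#' normalized day `t` is the one measured at `t - s`, respectively
#' `t - s + delta_t`). Values are never interpolated or rescaled;
#' sub-daily structure is carried along unchanged; normalized days falling
#' outside `timeline` (when given) are dropped.
#'
#' @param series Sub-daily (or daily) series tibble for a single plant with
#'   columns `plant_id`, `das`, optionally `time_of_day`, `leaf_count`,
#'   `area`.
#' @param s Integer leaf shift.
#' @param delta_t Integer area adjustment.
#' @param timeline Optional integer reference day grid to clip to.
#' @return Tibble with columns `plant_id`, `day` (normalized), possibly
#'   `time_of_day`, `leaf_count`, `area`.
#' @export
apply_shift <- function(series, s, delta_t = 0L, timeline = NULL) {
  check_series(series)
  s <- as.integer(s); delta_t <- as.integer(delta_t)
  has_tod <- "time_of_day" %in% names(series)
  keys <- c("plant_id", if (has_tod) "time_of_day")
  leaf <- series |>
    dplyr::select(dplyr::all_of(c(keys, "das", "leaf_count"))) |>
    dplyr::mutate(day = .data$das + s) |>
    dplyr::select(-"das")
  area <- series |>
    dplyr::select(dplyr::all_of(c(keys, "das", "area"))) |>
    dplyr::mutate(day = .data$das + s - delta_t) |>
    dplyr::select(-"das")
  out <- dplyr::full_join(leaf, area, by = c(keys, "day"))
  if (!is.null(timeline)) {
    out <- dplyr::filter(out, .data$day %in% as.integer(timeline))
  }
  cols <- c("plant_id", "day", if (has_tod) "time_of_day", "leaf_count", "area")
  out |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::arrange(.data$day, if (has_tod) .data$time_of_day else .data$day)
}

# ---- internal helpers -------------------------------------------------------

check_series <- function(series) {
  need <- c("plant_id", "das", "leaf_count", "area")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    rlang::abort(sprintf("series is missing column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  invisible(series)
}

one_plant <- function(daily) {
  if (length(unique(daily$plant_id)) != 1L) {
    rlang::abort("expected a single plant; got several plant_id values")
  }
  invisible(daily)
}
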