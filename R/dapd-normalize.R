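#' Developmentally normalize a population of trait time-series
#'
#' The full normalization: daily summaries are computed per plant, interior
#' gaps imputed, an exponential leaf trend fitted per plant, the population
#' mean trend assembled, and each plant's integer-day shift `s` selected by
#' MSD minimization against that trend, followed by a whole-day area
#' adjustment `delta_t` against the mean area trend. The shifts are then
#' applied to the raw (sub-daily) series; measured values are never altered,
#' only their day index. When a `genotype` column is present each genotype
#' group is normalized against its own mean trend.
#'
#' Plants whose trend cannot be fitted (or with no admissible shift) are
#' passed through unshifted and flagged in the report.
#'
#' Two systematic phase biases of the reference trend are removed so that
#' shifts are anchored correctly: per-plant trends are refit on the count
#' scale (rounding biases the log-scale fit upward where counts are small),
#' and the population mean curve is deflated by the lognormal factor
#' `exp(var(log(a_i)) / 2)` by which an arithmetic mean of exponentials
#' exceeds the typical individual's curve. With both corrections the
#' integer-day shifts are recovered absolutely whenever the population's
#' mean germination offset is within half a day of the reference timeline
#' (shifts are only identifiable relative to the population). Optionally
#' `center = TRUE` additionally subtracts the population median shift.
#'
#' @param series Series tibble (`plant_id`, `das`, optionally `time_of_day`
#'   and `genotype`, `leaf_count`, `area`).
#' @param k_range,min_overlap Shift-candidate window and overlap floor, see
#'   [msd_profile()].
#' @param delta_range Area-adjustment window, see [area_adjustment()].
#' @param leaf_window Early-development fit window, see [fit_leaf_trend()].
#' @param impute_method Imputation method, see [impute_series()].
#' @param score Shift scoring, `"msd"` (primary) or `"cor"`.
#' @param center Additionally re-anchor shifts and area adjustments to the
#'   population median (default `FALSE`; see Details).
#' @return Object of class `dapd_normalization`: list with `normalized`
#'   (tibble `plant_id`, `day`, `time_of_day`, `leaf_count`, `area`),
#'   `report` (tibble `plant_id`, `s`, `delta_t`, `min_msd`, `n_overlap`,
#'   `flagged`, `note`), `profiles` (named list of [msd_profile()]s),
#'   `leaf_trend` and `area_trend` ([population_mean_trend()] objects per
#'   genotype), `timeline`, and the input `series`. `tidy()` returns the
#'   report, `glance()` a one-row summary, `autoplot()` the dispersion
#'   comparison.
#' @export
normalize_population <- function(series,
                                 k_range = 7L,
                                 min_overlap = 5L,
                                 delta_range = 2L,
                                 leaf_window = c(2, 12),
                                 impute_method = "spline",
                                 score = "msd",
                                 center = FALSE) {
  check_series(series)
  has_geno <- "genotype" %in% names(series)
  groups <- if (has_geno) split(series, series$genotype) else list(all = series)

  all_norm <- list(); all_report <- list(); all_profiles <- list()
  leaf_trends <- list(); area_trends <- list()

  for (gname in names(groups)) {
    g <- groups[[gname]]
    ids <- unique(g$plant_id)
    if (length(ids) < 2) rlang::abort("need at least 2 plants per group")
    daily <- daily_summary(g)
    daily <- tryCatch(impute_series(daily, method = impute_method),
                      error = function(e) daily)
    by_plant <- split(daily, daily$plant_id)

    fits <- list(); area_fits <- list(); failed <- character(0)
    for (id in ids) {
      f <- tryCatch(fit_leaf_trend(by_plant[[id]], leaf_window = leaf_window,
                                   refine = TRUE),
                    error = function(e) NULL)
      fa <- tryCatch(fit_area_trend(by_plant[[id]]), error = function(e) NULL)
      if (is.null(f) || is.null(fa)) failed <- c(failed, id)
      fits[[id]] <- f; area_fits[[id]] <- fa
    }
    ok <- setdiff(ids, failed)
    if (!length(ok)) rlang::abort("no plant could be fitted")
    timeline <- sort(unique(g$das))
    trend <- population_mean_trend(fits[ok], timeline, bias_correct = TRUE)
    area_trend <- population_mean_trend(area_fits[ok], timeline,
                                        bias_correct = TRUE)
    leaf_trends[[gname]] <- trend
    area_trends[[gname]] <- area_trend

    # pass 1: per-plant shift solutions against the group reference
    sols <- list()
    for (id in ids) {
      if (id %in% failed) {
        sols[[id]] <- list(ok = FALSE, note = "trend fit failed; passed through unshifted")
        next
      }
      res <- tryCatch({
        prof <- msd_profile(by_plant[[id]], trend, k_range = k_range,
                            min_overlap = min_overlap, score = score)
        s <- select_shift(prof, on = if (score == "cor") "cor" else "msd")
        dt <- area_adjustment(by_plant[[id]], area_trend, s,
                              delta_range = delta_range,
                              min_overlap = min_overlap)
        list(ok = TRUE, prof = prof, s = s, dt = dt, note = "")
      }, error = function(e) NULL)
      sols[[id]] <- res %||%
        list(ok = FALSE, note = "no admissible shift; passed through unshifted")
    }

    # re-anchor: the reference phase is arbitrary, so report shifts (and
    # area adjustments) relative to the population median
    oks <- names(Filter(function(x) isTRUE(x$ok), sols))
    if (center && length(oks)) {
      m_s <- as.integer(floor(stats::median(vapply(sols[oks], `[[`, 0L, "s")) + 0.5))
      m_dt <- as.integer(floor(stats::median(vapply(sols[oks], `[[`, 0L, "dt")) + 0.5))
      for (id in oks) {
        sols[[id]]$s <- sols[[id]]$s - m_s
        sols[[id]]$dt <- sols[[id]]$dt - m_dt
      }
    }

    # pass 2: apply and report
    for (id in ids) {
      raw_i <- dplyr::filter(g, .data$plant_id == id)
      sol <- sols[[id]]
      if (!isTRUE(sol$ok)) {
        all_norm[[id]] <- apply_shift(raw_i, 0L, 0L, timeline = timeline)
        all_report[[id]] <- tibble::tibble(
          plant_id = id, genotype = gname, s = 0L, delta_t = 0L,
          min_msd = NA_real_, n_overlap = NA_integer_,
          flagged = TRUE, note = sol$note
        )
        next
      }
      all_norm[[id]] <- apply_shift(raw_i, sol$s, sol$dt, timeline = timeline)
      all_profiles[[id]] <- sol$prof
      raw_s <- select_shift(sol$prof, on = if (score == "cor") "cor" else "msd")
      at_s <- sol$prof[sol$prof$k == raw_s, ]
      all_report[[id]] <- tibble::tibble(
        plant_id = id, genotype = gname, s = sol$s, delta_t = sol$dt,
        min_msd = at_s$msd[1], n_overlap = as.integer(at_s$n_overlap[1]),
        flagged = FALSE, note = ""
      )
    }
  }

  report <- dplyr::bind_rows(all_report)
  if (!has_geno) report$genotype <- NULL
  structure(
    list(
      normalized = dplyr::bind_rows(all_norm),
      report = report,
      profiles = all_profiles,
      leaf_trend = if (has_geno) leaf_trends else leaf_trends[[1]],
      area_trend = if (has_geno) area_trends else area_trends[[1]],
      timeline = sort(unique(series$das)),
      series = series
    ),
    class = "dapd_normalization"
  )
}

#' @export
print.dapd_normalization <- function(x, ...) {
  n <- length(unique(x$report$plant_id))
  cat(sprintf("DAPD normalization of %d plants over days %d..%d\n",
              n, min(x$timeline), max(x$timeline)))
  cat(sprintf("  shifts s: %s\n",
              paste(names(table(x$report$s)), table(x$report$s),
                    sep = "×", collapse = ", ")))
  if (any(x$report$flagged)) {
    cat(sprintf("  %d plant(s) flagged (passed through unshifted)\n",
                sum(x$report$flagged)))
  }
  invisible(x)
}

#' Tidy a DAPD normalization
#'
#' `tidy()` returns the per-plant report (shift, area adjustment, minimum
#' MSD, flags); `glance()` a one-row summary including the final-day
#' dispersion ratio of raw over normalized area.
#'
#' @param x A `dapd_normalization` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dapd_normalization
#' @export
tidy.dapd_normalization <- function(x, ...) {
  x$report
}

#' @rdname tidy.dapd_normalization
#' @method glance dapd_normalization
#' @export
glance.dapd_normalization <- function(x, ...) {
  raw <- dispersion_curves(x$series)
  nrm <- dispersion_curves(x$normalized)
  day <- max(intersect(raw$day, nrm$day))
  ratio <- tryCatch(dispersion_ratio(raw, nrm, day), error = function(e) NA_real_)
  tibble::tibble(
    n_plants = length(unique(x$report$plant_id)),
    n_flagged = sum(x$report$flagged),
    mean_abs_shift = mean(abs(x$report$s)),
    final_day = day,
    sd_ratio_final_day = as.numeric(ratio)
  )
}
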