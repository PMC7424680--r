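#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth Logical matrices of equal shape.
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth))) {
    rlang::abort("`pred` and `truth` must have the same shape")
  }
  tibble::tibble(
    tp = sum(pred & truth),
    fp = sum(pred & !truth),
    fn = sum(!pred & truth),
    tn = sum(!pred & !truth)
  )
}

#' Segmentation accuracy metrics from confusion counts
#'
#' Precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, Jaccard `tp/(tp+fp+fn)` and
#' Dice `2tp/(2tp+fp+fn)`, reported as percentages. Degenerate cases are
#' flagged rather than raised: an empty prediction against an empty truth
#' scores 100 across the board; an empty prediction against a non-empty
#' truth scores precision 0.
#'
#' @param counts Tibble from [confusion_counts()] (or any data frame with
#'   `tp`, `fp`, `fn` columns; several rows allowed).
#' @return Tibble with columns `precision`, `recall`, `jaccard`, `dice`
#'   (percent) and `degenerate`.
#' @export
segmentation_metrics <- function(counts) {
  with(counts, {
    degenerate <- (tp + fp) == 0 | (tp + fn) == 0
    both_empty <- (tp + fp + fn) == 0
    pr <- ifelse(tp + fp > 0, tp / (tp + fp), ifelse(both_empty, 1, 0))
    rc <- ifelse(tp + fn > 0, tp / (tp + fn), ifelse(both_empty, 1, 0))
    jc <- ifelse(tp + fp + fn > 0, tp / (tp + fp + fn), 1)
    dc <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 1)
    tibble::tibble(
      precision = 100 * pr, recall = 100 * rc,
      jaccard = 100 * jc, dice = 100 * dc,
      degenerate = degenerate & !both_empty
    )
  })
}

#' Compare a predicted mask against ground truth
#'
#' Convenience wrapper: [confusion_counts()] followed by
#' [segmentation_metrics()].
#'
#' @inheritParams confusion_counts
#' @return One-row metrics tibble.
#' @export
mask_metrics <- function(pred, truth) {
  segmentation_metrics(confusion_counts(pred, truth))
}

#' Aggregate per-dataset metrics with an overall mean row
#'
#' Takes per-dataset metric rows (percent scale) and appends the unweighted
#' mean of each metric, rounded to 2 decimals, as a final `"Mean"` row —
#' the layout used to summarize accuracy across benchmark datasets.
#'
#' @param per_dataset Tibble with a `dataset` column and numeric metric
#'   columns (`precision`, `recall`, `jaccard`, `dice`).
#' @return The input with an appended `Mean` row (all numeric columns
#'   rounded to 2 decimals).
#' @export
aggregate_metrics <- function(per_dataset) {
  if (!nrow(per_dataset)) rlang::abort("need at least one dataset row")
  num <- names(per_dataset)[vapply(per_dataset, is.numeric, logical(1))]
  mean_row <- per_dataset |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num), mean)) |>
    dplyr::mutate(dataset = "Mean")
  out <- dplyr::bind_rows(per_dataset, mean_row)
  dplyr::mutate(out, dplyr::across(dplyr::all_of(num), ~ round(.x, 2)))
}

#' Per-day mean and dispersion of area across plants
#'
#' @param series Series tibble; the day column is `day` (normalized) when
#'   present, otherwise `das`. Sub-daily rows are averaged per plant and day
#'   first.
#' @param value Column to summarize (default `area`).
#' @return Tibble `day`, `n`, `mean`, `sd` (sample SD); days with fewer
#'   than 2 contributing plants are omitted.
#' @export
dispersion_curves <- function(series, value = "area") {
  day_col <- if ("day" %in% names(series)) "day" else "das"
  per_plant <- series |>
    dplyr::group_by(.data$plant_id, day = .data[[day_col]]) |>
    dplyr::summarise(v = mean(.data[[value]], na.rm = TRUE), .groups = "drop") |>
    dplyr::filter(is.finite(.data$v))
  per_plant |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$v),
                     sd = stats::sd(.data$v), .groups = "drop") |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::arrange(.data$day)
}

#' Dispersion ratio between raw and normalized curves at one day
#'
#' @param raw,normalized Tibbles from [dispersion_curves()].
#' @param day Day at which to take the ratio.
#' @return `sd_raw / sd_normalized`; `Inf` (with a warning) when the
#'   normalized SD is zero.
#' @export
dispersion_ratio <- function(raw, normalized, day) {
  r <- raw$sd[match(day, raw$day)]
  n <- normalized$sd[match(day, normalized$day)]
  if (is.na(r) || is.na(n)) rlang::abort("`day` absent from one of the curves")
  if (n == 0) {
    rlang::warn("normalized SD is zero at this day; ratio is infinite")
    return(Inf)
  }
  r / n
}

#' Classify the growth shape of a dispersion curve
#'
#' Fits the SD-versus-day curve with a straight line and with an
#' exponential (linear model on the log scale), and reports both R-squared
#' values plus which model fits better. Raw (sowing-time indexed) dispersion
#' is expected to grow superlinearly; the shape of the normalized curve is
#' what the comparison interrogates.
#'
#' @param curves Tibble from [dispersion_curves()].
#' @return One-row tibble: `r2_linear`, `r2_exponential`, `better`
#'   (`"linear"` or `"exponential"`).
#' @export
sd_growth_shape <- function(curves) {
  d <- dplyr::filter(curves, .data$sd > 0)
  if (nrow(d) < 4) rlang::abort("need >= 4 days with positive SD")
  lin <- stats::lm(sd ~ day, data = d)
  expf <- stats::lm(log(sd) ~ day, data = d)
  r2_lin <- summary(lin)$r.squared
  # compare on the original scale: back-transform the exponential fit
  pred <- exp(stats::fitted(expf))
  ss_res <- sum((d$sd - pred)^2)
  ss_tot <- sum((d$sd - mean(d$sd))^2)
  r2_exp <- 1 - ss_res / ss_tot
  tibble::tibble(
    r2_linear = r2_lin,
    r2_exponential = r2_exp,
    better = ifelse(r2_exp > r2_lin, "exponential", "linear")
  )
}

#' Detect plants deviating persistently from the population
#'
#' Per day, each plant's daily area is scored as a robust z value,
#' `(area - population median) / MAD` (MAD with the usual consistency
#' constant). A plant is flagged when its absolute score exceeds
#' `mad_threshold` on at least `persist_days` consecutive days. Days whose
#' MAD is zero are skipped.
#'
#' @param series Normalized (or raw) series tibble; day column as in
#'   [dispersion_curves()].
#' @param mad_threshold Robust z threshold (default 3.5).
#' @param persist_days Required run length in days (default 3).
#' @return Tibble: `plant_id`, `flagged`, `first_flag_day`, `max_score`
#'   (largest absolute robust z), one row per plant.
#' @export
detect_outliers <- function(series, mad_threshold = 3.5, persist_days = 3L) {
  day_col <- if ("day" %in% names(series)) "day" else "das"
  daily <- series |>
    dplyr::group_by(.data$plant_id, day = .data[[day_col]]) |>
    dplyr::summarise(v = mean(.data$area, na.rm = TRUE), .groups = "drop") |>
    dplyr::filter(is.finite(.data$v))
  if (length(unique(daily$plant_id)) < 5) {
    rlang::abort("need at least 5 plants for outlier detection")
  }
  scored <- daily |>
    dplyr::group_by(.data$day) |>
    dplyr::mutate(
      med = stats::median(.data$v),
      mad = stats::mad(.data$v),
      z = ifelse(.data$mad > 0, (.data$v - .data$med) / .data$mad, NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$z))
  flag_one <- function(df) {
    df <- dplyr::arrange(df, .data$day)
    hit <- abs(df$z) > mad_threshold
    # first day starting a run of >= persist_days consecutive flagged days
    first_day <- NA_integer_
    run_len <- 0L; run_start <- NA_integer_
    for (i in seq_len(nrow(df))) {
      contiguous <- i > 1L && df$day[i] == df$day[i - 1L] + 1L
      if (hit[i]) {
        if (run_len > 0L && contiguous) {
          run_len <- run_len + 1L
        } else {
          run_len <- 1L
          run_start <- df$day[i]
        }
        if (run_len >= persist_days) { first_day <- run_start; break }
      } else {
        run_len <- 0L
      }
    }
    tibble::tibble(
      flagged = !is.na(first_day),
      first_flag_day = first_day,
      max_score = max(abs(df$z))
    )
  }
  scored |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::group_modify(~ flag_one(.x)) |>
    dplyr::ungroup()
}
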