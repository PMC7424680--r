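#' Read and write trait time-series CSV
#'
#' The on-disk schema has columns `plant_id`, `das` (integer day after
#' sowing), `time_of_day` (minutes, may be empty), `leaf_count`, `area`;
#' empty measurement cells are read back as `NA` (missing), never as 0.
#' An optional `genotype` column is carried through when present.
#'
#' @param path CSV file path.
#' @return `read_series_csv()` returns a tibble; `write_series_csv()`
#'   returns `path` invisibly.
#' @export
read_series_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0), check.names = TRUE)
  need <- c("plant_id", "das", "time_of_day", "leaf_count", "area")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    rlang::abort(sprintf("series CSV is missing column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  parse_num <- function(x, col, integer = FALSE) {
    x <- trimws(x)
    empty <- x == "" | toupper(x) == "NA"
    pattern <- if (integer) "^-?[0-9]+$" else
      "^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$"
    bad <- !empty & !grepl(pattern, x)
    if (any(bad)) {
      line <- which(bad)[1] + 1L  # header occupies line 1
      rlang::abort(sprintf("malformed %s value '%s' at line %d of %s",
                           col, x[bad][1], line, path))
    }
    out <- rep(NA_real_, length(x))
    out[!empty] <- as.numeric(x[!empty])
    if (integer) as.integer(out) else out
  }
  out <- tibble::tibble(
    plant_id = raw$plant_id,
    das = parse_num(raw$das, "das", integer = TRUE),
    time_of_day = parse_num(raw$time_of_day, "time_of_day", integer = TRUE),
    leaf_count = parse_num(raw$leaf_count, "leaf_count"),
    area = parse_num(raw$area, "area")
  )
  if ("genotype" %in% names(raw)) out$genotype <- raw$genotype
  out
}

#' @rdname read_series_csv
#' @param series Series tibble (`plant_id`, `das`, `time_of_day`,
#'   `leaf_count`, `area`, optionally `genotype`).
#' @export
write_series_csv <- function(series, path) {
  check_series(series)
  df <- as.data.frame(series)
  if (!"time_of_day" %in% names(df)) df$time_of_day <- NA_integer_
  cols <- c("plant_id", "das", "time_of_day", "leaf_count", "area",
            intersect("genotype", names(df)))
  utils::write.csv(df[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Configuration files are JSON or YAML with (optionally nested) sections
#' `paths`, `layout`, `segmentation`, `dapd`, `evaluation` and a top-level
#' `seed`. Unknown keys are rejected so that typos fail loudly; all values
#' are validated against the parameter ranges of the functions they feed.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated named list of class `run_config` (defaults filled
#'   in).
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    rlang::abort("config must be .json, .yaml or .yml")
  }
  run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Named list of configuration values (see above).
#' @export
run_config <- function(cfg = list()) {
  defaults <- list(
    seed = 1L,
    paths = list(out_dir = "dapd_out", series_csv = NULL, image_dir = NULL),
    layout = list(n_rows = 4L, n_cols = 5L, tray_id = "tray1"),
    population = list(n_plants = 24L, missing_rate = 0),
    rosette = list(n_images = 6L, n_leaves_range = c(2L, 12L),
                   overlap_fraction = 0.2, background = "soil"),
    segmentation = list(n_gamma_iters = 7L, gamma_range = c(0.6, 1.6),
                        fg_low = 0.01, fg_high = 0.25, green_low = 40),
    dapd = list(k_range = 7L, delta_range = 2L, min_overlap = 5L,
                leaf_window = c(2, 12), impute_method = "spline"),
    evaluation = list(mad_threshold = 3.5, persist_days = 3L)
  )
  check_keys <- function(given, known, where) {
    unknown <- setdiff(names(given), known)
    if (length(unknown)) {
      rlang::abort(sprintf("unknown config key(s) in %s: %s", where,
                           paste(unknown, collapse = ", ")))
    }
  }
  check_keys(cfg, names(defaults), "top level")
  out <- defaults
  for (sec in names(cfg)) {
    if (sec == "seed") { out$seed <- as.integer(cfg$seed); next }
    check_keys(cfg[[sec]], names(defaults[[sec]]), sec)
    out[[sec]] <- utils::modifyList(defaults[[sec]], cfg[[sec]])
  }
  with(out$segmentation, {
    if (n_gamma_iters < 1) rlang::abort("n_gamma_iters must be >= 1")
    if (gamma_range[1] <= 0 || diff(gamma_range) < 0) {
      rlang::abort("gamma_range must be positive and increasing")
    }
  })
  if (out$dapd$k_range < 1 || out$dapd$min_overlap < 2) {
    rlang::abort("dapd: k_range >= 1 and min_overlap >= 2 required")
  }
  if (out$population$missing_rate < 0 || out$population$missing_rate > 1) {
    rlang::abort("population: missing_rate must be in [0, 1]")
  }
  structure(out, class = "run_config")
}
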