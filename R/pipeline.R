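#' Run pipeline stages end to end
#'
#' Executes the stages of the phenotyping workflow — `simulate` (synthetic
#' images + population series), `segment` (rosette masks from pot images),
#' `count_leaves` (per-leaf labels and counts from masks), `normalize`
#' (developmental normalization of the series), `evaluate` (segmentation
#' metrics against ground-truth masks) and `outliers` — writing all
#' artifacts (CSV tables, PNG images/masks, JSON logs) under
#' `config$paths$out_dir`. Every stage logs its parameters and seed to
#' stderr; outputs are deterministic for a fixed config seed.
#'
#' @param config A [run_config()] (or path to a config file).
#' @param stages Character vector of stages to run, in order.
#' @return Invisibly, a named list of the primary artifact paths.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "segment", "count_leaves",
                                    "normalize", "evaluate", "outliers")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(stage, ...) {
    message(sprintf("[dapd:%s] %s", stage, sprintf(...)))
  }
  artifacts <- list()

  for (stage in stages) {
    if (stage == "simulate") {
      log_msg(stage, "seed=%d, n_plants=%d, n_images=%d", config$seed,
              config$population$n_plants, config$rosette$n_images)
      pop <- generate_population(population_spec(
        n_plants = config$population$n_plants,
        missing_rate = config$population$missing_rate,
        seed = config$seed
      ))
      series_path <- file.path(out_dir, "series.csv")
      write_series_csv(pop$series, series_path)
      utils::write.csv(pop$true_shifts,
                       file.path(out_dir, "true_shifts.csv"),
                       row.names = FALSE)
      img_dir <- file.path(out_dir, "images")
      truth_dir <- file.path(out_dir, "truth")
      dir.create(img_dir, showWarnings = FALSE)
      dir.create(truth_dir, showWarnings = FALSE)
      nlr <- config$rosette$n_leaves_range
      for (i in seq_len(config$rosette$n_images)) {
        spec <- rosette_spec(
          n_leaves = nlr[1] + (i - 1L) %% (nlr[2] - nlr[1] + 1L),
          overlap_fraction = config$rosette$overlap_fraction,
          background = config$rosette$background
        )
        fx <- generate_rosette_image(spec, seed = config$seed + i)
        write_image(fx$image, file.path(img_dir, sprintf("pot_%03d.png", i)))
        write_mask(fx$truth$mask,
                   file.path(truth_dir, sprintf("pot_%03d_mask.png", i)))
        jsonlite::write_json(
          list(true_leaf_number = fx$truth$true_leaf_number,
               occluded_leaf_count = fx$truth$occluded_leaf_count),
          file.path(truth_dir, sprintf("pot_%03d.json", i)),
          auto_unbox = TRUE
        )
      }
      artifacts$series <- series_path
      artifacts$images <- img_dir
    } else if (stage == "segment") {
      img_dir <- config$paths$image_dir %||% file.path(out_dir, "images")
      if (!dir.exists(img_dir)) {
        rlang::abort(sprintf("segment: image directory '%s' not found", img_dir))
      }
      mask_dir <- file.path(out_dir, "masks")
      dir.create(mask_dir, showWarnings = FALSE)
      sc <- seg_config(
        n_gamma_iters = config$segmentation$n_gamma_iters,
        gamma_range = config$segmentation$gamma_range,
        thresholds = list(fg_low = config$segmentation$fg_low,
                          fg_high = config$segmentation$fg_high,
                          green_low = config$segmentation$green_low)
      )
      files <- sort(list.files(img_dir, pattern = "\\.(png|ppm)$",
                               full.names = TRUE))
      seg_log <- list()
      for (f in files) {
        crop <- read_image(f)
        m <- segment_rosette(crop, sc, seed = config$seed)
        stemname <- tools::file_path_sans_ext(basename(f))
        write_mask(m, file.path(mask_dir, paste0(stemname, "_mask.png")))
        seg_log[[stemname]] <- list(method = attr(m, "method"),
                                    gammas = attr(m, "gammas"),
                                    area_px = sum(m))
        log_msg(stage, "%s: method=%s area=%d", stemname,
                attr(m, "method"), sum(m))
      }
      jsonlite::write_json(seg_log, file.path(out_dir, "segmentation_log.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts$masks <- mask_dir
    } else if (stage == "count_leaves") {
      mask_dir <- file.path(out_dir, "masks")
      if (!dir.exists(mask_dir)) {
        rlang::abort("count_leaves: run the segment stage first")
      }
      rows <- list()
      for (f in sort(list.files(mask_dir, pattern = "_mask\\.png$",
                                full.names = TRUE))) {
        m <- read_mask(f)
        ll <- count_leaves(m)
        stemname <- sub("_mask$", "", tools::file_path_sans_ext(basename(f)))
        rows[[stemname]] <- tibble::tibble(image = stemname,
                                           leaf_count = ll$leaf_count,
                                           area_px = sum(m))
        log_msg(stage, "%s: %d leaves", stemname, ll$leaf_count)
      }
      counts_path <- file.path(out_dir, "leaf_counts.csv")
      utils::write.csv(dplyr::bind_rows(rows), counts_path, row.names = FALSE)
      artifacts$leaf_counts <- counts_path
    } else if (stage == "normalize") {
      series_path <- config$paths$series_csv %||% file.path(out_dir, "series.csv")
      if (!file.exists(series_path)) {
        rlang::abort(sprintf("normalize: series file '%s' not found", series_path))
      }
      series <- read_series_csv(series_path)
      res <- normalize_population(
        series,
        k_range = config$dapd$k_range,
        delta_range = config$dapd$delta_range,
        min_overlap = config$dapd$min_overlap,
        leaf_window = config$dapd$leaf_window,
        impute_method = config$dapd$impute_method
      )
      norm_path <- file.path(out_dir, "normalized.csv")
      df <- dplyr::rename(res$normalized, das = "day")
      write_series_csv(df, norm_path)
      utils::write.csv(res$report, file.path(out_dir, "normalization_report.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        lapply(res$profiles, function(p) as.list(as.data.frame(p))),
        file.path(out_dir, "msd_profiles.json"), digits = NA
      )
      log_msg(stage, "normalized %d plants, %d flagged",
              nrow(res$report), sum(res$report$flagged))
      artifacts$normalized <- norm_path
    } else if (stage == "evaluate") {
      mask_dir <- file.path(out_dir, "masks")
      truth_dir <- file.path(out_dir, "truth")
      if (!dir.exists(mask_dir) || !dir.exists(truth_dir)) {
        rlang::abort("evaluate: need masks/ and truth/ under out_dir")
      }
      rows <- list()
      for (f in sort(list.files(truth_dir, pattern = "_mask\\.png$",
                                full.names = TRUE))) {
        stemname <- sub("_mask$", "", tools::file_path_sans_ext(basename(f)))
        pred_path <- file.path(mask_dir, paste0(stemname, "_mask.png"))
        if (!file.exists(pred_path)) next
        met <- mask_metrics(read_mask(pred_path), read_mask(f))
        met$dataset <- stemname
        rows[[stemname]] <- met
      }
      if (!length(rows)) rlang::abort("evaluate: no matching mask pairs")
      tab <- aggregate_metrics(
        dplyr::select(dplyr::bind_rows(rows), "dataset", "precision",
                      "recall", "jaccard", "dice")
      )
      metrics_path <- file.path(out_dir, "segmentation_metrics.csv")
      utils::write.csv(tab, metrics_path, row.names = FALSE)
      log_msg(stage, "mean dice = %.2f", tab$dice[tab$dataset == "Mean"])
      artifacts$metrics <- metrics_path
    } else if (stage == "outliers") {
      norm_path <- file.path(out_dir, "normalized.csv")
      if (!file.exists(norm_path)) {
        rlang::abort("outliers: run the normalize stage first")
      }
      series <- read_series_csv(norm_path)
      rep <- detect_outliers(series,
                             mad_threshold = config$evaluation$mad_threshold,
                             persist_days = config$evaluation$persist_days)
      out_path <- file.path(out_dir, "outliers.csv")
      utils::write.csv(rep, out_path, row.names = FALSE)
      log_msg(stage, "%d plant(s) flagged", sum(rep$flagged))
      artifacts$outliers <- out_path
    } else {
      rlang::abort(sprintf("unknown stage '%s'", stage))
    }
  }
  invisible(artifacts)
}
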