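#' Excess-green index
#'
#' Per-pixel `2G - R - B`, the classic vegetation index separating green
#' plant tissue from soil and pot background; negatives are clipped to 0
#' and the result capped at 255 (8-bit convention).
#'
#' @param img RGB array (0-255).
#' @return Grayscale matrix (0-255).
#' @export
green_index <- function(img) {
  assert_rgb(img)
  pmin(pmax(2 * img[, , 2] - img[, , 1] - img[, , 3], 0), 255)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Equalizes the V (brightness) channel of the HSV representation tile by
#' tile with a clipped histogram, interpolating the tile mappings
#' bilinearly; H and S are exactly preserved (channels are rescaled
#' multiplicatively). Tiles containing a single intensity are mapped by the
#' identity, so constant images pass through unchanged.
#'
#' @param img RGB array (0-255).
#' @param clip_limit Histogram clip limit as a multiple of the mean bin
#'   count (typical 2-4).
#' @param tile_grid `c(rows, cols)` of tiles.
#' @return RGB array (0-255).
#' @export
enhance_contrast <- function(img, clip_limit = 2, tile_grid = c(8L, 8L)) {
  assert_rgb(img)
  nr <- dim(img)[1]; nc <- dim(img)[2]
  gr <- tile_grid[1]; gc <- tile_grid[2]
  vmax <- pmax(img[, , 1], img[, , 2], img[, , 3])
  v8 <- round(clip255(vmax))

  th <- nr / gr; tw <- nc / gc
  tile_r <- pmin(gr, pmax(1L, ceiling(row(v8) / th)))
  tile_c <- pmin(gc, pmax(1L, ceiling(col(v8) / tw)))
  tid <- (tile_c - 1L) * gr + tile_r
  ntiles <- gr * gc

  lut <- matrix(0, ntiles, 256)
  for (t in seq_len(ntiles)) {
    vals <- v8[tid == t]
    n <- length(vals)
    counts <- tabulate(vals + 1L, nbins = 256L)
    if (sum(counts > 0) <= 1L) {          # flat tile: identity mapping
      lut[t, ] <- 0:255
      next
    }
    cl <- clip_limit * n / 256
    excess <- sum(pmax(counts - cl, 0))
    counts <- pmin(counts, cl) + excess / 256
    cdf <- cumsum(counts)
    lut[t, ] <- round(255 * cdf / n)
  }

  # bilinear interpolation between tile mappings (tile-centre coordinates)
  interp_axis <- function(pix, tsize, ntile) {
    pos <- (pix - 0.5) / tsize + 0.5
    t0 <- floor(pos)
    w <- pos - t0
    t0c <- pmin(pmax(t0, 1), ntile)
    t1c <- pmin(pmax(t0 + 1, 1), ntile)
    w[t0 < 1] <- 0; w[t0 >= ntile] <- 0
    w[t0 >= ntile] <- 0
    list(t0 = t0c, t1 = t1c, w = w)
  }
  ri <- interp_axis(row(v8), th, gr)
  ci <- interp_axis(col(v8), tw, gc)
  vi <- as.vector(v8) + 1L
  gather <- function(tr, tc) {
    lut[cbind(as.vector((tc - 1L) * gr + tr), vi)]
  }
  vnew <- (1 - ri$w) * (1 - ci$w) * gather(ri$t0, ci$t0) +
    (1 - ri$w) * ci$w * gather(ri$t0, ci$t1) +
    ri$w * (1 - ci$w) * gather(ri$t1, ci$t0) +
    ri$w * ci$w * gather(ri$t1, ci$t1)
  vnew <- matrix(vnew, nr, nc)

  scale <- ifelse(vmax > 0, vnew / vmax, 1)
  out <- img
  for (ch in 1:3) out[, , ch] <- img[, , ch] * scale
  clip255(out)
}

#' Otsu global thresholding
#'
#' Finds the 8-bit threshold maximizing the between-class variance of the
#' intensity histogram and returns it with the binary mask of pixels above
#' it. Optional post-smoothing (median, Gaussian, hole filling) mirrors the
#' cleanup applied inside the segmentation pipeline.
#'
#' @param gray Grayscale matrix (values are clipped/rounded to 0-255).
#' @param median_radius,gaussian_sigma,fill Optional mask cleanup steps
#'   (0/`FALSE` = off).
#' @return List with `threshold` (numeric) and `mask` (logical matrix).
#' @export
otsu_binarize <- function(gray, median_radius = 0L, gaussian_sigma = 0,
                          fill = FALSE) {
  g <- round(clip255(gray))
  if (length(unique(as.vector(g))) < 2L) {
    rlang::abort("Otsu thresholding needs at least 2 distinct values")
  }
  counts <- tabulate(g + 1L, nbins = 256L)
  n <- sum(counts)
  p <- counts / n
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  w1 <- 1 - w0
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * w1)
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # midpoint of the maximizing plateau (two-level images give a flat
  # optimum between the levels)
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  thr <- mean(levels[range(best)])
  mask <- g > thr
  if (median_radius > 0) mask <- median_filter(mask * 1, median_radius) > 0.5
  if (gaussian_sigma > 0) mask <- gaussian_blur(mask * 1, gaussian_sigma) > 0.5
  if (isTRUE(fill)) mask <- fill_holes(mask)
  list(threshold = thr, mask = mask)
}

#' K-means background removal
#'
#' Clusters pixels in a (hue, saturation, excess-green) feature space and
#' keeps as foreground the cluster(s) with the highest mean excess-green.
#'
#' @param crop RGB pot crop (0-255).
#' @param k Number of clusters (>= 2); reduced with a warning when the crop
#'   has fewer distinct feature rows.
#' @param seed Integer seed for the cluster initialization.
#' @param keep_ratio Clusters whose mean excess-green is at least this
#'   fraction of the best cluster's are also kept.
#' @param min_green Minimum mean excess-green (8-bit units) for any cluster
#'   to count as plant; below it the mask is empty.
#' @return Logical mask.
#' @export
kmeans_background_removal <- function(crop, k = 3L, seed = 1L,
                                      keep_ratio = 0.5, min_green = 10) {
  assert_rgb(crop)
  if (k < 2) rlang::abort("`k` must be >= 2")
  hsv <- rgb_to_hsv_img(crop)
  gi <- green_index(crop)
  feats <- cbind(as.vector(hsv$h) / 360, as.vector(hsv$s), as.vector(gi) / 255)
  n_distinct <- nrow(unique(feats))
  if (n_distinct < k) {
    rlang::warn(sprintf("only %d distinct colors; reducing k from %d", n_distinct, k))
    k <- max(2L, n_distinct)
    if (n_distinct < 2L) return(matrix(FALSE, nrow(gi), ncol(gi)))
  }
  set.seed(seed)
  km <- stats::kmeans(feats, centers = k, nstart = 3, iter.max = 50)
  mean_gi <- tapply(as.vector(gi), km$cluster, mean)
  best <- max(mean_gi)
  if (best < min_green) return(matrix(FALSE, nrow(gi), ncol(gi)))
  keep <- as.integer(names(mean_gi)[mean_gi >= keep_ratio * best &
                                      mean_gi >= min_green])
  matrix(km$cluster %in% keep, nrow(gi), ncol(gi))
}

#' Hue-histogram clustering segmentation
#'
#' Applies gamma correction, builds the hue histogram of
#' candidate-plant pixels (saturated, non-dark), smooths it with a
#' Savitzky-Golay filter, delimits the green mode at the valleys of the
#' smoothed curve, and keeps the pixels inside that hue range. Hue clusters
#' that are not spatially correlated with the dominant plant component
#' (8-connectivity within a dilation radius) are removed.
#'
#' @param crop RGB pot crop (0-255).
#' @param gamma Gamma correction exponent (> 0).
#' @param sg_window,sg_order Savitzky-Golay window (bins, odd) and
#'   polynomial order.
#' @param bins Number of hue histogram bins over 0-360 degrees.
#' @param green_range Hue interval (degrees) in which the plant mode is
#'   sought.
#' @param min_sat,min_val Saturation/value floors defining candidate
#'   pixels.
#' @param dilate_radius Spatial-correlation dilation radius (px).
#' @param min_area Components smaller than this (px) are dropped unless
#'   they are the dominant one.
#' @param min_green_excess Plant-presence gate: the selected object must
#'   average at least this much excess green (8-bit units); hue alone can
#'   be noise-rotated on near-neutral soil, but real plant tissue is
#'   actually green.
#' @return Logical mask (empty, with a warning, when there are no
#'   candidate pixels).
#' @export
hue_cluster_mask <- function(crop, gamma = 1, sg_window = 11L, sg_order = 3L,
                             bins = 180L, green_range = c(60, 180),
                             min_sat = 0.15, min_val = 0.08,
                             dilate_radius = 5L, min_area = 10L,
                             min_green_excess = 15) {
  assert_rgb(crop)
  if (gamma <= 0) rlang::abort("`gamma` must be > 0")
  img <- 255 * (clip255(crop) / 255)^gamma
  hsv <- rgb_to_hsv_img(img)
  # candidate plant pixels: chromatic (saturation above an adaptive Otsu
  # cut, floored at min_sat) and not near-black
  sat_thr <- tryCatch(otsu_binarize(hsv$s * 255)$threshold / 255,
                      error = function(e) min_sat)
  cand <- hsv$s >= max(min_sat, sat_thr) & hsv$v >= min_val
  # isolated chromatic noise pixels are not plant tissue: keep only solid
  # chromatic regions
  cand <- majority_filter(cand)
  empty <- matrix(FALSE, nrow(cand), ncol(cand))
  if (!any(cand)) {
    rlang::warn("no candidate (saturated) pixels; returning empty mask")
    return(empty)
  }
  width <- 360 / bins
  hb <- pmin(bins - 1L, floor(hsv$h[cand] / width))         # 0-based bins
  hist <- tabulate(hb + 1L, nbins = bins)
  sm <- savitzky_golay(hist, window = sg_window, order = sg_order,
                       circular = TRUE)
  green_bins <- which((seq_len(bins) - 0.5) * width >= green_range[1] &
                        (seq_len(bins) - 0.5) * width <= green_range[2])
  if (max(sm[green_bins]) <= 0 ||
      max(sm[green_bins]) < 0.05 * max(sm)) {
    return(empty)  # no plant-coloured mode (e.g. a soil-only pot)
  }
  mode_bin <- green_bins[which.max(sm[green_bins])]

  # hue clusters: contiguous bin ranges where the smoothed curve stays
  # above the intersection level between modes (circular)
  level <- 0.05 * sm[mode_bin]
  above <- sm > level
  if (!above[mode_bin]) return(empty)
  cluster_id <- integer(bins)
  cid <- 0L
  for (i in seq_len(bins)) {
    if (!above[i]) next
    if (i > 1 && above[i - 1]) cluster_id[i] <- cluster_id[i - 1] else {
      cid <- cid + 1L; cluster_id[i] <- cid
    }
  }
  if (above[1] && above[bins] && cluster_id[1] != cluster_id[bins]) {
    cluster_id[cluster_id == cluster_id[bins]] <- cluster_id[1]  # circular wrap
  }

  bin_of <- matrix(NA_integer_, nrow(cand), ncol(cand))
  bin_of[cand] <- hb + 1L
  seed_cluster <- cluster_id[mode_bin]
  seed_px <- !is.na(bin_of) & cluster_id[ifelse(is.na(bin_of), 1L, bin_of)] == seed_cluster &
    !is.na(bin_of)
  if (!any(seed_px)) return(empty)

  # dominant plant component and its halo for the spatial-correlation test
  lab <- label_components(seed_px, connectivity = 8L)
  sizes <- tabulate(lab[lab > 0])
  dominant <- which.max(sizes)
  out <- lab == dominant
  halo <- binary_dilate(out, dilate_radius)
  for (id in seq_along(sizes)) {
    if (id == dominant || sizes[id] < min_area) next
    if (any(lab == id & halo)) out <- out | lab == id
  }
  # other hue clusters join where their components touch the dilated plant
  # region (spatially correlated); disconnected artifacts are removed
  for (cl in setdiff(unique(cluster_id[cluster_id > 0]), seed_cluster)) {
    px <- !is.na(bin_of) & cluster_id[ifelse(is.na(bin_of), 1L, bin_of)] == cl
    if (!any(px)) next
    clab <- label_components(px, connectivity = 8L)
    for (id in seq_len(max(clab))) {
      comp <- clab == id
      if (sum(comp) < min_area) next
      if (any(comp & halo)) out <- out | comp
    }
  }
  if (any(out) && mean(green_index(img)[out]) < min_green_excess) {
    return(empty)  # hue-selected object is not green: no plant present
  }
  out
}

#' Pot-image features driving algorithm selection
#'
#' Otsu-binarizes the excess-green image and summarizes the crop: the
#' foreground area fraction, the mean hue of the foreground, and the mean
#' excess-green over the foreground.
#'
#' @param crop RGB pot crop (0-255).
#' @return One-row tibble: `fg_area_fraction`, `mean_hue`,
#'   `green_excess_mean`.
#' @export
segment_features <- function(crop) {
  gi <- green_index(crop)
  ot <- tryCatch(otsu_binarize(gi), error = function(e) NULL)
  if (is.null(ot) || !any(ot$mask)) {
    return(tibble::tibble(fg_area_fraction = 0, mean_hue = NA_real_,
                          green_excess_mean = 0))
  }
  hsv <- rgb_to_hsv_img(crop)
  tibble::tibble(
    fg_area_fraction = mean(ot$mask),
    mean_hue = mean(hsv$h[ot$mask]),
    green_excess_mean = mean(gi[ot$mask])
  )
}

#' Choose a segmentation algorithm from pot features
#'
#' Deterministic decision rules: a tiny or absent foreground calls for the
#' sensitive hue-histogram method; a large foreground with weak excess
#' green indicates a cluttered background best handled by K-means;
#' otherwise the shape-analysis-assisted hue pipeline is used.
#'
#' @param features One-row tibble from [segment_features()].
#' @param thresholds Named list: `fg_low` (default 0.01), `fg_high` (0.25),
#'   `green_low` (8-bit excess-green cutoff, default 40).
#' @return One of `"hue_histogram"`, `"kmeans"`, `"shape_analysis"`.
#' @export
select_algorithm <- function(features,
                             thresholds = list(fg_low = 0.01, fg_high = 0.25,
                                               green_low = 40)) {
  stopifnot(all(is.finite(features$fg_area_fraction)))
  if (features$fg_area_fraction < thresholds$fg_low) return("hue_histogram")
  if (features$fg_area_fraction > thresholds$fg_high &&
      features$green_excess_mean < thresholds$green_low) {
    return("kmeans")
  }
  "shape_analysis"
}

#' Pixel-wise majority vote over masks
#'
#' @param masks List of logical matrices of equal shape (>= 1). A pixel is
#'   foreground when it is set in at least half of the masks (ties count
#'   as foreground).
#' @return Logical mask.
#' @export
consensus_mask <- function(masks) {
  if (!length(masks)) rlang::abort("need at least one mask")
  d <- dim(masks[[1]])
  for (m in masks) {
    assert_mask(m)
    if (!all(dim(m) == d)) rlang::abort("masks must share one shape")
  }
  acc <- Reduce(`+`, lapply(masks, `*`, 1))
  acc >= length(masks) / 2
}

#' Repair over-segmentation by spatial interpolation
#'
#' Interior holes and narrow notches left by the iterative segmentation are
#' filled by interpolating a foreground-probability field from the
#' surrounding pixels (a Gaussian-kernel smoother - the standard
#' nearby-observation predictor) and thresholding it back to binary, plus
#' topological hole filling. Iterated to a fixed point, so the operation is
#' monotone (never removes foreground) and idempotent.
#'
#' @param mask Logical mask.
#' @param sigma Interpolation kernel SD in px (roughly the notch radius
#'   that gets filled).
#' @param threshold Probability above which a background pixel is
#'   converted (must exceed 0.5 so straight edges are stable).
#' @param max_iter Safety cap on fixed-point iterations.
#' @return Logical mask containing the input.
#' @export
repair_oversegmentation <- function(mask, sigma = 2, threshold = 0.6,
                                    max_iter = 25L) {
  assert_mask(mask)
  cur <- mask
  for (i in seq_len(max_iter)) {
    nxt <- fill_holes(cur)
    prob <- gaussian_blur(nxt * 1, sigma)
    nxt <- nxt | (prob >= threshold)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

#' Segmentation pipeline configuration
#'
#' @param n_gamma_iters Number of random-gamma iterations (odd keeps the
#'   majority vote clean).
#' @param gamma_range Uniform sampling range for gamma.
#' @param clahe_clip,clahe_grid CLAHE parameters ([enhance_contrast()]).
#' @param thresholds Decision-tree thresholds ([select_algorithm()]).
#' @param kmeans_k K for the K-means method.
#' @param sg_window,sg_order,dilate_radius,min_area Hue-method parameters
#'   ([hue_cluster_mask()]).
#' @param repair_sigma,repair_threshold Over-segmentation repair
#'   parameters.
#' @param median_radius Final mask median smoothing radius.
#' @return A named list of class `seg_config`.
#' @export
seg_config <- function(n_gamma_iters = 7L, gamma_range = c(0.6, 1.6),
                       clahe_clip = 2, clahe_grid = c(8L, 8L),
                       thresholds = list(fg_low = 0.01, fg_high = 0.25,
                                         green_low = 40),
                       kmeans_k = 3L,
                       sg_window = 11L, sg_order = 3L,
                       dilate_radius = 5L, min_area = 10L,
                       repair_sigma = 2, repair_threshold = 0.6,
                       median_radius = 1L) {
  structure(
    list(n_gamma_iters = n_gamma_iters, gamma_range = gamma_range,
         clahe_clip = clahe_clip, clahe_grid = clahe_grid,
         thresholds = thresholds, kmeans_k = kmeans_k,
         sg_window = sg_window, sg_order = sg_order,
         dilate_radius = dilate_radius, min_area = min_area,
         repair_sigma = repair_sigma, repair_threshold = repair_threshold,
         median_radius = median_radius),
    class = "seg_config"
  )
}

#' Segment the rosette from a pot crop
#'
#' Full pipeline: contrast enhancement, feature-driven algorithm selection,
#' `n_gamma_iters` runs of the chosen method under randomly drawn gamma
#' values, pixel-wise consensus, over-segmentation repair and final
#' smoothing. Deterministic for a fixed seed.
#'
#' @param crop RGB pot crop (0-255).
#' @param config A [seg_config()].
#' @param seed Integer seed controlling the gamma draws (and K-means
#'   initialization).
#' @return Logical mask with attributes `method` (the decision-tree choice)
#'   and `gammas` (the gamma values used).
#' @export
segment_rosette <- function(crop, config = seg_config(), seed = 1L) {
  assert_rgb(crop)
  set.seed(seed)
  img <- enhance_contrast(crop, config$clahe_clip, config$clahe_grid)
  feats <- segment_features(img)
  method <- select_algorithm(feats, config$thresholds)
  gammas <- stats::runif(config$n_gamma_iters,
                         config$gamma_range[1], config$gamma_range[2])
  masks <- vector("list", config$n_gamma_iters)
  for (i in seq_along(gammas)) {
    masks[[i]] <- if (method == "kmeans") {
      g <- 255 * (img / 255)^gammas[i]
      suppressWarnings(
        kmeans_background_removal(g, k = config$kmeans_k,
                                  seed = seed + 1000L + i)
      )
    } else {
      suppressWarnings(
        hue_cluster_mask(img, gamma = gammas[i],
                         sg_window = config$sg_window,
                         sg_order = config$sg_order,
                         dilate_radius = config$dilate_radius,
                         min_area = config$min_area)
      )
    }
  }
  mask <- consensus_mask(masks)
  if (any(mask)) {
    mask <- repair_oversegmentation(mask, config$repair_sigma,
                                    config$repair_threshold)
    if (config$median_radius > 0) {
      mask <- median_filter(mask * 1, config$median_radius) > 0.5
    }
    mask <- fill_holes(mask)
  }
  attr(mask, "method") <- method
  attr(mask, "gammas") <- gammas
  mask
}
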