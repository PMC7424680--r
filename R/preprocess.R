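#' Describe a tray layout of pots
#'
#' Pot bounding boxes use row-major pixel coordinates with origin at the
#' top-left and half-open rectangles `[row0, row1) x [col0, col1)`.
#'
#' @param n_rows,n_cols Pot grid dimensions.
#' @param pot_bboxes List (row-major order) of integer vectors
#'   `c(row0, col0, row1, col1)`. If `NULL`, a regular grid covering
#'   `image_size` is built.
#' @param image_size `c(rows, cols)` of the tray image (needed to build or
#'   validate boxes).
#' @param tray_id Identifier used in output file names.
#' @return Object of class `tray_layout`.
#' @export
tray_layout <- function(n_rows, n_cols, pot_bboxes = NULL,
                        image_size = NULL, tray_id = "tray1") {
  if (is.null(pot_bboxes)) {
    if (is.null(image_size)) rlang::abort("give `pot_bboxes` or `image_size`")
    rb <- floor(seq(0, image_size[1], length.out = n_rows + 1))
    cb <- floor(seq(0, image_size[2], length.out = n_cols + 1))
    pot_bboxes <- list()
    for (i in seq_len(n_rows)) for (j in seq_len(n_cols)) {
      pot_bboxes[[length(pot_bboxes) + 1L]] <-
        c(rb[i], cb[j], rb[i + 1], cb[j + 1])
    }
  }
  if (length(pot_bboxes) != n_rows * n_cols) {
    rlang::abort("need one bbox per pot (row-major)")
  }
  for (b in pot_bboxes) {
    if (length(b) != 4 || b[3] <= b[1] || b[4] <= b[2] || any(b[1:2] < 0)) {
      rlang::abort("bboxes must be c(row0, col0, row1, col1) with positive extent")
    }
    if (!is.null(image_size) && (b[3] > image_size[1] || b[4] > image_size[2])) {
      rlang::abort("bbox outside image bounds")
    }
  }
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 pot_bboxes = pot_bboxes, tray_id = tray_id),
            class = "tray_layout")
}

#' Denoise an image
#'
#' Median filter (suppresses salt-and-pepper noise) followed by a Gaussian
#' filter (suppresses high-frequency noise), applied channel-wise. Zero
#' parameters give the identity.
#'
#' @param img RGB array (0-255) or grayscale matrix.
#' @param median_radius Median window radius in px (0 = off).
#' @param gaussian_sigma Gaussian SD in px (0 = off).
#' @return Image of the same shape.
#' @export
denoise <- function(img, median_radius = 1L, gaussian_sigma = 0.8) {
  if (median_radius < 0 || gaussian_sigma < 0) {
    rlang::abort("filter parameters must be >= 0")
  }
  one <- function(m) gaussian_blur(median_filter(m, median_radius), gaussian_sigma)
  if (is.matrix(img)) return(one(img))
  assert_rgb(img)
  for (ch in 1:3) img[, , ch] <- one(img[, , ch])
  img
}

#' Gray-world color-constancy correction
#'
#' Rescales each channel so that all channel means equal the global mean
#' intensity of the input, the classical gray-world assumption for
#' removing an illuminant color cast.
#'
#' @param img RGB array (0-255).
#' @return Corrected RGB array (clipped to 0-255).
#' @export
gray_world <- function(img) {
  assert_rgb(img)
  means <- c(mean(img[, , 1]), mean(img[, , 2]), mean(img[, , 3]))
  if (any(means == 0)) rlang::abort("cannot rescale a channel with zero mean")
  target <- mean(means)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * target / means[ch]
  clip255(img)
}

#' Affine color correction from color-checker patches
#'
#' Fits, per channel, contrast and brightness coefficients `alpha`, `beta`
#' minimizing `sum (reference - (alpha * observed + beta))^2` over the card
#' patches, then applies the correction to the whole image.
#'
#' @param img RGB array (0-255).
#' @param observed_patches,reference_patches Numeric matrices `n x 3` of
#'   patch mean RGB values (observed in the image, and their true values);
#'   at least 2 patches.
#' @return List with `correction` (tibble `channel`, `alpha`, `beta`) and
#'   `image` (corrected RGB array).
#' @export
card_affine_correct <- function(img, observed_patches, reference_patches) {
  assert_rgb(img)
  obs <- as.matrix(observed_patches); ref <- as.matrix(reference_patches)
  if (nrow(obs) < 2 || !all(dim(obs) == dim(ref))) {
    rlang::abort("need >= 2 matching patch pairs")
  }
  alpha <- numeric(3); beta <- numeric(3)
  for (ch in 1:3) {
    x <- obs[, ch]; y <- ref[, ch]
    if (stats::var(x) == 0) rlang::abort("degenerate patches: observed values identical")
    fit <- stats::lm(y ~ x)
    alpha[ch] <- unname(fit$coefficients[2])
    beta[ch] <- unname(fit$coefficients[1])
    if (alpha[ch] <= 0) rlang::abort("fitted contrast coefficient must be positive")
    img[, , ch] <- alpha[ch] * img[, , ch] + beta[ch]
  }
  list(
    correction = tibble::tibble(channel = c("R", "G", "B"),
                                alpha = alpha, beta = beta),
    image = clip255(img)
  )
}

#' Crop per-pot images from a tray image
#'
#' One crop per pot bbox, in row-major order, expanded by `adaptive_margin`
#' pixels on every side and clipped to the image bounds.
#'
#' @param img RGB array of the tray.
#' @param layout A [tray_layout()].
#' @param adaptive_margin Margin in px added around each bbox.
#' @return Named list of RGB arrays (`{tray}_{row}_{col}`).
#' @export
crop_pots <- function(img, layout, adaptive_margin = 0L) {
  assert_rgb(img)
  stopifnot(inherits(layout, "tray_layout"))
  nr <- dim(img)[1]; nc <- dim(img)[2]
  out <- list()
  idx <- 0L
  for (i in seq_len(layout$n_rows)) for (j in seq_len(layout$n_cols)) {
    idx <- idx + 1L
    b <- layout$pot_bboxes[[idx]]
    if (b[3] > nr || b[4] > nc) {
      rlang::abort(sprintf("pot (%d, %d) bbox outside the image", i, j))
    }
    r0 <- max(0L, b[1] - adaptive_margin); c0 <- max(0L, b[2] - adaptive_margin)
    r1 <- min(nr, b[3] + adaptive_margin); c1 <- min(nc, b[4] + adaptive_margin)
    out[[sprintf("%s_%d_%d", layout$tray_id, i, j)]] <-
      img[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
  }
  out
}
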