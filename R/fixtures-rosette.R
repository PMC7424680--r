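#' Specify a synthetic rosette image
#'
#' Describes a top-view Arabidopsis-like rosette rendered as green ellipses
#' placed at golden-angle phyllotaxis around a common centre, over a plain,
#' soil-textured or pot-rim background. The renderer keeps exact per-leaf
#' ground truth, so segmentation and leaf-counting accuracy can be scored
#' without any external annotated dataset.
#'
#' @param n_leaves Number of leaves (>= 0). Leaf 1 is the oldest; younger
#'   leaves are drawn on top and may occlude older ones.
#' @param leaf_length_px,leaf_width_px Ellipse major/minor diameters in px.
#' @param phyllotaxis_angle Angular step between successive leaves, degrees
#'   (default 137.5, the golden angle).
#' @param overlap_fraction Target pairwise leaf overlap in `[0, 1]`. At 0 the
#'   placement is repaired until all leaves are pixel-disjoint.
#' @param background One of `"plain"`, `"soil"`, `"pot_rim"`.
#' @param noise_sd Additive Gaussian pixel noise SD (8-bit units).
#' @param image_size `c(rows, cols)`.
#' @return An object of class `rosette_spec`.
#' @export
rosette_spec <- function(n_leaves = 6L,
                         leaf_length_px = 40,
                         leaf_width_px = 18,
                         phyllotaxis_angle = 137.5,
                         overlap_fraction = 0.15,
                         background = c("plain", "soil", "pot_rim"),
                         noise_sd = 4,
                         image_size = c(160L, 160L)) {
  background <- match.arg(background)
  if (n_leaves < 0) rlang::abort("`n_leaves` must be >= 0")
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    rlang::abort("`overlap_fraction` must be in [0, 1]")
  }
  if (any(image_size <= 0)) rlang::abort("`image_size` must be positive")
  structure(
    list(
      n_leaves = as.integer(n_leaves),
      leaf_length_px = leaf_length_px,
      leaf_width_px = leaf_width_px,
      phyllotaxis_angle = phyllotaxis_angle,
      overlap_fraction = overlap_fraction,
      background = background,
      noise_sd = noise_sd,
      image_size = as.integer(image_size)
    ),
    class = "rosette_spec"
  )
}

# pixel mask of a rotated ellipse, centre (cr, cc), half-axes a (along theta), b
ellipse_mask <- function(nr, nc, cr, cc, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  r <- matrix(seq_len(nr), nr, nc) - cr
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  # image axes: theta measured from +col axis, rows grow downwards
  u <- c * cos(th) + r * sin(th)
  w <- -c * sin(th) + r * cos(th)
  (u / a)^2 + (w / b)^2 <= 1
}

#' Render a synthetic rosette image with ground truth
#'
#' Draws the rosette described by `spec` and returns both the RGB image and
#' pixel-exact ground truth: the binary rosette mask, a per-leaf label image
#' (younger leaves painted over older ones), the true leaf number and the
#' number of fully occluded leaves. A leaf covered at 95% or more by younger
#' leaves counts as occluded and its residual sliver of visible pixels is
#' assigned to the covering leaf, so the number of distinct labels always
#' equals `true_leaf_number - occluded_leaf_count`.
#'
#' @param spec A [rosette_spec()].
#' @param seed Integer seed; identical `spec` + `seed` give bit-identical
#'   output.
#' @param angles Optional vector of explicit leaf angles (degrees),
#'   overriding phyllotaxis placement. Useful to build occlusion fixtures by
#'   stacking two leaves at the same angle.
#' @param size_factors Optional per-leaf size multipliers, overriding the
#'   age grading (needed to build full-occlusion fixtures, where a younger
#'   leaf must be at least as large as the leaf it covers).
#' @return A list with elements `image` (RGB array, 0-255) and `truth`
#'   (list: `mask`, `leaf_labels`, `true_leaf_number`, `occluded_leaf_count`).
#' @export
generate_rosette_image <- function(spec, seed = 1L, angles = NULL,
                                   size_factors = NULL) {
  stopifnot(inherits(spec, "rosette_spec"))
  set.seed(seed)
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  n <- spec$n_leaves
  L <- spec$leaf_length_px; W <- spec$leaf_width_px
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2

  if (is.null(angles)) {
    jitter <- if (spec$overlap_fraction == 0) rep(0, max(n, 1)) else
      stats::runif(max(n, 1), -4, 4)
    angles <- (seq_len(max(n, 1)) - 1) * spec$phyllotaxis_angle + jitter[seq_len(max(n, 1))]
  }
  angles <- angles[seq_len(n)]

  # Leaves emanate from a small apex core, as in a real rosette, with
  # age-graded sizes (leaf 1, the oldest, is full size; younger leaves are
  # progressively smaller, down to 40%). The inner gap from the centre to
  # the leaf bases shrinks as the target overlap grows; the disjoint
  # construction (overlap 0) omits the core and spreads leaves out.
  size_f <- if (!is.null(size_factors)) size_factors[seq_len(n)] else if (n > 1)
    1 - 0.6 * (seq_len(n) - 1) / (n - 1) else rep(1, n)
  L_i <- L * size_f
  W_i <- W * size_f
  core_r <- max(3, 0.12 * L)
  gap <- if (spec$overlap_fraction == 0) {
    0.35 * L
  } else {
    min(core_r + 1,
        max(2, core_r - 2 + (0.35 - spec$overlap_fraction) * 0.3 * L))
  }
  d <- gap + L_i / 2

  # a leaf = petiole (thin stalk over the inner 45% of its length) plus
  # blade (ellipse over the outer 55%), as in a real Arabidopsis leaf;
  # petioles create the deep notches between neighbouring blades
  leaf_mask <- function(i) {
    sn <- sin(angles[i] * pi / 180); cs <- cos(angles[i] * pi / 180)
    base <- d[i] - L_i[i] / 2
    pet_len <- 0.45 * L_i[i]
    petiole <- ellipse_mask(nr, nc,
                            cr + (base + pet_len / 2) * sn,
                            cc + (base + pet_len / 2) * cs,
                            pet_len / 2 + 1, max(1.5, 0.12 * W_i[i]),
                            angles[i])
    blade <- ellipse_mask(nr, nc,
                          cr + (base + L_i[i] - 0.275 * L_i[i]) * sn,
                          cc + (base + L_i[i] - 0.275 * L_i[i]) * cs,
                          0.275 * L_i[i], W_i[i] / 2, angles[i])
    petiole | blade
  }

  masks <- lapply(seq_len(n), leaf_mask)

  if (n > 0 && spec$overlap_fraction == 0) {
    # push overlapping leaves outwards until pixel-disjoint
    for (iter in seq_len(60)) {
      occ <- matrix(0L, nr, nc)
      for (m in masks) occ <- occ + m
      if (!any(occ > 1L)) break
      moved <- FALSE
      for (i in seq_len(n)[-1]) {
        overlaps_earlier <- any(masks[[i]] & Reduce(`|`, masks[seq_len(i - 1)]))
        if (overlaps_earlier) {
          d[i] <- d[i] + 2
          masks[[i]] <- leaf_mask(i)
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    occ <- matrix(0L, nr, nc)
    for (m in masks) occ <- occ + m
    if (any(occ > 1L)) rlang::abort("image too small to place disjoint leaves")
  }

  if (n > 0) {
    max_extent <- max(d + L_i / 2)
    if (max_extent > min(nr, nc) / 2 - 1) {
      rlang::abort("image too small to hold the rosette")
    }
  }

  labels <- matrix(0L, nr, nc)
  for (i in seq_len(n)) labels[masks[[i]]] <- i  # younger leaves overwrite
  if (n > 0 && spec$overlap_fraction > 0) {
    # apex core: newest tissue, carried with the youngest leaf's label
    core <- ellipse_mask(nr, nc, cr, cc, core_r, core_r, 0)
    labels[core] <- n
  }

  occluded <- integer(0)
  if (n > 0) {
    for (i in seq_len(n)) {
      full <- sum(masks[[i]])
      visible <- sum(labels == i)
      if (full > 0 && visible / full <= 0.05) occluded <- c(occluded, i)
    }
    # reassign residual slivers of occluded leaves to their coverer
    for (i in occluded) {
      sliver <- labels == i
      if (any(sliver)) {
        cover <- integer(0)
        for (j in seq_len(n)) {
          if (j != i && !(j %in% occluded) && any(masks[[j]] & masks[[i]])) {
            cover <- c(cover, j)
          }
        }
        labels[sliver] <- if (length(cover)) max(cover) else 0L
      }
    }
    keep <- setdiff(seq_len(n), occluded)
    labels[labels > 0] <- match(labels[labels > 0], keep)
    labels[is.na(labels)] <- 0L
    storage.mode(labels) <- "integer"
  }
  mask <- labels > 0L

  # ---- render ---------------------------------------------------------------
  h <- matrix(0, nr, nc); s <- matrix(0, nr, nc); v <- matrix(0, nr, nc)
  if (spec$background == "plain") {
    h[] <- 30; s[] <- 0.05
    v[] <- 0.16 + stats::rnorm(nr * nc, 0, 0.01)
  } else {
    # low-saturation brown noise, lightly smoothed
    h[] <- stats::runif(nr * nc, 18, 42)
    s[] <- 0.18 + gaussian_blur(matrix(stats::runif(nr * nc, -0.08, 0.08), nr, nc), 1)
    v[] <- 0.34 + gaussian_blur(matrix(stats::runif(nr * nc, -0.12, 0.12), nr, nc), 1)
    if (spec$background == "pot_rim") {
      rr <- sqrt((matrix(seq_len(nr), nr, nc) - cr)^2 +
                   (matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc)^2)
      rim <- rr > 0.44 * min(nr, nc) & rr < 0.49 * min(nr, nc)
      h[rim] <- 15; s[rim] <- 0.30; v[rim] <- 0.22
    }
  }
  if (n > 0) {
    leaf_h <- stats::runif(n, 95, 125)
    leaf_s <- stats::runif(n, 0.55, 0.75)
    leaf_v <- stats::runif(n, 0.45, 0.65)
    vis <- labels_to_original(labels, keep = if (length(occluded)) setdiff(seq_len(n), occluded) else seq_len(n))
    for (i in seq_len(n)) {
      px <- vis == i
      if (!any(px)) next
      h[px] <- leaf_h[i]; s[px] <- leaf_s[i]; v[px] <- leaf_v[i]
    }
  }
  img <- hsv_to_rgb_img(h, s, v)
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
  }
  img <- round(clip255(img))

  list(
    image = img,
    truth = list(
      mask = mask,
      leaf_labels = labels,
      true_leaf_number = n,
      occluded_leaf_count = length(occluded)
    )
  )
}

# map renumbered labels back to original leaf indices for colouring
labels_to_original <- function(labels, keep) {
  out <- labels
  out[labels > 0] <- keep[labels[labels > 0]]
  out
}

#' Standard seeded fixture suite
#'
#' The 20-image evaluation suite used by the package's own accuracy checks:
#' leaf counts spanning 2-12, alternating plain and soil backgrounds,
#' moderate overlap, with image (and leaf) size growing with the leaf count
#' as larger plants fill more of the frame.
#'
#' @param n_images Number of images (default 20).
#' @param overlap_fraction Target leaf overlap (default 0.2).
#' @param seed_base Seeds are `seed_base + 1:n_images`.
#' @return A list of lists with elements `spec` ([rosette_spec()]) and
#'   `seed`.
#' @export
rosette_suite_specs <- function(n_images = 20L, overlap_fraction = 0.2,
                                seed_base = 100L) {
  n_leaves <- rep(2:12, length.out = n_images)
  lapply(seq_len(n_images), function(i) {
    n <- n_leaves[i]
    px <- if (n <= 6) 160L else if (n <= 9) 200L else 240L
    list(
      spec = rosette_spec(
        n_leaves = n,
        leaf_length_px = if (n <= 6) 40 else if (n <= 9) 46 else 52,
        leaf_width_px = if (n <= 6) 16 else if (n <= 9) 17 else 18,
        overlap_fraction = overlap_fraction,
        background = if (i %% 2 == 0) "soil" else "plain",
        image_size = c(px, px)
      ),
      seed = seed_base + i
    )
  })
}
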