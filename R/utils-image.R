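# Internal raster primitives. Images are numeric arrays (rows x cols x 3,
# 8-bit values 0..255 stored as doubles); masks are logical matrices; label
# images are integer matrices with 0 = background. No external image package
# is used: everything below operates on plain matrices.

assert_rgb <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    rlang::abort(sprintf("`%s` must be a rows x cols x 3 numeric array", arg))
  }
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    rlang::abort(sprintf("`%s` must be a logical matrix", arg))
  }
  invisible(mask)
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- max(1, 1 - dr):min(nr, nr - dr)
  src_c <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(src_r) < 1 || length(src_c) < 1) return(out)
  out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  out
}

offsets8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)
offsets4 <- cbind(dr = c(-1L, 0L, 0L, 1L), dc = c(0L, -1L, 1L, 0L))

# Median filter with square window of given radius; edges use the clipped
# (replicated) window. radius 0 is the identity. The common radius-1 case is
# a vectorized 9-element selection network; larger radii fall back to apply().
median_filter <- function(m, radius) {
  if (radius <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  planes <- matrix(NA_real_, nr * nc, nrow(offs))
  for (i in seq_len(nrow(offs))) {
    planes[, i] <- as.vector(shift_mat(m, offs$dr[i], offs$dc[i], fill = NA))
  }
  med <- apply(planes, 1L, stats::median, na.rm = TRUE)
  matrix(med, nr, nc)
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with edge renormalization (so constant images are
# exactly preserved at the borders). sigma 0 is the identity.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  conv_axis <- function(m, along_rows) {
    acc <- matrix(0, nrow(m), ncol(m))
    wacc <- matrix(0, nrow(m), ncol(m))
    ones <- matrix(1, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      d <- i - r - 1L
      if (along_rows) {
        acc <- acc + k[i] * shift_mat(m, d, 0, fill = 0)
        wacc <- wacc + k[i] * shift_mat(ones, d, 0, fill = 0)
      } else {
        acc <- acc + k[i] * shift_mat(m, 0, d, fill = 0)
        wacc <- wacc + k[i] * shift_mat(ones, 0, d, fill = 0)
      }
    }
    acc / wacc
  }
  conv_axis(conv_axis(m, TRUE), FALSE)
}

# Connected-component labelling: scanline runs + union-find over the runs
# (near-linear, unlike naive label propagation).
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) return(lab)
  grow <- if (connectivity == 8L) 1L else 0L

  # runs of TRUE per row
  run_row <- integer(0); run_c0 <- integer(0); run_c1 <- integer(0)
  for (i in seq_len(nr)) {
    x <- mask[i, ]
    if (!any(x)) next
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values
    run_row <- c(run_row, rep.int(i, sum(sel)))
    run_c0 <- c(run_c0, starts[sel])
    run_c1 <- c(run_c1, ends[sel])
  }
  nrun <- length(run_row)
  parent <- seq_len(nrun)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) { nxt <- parent[x]; parent[x] <<- root; x <- nxt }
    root
  }
  prev_idx <- integer(0)
  prev_row <- -1L
  row_of <- split(seq_len(nrun), run_row)
  rows_present <- as.integer(names(row_of))
  for (ri in seq_along(rows_present)) {
    i <- rows_present[ri]
    cur_idx <- row_of[[ri]]
    if (i - prev_row == 1L) {
      for (a in cur_idx) {
        for (b in prev_idx) {
          if (run_c0[a] <= run_c1[b] + grow && run_c1[a] >= run_c0[b] - grow) {
            ra <- find(a); rb <- find(b)
            if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
          }
        }
      }
    }
    prev_idx <- cur_idx
    prev_row <- i
  }
  roots <- vapply(seq_len(nrun), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  for (k in seq_len(nrun)) {
    lab[run_row[k], run_c0[k]:run_c1[k]] <- ids[k]
  }
  lab
}

binary_dilate <- function(mask, radius = 1L) {
  assert_mask(mask)
  if (radius <= 0) return(mask)
  out <- mask
  for (step in seq_len(radius)) {
    acc <- out
    for (i in seq_len(nrow(offsets8))) {
      acc <- acc | shift_mat(out, offsets8[i, 1], offsets8[i, 2], fill = FALSE)
    }
    out <- acc
  }
  out
}

# Fill interior holes: background components not connected (4-conn) to the
# image border become foreground.
fill_holes <- function(mask) {
  assert_mask(mask)
  bg <- label_components(!mask, connectivity = 4L)
  nr <- nrow(mask); nc <- ncol(mask)
  border_ids <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
  border_ids <- border_ids[border_ids > 0]
  holes <- bg > 0 & !(bg %in% border_ids)
  mask | holes
}

# Exact Euclidean distance transform (distance of each TRUE pixel to the
# nearest FALSE pixel), Felzenszwalb-Huttenlocher lower envelope, two passes.
distance_transform <- function(mask) {
  assert_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  INF <- (nr + nc)^2
  f <- matrix(0, nr, nc)
  f[mask] <- INF

  dt1d <- function(f) {
    n <- length(f)
    d <- numeric(n)
    v <- integer(n); z <- numeric(n + 1L)
    k <- 1L
    v[1L] <- 1L
    z[1L] <- -Inf; z[2L] <- Inf
    for (q in 2:n) {
      repeat {
        s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
        if (s <= z[k]) { k <- k - 1L } else break
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
    k <- 1L
    for (q in 1:n) {
      while (z[k + 1L] < q) k <- k + 1L
      d[q] <- (q - v[k])^2 + f[v[k]]
    }
    d
  }

  for (j in seq_len(nc)) f[, j] <- dt1d(f[, j])
  for (i in seq_len(nr)) f[i, ] <- dt1d(f[i, ])
  sqrt(f)
}

# Local maxima of `m` restricted to `mask`: pixels >= all 8 neighbours and
# >= min_value. Plateaus yield multiple candidates (callers merge them).
local_maxima <- function(m, mask = NULL, min_value = -Inf) {
  nbr_max <- matrix(-Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(offsets8))) {
    nbr_max <- pmax(nbr_max, shift_mat(m, offsets8[i, 1], offsets8[i, 2], fill = -Inf))
  }
  out <- m >= nbr_max & m >= min_value
  if (!is.null(mask)) out <- out & mask
  out
}

# RGB array (0..255) -> list(h in [0,360), s in [0,1], v in [0,1])
rgb_to_hsv_img <- function(img) {
  assert_rgb(img)
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  list(
    h = matrix(hsv[1, ] * 360, d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
}

# h in degrees, s and v in [0,1] -> RGB array 0..255
hsv_to_rgb_img <- function(h, s, v) {
  hx <- pmin(pmax(h / 360, 0), 1 - 1e-9)
  cols <- grDevices::hsv(hx, pmin(pmax(s, 0), 1), pmin(pmax(v, 0), 1))
  m <- grDevices::col2rgb(cols)
  out <- array(0, c(nrow(h), ncol(h), 3))
  out[, , 1] <- m[1, ]; out[, , 2] <- m[2, ]; out[, , 3] <- m[3, ]
  out
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Savitzky-Golay smoothing of a numeric vector (circular padding suits the
# periodic hue histogram this is used on).
savitzky_golay <- function(y, window = 11L, order = 3L, circular = TRUE) {
  window <- as.integer(window)
  if (window %% 2L == 0L) rlang::abort("Savitzky-Golay window must be odd")
  if (order >= window) rlang::abort("polynomial order must be < window")
  half <- (window - 1L) %/% 2L
  x <- -half:half
  A <- outer(x, 0:order, `^`)
  # convolution coefficients = first row of (A'A)^{-1} A'
  coef <- solve(crossprod(A), t(A))[1L, ]
  n <- length(y)
  if (circular) {
    ypad <- c(y[(n - half + 1L):n], y, y[1:half])
  } else {
    ypad <- c(rep(y[1L], half), y, rep(y[n], half))
  }
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(coef * ypad[i:(i + window - 1L)])
  out
}

# Fast 3x3 majority vote on a logical mask (pixel + 8 neighbours >= 5).
majority_filter <- function(mask) {
  acc <- mask * 1
  for (i in seq_len(nrow(offsets8))) {
    acc <- acc + shift_mat(mask * 1, offsets8[i, 1], offsets8[i, 2], fill = 0)
  }
  acc >= 5
}
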