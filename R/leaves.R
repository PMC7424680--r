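#' Extract closed contours of a binary mask
#'
#' Traces the outer boundary of every connected component (Moore
#' neighbourhood border following, 8-connectivity), ordered by component
#' area descending. Interior hole boundaries are reported separately.
#'
#' @param mask Logical mask.
#' @return List with `outer` (list of `n x 2` matrices of row/col pixel
#'   coordinates, one closed contour per component) and `holes` (same, one
#'   per interior hole). Empty mask gives empty lists.
#' @export
extract_contours <- function(mask) {
  assert_mask(mask)
  lab <- label_components(mask, connectivity = 8L)
  n_comp <- max(lab)
  if (n_comp == 0) return(list(outer = list(), holes = list()))
  sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  outer <- lapply(order(sizes, decreasing = TRUE), function(id) {
    trace_boundary(lab == id)
  })
  holes_mask <- fill_holes(mask) & !mask
  holes <- list()
  if (any(holes_mask)) {
    hlab <- label_components(holes_mask, connectivity = 4L)
    holes <- lapply(seq_len(max(hlab)), function(id) trace_boundary(hlab == id))
  }
  list(outer = outer, holes = holes)
}

# Moore-neighbour boundary tracing of a single component (clockwise).
trace_boundary <- function(comp) {
  idx <- which(comp, arr.ind = TRUE)
  start <- idx[order(idx[, 1], idx[, 2])[1], ]
  if (sum(comp) == 1) return(matrix(start, 1, 2, dimnames = NULL))
  # clockwise Moore neighbourhood starting from "west"
  moore <- cbind(
    dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
    dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  )
  inside <- function(p) {
    p[1] >= 1 && p[1] <= nrow(comp) && p[2] >= 1 && p[2] <= ncol(comp) &&
      comp[p[1], p[2]]
  }
  contour <- matrix(0L, 0, 2)
  cur <- start
  backtrack <- 1L  # start scanning from the west
  max_steps <- 4L * sum(comp) + 8L
  steps_done <- 0L
  repeat {
    contour <- rbind(contour, cur)
    found <- FALSE
    for (step in seq_len(8)) {
      k <- ((backtrack - 1L + step - 1L) %% 8L) + 1L
      cand <- cur + moore[k, ]
      if (inside(cand)) {
        backtrack <- ((k + 5L) %% 8L) + 1L  # rotate back two positions
        cur <- cand
        found <- TRUE
        break
      }
    }
    steps_done <- steps_done + 1L
    if (!found || steps_done > max_steps) break
    if (all(cur == start) && nrow(contour) > 1) break
  }
  dimnames(contour) <- NULL
  contour
}

#' Locate the rosette centre
#'
#' Centroid of the mask refined by a radius-free circular-symmetry vote:
#' every boundary pixel casts votes along its inward normal (the gradient
#' of the smoothed mask) and the blurred accumulator peak is taken as the
#' centre. When the vote is flat the plain centroid is returned.
#'
#' @param mask Logical mask (non-empty).
#' @return Numeric `c(row, col)`.
#' @export
rosette_center <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) rlang::abort("cannot locate the centre of an empty mask")
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  boundary <- mask & !shrink1(mask)
  bidx <- which(boundary, arr.ind = TRUE)
  if (nrow(bidx) < 8) return(centroid)
  sm <- gaussian_blur(mask * 1, 2)
  gr <- (shift_mat(sm, -1, 0) - shift_mat(sm, 1, 0)) / 2   # d/drow (inward)
  gc <- (shift_mat(sm, 0, -1) - shift_mat(sm, 0, 1)) / 2
  acc <- matrix(0, nrow(mask), ncol(mask))
  rmax <- ceiling(max(dim(mask)) / 2)
  for (i in seq_len(nrow(bidx))) {
    p <- bidx[i, ]
    g <- c(gr[p[1], p[2]], gc[p[1], p[2]])
    nrm <- sqrt(sum(g^2))
    if (nrm < 1e-6) next
    g <- g / nrm
    steps <- seq(2, rmax, by = 1)
    rr <- round(p[1] + g[1] * steps); cc <- round(p[2] + g[2] * steps)
    ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    if (any(ok)) {
      ij <- cbind(rr[ok], cc[ok])
      acc[ij] <- acc[ij] + 1
    }
  }
  acc <- gaussian_blur(acc, 2)
  peak <- max(acc)
  if (peak < max(5, 0.05 * nrow(bidx))) return(centroid)
  w <- which(acc == peak, arr.ind = TRUE)
  c(mean(w[, 1]), mean(w[, 2]))
}

# erosion by one pixel (8-neighbourhood)
shrink1 <- function(mask) {
  out <- mask
  for (i in seq_len(nrow(offsets8))) {
    out <- out & shift_mat(mask, offsets8[i, 1], offsets8[i, 2], fill = FALSE)
  }
  out
}

#' Place one marker per leaf candidate
#'
#' Markers follow the contour-analysis route: for every connected
#' component, the angular profile of the radial boundary extent around the
#' rosette centre is computed, smoothed (circular Savitzky-Golay), and its
#' peaks are taken as leaf tips — each visible leaf sticks out as one
#' angular lobe. Adjacent peaks separated by a shallow valley (radial
#' prominence below `merge_depth`) are fused. One marker is then placed
#' per tip, at the deepest point of the distance transform along the ray
#' from the centre through the tip, so markers sit at leaf centres. Small
#' or profile-less components (for instance a single round blob) fall back
#' to their distance-transform maximum, so no foreground component is ever
#' unmarked.
#'
#' @param mask Logical mask.
#' @param center Optional `c(row, col)` rosette centre; computed per
#'   component (centroid) when omitted.
#' @param min_marker_sep Minimum marker separation in px (safety merge,
#'   default 4).
#' @param merge_depth Radial prominence (px) below which two angular peaks
#'   count as one leaf (default 2).
#' @param bin_deg Angular bin width of the radial profile, degrees.
#' @param min_dt Minimum distance value for a marker position (default
#'   2.2 px: a genuine leaf blade is several pixels wide, whereas petiole
#'   ends and boundary spurs are not and must not carry markers).
#' @return Integer marker matrix (0 background, 1..M markers) with
#'   attribute `coords` (`M x 2`).
#' @export
leaf_markers <- function(mask, center = NULL, min_marker_sep = 4,
                         merge_depth = 2, bin_deg = 3, min_dt = 2.2) {
  assert_mask(mask)
  markers <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) {
    attr(markers, "coords") <- matrix(0, 0, 2)
    return(markers)
  }
  dt <- distance_transform(mask)
  lab <- label_components(mask, connectivity = 8L)
  accepted <- matrix(0, 0, 2)

  for (id in seq_len(max(lab))) {
    comp <- lab == id
    npx <- sum(comp)
    fallback <- which(comp & dt == max(dt[comp]), arr.ind = TRUE)[1, , drop = FALSE]
    if (npx < 40) { accepted <- rbind(accepted, fallback); next }
    ctr <- if (!is.null(center) && npx == sum(mask)) center else {
      ci <- which(comp, arr.ind = TRUE); c(mean(ci[, 1]), mean(ci[, 2]))
    }
    tips <- tip_angles(comp, ctr, bin_deg = bin_deg,
                       merge_depth = merge_depth)
    if (nrow(tips) <= 1) {
      # a single-lobe component's best marker is its deepest point
      accepted <- rbind(accepted, fallback); next
    }
    got <- 0L
    for (t in seq_len(nrow(tips))) {
      pos <- marker_on_ray(comp, dt, ctr, tips[t, 1], tips[t, 2],
                           min_dt = min_dt)
      if (!is.null(pos)) { accepted <- rbind(accepted, pos); got <- got + 1L }
    }
    if (got == 0L) accepted <- rbind(accepted, fallback)
  }

  # safety merge: never two markers closer than min_marker_sep
  if (nrow(accepted) > 1) {
    ord <- order(dt[accepted], decreasing = TRUE)
    accepted <- accepted[ord, , drop = FALSE]
    keep <- matrix(0, 0, 2)
    for (i in seq_len(nrow(accepted))) {
      p <- accepted[i, ]
      if (nrow(keep) == 0 ||
          min(sqrt((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2)) >=
          min_marker_sep) {
        keep <- rbind(keep, p)
      }
    }
    accepted <- keep
  }

  for (i in seq_len(nrow(accepted))) {
    markers[accepted[i, 1], accepted[i, 2]] <- i
  }
  dimnames(accepted) <- NULL
  attr(markers, "coords") <- accepted
  markers
}

# Tip detection along the traced contour ("finger counting"): local
# maxima of the centre distance r(t) along the closed boundary, kept when
# they clearly overtop their separating notches (absolute prominence >=
# merge_depth AND peak/valley ratio >= 1.25). Robust to angular masking by
# larger leaves because the contour, not the angle, is the parameter.
# Returns a matrix with columns (angle_rad, tip_radius).
tip_angles <- function(comp, ctr, bin_deg = 3, merge_depth = 2) {
  contour <- trace_boundary(fill_holes(comp))
  np <- nrow(contour)
  if (np < 12) return(matrix(0, 0, 2))
  r <- sqrt((contour[, 1] - ctr[1])^2 + (contour[, 2] - ctr[2])^2)
  win <- min(15L, (np %/% 2) * 2 - 1)
  if (win < 5) return(matrix(0, 0, 2))
  r_s <- savitzky_golay(r, window = win, order = 2L, circular = TRUE)

  nxt <- c(2:np, 1L); prv <- c(np, 1:(np - 1L))
  is_peak <- r_s >= r_s[nxt] & r_s >= r_s[prv]
  peaks <- which(is_peak)
  if (length(peaks) > 1) {
    peaks <- peaks[c(TRUE, diff(peaks) > 1)]        # collapse plateaus
    if (length(peaks) > 1 && peaks[1] == 1L && is_peak[np]) peaks <- peaks[-1]
  }
  # merge the weaker of any pair not separated by a clear notch
  while (length(peaks) > 1) {
    ord <- sort(peaks)
    merged <- FALSE
    for (i in seq_along(ord)) {
      a <- ord[i]; b <- ord[ifelse(i == length(ord), 1, i + 1)]
      if (a == b) next
      seg <- if (a < b) a:b else c(a:np, 1:b)
      valley <- min(r_s[seg])
      weaker <- min(r_s[a], r_s[b])
      if (weaker - valley < merge_depth ||
          (valley > 0 && weaker / valley < 1.25)) {
        peaks <- setdiff(peaks, if (r_s[a] < r_s[b]) a else b)
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  if (!length(peaks)) return(matrix(0, 0, 2))
  ang <- atan2(contour[peaks, 1] - ctr[1], contour[peaks, 2] - ctr[2])
  cbind(ang, r_s[peaks])
}

# Deepest distance-transform point on the ray from the centre towards a
# tip, restricted to the outer 70% of the tip radius (the leaf body).
marker_on_ray <- function(comp, dt, ctr, angle, tip_r, min_dt = 1) {
  radii <- seq(max(2, 0.3 * tip_r), tip_r, by = 0.5)
  rr <- round(ctr[1] + sin(angle) * radii)
  cc <- round(ctr[2] + cos(angle) * radii)
  ok <- rr >= 1 & rr <= nrow(comp) & cc >= 1 & cc <= ncol(comp)
  rr <- rr[ok]; cc <- cc[ok]
  if (!length(rr)) return(NULL)
  ij <- cbind(rr, cc)
  inside <- comp[ij] & dt[ij] >= min_dt
  if (!any(inside)) return(NULL)
  ij <- ij[inside, , drop = FALSE]
  ij[which.max(dt[ij]), , drop = FALSE]
}

# Grow labels from markers over `mask`, deeper (higher dt) neighbours
# claiming contested pixels first: a BFS approximation of watershed
# flooding of the inverted distance transform.
flood_from_markers <- function(mask, markers, dt) {
  lab <- markers
  lab[!mask] <- 0L
  repeat {
    src_dt <- dt
    src_dt[lab == 0L] <- -Inf
    best_dt <- matrix(-Inf, nrow(mask), ncol(mask))
    best_lab <- matrix(0L, nrow(mask), ncol(mask))
    for (i in seq_len(nrow(offsets8))) {
      ndt <- shift_mat(src_dt, offsets8[i, 1], offsets8[i, 2], fill = -Inf)
      nlab <- shift_mat(lab, offsets8[i, 1], offsets8[i, 2], fill = 0L)
      upd <- ndt > best_dt
      best_dt[upd] <- ndt[upd]
      best_lab[upd] <- nlab[upd]
    }
    newly <- mask & lab == 0L & best_lab > 0L
    if (!any(newly)) break
    lab[newly] <- best_lab[newly]
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Count leaves by marker-controlled watershed
#'
#' Floods the inverted distance transform from the leaf markers, restricted
#' to the mask: regions grow outwards from each marker, deeper (higher
#' distance) pixels claiming contested ground first, which splits touching
#' convex leaves along their waist. The number of regions is the measured
#' leaf count; with fully occluded leaves it undercounts by exactly the
#' number of hidden leaves.
#'
#' @param mask Logical mask.
#' @param markers Optional marker matrix from [leaf_markers()].
#' @param ... Passed to [leaf_markers()] when `markers` is `NULL`.
#' @return Object of class `leaf_labels`: list with `labels` (integer
#'   matrix whose nonzero support equals `mask` exactly), `leaf_count`, and
#'   `markers` (coordinate matrix).
#' @export
count_leaves <- function(mask, markers = NULL, ...) {
  assert_mask(mask)
  if (!any(mask)) {
    return(structure(
      list(labels = matrix(0L, nrow(mask), ncol(mask)),
           leaf_count = 0L, markers = matrix(0, 0, 2)),
      class = "leaf_labels"
    ))
  }
  if (is.null(markers)) markers <- leaf_markers(mask, ...)
  dt <- distance_transform(mask)
  lab <- flood_from_markers(mask, markers, dt)
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  structure(
    list(labels = lab, leaf_count = length(ids),
         markers = attr(markers, "coords")),
    class = "leaf_labels"
  )
}

#' @export
print.leaf_labels <- function(x, ...) {
  cat(sprintf("Leaf labelling: %d leaves over %d foreground pixels\n",
              x$leaf_count, sum(x$labels > 0)))
  invisible(x)
}
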