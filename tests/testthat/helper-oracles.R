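# Independent brute-force oracles and small fixture builders shared by the
# tests. These deliberately use plain loops and first-principles formulas,
# not the package's own code paths.

# exhaustive Otsu: try all 256 thresholds, maximize between-class variance;
# ties (flat plateaus across empty histogram stretches) resolve to the
# midpoint of the maximizing range, the convention otsu_binarize() states
oracle_otsu <- function(gray) {
  g <- as.vector(round(pmin(pmax(gray, 0), 255)))
  v <- rep(-Inf, 256)
  for (t in 0:255) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(g); w1 <- 1 - w0
    v[t + 1] <- w0 * w1 * (mean(lo) - mean(hi))^2
  }
  best <- which(v >= max(v) - 1e-12) - 1
  mean(range(best))
}

# Eq.-style MSD by explicit loop: mean over trend days t of
# (leaf(t - k) - trend(t))^2, over days where the shifted series exists
oracle_msd <- function(daily, trend_days, trend_vals, k, min_overlap = 5) {
  s <- 0; n <- 0L
  for (i in seq_along(trend_days)) {
    t <- trend_days[i]
    j <- which(daily$das == t - k)
    if (length(j) == 1 && !is.na(daily$leaf[j])) {
      s <- s + (daily$leaf[j] - trend_vals[i])^2
      n <- n + 1L
    }
  }
  if (n < min_overlap) return(NULL)
  list(msd = s / n, n = n)
}

oracle_select_shift <- function(ks, msds) {
  best <- NULL
  for (i in seq_along(ks)) {
    if (is.null(best) ||
        msds[i] < msds[best] - 1e-300 ||
        (msds[i] == msds[best] &&
         (abs(ks[i]) < abs(ks[best]) ||
          (abs(ks[i]) == abs(ks[best]) && ks[i] < ks[best])))) {
      best <- i
    }
  }
  ks[best]
}

oracle_area_adjust <- function(daily, trend_days, trend_vals, s, delta_range,
                               min_overlap = 5) {
  cand <- list()
  for (dd in -delta_range:delta_range) {
    acc <- 0; n <- 0
    for (i in seq_along(trend_days)) {
      t <- trend_days[i]
      j <- which(daily$das == t - s + dd)
      if (length(j) == 1 && !is.na(daily$area[j]) && daily$area[j] > 0) {
        acc <- acc + (log(daily$area[j]) - log(trend_vals[i]))^2
        n <- n + 1
      }
    }
    if (n >= min_overlap) cand[[length(cand) + 1]] <- c(dd, acc / n)
  }
  if (!length(cand)) return(0L)
  m <- do.call(rbind, cand)
  oracle_select_shift(m[, 1], m[, 2])
}

# disk mask helper
disk_mask <- function(nr, nc, cr, cc, radius) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (r - cr)^2 + (c - cc)^2 <= radius^2
}

# a single-plant daily tibble from explicit vectors
make_daily <- function(das, leaf, area = NA_real_, id = "p1") {
  tibble::tibble(plant_id = id, das = as.integer(das),
                 leaf = leaf, area = area)
}

# small population helper with package defaults overridable
quick_pop <- function(n_plants = 20, seed = 1, ...) {
  generate_population(population_spec(n_plants = n_plants, seed = seed, ...))
}
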