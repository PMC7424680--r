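test_that("contour extraction counts components and reports holes apart", {
  empty <- matrix(FALSE, 10, 10)
  expect_length(extract_contours(empty)$outer, 0L)
  sq <- matrix(FALSE, 12, 12); sq[4:8, 4:8] <- TRUE
  ct <- extract_contours(sq)
  expect_length(ct$outer, 1L)
  # the traced contour walks the component border
  expect_true(all(sq[ct$outer[[1]]]))
  expect_true(all(ct$outer[[1]] >= 4 & ct$outer[[1]] <= 8))
  two <- disk_mask(30, 30, 8, 8, 4) | disk_mask(30, 30, 22, 22, 4)
  expect_length(extract_contours(two)$outer, 2L)
  ring <- disk_mask(30, 30, 15, 15, 9) & !disk_mask(30, 30, 15, 15, 4)
  ct2 <- extract_contours(ring)
  expect_length(ct2$outer, 1L)
  expect_length(ct2$holes, 1L)
  # flood-fill oracle: hole = interior background component
  expect_true(all(!ring[ct2$holes[[1]]]))
})

test_that("rosette centre finds symmetric centres and blob centroids", {
  d <- disk_mask(41, 41, 21, 21, 12)
  expect_equal(rosette_center(d), c(21, 21), tolerance = 1)
  off <- disk_mask(41, 41, 12, 30, 6)
  expect_equal(rosette_center(off), c(12, 30), tolerance = 1.5)
  # symmetric 4-leaf rosette: centre within 2 px of the image centre
  fx <- generate_rosette_image(
    rosette_spec(n_leaves = 4, phyllotaxis_angle = 90, overlap_fraction = 0.2),
    seed = 1, size_factors = rep(1, 4)
  )
  expect_equal(rosette_center(fx$truth$mask), c(80.5, 80.5), tolerance = 2)
  expect_error(rosette_center(matrix(FALSE, 5, 5)), "empty")
})

test_that("markers: one per disjoint blob, two for overlapping disk pair", {
  three <- disk_mask(60, 60, 15, 15, 6) | disk_mask(60, 60, 15, 45, 6) |
    disk_mask(60, 60, 45, 30, 6)
  mk <- leaf_markers(three)
  co <- attr(mk, "coords")
  expect_identical(nrow(co), 3L)
  centres <- rbind(c(15, 15), c(15, 45), c(45, 30))
  for (i in 1:3) {
    expect_lte(min(sqrt((centres[, 1] - co[i, 1])^2 +
                          (centres[, 2] - co[i, 2])^2)), 1.5)
  }
  # two disks with centres 1.5 r apart still give two markers
  pair <- disk_mask(40, 60, 20, 22, 10) | disk_mask(40, 60, 20, 37, 10)
  expect_identical(nrow(attr(leaf_markers(pair), "coords")), 2L)
  # empty mask gives no markers
  expect_identical(nrow(attr(leaf_markers(matrix(FALSE, 5, 5)), "coords")), 0L)
})

test_that("count_leaves: label support equals the mask, counts match blobs", {
  expect_identical(count_leaves(matrix(FALSE, 8, 8))$leaf_count, 0L)
  three <- disk_mask(60, 60, 15, 15, 6) | disk_mask(60, 60, 15, 45, 6) |
    disk_mask(60, 60, 45, 30, 6)
  ll <- count_leaves(three)
  expect_identical(ll$leaf_count, 3L)
  expect_identical(ll$labels > 0L, three)   # support conservation
  # disjoint-blob property sweep
  for (k in c(0, 1, 5, 9, 12)) {
    sp <- rosette_spec(n_leaves = k, overlap_fraction = 0, leaf_length_px = 30,
                       leaf_width_px = 12, image_size = c(200L, 200L),
                       background = "plain")
    fx <- generate_rosette_image(sp, seed = 40 + k)
    res <- count_leaves(fx$truth$mask)
    expect_identical(res$leaf_count, as.integer(k))
    expect_identical(res$labels > 0L, fx$truth$mask)
  }
})

test_that("overlapping-rosette fixture is counted exactly at moderate overlap", {
  fx <- generate_rosette_image(
    rosette_spec(n_leaves = 6, overlap_fraction = 0.2, background = "plain"),
    seed = 23
  )
  expect_identical(count_leaves(fx$truth$mask)$leaf_count,
                   fx$truth$true_leaf_number - fx$truth$occluded_leaf_count)
})

test_that("full occlusion lowers the count by exactly the hidden leaves", {
  fx <- generate_rosette_image(
    rosette_spec(n_leaves = 4, overlap_fraction = 0.2), seed = 5,
    angles = c(15, 140, 15, 265), size_factors = c(1, 0.9, 1, 0.8)
  )
  expect_identical(fx$truth$occluded_leaf_count, 1L)
  expect_identical(count_leaves(fx$truth$mask)$leaf_count,
                   fx$truth$true_leaf_number - fx$truth$occluded_leaf_count)
})
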