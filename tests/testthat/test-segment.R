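test_that("global window thresholding: closed interval and nesting", {
  s <- intensity_stack(array(c(10L, 50L, 200L), c(3, 1, 1)))
  expect_identical(as.vector(apply_global_threshold(s, 44, 255)$mask),
                   c(0L, 1L, 1L))
  expect_identical(as.vector(apply_global_threshold(s, 0, 255)$mask),
                   c(1L, 1L, 1L))
  expect_identical(as.vector(apply_global_threshold(s, 50, 50)$mask),
                   c(0L, 1L, 0L))
  expect_error(apply_global_threshold(s, 100, 50), "exceeds")

  r <- rand_stack(5, c(8, 8, 4))
  prev <- Inf
  for (tmin in seq(0, 250, by = 25)) {
    n <- sum(apply_global_threshold(r, tmin)$mask)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("region growing equals the exhaustive flood-fill oracle", {
  for (seed in 1:5) {
    s <- rand_stack(seed, c(6, 6, 6), maxv = 9L)
    set.seed(seed * 100)
    for (conn in c(6L, 18L, 26L)) {
      tmin <- sample(0:5, 1); tmax <- sample(6:9, 1)
      inr <- which(s$voxels >= tmin & s$voxels <= tmax, arr.ind = TRUE)
      if (nrow(inr) == 0) next
      pick <- inr[sample(nrow(inr), 1), ]
      seed_xyz <- c(pick[2], pick[1], pick[3])
      got <- region_grow_3d(s, seed_xyz, tmin, tmax, conn)$mask == 1L
      want <- oracle_flood_fill(s$voxels, seed_xyz, tmin, tmax, conn)
      expect_identical(got, want,
                       label = sprintf("seed %d conn %d", seed, conn))
    }
  }
})

test_that("region growing is maximal, connected, and validates its seed", {
  s <- rand_stack(9, c(6, 6, 6), maxv = 9L)
  m <- region_grow_3d(s, c(1, 1, 1), s$voxels[1, 1, 1], 9, 26L)
  # maximality: no in-range voxel adjacent to the region is left out
  lab <- label_components_3d(binary_mask(s$voxels >= s$voxels[1, 1, 1] &
                                         s$voxels <= 9), 26L)
  expect_identical(m$mask == 1L, lab$labels == lab$labels[1, 1, 1])

  u <- intensity_stack(array(5L, c(3, 3, 3)))
  expect_true(all(region_grow_3d(u, c(2, 2, 2), 5, 5)$mask == 1L))

  iso <- array(0L, c(3, 3, 3)); iso[2, 2, 2] <- 8L
  one <- region_grow_3d(intensity_stack(iso), c(2, 2, 2), 5, 9)
  expect_equal(sum(one$mask), 1L)

  expect_error(region_grow_3d(u, c(2, 2, 2), 6, 9),
               "seed \\(2, 2, 2\\) rejected: intensity 5")
  expect_error(region_grow_3d(u, c(9, 1, 1), 0, 9), "outside stack bounds")
})

test_that("threshold nesting holds for growing from a fixed seed", {
  s <- rand_stack(13, c(8, 8, 4), maxv = 50L)
  s$voxels[4, 4, 2] <- 50L
  prev <- NULL
  for (tmin in c(40, 30, 20, 10, 0)) {
    m <- region_grow_3d(s, c(4, 4, 2), tmin, 50)$mask
    if (!is.null(prev)) expect_true(all(m[prev == 1L] == 1L))
    prev <- m
  }
})

test_that("wand ROI: rightward search, fill, and oracle equivalence", {
  # start left of a 10x10 in-range square on a 20x20 slice
  sl <- matrix(0L, 20, 20)
  sl[6:15, 8:17] <- 150L
  roi <- wand_roi(sl, 2, 10, 100, 255)
  expect_equal(sum(roi), 100L)
  expect_true(all(roi[6:15, 8:17]))

  # start point already in range
  roi2 <- wand_roi(sl, 10, 10, 100, 255)
  expect_identical(roi2, roi)

  # annulus: interior hole is filled
  ann <- matrix(0L, 21, 21)
  for (y in 1:21) for (x in 1:21) {
    r <- sqrt((x - 11)^2 + (y - 11)^2)
    if (r >= 4 && r <= 8) ann[y, x] <- 200L
  }
  roi3 <- wand_roi(ann, 1, 11, 100, 255)
  expect_true(roi3[11, 11]) # hole included
  comp_plus_hole <- oracle_label_bfs(array(as.integer(ann >= 100),
                                           c(21, 21, 1)), 26)[, , 1] > 0
  expect_true(all(roi3[comp_plus_hole]))

  expect_error(wand_roi(sl, 18, 1, 100, 255), "no pixel")
  expect_error(wand_roi(sl, 30, 10, 100, 255), "outside slice")
})

test_that("wand ROI equals 8-connected component with holes filled", {
  for (seed in 1:4) {
    set.seed(seed)
    sl <- matrix(0L, 24, 24)
    # blobby random foreground
    for (k in 1:4) {
      cx <- sample(5:20, 1); cy <- sample(5:20, 1); r <- sample(2:5, 1)
      for (y in 1:24) for (x in 1:24)
        if ((x - cx)^2 + (y - cy)^2 <= r^2) sl[y, x] <- 180L
    }
    hit <- which(sl[12, ] >= 100)
    if (length(hit) == 0) next
    roi <- wand_roi(sl, 1, 12, 100, 255)
    lab <- oracle_label_bfs(array(as.integer(sl >= 100), c(24, 24, 1)), 26)
    comp <- lab[, , 1] == lab[12, hit[1], 1]
    # oracle hole fill: background 4-components not touching the border
    bg <- oracle_label_bfs(array(as.integer(!comp), c(24, 24, 1)), 6)[, , 1]
    border_labs <- setdiff(unique(c(bg[1, ], bg[24, ], bg[, 1], bg[, 24])), 0)
    want <- comp | (bg != 0 & !(bg %in% border_labs))
    expect_identical(roi, want, label = paste("seed", seed))
  }
})

test_that("GT from ROI parameters groups per-object across slices", {
  # cylinder phantom: same disc on every slice
  a <- array(0L, c(20, 20, 8))
  for (z in 1:8) a[6:15, 8:17, z] <- 150L
  s <- intensity_stack(a)
  params <- data.frame(objectId = 1L, slice = 3:7, startX = 2L,
                       startY = 10L, thetaMin = 100L, thetaMax = NA)
  gt <- build_gt_from_roi_params(s, params, filter_radius = 1L)
  st <- object_stats(gt$labels)
  expect_identical(st$label, 1L)
  # the 3x3 median prefilter erodes the 4 corner pixels of the square,
  # so each slice ROI has 100 - 4 = 96 px
  expect_identical(st$voxels, 96L * 5L)
  expect_identical(sort(unique(which(apply(gt$labels$labels > 0, 3, any)))),
                   3:7)
  # identical per-slice ROIs from reused parameters
  for (z in 4:7)
    expect_identical(gt$labels$labels[, , z], gt$labels$labels[, , 3])

  empty <- build_gt_from_roi_params(s, params[0, ])
  expect_true(all(empty$labels$labels == 0L))

  # two objects claiming the same pixels
  params2 <- rbind(params[1, ],
                   transform(params[1, ], objectId = 2L))
  expect_error(build_gt_from_roi_params(s, params2, 1L), "overlap")
  lw <- build_gt_from_roi_params(s, params2, 1L, on_overlap = "last-wins")
  expect_identical(setdiff(unique(as.vector(lw$labels$labels)), 0L), 2L)
})

test_that("dual thresholding: boundary and degenerate behaviour", {
  ph <- standard_fixtures("deep-attenuated")[[1]]
  seeds <- phantom_seeds(ph)
  ex <- ph$spec$extra

  # z_sep = Z makes every seed shallow: deep seed fails the high threshold
  expect_warning(
    allsh <- dual_threshold_segment(ph$image, seeds, ex$theta_shallow,
                                    ex$theta_deep,
                                    z_sep = dim(ph$image$voxels)[3]),
    "skipped")
  expect_identical(attr(allsh, "skipped"), 2L)
  expect_identical(sort(setdiff(unique(as.vector(allsh$labels)), 0L)), 1L)

  # equal thresholds degenerate to plain per-seed growing
  eq <- dual_threshold_segment(ph$image, seeds, ex$theta_deep,
                               ex$theta_deep, z_sep = ex$z_sep)
  plain1 <- region_grow_3d(ph$image, seeds[1, ], ex$theta_deep)
  expect_identical(eq$labels == 1L, plain1$mask == 1L)
})

test_that("dual thresholding recovers what a global threshold cannot", {
  ph <- standard_fixtures("deep-attenuated")[[1]]
  ex <- ph$spec$extra
  dual <- dual_threshold_segment(ph$image, phantom_seeds(ph),
                                 ex$theta_shallow, ex$theta_deep, ex$z_sep)
  expect_identical(dual$labels, ph$truth$labels) # exact by construction

  glob <- label_components_3d(
    apply_global_threshold(ph$image, ex$theta_shallow))
  co <- object_correspondence(ph$truth, glob)
  expect_identical(co$fn_objects, 2L) # the deep nucleus is missed entirely
})
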