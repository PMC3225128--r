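make_labels <- function(arr) label_stack(arr)

test_that("confusion counts: identities and brute-force tally", {
  g <- array(0L, c(10, 10, 1)); g[1:6, 1:5, 1] <- 1L # 30 voxels
  gt <- make_labels(g)
  cc <- confusion_counts(gt, gt)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 30L, fp = 0L, fn = 0L, tn = 70L))

  cc2 <- confusion_counts(gt, make_labels(array(0L, c(10, 10, 1))))
  expect_equal(cc2$fn, 30L)
  expect_equal(cc2$tp, 0L)
  expect_equal(cc2$tn, 70L)

  for (seed in 1:3) {
    a <- rand_mask(seed, c(5, 5, 5)); b <- rand_mask(seed + 50, c(5, 5, 5))
    cc3 <- confusion_counts(make_labels(a), make_labels(b))
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (i in seq_along(a)) {
      if (a[i] & b[i]) tp <- tp + 1
      else if (!a[i] & b[i]) fp <- fp + 1
      else if (a[i] & !b[i]) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(unclass(cc3)[c("tp", "fp", "tn", "fn")],
                 list(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_equal(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 125)
  }

  expect_error(confusion_counts(gt, make_labels(array(0L, c(9, 10, 1)))),
               "shape")
})

test_that("pixel metrics: formulas and degenerate conventions", {
  pm <- pixel_metrics(list(tp = 8, fp = 2, fn = 8))
  expect_equal(pm$precision, 0.8)
  expect_equal(pm$recall, 0.5)
  expect_equal(pm$fmeasure, 2 * 0.8 * 0.5 / 1.3)

  perfect <- pixel_metrics(list(tp = 0, fp = 0, fn = 0))
  expect_equal(unlist(unclass(perfect)), c(precision = 1, recall = 1,
                                           fmeasure = 1))
  worst <- pixel_metrics(list(tp = 0, fp = 3, fn = 2))
  expect_equal(unlist(unclass(worst)), c(precision = 0, recall = 0,
                                         fmeasure = 0))
})

test_that("F is the harmonic mean: bounds on random confusion counts", {
  set.seed(99)
  for (i in 1:50) {
    cc <- list(tp = sample(0:50, 1), fp = sample(0:50, 1),
               fn = sample(0:50, 1))
    pm <- pixel_metrics(cc)
    expect_gte(pm$fmeasure, min(pm$precision, pm$recall) - 1e-12)
    expect_lte(pm$fmeasure, max(pm$precision, pm$recall) + 1e-12)
    expect_lte(pm$fmeasure, (pm$precision + pm$recall) / 2 + 1e-12)
  }
})

two_sphere_world <- function() {
  g <- array(0L, c(16, 16, 8))
  g[3:6, 3:6, 3:6] <- 1L
  g[10:13, 10:13, 3:6] <- 2L
  g
}

test_that("object correspondence: one-to-one, merged, split, FP, FN", {
  g <- two_sphere_world()
  gt <- make_labels(g)
  co <- object_correspondence(gt, gt)
  expect_equal(nrow(co$one_to_one), 2L)
  expect_length(co$split, 0)
  expect_length(co$merged, 0)
  expect_length(co$fp_objects, 0)
  expect_length(co$fn_objects, 0)

  # one MS blob covering both GT objects -> merged
  blob <- array(0L, c(16, 16, 8)); blob[2:14, 2:14, 2:7] <- 9L
  co2 <- object_correspondence(gt, make_labels(blob))
  expect_equal(names(co2$merged), "9")
  expect_equal(co2$merged[["9"]], c(1L, 2L))

  # one GT object covered by two MS halves -> split
  half <- array(0L, c(16, 16, 8))
  half[3:6, 3:4, 3:6] <- 5L; half[3:6, 5:6, 3:6] <- 6L
  gt1 <- array(0L, c(16, 16, 8)); gt1[3:6, 3:6, 3:6] <- 1L
  co3 <- object_correspondence(make_labels(gt1), make_labels(half))
  expect_equal(co3$split[["1"]], c(5L, 6L))

  # FP and FN objects
  ms <- array(0L, c(16, 16, 8)); ms[3:6, 3:6, 3:6] <- 1L
  ms[15, 15, 8] <- 7L
  co4 <- object_correspondence(gt, make_labels(ms))
  expect_identical(co4$fp_objects, 7L)
  expect_identical(co4$fn_objects, 2L)
})

test_that("minimum overlap fraction prunes incidental edges", {
  g <- array(0L, c(10, 10, 1)); g[1:10, 1:5, 1] <- 1L # 50 voxels
  m <- array(0L, c(10, 10, 1)); m[1:10, 5:10, 1] <- 1L # overlap = 10
  co <- object_correspondence(make_labels(g), make_labels(m))
  expect_equal(nrow(co$one_to_one), 1L)
  co2 <- object_correspondence(make_labels(g), make_labels(m),
                               min_overlap_fraction = 0.5)
  expect_identical(co2$fn_objects, 1L)
  expect_identical(co2$fp_objects, 1L)
})

test_that("every label is classified (exhaustiveness invariant)", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- oracle_label_bfs(rand_mask(seed, c(8, 8, 4), 0.3), 26)
    m <- oracle_label_bfs(rand_mask(seed + 10, c(8, 8, 4), 0.3), 26)
    co <- object_correspondence(make_labels(g), make_labels(m))
    ms_seen <- c(co$one_to_one$ms, unlist(co$split),
                 as.integer(names(co$merged)), co$fp_objects)
    gt_seen <- c(co$one_to_one$gt, unlist(co$merged),
                 as.integer(names(co$split)), co$fn_objects)
    expect_setequal(ms_seen, setdiff(unique(as.vector(m)), 0L))
    expect_setequal(gt_seen, setdiff(unique(as.vector(g)), 0L))
    # one-to-one and FP/FN are exclusive of everything else
    expect_length(intersect(co$one_to_one$ms,
                            c(unlist(co$split),
                              as.integer(names(co$merged)))), 0)
    expect_length(intersect(co$fp_objects,
                            c(co$one_to_one$ms, unlist(co$split),
                              as.integer(names(co$merged)))), 0)
    expect_length(intersect(co$fn_objects,
                            c(co$one_to_one$gt, unlist(co$merged),
                              as.integer(names(co$split)))), 0)
  }
})

test_that("GT/MS swap exchanges p<->r, split<->merged, FP<->FN; F invariant", {
  for (seed in 1:3) {
    g <- oracle_label_bfs(rand_mask(seed, c(8, 8, 4), 0.35), 26)
    m <- oracle_label_bfs(rand_mask(seed + 30, c(8, 8, 4), 0.35), 26)
    gt <- make_labels(g); ms <- make_labels(m)
    a <- benchmark_stacks(gt, ms)$stack
    b <- benchmark_stacks(ms, gt)$stack
    expect_equal(a$metrics$precision, b$metrics$recall)
    expect_equal(a$metrics$recall, b$metrics$precision)
    expect_equal(a$metrics$fmeasure, b$metrics$fmeasure)
    expect_equal(a$confusion$fp, b$confusion$fn)
    expect_equal(a$confusion$fn, b$confusion$fp)
    expect_equal(unname(a$objects$split), unname(b$objects$merged))
    expect_equal(a$objects$fp_objects, b$objects$fn_objects)
  }
})

test_that("per-slice correspondence pinpoints merge slices exactly", {
  ph <- standard_fixtures("merge-bridge")[[1]]
  ms <- label_components_3d(
    apply_global_threshold(ph$image, ph$spec$extra$theta_ms))
  expect_equal(max(ms$labels), 1L) # the bridge fuses both nuclei
  Z <- dim(ph$truth$labels)[3]
  merged_on <- integer(0)
  for (z in seq_len(Z)) {
    sc <- slice_correspondence(ph$truth, ms, z)
    if (length(sc$merged)) merged_on <- c(merged_on, z)
  }
  expect_identical(merged_on, ph$spec$extra$bridge_slices)

  # empty slice in both stacks
  sc_empty <- slice_correspondence(ph$truth, ms, Z)
  expect_equal(sc_empty$n_gt + sc_empty$n_ms, 0)
  expect_length(sc_empty$merged, 0)
  expect_error(slice_correspondence(ph$truth, ms, Z + 1), "slice")
})

test_that("a slice-local MS speck is a per-slice FP object", {
  g <- two_sphere_world()
  m <- g
  m[15, 2, 4] <- 3L # extra speck on slice 4 only
  sc <- slice_correspondence(make_labels(g), make_labels(m), 4)
  expect_identical(sc$fp_objects, 3L)
  sc5 <- slice_correspondence(make_labels(g), make_labels(m), 5)
  expect_length(sc5$fp_objects, 0)
})

test_that("benchmark report aggregates, conserves and serialises", {
  g <- two_sphere_world()
  gt <- make_labels(g)
  rep <- benchmark_stacks(gt, gt)
  expect_equal(rep$stack$metrics$fmeasure, 1)
  for (s in rep$slices) {
    expect_equal(s$metrics$precision, 1)
    expect_equal(s$metrics$recall, 1)
    expect_equal(s$metrics$fmeasure, 1)
  }
  # conservation: per-slice counts sum to stack counts
  for (f in c("tp", "fp", "tn", "fn")) {
    expect_equal(sum(vapply(rep$slices, function(s) s$confusion[[f]], 0)),
                 rep$stack$confusion[[f]])
  }

  csv <- withr::local_tempfile(fileext = ".csv")
  write_benchmark_csv(rep, csv)
  df <- read.csv(csv, check.names = FALSE)
  expect_identical(ncol(df), 8L + 2L) # measure + slice columns + stack
  expect_identical(colnames(df)[c(1, 2, ncol(df))],
                   c("measure", "slice1", "stack"))
  expect_equal(as.numeric(df[df$measure == "fmeasure", "stack"]), 1)

  # the 68-slice layout rule
  g68 <- array(0L, c(4, 4, 68)); g68[2, 2, 10] <- 1L
  rep68 <- benchmark_stacks(make_labels(g68), make_labels(g68))
  write_benchmark_csv(rep68, csv)
  expect_identical(ncol(read.csv(csv, check.names = FALSE)), 70L)
})

test_that("side-by-side visual stack puts MS left, GT right", {
  g <- two_sphere_world()
  m <- array(0L, c(16, 16, 8)); m[3:6, 3:6, 3:6] <- 4L
  sbs <- side_by_side_stack(make_labels(g), make_labels(m))
  expect_identical(dim(sbs$labels), c(16L, 32L, 8L))
  expect_identical(sbs$labels[, 1:16, ], m)
  expect_identical(sbs$labels[, 17:32, ], g)
})

test_that("contour overlay draws exactly the region boundary", {
  s <- intensity_stack(array(40L, c(9, 9, 1)))
  empty <- overlay_contours(s, binary_mask(array(0L, c(9, 9, 1))))
  for (ch in 1:3) expect_true(all(empty$pixels[, , ch, 1] == 40L))

  m <- array(0L, c(9, 9, 1)); m[3:7, 3:7, 1] <- 1L # 5x5 square
  ov <- overlay_contours(s, binary_mask(m))
  green <- ov$pixels[, , 1, 1] == 0 & ov$pixels[, , 2, 1] == 255 &
    ov$pixels[, , 3, 1] == 0
  expect_equal(sum(green), 16L) # perimeter of a 5x5 block

  full <- overlay_contours(s, binary_mask(array(1L, c(9, 9, 1))))
  greenf <- full$pixels[, , 2, 1] == 255 & full$pixels[, , 1, 1] == 0
  expect_equal(sum(greenf), 4 * 9 - 4) # image-border ring only
  expect_false(greenf[5, 5])
})
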