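# Pixel-level and object-level performance evaluation of a machine
# segmentation (MS) against a ground truth (GT), per stack and per slice.

#' Voxel confusion counts between GT and MS
#'
#' Foreground is any nonzero label.  `tp` counts voxels foreground in both,
#' `fp` foreground only in MS, `fn` foreground only in GT, `tn` the
#' remainder; the four always sum to the number of voxels compared.
#'
#' @param gt,ms [label_stack()] (or [binary_mask()]) objects of identical
#'   shape.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(gt, ms) {
  check_same_shape(gt, ms, "GT stack", "MS stack")
  g <- stack_data(gt) > 0L
  m <- stack_data(ms) > 0L
  tp <- sum(g & m)
  fp <- sum(!g & m)
  fn <- sum(g & !m)
  tn <- length(g) - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn,
              x$fn))
  invisible(x)
}

#' Precision, recall and F-measure from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)` and the F-measure is
#' their harmonic mean.  Degenerate conventions: if GT and MS are both
#' empty (`tp = fp = fn = 0`) the agreement is perfect and all three are 1;
#' if `tp = 0` with a nonempty union all three are 0.
#'
#' @param counts A `confusion_counts` object (or list with `tp`, `fp`,
#'   `fn`).
#' @return An object of class `pixel_metrics` with fields `precision`,
#'   `recall`, `fmeasure`.
#' @export
pixel_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp + fn == 0) {
    p <- r <- f <- 1
  } else if (tp == 0) {
    p <- r <- f <- 0
  } else {
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    f <- 2 * p * r / (p + r)
  }
  structure(list(precision = p, recall = r, fmeasure = f),
            class = "pixel_metrics")
}

#' @export
print.pixel_metrics <- function(x, ...) {
  cat(sprintf("precision=%.4f recall=%.4f F=%.4f\n", x$precision, x$recall,
              x$fmeasure))
  invisible(x)
}

# Correspondence classification shared by the 3D and per-slice routes.
# `g`, `m` are integer arrays/matrices of labels.
correspondence_from_arrays <- function(g, m, min_overlap_fraction = 0) {
  gv <- as.vector(g); mv <- as.vector(m)
  gt_labels <- sort(unique(gv[gv != 0L]))
  ms_labels <- sort(unique(mv[mv != 0L]))
  both <- gv != 0L & mv != 0L
  edges <- data.frame(gt = integer(0), ms = integer(0), overlap = integer(0))
  if (any(both)) {
    tab <- table(gt = gv[both], ms = mv[both])
    idx <- which(tab > 0, arr.ind = TRUE)
    edges <- data.frame(
      gt = as.integer(rownames(tab))[idx[, 1]],
      ms = as.integer(colnames(tab))[idx[, 2]],
      overlap = as.integer(tab[idx]))
    if (min_overlap_fraction > 0) {
      gt_size <- table(factor(gv[gv != 0L], levels = gt_labels))
      need <- min_overlap_fraction *
        as.numeric(gt_size[as.character(edges$gt)])
      edges <- edges[edges$overlap >= pmax(1, need), , drop = FALSE]
    }
    edges <- edges[order(edges$gt, edges$ms), , drop = FALSE]
  }
  deg_gt <- table(factor(edges$gt, levels = gt_labels))
  deg_ms <- table(factor(edges$ms, levels = ms_labels))
  one <- edges[deg_gt[as.character(edges$gt)] == 1 &
               deg_ms[as.character(edges$ms)] == 1, c("gt", "ms"),
               drop = FALSE]
  split_gt <- gt_labels[deg_gt >= 2]
  split <- lapply(split_gt, function(gl) sort(edges$ms[edges$gt == gl]))
  names(split) <- split_gt
  merged_ms <- ms_labels[deg_ms >= 2]
  merged <- lapply(merged_ms, function(ml) sort(edges$gt[edges$ms == ml]))
  names(merged) <- merged_ms
  structure(list(
    n_gt = length(gt_labels), n_ms = length(ms_labels),
    gt_labels = gt_labels, ms_labels = ms_labels,
    one_to_one = one, split = split, merged = merged,
    fp_objects = ms_labels[deg_ms == 0],
    fn_objects = gt_labels[deg_gt == 0],
    edges = edges), class = "correspondence_report")
}

#' @export
print.correspondence_report <- function(x, ...) {
  cat(sprintf(
    "objects: GT=%d MS=%d | one-to-one=%d split=%d merged=%d FP=%d FN=%d\n",
    x$n_gt, x$n_ms, nrow(x$one_to_one), length(x$split), length(x$merged),
    length(x$fp_objects), length(x$fn_objects)))
  invisible(x)
}

#' Object-level correspondence between GT and MS labels
#'
#' Builds the bipartite overlap graph between GT and MS objects (an edge
#' requires at least one shared foreground voxel, and at least
#' `min_overlap_fraction` of the GT object when that is positive) and
#' classifies: a GT object with no partner is a false negative; an MS
#' object with no partner a false positive; a GT object with two or more
#' MS partners is split (one-to-many); an MS object with two or more GT
#' partners is merged (many-to-one); degree-1/degree-1 pairs are
#' one-to-one.  In correspondence chains an object can appear both as a
#' split member and inside a merged group; classification is exhaustive
#' per label, not per pair.
#'
#' @param gt,ms [label_stack()] objects of identical shape.
#' @param min_overlap_fraction Minimum overlap as a fraction of the GT
#'   object's voxel count for an edge to count (default 0: one shared
#'   voxel suffices).
#' @return A `correspondence_report`: object counts, `one_to_one` pairs,
#'   `split` (GT label -> MS labels), `merged` (MS label -> GT labels),
#'   `fp_objects`, `fn_objects`, and the raw overlap `edges`.
#' @export
object_correspondence <- function(gt, ms, min_overlap_fraction = 0) {
  check_same_shape(gt, ms, "GT stack", "MS stack")
  correspondence_from_arrays(stack_data(gt), stack_data(ms),
                             min_overlap_fraction)
}

#' Per-slice object correspondence
#'
#' Applies the correspondence classification to the 2D cross-sections of
#' the 3D labels on one slice.  Labels keep their 3D identity (slices are
#' not re-labelled), so the report can name which 3D objects merge on
#' which slice -- this pinpoints the exact optical section where an ROI
#' merge occurs.
#'
#' @param gt,ms [label_stack()] objects of identical shape.
#' @param slice 1-based slice number.
#' @param min_overlap_fraction As in [object_correspondence()].
#' @return A `correspondence_report` for that slice.
#' @export
slice_correspondence <- function(gt, ms, slice, min_overlap_fraction = 0) {
  check_same_shape(gt, ms, "GT stack", "MS stack")
  d <- stack_dim(gt)
  if (slice < 1L || slice > d[3])
    stop("slice must lie in 1..", d[3])
  correspondence_from_arrays(stack_data(gt)[, , slice],
                             stack_data(ms)[, , slice],
                             min_overlap_fraction)
}

#' Full benchmark of an MS stack against a GT stack
#'
#' Aggregates pixel-level confusion counts and metrics plus object-level
#' correspondence for the whole stack and for every individual slice.
#'
#' @param gt,ms [label_stack()] objects of identical shape.
#' @param min_overlap_fraction As in [object_correspondence()].
#' @return An object of class `benchmark_report`: `stack` (fields
#'   `confusion`, `metrics`, `objects`) and `slices`, a list with one such
#'   entry per slice.
#' @export
benchmark_stacks <- function(gt, ms, min_overlap_fraction = 0) {
  check_same_shape(gt, ms, "GT stack", "MS stack")
  d <- stack_dim(gt)
  stack_part <- list(confusion = confusion_counts(gt, ms),
                     objects = object_correspondence(gt, ms,
                                                     min_overlap_fraction))
  stack_part$metrics <- pixel_metrics(stack_part$confusion)
  g3 <- stack_data(gt); m3 <- stack_data(ms)
  slices <- lapply(seq_len(d[3]), function(z) {
    g <- g3[, , z]; m <- m3[, , z]
    tp <- sum(g > 0L & m > 0L)
    fp <- sum(g == 0L & m > 0L)
    fn <- sum(g > 0L & m == 0L)
    cc <- structure(list(tp = tp, fp = fp, tn = length(g) - tp - fp - fn,
                         fn = fn), class = "confusion_counts")
    list(confusion = cc, metrics = pixel_metrics(cc),
         objects = correspondence_from_arrays(g, m, min_overlap_fraction))
  })
  structure(list(stack = stack_part, slices = slices, dim = d),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark over %d slice(s) of %d x %d pixels\n", x$dim[3],
              x$dim[1], x$dim[2]))
  cat("stack level: ")
  print(x$stack$metrics)
  print(x$stack$objects)
  invisible(x)
}

fmt_groups <- function(groups) {
  if (length(groups) == 0L) return("")
  paste(vapply(names(groups), function(k)
    paste0(k, "=", paste(groups[[k]], collapse = ";")), ""), collapse = "|")
}

fmt_labels <- function(v) paste(v, collapse = ";")

report_column <- function(part) {
  cc <- part$confusion; pm <- part$metrics; ob <- part$objects
  c(nGT = ob$n_gt, nMS = ob$n_ms,
    tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
    precision = format(pm$precision, digits = 6),
    recall = format(pm$recall, digits = 6),
    fmeasure = format(pm$fmeasure, digits = 6),
    mergedCount = length(ob$merged), mergedLabels = fmt_groups(ob$merged),
    splitCount = length(ob$split), splitLabels = fmt_groups(ob$split),
    fpObjectCount = length(ob$fp_objects),
    fpObjectLabels = fmt_labels(ob$fp_objects),
    fnObjectCount = length(ob$fn_objects),
    fnObjectLabels = fmt_labels(ob$fn_objects))
}

#' Write a benchmark report as CSV
#'
#' One column per optical slice (named `slice1`, `slice2`, ...) plus a
#' final whole-stack column; rows are the benchmark measures.  Groups of
#' merged/split labels are written as `owner=member;member` and multiple
#' groups are joined with `|`.
#'
#' @param report A [benchmark_stacks()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark_csv <- function(report, path) {
  stopifnot(inherits(report, "benchmark_report"))
  cols <- c(lapply(report$slices, report_column),
            list(report_column(report$stack)))
  m <- do.call(cbind, cols)
  colnames(m) <- c(paste0("slice", seq_along(report$slices)), "stack")
  df <- data.frame(measure = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Horizontally combined MS | GT visual stack
#'
#' Combines the MS (left) and GT (right) labelled stacks side by side so
#' the two segmentations can be compared slice by slice in any TIFF
#' viewer.
#'
#' @param gt,ms [label_stack()] objects of identical shape.
#' @return A [label_stack()] of width `2 * W`.
#' @export
side_by_side_stack <- function(gt, ms) {
  check_same_shape(gt, ms, "GT stack", "MS stack")
  d <- stack_dim(gt)
  out <- array(0L, dim = c(d[1], 2L * d[2], d[3]))
  out[, seq_len(d[2]), ] <- stack_data(ms)
  out[, d[2] + seq_len(d[2]), ] <- stack_data(gt)
  label_stack(out, calibration = gt$calibration)
}

slice_boundary <- function(m) {
  d <- dim(m)
  up <- rbind(FALSE, m[-d[1], , drop = FALSE])
  down <- rbind(m[-1, , drop = FALSE], FALSE)
  left <- cbind(FALSE, m[, -d[2], drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & down & left & right)
}

#' Draw segmentation contours on the original stack
#'
#' Produces an RGB copy of the grayscale stack in which the one-pixel
#' outer boundary of every 2D foreground region (a foreground pixel with a
#' 4-neighbour outside the region, image borders included) is drawn in a
#' solid colour, default green.  16-bit input is linearly rescaled to
#' 8 bits for display.
#'
#' @param stack An [intensity_stack()].
#' @param mask A [binary_mask()] of identical shape.
#' @param colour Length-3 integer RGB vector in 0..255.
#' @return An object of class `rgb_stack`: field `pixels` is an
#'   `(H, W, 3, Z)` array in 0..255, plus the stack's calibration.
#' @export
overlay_contours <- function(stack, mask, colour = c(0L, 255L, 0L)) {
  stopifnot(inherits(stack, "intensity_stack"))
  check_same_shape(stack, mask, "intensity stack", "mask")
  stopifnot(length(colour) == 3L, all(colour >= 0 & colour <= 255))
  d <- dim(stack$voxels)
  gray <- if (stack$bit_depth == 16L)
    round(stack$voxels / 65535 * 255) else stack$voxels
  px <- array(0L, dim = c(d[1], d[2], 3L, d[3]))
  for (z in seq_len(d[3])) {
    sl <- gray[, , z]
    b <- slice_boundary(mask$mask[, , z] == 1L)
    for (ch in 1:3) {
      chan <- sl
      chan[b] <- colour[ch]
      px[, , ch, z] <- chan
    }
  }
  structure(list(pixels = px, calibration = stack$calibration),
            class = "rgb_stack")
}

#' Write an RGB stack as a multi-page TIFF
#'
#' @param x An `rgb_stack` from [overlay_contours()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb_stack <- function(x, path) {
  stopifnot(inherits(x, "rgb_stack"))
  cal <- x$calibration
  write_tiff(path, x$pixels, bits = 8L, dx = cal$dx, dy = cal$dy,
             dz = cal$dz)
  invisible(path)
}
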