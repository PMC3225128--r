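# Ground-truth segmentation routes: global window thresholding, seeded 3D
# connected-threshold region growing, slice-wise wand ROIs and
# dual-threshold depth compensation.

theta_max_default <- function(stack) 2L^stack$bit_depth - 1L

check_window <- function(theta_min, theta_max) {
  if (!is.finite(theta_min) || !is.finite(theta_max))
    stop("thresholds must be finite numbers")
  if (theta_min > theta_max)
    stop("thetaMin (", theta_min, ") exceeds thetaMax (", theta_max, ")")
  invisible(TRUE)
}

#' Global window threshold
#'
#' A voxel is foreground iff its intensity lies in the closed interval
#' `[thetaMin, thetaMax]`.
#'
#' @param stack An [intensity_stack()].
#' @param theta_min,theta_max Intensity window; `theta_max` defaults to the
#'   maximum representable intensity of the stack's bit depth.
#' @return A [binary_mask()].
#' @export
apply_global_threshold <- function(stack, theta_min,
                                   theta_max = theta_max_default(stack)) {
  stopifnot(inherits(stack, "intensity_stack"))
  check_window(theta_min, theta_max)
  binary_mask(stack$voxels >= theta_min & stack$voxels <= theta_max,
              calibration = stack$calibration)
}

#' Seeded 3D connected-threshold region growing
#'
#' Grows from the seed voxel to the maximal connected set in which every
#' voxel's intensity lies in `[thetaMin, thetaMax]`, under the chosen
#' connectivity.  The result is independent of traversal order.
#'
#' @param stack An [intensity_stack()].
#' @param seed Integer vector `c(x, y, z)` of 1-based seed coordinates, or
#'   a one-row seed data frame from [read_seeds()].
#' @param theta_min,theta_max Intensity window; `theta_max` defaults to the
#'   maximum representable intensity.
#' @param connectivity 6, 18 or 26 (default 26, the most permissive).
#' @return A [binary_mask()] of the grown region.
#' @export
region_grow_3d <- function(stack, seed, theta_min,
                           theta_max = theta_max_default(stack),
                           connectivity = 26L) {
  stopifnot(inherits(stack, "intensity_stack"))
  check_window(theta_min, theta_max)
  if (is.data.frame(seed)) seed <- c(seed$x[1], seed$y[1], seed$z[1])
  if (length(seed) != 3L) stop("seed must be c(x, y, z)")
  d <- dim(stack$voxels)
  x <- as.integer(seed[1]); y <- as.integer(seed[2]); z <- as.integer(seed[3])
  if (x < 1L || x > d[2] || y < 1L || y > d[1] || z < 1L || z > d[3])
    stop(sprintf("seed (%d, %d, %d) outside stack bounds (%d x %d x %d)",
                 x, y, z, d[2], d[1], d[3]))
  sval <- stack$voxels[y, x, z]
  if (sval < theta_min || sval > theta_max)
    stop(sprintf(
      "seed (%d, %d, %d) rejected: intensity %d outside [%d, %d]",
      x, y, z, sval, as.integer(theta_min), as.integer(theta_max)))
  m <- .cpp_region_grow(stack$voxels, y - 1L, x - 1L, z - 1L,
                        as.integer(theta_min), as.integer(theta_max),
                        as.integer(connectivity))
  binary_mask(m, calibration = stack$calibration)
}

# Fill interior holes of a 2D logical mask: background 4-connected
# components that do not touch the image border become foreground.
fill_holes_2d <- function(mask) {
  d <- dim(mask)
  bg <- array(as.integer(!mask), dim = c(d[1], d[2], 1L))
  lab <- .cpp_label_components(bg, 6L) # 6 on one slice = 4-neighbourhood
  border <- unique(c(lab[1, , 1], lab[d[1], , 1], lab[, 1, 1], lab[, d[2], 1]))
  border <- setdiff(border, 0L)
  hole <- lab[, , 1] != 0L & !(lab[, , 1] %in% border)
  mask | hole
}

#' Wand-style 2D ROI selection
#'
#' Emulates the magic-wand selection used in slice-based ground-truth
#' editing: starting at `(startX, startY)` the slice is scanned rightwards
#' (+x) until a pixel with intensity in `[thetaMin, thetaMax]` is found
#' (the start pixel itself counts); the ROI is the filled interior of the
#' traced outer contour of the 8-connected in-range component containing
#' that pixel, i.e. the component with its interior holes included.
#'
#' @param slice_image Integer matrix `(H, W)`, normally a slice of the
#'   median-filtered stack.
#' @param start_x,start_y 1-based start pixel.
#' @param theta_min,theta_max Intensity window.
#' @return Logical matrix `(H, W)`, `TRUE` inside the ROI.
#' @export
wand_roi <- function(slice_image, start_x, start_y, theta_min, theta_max) {
  if (!is.matrix(slice_image)) stop("slice_image must be a matrix")
  check_window(theta_min, theta_max)
  d <- dim(slice_image)
  start_x <- as.integer(start_x); start_y <- as.integer(start_y)
  if (start_x < 1L || start_x > d[2] || start_y < 1L || start_y > d[1])
    stop(sprintf("start point (%d, %d) outside slice bounds", start_x,
                 start_y))
  row <- slice_image[start_y, , drop = TRUE]
  hit <- which(row >= theta_min & row <= theta_max & seq_along(row) >= start_x)
  if (length(hit) == 0L)
    stop(sprintf(
      "no pixel with intensity in [%d, %d] right of start point (%d, %d)",
      as.integer(theta_min), as.integer(theta_max), start_x, start_y))
  hx <- hit[1]
  in_range <- slice_image >= theta_min & slice_image <= theta_max
  lab <- .cpp_label_components(array(as.integer(in_range), c(d, 1L)), 26L)
  comp <- lab[, , 1] == lab[start_y, hx, 1]
  fill_holes_2d(comp)
}

#' Build a ground truth from stored wand ROI parameters
#'
#' The stack is median-filtered once (the wand operates on smoothed
#' intensities), then every ROI row is applied to its slice with
#' [wand_roi()].  All ROIs sharing one `objectId`, across slices, form one
#' 3D labelled object (label = objectId); the binary mask is the union of
#' all objects.  Rows whose `thetaMax` is `NA` use the maximum intensity of
#' the stack's bit depth.
#'
#' @param stack An [intensity_stack()] (raw, unfiltered).
#' @param params ROI parameter data frame from [read_roi_params()].
#' @param filter_radius Median prefilter radius (default 3, the 7 x 7
#'   window).
#' @param on_overlap `"error"` (default) to fail when two different
#'   objectIds claim the same voxel, or `"last-wins"` to let later rows
#'   override earlier ones.
#' @return A list with elements `mask` ([binary_mask()]) and `labels`
#'   ([label_stack()]).
#' @export
build_gt_from_roi_params <- function(stack, params, filter_radius = 3L,
                                     on_overlap = c("error", "last-wins")) {
  stopifnot(inherits(stack, "intensity_stack"))
  on_overlap <- match.arg(on_overlap)
  d <- dim(stack$voxels)
  labels <- array(0L, dim = d)
  if (nrow(params) > 0) {
    need <- c("objectId", "slice", "startX", "startY", "thetaMin", "thetaMax")
    stopifnot(all(need %in% names(params)))
    if (any(params$slice < 1L | params$slice > d[3]))
      stop("ROI slice number outside stack range 1..", d[3])
    smooth <- median_filter_2d(stack, filter_radius)
    tmax_default <- theta_max_default(stack)
    for (i in seq_len(nrow(params))) {
      p <- params[i, ]
      tmax <- if (is.na(p$thetaMax)) tmax_default else p$thetaMax
      roi <- wand_roi(smooth$voxels[, , p$slice], p$startX, p$startY,
                      p$thetaMin, tmax)
      sl <- labels[, , p$slice]
      clash <- roi & sl != 0L & sl != p$objectId
      if (any(clash)) {
        if (on_overlap == "error") {
          idx <- which(clash, arr.ind = TRUE)[1, ]
          stop(sprintf(
            "objects %d and %d overlap at pixel (x=%d, y=%d) on slice %d",
            sl[idx[1], idx[2]], p$objectId, idx[2], idx[1], p$slice))
        }
      }
      sl[roi] <- p$objectId
      labels[, , p$slice] <- sl
    }
  }
  list(mask = binary_mask(labels > 0L, calibration = stack$calibration),
       labels = label_stack(labels, calibration = stack$calibration))
}

#' Dual-threshold segmentation with depth compensation
#'
#' Compensates axial light attenuation by growing shallow and deep objects
#' with different minimum thresholds: a seed on a slice at or above the
#' demarcation slice `z_sep` (1-based; slice 1 is shallowest) uses
#' `theta_shallow`, a deeper seed uses `theta_deep`.  Each grown region is
#' written with its seed's `objectId` as label.  When regions collide the
#' first seed wins and a warning names the labels involved; a seed whose
#' intensity falls below its chosen threshold is skipped with a warning
#' (not a global failure).
#'
#' @param stack An [intensity_stack()].
#' @param seeds Seed data frame from [read_seeds()] (`objectId,x,y,z`,
#'   1-based).
#' @param theta_shallow,theta_deep Minimum thresholds for shallow and deep
#'   seeds.
#' @param z_sep Demarcation slice (1-based); `z_sep = Z` makes every seed
#'   shallow.
#' @param theta_max Maximum threshold, default the bit-depth maximum.
#' @param connectivity 6, 18 or 26.
#' @return A [label_stack()]; attribute `skipped` lists rejected seed ids.
#' @export
dual_threshold_segment <- function(stack, seeds, theta_shallow, theta_deep,
                                   z_sep,
                                   theta_max = theta_max_default(stack),
                                   connectivity = 26L) {
  stopifnot(inherits(stack, "intensity_stack"))
  d <- dim(stack$voxels)
  if (z_sep < 1L || z_sep > d[3])
    stop("demarcation slice must lie in 1..", d[3])
  labels <- array(0L, dim = d)
  skipped <- integer(0)
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    tmin <- if (s$z <= z_sep) theta_shallow else theta_deep
    grown <- tryCatch(
      region_grow_3d(stack, c(s$x, s$y, s$z), tmin, theta_max, connectivity),
      error = function(e) e)
    if (inherits(grown, "error")) {
      warning("seed ", s$objectId, " skipped: ", conditionMessage(grown),
              call. = FALSE)
      skipped <- c(skipped, s$objectId)
      next
    }
    m <- grown$mask == 1L
    clash <- m & labels != 0L
    if (any(clash)) {
      warning(sprintf(
        "object %d overlaps previously grown label(s) %s; first seed wins",
        s$objectId, paste(setdiff(unique(labels[clash]), 0L), collapse = ", ")),
        call. = FALSE)
      m <- m & labels == 0L
    }
    labels[m] <- s$objectId
  }
  out <- label_stack(labels, calibration = stack$calibration)
  attr(out, "skipped") <- skipped
  out
}
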