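#' Voxel calibration
#'
#' Physical size of one voxel in micrometres along x, y and z.  The voxel
#' volume `dx * dy * dz` converts voxel counts into \eqn{\mu m^3}.
#'
#' @param dx,dy,dz Strictly positive voxel spacings in micrometres.
#' @return An object of class `voxel_calibration` with fields `dx`, `dy`,
#'   `dz`.
#' @examples
#' cal <- voxel_calibration(0.2, 0.2, 1.0)
#' voxel_volume(cal) # 0.04 um^3
#' @export
voxel_calibration <- function(dx = 1, dy = 1, dz = 1) {
  for (v in list(dx, dy, dz)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("calibration spacings must be single strictly positive numbers")
  }
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 dz = as.numeric(dz)),
            class = "voxel_calibration")
}

#' @rdname voxel_calibration
#' @param cal A `voxel_calibration`.
#' @export
voxel_volume <- function(cal) {
  stopifnot(inherits(cal, "voxel_calibration"))
  cal$dx * cal$dy * cal$dz
}

#' @export
print.voxel_calibration <- function(x, ...) {
  cat(sprintf("voxel calibration: %g x %g x %g um (voxel volume %g um^3)\n",
              x$dx, x$dy, x$dz, voxel_volume(x)))
  invisible(x)
}

as_array3d <- function(x, what = "array") {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(what, " must be a 3D array (H, W, Z) or a matrix")
  if (any(dim(x) < 1L)) stop(what, " dimensions must all be >= 1")
  storage.mode(x) <- "integer"
  x
}

#' Calibrated grayscale image stack
#'
#' A 3D array of non-negative integer intensities with array layout
#' `[y, x, z]` (rows, columns, slices; slice 1 is the shallowest optical
#' section), a bit depth of 8 or 16, and a [voxel_calibration()].
#'
#' @param voxels 3D integer array `(H, W, Z)`; a matrix is treated as a
#'   single-slice stack.
#' @param bit_depth 8 or 16.
#' @param calibration A [voxel_calibration()].
#' @return An object of class `intensity_stack` with fields `voxels`,
#'   `bit_depth`, `calibration`.
#' @export
intensity_stack <- function(voxels, bit_depth = 8,
                            calibration = voxel_calibration()) {
  voxels <- as_array3d(voxels, "voxels")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (anyNA(voxels)) stop("voxels must not contain NA")
  if (min(voxels) < 0) stop("voxels must be non-negative")
  if (max(voxels) > 2^bit_depth - 1)
    stop("voxel values exceed 2^bit_depth - 1")
  stopifnot(inherits(calibration, "voxel_calibration"))
  structure(list(voxels = voxels, bit_depth = as.integer(bit_depth),
                 calibration = calibration),
            class = "intensity_stack")
}

#' Labelled object stack
#'
#' A 3D array of non-negative integer labels: 0 is background and each
#' positive value identifies one segmented object.  Labels need not be
#' contiguous.
#'
#' @param labels 3D integer array `(H, W, Z)` of labels; a matrix is
#'   treated as a single-slice stack.
#' @param calibration A [voxel_calibration()].
#' @return An object of class `label_stack` with fields `labels`,
#'   `calibration`.
#' @export
label_stack <- function(labels, calibration = voxel_calibration()) {
  labels <- as_array3d(labels, "labels")
  if (anyNA(labels)) stop("labels must not contain NA")
  if (min(labels) < 0) stop("labels must be non-negative")
  stopifnot(inherits(calibration, "voxel_calibration"))
  structure(list(labels = labels, calibration = calibration),
            class = "label_stack")
}

#' Binary foreground mask
#'
#' A 3D array of 0/1 values marking background/foreground voxels.
#'
#' @param mask 3D array of 0/1 (or logical) values; a matrix is treated as
#'   a single-slice stack.
#' @param calibration A [voxel_calibration()].
#' @return An object of class `binary_mask` with fields `mask`,
#'   `calibration`.
#' @export
binary_mask <- function(mask, calibration = voxel_calibration()) {
  if (is.logical(mask)) {
    storage.mode(mask) <- "integer"
  }
  mask <- as_array3d(mask, "mask")
  if (anyNA(mask)) stop("mask must not contain NA")
  if (!all(mask == 0L | mask == 1L)) stop("mask values must be 0 or 1")
  stopifnot(inherits(calibration, "voxel_calibration"))
  structure(list(mask = mask, calibration = calibration),
            class = "binary_mask")
}

stack_dim <- function(x) {
  dim(stack_data(x))
}

stack_data <- function(x) {
  if (inherits(x, "intensity_stack")) return(x$voxels)
  if (inherits(x, "label_stack")) return(x$labels)
  if (inherits(x, "binary_mask")) return(x$mask)
  stop("not a stack object")
}

#' @export
print.intensity_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("intensity_stack: %d x %d pixels, %d slices, %d-bit, range [%d, %d]\n",
              d[1], d[2], d[3], x$bit_depth, min(x$voxels), max(x$voxels)))
  print(x$calibration)
  invisible(x)
}

#' @export
print.label_stack <- function(x, ...) {
  d <- dim(x$labels)
  labs <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("label_stack: %d x %d pixels, %d slices, %d object label(s)\n",
              d[1], d[2], d[3], length(labs)))
  print(x$calibration)
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("binary_mask: %d x %d pixels, %d slices, %d foreground voxel(s)\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

check_same_shape <- function(a, b, what_a = "first stack",
                             what_b = "second stack") {
  da <- stack_dim(a); db <- stack_dim(b)
  if (!identical(da, db))
    stop(sprintf("%s has shape (%s) but %s has shape (%s)",
                 what_a, paste(da, collapse = ","),
                 what_b, paste(db, collapse = ",")))
  invisible(TRUE)
}
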