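#' Connected-component labelling in 3D
#'
#' Every maximal connected set of foreground voxels receives a distinct
#' label starting at 1, assigned in scan order of each component's first
#' voxel (y fastest, then x, then z), so labelling is deterministic.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A [label_stack()].
#' @export
label_components_3d <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- .cpp_label_components(mask$mask, as.integer(connectivity))
  label_stack(lab, calibration = mask$calibration)
}

#' Connected-component labelling of a 2D slice
#'
#' @param mask_slice Logical or 0/1 integer matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of labels, 0 = background.
#' @export
label_components_2d <- function(mask_slice, connectivity = 8L) {
  if (!is.matrix(mask_slice)) stop("mask_slice must be a matrix")
  if (!connectivity %in% c(4L, 8L)) stop("2D connectivity must be 4 or 8")
  conn3 <- if (connectivity == 4L) 6L else 26L
  m <- array(as.integer(mask_slice != 0), dim = c(dim(mask_slice), 1L))
  .cpp_label_components(m, conn3)[, , 1]
}

#' Per-object volumetry
#'
#' One record per distinct nonzero label, sorted by label: voxel count,
#' physical volume (voxel count times voxel volume, \eqn{\mu m^3}) and
#' centroid (arithmetic mean of 1-based voxel coordinates).
#'
#' @param labels A [label_stack()].
#' @return Data frame with columns `label`, `voxels`, `volume_um3`, `cx`,
#'   `cy`, `cz` (empty for an all-background stack).
#' @export
object_stats <- function(labels) {
  stopifnot(inherits(labels, "label_stack"))
  lab <- labels$labels
  fg <- which(lab != 0L)
  if (length(fg) == 0L)
    return(data.frame(label = integer(0), voxels = integer(0),
                      volume_um3 = numeric(0), cx = numeric(0),
                      cy = numeric(0), cz = numeric(0)))
  d <- dim(lab)
  vals <- lab[fg]
  idx0 <- fg - 1L
  y <- idx0 %% d[1] + 1L
  x <- (idx0 %/% d[1]) %% d[2] + 1L
  z <- idx0 %/% (d[1] * d[2]) + 1L
  f <- factor(vals)
  n <- as.integer(table(f))
  vv <- voxel_volume(labels$calibration)
  data.frame(label = as.integer(levels(f)),
             voxels = n,
             volume_um3 = n * vv,
             cx = as.numeric(tapply(x, f, mean)),
             cy = as.numeric(tapply(y, f, mean)),
             cz = as.numeric(tapply(z, f, mean)))
}
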