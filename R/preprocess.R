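#' Slice-wise 2D median filter
#'
#' Smooths every optical slice independently with a square median window of
#' side `2 * radius + 1` (radius 3 gives the 7 x 7 window used throughout
#' the ground-truth workflow).  Borders are handled by edge replication, so
#' no artificial dark rim is introduced next to the image edge.  The result
#' keeps the input's shape, bit depth and calibration.
#'
#' @param stack An [intensity_stack()].
#' @param radius Integer window radius in pixels, `>= 0`; 0 is the
#'   identity.
#' @return A filtered [intensity_stack()].
#' @examples
#' s <- intensity_stack(array(7L, c(8, 8, 2)))
#' identical(median_filter_2d(s, 3)$voxels, s$voxels) # constants unchanged
#' @export
median_filter_2d <- function(stack, radius = 3L) {
  stopifnot(inherits(stack, "intensity_stack"))
  if (!is.numeric(radius) || length(radius) != 1L || radius != round(radius) ||
      radius < 0)
    stop("radius must be a single non-negative integer")
  out <- .cpp_median_filter(stack$voxels, as.integer(radius))
  intensity_stack(out, bit_depth = stack$bit_depth,
                  calibration = stack$calibration)
}
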