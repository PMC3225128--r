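pages_to_array <- function(pages) {
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]]); Z <- length(pages)
  a <- array(0, dim = c(H, W, Z))
  for (z in seq_len(Z)) a[, , z] <- pages[[z]]
  a
}

resolve_calibration <- function(tf, calibration, path) {
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "voxel_calibration"))
    return(calibration)
  }
  if (is.finite(tf$dx) && is.finite(tf$dy)) {
    dz <- if (is.finite(tf$dz)) tf$dz else 1
    return(voxel_calibration(tf$dx, tf$dy, dz))
  }
  warning("no voxel calibration in '", basename(path),
          "' and no override given; assuming 1.0 um isotropic",
          call. = FALSE)
  voxel_calibration(1, 1, 1)
}

#' Read a grayscale multi-page TIFF as an intensity stack
#'
#' Page order is preserved: page 1 becomes slice 1 (the shallowest optical
#' section).  Voxel calibration is taken from the TIFF resolution tags and
#' ImageJ-style `spacing` description when present; an explicit
#' `calibration` always wins.  A file with neither triggers a warning and a
#' 1 um isotropic default.
#'
#' @param path Path to an uncompressed 8- or 16-bit grayscale TIFF stack.
#' @param calibration Optional [voxel_calibration()] override.
#' @return An [intensity_stack()].
#' @export
read_intensity_stack <- function(path, calibration = NULL) {
  tf <- read_tiff(path)
  if (tf$samples != 1L)
    stop("'", basename(path), "' is not grayscale (RGB stacks cannot be ",
         "read as intensity data)", call. = FALSE)
  if (!tf$bits %in% c(8L, 16L))
    stop("unsupported bit depth ", tf$bits,
         " for intensity data (want 8 or 16)", call. = FALSE)
  intensity_stack(pages_to_array(tf$pages), bit_depth = tf$bits,
                  calibration = resolve_calibration(tf, calibration, path))
}

#' Write an intensity stack as a multi-page grayscale TIFF
#'
#' @param stack An [intensity_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_stack <- function(stack, path) {
  stopifnot(inherits(stack, "intensity_stack"))
  cal <- stack$calibration
  write_tiff(path, stack$voxels, bits = stack$bit_depth,
             dx = cal$dx, dy = cal$dy, dz = cal$dz)
  invisible(path)
}

#' Write a labelled stack as a multi-page TIFF
#'
#' Labels up to 65535 are stored as 16-bit; anything larger as 32-bit.
#' The read-back is bit-exact.
#'
#' @param labels A [label_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_stack <- function(labels, path) {
  stopifnot(inherits(labels, "label_stack"))
  mx <- max(labels$labels)
  bits <- if (mx <= 65535) 16L else 32L
  cal <- labels$calibration
  write_tiff(path, labels$labels, bits = bits,
             dx = cal$dx, dy = cal$dy, dz = cal$dz)
  invisible(path)
}

#' Read a labelled stack from a multi-page TIFF
#'
#' @param path Path to an 8-, 16- or 32-bit integer TIFF stack (0 =
#'   background).
#' @param calibration Optional [voxel_calibration()] override.
#' @return A [label_stack()].
#' @export
read_label_stack <- function(path, calibration = NULL) {
  tf <- read_tiff(path)
  if (tf$samples != 1L)
    stop("'", basename(path), "' is not a single-channel label stack",
         call. = FALSE)
  label_stack(pages_to_array(tf$pages),
              calibration = resolve_calibration(tf, calibration, path))
}

#' Read object seed coordinates from CSV
#'
#' Accepts either a headered file with columns `objectId,x,y,z` or a
#' headerless 3-column `x,y,z` file, in which case ids 1..n are assigned in
#' file order.  Coordinates are 1-based: `x` is the column, `y` the row and
#' `z` the slice number as displayed by ImageJ.
#'
#' @param path CSV file path.
#' @return A data frame with columns `objectId`, `x`, `y`, `z`.
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- read.csv(path, header = has_header, strip.white = TRUE)
  if (!has_header) {
    if (ncol(df) != 3L)
      stop("headerless seed file must have exactly 3 columns (x,y,z)")
    names(df) <- c("x", "y", "z")
    df$objectId <- seq_len(nrow(df))
  } else {
    names(df) <- tolower(names(df))
    need <- c("objectid", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("seed file must have columns objectId,x,y,z")
    df <- data.frame(objectId = df$objectid, x = df$x, y = df$y, z = df$z)
  }
  df <- df[, c("objectId", "x", "y", "z")]
  for (cn in names(df)) {
    if (anyNA(df[[cn]]) || !is.numeric(df[[cn]]))
      stop("seed file column '", cn, "' contains non-numeric or missing values")
    df[[cn]] <- as.integer(df[[cn]])
  }
  if (anyDuplicated(df$objectId))
    stop("duplicate objectId in seed file: ",
         paste(unique(df$objectId[duplicated(df$objectId)]), collapse = ", "))
  if (any(df$objectId < 1L)) stop("objectId must be a positive integer")
  df
}

#' Write seeds to CSV
#'
#' @param seeds Data frame as returned by [read_seeds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seeds <- function(seeds, path) {
  stopifnot(all(c("objectId", "x", "y", "z") %in% names(seeds)))
  write.csv(seeds[, c("objectId", "x", "y", "z")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read wand ROI parameters from CSV
#'
#' Each row describes one 2D ROI: the object it belongs to, the 1-based
#' slice number, the wand start point (`startX`, `startY`, 1-based pixel
#' coordinates) and the intensity window `thetaMin..thetaMax`.  An empty
#' `thetaMax` means "maximum intensity of the bit depth", resolved when the
#' ROI is applied to a stack; it is returned as `NA` here.
#'
#' @param path CSV file with header
#'   `objectId,slice,startX,startY,thetaMin,thetaMax`.
#' @return A data frame with those six columns (`thetaMax` possibly `NA`).
#' @export
read_roi_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, header = TRUE, strip.white = TRUE)
  names(df) <- sub("^thetamin$", "thetaMin",
                   sub("^thetamax$", "thetaMax",
                       sub("^startx$", "startX",
                           sub("^starty$", "startY",
                               sub("^objectid$", "objectId",
                                   tolower(names(df)))))))
  need <- c("objectId", "slice", "startX", "startY", "thetaMin", "thetaMax")
  if (!all(need %in% names(df)))
    stop("ROI parameter file must have columns ",
         paste(need, collapse = ","))
  df <- df[, need]
  for (cn in setdiff(need, "thetaMax")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad))
      stop("malformed ROI parameter row ", bad[1], ": column '", cn,
           "' is not numeric")
    df[[cn]] <- as.integer(df[[cn]])
  }
  df$thetaMax <- suppressWarnings(as.numeric(df$thetaMax))
  df$thetaMax <- ifelse(is.na(df$thetaMax), NA_integer_,
                        as.integer(df$thetaMax))
  bad <- which(!is.na(df$thetaMax) & df$thetaMin > df$thetaMax)
  if (length(bad))
    stop("ROI parameter row ", bad[1], ": thetaMin (", df$thetaMin[bad[1]],
         ") exceeds thetaMax (", df$thetaMax[bad[1]], ")")
  if (any(df$objectId < 1L)) stop("objectId must be a positive integer")
  df
}

#' Write wand ROI parameters to CSV
#'
#' @param params Data frame as returned by [read_roi_params()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_params <- function(params, path) {
  need <- c("objectId", "slice", "startX", "startY", "thetaMin", "thetaMax")
  stopifnot(all(need %in% names(params)))
  write.csv(params[, need], path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}
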