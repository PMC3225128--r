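# Calibrated synthetic phantoms with exactly known ground truth.
#
# A phantom emulates the imaging challenges of live fluorescence z-stacks
# of labelled nuclei: bright roughly ellipsoidal nuclei, a diffuse haze of
# unincorporated label hugging them, small bright droplet-like blobs
# attached to or near nuclei, depth-dependent signal attenuation and read
# noise.  The ground truth is defined on the noiseless, unattenuated
# per-nucleus field, so corruption only ever affects the image, never the
# gold standard.

nucleus_profile <- function(rho, edge) {
  # plateau of 1 inside rho <= 1, smooth cosine falloff to 0 at rho = edge
  out <- numeric(length(rho))
  out[rho <= 1] <- 1
  ramp <- rho > 1 & rho < edge
  if (edge > 1)
    out[ramp] <- 0.5 * (1 + cos(pi * (rho[ramp] - 1) / (edge - 1)))
  out
}

#' Phantom specification
#'
#' @param shape Integer `c(H, W, Z)` stack shape.
#' @param nuclei List of nuclei, each `list(centre = c(x, y, z), radii =
#'   c(rx, ry, rz) or scalar, peak = intensity)`.  Truth label `k` is the
#'   voxel set where nucleus `k`'s noiseless, unattenuated field reaches
#'   `iso_level` after quantisation; nuclei must be placed so these truth
#'   regions are disjoint.
#' @param iso_level Intensity defining the true object surface; must
#'   satisfy `peak > iso_level > haze_amplitude`.
#' @param bit_depth 8 or 16.
#' @param calibration A [voxel_calibration()].
#' @param edge Ellipsoid falloff edge in normalised radius units (`>= 1`;
#'   1 gives hard-edged objects, larger values a smoother rim).
#' @param haze_amplitude Peak intensity of the diffuse haze halo around
#'   each nucleus (0 disables).
#' @param haze_scale Halo extent as a multiple of the nucleus radii.
#' @param droplets List of confounder blobs, each `list(centre = c(x, y,
#'   z), radius, intensity)`; never part of the truth.
#' @param attenuation Per-slice multiplicative decay: slice `z` is scaled
#'   by `exp(-attenuation * (z - 1))` (slice 1 is shallowest).
#' @param noise_sigma Additive Gaussian read-noise standard deviation.
#' @param noise `"gaussian"` (default) or `"poisson"`.
#' @param rng_seed Integer seed; phantoms are bit-reproducible given the
#'   seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, nuclei, iso_level, bit_depth = 8L,
                         calibration = voxel_calibration(0.25, 0.25, 1),
                         edge = 1.5, haze_amplitude = 0, haze_scale = 2.5,
                         droplets = list(), attenuation = 0,
                         noise_sigma = 0, noise = c("gaussian", "poisson"),
                         rng_seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  noise <- match.arg(noise)
  if (edge < 1) stop("edge must be >= 1")
  if (attenuation < 0 || noise_sigma < 0)
    stop("attenuation and noise_sigma must be >= 0")
  for (nuc in nuclei) {
    if (is.null(nuc$centre) || is.null(nuc$radii) || is.null(nuc$peak))
      stop("each nucleus needs centre, radii and peak")
    if (nuc$peak <= iso_level)
      stop("nucleus peak intensity must exceed iso_level")
  }
  if (length(nuclei) > 0 && haze_amplitude >= iso_level)
    stop("haze_amplitude must stay below iso_level")
  structure(list(shape = as.integer(shape), nuclei = nuclei,
                 iso_level = iso_level, bit_depth = as.integer(bit_depth),
                 calibration = calibration, edge = edge,
                 haze_amplitude = haze_amplitude, haze_scale = haze_scale,
                 droplets = droplets, attenuation = attenuation,
                 noise_sigma = noise_sigma, noise = noise,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

ellipsoid_rho <- function(coords, centre, radii) {
  if (length(radii) == 1L) radii <- rep(radii, 3L)
  sqrt(((coords$x - centre[1]) / radii[1])^2 +
       ((coords$y - centre[2]) / radii[2])^2 +
       ((coords$z - centre[3]) / radii[3])^2)
}

phantom_coords <- function(shape) {
  H <- shape[1]; W <- shape[2]; Z <- shape[3]
  list(y = array(rep(seq_len(H), times = W * Z), dim = shape),
       x = array(rep(rep(seq_len(W), each = H), times = Z), dim = shape),
       z = array(rep(seq_len(Z), each = H * W), dim = shape))
}

#' Generate a phantom from a specification
#'
#' Renders every nucleus as an ellipsoidal plateau with smooth falloff,
#' adds haze halos and droplet blobs, applies depth attenuation, adds
#' noise and quantises to the bit depth.  The truth labelling is derived
#' from the noiseless, unattenuated per-nucleus fields alone (haze and
#' droplets are confounders, attenuation and noise only corrupt the
#' image).
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: `image` (an
#'   [intensity_stack()]), `truth` (a [label_stack()]; nucleus `k` has
#'   label `k`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  co <- phantom_coords(shape)
  field <- array(0, dim = shape)
  truth <- array(0L, dim = shape)
  for (k in seq_along(spec$nuclei)) {
    nuc <- spec$nuclei[[k]]
    rho <- ellipsoid_rho(co, nuc$centre, nuc$radii)
    nf <- nuc$peak * nucleus_profile(rho, spec$edge)
    tr <- round(nf) >= spec$iso_level
    if (any(truth[tr] != 0L))
      stop("truth regions of nuclei ", unique(truth[tr][truth[tr] != 0L])[1],
           " and ", k, " overlap; place nuclei disjointly")
    truth[tr] <- k
    field <- field + nf
    if (spec$haze_amplitude > 0) {
      radii <- nuc$radii
      if (length(radii) == 1L) radii <- rep(radii, 3L)
      hrho <- ellipsoid_rho(co, nuc$centre, radii * spec$haze_scale)
      field <- field + spec$haze_amplitude * exp(-(hrho^2) / 0.5)
    }
  }
  for (dr in spec$droplets) {
    rho <- ellipsoid_rho(co, dr$centre, dr$radius)
    field <- field + dr$intensity * nucleus_profile(rho, spec$edge)
  }
  if (spec$attenuation > 0)
    field <- field * exp(-spec$attenuation * (co$z - 1))
  if (spec$noise_sigma > 0 || spec$noise == "poisson") {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(spec$rng_seed)
    if (spec$noise == "poisson") {
      field <- rpois(length(field), pmax(field, 0))
      dim(field) <- shape
    }
    if (spec$noise_sigma > 0)
      field <- field + rnorm(length(field), sd = spec$noise_sigma)
  }
  maxv <- 2^spec$bit_depth - 1
  img <- pmin(pmax(round(field), 0), maxv)
  dim(img) <- shape
  structure(list(
    image = intensity_stack(img, bit_depth = spec$bit_depth,
                            calibration = spec$calibration),
    truth = label_stack(truth, calibration = spec$calibration),
    spec = spec), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d nucleus/nuclei, iso level %g, seed %d\n",
              length(x$spec$nuclei), x$spec$iso_level, x$spec$rng_seed))
  print(x$image)
  invisible(x)
}

#' Seed table of a phantom
#'
#' Nucleus centres as a 1-based `objectId,x,y,z` seed data frame, ready
#' for [region_grow_3d()] or [dual_threshold_segment()].
#'
#' @param phantom A [generate_phantom()] result.
#' @return Seed data frame.
#' @export
phantom_seeds <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  ctr <- t(vapply(phantom$spec$nuclei,
                  function(n) as.numeric(n$centre), numeric(3)))
  data.frame(objectId = seq_along(phantom$spec$nuclei),
             x = as.integer(round(ctr[, 1])),
             y = as.integer(round(ctr[, 2])),
             z = as.integer(round(ctr[, 3])))
}

#' Deterministic named phantom fixtures
#'
#' Six pinned-seed phantoms exercising the failure modes the toolkit is
#' built around:
#' \describe{
#'   \item{`clean-nuclei`}{Three well-separated noiseless spheres; seeded
#'     growing at the iso level recovers each truth object exactly.}
#'   \item{`attached-droplet`}{A nucleus with one droplet touching it and
#'     one detached droplet nearby; a low threshold annexes the attached
#'     droplet and turns the detached one into a false-positive object.}
#'   \item{`free-histone`}{A metaphase-like elongated blob hugged by a
#'     haze halo; thresholds below the halo intensity inflate the object.}
#'   \item{`low-contrast`}{Haze amplitude close to the iso level plus
#'     strong noise, so global thresholding produces speckle.}
#'   \item{`deep-attenuated`}{Two identical nuclei at different depths
#'     under exponential attenuation: a single global threshold misses the
#'     deep one entirely, dual thresholding recovers both exactly
#'     (parameters in `spec$extra`: `theta_shallow`, `theta_deep`,
#'     `z_sep`).}
#'   \item{`merge-bridge`}{Two axially offset nuclei joined by a bright
#'     thin bridge present only on the slices in `spec$extra$bridge_slices`;
#'     thresholded MS merges them exactly there.}
#' }
#'
#' @param names Optional character vector selecting a subset.
#' @return Named list of `phantom` objects.
#' @export
standard_fixtures <- function(names = NULL) {
  specs <- list(
    "clean-nuclei" = phantom_spec(
      shape = c(64L, 64L, 24L),
      nuclei = list(
        list(centre = c(16, 16, 8), radii = c(6, 6, 4), peak = 200),
        list(centre = c(48, 16, 12), radii = c(6, 6, 4), peak = 200),
        list(centre = c(32, 48, 16), radii = c(5, 5, 4), peak = 200)),
      iso_level = 100, rng_seed = 101L),
    "attached-droplet" = phantom_spec(
      shape = c(64L, 64L, 16L),
      nuclei = list(
        list(centre = c(24, 24, 8), radii = c(6, 6, 4), peak = 200)),
      iso_level = 100,
      droplets = list(
        list(centre = c(33, 24, 8), radius = 2.5, intensity = 140),
        list(centre = c(50, 50, 8), radius = 2, intensity = 140)),
      noise_sigma = 2, rng_seed = 102L),
    "free-histone" = phantom_spec(
      shape = c(64L, 64L, 16L),
      nuclei = list(
        list(centre = c(32, 32, 8), radii = c(8, 4, 3), peak = 220)),
      iso_level = 110, haze_amplitude = 70, haze_scale = 2.2,
      noise_sigma = 3, rng_seed = 103L),
    "low-contrast" = phantom_spec(
      shape = c(64L, 64L, 16L),
      nuclei = list(
        list(centre = c(32, 32, 8), radii = c(7, 7, 4), peak = 160)),
      iso_level = 100, haze_amplitude = 85, haze_scale = 2.5,
      noise_sigma = 6, rng_seed = 104L),
    "deep-attenuated" = phantom_spec(
      shape = c(48L, 48L, 32L),
      nuclei = list(
        list(centre = c(16, 16, 6), radii = c(5, 5, 4), peak = 200),
        list(centre = c(32, 32, 24), radii = c(5, 5, 4), peak = 200)),
      iso_level = 100, edge = 1, attenuation = 0.04, rng_seed = 105L),
    "merge-bridge" = phantom_spec(
      shape = c(48L, 64L, 22L),
      nuclei = list(
        list(centre = c(20, 24, 8), radii = c(5, 5, 4), peak = 200),
        list(centre = c(44, 24, 14), radii = c(5, 5, 4), peak = 200)),
      iso_level = 100, edge = 1,
      droplets = lapply(seq(22, 42, by = 2), function(x)
        list(centre = c(x, 24, 11), radius = 1.6, intensity = 150)),
      rng_seed = 106L))
  extras <- list(
    "deep-attenuated" = list(theta_shallow = 120, theta_deep = 60,
                             z_sep = 15),
    "merge-bridge" = list(bridge_slices = 10:12, theta_ms = 120))
  if (is.null(names)) names <- base::names(specs)
  unknown <- setdiff(names, base::names(specs))
  if (length(unknown))
    stop("unknown fixture name(s): ", paste(unknown, collapse = ", "))
  out <- lapply(names, function(nm) {
    ph <- generate_phantom(specs[[nm]])
    ph$spec$extra <- extras[[nm]]
    ph
  })
  stats::setNames(out, names)
}
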