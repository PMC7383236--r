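#' Eye model for the larval zebrafish
#'
#' Bundles the gross optical geometry of the spherical larval eye: eyeball
#' diameter, monocular field of view, and the eye-convergence angles adopted
#' at rest and during hunting. The eyeball and lens are treated as concentric
#' spheres, so every retinal point collects light from the antipodal
#' direction through the lens center.
#'
#' @param eye_diameter Eyeball diameter in micrometers.
#' @param monocular_fov Monocular field of view in degrees.
#' @param convergence_rest,convergence_hunt Total binocular convergence angle
#'   (degrees) at rest and during prey pursuit.
#' @return An object of class `eye_model`.
#' @examples
#' eye_model()
#' @export
eye_model <- function(eye_diameter = 300, monocular_fov = 169,
                      convergence_rest = 36, convergence_hunt = 76) {
  if (!is.numeric(eye_diameter) || eye_diameter <= 0)
    stop("`eye_diameter` must be positive", call. = FALSE)
  if (!is.numeric(monocular_fov) || monocular_fov <= 0 || monocular_fov >= 360)
    stop("`monocular_fov` must lie in (0, 360) degrees", call. = FALSE)
  structure(
    list(eye_diameter = eye_diameter, monocular_fov = monocular_fov,
         convergence_rest = convergence_rest,
         convergence_hunt = convergence_hunt),
    class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat("<eye_model>\n")
  cat(sprintf("  eyeball diameter : %g um\n", x$eye_diameter))
  cat(sprintf("  monocular FOV    : %g deg\n", x$monocular_fov))
  cat(sprintf("  convergence      : %g deg (rest), %g deg (hunting)\n",
              x$convergence_rest, x$convergence_hunt))
  invisible(x)
}

#' Binocular overlap of the two visual fields
#'
#' Overlap of the two monocular fields for a given total convergence angle,
#' assuming laterally pointing eyes at rest that each rotate nose-ward by
#' half the convergence angle: overlap = FOV + convergence - 180.
#'
#' @param eye An [eye_model()].
#' @param convergence Total convergence angle in degrees; defaults to the
#'   model's resting value.
#' @return Overlap in degrees (can be negative if the fields do not meet).
#' @export
binocular_overlap <- function(eye = eye_model(), convergence = eye$convergence_rest) {
  eye$monocular_fov + convergence - 180
}

#' Photon catch probability of a cone outer segment
#'
#' Probability that a photon traversing a photoreceptor outer segment of
#' length `l` is absorbed, `F = l*k / (2.3 + l*k)`, the saturating
#' length-dependence measured for cyprinid photoreceptors. `k` is the
#' photoreceptor-type-specific absorption coefficient.
#'
#' @param l Outer segment length in micrometers (vectorized).
#' @param k Absorption coefficient per micrometer.
#' @return Absorption probability in `[0, 1)`.
#' @examples
#' photon_catch(9.0) / photon_catch(0.6)  # strike-zone vs ventral cones
#' @export
photon_catch <- function(l, k = 0.03) {
  if (any(!is.finite(l)) || any(l < 0))
    stop("outer segment length `l` must be finite and >= 0", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("absorption coefficient `k` must be a single positive number",
         call. = FALSE)
  l * k / (2.3 + l * k)
}

#' Visual angle subtended by an object
#'
#' Exact angular subtense `2*atan((size/2)/distance)` of an object seen from
#' a given distance. A 100-um paramecium subtends ~5.7 deg at 1 mm strike
#' distance but only ~1.8 deg at the 3.25 mm detection limit.
#'
#' @param object_size Object diameter in micrometers.
#' @param distance Viewing distance in millimeters.
#' @return Angle in degrees.
#' @examples
#' angular_subtense(100, 1.0)
#' angular_subtense(100, 3.25)
#' @export
angular_subtense <- function(object_size, distance) {
  if (any(!is.finite(distance)) || any(distance <= 0))
    stop("`distance` must be positive", call. = FALSE)
  if (any(!is.finite(object_size)) || any(object_size < 0))
    stop("`object_size` must be >= 0", call. = FALSE)
  2 * atan((object_size / 2) / (distance * 1000)) * 180 / pi
}

#' Composite fold-variation in UV sensitivity
#'
#' Multiplies the independent factors that set regional UV sensitivity:
#' cone-density fold, photon-catch fold, and (optionally) the factor-2
#' binocular superposition of the two strike zones once the eyes converge.
#'
#' @param density_fold Cone density ratio (>= 1).
#' @param catch_fold Photon-catch probability ratio (>= 1).
#' @param binocular If `TRUE`, double for binocular superposition.
#' @return The composite sensitivity fold.
#' @examples
#' sensitivity_fold(3, 14)        # monocular
#' sensitivity_fold(3, 14, TRUE)  # binocular, eyes converged
#' @export
sensitivity_fold <- function(density_fold, catch_fold, binocular = FALSE) {
  stopifnot(is.numeric(density_fold), is.numeric(catch_fold),
            all(density_fold >= 1), all(catch_fold >= 1))
  density_fold * catch_fold * (if (isTRUE(binocular)) 2 else 1)
}

## ---- retinal point sets & projection ------------------------------------

#' Points on the retinal sphere
#'
#' A set of retinal positions stored as unit vectors on the eye sphere.
#' Accepts either an n x 3 matrix of (possibly unnormalized) 3-D coordinates
#' or an n x 2 matrix of (latitude, longitude) in degrees.
#'
#' @param points Numeric matrix, n x 3 (x, y, z) or n x 2 (lat_deg, lon_deg).
#' @param labels Optional character vector of zone tags.
#' @param tol Tolerance for the on-sphere check after normalization.
#' @return A `retinal_points` object: list with unit-vector matrix `xyz` and
#'   `labels`.
#' @export
retinal_points <- function(points, labels = NULL, tol = 1e-6) {
  points <- as.matrix(points)
  if (ncol(points) == 2L) {
    lat <- points[, 1] * pi / 180
    lon <- points[, 2] * pi / 180
    xyz <- cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
  } else if (ncol(points) == 3L) {
    r <- sqrt(rowSums(points^2))
    if (any(r == 0)) stop("zero-length retinal vector", call. = FALSE)
    if (any(abs(r - 1) > 1e-3 + tol)) {
      # accept raw coordinates on a sphere of any radius, normalize
      points <- points / r
    } else {
      points <- points / r
    }
    xyz <- points
  } else stop("`points` must have 2 or 3 columns", call. = FALSE)
  if (!is.null(labels) && length(labels) != nrow(xyz))
    stop("`labels` length must match number of points", call. = FALSE)
  structure(list(xyz = xyz, labels = labels), class = "retinal_points")
}

#' Project retinal points into the visual field
#'
#' Maps each retinal point to the visual direction it surveys: the straight
#' line from the retinal location through the common center of eyeball and
#' lens, i.e. the antipodal direction on the sphere, expressed as (azimuth,
#' elevation) in degrees. `eye_azimuth` rotates the whole eye about the
#' vertical axis (positive = nose-ward), so a laterally resting right eye is
#' `eye_azimuth = 90`.
#'
#' Points that project onto the vertical poles (|elevation| = 90) have an
#' undefined azimuth; they are kept and flagged in the `singular` column
#' rather than dropped.
#'
#' @param retina A [retinal_points()] object.
#' @param eye An [eye_model()] (carried for provenance; the projection is
#'   purely directional).
#' @param eye_azimuth Azimuthal rotation of the optical axis, degrees.
#' @return A data.frame with columns `azimuth`, `elevation` (degrees),
#'   `singular` (logical), plus `zone` when labels are present.
#' @export
project_to_visual_field <- function(retina, eye = eye_model(), eye_azimuth = 0) {
  stopifnot(inherits(retina, "retinal_points"))
  v <- -retina$xyz  # antipodal ray through the lens center
  th <- eye_azimuth * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  v <- v %*% t(rot)
  elev <- asin(pmin(1, pmax(-1, v[, 3]))) * 180 / pi
  singular <- abs(abs(elev) - 90) < 1e-9
  az <- atan2(v[, 2], v[, 1]) * 180 / pi
  az[singular] <- 0  # undefined at the poles; flagged, not dropped
  out <- data.frame(azimuth = az, elevation = elev, singular = singular)
  if (!is.null(retina$labels)) out$zone <- retina$labels
  out
}

#' Back-project visual-field directions onto the retina
#'
#' Inverse of [project_to_visual_field()]: returns the retinal unit vectors
#' whose antipodal rays point at the given (azimuth, elevation) directions.
#'
#' @param azimuth,elevation Visual directions in degrees.
#' @param eye_azimuth Eye rotation used in the forward projection.
#' @return A [retinal_points()] object.
#' @export
back_project <- function(azimuth, elevation, eye_azimuth = 0) {
  az <- azimuth * pi / 180
  el <- elevation * pi / 180
  v <- cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  th <- -eye_azimuth * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  retinal_points(-(v %*% t(rot)))
}

#' Nyquist detectability of a target on a sampling array
#'
#' A target of angular size `target_angle` is resolvable by an array of mean
#' density `density` (samples per square degree) when it spans at least two
#' mean sampling intervals, `target_angle >= 2 / sqrt(density)`.
#'
#' @param density Sampling density, cones per square degree.
#' @param target_angle Target angular size in degrees.
#' @return List with `detectable` (logical), `margin` (ratio of target angle
#'   to the Nyquist requirement; >= 1 means detectable), and
#'   `sampling_interval` (degrees).
#' @examples
#' nyquist_check(0.19, 1.8)  # strike-zone density vs distant paramecium
#' @export
nyquist_check <- function(density, target_angle) {
  stopifnot(is.numeric(density), density > 0, is.numeric(target_angle),
            target_angle >= 0)
  interval <- 1 / sqrt(density)
  margin <- target_angle / (2 * interval)
  list(detectable = margin >= 1, margin = margin,
       sampling_interval = interval)
}
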