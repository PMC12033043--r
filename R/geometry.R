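# Diffraction geometry: orientation angles, tilt series, detector mapping.
#
# Conventions (fixed throughout the package):
#  * Lab frame: right-handed X, Y, Z with Z along the incident beam;
#    detector X to the right and Y down when viewing along the beam.
#  * Pixel coordinates are 0-based, pixel-center.
#  * All angles cross module boundaries in degrees; radians internally.
#  * The orientation (theta, phi, psi) gives the incident-beam direction in
#    the crystal frame as (sin th cos ph, sin th sin ph, cos th), followed
#    by a rotation psi of the crystal about the beam.  The crystal->lab
#    matrix is the passive Euler sequence Rz(psi) Ry(theta) Rz(phi), i.e.
#    R = Rz(-psi) %*% Ry(-theta) %*% Rz(-phi) in active-matrix form.

.deg <- pi / 180

.rotz <- function(a) {
  ca <- cos(a); sa <- sin(a)
  rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1))
}
.roty <- function(a) {
  ca <- cos(a); sa <- sin(a)
  rbind(c(ca, 0, sa), c(0, 1, 0), c(-sa, 0, ca))
}

# Rodrigues rotation about unit axis by angle (radians)
.rot_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Relativistic electron wavelength
#'
#' @param energy_kev Electron kinetic energy in keV.
#' @return de Broglie wavelength in Angstrom.
#' @examples
#' electron_wavelength(200)  # ~0.0251 A
#' @export
electron_wavelength <- function(energy_kev) {
  V <- energy_kev * 1e3
  12.2639 / sqrt(V * (1 + 0.97845e-6 * V))
}

#' Crystal-to-lab orientation matrix
#'
#' @param theta,phi Polar angles (degrees) of the incident-beam direction
#'   in the crystal frame.
#' @param psi Rotation (degrees) of the crystal about the beam.
#' @return Orthonormal 3x3 matrix mapping crystal-frame vectors to the lab
#'   frame (beam along lab +Z).
#' @seealso [matrix_to_orientation()]
#' @export
orientation_matrix <- function(theta, phi, psi) {
  .rotz(-psi * .deg) %*% .roty(-theta * .deg) %*% .rotz(-phi * .deg)
}

#' Recover orientation angles from a rotation matrix
#'
#' Inverse of [orientation_matrix()]; the gimbal locus theta in {0, 180}
#' returns phi = 0 with psi carrying the whole in-plane rotation.
#'
#' @param R 3x3 rotation matrix (crystal -> lab).
#' @return Named vector `c(theta, phi, psi)` in degrees, theta in
#'   \[0, 180\], phi and psi in \[0, 360).
#' @export
matrix_to_orientation <- function(R) {
  n <- drop(t(R) %*% c(0, 0, 1))   # beam direction in crystal frame
  theta <- acos(max(-1, min(1, n[3])))
  if (abs(sin(theta)) < 1e-12) {
    phi <- 0
    # R reduces to Rz(-psi) (theta=0) or Rz(-psi)*Ry(pi) (theta=pi)
    psi <- atan2(-R[2, 1], R[1, 1])
    if (theta > pi / 2) psi <- atan2(R[2, 1], -R[1, 1])
  } else {
    phi <- atan2(n[2], n[1])
    R0 <- .roty(-theta) %*% .rotz(-phi)
    # residual rotation about the beam: R = Rz(-psi) R0
    D <- R %*% t(R0)
    psi <- atan2(-D[2, 1], D[1, 1])
  }
  out <- c(theta = theta, phi = phi, psi = psi) / .deg
  out[c("phi", "psi")] <- out[c("phi", "psi")] %% 360
  out
}

#' Tilt-series state
#'
#' @param omega_axis_deg Direction of the tilt axis in the lab XY plane
#'   (one angle from +X, degrees); the axis is perpendicular to the beam
#'   by construction.
#' @param omega_angles_deg Per-image nominal tilt angles (degrees).
#' @param scale_corrections Per-image multiplicative intensity factors;
#'   image 1 is the reference and is forced to 1.
#' @param omega_corrections Per-image additive tilt offsets (degrees);
#'   image 1 is forced to 0.
#' @return A `tilt_state` list.
#' @export
tilt_state <- function(omega_axis_deg = 0, omega_angles_deg = 0,
                       scale_corrections = NULL, omega_corrections = NULL) {
  n <- length(omega_angles_deg)
  if (is.null(scale_corrections)) scale_corrections <- rep(1, n)
  if (is.null(omega_corrections)) omega_corrections <- rep(0, n)
  stopifnot(length(scale_corrections) == n, length(omega_corrections) == n)
  scale_corrections[1] <- 1
  omega_corrections[1] <- 0
  structure(list(omega_axis_deg = omega_axis_deg,
                 omega_angles_deg = omega_angles_deg,
                 scale_corrections = scale_corrections,
                 omega_corrections = omega_corrections),
            class = "tilt_state")
}

# total rotation for one image of a tilt series: R_omega %*% R
.image_rotation_matrix <- function(R, tilt, image_index = 1L) {
  if (is.null(tilt)) return(R)
  ang <- (tilt$omega_angles_deg[image_index] +
          tilt$omega_corrections[image_index]) * .deg
  if (abs(ang) < 1e-15) return(R)
  ax <- c(cos(tilt$omega_axis_deg * .deg), sin(tilt$omega_axis_deg * .deg), 0)
  .rot_axis(ax, ang) %*% R
}

#' Lab-frame reciprocal vectors
#'
#' Applies the crystal orientation and (optionally) the tilt rotation of
#' one image of a tilt series to crystal-frame reciprocal vectors.
#'
#' @param hvec n x 3 matrix of crystal-frame reciprocal vectors (1/A).
#' @param R Crystal-to-lab rotation matrix.
#' @param tilt Optional [tilt_state()].
#' @param image_index Image number within the tilt series (1-based).
#' @return n x 3 matrix of lab-frame vectors.
#' @export
h_lab <- function(hvec, R, tilt = NULL, image_index = 1L) {
  Rt <- .image_rotation_matrix(R, tilt, image_index)
  rbind(hvec) %*% t(Rt)
}

#' Detector geometry
#'
#' Camera length `camera_length` (Leff) absorbs lens magnification:
#' `magnification = camera_length / distance`.  Editing either of the
#' redundant fields through [setting_update()] keeps them consistent.
#'
#' @param pixel_size_mm Pixel size in mm (equal in X and Y).
#' @param distance_mm Real sample-detector distance L in mm.
#' @param camera_length_mm Effective camera length Leff in mm.
#' @param beam_center Length-2 vector, beam center on the detector (pixels).
#' @param image_rotation_deg In-plane image rotation due to the magnetic
#'   lens (degrees), applied about the beam center.
#' @param distortion Length-2 vector `c(epsilon, phi0_deg)`: elliptical
#'   correction `r -> r * (1 + eps * cos 2(azimuth - phi0))`.
#' @param energy_kev Electron energy in keV (sets the wavelength).
#' @return A `detector_geometry` list (includes derived `wavelength` in A
#'   and `magnification`).
#' @export
detector_geometry <- function(pixel_size_mm = 0.05, distance_mm = 500,
                              camera_length_mm = distance_mm,
                              beam_center = c(512, 512),
                              image_rotation_deg = 0,
                              distortion = c(0, 0),
                              energy_kev = 200) {
  stopifnot(pixel_size_mm > 0, distance_mm > 0, camera_length_mm > 0)
  structure(list(pixel_size_mm = pixel_size_mm,
                 distance_mm = distance_mm,
                 camera_length_mm = camera_length_mm,
                 magnification = camera_length_mm / distance_mm,
                 beam_center = beam_center,
                 image_rotation_deg = image_rotation_deg,
                 distortion = distortion,
                 energy_kev = energy_kev,
                 wavelength = electron_wavelength(energy_kev)),
            class = "detector_geometry")
}

#' Project reciprocal-space points onto the detector
#'
#' Gnomonic projection of the diffracted direction `k_f = k_i + point`
#' (`x_mm = Leff k_fx / k_fz`), followed by the in-plane image rotation
#' about the beam center, the elliptical distortion, and conversion to
#' 0-based pixel coordinates.
#'
#' @param points n x 3 matrix of lab-frame reciprocal positions (1/A) on or
#'   near the Ewald sphere.
#' @param geom A [detector_geometry()].
#' @return n x 2 matrix of pixel coordinates; rows with `k_fz <= 0`
#'   (non-projectable, behind the detector) are `NA`.
#' @export
project_to_detector <- function(points, geom) {
  points <- rbind(points)
  k <- 1 / geom$wavelength
  kf <- points
  kf[, 3] <- kf[, 3] + k
  ok <- kf[, 3] > 0
  x <- y <- rep(NA_real_, nrow(points))
  Leff <- geom$camera_length_mm
  x[ok] <- Leff * kf[ok, 1] / kf[ok, 3]
  y[ok] <- Leff * kf[ok, 2] / kf[ok, 3]
  rot <- geom$image_rotation_deg * .deg
  if (rot != 0) {
    xr <- x * cos(rot) - y * sin(rot)
    yr <- x * sin(rot) + y * cos(rot)
    x <- xr; y <- yr
  }
  eps <- geom$distortion[1]
  if (eps != 0) {
    az <- atan2(y, x)
    f <- 1 + eps * cos(2 * (az - geom$distortion[2] * .deg))
    x <- x * f                          # radial scaling at fixed azimuth
    y <- y * f
  }
  cbind(x = x / geom$pixel_size_mm + geom$beam_center[1],
        y = y / geom$pixel_size_mm + geom$beam_center[2])
}
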