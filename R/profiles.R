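# Gaussian diffracting-power profiles of reciprocal lattice points and
# their intersection with the Ewald sphere.
#
# Each RLP is broadened by four mutually independent Gaussian effects:
# finite domain size (shape transform), mosaicity (orientation spread of
# domains), beam divergence, and energy bandwidth.  Divergence and
# bandwidth are folded into an "effective mosaicity"; the shape transform
# adds a radial (relrod) width.  Intensities follow from the integral of
# the resulting trivariate Gaussian over the Ewald sphere, with the
# excitation error measured as arc length on the constant-|h| sphere S_h
# (a geometric curvature correction to the tangent-plane approximation).

#' Gaussian width equivalent of a finite domain size
#'
#' Converts a plate thickness `t` or sphere diameter `D` (Angstrom) into
#' the standard deviations of the unit-peak Gaussian that best
#' approximates (in the minimax sense) the exact reciprocal-space
#' intensity profile: `sigma_z = extent / c` with c = 2.35 for a thin
#' plate (sinc^2 profile) and c = 2.99 for a solid sphere, and the
#' Fourier-pair width `sigma_q = 1 / (2 pi sigma_z)`.
#'
#' @param kind `"plate"` or `"sphere"`.
#' @param extent Plate thickness t or sphere diameter D in Angstrom.
#' @return List with `sigma_z` (Angstrom) and `sigma_q` (1/Angstrom).
#' @seealso [gaussian_minimax_factor()] which recomputes the factors.
#' @export
shape_sigma_from_size <- function(kind = c("plate", "sphere"), extent) {
  kind <- match.arg(kind)
  if (!(extent > 0)) stop("extent must be positive")
  cfac <- if (kind == "plate") 2.35 else 2.99
  sigma_z <- extent / cfac
  list(sigma_z = sigma_z, sigma_q = 1 / (2 * pi * sigma_z))
}

#' Exact relrod intensity profile of a simple domain shape
#'
#' Unit-peak reciprocal-space intensity profile along q for a thin plate
#' of unit thickness (`sinc^2(pi q)`) or a solid sphere of unit diameter
#' (1-D Fourier transform of the z-projected shape autocorrelation).
#'
#' @param kind `"plate"` or `"sphere"`.
#' @param q Reciprocal coordinate in units of 1/extent.
#' @return Profile values, unit peak at q = 0.
#' @export
relrod_profile <- function(kind = c("plate", "sphere"), q) {
  kind <- match.arg(kind)
  if (kind == "plate") {
    out <- ifelse(q == 0, 1, (sin(pi * q) / (pi * q))^2)
    return(out)
  }
  # solid sphere, D = 1: ACF A(r) = 1 - 3r/2 + r^3/2 on [0,1];
  # z-projection Pz(z) = 2 pi int_{|z|}^1 A(r) r dr, then cosine transform.
  z <- seq(0, 1, length.out = 2001)
  # antiderivative of A(r) * r: r^2/2 - r^3/2 + r^5/10
  G <- function(r) r^2 / 2 - r^3 / 2 + r^5 / 10
  Pz <- G(1) - G(z)
  vapply(q, function(qi) {
    num <- .trapz(z, Pz * cos(2 * pi * qi * z))
    den <- .trapz(z, Pz)
    num / den
  }, numeric(1))
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

#' Minimax Gaussian-approximation factor for a domain shape
#'
#' Recomputes, from the exact profile, the factor `c` such that the
#' unit-peak Gaussian with `sigma_q = c / (2 pi)` (extent = 1) minimizes
#' the maximum absolute deviation from [relrod_profile()] on a dense grid
#' `q` in `[0, qmax]`.  Expected values: 2.35 (plate), 2.99 (sphere).
#'
#' @param kind `"plate"` or `"sphere"`.
#' @param qmax Upper end of the fitting grid (units of 1/extent).
#' @param n Number of grid points.
#' @return The optimal factor `c`.
#' @export
gaussian_minimax_factor <- function(kind = c("plate", "sphere"),
                                    qmax = 3, n = 3001) {
  kind <- match.arg(kind)
  q <- seq(1e-9, qmax, length.out = n)
  prof <- relrod_profile(kind, q)
  dev_max <- function(cc) {
    sq <- cc / (2 * pi)
    max(abs(prof - exp(-q^2 / (2 * sq^2))))
  }
  stats::optimize(dev_max, c(1.2, 5), tol = 1e-7)$minimum
}

#' Mosaicity model
#'
#' Orientation spread of the coherently diffracting domains, described by
#' a trivariate normal distribution of rotation vectors (lab frame).
#'
#' @param mode `"isotropic"` or `"anisotropic"`.
#' @param sigma_deg Isotropic spread (degrees; standard deviation of each
#'   rotation-vector component).
#' @param sigmas_deg Length-3 principal standard deviations (degrees),
#'   anisotropic mode.
#' @param euler_deg Length-3 Euler angles (Z-Y-Z, degrees) orienting the
#'   principal axes in the lab frame.
#' @return A `mosaicity_model` with `cov` (rad^2, lab frame) populated.
#' @export
mosaicity_model <- function(mode = c("isotropic", "anisotropic"),
                            sigma_deg = 1,
                            sigmas_deg = c(1, 1, 1),
                            euler_deg = c(0, 0, 0)) {
  mode <- match.arg(mode)
  if (mode == "isotropic") {
    s <- sigma_deg * .deg
    cov <- diag(rep(s^2, 3))
  } else {
    U <- .rotz(euler_deg[1] * .deg) %*% .roty(euler_deg[2] * .deg) %*%
      .rotz(euler_deg[3] * .deg)
    cov <- U %*% diag((sigmas_deg * .deg)^2) %*% t(U)
  }
  structure(list(mode = mode, sigma_deg = sigma_deg,
                 sigmas_deg = sigmas_deg, euler_deg = euler_deg, cov = cov),
            class = "mosaicity_model")
}

#' Shape transform (finite-size) model
#'
#' Standard mode: reciprocal lattice rods of width `sigma_shp` along a
#' direction tilted from the lab Z axis.  ANISO mode: full 3x3 covariance
#' (crystal-fixed), from principal widths and Euler angles.
#'
#' @param mode `"standard"` or `"aniso"`.
#' @param sigma_shp Relrod Gaussian width (1/Angstrom), standard mode.
#' @param tilt_deg,tilt_azimuth_deg Relrod direction: tilt from +Z and its
#'   azimuth (degrees), standard mode.
#' @param sigmas Length-3 principal widths (1/Angstrom), ANISO mode;
#'   degenerate (zero) values allowed.
#' @param euler_deg Euler angles (Z-Y-Z, degrees) of the principal axes in
#'   the crystal frame, ANISO mode.
#' @return A `shape_transform`; ANISO mode carries `cov` (1/A^2,
#'   crystal frame), standard mode carries the unit `direction` (lab).
#' @export
shape_transform <- function(mode = c("standard", "aniso"),
                            sigma_shp = 0.002,
                            tilt_deg = 0, tilt_azimuth_deg = 0,
                            sigmas = c(0.002, 0.002, 0.002),
                            euler_deg = c(0, 0, 0)) {
  mode <- match.arg(mode)
  if (mode == "standard") {
    dir <- drop(.rotz(tilt_azimuth_deg * .deg) %*% .roty(tilt_deg * .deg) %*% c(0, 0, 1))
    structure(list(mode = mode, sigma_shp = sigma_shp, tilt_deg = tilt_deg,
                   tilt_azimuth_deg = tilt_azimuth_deg, direction = dir),
              class = "shape_transform")
  } else {
    U <- .rotz(euler_deg[1] * .deg) %*% .roty(euler_deg[2] * .deg) %*%
      .rotz(euler_deg[3] * .deg)
    cov <- U %*% diag(sigmas^2) %*% t(U)
    structure(list(mode = mode, sigmas = sigmas, euler_deg = euler_deg,
                   cov = cov),
              class = "shape_transform")
  }
}

#' Beam model
#'
#' @param sigma_divg Divergence half-angle spread, radians (rotationally
#'   symmetric normal distribution of incident wavevectors).
#' @param sigma_bwdth Fractional energy bandwidth Delta lambda / lambda.
#' @return A `beam_model`.
#' @export
beam_model <- function(sigma_divg = 0, sigma_bwdth = 0) {
  stopifnot(sigma_divg >= 0, sigma_bwdth >= 0)
  structure(list(sigma_divg = sigma_divg, sigma_bwdth = sigma_bwdth),
            class = "beam_model")
}

# bandwidth -> equivalent angular spread: a radius change k*sigma_bwdth
# shifts the Ewald sphere near the RLP by ~ (h^2 lambda / 2) sigma_bwdth,
# i.e. an angular spread (lambda/2) * h * sigma_bwdth.
.bandwidth_const <- function(lambda) lambda / 2

#' Effective isotropic mosaic width
#'
#' Quadrature combination of mosaic spread, beam divergence and the
#' bandwidth-equivalent angular spread:
#' `sigma_MOS^2 = sigma_mos^2 + sigma_divg^2 + (a h sigma_bwdth)^2`
#' with `a = lambda / 2`.
#'
#' @param mos An isotropic [mosaicity_model()].
#' @param beam A [beam_model()].
#' @param h_len |h| = 1/d in 1/Angstrom (vector ok).
#' @param lambda Wavelength in Angstrom.
#' @param bandwidth_const Override for the constant `a` (default
#'   `lambda/2`).
#' @return Effective sigma in radians, same length as `h_len`.
#' @export
effective_mosaic_sigma <- function(mos, beam, h_len, lambda,
                                   bandwidth_const = NULL) {
  stopifnot(mos$mode == "isotropic")
  a <- if (is.null(bandwidth_const)) .bandwidth_const(lambda) else bandwidth_const
  sqrt((mos$sigma_deg * .deg)^2 + beam$sigma_divg^2 +
         (a * h_len * beam$sigma_bwdth)^2)
}

#' Effective anisotropic mosaic covariance
#'
#' Adds to the mosaic rotation-vector covariance the divergence term
#' `sigma_divg^2 (I - zz^T)` (beam tilts are rotations about axes in the
#' lab XY plane) and the bandwidth term `(a h sigma_bwdth)^2 I`, embedded
#' isotropically so that the excitation-critical marginal reproduces
#' [effective_mosaic_sigma()].
#'
#' @inheritParams effective_mosaic_sigma
#' @param mos A [mosaicity_model()] (either mode).
#' @param h_len Scalar |h| in 1/Angstrom.
#' @return 3x3 covariance matrix (rad^2, lab frame).
#' @export
effective_mosaic_cov <- function(mos, beam, h_len, lambda,
                                 bandwidth_const = NULL) {
  a <- if (is.null(bandwidth_const)) .bandwidth_const(lambda) else bandwidth_const
  zz <- diag(c(1, 1, 0))
  mos$cov + beam$sigma_divg^2 * zz +
    (a * h_len * beam$sigma_bwdth)^2 * diag(3)
}

#' Local reflection frame
#'
#' Right-handed orthonormal triple with `e3` along the reciprocal vector,
#' `e1` along `k_i x h` and `e2 = e3 x e1`.  When `h` is parallel to the
#' beam the convention `e1 = (1,0,0)` is used.
#'
#' @param h Lab-frame reciprocal vector (length 3).
#' @param k_i Incident wavevector (length 3), default along +Z.
#' @return List with unit vectors `e1`, `e2`, `e3`.
#' @export
local_frame <- function(h, k_i = c(0, 0, 1)) {
  hn <- sqrt(sum(h^2))
  if (hn == 0) stop("local frame undefined for h = 0")
  e3 <- h / hn
  cr <- c(k_i[2] * h[3] - k_i[3] * h[2],
          k_i[3] * h[1] - k_i[1] * h[3],
          k_i[1] * h[2] - k_i[2] * h[1])
  ncr <- sqrt(sum(cr^2))
  e1 <- if (ncr < 1e-12 * hn * sqrt(sum(k_i^2)) || ncr == 0) c(1, 0, 0) else cr / ncr
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  list(e1 = e1, e2 = e2, e3 = e3)
}

#' Tangent-plane covariance of the rotated reciprocal vector
#'
#' Rotates the effective rotation-vector covariance into the local
#' `(omega1, omega2, omega3)` frame, marginalizes out the component along
#' `h` (rotations about `h` do not move the RLP) and maps rotations to
#' tangent-plane displacements: for the 2x2 block
#' `S = [[S11, S12], [S12, S22]]` the displacement covariance is
#' `Sigma_h = h^2 [[S22, -S12], [-S12, S11]]` in `(e1, e2)` coordinates.
#'
#' @param cov_eff 3x3 rotation-vector covariance (rad^2, lab frame).
#' @param frame A [local_frame()].
#' @param h_len |h| in 1/Angstrom.
#' @return 2x2 covariance in (1/Angstrom)^2.
#' @export
tangent_covariance <- function(cov_eff, frame, h_len) {
  E <- cbind(frame$e1, frame$e2)
  S <- t(E) %*% cov_eff %*% E
  h_len^2 * rbind(c(S[2, 2], -S[1, 2]), c(-S[1, 2], S[1, 1]))
}

# ---------------------------------------------------------------------------
# Vectorized prediction core.
#
# H:    n x 3 lab-frame reciprocal vectors
# hlen: |h| per reflection
# Returns per-reflection intensity profile factors, excitation errors and
# on-sphere centroid positions (lab frame), NA-safe.

.cross_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# local frames for all rows; k_i along +Z
.local_frames <- function(H, hlen) {
  e3 <- H / hlen
  e1 <- cbind(-H[, 2], H[, 1], 0)
  n1 <- sqrt(rowSums(e1^2))
  deg <- n1 < 1e-12 * hlen
  e1 <- e1 / ifelse(n1 > 0, n1, 1)
  if (any(deg)) e1[deg, ] <- matrix(rep(c(1, 0, 0), sum(deg)), ncol = 3, byrow = TRUE)
  e2 <- .cross_rows(e3, e1)
  list(e1 = e1, e2 = e2, e3 = e3)
}

# arc-length excitation error on S_h and the intersection point A (lab frame)
# for every row; k = 1/lambda.
.arc_excitation <- function(H, hlen, fr, k) {
  m <- sqrt(H[, 1]^2 + H[, 2]^2 + (H[, 3] + k)^2)
  zeta <- m - k
  # in-plane (e2, e3) coordinates of the beam direction
  u2 <- fr$e2[, 3]      # zhat . e2
  u3 <- fr$e3[, 3]      # zhat . e3
  nu <- sqrt(u2^2 + u3^2)
  u2 <- u2 / nu; u3 <- u3 / nu
  cg <- pmax(-1, pmin(1, -hlen / (2 * k)))
  sg <- sqrt(1 - cg^2)
  # two candidates; keep the one closest to the RLP direction (0, 1)
  bplus <- cg * u3 + sg * u2
  bminus <- cg * u3 - sg * u2
  s <- ifelse(bplus >= bminus, 1, -1)
  Abeta <- pmax(-1, pmin(1, cg * u3 + s * sg * u2))
  Aalpha <- cg * u2 - s * sg * u3
  e_arc <- hlen * acos(Abeta) * sign(zeta)
  A <- hlen * (Aalpha * fr$e2 + Abeta * fr$e3)
  list(e_arc = e_arc, zeta = zeta, m = m, A = A)
}

# signed distance along direction r (unit, lab) from the RLP to the Ewald
# sphere, and the hit point B; NA when the line misses the sphere.
.rod_excitation <- function(H, r, k, zeta) {
  kf0 <- H
  kf0[, 3] <- kf0[, 3] + k
  if (is.matrix(r)) {
    b <- rowSums(kf0 * r)
  } else {
    b <- kf0 %*% r
    r <- matrix(r, nrow(H), 3, byrow = TRUE)
  }
  b <- as.numeric(b)
  disc <- b^2 - (rowSums(kf0^2) - k^2)
  ok <- disc >= 0
  t1 <- t2 <- rep(NA_real_, nrow(H))
  sq <- sqrt(pmax(0, disc))
  t1[ok] <- (-b + sq)[ok]
  t2[ok] <- (-b - sq)[ok]
  tt <- ifelse(abs(t1) <= abs(t2), t1, t2)
  B <- H + tt * r
  list(e_shp = -tt * ifelse(sign(zeta) == 0, 1, 1), t = tt, B = B,
       e_signed = abs(tt) * sign(zeta))
}

#' Predict spots with the anisotropic (full-covariance) model
#'
#' For every reflection: (i) the effective mosaic covariance (mosaicity +
#' divergence + bandwidth) is mapped to a tangent-plane displacement
#' covariance at the RLP; (ii) the shape-transform covariance, rotated to
#' the lab frame, is convolved in (3x3 addition in the local frame, the
#' mosaic part carrying zero radial variance); (iii) the excitation error
#' is measured as arc length on the constant-|h| sphere S_h to the
#' intersection with the Ewald sphere; (iv) the integrated intensity is
#' `scale * F2 * exp(-B h^2 / 2)` times the Gaussian surface integral
#' across the Ewald sphere; (v) the centroid is the conditional mean on
#' the Ewald trace, mapped back to S_h by the spherical exponential map
#' and projected to the detector.
#'
#' @param refl Reflection table from [generate_reflections()].
#' @param R Crystal-to-lab rotation matrix ([orientation_matrix()]).
#' @param mos A [mosaicity_model()].
#' @param shape A [shape_transform()] (either mode; standard mode enters
#'   as the degenerate covariance `sigma_shp^2 d d^T`).
#' @param beam A [beam_model()].
#' @param geom A [detector_geometry()].
#' @param tilt Optional [tilt_state()]; `image_index` selects the image.
#' @param image_index Image number within a tilt series.
#' @param scale Overall intensity scale factor.
#' @param b_factor Global B factor; intensities are damped by
#'   `exp(-B h^2 / 2)`.
#' @param cutoff_sigma Reflections with excitation error beyond this many
#'   combined sigmas are dropped (Gaussian tail < 1e-4 of peak at 4).
#' @param detail Additionally return the detector-plane (lab XY)
#'   projection of the reflection profile covariance (columns `fp_xx,
#'   fp_xy, fp_yy` in 1/Angstrom^2), used for image rendering.
#' @return `data.frame` with columns `h, k, l, x, y, I, partiality,
#'   e_mos, e_shp, h_len, F2`; non-projectable rows are dropped with a
#'   `dropped` attribute counting them.
#' @export
aniso_predict <- function(refl, R, mos, shape, beam, geom,
                          tilt = NULL, image_index = 1L,
                          scale = 1, b_factor = 0, cutoff_sigma = 4,
                          detail = FALSE) {
  n <- nrow(refl)
  empty <- refl[0, c("h", "k", "l")]
  if (n == 0) return(.empty_prediction())
  Rt <- .image_rotation_matrix(R, tilt, image_index)
  H <- as.matrix(refl[, c("hx", "hy", "hz")]) %*% t(Rt)
  hlen <- refl$h_len
  k <- 1 / geom$wavelength

  # effective mosaic covariance, h-independent part
  S0 <- mos$cov + beam$sigma_divg^2 * diag(c(1, 1, 0))
  a <- .bandwidth_const(geom$wavelength)
  ch <- (a * hlen * beam$sigma_bwdth)^2          # isotropic, h-dependent

  # cheap prefilter: the perpendicular distance to the Ewald sphere bounds
  # the arc-length excitation error from below, and the profile variance
  # across the sphere is bounded by the largest eigenvalues
  Sshp <- .shape_cov_lab(shape, Rt)
  lam_mos <- max(eigen(S0, symmetric = TRUE, only.values = TRUE)$values)
  lam_shp <- max(eigen(Sshp, symmetric = TRUE, only.values = TRUE)$values)
  zeta0 <- sqrt(H[, 1]^2 + H[, 2]^2 + (H[, 3] + k)^2) - k
  vbound <- hlen^2 * (lam_mos + ch) + lam_shp
  pre <- zeta0^2 <= cutoff_sigma^2 * vbound
  if (!any(pre)) return(.empty_prediction())
  refl <- refl[pre, , drop = FALSE]
  H <- H[pre, , drop = FALSE]; hlen <- hlen[pre]; ch <- ch[pre]

  fr <- .local_frames(H, hlen)
  arc <- .arc_excitation(H, hlen, fr, k)

  quad <- function(A, M, B) {
    rowSums((A %*% M) * B)
  }
  E11 <- quad(fr$e1, S0, fr$e1) + ch
  E12 <- quad(fr$e1, S0, fr$e2)
  E22 <- quad(fr$e2, S0, fr$e2) + ch
  h2 <- hlen^2
  M11 <- h2 * E22; M22 <- h2 * E11; M12 <- -h2 * E12

  S11 <- quad(fr$e1, Sshp, fr$e1); S12 <- quad(fr$e1, Sshp, fr$e2)
  S13 <- quad(fr$e1, Sshp, fr$e3); S22 <- quad(fr$e2, Sshp, fr$e2)
  S23 <- quad(fr$e2, Sshp, fr$e3); S33 <- quad(fr$e3, Sshp, fr$e3)

  C12 <- M12 + S12; C13 <- S13
  C22 <- M22 + S22; C23 <- S23; C33 <- S33

  # Ewald-sphere unit normal in local coordinates (n . e1 = 0 exactly)
  n2 <- k * fr$e2[, 3] / arc$m
  n3 <- (hlen + k * fr$e3[, 3]) / arc$m
  v <- n2^2 * C22 + 2 * n2 * n3 * C23 + n3^2 * C33

  # surface integral across the Ewald sphere: Gaussian in the
  # perpendicular offset; the arc-length excitation error measured along
  # e2 projects onto the surface normal with factor n2
  e <- arc$e_arc
  dperp <- n2 * e
  keep <- v > 0 & dperp^2 <= (cutoff_sigma^2) * v
  if (!any(keep)) return(.empty_prediction())
  idx <- which(keep)

  p <- exp(-dperp[idx]^2 / (2 * v[idx])) / sqrt(2 * pi * v[idx])
  I <- scale * refl$F2[idx] * exp(-b_factor * hlen[idx]^2 / 2) * p

  # conditional mean on the cutting plane, back onto S_h
  d <- -dperp[idx]
  Cn1 <- C12[idx] * n2[idx] + C13[idx] * n3[idx]
  Cn2 <- C22[idx] * n2[idx] + C23[idx] * n3[idx]
  Cn3 <- C23[idx] * n2[idx] + C33[idx] * n3[idx]
  d1 <- Cn1 * d / v[idx]; d2 <- Cn2 * d / v[idx]; d3 <- Cn3 * d / v[idx]
  hl <- hlen[idx]
  phi1 <- -d2 / hl; phi2 <- d1 / hl
  rad <- hl + d3
  e3i <- fr$e3[idx, , drop = FALSE]; e2i <- fr$e2[idx, , drop = FALSE]
  e1i <- fr$e1[idx, , drop = FALSE]
  e3p <- cos(phi1) * e3i - sin(phi1) * e2i
  X <- rad * (cos(phi2) * e3p + sin(phi2) * cos(phi1) * e1i)

  xy <- project_to_detector(X, geom)
  roddir <- .relrod_direction(shape)
  rod <- .rod_excitation(H[idx, , drop = FALSE], roddir, k, arc$zeta[idx])

  ok <- !is.na(xy[, 1])
  out <- data.frame(h = refl$h[idx], k = refl$k[idx], l = refl$l[idx],
                    x = xy[, 1], y = xy[, 2], I = I, partiality = p,
                    e_mos = e[idx], e_shp = rod$e_signed,
                    h_len = hl, F2 = refl$F2[idx])
  if (detail) {
    e1x <- e1i[, 1]; e1y <- e1i[, 2]; e2x <- e2i[, 1]; e2y <- e2i[, 2]
    m11 <- M11[idx]; m12 <- M12[idx]; m22 <- M22[idx]
    out$fp_xx <- m11 * e1x^2 + 2 * m12 * e1x * e2x + m22 * e2x^2 + Sshp[1, 1]
    out$fp_xy <- m11 * e1x * e1y + m12 * (e1x * e2y + e2x * e1y) +
      m22 * e2x * e2y + Sshp[1, 2]
    out$fp_yy <- m11 * e1y^2 + 2 * m12 * e1y * e2y + m22 * e2y^2 + Sshp[2, 2]
  }
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Predict spots with the standard (isotropic + relrod) model
#'
#' Combines the effective isotropic mosaic width with the relrod width
#' per `sigma*^2 = sigma_shp^2 + (h sigma_MOS)^2`, evaluates Gaussian
#' densities at the two extreme-case excitation errors (point A on the
#' mosaic arc, point B on the relrod) and averages intensity and centroid
#' with weights proportional to `h sigma_MOS / e_mos` and
#' `sigma_shp / e_shp` (normalized; excitation errors are floored at
#' 1e-6 1/Angstrom to regularize the on-sphere limit where both cases
#' coincide).
#'
#' @inheritParams aniso_predict
#' @param shape A standard-mode [shape_transform()].
#' @return Same layout as [aniso_predict()].
#' @export
standard_predict <- function(refl, R, mos, shape, beam, geom,
                             tilt = NULL, image_index = 1L,
                             scale = 1, b_factor = 0, cutoff_sigma = 4) {
  stopifnot(shape$mode == "standard", mos$mode == "isotropic")
  if (nrow(refl) == 0) return(.empty_prediction())
  Rt <- .image_rotation_matrix(R, tilt, image_index)
  H <- as.matrix(refl[, c("hx", "hy", "hz")]) %*% t(Rt)
  hlen <- refl$h_len
  k <- 1 / geom$wavelength

  sigM <- effective_mosaic_sigma(mos, beam, hlen, geom$wavelength)
  sstar2 <- shape$sigma_shp^2 + (hlen * sigM)^2
  # prefilter: both excitation errors are bounded below by the
  # perpendicular distance to the Ewald sphere
  zeta0 <- sqrt(H[, 1]^2 + H[, 2]^2 + (H[, 3] + k)^2) - k
  pre <- zeta0^2 <= cutoff_sigma^2 * sstar2
  if (!any(pre)) return(.empty_prediction())
  refl <- refl[pre, , drop = FALSE]
  H <- H[pre, , drop = FALSE]; hlen <- hlen[pre]
  sigM <- sigM[pre]; sstar2 <- sstar2[pre]

  fr <- .local_frames(H, hlen)
  arc <- .arc_excitation(H, hlen, fr, k)
  rod <- .rod_excitation(H, .relrod_direction(shape), k, arc$zeta)
  e_mos <- arc$e_arc
  e_shp <- rod$e_signed

  emin2 <- pmin(e_mos^2, ifelse(is.na(e_shp), Inf, e_shp^2))
  keep <- sstar2 > 0 & emin2 <= cutoff_sigma^2 * sstar2
  if (!any(keep)) return(.empty_prediction())
  idx <- which(keep)

  ss <- sqrt(sstar2[idx])
  dens <- function(e) ifelse(is.na(e), 0, exp(-e^2 / (2 * ss^2)) / (ss * sqrt(2 * pi)))
  IA <- dens(e_mos[idx])
  IB <- dens(e_shp[idx])
  reg <- 1e-6
  wA <- hlen[idx] * sigM[idx] / pmax(abs(e_mos[idx]), reg)
  wB <- shape$sigma_shp / pmax(abs(ifelse(is.na(e_shp[idx]), Inf, e_shp[idx])), reg)
  wB[is.na(e_shp[idx])] <- 0
  tot <- wA + wB
  both0 <- tot <= 0
  wA[both0] <- 0.5; wB[both0] <- 0.5; tot[both0] <- 1
  wA <- wA / tot; wB <- wB / tot

  p <- wA * IA + wB * IB
  I <- scale * refl$F2[idx] * exp(-b_factor * hlen[idx]^2 / 2) * p

  xyA <- project_to_detector(arc$A[idx, , drop = FALSE], geom)
  xyB <- project_to_detector(rod$B[idx, , drop = FALSE], geom)
  noB <- is.na(xyB[, 1])
  xyB[noB, ] <- xyA[noB, , drop = FALSE]
  x <- wA * xyA[, 1] + wB * xyB[, 1]
  y <- wA * xyA[, 2] + wB * xyB[, 2]

  ok <- !is.na(x)
  out <- data.frame(h = refl$h[idx], k = refl$k[idx], l = refl$l[idx],
                    x = x, y = y, I = I, partiality = p,
                    e_mos = e_mos[idx], e_shp = e_shp[idx],
                    h_len = hlen[idx], F2 = refl$F2[idx])[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!ok)
  out
}

.empty_prediction <- function() {
  out <- data.frame(h = integer(0), k = integer(0), l = integer(0),
                    x = numeric(0), y = numeric(0), I = numeric(0),
                    partiality = numeric(0), e_mos = numeric(0),
                    e_shp = numeric(0), h_len = numeric(0), F2 = numeric(0))
  attr(out, "dropped") <- 0L
  out
}

# lab-frame shape covariance; ANISO covariance is crystal-fixed and
# co-rotates with the lattice, the standard relrod is lab-fixed.
.shape_cov_lab <- function(shape, Rt) {
  if (shape$mode == "aniso") Rt %*% shape$cov %*% t(Rt)
  else shape$sigma_shp^2 * tcrossprod(shape$direction)
}

.relrod_direction <- function(shape) {
  if (shape$mode == "standard") shape$direction
  else {
    # dominant principal axis of the ANISO covariance (reporting only)
    ev <- eigen(shape$cov, symmetric = TRUE)
    ev$vectors[, 1]
  }
}
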