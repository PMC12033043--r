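# helpers to place an RLP at a controlled arc offset from the Ewald sphere
.place_rlp <- function(h, off_rad, k, az = 0.7) {
  hz <- -h^2 / (2 * k)                    # exactly on the sphere
  rho <- sqrt(h^2 - hz^2)
  hv <- c(rho * cos(az), rho * sin(az), hz)
  ax <- c(-sin(az), cos(az), 0)           # rotate within the (k_i, h) plane
  drop(relrod:::.rot_axis(ax, off_rad) %*% hv)
}

.one_refl <- function(hv) {
  data.frame(h = 1, k = 0, l = 0, hx = hv[1], hy = hv[2], hz = hv[3],
             h_len = sqrt(sum(hv^2)), d = 1 / sqrt(sum(hv^2)), F2 = 1)
}

test_that("finite-size Gaussian widths use the minimax factors", {
  p <- shape_sigma_from_size("plate", 235)
  expect_equal(p$sigma_z, 100)
  expect_equal(p$sigma_q, 1 / (2 * pi * 100), tolerance = 1e-12)
  s <- shape_sigma_from_size("sphere", 299)
  expect_equal(s$sigma_z, 100)
  expect_lt(shape_sigma_from_size("plate", 1e9)$sigma_q, 1e-9)
  expect_error(shape_sigma_from_size("plate", -1), "positive")
})

test_that("minimax factors are re-derivable from the exact profiles", {
  expect_equal(gaussian_minimax_factor("plate"), 2.35, tolerance = 0.005)
  expect_equal(gaussian_minimax_factor("sphere"), 2.99, tolerance = 0.005)
})

test_that("effective mosaic width combines in quadrature", {
  mos <- mosaicity_model("isotropic", sigma_deg = 3 / pi * 180 / 1000)  # 3 mrad
  beam <- beam_model(sigma_divg = 4e-3)
  expect_equal(effective_mosaic_sigma(mos, beam, 0.5, 0.025), 5e-3,
               tolerance = 1e-12)
  # no beam terms: identity
  expect_equal(effective_mosaic_sigma(mos, beam_model(), 0.5, 0.025),
               3e-3, tolerance = 1e-12)
  # bandwidth-only: proportional to |h|
  mos0 <- mosaicity_model("isotropic", sigma_deg = 0)
  bw <- beam_model(sigma_bwdth = 1e-3)
  r <- effective_mosaic_sigma(mos0, bw, 0.8, 0.025) /
    effective_mosaic_sigma(mos0, bw, 0.4, 0.025)
  expect_equal(r, 2, tolerance = 1e-12)
})

test_that("effective mosaic covariance embeds divergence as a rank-2 update", {
  sig <- 2 * pi / 180
  mos <- mosaicity_model("isotropic", sigma_deg = 2)
  beam <- beam_model(sigma_divg = 1e-3)
  S <- effective_mosaic_cov(mos, beam, 0.5, 0.025)
  ev <- sort(eigen(S, symmetric = TRUE)$values)
  expect_equal(ev, c(sig^2, sig^2 + 1e-6, sig^2 + 1e-6), tolerance = 1e-12)
  # beam terms zero: covariance unchanged
  expect_equal(effective_mosaic_cov(mos, beam_model(), 0.5, 0.025), mos$cov)
  # excitation-critical marginal agrees with the scalar combination:
  # omega_1 is a rotation about an axis in the XY plane (e1 is always in
  # XY), which carries the full divergence variance
  beam2 <- beam_model(sigma_divg = 1.5e-3, sigma_bwdth = 2e-3)
  h <- 0.6; lam <- 0.025
  fr <- local_frame(c(h, 0, 0))
  Seff <- effective_mosaic_cov(mos, beam2, h, lam)
  v1 <- drop(t(fr$e1) %*% Seff %*% fr$e1)
  expect_equal(sqrt(v1), effective_mosaic_sigma(mos, beam2, h, lam),
               tolerance = 1e-12)
})

test_that("local frames are right-handed with the documented fallback", {
  fr <- local_frame(c(1, 0, 0))
  expect_equal(fr$e3, c(1, 0, 0)); expect_equal(fr$e1, c(0, 1, 0))
  expect_equal(fr$e2, c(0, 0, 1))
  set.seed(31)
  for (i in 1:20) {
    h <- rnorm(3)
    fr <- local_frame(h)
    E <- cbind(fr$e1, fr$e2, fr$e3)
    expect_equal(t(E) %*% E, diag(3), tolerance = 1e-12)
    expect_equal(det(E), 1, tolerance = 1e-12)
  }
  expect_equal(local_frame(c(0, 0, 1))$e1, c(1, 0, 0))   # h || beam
  expect_error(local_frame(c(0, 0, 0)), "h = 0")
})

test_that("tangent covariance swaps and negates per the rotation-to-shift map", {
  fr <- local_frame(c(0.4, 0.1, -0.02))
  E <- cbind(fr$e1, fr$e2, fr$e3)
  set.seed(41)
  for (i in 1:200) {
    A <- matrix(rnorm(9), 3); S <- crossprod(A)       # random PSD
    h <- runif(1, 0.1, 1.5)
    got <- tangent_covariance(S, fr, h)
    S12 <- (t(E) %*% S %*% E)[1:2, 1:2]
    expect_equal(got, h^2 * rbind(c(S12[2, 2], -S12[1, 2]),
                                  c(-S12[1, 2], S12[1, 1])),
                 tolerance = 1e-12)
    expect_equal(det(got), h^4 * det(S12), tolerance = 1e-9 * max(1, det(got)))
  }
  # isotropic in, isotropic out, for any h direction
  for (i in 1:5) {
    fr2 <- local_frame(rnorm(3))
    expect_equal(tangent_covariance(diag(3) * 4e-4, fr2, 0.7),
                 0.7^2 * 4e-4 * diag(2), tolerance = 1e-15)
  }
})

test_that("isotropic-mosaicity intensities reduce to the closed form", {
  lam <- electron_wavelength(200); k <- 1 / lam
  geom <- detector_geometry(energy_kev = 200)
  mos <- mosaicity_model("isotropic", sigma_deg = 2)
  sig <- 2 * pi / 180
  shape0 <- shape_transform("aniso", sigmas = c(0, 0, 0))
  h <- 0.55
  p0 <- aniso_predict(.one_refl(.place_rlp(h, 0, k)), diag(3), mos, shape0,
                      beam_model(), geom)
  for (off in c(0.004, 0.01, 0.02, -0.015)) {
    pr <- aniso_predict(.one_refl(.place_rlp(h, off, k)), diag(3), mos,
                        shape0, beam_model(), geom)
    e <- pr$e_mos
    expect_equal(abs(e), h * abs(off), tolerance = 1e-6)  # arc length
    expect_equal(pr$I / p0$I, exp(-e^2 / (2 * h^2 * sig^2)), tolerance = 2e-3)
    expect_lt(pr$partiality, p0$partiality)
  }
  # on the sphere: centroid is the geometric projection of the RLP
  hv <- .place_rlp(h, 0, k)
  xy <- project_to_detector(hv, geom)
  expect_equal(c(p0$x, p0$y), c(xy), tolerance = 1e-9)
})

test_that("ANISO intensities match a Monte-Carlo rotation-vector oracle", {
  lam <- electron_wavelength(200); k <- 1 / lam
  geom <- detector_geometry(energy_kev = 200)
  shape0 <- shape_transform("aniso", sigmas = c(0, 0, 0))
  set.seed(77)
  for (case in 1:4) {
    mos <- mosaicity_model("anisotropic", sigmas_deg = runif(3, 1, 3),
                           euler_deg = runif(3, 0, 360))
    h <- runif(1, 0.3, 0.8)
    hv <- .place_rlp(h, runif(1, -0.025, 0.025), k, az = runif(1, 0, 2 * pi))
    pr <- aniso_predict(.one_refl(hv), diag(3), mos, shape0, beam_model(),
                        geom, cutoff_sigma = 10)
    expect_equal(nrow(pr), 1L)
    n <- 2e5
    L <- t(chol(mos$cov))
    w <- t(L %*% matrix(rnorm(3 * n), 3))
    th <- sqrt(rowSums(w^2)); ax <- w / pmax(th, 1e-15)
    cth <- cos(th); sth <- sin(th)
    crossv <- cbind(ax[, 2] * hv[3] - ax[, 3] * hv[2],
                    ax[, 3] * hv[1] - ax[, 1] * hv[3],
                    ax[, 1] * hv[2] - ax[, 2] * hv[1])
    dotv <- ax[, 1] * hv[1] + ax[, 2] * hv[2] + ax[, 3] * hv[3]
    hp <- cth * matrix(hv, n, 3, byrow = TRUE) + sth * crossv +
      (1 - cth) * dotv * ax
    zeta <- sqrt(hp[, 1]^2 + hp[, 2]^2 + (hp[, 3] + k)^2) - k
    eps <- 0.1 * stats::sd(zeta)
    frac <- mean(abs(zeta) < eps)
    dens <- frac / (2 * eps)
    se <- sqrt(frac * (1 - frac) / n) / (2 * eps)
    expect_lt(abs(pr$partiality - dens), 4 * se)
  }
})

test_that("standard modeling interpolates between the two extreme cases", {
  lam <- electron_wavelength(200); k <- 1 / lam
  geom <- detector_geometry(energy_kev = 200)
  h <- 0.5
  hv <- .place_rlp(h, 0.01, k)
  refl <- .one_refl(hv)
  mos_small <- mosaicity_model("isotropic", sigma_deg = 1e-4)
  mos_big <- mosaicity_model("isotropic", sigma_deg = 2)
  # sigma_shp >> h sigma_MOS: pure relrod (case B)
  shpB <- shape_transform("standard", sigma_shp = 0.01)
  prB <- standard_predict(refl, diag(3), mos_small, shpB, beam_model(), geom)
  rodB <- relrod:::.rod_excitation(matrix(hv, 1), c(0, 0, 1), k,
                                   sign(sqrt(sum((hv + c(0,0,k))^2)) - k))
  xyB <- project_to_detector(rodB$B, geom)
  expect_equal(c(prB$x, prB$y), c(xyB), tolerance = 1e-3)
  sstar <- sqrt(0.01^2 + (h * relrod::effective_mosaic_sigma(mos_small, beam_model(), h, lam))^2)
  expect_equal(prB$I, exp(-prB$e_shp^2 / (2 * sstar^2)) / (sstar * sqrt(2 * pi)),
               tolerance = 1e-4)
  # sigma_shp << h sigma_MOS: pure mosaic arc (case A)
  shpA <- shape_transform("standard", sigma_shp = 1e-8)
  prA <- standard_predict(refl, diag(3), mos_big, shpA, beam_model(), geom)
  sstarA <- h * relrod::effective_mosaic_sigma(mos_big, beam_model(), h, lam)
  expect_equal(prA$I, exp(-prA$e_mos^2 / (2 * sstarA^2)) / (sstarA * sqrt(2 * pi)),
               tolerance = 1e-4)
  # on the sphere both cases coincide at the peak density
  pr0 <- standard_predict(.one_refl(.place_rlp(h, 0, k)), diag(3), mos_big,
                          shpB, beam_model(), geom)
  s0 <- sqrt(0.01^2 + (h * relrod::effective_mosaic_sigma(mos_big, beam_model(), h, lam))^2)
  expect_equal(pr0$partiality, 1 / (s0 * sqrt(2 * pi)), tolerance = 1e-6)
})

test_that("ANISO with isotropic spread reproduces standard case A within 1%", {
  lam <- electron_wavelength(200); k <- 1 / lam
  geom <- detector_geometry(energy_kev = 200)
  mosA <- mosaicity_model("anisotropic", sigmas_deg = c(2, 2, 2))
  mosI <- mosaicity_model("isotropic", sigma_deg = 2)
  shp_none_a <- shape_transform("aniso", sigmas = c(0, 0, 0))
  shp_none_s <- shape_transform("standard", sigma_shp = 1e-9)
  h <- 0.45; sig <- 2 * pi / 180
  offs <- seq(-3, 3, by = 0.5) * sig     # up to 3 sigma of arc offset
  for (off in offs) {
    refl <- .one_refl(.place_rlp(h, off, k))
    pa <- aniso_predict(refl, diag(3), mosA, shp_none_a, beam_model(), geom,
                        cutoff_sigma = 5)
    ps <- standard_predict(refl, diag(3), mosI, shp_none_s, beam_model(),
                           geom, cutoff_sigma = 5)
    expect_equal(pa$I, ps$I, tolerance = 0.01)
    expect_equal(pa$x, ps$x, tolerance = 0.5)
  }
})

test_that("intensities are invariant under rotation about the beam", {
  proj <- synthetic_project_cached(seed = 4)
  st <- proj$truth$setting
  refl <- generate_reflections(proj$structure, st$control$dmin)
  p1 <- predict_spots(st, refl = refl)
  st2 <- st
  st2$orientation[3] <- st2$orientation[3] + 133.7
  p2 <- predict_spots(st2, refl = refl)
  expect_equal(nrow(p1), nrow(p2))
  key <- function(p) paste(p$h, p$k, p$l)
  m <- match(key(p1), key(p2))
  expect_false(anyNA(m))
  expect_equal(p1$I, p2$I[m], tolerance = 1e-9)
  # detector radii are also invariant
  r <- function(p) sqrt((p$x - 511.5)^2 + (p$y - 511.5)^2)
  expect_equal(r(p1), r(p2)[m], tolerance = 1e-6)
})

test_that("total predicted intensity is continuous in the orientation", {
  proj <- synthetic_project_cached(seed = 4)
  st <- proj$truth$setting
  refl <- generate_reflections(proj$structure, st$control$dmin)
  base <- sum(predict_spots(st, refl = refl)$I)
  for (d in list(c(0.01, 0, 0), c(0, 0.01, 0), c(0, 0, 0.01))) {
    st2 <- st; st2$orientation <- st2$orientation + d
    expect_equal(sum(predict_spots(st2, refl = refl)$I), base,
                 tolerance = 0.02)
  }
})
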