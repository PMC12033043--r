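test_that("the SO(3) grid has the advertised size and structure", {
  g1 <- build_grid(1)
  expect_equal(g1$n_directions, 12L)
  g <- build_grid(16, psi_step = 2)
  expect_equal(g$n_directions, 12 * 16^2)
  expect_error(build_grid(12), "power of 2")
  expect_error(build_grid(16, psi_step = 7), "divide")
})

test_that("gridscan peaks at the generating orientation and is resumable", {
  grid <- build_grid(8)
  # truth placed exactly on a grid direction
  pick <- grid$visit_order[37]
  truth_or <- c(grid$theta[pick + 1], grid$phi[pick + 1], 17)
  tr <- synthetic_truth(setting = synthetic_default_setting(truth_or),
                        noise_sigma = 0, jitter_px = 0, seed = 12)
  proj <- make_synthetic_project(tr, file.path(tempdir(), "noiseless12"))
  st0 <- setting_update(tr$setting, orientation = c(0, 0, 0))
  refl <- generate_reflections(proj$structure, st0$control$dmin)
  map <- gridscan(st0, proj$spots, refl = refl, grid = grid)
  expect_equal(map$pix[which.max(map$fom)], pick)
  # noiseless FOM is flat over the psi window keeping all predictions
  # inside their ambits, so the argmax can sit one bin off
  dpsi <- abs(map$psi[which.max(map$fom)] - 17)
  expect_lte(min(dpsi, 360 - dpsi), 1)
  expect_true(all(map$fom >= 0 & map$fom <= 1))
  # noiseless: the generating direction dominates the rest of the map
  # (the FOM stays below 1 because sub-threshold spots were culled from
  # the reduced data while their predicted intensity remains)
  expect_gt(max(map$fom), 0.9)
  expect_gt(max(map$fom), 1.3 * sort(map$fom, decreasing = TRUE)[20])

  # partial scan + resume equals the single scan (determinism)
  m1 <- gridscan(st0, proj$spots, refl = refl, grid = grid,
                 n_directions = 150)
  m2 <- gridscan(st0, proj$spots, refl = refl, grid = grid,
                 n_directions = 300, resume = m1)
  m3 <- gridscan(st0, proj$spots, refl = refl, grid = grid,
                 n_directions = 300)
  expect_equal(as.data.frame(m2), as.data.frame(m3))

  # checkpoint round trip preserves the map and its grid spec
  ck <- tempfile(fileext = ".tsv")
  write_checkpoint(m2, ck)
  m2b <- read_checkpoint(ck)
  expect_equal(as.data.frame(m2b), as.data.frame(m2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(m2b, "grid")$nside, 8L)

  # resolution window filters the observed spots used
  mwide <- gridscan(st0, proj$spots, refl = refl, grid = grid,
                    n_directions = 12)
  mnarrow <- gridscan(st0, proj$spots, refl = refl, grid = grid,
                      n_directions = 12, dmin = 1.2, dmax = 3)
  expect_lt(attr(mnarrow, "n_spots_used"), attr(mwide, "n_spots_used"))
  expect_error(gridscan(st0, proj$spots, refl = refl, grid = grid,
                        dmin = 25, dmax = 30), "resolution")
})

test_that("top orientations respect the angular separation rule", {
  map <- data.frame(pix = 0:3, theta = c(10, 12, 90, 150),
                    phi = c(0, 5, 180, 300), fom = c(0.9, 0.8, 0.7, 0.6),
                    psi = c(1, 2, 3, 4))
  top1 <- top_orientations(map, 1)
  expect_equal(top1$fom, 0.9)
  # peaks ~4.3 deg apart: only the stronger survives min_sep = 12
  t12 <- top_orientations(map, 4, min_sep = 12)
  expect_equal(nrow(t12), 3L)
  expect_false(0.8 %in% t12$fom)
  # min_sep = 0: plain top-n
  t0 <- top_orientations(map, 2, min_sep = 0)
  expect_equal(t0$fom, c(0.9, 0.8))
})

test_that("geofit is a fixed point at the noiseless truth", {
  tr <- synthetic_truth(noise_sigma = 0, jitter_px = 0, seed = 19)
  proj <- make_synthetic_project(tr, file.path(tempdir(), "noiseless19"))
  st <- tr$setting
  refl <- generate_reflections(proj$structure, st$control$dmin)
  fit <- geofit(st, proj$spots, refl = refl,
                fit = c("theta", "phi", "psi", "sigma_mos", "scale"))
  expect_lte(fit$S_after, fit$S_before + 1e-9)
  # relative cost is negligible against the intensity scale
  scale_S <- sum(proj$spots$I^1.5)       # magnitude of sum w * I_obs^2
  expect_lt(fit$S_after / scale_S, 1e-6)
  expect_equal(unname(fit$par_after), unname(fit$par_before),
               tolerance = 1e-3)
  expect_equal(fit$metrics$R_I, 0, tolerance = 1e-4)
})

test_that("an empty fit mask returns the input setting unchanged", {
  proj <- synthetic_project_cached(seed = 2)
  st <- proj$truth$setting
  refl <- generate_reflections(proj$structure, st$control$dmin)
  fit <- geofit(st, proj$spots, refl = refl, fit = character(0))
  expect_identical(fit$setting_after, st)
  expect_equal(fit$S_after, fit$S_before)
  expect_equal(fit$convergence$niter, 0L)
})

test_that("geofit recovers a 0.5 degree orientation perturbation", {
  # noiseless fixture: recovery precision is then set by the optimizer,
  # not by the injected noise floor
  proj <- synthetic_project_cached(seed = 23, noise_sigma = 0,
                                   jitter_px = 0)
  st <- proj$truth$setting
  refl <- generate_reflections(proj$structure, st$control$dmin)
  st1 <- st
  st1$orientation <- st1$orientation + c(0.35, 0.35, 0.4) # ~0.5 deg off
  st1$control$target <- "sqrt(I)"
  fit <- geofit(st1, proj$spots, refl = refl,
                fit = c("theta", "phi", "psi"), balance_pos_weight = TRUE)
  Rt <- orientation_matrix(st$orientation[1], st$orientation[2],
                           st$orientation[3])
  pa <- fit$par_after
  Rf <- orientation_matrix(pa["theta"], pa["phi"], pa["psi"])
  expect_lt(rotation_distance_deg(Rt, Rf), 0.05)
  expect_lte(fit$S_after, fit$S_before)
})

test_that("frozen parameters and gating rules are enforced", {
  proj <- synthetic_project_cached(seed = 2)
  st <- proj$truth$setting
  refl <- generate_reflections(proj$structure, st$control$dmin)
  expect_error(geofit(st, proj$spots, refl = refl, fit = "omega_axis"),
               "unknown")
  expect_error(geofit(st, proj$spots, refl = refl, fit = "image_rotation"),
               "multi-image")
  # per-image corrections do not even exist in a single-image project
  expect_error(geofit(st, proj$spots, refl = refl, fit = "scale_corr_2"),
               "unknown")
  # ... and in a tilt series they are gated by the control flags
  st2 <- st
  st2$tilt <- tilt_state(0, c(0, 5))
  expect_error(geofit(st2, list(proj$spots, proj$spots), refl = refl,
                      fit = "scale_corr_2"), "k0_corr")
  expect_error(geofit(st2, list(proj$spots, proj$spots), refl = refl,
                      fit = "omega_corr_2"), "omg_corr")
  fit <- geofit(st, proj$spots, refl = refl, fit = c("scale"))
  # everything not fitted is bit-identical
  expect_identical(fit$setting_after$orientation, st$orientation)
  expect_identical(fit$setting_after$mosaicity, st$mosaicity)
  expect_identical(fit$setting_after$beam_center, st$beam_center)
})

test_that("per-spot reports decompose and conserve intensity", {
  proj <- synthetic_project_cached(seed = 2)
  st <- proj$truth$setting
  refl <- generate_reflections(proj$structure, st$control$dmin)
  fit <- geofit(st, proj$spots, refl = refl, fit = character(0))
  rep <- per_spot_report(fit)
  # spots ordered by descending observed intensity
  first_rows <- rep[!duplicated(rep$spot_id), ]
  expect_true(!is.unsorted(rev(first_rows$I_obs)))
  # per spot: contributions sorted strongest-first and summing to I_clc
  for (sid in unique(rep$spot_id)) {
    blk <- rep[rep$spot_id == sid, ]
    expect_equal(sum(blk$I_contrib), blk$I_clc[1], tolerance = 1e-9)
    ind <- blk[!is.na(blk$h), ]
    if (nrow(ind) > 1) expect_true(!is.unsorted(rev(ind$I_contrib)))
    expect_lte(nrow(ind), 5L)            # at most five individual lines
  }
  # a crowded spot gets a remainder aggregate
  n_contrib <- vapply(fit$parts[[1]]$assignment$J, length, 0L)
  if (any(n_contrib > 5)) {
    sid <- proj$spots$id[which(n_contrib > 5)[1]]
    blk <- rep[rep$spot_id == sid, ]
    expect_equal(nrow(blk), 6L)
    expect_true(is.na(blk$h[6]))
  }
})

test_that("the end-to-end indexing workflow recovers the truth", {
  proj <- synthetic_project_cached(seed = 3)
  st0 <- setting_update(proj$truth$setting, orientation = c(0, 0, 0))
  st0$mosaicity <- mosaicity_model("isotropic", 1.5)
  refl <- generate_reflections(proj$structure, st0$control$dmin)
  res <- index_pattern(st0, proj$spots, refl = refl, grid = build_grid(8))
  tru <- proj$truth$setting$orientation
  Rt <- orientation_matrix(tru[1], tru[2], tru[3])
  pa <- res$par_after
  Rf <- orientation_matrix(pa["theta"], pa["phi"], pa["psi"])
  # the inversion image of a centrosymmetric pattern (the pattern rotated
  # 180 degrees about the beam) is an equally valid indexing solution
  err <- min(rotation_distance_deg(Rt, Rf),
             rotation_distance_deg(diag(c(-1, -1, 1)) %*% Rt, Rf))
  expect_lt(err, 0.5)
  expect_lt(abs(pa["sigma_mos"] - 2) / 2, 0.15)
})
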