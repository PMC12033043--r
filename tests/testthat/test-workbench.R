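test_that("reduced data round-trips and is validated", {
  sp <- data.frame(id = c("a", "b", "c"), x = c(1.5, 2.5, 3.5),
                   y = c(4, 5, 6), I = c(10, 20, 30))
  f <- tempfile(fileext = ".tsv")
  write_reduced_data(sp, f)
  back <- read_reduced_data(f)
  expect_equal(back, sp)

  writeLines("id\tx\ty\n1\t2\t3", f)
  expect_error(read_reduced_data(f), "I")

  writeLines(c("id\tx\ty\tI", "a\t1\t2\t5", "b\t1\t2\t-1"), f)
  expect_warning(ok <- read_reduced_data(f), "non-positive")
  expect_equal(nrow(ok), 1L)

  writeLines(c("id\tx\ty\tI\tsigI", "a\t1\t2\t5\t0.3"), f)
  expect_warning(read_reduced_data(f), "sigI")
})

test_that("settings round-trip with schema versioning and field checks", {
  st <- ued_setting(id = "00042", energy_kev = 300,
                    orientation = c(12, 34, 56),
                    mosaicity = mosaicity_model("anisotropic",
                                                sigmas_deg = c(1, 2, 3),
                                                euler_deg = c(10, 20, 30)),
                    shape = shape_transform("standard", sigma_shp = 0.004,
                                            tilt_deg = 5),
                    control = control_params(dmin = 0.8, target = "sqrt(I)",
                                             pos_weight = 2))
  f <- tempfile(fileext = ".yml")
  write_settings(st, f)
  back <- read_settings(f)[[1]]
  expect_equal(back$orientation, st$orientation)
  expect_equal(back$energy_kev, 300)
  expect_equal(back$wavelength, st$wavelength, tolerance = 1e-12)
  expect_equal(back$mosaicity$cov, st$mosaicity$cov, tolerance = 1e-12)
  expect_equal(back$shape$sigma_shp, 0.004)
  expect_equal(back$control$target, "sqrt(I)")
  expect_equal(back$control$pos_weight, 2)

  # unknown fields fail loudly instead of being dropped
  doc <- yaml::read_yaml(f)
  doc$settings[[1]]$bogus_field <- 1
  yaml::write_yaml(doc, f)
  expect_error(read_settings(f), "bogus_field")
  # schema version mismatch is an explicit migration error
  doc$settings[[1]]$bogus_field <- NULL
  doc$schema_version <- 99
  yaml::write_yaml(doc, f)
  expect_error(read_settings(f), "version")
})

test_that("redundant setting fields stay mutually consistent", {
  st <- ued_setting(distance_mm = 500, camera_length_mm = 600)
  expect_equal(st$magnification, 1.2)
  st2 <- setting_update(st, camera_length_mm = 750)
  expect_equal(st2$magnification, 1.5)
  st3 <- setting_update(st, magnification = 2)
  expect_equal(st3$camera_length_mm, 1000)
  st4 <- setting_update(st, energy_kev = 300)
  expect_equal(st4$wavelength, electron_wavelength(300))
  st5 <- setting_update(st, wavelength = 0.0251)
  expect_equal(electron_wavelength(st5$energy_kev), 0.0251, tolerance = 1e-9)
  expect_error(setting_update(st, not_a_field = 1), "unknown")
})

test_that("pattern merging composes with external merging", {
  proj <- synthetic_project_cached(seed = 2)
  st <- proj$truth$setting
  raw <- simulate_pattern(st, proj$structure, merge = FALSE)
  merged <- simulate_pattern(st, proj$structure, merge = TRUE,
                             spots = proj$spots)
  asn <- suppressWarnings(assign_predictions(raw, proj$spots,
                                             st$control$ambit))
  ext <- merge_assigned(asn, raw)
  expect_equal(merged$I_clc, ext$I_clc, tolerance = 1e-12)
  expect_equal(merged$x_clc, ext$x_clc, tolerance = 1e-12)
  # zero-intensity reflections never appear
  expect_true(all(raw$I > 0))
})

test_that("rendered images conserve intensity and broaden with divergence", {
  proj <- synthetic_project_cached(seed = 2)
  st <- proj$truth$setting
  # low-resolution cut keeps all footprints well inside the frame
  st$control$dmin <- 2.5
  img <- simulate_image(st, proj$structure, image_shape = c(1024, 1024))
  expect_true(all(img >= 0))
  preds <- simulate_pattern(st, proj$structure)
  expect_equal(sum(img), sum(preds$I), tolerance = 5e-3)

  # no reflections in range: an all-zero image
  st0 <- st; st0$control$dmin <- 50
  expect_equal(sum(simulate_image(st0, proj$structure,
                                  image_shape = c(1024, 1024))), 0)
  expect_error(simulate_image(st, proj$structure, image_shape = c(64, 64)),
               "beam center")

  # divergence strictly increases a spot's second moment
  moment2 <- function(im, x0, y0, w = 12) {
    xs <- (x0 - w):(x0 + w); ys <- (y0 - w):(y0 + w)
    blk <- im[ys + 1, xs + 1]
    dx2 <- outer(rep(1, length(ys)), (xs - x0)^2)
    dy2 <- outer((ys - y0)^2, rep(1, length(xs)))
    sum(blk * (dx2 + dy2)) / sum(blk)
  }
  top <- preds[which.max(preds$I), ]
  st_div <- setting_update(st, divergence = 2e-3)
  img2 <- simulate_image(st_div, proj$structure, image_shape = c(1024, 1024))
  m1 <- moment2(img, round(top$x), round(top$y))
  m2 <- moment2(img2, round(top$x), round(top$y))
  expect_gt(m2, m1)

  # masked detector regions render as zero (window fully inside the disk)
  msk <- detector_mask("circle", center = c(top$x, top$y), radius = 8)
  img3 <- simulate_image(st, proj$structure, image_shape = c(1024, 1024),
                         mask = msk)
  expect_equal(moment2(img3, round(top$x), round(top$y), 4), NaN)
})

test_that("the synthetic generator is seed-deterministic", {
  d1 <- file.path(tempdir(), "det_a"); d2 <- file.path(tempdir(), "det_b")
  p1 <- make_synthetic_project(synthetic_truth(seed = 31), d1)
  p2 <- make_synthetic_project(synthetic_truth(seed = 31), d2)
  expect_identical(readLines(p1$reduced), readLines(p2$reduced))
  expect_identical(readLines(p1$cif), readLines(p2$cif))
  p3 <- make_synthetic_project(synthetic_truth(seed = 32),
                               file.path(tempdir(), "det_c"))
  expect_false(identical(readLines(p1$reduced), readLines(p3$reduced)))
})

test_that("noiseless reduced data equals the merged simulation", {
  tr <- synthetic_truth(noise_sigma = 0, jitter_px = 0, seed = 8)
  proj <- make_synthetic_project(tr, file.path(tempdir(), "noiseless8"))
  sim <- simulate_pattern(tr$setting, proj$structure, merge = TRUE,
                          spots = proj$spots)
  expect_equal(proj$spots$I, sim$I_clc, tolerance = 1e-9)
  expect_equal(proj$spots$x, sim$x_clc, tolerance = 1e-9)
  expect_equal(proj$spots$y, sim$y_clc, tolerance = 1e-9)
})

test_that("intensity noise has the requested log-scale spread", {
  tr <- synthetic_truth(noise_sigma = 0.1, jitter_px = 0, seed = 15,
                        max_spots = 200, detection_threshold = 5e-4)
  proj <- make_synthetic_project(tr, file.path(tempdir(), "noisecal"))
  lr <- log(proj$spots$I / proj$I_true)
  n <- length(lr)
  expect_gte(n, 100)
  se <- 0.1 / sqrt(2 * (n - 1))          # SE of a sample sd
  expect_lt(abs(stats::sd(lr) - 0.1), 3 * se)
})

test_that("masked regions contribute no spots or predictions", {
  proj <- synthetic_project_cached(seed = 2)
  st <- proj$truth$setting
  msk <- detector_mask("circle", center = st$beam_center, radius = 150)
  pat <- simulate_pattern(st, proj$structure, mask = msk)
  r <- sqrt((pat$x - st$beam_center[1])^2 + (pat$y - st$beam_center[2])^2)
  expect_true(all(r > 150))
  expect_false(any(mask_contains(msk, pat$x, pat$y)))
  # union and rectangle masks compose
  msk2 <- detector_mask("union", members = list(
    msk, detector_mask("rect", xlim = c(0, 10), ylim = c(0, 10))))
  expect_true(mask_contains(msk2, 5, 5))
  expect_true(mask_contains(msk2, st$beam_center[1], st$beam_center[2]))
  expect_false(mask_contains(msk2, 900, 900))
})
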