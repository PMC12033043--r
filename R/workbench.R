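# Project-level operations: pattern and image simulation, the synthetic
# fixture generator, and project serialization.

#' Simulate a diffraction pattern
#'
#' Predicts the Bragg-spot list of one image under a setting; with
#' `merge = TRUE` the predictions are merged within the ambits of a
#' supplied observed-spot table (intensity sums, intensity-weighted
#' centroids), mirroring how observed spots arise as superpositions.
#'
#' @param setting A [ued_setting()].
#' @param structure A `crystal_structure`.
#' @param merge Merge predictions into the ambits of `spots`?
#' @param spots Observed-spot table (required when `merge = TRUE`).
#' @param image_index Image of a tilt series.
#' @param mask Optional [detector_mask()].
#' @return Prediction table ([aniso_predict()] layout), or the merged
#'   per-spot table when `merge = TRUE`.
#' @export
simulate_pattern <- function(setting, structure, merge = FALSE, spots = NULL,
                             image_index = 1L, mask = NULL) {
  preds <- predict_spots(setting, structure = structure,
                         image_index = image_index)
  preds <- preds[preds$I > 0, , drop = FALSE]
  if (!is.null(mask) && nrow(preds))
    preds <- preds[!mask_contains(mask, preds$x, preds$y), , drop = FALSE]
  if (!merge) return(preds)
  if (is.null(spots)) stop("merge = TRUE requires an observed-spot table")
  asn <- assign_predictions(preds, spots, setting$control$ambit, mask)
  cbind(spots[, c("id", "x", "y", "I")], merge_assigned(asn, preds))
}

#' Simulate a diffraction image
#'
#' Renders every predicted reflection as a two-dimensional Gaussian
#' footprint: the detector-plane projection of its reciprocal-space
#' profile, plus the divergence footprint (`sigma_divg * Leff`) and a
#' radial bandwidth smear -- broadenings that affect images but not the
#' integrated pattern.  Simulation always uses the full-covariance
#' (ANISO) model regardless of the setting's modeling flag.  The pixel
#' sum of a spot equals its predicted intensity (footprints are
#' normalized over their rendered window, truncated at 4 sigma).
#'
#' @param setting A [ued_setting()].
#' @param structure A `crystal_structure`.
#' @param image_shape `c(ny, nx)` in pixels.
#' @param image_index Image of a tilt series.
#' @param mask Optional [detector_mask()]; masked pixels render as 0.
#' @return `ny x nx` numeric matrix (row = y, column = x; 0-based pixel
#'   centers), nonnegative.
#' @export
simulate_image <- function(setting, structure, image_shape = c(1024, 1024),
                           image_index = 1L, mask = NULL) {
  bc <- setting$beam_center
  if (bc[1] < 0 || bc[1] > image_shape[2] - 1 ||
      bc[2] < 0 || bc[2] > image_shape[1] - 1)
    stop("image_shape does not contain the beam center")
  s_aniso <- setting
  s_aniso$control$aniso <- TRUE
  if (s_aniso$shape$mode == "standard") {
    shp <- s_aniso$shape
    s_aniso$shape <- shape_transform("aniso",
      sigmas = c(1e-6, 1e-6, shp$sigma_shp),
      euler_deg = c(shp$tilt_azimuth_deg, shp$tilt_deg, 0))
  }
  refl <- generate_reflections(structure, setting$control$dmin,
                               setting$control$dmax)
  geom <- setting_geometry(s_aniso)
  preds <- aniso_predict(refl, setting_rotation(s_aniso), s_aniso$mosaicity,
                         s_aniso$shape, setting_beam(s_aniso), geom,
                         tilt = s_aniso$tilt, image_index = image_index,
                         scale = s_aniso$scale, b_factor = s_aniso$b_factor,
                         detail = TRUE)
  img <- matrix(0, image_shape[1], image_shape[2])
  if (!nrow(preds)) return(img)
  sconv <- geom$camera_length_mm * geom$wavelength / geom$pixel_size_mm
  divg_px <- (setting$divergence * geom$camera_length_mm / geom$pixel_size_mm)^2
  for (i in seq_len(nrow(preds))) {
    if (preds$I[i] <= 0) next
    Cxx <- sconv^2 * preds$fp_xx[i] + divg_px
    Cxy <- sconv^2 * preds$fp_xy[i]
    Cyy <- sconv^2 * preds$fp_yy[i] + divg_px
    # radial bandwidth smear
    rx <- preds$x[i] - bc[1]; ry <- preds$y[i] - bc[2]
    rr <- sqrt(rx^2 + ry^2)
    if (rr > 0 && setting$bandwidth > 0) {
      ux <- rx / rr; uy <- ry / rr
      sb2 <- (setting$bandwidth * rr)^2
      Cxx <- Cxx + sb2 * ux^2; Cxy <- Cxy + sb2 * ux * uy
      Cyy <- Cyy + sb2 * uy^2
    }
    # floor at a fraction of a pixel so footprints are resolvable
    Cxx <- Cxx + 0.08; Cyy <- Cyy + 0.08
    det <- Cxx * Cyy - Cxy^2
    if (det <= 0) next
    w <- ceiling(4 * sqrt(max(Cxx, Cyy)))
    x0 <- round(preds$x[i]); y0 <- round(preds$y[i])
    xs <- max(0, x0 - w):min(image_shape[2] - 1, x0 + w)
    ys <- max(0, y0 - w):min(image_shape[1] - 1, y0 + w)
    if (!length(xs) || !length(ys)) next
    dx <- xs - preds$x[i]; dy <- ys - preds$y[i]
    # quadratic form with inverse covariance
    ixx <- Cyy / det; iyy <- Cxx / det; ixy <- -Cxy / det
    Q <- outer(dy^2 * iyy, dx^2 * ixx, "+") +
      2 * ixy * outer(dy, dx)
    G <- exp(-Q / 2)
    sG <- sum(G)
    if (sG <= 0) next
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + preds$I[i] * G / sG
  }
  if (!is.null(mask)) {
    xg <- matrix(rep(0:(image_shape[2] - 1), each = image_shape[1]),
                 image_shape[1])
    yg <- matrix(rep(0:(image_shape[1] - 1), image_shape[2]), image_shape[1])
    img[mask_contains(mask, as.vector(xg), as.vector(yg))] <- 0
  }
  img
}

#' Synthetic ground truth specification
#'
#' @param setting The generating [ued_setting()].
#' @param noise_sigma Multiplicative log-normal intensity noise (sdlog).
#' @param jitter_px Gaussian centroid jitter per coordinate (pixels).
#' @param detection_threshold Spots weaker than this fraction of the
#'   strongest spot are dropped.
#' @param max_spots Keep at most this many strongest spots.
#' @param merge_radius_px Predictions closer than this merge into one
#'   observed spot.
#' @param seed RNG seed; regeneration with the same seed is
#'   byte-identical.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(setting = synthetic_default_setting(),
                            noise_sigma = 0.1, jitter_px = 0.3,
                            detection_threshold = 2e-3, max_spots = 90,
                            merge_radius_px = 6, seed = 1) {
  structure(list(setting = setting, noise_sigma = noise_sigma,
                 jitter_px = jitter_px,
                 detection_threshold = detection_threshold,
                 max_spots = max_spots, merge_radius_px = merge_radius_px,
                 seed = seed),
            class = "synthetic_truth")
}

#' Default generating conditions of the synthetic fixture
#'
#' A 200 keV beam, 500 mm camera, 0.05 mm pixels, a quasi-single crystal
#' with 2 degrees of isotropic mosaic spread and ~300 Angstrom plate-like
#' domains -- conditions typical of transmission UED on molecular
#' crystals.
#'
#' @param orientation Generating orientation `c(theta, phi, psi)` deg.
#' @param sigma_mos_deg Isotropic mosaic spread (degrees).
#' @param aniso Use ANISO modeling in the truth setting?
#' @return A [ued_setting()].
#' @export
synthetic_default_setting <- function(orientation = c(38, 121, 47),
                                      sigma_mos_deg = 2, aniso = FALSE) {
  sq <- shape_sigma_from_size("plate", 300)$sigma_q
  ued_setting(id = "truth",
              energy_kev = 200,
              pixel_size_mm = 0.05,
              distance_mm = 500,
              beam_center = c(511.5, 511.5),
              orientation = orientation,
              mosaicity = mosaicity_model("isotropic", sigma_deg = sigma_mos_deg),
              shape = shape_transform("standard", sigma_shp = sq),
              scale = 1e4,
              control = control_params(dmin = 1.2, dmax = Inf,
                                       aniso = aniso, target = "I"))
}

# deterministic toy molecular crystal (triclinic P-1, 9-atom asymmetric
# unit) written as CIF text; synthetic stand-in for real structures.
.toy_cif_text <- function() {
  paste(c(
    "data_synthetic_toy",
    "_cell_length_a    11.20",
    "_cell_length_b    12.80",
    "_cell_length_c     9.60",
    "_cell_angle_alpha 95.0",
    "_cell_angle_beta 102.0",
    "_cell_angle_gamma 88.0",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x,y,z'",
    "'-x,-y,-z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "_atom_site_B_iso_or_equiv",
    "S1  S 0.1180 0.2310 0.3370 1.0 2.5",
    "N1  N 0.2540 0.1120 0.4410 1.0 2.0",
    "O1  O 0.3720 0.3480 0.1290 1.0 2.2",
    "C1  C 0.2010 0.2890 0.2180 1.0 1.8",
    "C2  C 0.3330 0.1840 0.3150 1.0 1.8",
    "C3  C 0.4450 0.2620 0.4060 1.0 1.9",
    "C4  C 0.0870 0.4110 0.1520 1.0 2.1",
    "C5  C 0.5210 0.0730 0.2470 1.0 2.0",
    "O2  O 0.6040 0.1490 0.0680 1.0 2.4"),
    collapse = "\n")
}

#' Generate a synthetic project on disk
#'
#' Writes a toy CIF (triclinic P-1 molecular cell), simulates its
#' diffraction pattern under the truth setting, merges overlapping
#' predictions into observed "spots", applies seeded multiplicative
#' log-normal intensity noise and Gaussian centroid jitter, drops
#' sub-threshold spots, and writes the reduced-data table, a rendered
#' diffraction image (PNG), an optional beamstop mask, and the hidden
#' truth file.
#'
#' @param truth A [synthetic_truth()].
#' @param out_dir Output directory (created if missing).
#' @param write_image Render and write the diffraction image (PNG)?
#' @param beamstop_px Radius of the central beamstop mask disk (pixels);
#'   0 disables the mask.
#' @return A list: file paths, the truth, and the in-memory reduced
#'   data.
#' @export
make_synthetic_project <- function(truth = synthetic_truth(), out_dir,
                                   write_image = FALSE, beamstop_px = 30) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(truth$seed)
  cif_path <- file.path(out_dir, "structure_synthetic.cif")
  writeLines(.toy_cif_text(), cif_path)
  str <- parse_cif(cif_path)
  st <- truth$setting
  mask <- if (beamstop_px > 0)
    detector_mask("circle", center = st$beam_center, radius = beamstop_px)
  else NULL

  preds <- simulate_pattern(st, str)
  spots <- .merge_close_predictions(preds, truth$merge_radius_px)
  if (!is.null(mask))
    spots <- spots[!mask_contains(mask, spots$x, spots$y), , drop = FALSE]
  # detection threshold and cap before noise (emulates peak picking)
  spots <- spots[spots$I >= truth$detection_threshold * max(spots$I), , drop = FALSE]
  spots <- utils::head(spots[order(-spots$I), , drop = FALSE], truth$max_spots)
  # make the noiseless list a fixed point of the downstream ambit-merge
  # rule: re-derive intensities and centroids from the final ambits
  for (pass in 1:2) {
    asn <- suppressWarnings(assign_predictions(preds, spots, NULL))
    merged <- merge_assigned(asn, preds)
    spots <- data.frame(x = merged$x_clc, y = merged$y_clc,
                        I = merged$I_clc)[merged$matched, , drop = FALSE]
  }
  n <- nrow(spots)
  I_true <- spots$I
  spots$I <- I_true * exp(stats::rnorm(n, 0, truth$noise_sigma))
  spots$x <- spots$x + stats::rnorm(n, 0, truth$jitter_px)
  spots$y <- spots$y + stats::rnorm(n, 0, truth$jitter_px)
  spots <- data.frame(id = sprintf("S%04d", seq_len(n)),
                      x = spots$x, y = spots$y, I = spots$I,
                      stringsAsFactors = FALSE)
  reduced_path <- file.path(out_dir, "reduced.tsv")
  write_reduced_data(spots, reduced_path)

  image_path <- NULL
  if (write_image) {
    img <- simulate_image(st, str, image_shape = c(1024, 1024), mask = mask)
    img <- img / max(img, 1e-12)
    image_path <- file.path(out_dir, "image_synthetic.png")
    png::writePNG(pmin(1, img^0.25), image_path)  # gamma for visibility
  }
  truth_path <- file.path(out_dir, "truth.yml")
  write_settings(st, file.path(out_dir, "truth_setting.yml"))
  yaml::write_yaml(list(seed = truth$seed, noise_sigma = truth$noise_sigma,
                        jitter_px = truth$jitter_px,
                        detection_threshold = truth$detection_threshold,
                        n_spots = n, I_true = I_true), truth_path)
  list(cif = cif_path, reduced = reduced_path, image = image_path,
       truth_file = truth_path, truth = truth, spots = spots,
       structure = str, mask = mask, I_true = I_true)
}

# greedy merge of predictions closer than r (descending intensity seeds)
.merge_close_predictions <- function(preds, r) {
  if (!nrow(preds)) return(preds[, c("x", "y", "I")])
  p <- preds[order(-preds$I), , drop = FALSE]
  used <- rep(FALSE, nrow(p))
  out <- list()
  for (i in seq_len(nrow(p))) {
    if (used[i]) next
    d2 <- (p$x - p$x[i])^2 + (p$y - p$y[i])^2
    grp <- which(!used & d2 < r^2)
    used[grp] <- TRUE
    Ig <- sum(p$I[grp])
    out[[length(out) + 1]] <- data.frame(
      x = sum(p$x[grp] * p$I[grp]) / Ig,
      y = sum(p$y[grp] * p$I[grp]) / Ig,
      I = Ig)
  }
  do.call(rbind, out)
}
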