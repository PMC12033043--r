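# A "setting" is one complete parameter set describing a candidate
# interpretation of a diffraction pattern: model parameters (geometry,
# beam, sample imperfections) plus control parameters (how predictions
# are matched and scored).  Redundant fields (energy <-> wavelength,
# distance <-> camera length <-> magnification) are kept consistent on
# every edit through setting_update().

.settings_schema_version <- 1L

#' Control parameters
#'
#' @param dmin,dmax Resolution range in Angstrom.
#' @param ambit Ambit radius in pixels, or `NULL` for the non-overlap
#'   maximum.
#' @param mask Logical: apply the project's detector mask.
#' @param target `"I"` or `"sqrt(I)"`: intensity residual convention.
#' @param pos_weight Weight w_P of the position part of the cost.
#' @param fpred_weight Weight w2 of non-matching ("false") predictions.
#' @param aniso Logical: full-covariance (ANISO) or standard modeling.
#' @param tilt_use Logical: honor the relrod tilt (standard modeling).
#' @param k0_corr,omg_corr Logical: per-image intensity / tilt-angle
#'   corrections (multi-image projects only).
#' @return A `control_params` list.
#' @export
control_params <- function(dmin = 1, dmax = Inf, ambit = NULL, mask = FALSE,
                           target = c("I", "sqrt(I)"), pos_weight = 0,
                           fpred_weight = 0, aniso = FALSE, tilt_use = FALSE,
                           k0_corr = FALSE, omg_corr = FALSE) {
  target <- match.arg(target)
  stopifnot(dmin > 0, dmin < dmax, pos_weight >= 0, fpred_weight >= 0)
  structure(list(dmin = dmin, dmax = dmax, ambit = ambit, mask = mask,
                 target = target, pos_weight = pos_weight,
                 fpred_weight = fpred_weight, aniso = aniso,
                 tilt_use = tilt_use, k0_corr = k0_corr,
                 omg_corr = omg_corr),
            class = "control_params")
}

#' Create a parameter setting
#'
#' @param id Setting identifier (free text; run tools zero-pad counters).
#' @param energy_kev Electron energy in keV (sets the wavelength).
#' @param divergence Beam divergence half-angle spread in radians.
#' @param bandwidth Fractional energy bandwidth.
#' @param pixel_size_mm,distance_mm,camera_length_mm,beam_center,image_rotation_deg,distortion
#'   Detector geometry, see [detector_geometry()].
#' @param orientation `c(theta, phi, psi)` in degrees.
#' @param mosaicity A [mosaicity_model()].
#' @param shape A [shape_transform()].
#' @param scale Overall intensity scale factor.
#' @param b_factor Global B-factor; intensities damped by
#'   `exp(-B h^2 / 2)`.
#' @param omega_axis_deg,omega_angles_deg,scale_corrections,omega_corrections
#'   Tilt-series state, see [tilt_state()]; single-image projects keep
#'   the defaults.
#' @param control A [control_params()].
#' @param note Free-text note.
#' @return A `ued_setting`.
#' @export
ued_setting <- function(id = "00000",
                        energy_kev = 200,
                        divergence = 0,
                        bandwidth = 0,
                        pixel_size_mm = 0.05,
                        distance_mm = 500,
                        camera_length_mm = distance_mm,
                        beam_center = c(512, 512),
                        image_rotation_deg = 0,
                        distortion = c(0, 0),
                        orientation = c(0, 0, 0),
                        mosaicity = mosaicity_model(),
                        shape = shape_transform(),
                        scale = 1,
                        b_factor = 0,
                        omega_axis_deg = 0,
                        omega_angles_deg = 0,
                        scale_corrections = NULL,
                        omega_corrections = NULL,
                        control = control_params(),
                        note = "") {
  s <- structure(list(
    id = id,
    energy_kev = energy_kev,
    wavelength = electron_wavelength(energy_kev),
    divergence = divergence,
    bandwidth = bandwidth,
    pixel_size_mm = pixel_size_mm,
    distance_mm = distance_mm,
    camera_length_mm = camera_length_mm,
    magnification = camera_length_mm / distance_mm,
    beam_center = beam_center,
    image_rotation_deg = image_rotation_deg,
    distortion = distortion,
    orientation = orientation,
    mosaicity = mosaicity,
    shape = shape,
    scale = scale,
    b_factor = b_factor,
    tilt = tilt_state(omega_axis_deg, omega_angles_deg,
                      scale_corrections, omega_corrections),
    control = control,
    note = note), class = "ued_setting")
  s
}

#' @export
print.ued_setting <- function(x, ...) {
  o <- x$orientation
  cat(sprintf("setting %s: %g keV (lambda %.5g A), Leff %g mm, orientation (%.3f, %.3f, %.3f) deg\n",
              x$id, x$energy_kev, x$wavelength, x$camera_length_mm,
              o[1], o[2], o[3]))
  cat(sprintf("  mosaicity %s, shape %s, %s modeling, d in [%g, %g] A\n",
              x$mosaicity$mode, x$shape$mode,
              if (x$control$aniso) "ANISO" else "standard",
              x$control$dmin, x$control$dmax))
  invisible(x)
}

#' Edit a setting, keeping redundant fields consistent
#'
#' Updating `energy_kev` refreshes `wavelength` (and vice versa, through
#' the relativistic energy-wavelength relation); updating any of
#' `distance_mm`, `camera_length_mm`, `magnification` keeps
#' `magnification = camera_length_mm / distance_mm` true (editing the
#' magnification moves the camera length).
#'
#' @param setting A [ued_setting()].
#' @param ... Named fields to replace; unknown names are an error.
#' @return The updated setting.
#' @export
setting_update <- function(setting, ...) {
  upd <- list(...)
  for (nm in names(upd)) {
    if (!nm %in% names(setting))
      stop(sprintf("unknown setting field '%s'", nm))
    setting[[nm]] <- upd[[nm]]
    if (nm == "energy_kev")
      setting$wavelength <- electron_wavelength(setting$energy_kev)
    if (nm == "wavelength") {
      # invert lambda = 12.2639 / sqrt(V (1 + 0.97845e-6 V))
      cc <- (12.2639 / setting$wavelength)^2
      b <- 0.97845e-6
      V <- (-1 + sqrt(1 + 4 * b * cc)) / (2 * b)
      setting$energy_kev <- V / 1e3
    }
    if (nm == "magnification")
      setting$camera_length_mm <- setting$magnification * setting$distance_mm
    if (nm %in% c("distance_mm", "camera_length_mm"))
      setting$magnification <- setting$camera_length_mm / setting$distance_mm
  }
  setting
}

# component extractors -------------------------------------------------------

setting_geometry <- function(setting) {
  detector_geometry(pixel_size_mm = setting$pixel_size_mm,
                    distance_mm = setting$distance_mm,
                    camera_length_mm = setting$camera_length_mm,
                    beam_center = setting$beam_center,
                    image_rotation_deg = setting$image_rotation_deg,
                    distortion = setting$distortion,
                    energy_kev = setting$energy_kev)
}

setting_beam <- function(setting) {
  beam_model(sigma_divg = setting$divergence, sigma_bwdth = setting$bandwidth)
}

setting_rotation <- function(setting) {
  o <- setting$orientation
  orientation_matrix(o[1], o[2], o[3])
}

#' Predict the diffraction pattern of one image under a setting
#'
#' Applies the setting's modeling flag (`control$aniso`) to a
#' pre-enumerated reflection table.  In standard modeling the relrod
#' direction is the shape transform's tilt when `control$tilt_use` is
#' set (co-rotating with the sample tilt), otherwise straight down the
#' beam.  Per-image intensity corrections are applied when
#' `control$k0_corr` is set.
#'
#' @param setting A [ued_setting()].
#' @param refl Reflection table from [generate_reflections()] (already
#'   resolution-filtered, or pass `structure` instead).
#' @param structure Optionally a `crystal_structure`; reflections are
#'   then enumerated with the setting's resolution range.
#' @param image_index Image of the tilt series to predict.
#' @return Prediction table as in [aniso_predict()].
#' @export
predict_spots <- function(setting, refl = NULL, structure = NULL,
                          image_index = 1L) {
  if (is.null(refl)) {
    if (is.null(structure)) stop("give either refl or structure")
    refl <- generate_reflections(structure, setting$control$dmin,
                                 setting$control$dmax)
  }
  geom <- setting_geometry(setting)
  beam <- setting_beam(setting)
  R <- setting_rotation(setting)
  tilt <- setting$tilt
  sc <- setting$scale
  if (setting$control$k0_corr)
    sc <- sc * tilt$scale_corrections[image_index]
  if (!setting$control$omg_corr) {
    tilt <- tilt_state(tilt$omega_axis_deg, tilt$omega_angles_deg)
  }
  if (setting$control$aniso) {
    aniso_predict(refl, R, setting$mosaicity, setting$shape, beam, geom,
                  tilt = tilt, image_index = image_index,
                  scale = sc, b_factor = setting$b_factor)
  } else {
    shp <- setting$shape
    if (shp$mode != "standard")
      stop("standard modeling requires a standard-mode shape transform")
    if (!setting$control$tilt_use) {
      shp <- shape_transform("standard", sigma_shp = shp$sigma_shp)
    } else {
      ang <- (tilt$omega_angles_deg[image_index] +
                tilt$omega_corrections[image_index]) * .deg
      if (abs(ang) > 0) {
        ax <- c(cos(tilt$omega_axis_deg * .deg),
                sin(tilt$omega_axis_deg * .deg), 0)
        shp$direction <- drop(.rot_axis(ax, ang) %*% shp$direction)
      }
    }
    mos <- setting$mosaicity
    if (mos$mode != "isotropic")
      stop("standard modeling requires isotropic mosaicity")
    standard_predict(refl, R, mos, shp, beam, geom,
                     tilt = tilt, image_index = image_index,
                     scale = sc, b_factor = setting$b_factor)
  }
}

# settings file I/O -----------------------------------------------------------

.setting_to_list <- function(s) {
  list(id = s$id, energy_kev = s$energy_kev, divergence = s$divergence,
       bandwidth = s$bandwidth, pixel_size_mm = s$pixel_size_mm,
       distance_mm = s$distance_mm, camera_length_mm = s$camera_length_mm,
       beam_center = as.numeric(s$beam_center),
       image_rotation_deg = s$image_rotation_deg,
       distortion = as.numeric(s$distortion),
       orientation = as.numeric(s$orientation),
       mosaicity = list(mode = s$mosaicity$mode,
                        sigma_deg = s$mosaicity$sigma_deg,
                        sigmas_deg = as.numeric(s$mosaicity$sigmas_deg),
                        euler_deg = as.numeric(s$mosaicity$euler_deg)),
       shape = if (s$shape$mode == "standard")
         list(mode = "standard", sigma_shp = s$shape$sigma_shp,
              tilt_deg = s$shape$tilt_deg,
              tilt_azimuth_deg = s$shape$tilt_azimuth_deg)
       else list(mode = "aniso", sigmas = as.numeric(s$shape$sigmas),
                 euler_deg = as.numeric(s$shape$euler_deg)),
       scale = s$scale, b_factor = s$b_factor,
       omega_axis_deg = s$tilt$omega_axis_deg,
       omega_angles_deg = as.numeric(s$tilt$omega_angles_deg),
       scale_corrections = as.numeric(s$tilt$scale_corrections),
       omega_corrections = as.numeric(s$tilt$omega_corrections),
       control = unclass(s$control)[!vapply(unclass(s$control), is.null, TRUE)],
       note = s$note)
}

.setting_from_list <- function(x) {
  known <- c("id", "energy_kev", "divergence", "bandwidth", "pixel_size_mm",
             "distance_mm", "camera_length_mm", "beam_center",
             "image_rotation_deg", "distortion", "orientation", "mosaicity",
             "shape", "scale", "b_factor", "omega_axis_deg",
             "omega_angles_deg", "scale_corrections", "omega_corrections",
             "control", "note")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop(sprintf("unknown setting field(s) in file: %s",
                 paste(bad, collapse = ", ")))
  mos <- do.call(mosaicity_model, x$mosaicity)
  shp <- do.call(shape_transform, x$shape)
  ctl_in <- x$control %||% list()
  if (!is.null(ctl_in$dmax) && is.character(ctl_in$dmax))
    ctl_in$dmax <- as.numeric(ctl_in$dmax)     # YAML ".inf"
  ctl <- do.call(control_params, ctl_in)
  ued_setting(id = x$id %||% "00000",
              energy_kev = x$energy_kev %||% 200,
              divergence = x$divergence %||% 0,
              bandwidth = x$bandwidth %||% 0,
              pixel_size_mm = x$pixel_size_mm %||% 0.05,
              distance_mm = x$distance_mm %||% 500,
              camera_length_mm = x$camera_length_mm %||% (x$distance_mm %||% 500),
              beam_center = x$beam_center %||% c(512, 512),
              image_rotation_deg = x$image_rotation_deg %||% 0,
              distortion = x$distortion %||% c(0, 0),
              orientation = x$orientation %||% c(0, 0, 0),
              mosaicity = mos, shape = shp,
              scale = x$scale %||% 1, b_factor = x$b_factor %||% 0,
              omega_axis_deg = x$omega_axis_deg %||% 0,
              omega_angles_deg = x$omega_angles_deg %||% 0,
              scale_corrections = x$scale_corrections,
              omega_corrections = x$omega_corrections,
              control = ctl, note = x$note %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write settings to a file
#'
#' Human-readable, versioned YAML; one document holding the schema
#' version and the list of settings.
#'
#' @param settings A single setting or list of [ued_setting()].
#' @param path Output file path.
#' @export
write_settings <- function(settings, path) {
  if (inherits(settings, "ued_setting")) settings <- list(settings)
  doc <- list(schema_version = .settings_schema_version,
              settings = lapply(settings, .setting_to_list))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read settings from a file
#'
#' @param path Settings file written by [write_settings()].
#' @return List of `ued_setting` objects.
#' @export
read_settings <- function(path) {
  doc <- yaml::read_yaml(path)
  ver <- doc$schema_version
  if (is.null(ver) || ver != .settings_schema_version)
    stop(sprintf("settings schema version %s cannot be migrated (expected %d)",
                 ver %||% "<missing>", .settings_schema_version))
  lapply(doc$settings, .setting_from_list)
}
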