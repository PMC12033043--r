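# GeoFit: bounded trust-region least-squares refinement of the model
# parameters of a setting against one image or a tilt series.
#
# The residual vector has a fixed layout (every observed spot always
# contributes; the no-hit term is aggregated), so the optimizer sees a
# smooth problem between ambit reassignments; assignments are recomputed
# at every evaluation and the trust region absorbs the induced
# piecewise-smoothness.

# fittable parameters and their box constraints --------------------------------
.par_catalog <- function(setting, n_images) {
  mos <- setting$mosaicity; shp <- setting$shape
  rows <- list(
    c("magnification", setting$magnification, 1e-6, Inf),
    c("beam_center_x", setting$beam_center[1], -Inf, Inf),
    c("beam_center_y", setting$beam_center[2], -Inf, Inf),
    c("image_rotation", setting$image_rotation_deg, -Inf, Inf),
    c("distortion_eps", setting$distortion[1], -0.5, 0.5),
    c("distortion_phi0", setting$distortion[2], -Inf, Inf),
    c("theta", setting$orientation[1], -Inf, Inf),
    c("phi", setting$orientation[2], -Inf, Inf),
    c("psi", setting$orientation[3], -Inf, Inf),
    c("scale", setting$scale, 1e-12, Inf),
    c("b_factor", setting$b_factor, -Inf, Inf))
  if (mos$mode == "isotropic") {
    rows <- c(rows, list(c("sigma_mos", mos$sigma_deg, 0, Inf)))
  } else {
    for (i in 1:3) rows <- c(rows, list(
      c(paste0("mos_sig", i), mos$sigmas_deg[i], 0, Inf)))
    for (i in 1:3) rows <- c(rows, list(
      c(paste0("mos_eul", i), mos$euler_deg[i], -Inf, Inf)))
  }
  if (shp$mode == "standard") {
    rows <- c(rows, list(c("sigma_shp", shp$sigma_shp, 0, Inf),
                         c("shape_tilt", shp$tilt_deg, -90, 90),
                         c("shape_tilt_az", shp$tilt_azimuth_deg, -Inf, Inf)))
  } else {
    for (i in 1:3) rows <- c(rows, list(
      c(paste0("shp_sig", i), shp$sigmas[i], 0, Inf)))
    for (i in 1:3) rows <- c(rows, list(
      c(paste0("shp_eul", i), shp$euler_deg[i], -Inf, Inf)))
  }
  if (n_images > 1) {
    for (i in 2:n_images) rows <- c(rows, list(
      c(paste0("scale_corr_", i), setting$tilt$scale_corrections[i], 1e-6, Inf),
      c(paste0("omega_corr_", i), setting$tilt$omega_corrections[i], -Inf, Inf)))
  }
  df <- data.frame(name = vapply(rows, `[`, "", 1),
                   value = as.numeric(vapply(rows, `[`, "", 2)),
                   lower = as.numeric(vapply(rows, `[`, "", 3)),
                   upper = as.numeric(vapply(rows, `[`, "", 4)),
                   stringsAsFactors = FALSE)
  rownames(df) <- df$name
  df
}

# push a named parameter vector back into a setting
.apply_params <- function(setting, par) {
  nm <- names(par)
  g <- function(key, cur) if (key %in% nm) par[[key]] else cur
  if ("magnification" %in% nm)
    setting <- setting_update(setting, magnification = par[["magnification"]])
  setting$beam_center <- c(g("beam_center_x", setting$beam_center[1]),
                           g("beam_center_y", setting$beam_center[2]))
  setting$image_rotation_deg <- g("image_rotation", setting$image_rotation_deg)
  setting$distortion <- c(g("distortion_eps", setting$distortion[1]),
                          g("distortion_phi0", setting$distortion[2]))
  setting$orientation <- c(g("theta", setting$orientation[1]),
                           g("phi", setting$orientation[2]),
                           g("psi", setting$orientation[3]))
  setting$scale <- g("scale", setting$scale)
  setting$b_factor <- g("b_factor", setting$b_factor)
  mos <- setting$mosaicity
  if (mos$mode == "isotropic") {
    if ("sigma_mos" %in% nm)
      setting$mosaicity <- mosaicity_model("isotropic", sigma_deg = par[["sigma_mos"]])
  } else {
    sig <- vapply(1:3, function(i) g(paste0("mos_sig", i), mos$sigmas_deg[i]), 0)
    eul <- vapply(1:3, function(i) g(paste0("mos_eul", i), mos$euler_deg[i]), 0)
    setting$mosaicity <- mosaicity_model("anisotropic", sigmas_deg = sig,
                                         euler_deg = eul)
  }
  shp <- setting$shape
  if (shp$mode == "standard") {
    setting$shape <- shape_transform("standard",
      sigma_shp = g("sigma_shp", shp$sigma_shp),
      tilt_deg = g("shape_tilt", shp$tilt_deg),
      tilt_azimuth_deg = g("shape_tilt_az", shp$tilt_azimuth_deg))
  } else {
    sig <- vapply(1:3, function(i) g(paste0("shp_sig", i), shp$sigmas[i]), 0)
    eul <- vapply(1:3, function(i) g(paste0("shp_eul", i), shp$euler_deg[i]), 0)
    setting$shape <- shape_transform("aniso", sigmas = sig, euler_deg = eul)
  }
  tl <- setting$tilt
  n <- length(tl$omega_angles_deg)
  if (n > 1) {
    for (i in 2:n) {
      tl$scale_corrections[i] <- g(paste0("scale_corr_", i), tl$scale_corrections[i])
      tl$omega_corrections[i] <- g(paste0("omega_corr_", i), tl$omega_corrections[i])
    }
    setting$tilt <- tl
  }
  setting
}

# fixed-layout residual vector over all images
.fit_residuals <- function(setting, spots_list, refl, r_a_list, mask = NULL) {
  ctl <- setting$control
  res <- numeric(0)
  for (img in seq_along(spots_list)) {
    spots <- spots_list[[img]]
    preds <- predict_spots(setting, refl = refl, image_index = img)
    asn <- suppressWarnings(
      assign_predictions(preds, spots, r_a_list[[img]], mask))
    merged <- merge_assigned(asn, preds)
    if (ctl$target == "I") {
      ri <- (merged$I_clc - spots$I) * spots$I^(-0.25)
    } else {
      ri <- sqrt(pmax(merged$I_clc, 0)) - sqrt(spots$I)
    }
    res <- c(res, ri)
    if (ctl$pos_weight > 0) {
      dx <- ifelse(merged$matched, merged$x_clc - spots$x, r_a_list[[img]])
      dy <- ifelse(merged$matched, merged$y_clc - spots$y, 0)
      res <- c(res, sqrt(ctl$pos_weight) * c(dx, dy))
    }
    if (ctl$fpred_weight > 0) {
      nh <- asn$nohits
      Snh <- if (!length(nh)) 0
        else if (ctl$target == "I") sum(preds$I[nh]^2) else sum(preds$I[nh])
      res <- c(res, sqrt(ctl$fpred_weight * Snh))
    }
  }
  res
}

#' Nonlinear least-squares refinement of a setting (GeoFit)
#'
#' Minimizes the combined intensity-plus-position cost over the selected
#' free parameters by bounded Levenberg-Marquardt least squares
#' (`minpack.lm::nls.lm`).  Frozen parameters are returned bit-identical;
#' sigma-type parameters are kept non-negative and the scale positive by
#' box constraints.  Ambit assignments are recomputed at every residual
#' evaluation.
#'
#' @param setting Starting [ued_setting()].
#' @param spots Reduced data: one table, or a list of tables for a tilt
#'   series.
#' @param structure `crystal_structure` (or pass `refl`).
#' @param refl Optional pre-enumerated reflection table.
#' @param fit Character vector of parameter names to free; see Details.
#' @param mask Optional [detector_mask()].
#' @param max_iter Maximum optimizer iterations.
#' @param balance_pos_weight If `TRUE`, the position weight w_P is set so
#'   that the position part of the cost equals the intensity part at the
#'   starting setting (self-scaling; the sub-ambit position information
#'   is otherwise invisible to the intensity-only cost).
#' @details Fittable names: `magnification`, `beam_center_x/y`,
#'   `image_rotation` (multi-image projects only), `distortion_eps`,
#'   `distortion_phi0`, `theta`, `phi`, `psi`, `scale`, `b_factor`,
#'   `sigma_mos` (or `mos_sig1..3`, `mos_eul1..3`), `sigma_shp`,
#'   `shape_tilt`, `shape_tilt_az` (or `shp_sig1..3`, `shp_eul1..3`),
#'   and `scale_corr_i` / `omega_corr_i` (i >= 2, multi-image, gated by
#'   the `k0_corr` / `omg_corr` control flags).  The tilt-axis direction
#'   is never fittable.
#' @return A `geofit_result`: settings and cost breakdowns before/after,
#'   quality metrics, convergence diagnostics, the final assignment and
#'   prediction tables (per image), and the free-parameter table.
#' @export
geofit <- function(setting, spots, structure = NULL, refl = NULL,
                   fit = c("theta", "phi", "psi"), mask = NULL,
                   max_iter = 200, balance_pos_weight = FALSE) {
  if (is.data.frame(spots)) spots <- list(spots)
  n_images <- length(spots)
  if (length(setting$tilt$omega_angles_deg) < n_images)
    stop("setting's tilt state has fewer images than the reduced data")
  if (is.null(refl)) {
    if (is.null(structure)) stop("give either refl or structure")
    refl <- generate_reflections(structure, setting$control$dmin,
                                 setting$control$dmax)
  }
  cat_tab <- .par_catalog(setting, n_images)
  bad <- setdiff(fit, cat_tab$name)
  if (length(bad))
    stop(sprintf("unknown or unavailable fit parameter(s): %s",
                 paste(bad, collapse = ", ")))
  if (n_images == 1 && "image_rotation" %in% fit)
    stop("image_rotation can only be fitted in a multi-image project")
  if (!setting$control$k0_corr && any(grepl("^scale_corr_", fit)))
    stop("scale corrections are gated by the k0_corr control flag")
  if (!setting$control$omg_corr && any(grepl("^omega_corr_", fit)))
    stop("omega corrections are gated by the omg_corr control flag")

  r_a_list <- lapply(spots, function(sp)
    setting$control$ambit %||% default_ambit_radius(sp))

  score <- function(stg) {
    S <- 0
    parts <- vector("list", n_images)
    for (img in seq_len(n_images)) {
      preds <- predict_spots(stg, refl = refl, image_index = img)
      asn <- suppressWarnings(
        assign_predictions(preds, spots[[img]], r_a_list[[img]], mask))
      merged <- merge_assigned(asn, preds)
      cb <- cost_function(merged, spots[[img]], asn, preds, stg$control)
      S <- S + cb$S_total
      parts[[img]] <- list(preds = preds, assignment = asn,
                           merged = merged, cost = cb)
    }
    list(S = S, parts = parts)
  }
  before <- score(setting)
  if (!any(vapply(before$parts, function(p) any(p$merged$matched), TRUE)))
    stop("starting setting matches no observed spot; refine the orientation first")
  if (balance_pos_weight) {
    SI <- sum(vapply(before$parts, function(p) p$cost$S_I_hits, 0))
    SP <- sum(vapply(before$parts, function(p) p$cost$S_P, 0))
    setting$control$pos_weight <- SI / max(SP, 1e-12)
    before <- score(setting)
  }

  result_info <- list(niter = 0L, message = "no free parameters",
                      converged = TRUE)
  setting_after <- setting
  if (length(fit)) {
    p0 <- stats::setNames(cat_tab[fit, "value"], fit)
    fn <- function(p) {
      names(p) <- fit
      .fit_residuals(.apply_params(setting, p), spots, refl, r_a_list, mask)
    }
    ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter,
                                       ftol = 1e-10, ptol = 1e-10)
    lm <- minpack.lm::nls.lm(par = p0, fn = fn,
                             lower = cat_tab[fit, "lower"],
                             upper = cat_tab[fit, "upper"], control = ctrl)
    pa <- stats::setNames(as.numeric(lm$par), fit)
    cand <- .apply_params(setting, pa)
    result_info <- list(niter = lm$niter, message = lm$message,
                        converged = lm$info %in% 1:4)
    after_score <- score(cand)
    if (after_score$S <= before$S + 1e-12) {
      setting_after <- cand
    } else {
      result_info$message <- paste(result_info$message,
                                   "(no improvement; kept starting values)")
    }
  }
  after <- score(setting_after)
  merged_all <- do.call(rbind, lapply(after$parts, `[[`, "merged"))
  spots_all <- do.call(rbind, spots)
  structure(list(setting_before = setting, setting_after = setting_after,
                 fit = fit,
                 par_before = stats::setNames(cat_tab[fit, "value"], fit),
                 par_after = stats::setNames(
                   vapply(fit, function(nm) .par_catalog(setting_after, n_images)[nm, "value"], 0), fit),
                 S_before = before$S, S_after = after$S,
                 cost = lapply(after$parts, `[[`, "cost"),
                 metrics = quality_metrics(merged_all, spots_all),
                 parts = after$parts,
                 spots = spots,
                 convergence = result_info),
            class = "geofit_result")
}

#' @export
print.geofit_result <- function(x, ...) {
  cat(sprintf("GeoFit: S %.6g -> %.6g in %d iteration(s); R_I = %.4f, matched %.0f%%\n",
              x$S_before, x$S_after, x$convergence$niter,
              x$metrics$R_I, 100 * x$metrics$matched_fraction))
  if (length(x$fit)) {
    tab <- data.frame(before = x$par_before, after = x$par_after)
    print(tab)
  }
  invisible(x)
}

#' Per-spot reflection decomposition
#'
#' For every observed spot (sorted by descending observed intensity):
#' the up-to-five strongest contributing reflections, strongest first,
#' with their Laue indices, intensities and excitation errors, plus a
#' sixth "remainder" aggregate when more reflections contribute.  The
#' listed contributions plus the remainder always sum to the spot's
#' calculated intensity.
#'
#' @param fitres A [geofit()] result.
#' @param image_index Image of the tilt series to report.
#' @param max_contrib Number of individual contributions to list.
#' @return `data.frame` in long format: one row per contribution
#'   (`rank = "remainder"` rows aggregate the rest), with per-spot
#'   columns `spot_id, x_obs, y_obs, I_obs, x_clc, y_clc, I_clc`.
#' @export
per_spot_report <- function(fitres, image_index = 1L, max_contrib = 5L) {
  part <- fitres$parts[[image_index]]
  spots <- fitres$spots[[image_index]]
  preds <- part$preds; asn <- part$assignment; merged <- part$merged
  ord <- order(-spots$I)
  rows <- list()
  for (io in ord) {
    j <- asn$J[[io]]
    base <- data.frame(spot_id = spots$id[io],
                       x_obs = spots$x[io], y_obs = spots$y[io],
                       I_obs = spots$I[io],
                       x_clc = merged$x_clc[io], y_clc = merged$y_clc[io],
                       I_clc = merged$I_clc[io], stringsAsFactors = FALSE)
    if (!length(j)) {
      rows[[length(rows) + 1]] <- cbind(base, rank = NA_integer_,
        h = NA_integer_, k = NA_integer_, l = NA_integer_,
        I_contrib = 0, e_mos = NA_real_, e_shp = NA_real_)
      next
    }
    j <- j[order(-preds$I[j])]
    top <- utils::head(j, max_contrib)
    tab <- cbind(base[rep(1, length(top)), , drop = FALSE],
                 rank = seq_along(top),
                 h = preds$h[top], k = preds$k[top], l = preds$l[top],
                 I_contrib = preds$I[top],
                 e_mos = preds$e_mos[top], e_shp = preds$e_shp[top])
    if (length(j) > length(top)) {
      rest <- setdiff(j, top)
      tab <- rbind(tab, cbind(base, rank = length(top) + 1L,
        h = NA_integer_, k = NA_integer_, l = NA_integer_,
        I_contrib = sum(preds$I[rest]),
        e_mos = NA_real_, e_shp = NA_real_))
    }
    rows[[length(rows) + 1]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Index a pattern end to end: grid scan plus refinement
#'
#' Convenience workflow: score beam directions on the SO(3) grid
#' ([gridscan()]), seed a setting from the best orientation, and refine
#' orientation, isotropic mosaic width and scale by [geofit()] with the
#' square-root intensity target and a self-balanced position weight (the
#' combination that makes sub-ambit position information effective).
#'
#' @param setting Starting [ued_setting()] (its orientation is ignored).
#' @param spots Reduced-data table.
#' @param structure `crystal_structure` (or pass `refl`).
#' @param refl Optional pre-enumerated reflection table.
#' @param grid SO(3) grid ([build_grid()]); default nside 16 is a coarse
#'   locator, sufficient when followed by refinement.
#' @param n_directions Beam directions to visit.
#' @param fit Parameters to refine after the scan.
#' @param mask Optional [detector_mask()].
#' @return The [geofit()] result, with the FOM map in `$fom_map`.
#' @export
index_pattern <- function(setting, spots, structure = NULL, refl = NULL,
                          grid = build_grid(16), n_directions = grid$n_directions,
                          fit = c("theta", "phi", "psi", "sigma_mos", "scale"),
                          mask = NULL) {
  if (is.null(refl)) {
    if (is.null(structure)) stop("give either refl or structure")
    refl <- generate_reflections(structure, setting$control$dmin,
                                 setting$control$dmax)
  }
  map <- gridscan(setting, spots, refl = refl, grid = grid,
                  n_directions = n_directions, mask = mask)
  top <- top_orientations(map, 1, min_sep = 0)
  st <- setting
  st$orientation <- c(top$theta[1], top$phi[1], top$psi[1])
  st$control$target <- "sqrt(I)"
  res <- geofit(st, spots, refl = refl, fit = fit, mask = mask,
                balance_pos_weight = TRUE)
  res$fom_map <- map
  res
}
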