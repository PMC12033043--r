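# GridScan: exhaustive orientation search over SO(3), parameterized as
# HEALPix beam directions (Theta, Phi) x in-plane rotations Psi.  For a
# fixed beam direction the excitation errors -- hence the predicted
# intensities -- are independent of Psi (rotation about the beam), so
# each direction is scored by a fast azimuthal sweep: every
# (prediction, spot) pair contributes over a contiguous Psi window.

#' Build the SO(3) orientation grid
#'
#' @param nside HEALPix resolution parameter (power of 2); the default 64
#'   yields 49152 beam directions at 0.92 degree resolution.
#' @param psi_step Psi sampling step in degrees (must divide 360).
#' @return An `so3_grid`: pixel-center directions (ring scheme), the
#'   hierarchical coarse-to-fine visit order, and the Psi step.
#' @export
build_grid <- function(nside = 64, psi_step = 1) {
  nside <- .check_nside(nside)
  if (360 %% psi_step != 0) stop("psi_step must divide 360")
  ang <- healpix_pix2ang(nside)
  structure(list(nside = nside,
                 n_directions = healpix_npix(nside),
                 theta = acos(pmax(-1, pmin(1, ang[, "z"]))) / .deg,
                 phi = ang[, "phi"] / .deg,
                 psi_step = psi_step,
                 visit_order = healpix_visit_order(nside)),
            class = "so3_grid")
}

#' @export
print.so3_grid <- function(x, ...) {
  cat(sprintf("SO(3) grid: nside %d -> %d directions x %d psi steps = %d orientations\n",
              x$nside, x$n_directions, 360 %/% x$psi_step,
              x$n_directions * (360 %/% x$psi_step)))
  invisible(x)
}

# resolution of an observed spot from its detector radius
.spot_resolution <- function(spots, geom) {
  dx <- (spots$x - geom$beam_center[1]) * geom$pixel_size_mm
  dy <- (spots$y - geom$beam_center[2]) * geom$pixel_size_mm
  r <- sqrt(dx^2 + dy^2)
  tth <- atan2(r, geom$camera_length_mm)
  h <- 2 * sin(tth / 2) / geom$wavelength
  ifelse(h > 0, 1 / h, Inf)
}

#' Grid scan over crystal orientations
#'
#' Evaluates, for each visited beam direction, the maximum figure of
#' merit over all Psi rotations, using the active setting's parameters
#' except the orientation and the resolution range.  The scan is
#' deterministic, interruptible (stop at `n_directions`) and resumable
#' (`resume` a previous map); results are independent of chunking.
#'
#' The elliptical distortion correction is ignored during scanning (it
#' shifts radii by well under an ambit radius); the full model is
#' applied in the subsequent least-squares refinement.
#'
#' @param setting Active [ued_setting()].
#' @param spots Reduced data of the scanned image.
#' @param structure `crystal_structure` (or pass a pre-enumerated `refl`).
#' @param refl Optional reflection table (overrides `structure`).
#' @param grid An [build_grid()] result.
#' @param n_directions Number of beam directions to visit (hierarchical
#'   order), up to `grid$n_directions`.
#' @param dmin,dmax Resolution range for the scan (overrides the
#'   setting).
#' @param mask Optional [detector_mask()] applied to the observed spots.
#' @param image_index Image of a tilt series to scan.
#' @param resume A previous `fom_map` to extend.
#' @return A `fom_map` data.frame: `pix, theta, phi, fom, psi` for each
#'   visited direction (visit order), with the grid spec in attributes.
#' @export
gridscan <- function(setting, spots, structure = NULL, refl = NULL,
                     grid = build_grid(64), n_directions = grid$n_directions,
                     dmin = setting$control$dmin, dmax = setting$control$dmax,
                     mask = NULL, image_index = 1L, resume = NULL) {
  if (is.null(refl)) {
    if (is.null(structure)) stop("give either refl or structure")
    refl <- generate_reflections(structure, dmin, dmax)
  }
  geom <- setting_geometry(setting)
  if (!is.null(mask)) spots <- spots[!mask_contains(mask, spots$x, spots$y), , drop = FALSE]
  dres <- .spot_resolution(spots, geom)
  spots <- spots[dres >= dmin & dres <= dmax, , drop = FALSE]
  if (nrow(spots) == 0) stop("no observed spots in the resolution range")

  r_a_px <- setting$control$ambit %||% default_ambit_radius(spots)
  if (nrow(spots) >= 2) r_a_px <- min(r_a_px, default_ambit_radius(spots))

  # observation geometry in mm about the beam center
  ox <- (spots$x - geom$beam_center[1]) * geom$pixel_size_mm
  oy <- (spots$y - geom$beam_center[2]) * geom$pixel_size_mm
  r_o <- sqrt(ox^2 + oy^2)
  az_o <- atan2(oy, ox)
  r_a <- r_a_px * geom$pixel_size_mm
  I_obs <- spots$I
  sum_obs <- sum(I_obs)

  geom0 <- geom; geom0$distortion <- c(0, 0)   # scan without distortion
  npsi <- 360L %/% as.integer(grid$psi_step)
  psis <- (seq_len(npsi) - 1L) * grid$psi_step

  n_directions <- min(n_directions, grid$n_directions)
  done <- if (is.null(resume)) integer(0) else resume$pix
  todo <- setdiff(grid$visit_order[seq_len(n_directions)], done)

  fom_v <- numeric(length(todo)); psi_v <- numeric(length(todo))
  setting0 <- setting
  for (ii in seq_along(todo)) {
    p <- todo[ii]
    th <- grid$theta[p + 1]; ph <- grid$phi[p + 1]
    setting0$orientation <- c(th, ph, 0)
    preds <- predict_spots(.strip_distortion(setting0), refl = refl,
                           image_index = image_index)
    totI <- sum(preds$I)
    if (!nrow(preds) || totI <= 0) { fom_v[ii] <- 0; psi_v[ii] <- 0; next }
    # negligible predictions cannot move the FOM; keep the exact denominator
    preds <- preds[preds$I >= 1e-5 * totI, , drop = FALSE]
    sc <- .psi_sweep(preds, geom0, r_o, az_o, I_obs, r_a, npsi, grid$psi_step)
    denom <- sqrt(totI * sum_obs)
    f <- sc / denom
    j <- which.max(f)
    fom_v[ii] <- f[j]; psi_v[ii] <- psis[j]
  }
  new <- data.frame(pix = todo,
                    theta = grid$theta[todo + 1], phi = grid$phi[todo + 1],
                    fom = fom_v, psi = psi_v)
  out <- if (is.null(resume)) new else rbind(resume, new)
  attr(out, "grid") <- list(nside = grid$nside, psi_step = grid$psi_step)
  attr(out, "r_a_px") <- r_a_px
  attr(out, "n_spots_used") <- nrow(spots)
  class(out) <- c("fom_map", class(out))
  out
}

.strip_distortion <- function(setting) {
  setting$distortion <- c(0, 0)
  setting
}

# azimuthal sweep: for each psi bin, sum_io sqrt(I_obs * sum of matched
# prediction intensities); returns the numerator vector over psi bins.
# A (prediction, spot) pair matches over a contiguous psi window whose
# half-width follows from the circle-circle overlap of their radii.
.psi_sweep <- function(preds, geom, r_o, az_o, I_obs, r_a, npsi, psi_step) {
  px <- (preds$x - geom$beam_center[1]) * geom$pixel_size_mm
  py <- (preds$y - geom$beam_center[2]) * geom$pixel_size_mm
  r_p <- sqrt(px^2 + py^2)
  az_p <- atan2(py, px)
  Ip <- preds$I
  nobs <- length(r_o); npred <- length(r_p)
  two_pi <- 2 * pi
  RR <- 2 * outer(r_o, r_p)
  cmin <- (outer(r_o^2, r_p^2, "+") - r_a^2) / RR        # nobs x npred
  # degenerate concentric pairs: all-psi match iff radii differ by < r_a
  if (any(degen <- RR == 0))
    cmin[degen] <- c(Inf, -Inf)[(abs(outer(r_o, r_p, "-"))[degen] < r_a) + 1L]

  idx <- which(cmin < 1)
  acc <- matrix(0, nobs, npsi)
  if (!length(idx)) return(colSums(sqrt(acc * I_obs)))
  io <- (idx - 1L) %% nobs + 1L
  jp <- (idx - 1L) %/% nobs + 1L
  cm <- cmin[idx]

  addup <- function(li, vals) {         # acc[li] += vals with duplicates
    o <- order(li)
    ls <- li[o]
    cs <- cumsum(vals[o])
    last <- c(ls[-1] != ls[-length(ls)], TRUE)
    acc[ls[last]] <<- acc[ls[last]] + diff(c(0, cs[last]))
  }
  full <- cm <= -1
  if (any(full)) {
    base <- numeric(nobs)
    bi <- io[full]
    o <- order(bi); bs <- bi[o]; cs <- cumsum(Ip[jp[full]][o])
    last <- c(bs[-1] != bs[-length(bs)], TRUE)
    base[bs[last]] <- diff(c(0, cs[last]))
    acc <- acc + base                    # recycles down columns
  }
  part <- which(!full)
  if (length(part)) {
    iop <- io[part]; jpp <- jp[part]
    half <- acos(cm[part])
    # crystal rotation by psi rotates the pattern by -psi about the beam
    ctr <- (az_p[jpp] - az_o[iop]) %% two_pi
    lo <- (ctr - half) / two_pi * npsi
    hi <- (ctr + half) / two_pi * npsi
    b0 <- ceiling(lo); b1 <- floor(hi)
    lens <- pmax(0L, as.integer(b1 - b0 + 1))
    keep <- lens > 0L
    if (any(keep)) {
      lens <- lens[keep]
      bins <- (rep.int(as.integer(b0[keep]), lens) + sequence(lens) - 1L) %% npsi
      li <- bins * nobs + rep.int(iop[keep], lens)       # 1-based linear index
      addup(li, rep.int(Ip[jpp[keep]], lens))
    }
  }
  colSums(sqrt(acc * I_obs))
}

#' Best grid orientations with angular separation
#'
#' Greedy selection by descending FOM, skipping beam directions within
#' `min_sep` degrees of an already selected one.  Inversion mates
#' (centrosymmetric ambiguity of kinematic intensities) are not
#' deduplicated; both hemispheres are reported.
#'
#' @param map A `fom_map` from [gridscan()].
#' @param n Number of orientations to export.
#' @param min_sep Minimum angular separation in degrees (default 12).
#' @return `data.frame` with `theta, phi, psi, fom`, best first.
#' @export
top_orientations <- function(map, n = 10, min_sep = 12) {
  if (!nrow(map)) stop("empty FOM map")
  ord <- order(-map$fom)
  th <- map$theta * .deg; ph <- map$phi * .deg
  vx <- sin(th) * cos(ph); vy <- sin(th) * sin(ph); vz <- cos(th)
  sel <- integer(0)
  cmin <- cos(min_sep * .deg)
  for (i in ord) {
    if (length(sel) >= n) break
    if (length(sel) && min_sep > 0) {
      dots <- vx[i] * vx[sel] + vy[i] * vy[sel] + vz[i] * vz[sel]
      if (any(dots > cmin)) next
    }
    sel <- c(sel, i)
  }
  out <- data.frame(theta = map$theta[sel], phi = map$phi[sel],
                    psi = map$psi[sel], fom = map$fom[sel])
  rownames(out) <- NULL
  out
}

#' Write / read a grid-scan checkpoint
#'
#' Key-value header (grid spec) plus the visited-direction table, as
#' plain text; [gridscan()] can resume from the returned map.
#'
#' @param map A `fom_map`.
#' @param path Checkpoint file path.
#' @export
write_checkpoint <- function(map, path) {
  g <- attr(map, "grid")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# nside\t%d", g$nside),
               sprintf("# psi_step\t%g", g$psi_step),
               sprintf("# r_a_px\t%.10g", attr(map, "r_a_px") %||% NA)), con)
  utils::write.table(as.data.frame(map), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @param path Checkpoint file path.
#' @return `read_checkpoint`: the restored `fom_map`.
#' @export
read_checkpoint <- function(path) {
  hdr <- readLines(path, n = 3)
  gv <- function(i) strsplit(hdr[i], "\t")[[1]][2]
  map <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  attr(map, "grid") <- list(nside = as.integer(gv(1)), psi_step = as.numeric(gv(2)))
  attr(map, "r_a_px") <- as.numeric(gv(3))
  class(map) <- c("fom_map", class(map))
  map
}
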