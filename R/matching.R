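# Ambit assignment, merging of predictions, cost function and quality
# metrics.  Each observed spot owns a disjoint circular neighborhood
# ("ambit") of radius r_a; predictions landing strictly inside an ambit
# are attributed to that spot, all others are "no-hits".

#' Default ambit radius
#'
#' The maximum radius with no overlapping ambits: half the minimum
#' pairwise distance between observed spot centers.
#'
#' @param spots Reduced-data table with columns `x`, `y` (pixels).
#' @return Radius in pixels.
#' @export
default_ambit_radius <- function(spots) {
  n <- nrow(spots)
  if (n < 2)
    stop("fewer than two spots: set the ambit radius explicitly")
  ## O(n^2) over spot pairs is fine at reduced-data sizes (<= a few 100)
  d2min <- Inf
  xy <- cbind(spots$x, spots$y)
  for (i in seq_len(n - 1)) {
    dx <- xy[(i + 1):n, 1] - xy[i, 1]
    dy <- xy[(i + 1):n, 2] - xy[i, 2]
    d2min <- min(d2min, min(dx * dx + dy * dy))
  }
  sqrt(d2min) / 2
}

#' Assign predictions to observed-spot ambits
#'
#' Membership is strict (`distance < r_a`).  A user radius larger than
#' the non-overlap maximum is clipped down with a warning, keeping the
#' ambits disjoint so that every prediction belongs to at most one spot.
#' Predictions whose centers fall in a masked detector region are
#' discarded before assignment.
#'
#' @param preds Prediction table (columns `x`, `y`, `I`).
#' @param spots Reduced-data table (columns `x`, `y`).
#' @param r_a Ambit radius in pixels; default from
#'   [default_ambit_radius()].
#' @param mask Optional detector mask (see [detector_mask()]).
#' @return An `ambit_assignment`: list with `J` (per-spot integer vectors
#'   of prediction row indices), `nohits`, `masked` (discarded prediction
#'   rows), and the effective `r_a`.
#' @export
assign_predictions <- function(preds, spots, r_a = NULL, mask = NULL) {
  if (nrow(spots) >= 2) {
    rmax <- default_ambit_radius(spots)
    if (is.null(r_a)) r_a <- rmax
    else if (r_a > rmax + 1e-12) {
      warning(sprintf("ambit radius %.3g overlaps; clipped to %.3g px", r_a, rmax))
      r_a <- rmax
    }
  } else if (is.null(r_a)) {
    stop("fewer than two spots: set the ambit radius explicitly")
  }
  keep <- seq_len(nrow(preds))
  masked <- integer(0)
  if (!is.null(mask) && nrow(preds)) {
    inm <- mask_contains(mask, preds$x, preds$y)
    masked <- keep[inm]
    keep <- keep[!inm]
  }
  J <- vector("list", nrow(spots))
  assigned <- rep(FALSE, length(keep))
  if (length(keep) && nrow(spots)) {
    px <- preds$x[keep]; py <- preds$y[keep]
    for (io in seq_len(nrow(spots))) {
      d2 <- (px - spots$x[io])^2 + (py - spots$y[io])^2
      hit <- d2 < r_a^2                 # strict inequality
      J[[io]] <- keep[hit]
      assigned <- assigned | hit
    }
  }
  structure(list(J = J, nohits = keep[!assigned], masked = masked,
                 r_a = r_a),
            class = "ambit_assignment")
}

#' Merge assigned predictions per spot
#'
#' Intensity sum and intensity-weighted centroid of the predictions in
#' each spot's ambit.  Spots with an empty ambit (or zero total
#' intensity) are flagged unmatched.
#'
#' @param assignment An [assign_predictions()] result.
#' @param preds The prediction table the assignment refers to.
#' @return `data.frame` with `I_clc, x_clc, y_clc, n_contrib, matched`.
#' @export
merge_assigned <- function(assignment, preds) {
  n <- length(assignment$J)
  I_clc <- x_clc <- y_clc <- numeric(n)
  matched <- logical(n)
  n_contrib <- integer(n)
  for (io in seq_len(n)) {
    j <- assignment$J[[io]]
    n_contrib[io] <- length(j)
    if (!length(j)) next
    Ij <- preds$I[j]
    I_clc[io] <- sum(Ij)
    if (I_clc[io] > 0) {
      x_clc[io] <- sum(preds$x[j] * Ij) / I_clc[io]
      y_clc[io] <- sum(preds$y[j] * Ij) / I_clc[io]
      matched[io] <- TRUE
    }
  }
  x_clc[!matched] <- NA_real_
  y_clc[!matched] <- NA_real_
  data.frame(I_clc = I_clc, x_clc = x_clc, y_clc = y_clc,
             n_contrib = n_contrib, matched = matched)
}

#' Cost function of a prediction against the reduced data
#'
#' `S = S(I,hits) + w2 * S(I,nohits) + wP * S(P)` with
#' * `S(I,hits)`: summed over all observed spots; for `target = "I"`
#'   weighted squared intensity residuals with `w_io = I_obs^(-1/2)`, for
#'   `target = "sqrt(I)"` squared residuals of the intensity square
#'   roots (unmatched spots enter with `I_clc = 0`);
#' * `S(I,nohits)`: predictions outside all ambits, fitted toward zero
#'   (`sum I^2` resp. `sum I`);
#' * `S(P)`: squared centroid distances, `r_a^2` for unmatched spots.
#'
#' @param merged Result of [merge_assigned()].
#' @param spots Reduced-data table (columns `x`, `y`, `I`).
#' @param assignment The [assign_predictions()] result.
#' @param preds Prediction table (for the no-hit term).
#' @param control A [control_params()] (uses `target`, `pos_weight`,
#'   `fpred_weight`).
#' @return A `cost_breakdown` list: `S_I_hits, S_I_nohits, S_P, S_total`,
#'   per-spot residual table, and the control echo.
#' @export
cost_function <- function(merged, spots, assignment, preds, control) {
  target <- control$target
  I_obs <- spots$I
  I_clc <- merged$I_clc
  if (target == "I") {
    w <- I_obs^(-0.5)
    res_I <- sqrt(w) * (I_clc - I_obs)
  } else {
    res_I <- sqrt(I_clc) - sqrt(I_obs)
  }
  S_I_hits <- sum(res_I^2)
  nh <- assignment$nohits
  S_I_nohits <- if (!length(nh)) 0
    else if (target == "I") sum(preds$I[nh]^2) else sum(preds$I[nh])
  d2 <- ifelse(merged$matched,
               (merged$x_clc - spots$x)^2 + (merged$y_clc - spots$y)^2,
               assignment$r_a^2)
  S_P <- sum(d2)
  S_total <- S_I_hits + control$fpred_weight * S_I_nohits +
    control$pos_weight * S_P
  structure(list(S_I_hits = S_I_hits, S_I_nohits = S_I_nohits,
                 S_P = S_P, S_total = S_total,
                 residuals = data.frame(res_I = res_I, d2 = d2,
                                        matched = merged$matched),
                 control = list(target = target,
                                pos_weight = control$pos_weight,
                                fpred_weight = control$fpred_weight)),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("cost: S_total = %.6g  (I,hits %.6g | I,nohits %.6g | P %.6g; wP=%g w2=%g target=%s)\n",
              x$S_total, x$S_I_hits, x$S_I_nohits, x$S_P,
              x$control$pos_weight, x$control$fpred_weight, x$control$target))
  invisible(x)
}

#' Crystallographic agreement metrics
#'
#' Linear-scale R factors: `R_I = sum |k I_clc - I_obs| / sum I_obs` with
#' `k` the least-squares scale, `R_sqrtI` the analogue on square roots,
#' and the matched-spot fraction.  These conventional definitions are
#' used for all reports.
#'
#' @param merged Result of [merge_assigned()].
#' @param spots Reduced-data table.
#' @return List `R_I, R_sqrtI, matched_fraction` (metrics are `NA` with a
#'   `reason` attribute when no spot is matched).
#' @export
quality_metrics <- function(merged, spots) {
  m <- merged$matched
  mf <- mean(m)
  if (!any(m)) {
    out <- list(R_I = NA_real_, R_sqrtI = NA_real_, matched_fraction = 0)
    attr(out, "reason") <- "no matched spots"
    return(out)
  }
  Ic <- merged$I_clc[m]; Io <- spots$I[m]
  k1 <- sum(Ic * Io) / sum(Ic^2)
  R_I <- sum(abs(k1 * Ic - Io)) / sum(Io)
  sc <- sqrt(Ic); so <- sqrt(Io)
  k2 <- sum(sc * so) / sum(sc^2)
  R_sqrtI <- sum(abs(k2 * sc - so)) / sum(so)
  list(R_I = R_I, R_sqrtI = R_sqrtI, matched_fraction = mf)
}

#' Figure of merit of a predicted pattern
#'
#' Normalized square-root overlap between matched predicted and observed
#' intensities,
#' `FOM = sum_io sqrt(I_clc,io * I_obs,io) / sqrt(sum_all I_clc * sum_io I_obs)`.
#' It is 1 exactly when predictions are proportional to observations with
#' nothing predicted outside the ambits, 0 when nothing matches, and is
#' invariant under rescaling of either side.
#'
#' @param preds Prediction table (`x`, `y`, `I`).
#' @param spots Reduced-data table (`x`, `y`, `I`).
#' @param r_a Ambit radius (default: non-overlap maximum).
#' @param mask Optional detector mask.
#' @return FOM in \[0, 1\].
#' @export
fom <- function(preds, spots, r_a = NULL, mask = NULL) {
  if (!nrow(preds)) return(0)
  asn <- assign_predictions(preds, spots, r_a, mask)
  merged <- merge_assigned(asn, preds)
  tot_clc <- sum(preds$I[setdiff(seq_len(nrow(preds)), asn$masked)])
  if (tot_clc <= 0) return(0)
  sum(sqrt(merged$I_clc * spots$I)) / sqrt(tot_clc * sum(spots$I))
}
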