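#' Construct a unit cell
#'
#' Builds a `unit_cell` object from cell lengths (Angstrom) and angles
#' (degrees), including the real-space basis matrix, the crystallographic
#' reciprocal basis (no 2*pi factor) and the cell volume.
#'
#' The real basis follows the standard crystallographic convention: `a`
#' along x, `b` in the xy plane.  Rows of `real_basis` are the basis
#' vectors; rows of `recip_basis` are a*, b*, c* and satisfy
#' `real_basis %*% t(recip_basis) == diag(3)`.
#'
#' @param a,b,c Cell lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return An object of class `unit_cell` with fields `a, b, c, alpha,
#'   beta, gamma, real_basis, recip_basis, volume`.
#' @examples
#' cell <- unit_cell(10, 10, 10)
#' cell$volume           # 1000
#' d_spacing(cell, c(1, 1, 0))
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  # c-vector z component from the metric
  cz2 <- 1 - cb^2 - ((ca - cb * cg) / sg)^2
  if (cz2 <= 0) stop("degenerate cell: angles are metrically inconsistent")
  real_basis <- rbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(c * cb, c * (ca - cb * cg) / sg, c * sqrt(cz2)))
  rownames(real_basis) <- c("a", "b", "c")
  vol <- det(real_basis)
  if (vol <= 1e-9) stop("degenerate cell: volume is not positive")
  recip_basis <- t(solve(real_basis))
  rownames(recip_basis) <- c("a*", "b*", "c*")
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 real_basis = real_basis, recip_basis = recip_basis,
                 volume = vol),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.4g b=%.4g c=%.4g A  alpha=%.4g beta=%.4g gamma=%.4g deg  V=%.6g A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Reciprocal basis of a unit cell
#'
#' @param cell A `unit_cell`.
#' @return 3x3 matrix whose rows are a*, b*, c* in 1/Angstrom.
#' @export
reciprocal_basis <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  cell$recip_basis
}

#' Resolution (d-spacing) of a reflection
#'
#' `d = 1 / |h a* + k b* + l c*|`.
#'
#' @param cell A `unit_cell`.
#' @param hkl Integer triple (or n x 3 matrix of triples).
#' @return d-spacing(s) in Angstrom.
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  hkl <- rbind(hkl)
  if (any(rowSums(hkl != 0) == 0)) stop("d-spacing undefined for (0,0,0)")
  hvec <- hkl %*% cell$recip_basis
  d <- 1 / sqrt(rowSums(hvec^2))
  if (length(d) == 1L) d <- d[[1]]
  d
}

#' Squared structure-factor magnitude |F(hkl)|^2
#'
#' Kinematical structure factor over the symmetry-expanded site list,
#' `F = sum_sites occ * f(s) * exp(-B_iso s^2) * exp(2 pi i hkl . xyz)`,
#' with `s = 1/(2 d)`.  Scattering amplitudes come from the bundled
#' electron form-factor table.
#'
#' @param structure A `crystal_structure` (see [parse_cif()]).
#' @param hkl Integer triple or n x 3 matrix.
#' @return |F|^2 value(s), arbitrary consistent units (Angstrom^2 per cell).
#' @export
structure_factor_sq <- function(structure, hkl) {
  stopifnot(inherits(structure, "crystal_structure"))
  hkl <- rbind(hkl)
  d <- d_spacing(structure$cell, hkl)
  s <- 1 / (2 * d)
  sites <- structure$sites
  frac <- as.matrix(sites[, c("x", "y", "z")])
  phase <- 2 * pi * (hkl %*% t(frac))          # n_hkl x n_sites
  # per-site, per-hkl amplitude: occ * f(s) * exp(-B s^2)
  amp <- matrix(0, nrow(hkl), nrow(sites))
  for (sym in unique(sites$symbol)) {
    idx <- which(sites$symbol == sym)
    fs <- electron_form_factor(sym, s)
    amp[, idx] <- fs * rep(sites$occupancy[idx], each = nrow(hkl))
  }
  amp <- amp * exp(-outer(s^2, sites$b_iso))
  re <- rowSums(amp * cos(phase))
  im <- rowSums(amp * sin(phase))
  F2 <- re^2 + im^2
  if (length(F2) == 1L) F2 <- F2[[1]]
  F2
}

#' Enumerate reflections in a resolution range
#'
#' All `hkl != (0,0,0)` with `dmin <= d <= dmax`, each carrying its
#' reciprocal vector (crystal frame), `|h| = 1/d`, d-spacing and |F|^2.
#' Ordering is deterministic: by increasing |h|, then lexicographic hkl.
#' Symmetry-equivalent reflections are never merged; every reciprocal
#' lattice point is predicted independently.
#'
#' @param structure A `crystal_structure`.
#' @param dmin,dmax Resolution range in Angstrom (`0 < dmin < dmax`).
#' @return A `data.frame` with columns `h, k, l, hx, hy, hz, h_len, d, F2`.
#' @export
generate_reflections <- function(structure, dmin, dmax = Inf) {
  stopifnot(inherits(structure, "crystal_structure"))
  if (!(dmin > 0)) stop("dmin must be positive")
  if (dmin >= dmax) stop("dmin must be smaller than dmax")
  B <- structure$cell$recip_basis
  hmax <- 1 / dmin
  # bounding box: |h_i| <= hmax / row spacing; use rows of real basis:
  # the max index along each axis is hmax * |a_i| (since h.a_i = integer)
  lim <- ceiling(hmax * c(structure$cell$a, structure$cell$b, structure$cell$c))
  grid <- as.matrix(expand.grid(h = -lim[1]:lim[1],
                                k = -lim[2]:lim[2],
                                l = -lim[3]:lim[3]))
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  hvec <- grid %*% B
  hlen <- sqrt(rowSums(hvec^2))
  keep <- hlen >= 1 / dmax & hlen <= 1 / dmin
  grid <- grid[keep, , drop = FALSE]
  hvec <- hvec[keep, , drop = FALSE]
  hlen <- hlen[keep]
  ord <- order(hlen, grid[, 1], grid[, 2], grid[, 3])
  grid <- grid[ord, , drop = FALSE]; hvec <- hvec[ord, , drop = FALSE]
  hlen <- hlen[ord]
  F2 <- if (nrow(grid)) structure_factor_sq(structure, grid) else numeric(0)
  out <- data.frame(h = grid[, 1], k = grid[, 2], l = grid[, 3],
                    hx = hvec[, 1], hy = hvec[, 2], hz = hvec[, 3],
                    h_len = hlen, d = 1 / hlen, F2 = as.numeric(F2))
  rownames(out) <- NULL
  out
}
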