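# HEALPix (Hierarchical Equal Area isoLatitude Pixelisation) of the sphere,
# ring and nested schemes, as needed for the SO(3) orientation grid.
# Implemented from the canonical construction: npix = 12 nside^2 equal-area
# pixels on iso-latitude rings; polar-cap ring i holds 4i pixels at
# z = 1 - i^2/(3 nside^2), the equatorial belt rings hold 4 nside pixels at
# z = 2/(3 nside) spacing.

#' Number of HEALPix pixels
#' @param nside Resolution parameter (power of 2).
#' @return `12 * nside^2`.
#' @export
healpix_npix <- function(nside) 12L * as.integer(nside)^2

.check_nside <- function(nside) {
  if (length(nside) != 1 || nside < 1 || bitwAnd(as.integer(nside), as.integer(nside) - 1L) != 0L)
    stop("nside must be a positive power of 2")
  as.integer(nside)
}

#' Pixel centers in the ring scheme
#'
#' @param nside Resolution parameter (power of 2).
#' @param pix 0-based ring-scheme pixel indices (default: all pixels).
#' @return Matrix with columns `z` (cos colatitude) and `phi` (radians).
#' @export
healpix_pix2ang <- function(nside, pix = seq_len(healpix_npix(nside)) - 1L) {
  nside <- .check_nside(nside)
  npix <- 12 * nside^2
  if (any(pix < 0 | pix >= npix)) stop("pixel index out of range")
  ncap <- 2 * nside * (nside - 1)
  fact2 <- 4 / npix
  fact1 <- 2 * nside * fact2
  z <- phi <- numeric(length(pix))

  north <- pix < ncap
  if (any(north)) {
    p <- pix[north]
    iring <- floor((1 + sqrt(1 + 2 * p + 1e-9)) / 2)
    iphi <- (p + 1) - 2 * iring * (iring - 1)
    z[north] <- 1 - iring^2 * fact2
    phi[north] <- (iphi - 0.5) * pi / (2 * iring)
  }
  eq <- !north & pix < npix - ncap
  if (any(eq)) {
    ip <- pix[eq] - ncap
    iring <- ip %/% (4 * nside) + nside
    iphi <- ip %% (4 * nside) + 1
    fodd <- ifelse((iring + nside) %% 2 == 1, 1, 0.5)
    z[eq] <- (2 * nside - iring) * fact1
    phi[eq] <- (iphi - fodd) * pi / (2 * nside)
  }
  south <- !north & !eq
  if (any(south)) {
    ip <- npix - pix[south]
    iring <- floor((1 + sqrt(2 * ip - 1 + 1e-9)) / 2)
    iphi <- 4 * iring + 1 - (ip - 2 * iring * (iring - 1))
    z[south] <- -1 + iring^2 * fact2
    phi[south] <- (iphi - 0.5) * pi / (2 * iring)
  }
  cbind(z = z, phi = phi %% (2 * pi))
}

#' Containing pixel of directions (ring scheme)
#'
#' @param nside Resolution parameter.
#' @param z Cosine of colatitude (vector).
#' @param phi Azimuth in radians (vector).
#' @return 0-based ring-scheme pixel indices.
#' @export
healpix_ang2pix <- function(nside, z, phi) {
  nside <- .check_nside(nside)
  npix <- 12 * nside^2
  ncap <- 2 * nside * (nside - 1)
  za <- abs(z)
  tt <- (phi %% (2 * pi)) * (2 / pi)         # in [0, 4)
  pix <- integer(length(z))

  eq <- za <= 2 / 3
  if (any(eq)) {
    temp1 <- nside * (0.5 + tt[eq])
    temp2 <- nside * (z[eq] * 0.75)
    jp <- floor(temp1 - temp2)
    jm <- floor(temp1 + temp2)
    ir <- nside + 1 + jp - jm
    kshift <- 1 - ir %% 2
    ip <- (jp + jm - nside + kshift + 1) %/% 2
    ip <- ip %% (4 * nside)
    pix[eq] <- ncap + (ir - 1) * 4 * nside + ip
  }
  if (any(!eq)) {
    ttc <- tt[!eq]
    tp <- ttc - floor(ttc)
    tmp <- nside * sqrt(3 * (1 - za[!eq]))
    jp <- floor(tp * tmp)
    jm <- floor((1 - tp) * tmp)
    ir <- jp + jm + 1
    ip <- floor(ttc * ir)
    ip <- ip %% (4 * ir)
    pix[!eq] <- ifelse(z[!eq] > 0,
                       2 * ir * (ir - 1) + ip,
                       npix - 2 * ir * (ir + 1) + ip)
  }
  as.integer(pix)
}

# ring-scheme index from nested face/x/y triplet (internal)
.nest_fxy_to_ring <- function(nside, f, x, y) {
  jrll <- c(2, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4)
  jpll <- c(1, 3, 5, 7, 0, 2, 4, 6, 1, 3, 5, 7)
  npix <- 12 * nside^2
  ncap <- 2 * nside * (nside - 1)
  jr <- jrll[f + 1] * nside - x - y - 1     # ring counted from north, 1-based
  nr <- integer(length(jr)); kshift <- integer(length(jr)); n_before <- numeric(length(jr))
  north <- jr < nside
  south <- jr > 3 * nside
  belt <- !north & !south
  nr[north] <- jr[north]
  kshift[north] <- 0
  n_before[north] <- 2 * nr[north] * (nr[north] - 1)
  nr[south] <- 4 * nside - jr[south]
  kshift[south] <- 0
  n_before[south] <- npix - 2 * nr[south] * (nr[south] + 1)
  nr[belt] <- nside
  kshift[belt] <- (jr[belt] - nside) %% 2
  n_before[belt] <- ncap + (jr[belt] - nside) * 4 * nside
  jp <- (jpll[f + 1] * nr + x - y + 1 + kshift) %/% 2
  jp <- ifelse(jp > 4 * nr, jp - 4 * nr, ifelse(jp < 1, jp + 4 * nr, jp))
  as.integer(n_before + jp - 1)
}

# de-interleave the 2k bits of w into (x, y) (internal)
.deinterleave <- function(w, k) {
  x <- integer(length(w)); y <- integer(length(w))
  for (b in 0:(k - 1)) {
    x <- x + bitwShiftL(bitwAnd(bitwShiftR(w, 2L * b), 1L), b)
    y <- y + bitwShiftL(bitwAnd(bitwShiftR(w, 2L * b + 1L), 1L), b)
  }
  list(x = x, y = y)
}

#' Nested-to-ring index conversion
#' @param nside Resolution parameter (power of 2).
#' @param pnest 0-based nested-scheme indices.
#' @return 0-based ring-scheme indices.
#' @export
healpix_nest2ring <- function(nside, pnest) {
  nside <- .check_nside(nside)
  f <- pnest %/% nside^2
  w <- pnest %% nside^2
  k <- as.integer(round(log2(nside)))
  if (k == 0) return(.nest_fxy_to_ring(nside, f, 0L, 0L))
  xy <- .deinterleave(as.integer(w), k)
  .nest_fxy_to_ring(nside, f, xy$x, xy$y)
}

# base-4 digit reversal of the k digit pairs (internal; visit order)
.digitrev4 <- function(w, k) {
  out <- integer(length(w))
  for (j in 0:(k - 1))
    out <- out + bitwShiftL(bitwAnd(bitwShiftR(w, 2L * j), 3L),
                            2L * (k - 1L - j))
  out
}

#' Hierarchical (coarse-to-fine) visit order of HEALPix pixels
#'
#' Orders ring-scheme pixel indices so that any prefix of the sequence
#' covers the sphere quasi-uniformly: the within-face part of the nested
#' index is base-4 digit-reversed about the face center, so the first 12
#' pixels sit near the base-face centers, the first 48 sample the
#' nside=2 refinement, and so on.
#'
#' @param nside Resolution parameter (power of 2).
#' @return Integer vector of 0-based ring-scheme indices, length
#'   `12 * nside^2`.
#' @export
healpix_visit_order <- function(nside) {
  nside <- .check_nside(nside)
  k <- as.integer(round(log2(nside)))
  f <- rep(0:11, each = nside^2)
  w <- rep.int(seq_len(nside^2) - 1L, 12L)
  if (k > 0) {
    center <- 3L * 4L^(k - 1L)           # interleaved (nside/2, nside/2)
    wkey <- .digitrev4(bitwXor(as.integer(w), center), k)
  } else wkey <- w
  ord <- order(wkey, f)
  pnest <- f * nside^2 + w
  healpix_nest2ring(nside, pnest[ord])
}

#' Unit vectors of pixel centers
#' @param nside Resolution parameter.
#' @return `npix x 3` matrix of unit vectors (ring-scheme order).
#' @export
healpix_vectors <- function(nside) {
  ang <- healpix_pix2ang(nside)
  st <- sqrt(pmax(0, 1 - ang[, "z"]^2))
  cbind(x = st * cos(ang[, "phi"]), y = st * sin(ang[, "phi"]), z = ang[, "z"])
}

#' Maximum angular gap of the HEALPix grid
#'
#' Samples uniformly random directions and reports the maximum angular
#' distance (degrees) to the nearest pixel center -- the covering radius
#' estimate of the orientation grid.
#'
#' @param nside Resolution parameter.
#' @param n_samples Number of random directions.
#' @param seed RNG seed.
#' @return Maximum observed angular distance in degrees.
#' @export
healpix_max_gap <- function(nside, n_samples = 1e5, seed = 1) {
  centers <- healpix_vectors(nside)
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  worst <- 0
  chunk <- max(1L, as.integer(2e7 / nrow(centers)))
  for (i0 in seq(1, n_samples, by = chunk)) {
    i1 <- min(n_samples, i0 + chunk - 1)
    dots <- v[i0:i1, , drop = FALSE] %*% t(centers)
    best <- apply(dots, 1, max)
    worst <- max(worst, acos(pmin(1, best)))
  }
  worst / .deg
}
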