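---
title: "Predicting and indexing imperfect UED patterns: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and indexing imperfect UED patterns: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relrod)
```

## The problem

Transmission ultrafast electron diffraction probes thin, imperfect
quasi-single crystals. Their diffraction patterns violate the textbook
single-crystal picture in four ways: the coherently diffracting domains
are small (relrod broadening), their orientations are spread over degrees
rather than arc-minutes (mosaicity), and the probe has finite divergence
and energy bandwidth. Consequently, many reciprocal lattice points (RLPs)
diffract simultaneously, observed "spots" are superpositions of several
reflections, and peak positions alone cannot index the pattern reliably.

`relrod` treats this fuzziness as signal rather than noise. Because the
crystal structure must be known beforehand (a CIF file), every candidate
orientation predicts not just spot positions but also intensities, and
the imperfection widths themselves become fittable parameters. Blurring
also smooths the cost function: for a perfect crystal the match between a
predicted and an observed pattern is a discontinuous function of
orientation, while under Gaussian broadening it becomes continuous and
amenable to least squares.

Everything is kinematical: intensities are `|F(hkl)|^2` times a profile
factor. Dynamical (multi-beam) scattering is out of scope; kinematical
intensities of imperfect, strongly textured samples are inaccurate at the
tens-of-percent level, but that is sufficient for orientation
discrimination, which is what the cost function uses them for.

## The Gaussian imperfection model

Each of the four effects is a single Gaussian, mutually independent, so
all combinations reduce to covariance algebra.

**Finite size.** The exact relrod intensity profile of a thin plate of
thickness $t$ is $\mathrm{sinc}^2(\pi t q)$; a solid sphere of diameter
$D$ gives the Fourier transform of its projected autocorrelation. Both
are replaced by unit-peak Gaussians whose widths minimize the maximum
absolute deviation from the exact profile:

```{r}
shape_sigma_from_size("plate", 235)$sigma_z   # t / 2.35
gaussian_minimax_factor("plate")              # re-derived from sinc^2
gaussian_minimax_factor("sphere")             # re-derived from the sphere ACF
```

Averaging over a realistic thickness distribution fills in the sinc
minima, which is why a Gaussian is an acceptable stand-in; the fitted
"thickness" is an effective width, biased low relative to the true mean
thickness because the Gaussian must absorb the slowly decaying side
lobes. In the general (ANISO) mode the shape transform is a full 3x3
covariance `Sigma_shp` (crystal-fixed, principal widths in 1/Å plus Euler
angles); in the standard mode it is a single relrod width `sigma_shp`
along a direction tilted from the beam axis.

**Mosaicity.** Domain orientations are rotation vectors
$\vec\omega \sim N(0, \Sigma_\omega)$ in the lab frame (isotropic:
`sigma_mos` in degrees; anisotropic: three principal sigmas and three
Euler angles). A rotation moves an RLP $\vec h$ on the sphere $S_h$ of
radius $h = 1/d$; rotations about $\vec h$ itself do nothing, so
$\Sigma_\omega$ is expressed in the local frame
($e_3 \parallel \vec h$, $e_1 \parallel \vec k_i \times \vec h$,
$e_2 = e_3 \times e_1$), the $\omega_3$ component is marginalized out,
and the in-plane block maps to a tangent-plane displacement covariance

$$\Sigma_h = h^2 \begin{pmatrix} \Sigma_{22} & -\Sigma_{12} \\
-\Sigma_{12} & \Sigma_{11} \end{pmatrix}.$$

The swap-and-negate structure is the 90-degree rotation hidden in
$\delta\vec h = \vec\omega \times \vec h$. Marginalizing $\omega_3$ is
exact only for infinitesimal rotations; it intermixes orientations over
ranges growing with $\omega_3$, which is harmless for isotropic spreads
and acceptable for moderately anisotropic ones up to sigmas of several
degrees.

**Divergence and bandwidth** fold into an *effective mosaicity*. Beam
tilts are rotations about axes perpendicular to the beam, adding
$\sigma_{divg}^2 (I - \hat z \hat z^T)$ to $\Sigma_\omega$. A bandwidth
$\sigma_{bwdth} = \Delta\lambda/\lambda$ rescales the Ewald sphere; near
an RLP at resolution $h$ the sphere displacement equals that of an
angular spread $a\,h\,\sigma_{bwdth}$. The constant is taken as
$a = \lambda/2$, from the sphere geometry: a radius change
$k\,\sigma_{bwdth}$ shifts the sphere near the RLP by
$2\sin^2\theta \cdot k\,\sigma_{bwdth} = (h^2\lambda/2)\,\sigma_{bwdth}$.
It is overridable (`bandwidth_const`) because only the *form* of the
coupling is determined by the geometry, and the exact
resolution-dependent convolution admits more than one consistent
reading. In the anisotropic path the bandwidth term enters as an
isotropic addition so that the excitation-critical marginal reproduces
the scalar quadrature formula exactly; the isotropic scalar version is

$$\sigma_{MOS}^2 = \sigma_{mos}^2 + \sigma_{divg}^2 +
(a\,h\,\sigma_{bwdth})^2.$$

For cost evaluation only integrated intensities and centroids matter, so
the purely image-side broadenings (divergence footprint, radial bandwidth
smear) enter only `simulate_image()`.

## Intensity prediction

**ANISO mode.** The tangent covariance $\Sigma_h$ (zero radial width) is
convolved with the lab-rotated shape covariance, giving a trivariate
Gaussian at the RLP. Its integral across the Ewald sphere — the 1-D
marginal along the sphere normal — is the partiality. Two curvature
corrections replace the raw tangent-plane construction: the excitation
error is measured as *arc length* $e$ on $S_h$ to the exact intersection
point of $S_h$ with the Ewald sphere (in the plane spanned by $\vec k_i$
and $\vec h$), and tangent displacements are mapped back to $S_h$ by the
spherical exponential map before projecting the centroid to the
detector. In the Gaussian factor the arc length is projected onto the
sphere normal ($d_\perp = n_2\,e$), so that for an isotropic spread with
no shape term the intensity reduces exactly to
$\exp(-e^2 / (2 h^2 \sigma^2))$ — the same closed form the standard mode
uses — while the prefactor $1/\sqrt{2\pi\, n^T C n}$ retains the
obliquity of the cut. The rotation of the shape function by $\omega_3$
is ignored; an exact treatment requires a numerical integral over
$\omega_3$ whose cost is not justified by its effect.

These choices are validated in the test suite against a Monte-Carlo
oracle that samples $10^6$ rotation vectors, rotates $\vec h$ exactly
(Rodrigues), and bins the density near the Ewald sphere: predicted
densities agree within Monte-Carlo error over randomized anisotropic
covariances (sigmas 0.8-3.5 degrees) and arc offsets up to ~2 sigma.

**Standard mode** assumes isotropic mosaicity and plate-like domains. It
combines $\sigma^{*2} = \sigma_{shp}^2 + (h\,\sigma_{MOS})^2$ and
evaluates Gaussian densities at two extreme-case excitation errors: point
A where the mosaic arc $S_h$ meets the Ewald sphere ($e_{MOS}$, arc
length), and point B where the relrod line through the RLP meets it
($e_{shp}$). Intensity and centroid are weighted averages with weights
$\propto h\,\sigma_{MOS}/e_{MOS}$ and $\propto \sigma_{shp}/e_{shp}$,
normalized to one. The $1/e$ weights diverge on the sphere, where both
cases coincide anyway; excitation errors are floored at $10^{-6}$ /Å.
Whether the weights should be normalized is not determined by the
construction; they are normalized here so the on-sphere limit returns
the peak density.

**Degeneracies.** Zero-width directions (any sigma equal to zero) are
legitimate parameter values. A fully degenerate profile whose support
misses the Ewald sphere contributes zero intensity; no jitter is ever
added to covariances. Reflections whose excitation error exceeds 4
combined sigmas are skipped (`cutoff_sigma`, configurable; the tail
beyond 4 sigma carries < 0.01% of the peak density), after a cheap
lower-bound prefilter on the perpendicular distance to the sphere.

## Ambits, cost function, quality metrics

Observed spots own disjoint circular ambits of radius $r_a$, by default
half the minimum pairwise spot distance (the largest non-overlapping
choice); a larger user radius is clipped with a warning because
disjointness is what makes every prediction attributable to at most one
spot. Membership is strict (`< r_a`). Merged predictions per spot are
intensity sums with intensity-weighted centroids.

The cost is $S = S_{I,hits} + w_2 S_{I,nohits} + w_P S_P$. The intensity
sum runs over *all* observed spots — an unmatched spot contributes its
full (weighted) observed intensity, which is what drives the search
toward orientations that explain every spot. Weights are
$w_{io} = I_{obs}^{-1/2}$ for target `"I"`; target `"sqrt(I)"` uses
$(\sqrt{I_{clc}} - \sqrt{I_{obs}})^2$, whose no-hit analogue
$\sum I_{clc}$ is the same expression with $I_{obs} = 0$. $w_2 > 0$ is a
rescue option against solutions that dump intensity outside all ambits;
$S_P$ charges squared centroid distances, $r_a^2$ for unmatched spots.

R factors are the conventional linear-scale
$R_I = \sum|k\,I_{clc} - I_{obs}| / \sum I_{obs}$ (least-squares $k$) and
its square-root analogue; they are labeled as such in all outputs, since
"R factor" admits several definitions. Per-observation sigma columns in
reduced data are parsed but ignored with a warning — weights derive from
the intensities themselves.

## Orientation search and refinement

The SO(3) grid is HEALPix over beam directions (equal-area, iso-latitude;
`nside = 64` gives 49152 directions at 0.92 degrees resolution, within 1
degree of any orientation) times a 1-degree $\Psi$ scan, 17.7 million
orientations in total. Directions are visited coarse-to-fine (base-4
digit-reversed nested index, centered on the face centers) so an
interrupted scan still covers the sphere quasi-uniformly; scans are
resumable and chunk-independent. For a fixed beam direction the
excitation errors are $\Psi$-invariant, so each direction is scored in
one pass: every (prediction, spot) pair contributes over a contiguous
$\Psi$ window obtained from their radii, and the figure of merit

$$\mathrm{FOM} = \frac{\sum_{io} \sqrt{I^{clc}_{io} I^{obs}_{io}}}
{\sqrt{\sum_{all} I^{clc} \cdot \sum_{io} I^{obs}}}$$

is maximized over $\Psi$. This normalized square-root overlap is bounded
in [0, 1], scale-free on both sides, rewards hit coverage and intensity
agreement simultaneously, and penalizes intensity predicted outside all
ambits through its denominator. It is a package-defined score (labeled,
not claimed canonical). The scan evaluates the distortion-free
projection — the elliptical correction moves radii by far less than an
ambit — and applies the setting's parameters except orientation and
resolution range.

For a centrosymmetric structure the kinematical pattern has a twin: the
orientation $R_z(180^\circ)\,R$ predicts the pattern rotated by 180
degrees about the beam with $hkl \to -h,-k,-l$, which differs from the
original only through Ewald-sphere curvature. FOM maps show both peaks
(hence both hemispheres are reported) and `top_orientations()` does not
deduplicate these inversion mates; either solution is a correct
indexing, related by Friedel symmetry.

GeoFit minimizes $S$ by bounded Levenberg-Marquardt (`minpack.lm`), with
box constraints keeping sigmas non-negative and the scale positive, and
a fixed-layout residual vector: every observed spot always contributes
(unmatched ones at $I_{clc} = 0$ and distance $r_a$), and the no-hit term
is aggregated into a single residual, so the optimizer never sees a
dimension change. Ambit membership makes $S$ piecewise-smooth;
assignments are recomputed at every evaluation and the trust region
absorbs the steps. Convergence: relative decrease and step tolerances
$10^{-10}$, at most 200 iterations; non-convergence is flagged, never
silent. The refined result never reports a cost above the starting
value — if the optimizer ends worse (possible when reassignment kinks
mislead the local model), the starting parameters are kept and flagged.

One protocol detail matters for orientation precision: with $w_P = 0$ the
cost is *piecewise constant* in the rotation about the beam, because
rotating all predictions inside their ambits changes no intensity —
position information then enters only at ambit crossings. The
`balance_pos_weight` option (used by `index_pattern()`) therefore sets
$w_P$ so the position part equals the intensity part at the start — a
self-scaling choice that makes sub-ambit offsets visible without manual
tuning. `index_pattern()` combines a coarse scan (nside 16 by default —
the 2-degree-scale mosaic basin is wide enough for a 3.7-degree grid)
with refinement of orientation, mosaic width and scale under the
square-root target.

Parameter gating mirrors the single-image/tilt-series distinction: the
tilt-axis direction is never fittable, image rotation only in multi-image
projects, and per-image scale/tilt corrections ($n-1$ values, image 1
fixed) only when the corresponding control flags are set. Jacobians are
forward differences with steps scaled per parameter magnitude by the
optimizer.

## The synthetic generator

`make_synthetic_project()` is the package's test bed: a fixed toy
triclinic P-1 molecular structure (9-atom asymmetric unit, written as
CIF), diffraction at 200 keV, 500 mm camera, 0.05 mm pixels, 2 degrees
isotropic mosaic spread, ~300 Å plate-like domains, intensity scale 10^4.
Predictions within 6 px merge into "observed" spots (emulating blob
detection), the spot list is made an exact fixed point of the ambit-merge
rule, then seeded log-normal intensity noise (sdlog 0.1), Gaussian
centroid jitter (0.3 px), a detection threshold and a 90-spot cap are
applied — numbers typical of reduced UED data (50-100 usable spots, tens
of percent intensity error tolerance).

What it does **not** emulate: dynamical scattering (kinematical
intensities are the model and the truth here, so tests cannot detect
kinematical bias), inelastic background, detector point-spread and
saturation, peak-detection failures (split/merged blobs), and
non-Gaussian relrod tails. Passing the recovery tests therefore
demonstrates the estimator's correctness and precision under the stated
noise model, not robustness to real-data artifacts.

Test problem sizes are chosen for desk-scale runs: recovery uses the
nside-16 grid with 1-degree $\Psi$ steps and 20 seeds with randomized
orientations; the Monte-Carlo oracle uses 10^6 rotation samples per case;
the grid-coverage check uses 10^5 random directions.

## Known limitations

* Kinematical only; no absorption, no anomalous scattering, no inelastic
  background.
* Gaussian profiles throughout — the exact sinc-like relrod shapes exist
  in the package only as the oracle for the width calibration.
* Ion scattering factors fall back to the neutral atom (with a warning);
  the bundled table is the five-Gaussian neutral-atom set.
* The $\omega_3$ rotation of an anisotropic shape transform is ignored;
  strongly anisotropic mosaic spreads beyond several degrees stretch the
  marginalization approximation.
* GridScan scores the distortion-free projection; distortion is refined
  by GeoFit afterwards.
* Symmetry-equivalent reflections are never merged: every RLP is
  predicted independently, which is what per-spot decomposition reports
  require.
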