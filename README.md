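# relrod

Indexing and geometry refinement for single-crystal **ultrafast electron
diffraction (UED)** patterns.

UED samples are rarely good single crystals: they are thin, bent,
mosaic-spread ensembles of small domains, probed by a divergent beam with
finite energy bandwidth. Bragg-peak positions alone are then too imprecise
to index a pattern. `relrod` follows the opposite strategy: it predicts
*both* positions and intensities of Bragg spots from the known crystal
structure under an explicit Gaussian imperfection model, and finds the
crystal orientation and geometry parameters that best explain all of the
reduced data at once.

It is aimed at experimentalists reducing UED images of molecular or
inorganic crystals whose structure is known a priori (a CIF file), and at
method developers who need a transparent, scriptable kinematical
prediction engine.

## Model

Within the kinematical approximation the intensity of reflection *hkl* is
proportional to |F(hkl)|² (electron structure factors from the Peng
five-Gaussian parameterization) times a profile factor. Each reciprocal
lattice point (RLP) is broadened by four independent Gaussian effects:

* **finite domain size** — a shape-transform covariance; a plate of
  thickness *t* maps to a relrod of width σ_z = *t*/2.35, a sphere of
  diameter *D* to σ_z = *D*/2.99 (minimax-optimal Gaussian widths);
* **mosaicity** — a trivariate normal distribution of domain rotation
  vectors ω with covariance Σω (isotropic or fully anisotropic);
* **beam divergence** σ_divg and **energy bandwidth** Δλ/λ, folded into an
  *effective mosaicity*:
  σ_MOS² = σ_mos² + σ_divg² + (a·h·σ_bwdth)², a = λ/2.

Rotations move an RLP on the sphere S_h of radius h = 1/d; in the
tangent-plane approximation the displacement covariance is
Σ_h = h²·[[Σ22, −Σ12], [−Σ12, Σ11]] from the in-plane block of the
rotation-vector covariance. The predicted intensity is the integral of the
resulting Gaussian across the Ewald sphere, with the excitation error
measured as arc length on S_h (a curvature correction), and the centroid
is the conditional mean on the Ewald trace projected to the detector.

Predictions are matched to observed spots through disjoint circular
**ambits** of radius r_a around each spot (by default half the minimum
spot separation); contributions merge by intensity sums and
intensity-weighted centroids. The cost function is

S = S(I,hits) + w₂·S(I,nohits) + w_P·S(P)

with intensity residuals weighted by I_obs^(−1/2) (target `"I"`) or taken
on square roots (target `"sqrt(I)"`), and S(P) the squared centroid
distances (r_a² for unmatched spots). The orientation is located by an
exhaustive **GridScan** over 12·nside²·(360/ψ-step) orientations — HEALPix
beam directions × in-plane rotations — scored by a normalized √-overlap
figure of merit, then all parameters are refined by bounded
Levenberg-Marquardt least squares (**GeoFit**), with per-spot
decomposition into up to five contributing reflections.

## Worked example

A synthetic project (toy triclinic P-1 structure, 2° mosaic spread, 10%
intensity noise, 0.3 px centroid jitter) is generated, then indexed from
scratch — coarse grid scan (nside 16, 3072 beam directions × 360 ψ) plus
refinement:

```r
library(relrod)

proj  <- make_synthetic_project(synthetic_truth(seed = 42), "demo")
spots <- read_reduced_data(file.path("demo", "reduced.tsv"))
str   <- parse_cif(file.path("demo", "structure_synthetic.cif"))

st0 <- setting_update(synthetic_default_setting(), orientation = c(0, 0, 0))
st0$mosaicity <- mosaicity_model("isotropic", 1.5)

res <- index_pattern(st0, spots, structure = str, grid = build_grid(16))
print(res)
#> GeoFit: S 6.11849e+07 -> 2.07525e+06 in 5 iteration(s); R_I = 0.0819, matched 100%
#>                before        after
#> theta        38.74419    37.986879
#> phi         121.15385   121.040000
#> psi          48.00000    46.986765
#> sigma_mos     1.50000     1.975183
#> scale     10000.00000 10225.020621
```

The generating truth was orientation (38, 121, 47) with σ_mos = 2°: the
workflow recovers the orientation to ~0.05° and the mosaic spread to
~1%, with a final R factor of 0.082 — the level set by the injected 10%
intensity noise. The per-spot report decomposes every observed spot into
contributing reflections:

```r
head(per_spot_report(res)[, c("spot_id", "I_obs", "I_clc", "h", "k", "l",
                              "I_contrib", "e_mos")], 3)
#>   spot_id    I_obs    I_clc  h  k  l I_contrib    e_mos
#> 1   S0001 55068560 49680153  2 -3  2  49680153  0.00105
#> 2   S0002 44622120 48908494 -2  3 -2  48908494  0.00255
#> 3   S0003 30376288 30178116  0 -2  1  30178116 -0.00792
```

(`e_mos`, `e_shp` are the excitation errors in 1/Å measured along the
mosaic arc and along the relrod.)

A command-line interface wrapping these functions is installed at
`exec/relrod` (subcommands `synth`, `predict`, `simulate-image`,
`gridscan`, `top`, `geofit`, `report`).

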