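---
title: "Methods: LULC change, LST retrieval and their coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LULC change, LST retrieval and their coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lulcst)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, what the synthetic scenes do and do
not emulate, and the numerical decisions taken where the methodology is
genuinely open.

## The analysis in one paragraph

Two multispectral scenes of the same area, years apart, are each pushed
through: (i) a thermal chain that turns thermal-band digital numbers (DN)
into top-of-atmosphere radiance, brightness temperature and finally an
emissivity-corrected land surface temperature (LST); (ii) NDVI and the
NDVI-derived proportion of vegetation and emissivity; (iii) a supervised
Gaussian maximum-likelihood classification (MLC) into six land-cover
classes (urbanized, forests, agricultural, bare, rocks, water) from labeled
training points; and (iv) an error-matrix accuracy assessment on held-out
points. Across the two dates, per-class areas yield change statistics, and
per class the LST–NDVI relation is summarized by a bivariate ordinary
least-squares fit.

## Thermal chain

For OLI/TIRS sensors radiance is the linear rescaling
$L_\lambda = M_L\,Q_{cal} + (A_L - O_i)$; for TM it is the two-point form
$L_\lambda = \frac{L_{max}-L_{min}}{Q_{max}-Q_{min}}(Q_{cal}-Q_{min}) +
L_{min}$, which maps the calibrated DN range endpoints exactly onto the
radiance endpoints. An alternative parenthesization that multiplies
$(Q_{cal}-Q_{min}) + L_{min}$ wholesale by the gain circulates in parts of
the applied literature; it breaks both endpoint identities, so the package
uses the standard form and keeps the alternative behind
`literal_eq2 = TRUE` purely for comparison.

Brightness temperature inverts the Planck relation,
$BT = K_2 / \ln(K_1/L_\lambda + 1) - 273.15$ (°C), with the sensor thermal
constants ($K_1 = 607.76$, $K_2 = 1260.56$ for TM band 6). $BT$ is strictly
increasing in radiance; cells with a non-positive log argument are flagged
as nodata and counted rather than silently clamped.

The single-channel LST is
$LST = BT \,/\, \bigl(1 + (\lambda\,BT/c_2)\ln E\bigr)$ with
$c_2 = 14388\ \mu m\,K$ and $\lambda$ = 11.5 µm (TM band 6) or 10.8 µm
(OLI/TIRS band 10). The default mode (`celsius_literal`) feeds the Celsius
$BT$ directly into this formula — the form in common applied use, even
though it mixes a Celsius temperature with the Kelvin-based constant
$c_2$. Because this unit inconsistency deserves visibility rather than
silent correction, a `kelvin_physical` mode evaluates the identical formula
on the Kelvin scale and converts back; the mode used is recorded in the
output's attributes. At typical terrestrial temperatures the two differ by
a few tenths of a degree.

NDVI is computed on DN values by default (with the index being invariant to
a common band rescaling, reflectance inputs work unchanged), and the
proportion of vegetation uses the scene's own observed NDVI minimum and
maximum as scaling endpoints unless overridden — i.e. the endpoints are
read from the NDVI image, which makes PV scene-relative. The min–max ratio
is clipped to [0, 1] *before* squaring, so PV and emissivity
($E = 0.004\,PV + 0.986 \in [0.986, 0.990]$) are always in range even when
explicit endpoints narrower than the data are supplied.

## Classification

Signatures are per-class sample means and covariances (denominator
$n-1$) of the band values at training pixels, taken from the three-band
composite used for classification. A ridge
$\varepsilon = 10^{-6} \times \text{mean diagonal}$ (absolute $10^{-6}$
when the diagonal is all zero) is added when the smallest eigenvalue falls
below it: this leaves well-conditioned covariances untouched to ~6
significant digits but keeps degenerate training sets (e.g. duplicated
points) classifiable. Each pixel gets the class maximizing
$g_i(x) = \ln p_i - \tfrac12\ln|\Sigma_i| -
\tfrac12 (x-\mu_i)^\top \Sigma_i^{-1} (x-\mu_i)$, computed via Cholesky
factorization. Priors $p_i$ are equal by default — nothing in the
methodology dictates otherwise — and can be set per class. Ties break to
the lowest class index, a deterministic rule the tests rely on. With equal
priors and a shared covariance the rule reduces to minimum-Mahalanobis
classification, which the test suite verifies on random scenes.

Training-point selection follows the practice of drawing a minimum of 40
random sample points per class; in the synthetic pipeline they are sampled
uniformly without replacement from the truth map and the held-out accuracy
points are redrawn from the map with training pixels masked out, so the
two sets are disjoint.

## Accuracy assessment

The error matrix is oriented rows = predicted, columns = reference (stated
in all outputs, since the convention varies between software packages).
Producer's accuracy is the diagonal over the column total (100% minus
omission error), user's accuracy the diagonal over the row total (100%
minus commission error), overall accuracy the trace over the total, and
Kappa is Cohen's $(p_o - p_e)/(1 - p_e)$ with
$p_e = \sum_k r_k c_k / n^2$. Tables render at two decimals; machine
outputs keep full precision.

## Change statistics

Per class, $C_a = T_a(\text{year 2}) - T_a(\text{year 1})$,
$C_e = C_a / T_a(\text{year 1})$, percentage change $= 100\,C_e$. The
annual rate is not pinned down by the defining formulas, so the package
defaults to the linear $100\,C_e / \text{interval}$ — the rule consistent
with published two-date tables we reproduce in the acceptance tests — and
offers the compound $((A_2/A_1)^{1/n} - 1)\cdot 100$ behind
`rate = "compound"`. Classes with zero first-date area report $C_a$ but
missing extent and rates. Pixel areas use the 30 m grid
(0.09 ha per pixel) unless the raster says otherwise.

## LST–NDVI relation

LST is the response and NDVI the predictor (the direction matters and is
stated, since "relationship" alone is ambiguous): an OLS fit per class at
20 randomly sampled pixels per class by default, reporting slope
(°C per NDVI unit), intercept (°C) and unsigned $R^2$ — the slope's sign
carries the direction of the association. The fit is delegated to
`stats::lm`; the tests independently verify the closed-form slope,
intercept, the centroid property and $R^2 = 1 - SSE/SST$.

## The synthetic scene generator

The generator exists so that every downstream stage has a ground truth. It
emulates:

* a six-class mosaic with controllable per-class area fractions
  (defaulting to the published Penang Island class shares, which also make
  the synthetic change table qualitatively mirror the published one);
* class-conditional multivariate-normal optical DNs over three bands
  (green, red, NIR) and normal thermal DNs, clipped to the calibrated DN
  range;
* a spatial structure of contiguous rectangular patches: the grid is cut
  into `region_scale` × `region_scale` tiles, the tile order is shuffled
  (seeded) and tiles are filled class by class, which realizes the target
  fractions to within one pixel while keeping classes spatially blocky;
* spectra chosen to reproduce the qualitative class structure of a tropical
  urbanizing scene — class-mean NDVI ordered forests (~0.55) >
  agricultural (~0.40) > urbanized (~0.05) > bare (~0.02) > rocks (~0) >
  water (~−0.40), within the 0.1–0.75 range for healthy vegetation and
  negative for water, and thermal DNs ordered urbanized > bare > rocks >
  agricultural > forests ≈ water so the hottest classes are the built and
  bare surfaces. One published table prints an NDVI of −0.98 for rocks
  while the accompanying text places rock and soil near zero; the synthetic
  defaults follow the near-zero physics.

It deliberately does **not** emulate radiative transfer, atmospheric
effects, sensor noise correlation, mixed pixels, topography or clouds.
Passing tests therefore demonstrate the correctness of the *algorithms*
under the stated statistical model — near-perfect classification of
well-separated Gaussian classes says nothing about accuracy achievable on
real Landsat scenes, where published overall accuracies in the high 80s
are typical.

Default noise levels are `band_sd = 3` DN and `thermal_sd = 2` DN around
class means spaced tens of DN apart: strongly separable, as appropriate
for verifying machinery rather than stress-testing it. Separability is a
free parameter (`band_sd`, `thermal_sd`, `band_cov`) precisely because no
spectral statistics are published for the real training classes.

All randomness flows from one master seed split into fixed per-stage
substreams (truth map, scene draw, training sample, reference sample,
regression sample), so any artifact can be regenerated independently and
whole runs are bit-reproducible.

## Raster and metadata formats

Rasters travel as ESRI ASCII Grid — a plain-text, widely interchangeable
GIS format that keeps every fixture and output human-readable and
diff-able; multi-band scenes use a documented `nbands` stack extension of
the same format, and calibration metadata is flat `KEY = value` text (an
MTL-style subset). Nodata propagates through every operation: any cell
that is nodata in an input is nodata in the output, and each stage counts
the cells it flags (clamped DNs, non-physical radiances, non-positive LST
denominators) instead of failing.

## Problem sizes and tolerances in the test suite

The suite verifies the thermal chain against an independent straight-line
re-implementation on a 256×256 random scene at 1e-9; MLC against a
brute-force density-maximization oracle on 50×50 six-class scenes; held-out
accuracy (40 train + 40 test points per class) on 120×120–150×150 scenes;
truth-map fraction realization on 200×200; and slope recovery across 500
regression replicates at n = 20 points. These sizes are chosen to exercise
every code path at full statistical strength while keeping the whole suite
in the order of seconds.

## Known limitations

* The TOA chain stops where the methodology stops: no atmospheric
  correction (transmittance, upwelling radiance) and no split-window LST.
* Emissivity is the two-parameter NDVI form only; no per-cover emissivity
  lookup.
* Change analysis is per-class aggregate; no pixel-wise transition
  matrices.
* Published accuracy figures and per-class LST/NDVI means from real scenes
  depend on unpublished imagery and ground truth and are not reproducible
  from this package; what the package reproduces exactly is the change
  arithmetic from the published area tables (one published change row —
  water bodies — is internally inconsistent with its own area table and is
  documented rather than patched).
* No reprojection or resampling; all grids in one analysis must share a
  grid geometry.
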