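---
title: "Methods: UAS multi-sensor feature extraction and soybean yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UAS multi-sensor feature extraction and soybean yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`uasyield` implements a complete high-throughput phenotyping analysis for
soybean breeding trials flown with two optical sensors on an unmanned
aircraft system (UAS): a four-band multispectral camera (green, red,
red-edge, near-infrared) producing reflectance orthomosaics, and an RGB
camera whose photogrammetric reconstruction yields dense 3-D point clouds.
From these products the package extracts, per breeding plot, 48 radiometric
and 12 geometric features across two study dates, fits bagged-forest and
boosted-tree regressions of grain yield (kg/ha) on those 60 features, and
assesses the predictions with bias/error statistics, a robust linear fit
with studentized-residual outlier screening, a robust normality test and
family-grouped errors.

No flight or harvest data ship with the package. A synthetic-field
generator stands in for them, with enough statistical structure that every
downstream stage — end-member segmentation, registration, terrain
differencing, volume integration, model fitting — is exercised against
known ground truth.

## The synthetic field

`field_spec()` describes a rectangular grid of rectangular plots. Crop rows
run along the plot length at 0.76 m spacing, 6 (or 8) rows per plot; the
multispectral ground sample distance defaults to 5.08 cm and the RGB one to
2.54 cm. Latent per-plot traits drive all products
(`simulate_plot_truths()`):

* canopy-cover fraction `cc ~ Beta(19.2, 4.8)` (mean 0.80, SD 0.08);
* mean canopy height, 0.578 m at the first study date growing to 0.798 m at
  the second, plot SD 0.10 m;
* a chlorophyll scalar `chl ~ N(1, 0.15)` scaling the NIR/G contrast.

These centers reproduce the scale of a rainfed soybean trial at late-R4 /
early-R5: vegetation band medians near G 6.2, R 2.5, RE 32, NIR 55 percent
reflectance at the first date, deviation-cloud mean heights near 0.58 m and
0.80 m, and — through the default yield coefficients
`yield = -4624.6 + 4000 cc + 3500 h + 2800 chl + N(0, 350)` — a marginal
yield distribution with mean ≈ 3783 kg/ha and SD ≈ 770 kg/ha.

The orthomosaic (`generate_orthomosaic()`) renders each plot's rows as
vegetation stripes whose total width realizes `cc` exactly (up to pixel
quantization), over a bare-soil background (NIR ≈ 15), with per-pixel
Gaussian noise truncated at zero. The vegetation/soil NIR separation is
about 40 noise SDs, so two-class clustering has a well-defined optimum.

The terrain (`generate_clouds()`) is a gentle quadric
`z = c0 + c1 x + c2 y + c3 x² + c4 xy + c5 y²` — deliberately curved so the
local quadric model downstream is non-trivially exercised — plus
tillage-scale micro-relief: three obliquely oriented, incommensurate
sinusoids (default amplitude 2 cm, wavelengths 0.7–5 m). The micro-relief
emulates soil-surface texture and is what makes a point-to-point
registration horizontally observable; on a featureless plane the ICP
problem is degenerate in x–y. Terrain and canopy clouds are sampled at 120
points/m² (photogrammetric products of this kind exceed 100 points/m²) with
8 mm vertical noise. Canopy clouds add the per-plot height over the
vegetation stripes with a 15% within-plot coefficient of variation, receive
a known rigid perturbation (yaw about the field center plus translation,
recorded in metadata), an optional global *reconstruction height bias*
applied to elevated surfaces only (canopy and bars, not bare ground — a
rigid registration could absorb a whole-cloud shift, whereas surface
smoothing in dense matching biases precisely the elevated structures), and
a configurable fraction of gross z-outliers. Five fixed calibration bars of
known height are rendered as point discs in the field border of every
cloud; their top centers double as tie points for coarse registration, as
ground-control picking would in a survey.

What the generator does *not* emulate: the imaging process itself (camera
model, bundle adjustment, occlusion), atmospheric and BRDF effects, weeds
and lodging, phenology dynamics, and spatially correlated yield variation
(soil gradients, alpha-lattice block effects). Tests passing on this field
therefore validate the computational chain, not the field biology.

## Plot grid and clipping

`build_plot_polygons()` reproduces a field-map script: axis-aligned plot
rectangles ordered from the top-right, row-major to the bottom-left,
skipping the alley, with an optional symmetric shrink margin against border
effects. Raster clipping keeps pixels whose centers fall in the half-open
`[min, max)` rectangle; cloud clipping applies the same half-open rule to
point coordinates. The two rules make adjacent plots partition space — no
pixel or point is counted twice, which the tests assert. Coordinates are
meters in a local planar frame; EPSG-style georeferencing is metadata only.

## Radiometric stage

Per plot, the NIR band is split into soybean and soil end-members by
one-dimensional 2-means clustering (`segment_vegetation()`). Initialization
is deterministic at the 10th and 90th percentiles with Lloyd iterations
(tolerance 1e-6, 100 iterations cap), removing seed sensitivity from a 1-D
problem; the reported threshold is the centroid midpoint. A degenerate-
clustering guard rejects plots whose centroid separation is below 4 pooled
within-cluster SDs: a unimodal Gaussian band scores ≈ 2.7 on this ratio
while a genuine soil/canopy contrast scores far above 10, so an all-soil
(or all-canopy) plot raises an error instead of returning an arbitrary
split.

Statistics of the soybean pixels are computed per band in Gaussian and
robust families (`robust_stats()`): mean and SD; median; MAD and
`NMAD = 1.4826·MAD`; the square root of the biweight midvariance with
`U = (x − m)/(9 MAD)` and weights zeroed for `|U| ≥ 1`; percentiles at
2.5/25/75/97.5%; and interpercentile ranges IQR, `IPR90 = P95 − P5`,
`IPR99 = P99.5 − P0.5`. Percentiles interpolate linearly between order
statistics (the default convention of `quantile()`); for a constant sample
all dispersion estimates are defined as zero.

Canopy cover is pixel counting times the squared ground sample distance.
Row counting builds a Canny edge map (Gaussian smoothing σ = 1 px, Sobel
gradients, non-maximum suppression, hysteresis with the high threshold from
Otsu's method on the gradient magnitudes and the low threshold at half of
it), projects edge support across the row direction and counts lines
spanning at least 90% of the plot length; each complete row contributes its
two boundary lines. Row length is the projected extent of the vegetation
pixels on the first eigenvector of their coordinate covariance (another
defensible reading — counting pixels along that axis — differs only by the
cover fraction; the projected range is implemented). Both row features are
computed but excluded from the default model feature set: at high canopy
cover adjacent rows close and the features carry little variation.

Eleven vegetation indices are computed from the per-band medians
(`compute_vis()`): NDVI, SAVI (L = 0.5), MSAVI, GESAVI, CIre, CIg, VARI,
RVI, DVI, RDVI, TVI. Two forms deserve note. MSAVI is implemented in its
canonical single-difference form
`(2 NIR + 1 − sqrt((2 NIR + 1)² − 8(NIR − R)))/2`; the variant that squares
`(NIR − R)` produces a negative discriminant on percent-scale reflectance
and cannot have been computed. GESAVI is implemented from its soil line
`NIR = a·R + b` as `(NIR − b − aR)/(R + z)` with literature defaults
`a = 1, b = 0, z = 0.35`. The green chlorophyll index defaults to the ratio
form `NIR/G − 1`, consistent with its red-edge sibling; a
`cig_as_printed` flag restores the subtractive `(NIR − G) − 1` variant that
sometimes appears in index tables. VARI is implemented as `(G − R)/(G + R)`
since no blue band exists on this sensor.

The per-date model feature row is 24 columns: canopy-cover percent,
mean/median/SD for four bands, and the 11 indices.

## Geometric stage

Clouds are filtered by neighborhood statistics (`filter_outliers()`): a
point is discarded when its mean distance to its 8 nearest neighbors
exceeds the cloud mean by 2 SDs; removing more than 5% of a cloud raises a
data-quality warning.

Each study-date cloud is registered onto the terrain reference by
point-to-point ICP (`icp_register()`) restricted to a rigid transform:
terrain differencing must preserve scale, and scale is already fixed by
ground control in the survey workflow. The correspondence set per iteration
discards pairs farther than 3× the median closest-point distance — an
adaptive gate against non-overlapping border points that, unlike a fixed
trimming fraction, does not bias the inlier set. Iterations stop when the
RMS changes by less than 1e-6 m (50 iterations cap); moving clouds are
deterministically subsampled to 50 000 correspondences. ICP is initialized
from tie points (`coarse_align()`, a closed-form Kabsch solve on the bar
tops), mirroring the manual ground-control picking that precedes fine
registration; from an uninitialized pose a point-to-point ICP on terrain
with meter-scale texture can lock onto the wrong relief. On matched copies
of a cloud the implementation recovers a perturbation to machine precision;
between independently sampled flights the pose error is millimeters to a
few centimeters, limited by sampling noise, which is ample for terrain
differencing (terrain slopes of a few percent convert a 2 cm horizontal
error into sub-millimeter height error).

Canopy height (`height_deviation()`) fits, for every canopy point, a
6-coefficient quadric to its 12 nearest terrain points (nearest in the
horizontal plane; 12 = twice the minimum for the fit, against noise) and
takes the height above the evaluated surface, clamped below at 0 m. The
per-point solves are batched in compiled code. Rank-deficient
neighborhoods fall back to a plane (then to the mean neighbor height) and
are flagged. Bars are excised from the terrain model within 0.2 m first —
just beyond the bar footprint; a wider hole forces the quadric to
extrapolate across the micro-relief and costs about a centimeter of bar
accuracy.

Heights are calibrated against the five bars
(`calibrate_heights()`): the estimated bar height is the median of the
height field within 0.12 m of the bar location, a constant offset
`mean(measured − estimated)` is applied, and the post-calibration mean
absolute bar residual must fall below 0.025 m — the order of agreement a
field check of this kind reports. Calibration runs after the raw deviation
and before clamping-sensitive summaries.

Canopy volume (`mesh_volume()`) triangulates the per-plot heights (2.5-D
Delaunay), applies one pass of Laplacian smoothing of vertex heights
(λ = 0.5) over the mesh edges as an anti-noise refinement, and integrates
prisms over a 0.45 m grid covering the plot footprint — the grid step a
practitioner chooses as a resolution/cost trade-off; edge cells are clipped
to the footprint and cells outside the convex hull of the support (mesh
holes) are filled from the nearest vertex (planar fill). Volume is reported
in dm³, heights in cm. Volume integrates above the *terrain*, consistent
with the deviation cloud (integrating above the plot's own minimum is the
alternative reading; it differs only by a constant times the footprint).

The growth increment between the dates is realized as per-point height
differences on the later date's support, pairing each point with its
horizontally nearest earlier-date point within 10 cm and dropping unmatched
points. Per plot and per source (first date, second date, increment) the
model features are volume, maximum height and the within-plot variation
percentages `100·SD/mean` of the grid-cell volumes and of the point heights
— 12 geometric features; mean and SD of height are kept as auxiliary
columns.

## Yield models

`assemble_feature_table()` inner-joins the two radiometric tables, the
geometric table and the yields by plot, drops auxiliary columns and any
plot with missing features (logged), and exposes exactly 60 feature
columns. `split_train_test()` withholds `round(0.15 n)` plots uniformly at
random under a fixed seed — 126 of 840.

Both regressors use 1000 trees with a maximum depth of 5. The bagged
forest is fit with `ranger` (which exposes an exact depth cap) with
`mtry = p/3`, the standard regression-forest default; the boosted trees use
`xgboost` with learning rate 0.06, subsample 0.8 and squared-error loss,
single-threaded for determinism. The depth-5 cap is applied to both
algorithms — the most literal reading of the stated setup, which mentions
the cap once across the two model descriptions. Importances are normalized
to sum to one; `feature_importance_report()` flags the minimal prefix
exceeding a cumulative threshold (default 71%).

The accuracy statistic is
`ACC = 100 − (100/n) Σ (x_pred − x_act)/x_pred` — signed relative errors
with the *predicted* value in the denominator, exactly as specified for
this analysis. Signed errors cancel, so ACC is not bounded above by 100 and
a near-unbiased model scores near 100 regardless of spread; the
absolute-value variant is therefore always reported alongside
(`acc_abs_pct`). `ablation_study()` refits on RGB-only, MSI-only and
single-date subsets under the same split and reports the test MAE change.

## Evaluation suite

`error_metrics()` reports MBE, AMBE, RMSE, the NMAD of the residuals,
signed and absolute mean percent errors, and the Nash–Sutcliffe efficiency.
The efficiency denominator uses deviations of the *measured* values from
their mean (the standard form, the one that equals 1 for a perfect
prediction); a flag switches to the variant with predicted values in the
denominator deviations, which some reports print — with that variant a
perfect prediction still scores 1 but finite-error values are not
comparable between the two forms, so neither is asserted against external
tables.

`robust_linear_fit()` fits predicted on measured yield by iteratively
reweighted least squares with Tukey bisquare weights (tuning constant
4.685), the scale re-estimated each iteration as the NMAD of the residuals,
at most 50 iterations or a 1e-8 coefficient tolerance. Externally
studentized residuals `sr_i = r_i / sqrt(MS_res(−i) (1 − h_ii))` — with
leave-one-out mean squared residual and hat-matrix leverage — are compared
to the two-tailed t quantile at α = 0.05 with `n − p − 1` degrees of
freedom; flagged points are excluded from the reported R², RMSE and NMAD of
the fit. On an ordinary least-squares fit the studentization reproduces
`rstudent()` exactly, which the tests assert.

The robust Jarque–Bera test replaces the sample SD in the moment ratios by
the MAD-based scale `J = sqrt(π/2)·mean|x − median|`:
`RJB = n/6 (m₃/J³)² + n/64 (m₄/J⁴ − 3)²`, compared to χ²(2). The constants
6 and 64 are the standard choice for this robust variant; the size and
power of the test at n = 500 are verified by simulation in the test suite.

`family_errors()` groups the per-plot absolute percent errors of the test
set by family, keeps families represented by 4–6 test plots — enough for a
stable mean without dominating the panel — and sorts ascending.

## Problem sizes and reproducibility

The package's reference synthetic study uses 840 plots (28 × 30) of
2.5 m × 4.56 m (6 rows at 0.76 m), clouds at 120 points/m², and both models
at their full 1000-tree configuration; the end-to-end run, including
generation, completes in minutes on a single core. Unit tests use smaller
fields (4–30 plots) chosen so each operation's ground truth is unambiguous
— for example, row counting is verified at 55% canopy cover, where row
stripes are cleanly separated; at the 80% cover of the main study adjacent
rows begin to close and edge lines merge, which is the same reason the row
features are excluded from the model.

All generators are deterministic given `field_spec(seed = )`: re-running
any of them with the same seed is byte-identical, and the model stage is
single-threaded with fixed seeds, so the full pipeline is reproducible end
to end.

## Known limitations

* Plot polygons are axis-aligned; rotated or hand-digitized field maps are
  out of scope.
* The ICP is point-to-point and rigid; between independently sampled noisy
  flights its horizontal accuracy is limited by surface texture, and a
  coarse tie-point initialization is required at meter-scale displacements.
* Row counting assumes row stripes parallel to the plot length and degrades
  once the canopy closes.
* The accuracy statistic's signed form can exceed 100; comparisons across
  models should use the absolute variant or the error metrics.
* Synthetic yields are independent across plots; spatial field effects and
  genotype-by-environment structure are not represented.
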