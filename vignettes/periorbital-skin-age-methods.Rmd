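---
title: "Periorbital skin age: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Periorbital skin age: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

The skin around the eyes ages visibly earlier than most of the face: it is
thin, poor in sebaceous glands, and folded constantly by the orbicularis
oculi. `periskin` turns that observation into a quantitative pipeline: seven
periorbital aging indices are extracted from image patches and landmark
geometry, combined into linear age-prediction models whose output — the
*periorbital skin age* — is then tested as a marker of disease history. This
vignette explains each stage's model, its tunable parameters, and the design
choices that were genuinely open, so that a reader can judge what the
package's passing tests do and do not establish.

```{r setup}
library(periskin)
```

## The seven indices

Three wrinkle indices (`Wb` beside the eyes, `Wu` under the eyes, `Wa` above
the inner corner), two pigmented-spot indices (`Pb`, `Pu` for the same two
regions), and two morphology indices: eye droopiness

$$M_d = H_1 - H_2,$$

the height difference between the medial and lateral canthus (heights
measured image-up, so a drooping outer corner increases $M_d$), and temporal
width

$$M_w = \frac{L_2 + L_3}{L_1},$$

the summed distances from each outer canthus to its same-side facial
outline, normalized by the facial width $L_1$ so the index is invariant to
face size. Every index is reported on a 0–100 scale. Left and right regions
are scored separately and averaged when a single per-subject value is
needed.

Two open geometric conventions had to be fixed. Heights are measured
upward from the bottom of the image (`height = image_height - y` with the
usual top-left pixel origin), which gives $M_d$ the sign meaning "larger =
droopier". $L_2$ and $L_3$ are measured horizontally at the canthus height
against the outline polyline interpolated at that height, and $L_1$ is taken
between the two outline interpolations at the mid-canthus height; any
monotone outline parameterization would do, and the tests only rely on the
documented one.

## Wrinkle detection

A wrinkle is a dark elongated intensity valley. The detector computes, at
each smoothing scale $\sigma$, the scale-normalized Hessian (second
derivatives of the Gaussian-smoothed image multiplied by $\sigma^2$) and its
eigenvalues $|\lambda_1| \le |\lambda_2|$. A dark ridge has $\lambda_2 > 0$
large and $|\lambda_1|$ small; the response combines a blob-suppression term
$\exp(-(\lambda_1/\lambda_2)^2 / 2\beta^2)$ with a structure-magnitude term
$1 - \exp(-S^2/2c^2)$, where $S$ is the Hessian Frobenius norm. Pixels with
the wrong ridge polarity are zeroed and the map is the maximum over scales,
rescaled to $[0, 1]$.

Parameters and defaults:

* `scales` (px): `c(1.5, 3)`. A furrow of width $w$ is matched by
  $\sigma \approx w/2$; the defaults cover the 3–6 px furrows the synthetic
  fixtures draw.
* `beta`: 0.5, the conventional blob-suppression weight.
* $c$: half the per-scale maximum of $S$, recomputed per image, so the
  magnitude term adapts to contrast. A structureless image has $S \equiv 0$
  and, by explicit guard, a zero response map.

The second-derivative Gaussian kernel is mean-subtracted so its taps sum to
exactly zero; without this, an intensity offset leaks into the discrete
Hessian and the response is no longer exactly invariant to adding a
constant to the image — an invariance the test suite asserts to
$10^{-10}$.

## FFT enhancement

The response map is Fourier transformed; coefficients outside a radial
wavelength band are zeroed, in-band coefficients whose magnitude falls below
a percentile gate are zeroed, and the map is inverse transformed, clipped to
be non-negative and min–max rescaled (a constant map rescales to zero). The
DC coefficient is always retained so the mean level survives the round
trip — this is what makes a pure in-band sinusoid reconstruct exactly (up to
the affine rescale) while a stop-band checkerboard is annihilated.

The band deserves comment, because the obvious default is wrong. A
band of "plausible wrinkle widths" (say 2–16 px) cuts the long-wavelength
envelope that a coherent furrow carries *along its axis*, and cutting
harmonics near the patch scale spreads broad halo artifacts over sparsely
occupied maps; both effects measurably degraded overlap with ground-truth
masks during development. Since the ridge response entering this step is
already background-free (the Hessian removes constant and linear trends),
long-wavelength suppression is redundant. The defaults are therefore
`wavelengths = c(2, 128)` — at typical patch sizes only pixel-scale noise is
cut — with a 90th-`percentile` magnitude gate carrying the denoising:
coherent ridge energy concentrates in few strong coefficients, speckle
spreads thinly across many weak ones.

## Scores and calibration

The "area detected as wrinkles" is the fraction of enhanced-map pixels above
a binarization threshold, fixed at 0.2 of the map maximum; the monotonicity
tests are run at 0.1, 0.2 and 0.3 to show the choice is not load-bearing.
The spot scorer estimates the background skin tone by large-kernel Gaussian
smoothing (the kernel is clamped to fit the patch), marks pixels darker than
background by more than 15 intensity units, and keeps connected components
whose equivalent radius lies in 1.5–8 px with bounded elongation. It
reproduces the *interface* of a device-measured 0–100 spot severity — an
area-based score — not any particular instrument's algorithm.

Raw area fractions are mapped to 0–100 by an affine map between reference
bounds set to the 1st/99th percentiles of a calibration cohort of at least
30 patches (percentiles rather than min–max, to resist outliers), then
clipped. Bounds persist to JSON with 17 significant digits so reloaded
calibrations reproduce scores bit-exactly. The same percentile-bounds
normalization is applied to the raw morphology values; with bounds at the
0th/100th percentiles the map is strictly affine and preserves Pearson
correlations exactly, which is how the correlation-invariance test is run —
the default 1st/99th bounds clip about 2% of values and trade that
exactness for robustness.

## The synthetic cohort

No subject-level data ship with the package; the generator creates cohorts
with the statistical structure the analysis assumes, at the study design:
five 10-year decades spanning ages 20–69, 400 subjects per decade in the
build design ($n = 2{,}000$) and 103 per decade in the validation design
($n = 515$), ages uniform within decade.

Each index is generated from a single age factor,

$$x_i = r_i\,z + \sqrt{1 - r_i^2}\,\varepsilon_i,$$

with $z$ the within-cohort age z-score, $\varepsilon_i$ independent standard
Gaussian noise, and the $r_i$ set to the correlation structure the analysis
is calibrated to: 0.588, 0.603, 0.584 for the three wrinkle indices, 0.723
and 0.758 for the two spot indices, 0.174 and 0.518 for droopiness and
temporal width. The latent value is mapped affinely from $\pm 4$ SD onto
$[0, 100]$ and clipped; clipping at four standard deviations is rare enough
not to move the realized correlations materially (the generator's own test
requires the realized $r$ within $\pm 0.03$ of target at $n = 2{,}000$).

Features are **conditionally independent given age**. Real skin indices
surely share non-age variance (lighting, skin phototype, measurement
artifacts); the package makes the independence assumption deliberately,
because it buys a closed-form oracle (below) and because only marginal
age correlations are available as calibration targets. Passing tests
therefore validate the estimation machinery, not the claim that real
periorbital indices are conditionally independent.

Disease flags follow per-disease logistic models in age,
$\operatorname{logit} P(D_j) = a_j + b_j(\text{age} - 45)$. Intercepts put
prevalence in the 2–20% range at the mean age; slopes are positive
(0.06–0.09 per year) for the five conditions modeled as age-linked
(hypertension, hyperlipidemia, fatty liver, kidney disease, diabetes) and
zero for heart disease and cancer, which are modeled as age-independent —
prevalences and slopes are stated assumptions of the generator, not
published facts. `D0` is the union of `D1`–`D7`. Lifestyle covariates
(log-normal sun-exposure hours, ordinal sunscreen frequency, 6% smoking)
are generated independent of everything, so covariate-adjusted analyses
exercise the machinery without asserting a particular confounding
structure.

Synthetic image patches place sinusoidal wrinkle polylines (Gaussian
cross-section of standard deviation width/2) and soft-edged dark ellipses
inside landmark-defined regions on a noisy background, and return the true
masks, curves and landmarks. Wrinkle base heights use six fixed slots
recycled by index, so under one seed the first $k$ curves are identical
whatever the requested count — the "fixed geometry" that count-monotonicity
oracles require. The images emulate geometry and contrast, not photographic
realism: no texture, pores, specular highlights, hair, or left/right
asymmetry. Detector results on them bound what the code does on clean
structure, not its performance on photographs.

## Age models

The nine models are fixed feature subsets (wrinkles only; morphology only;
spots only; the three pairwise category unions; all seven; and the two
device-only variants dropping `Wa`), each fit by OLS
($y = \beta_0 + \sum_i \beta_i x_i + \varepsilon$). Performance is the mean
Pearson $r$ between predicted and actual age over 10-fold cross-validation;
folds are a seeded simple random partition (an age-stratified option exists
but is off by default, since stratification was an open choice), assigned
in subject-id order so the result does not depend on row order. Final
equations are refit on the full build cohort, then validated on the
independent cohort.

Under the one-factor generative model the population multiple correlation
of age on a subset is available in closed form by Sherman–Morrison
inversion of the implied covariance:

$$R = \sqrt{\frac{S}{1 + S}}, \qquad S = \sum_{i}
\frac{r_i^2}{1 - r_i^2},$$

which for all seven indices gives $R = 0.904$. The acceptance suite first
verifies this formula against a 200,000-sample Monte-Carlo fit, then
requires the model-7 CV mean $r$ at $n = 2{,}000$ to match it within
$\pm 0.02$. The same formula orders the subsets: the pigmentation-bearing
models dominate the morphology-only and the two-wrinkle models, and the
tests check that the fitted pipeline reproduces this ordering across seeds.

Because all indices increase with age, they are positively correlated with
one another, and OLS on near-collinear positive predictors can flip
individual signs. Refinement iteratively removes the most-negative
coefficient and refits until all are non-negative ("double-prime" models).
Iterative refit, rather than a single pass, is used because removing one
variable can flip another's sign; the removal sequence is recorded on the
model object. Predictions are never clipped; implausible values (outside
0–120 years) warn but are reported, since silently clipping a biomarker
would bias downstream regressions.

## Disease association

For each of `D0`–`D7` the package fits logistic regressions of the flag on
chronological age and on periorbital skin age, reporting the predictor's
log-odds coefficient with a Wald p-value (Wald is the default because the
choice was open; a likelihood-ratio p is available). Benjamini–Hochberg
adjustment is applied across the eight skin-age tests — the family includes
`D0` by default, matching the reported table shape, with a
`diseases_only` option. Quasi-complete separation and single-class outcomes
raise errors with guidance rather than returning unstable estimates.

PCA of the seven binary indicators uses the correlation convention
(column-standardized 0/1 matrix); centering/scaling of binary indicators
was an open choice, and the correlation convention keeps rare diseases from
being swamped by common ones. Zero-variance columns are dropped with a
warning, and PC1's sign is fixed so its loadings sum positive, making the
PC1/skin-age correlation's sign reproducible. Note that under the default
disease model only five of seven diseases share the age factor, so the
all-loadings-same-sign property is asserted on dedicated one-factor
simulations, not on the default cohort.

## Problem sizes and numerical choices

The test and analysis scales are the study design itself where it matters
($n = 2{,}000$ build, $n = 515$ validation, $k = 10$ folds) and deliberately
small elsewhere: image fixtures are 64–160 px squares, fixture families use
a handful of seeds, the null-calibration simulation uses 500 replicates and
slope-recovery 100, and the disease-pattern rate uses 400 replicates so its
Monte-Carlo error (±0.013) is small against the 0.90 bound being tested.
Exact-identity checks (normal equations, eigendecompositions, affine
invariances) are asserted at $10^{-8}$–$10^{-12}$; detector localization at
1 px, the discretization limit. Degenerate inputs fail loudly by policy:
zero-spread calibrations, all-zero disease matrices, zero facial width and
rank-deficient designs are errors, not silent NAs.

## Known limitations

* Landmarks are inputs; the package does not detect them in photographs.
* The synthetic images omit photographic nuisance structure, so image-stage
  tests certify algorithmic correctness on clean geometry only.
* The spot scorer is an area-based stand-in defined by this package, not a
  reimplementation of any measurement device.
* Conditional independence of features given age is an assumption of the
  generator; on real data, shared non-age variance would lower the
  attainable model performance below the closed-form benchmark.
* Cohorts are cross-sectional; nothing here supports longitudinal or causal
  interpretation.
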