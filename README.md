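# periskin

Periorbital (eye-region) skin is thin, gland-poor and constantly folded by
the orbicularis oculi, so it wrinkles, sags and pigments earlier than most
facial skin — which makes it a convenient, non-invasive window on biological
aging. `periskin` implements a complete analysis chain around that idea, for
researchers in quantitative dermatology and aging biomarkers:

1. **Seven aging indices.** Wrinkles beside/under/above-inner-corner of the
   eyes (`Wb`, `Wu`, `Wa`) scored by a multi-scale Hessian-eigenvalue
   dark-ridge detector with FFT-based enhancement; pigmented spots (`Pb`,
   `Pu`) scored by a background-subtraction blob detector; and two landmark
   morphology indices — eye droopiness `Md = H1 − H2` (medial minus lateral
   canthus height) and temporal width `Mw = (L2 + L3) / L1` (outer-canthus
   to facial-outline distances over facial width). All indices are
   calibrated onto a 0–100 scale.
2. **Nine age-prediction models.** Fixed feature subsets fit by OLS
   (`y = β0 + Σ βi xi + ε`), evaluated by 10-fold cross-validation (mean
   Pearson *r* between predicted and actual age), refit on the full build
   cohort, refined by iterative removal of negative coefficients
   (collinearity-driven sign flips), and validated on an independent
   cohort. The model-7 prediction — from all seven indices — is the
   **periorbital skin age**.
3. **Disease association.** Logistic regressions of disease-history flags
   (`D0` any disease, `D1`–`D7` individual) on skin age, crude and
   covariate-adjusted, with Benjamini–Hochberg FDR control; PCA of the
   binary disease indicators and the PC1/skin-age Pearson correlation.
4. **A synthetic-data module.** Image patches with ground-truth wrinkles,
   spots and landmarks, and cohort tables with a configurable feature–age
   correlation structure (defaults: 0.588/0.603/0.584 wrinkles,
   0.723/0.758 spots, 0.174/0.518 morphology; 400 subjects per decade for
   the build design, 103 for validation). Every downstream stage is
   testable against known truth, and the one-factor design yields a
   closed-form performance benchmark `R = sqrt(S/(1+S))`,
   `S = Σ ri²/(1−ri²)`.

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(simulate → image features → models → associations), each writing tables
under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_image_features.R
Rscript analysis/03_fit_models.R
Rscript analysis/04_associations.R
```

`03_fit_models.R` prints, for each model, the cross-validated *r*, the
closed-form benchmark, and the independent-validation *r*:

```
model performance (10-fold CV / closed-form benchmark / validation):
  model 1 [Wb+Wu+Wa            ] r = 0.793 / 0.786 / 0.783
  model 2 [Md+Mw               ] r = 0.557 / 0.534 / 0.584
  model 3 [Pb+Pu               ] r = 0.838 / 0.842 / 0.828
  model 4 [Wb+Wu+Wa+Md+Mw      ] r = 0.822 / 0.818 / 0.827
  model 5 [Wb+Wu+Wa+Pb+Pu      ] r = 0.891 / 0.896 / 0.894
  model 6 [Md+Mw+Pb+Pu         ] r = 0.858 / 0.860 / 0.850
  model 7 [Wb+Wu+Wa+Md+Mw+Pb+Pu] r = 0.899 / 0.904 / 0.904
  model 8 [Wb+Wu               ] r = 0.748 / 0.724 / 0.709
  model 9 [Wb+Wu+Pb+Pu         ] r = 0.881 / 0.883 / 0.877
```

Every CV estimate tracks its analytic benchmark to ~0.02, the
pigmentation-bearing models (3, 5, 6, 7, 9) dominate the morphology-only
and wrinkle-pair models (2, 8), and validation performance matches CV —
the three properties the model stage is designed around. `04_associations.R`
then reports, on the validation cohort (n = 515):

```
disease associations (beta on skin age, FDR q):
  D0: beta = 0.084, p = 5.4e-21, q = 4.3e-20  *
  D1: beta = -0.003, p = 0.86, q = 0.86
  ...
PC1 explains 21.1% of disease-indicator variance; r(PC1, skin age) = 0.52
D0 ~ skin age: crude beta = 0.084 (p = 5.4e-21); age-adjusted -0.030 (p = 0.12)
```

The five age-linked diseases in the generator (D2–D6) come out
FDR-significant; heart disease (D1) does not, cancer (D7) is a borderline
case that varies by seed; and because the synthetic diseases depend on age
alone, age adjustment absorbs the skin-age association — the mediation
structure the generator encodes.

Directly in R, the core objects compose in a few lines:

```r
library(periskin)
build <- generate_cohort(cohort_config(n_per_decade = 400, seed = 1))
cv    <- cross_validate(build, model_catalog()$m7, k = 10, seed = 2)
m7    <- refine_model(fit_age_model(build, model_catalog()$m7), build)
val   <- generate_cohort(cohort_config(n_per_decade = 103, seed = 3))
skin  <- predict(m7, val)          # periorbital skin age, years
association_table(val, skin)       # Table of beta / p / FDR q per disease
```

## Scope

Landmarks are inputs, not detected; the synthetic images emulate geometry
and contrast, not photographic realism; and the spot scorer is an
area-based stand-in with a device-like 0–100 interface, not a
reimplementation of any instrument. See the methods vignette
(`vignettes/periorbital-skin-age-methods.Rmd`) for the models, parameter
rationale and limitations.
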