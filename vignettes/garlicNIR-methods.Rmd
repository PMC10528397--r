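---
title: "Models and design choices in garlicNIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in garlicNIR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The problem and the data model

A ground-garlic sample doped with a mass fraction $y$ (% w/w) of an
adulterant (corn flour or corn starch) yields an FT-NIR absorbance spectrum
$x \in \mathbb{R}^p$ on a wavelength grid (1000–2500 nm; the default grid
uses 2 nm spacing, $p = 751$). Under Beer–Lambert-style linear mixing the
clean spectrum is a convex combination of the two pure-component
("endmember") spectra,

$$x(y) = (1 - y/100)\, e_{\mathrm{garlic}} + (y/100)\, e_{\mathrm{adulterant}},$$

so the noiseless, scatter-free data matrix has centered rank 1 and one
latent variable recovers $y$ exactly. Real powder measurements add
per-sample multiplicative gain and additive offset (packing-density
scatter), smooth baseline drift, channel noise, and replicate-to-replicate
composition variation. The whole analysis chain exists to undo or absorb
those distortions.

A `SpectraSet` (S4, built on `SummarizedExperiment`) carries the absorbance
matrix, the strictly increasing wavelength grid, and per-sample metadata
(`sample_id`, `adulterant`, `fraction`, `replicate`, `set_label`). The
interchange format is a wide CSV with 15-significant-digit numbers, making
read/write round trips lossless at working precision.

## The concentration design

The study covers 26 adulterant levels in triplicate: 15 calibration levels
(0, 0.5, 1, 2, 3, 5, 10, 15, 20, 25, 30, 35, 50, 70, 100 % w/w; 45
samples) and 11 interleaved validation levels (2.5, 4, 7.5, 9.5, 11.5,
13.5, 17.5, 22.5, 27.5, 32.5, 60 % w/w; 33 samples). The calibration set
spans the full range; validation levels sit between calibration levels so
prediction is tested by interpolation, not extrapolation.

## Preprocessing

Every method operates per spectrum unless noted, and every data-dependent
parameter is learned on the calibration (training) set only and replayed
unchanged on other sets (`fitScheme()` / `applyScheme()`), so no validation
information leaks into model construction:

- **SNV**: $(x - \bar x)/s_x$ with the $n-1$ denominator; removes offset
  and gain per spectrum.
- **MSC**: regress $x = a + b\,r + e$ on the reference $r$ (the mean
  training spectrum) over wavelengths; correct to $(x - a)/b$. **EMSC**
  adds polynomial terms in normalized wavelength (degree 2 by default) to
  the regression and subtracts them before dividing by $b$.
- **ISC / EISC**: the inverse-direction fits ($r$ regressed on $x$, plus
  polynomial terms for EISC); the corrected spectrum is the fitted value.
  For exactly affine distortions ISC and MSC agree; their residual
  treatment differs otherwise.
- **Detrending**: subtract the least-squares polynomial (degree 2) in
  normalized wavelength; an orthogonal projection, hence idempotent.
- **Savitzky–Golay** smoothing and 1st/2nd derivatives: local
  least-squares polynomial convolution (default window 15 points,
  polynomial degree 2), delegated to `signal::sgolayfilt`, which fits
  boundary polynomials at the edges so the wavelength axis never shrinks.
  Derivatives are divided by (grid spacing)$^m$, giving AU/nm units; this
  requires — and the code enforces — a uniform grid.
- **Unit-variance scaling**: columns divided by training-set column SDs.

The default catalogue crosses an SG stage (none / smooth / 1st / 2nd
derivative), a scatter stage (none / SNV / MSC / EMSC / ISC / EISC /
detrend) and optional unit-variance scaling, in that order:
$4 \times 7 \times 2 = 56$ schemes, the raw-spectra scheme included. The
composition rule (derivative before scatter correction before scaling) is
one defensible convention among several in chemometric practice; the
catalogue is fully configurable through `buildCatalogue()` and the count is
asserted in tests rather than hard-coded anywhere.

## Calibration models

Both models first column-center $X$ and $y$ (centering inside the model,
scaling only ever as a preprocessing step, keeps the 56-scheme search
well-defined):

- **PCR** regresses the centered response on the first $f$ principal
  component scores (SVD-based) and folds the coefficients back to
  wavelength space.
- **PLSR** uses NIPALS PLS1 with X-deflation only (y-deflation is redundant
  for a univariate response): $w_k \propto X_k^\top y$ (unit norm),
  $t_k = X_k w_k$, $p_k = X_k^\top t_k / t_k^\top t_k$,
  $q_k = y^\top t_k / t_k^\top t_k$; $\beta = W(P^\top W)^{-1}q$. If the
  residual covariance vanishes ($\|X_k^\top y\| < 10^{-14}$) the
  decomposition stops early with a warning and $f$ is reduced.

At full rank both coincide with ordinary least squares (a test asserts
agreement to $10^{-8}$ against the normal equations, and an independent
PLS implementation serves as a cross-check). PCA loadings carry a
deterministic sign convention (largest-magnitude element positive) so score
plots reproduce across platforms.

Figures of merit: RMSEC/RMSEP, $R^2 = 1 - SS_{res}/SS_{tot}$ (not a squared
correlation, so bias is penalized), and RMSEP as a percentage of the
calibration range. Complexity can be selected by leave-one-out
cross-validation with a 2 % parsimony tolerance (smallest $f$ within 2 % of
the RMSECV minimum) — the tolerance is exposed because no sharper rule is
canonical.

## The exhaustive search and the selection rule

`gridSearch()` refits each scheme on the calibration set, applies it to the
validation set, and scores every $(scheme, kind, f)$ triple — 840 models
per method with the defaults, 1680 in total; one latent decomposition per
scheme yields the whole $f$-path, and failures are recorded per row rather
than aborting the grid. `selectOptimal()` formalizes "smallest and most
comparable errors with fewest latent variables": rows must satisfy
$|RMSEP - RMSEC| \le 0.25\,\min(RMSEC, RMSEP)$ (tolerance configurable;
the published account of comparability is qualitative, so 25 % is a
documented default), then ranking is lexicographic by
$(RMSEP, f, RMSEC, scheme, kind)$, which also makes the choice invariant
to row order.

## Discrimination and its Monte Carlo validation

PLS-DA fits PLSR to a class code ($-1$/$+1$, alphabetical label order) and
assigns by sign, ties to $+1$; no priors are used because the groups are
balanced by design. Uncertainty is estimated by the resampling protocol of
the discrimination study: a model set of 50 samples per group and a fixed
external validation set of 25 per group; at each of 500 iterations, 35 per
group are drawn without replacement for training and the remaining 15 form
an internal test set; CCR, sensitivity and specificity (in %) are
aggregated as mean ± SD ($n-1$) per set. The complexity curve selects the
$f$ maximizing mean internal-test CCR (ties to the smallest $f$) — the
external set deliberately plays no role in selection.

## One-class detection

OC-PLS builds a latent decomposition of the target-class spectra alone and
accepts a sample only if two statistics both stay under their thresholds:
the Mahalanobis score distance
$d_i^2 = \sum_k (t_{ik} - \bar t_k)^2 / s_k^2$ (NIPALS scores are
orthogonal, so a diagonal covariance is exact on the training set) against
the Hotelling-type limit $\frac{f(n^2-1)}{n(n-f)} F_{1-\alpha/2}(f, n-f)$,
and the squared reconstruction residual $q_i = \|x_i - t_i P^\top\|^2$
against the Box approximation $g\,\chi^2_h(1-\alpha/2)$ with
$g = v/2m$, $h = 2m^2/v$ ($m, v$ the training mean and variance of $q$).
The nominal false-rejection rate $\alpha$ (default 0.05) is split evenly
between the two rules; requiring both reflects that score-space and
residual-space departures are different failure modes.

One modeling point deserves emphasis: a PLS decomposition of
*column-centered* spectra against a constant response is degenerate —
$X^\top \mathbf{1} = 0$ exactly after centering — so the decomposition here
follows the standard one-class PLS formulation with uncentered $X$ and unit
response; the first component absorbs the class mean and the score
statistics are taken about the training score means.

The threshold calibration assumes approximately Gaussian scores and a
well-behaved residual distribution. The package therefore verifies nominal
acceptance on 200 replicate simulations of a *fixed* mixture (Gaussian
variability by construction); the full concentration design is strongly
non-Gaussian in score space (scores track the skewed level layout) and is
not a calibration test of the thresholds.

## The synthetic generator: what it emulates, what it does not

Endmembers are sums of Gaussian absorption bands on a rising linear
baseline, with band centers at each powder's characteristic
overtone/combination positions (garlic ≈ 1160, 1450, 1725, 1930, 2100,
2235, 2325 nm; corn flour ≈ 1445, 1725, 1930, 2100, 2280 nm; corn starch
sharing the carbohydrate bands 1445/1930/2225 nm with distinct amplitudes
and a systematically lower level above 1400 nm). Amplitudes and widths are
illustrative defaults — no public spectra exist to fit them to — and are
documented in `garlicEndmember()` and friends; they must not be read as
quantitative reproductions of any measured spectrum.

Measurement effects are $x' = a + b\,x + d\,\lambda_{norm} + \varepsilon$
with $b = e^{N(0, 0.05^2)}$ (≈5 % scatter gain), $a \sim N(0, 0.02^2)$ AU
offset, $d \sim N(0, 0.005^2)$ AU drift, and $\varepsilon$ i.i.d.
$N(0, (2\times10^{-4})^2)$ AU channel noise — the last consistent with
scan-averaged FT-NIR. Replicates perturb band amplitudes with 1 % relative
Gaussian noise, so triplicates share smooth structure the way repacked
powders do. Each sample draws from a seed substream derived from the master
seed and its design index, so simulations are pure functions of their
arguments and adding samples never perturbs earlier draws.

Not emulated: Kubelka–Munk/radiative-transfer scattering physics,
instrument line shape, wavelength-correlated (pink) noise, moisture
effects, and nonlinear detector response. Consequently, passing tests on
synthetic data demonstrate the correctness and internal consistency of the
algorithms under the stated noise model — not instrument-level performance
on real powders.

### Separability of the discrimination classes

Under the default noise levels the *full* 25-level two-adulterant design is
not linearly separable: at sub-percent doping the class signal (fraction ×
flour/starch endmember difference) is far smaller than replicate
variability, and no preprocessing can recreate information that is absent.
The Monte Carlo protocol is therefore verified on a constructed separable
scenario (`simulateSeparableClasses()`: doping levels 20–50 % w/w, 75
samples per group, 50/25 model/validation split), where the between-class
difference dominates within-class variation by an order of magnitude — the
regime in which perfect discrimination is the correct expected outcome.
The non-separable full design remains available
(`simulateDiscriminationStudy()`) and is used to test distribution-free
properties (e.g., CCR bounded by sensitivity and specificity).

## Numerical choices and degenerate inputs

- SDs use the $n-1$ denominator throughout.
- SNV, MSC, ISC and unit-variance scaling reject constant spectra/columns
  as degenerate rather than dividing by zero; MSC/ISC/EISC fits with
  $|b| < 10^{-12}$ are errors.
- Rank-deficient EMSC/EISC designs (reference collinear with the
  polynomial) are errors.
- PCR treats singular values below $10^{-12}$ of the largest as zero.
- Ties: PLS-DA scores exactly at the threshold go to $+1$; equal-RMSEP
  search rows go to the smaller $f$; equal internal-test CCR goes to the
  smaller $f$.
- All Monte Carlo machinery restores the caller's RNG state and is
  bit-reproducible given a seed.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on small grids (typically 60 wavelengths, a few
dozen samples). The acceptance script and end-to-end tests use the full
default conditions: 751 wavelengths, the 45 + 33 design, the 56-scheme ×
15-complexity grid for both methods and both adulterants, a 25-seed
repeat of the preprocessing-vs-raw comparison, the 500-iteration Monte
Carlo protocol, and $n = 200$ for the one-class acceptance check. These
sizes are the study's stated conditions where it states them and the
package's documented choices where it does not.

## Known limitations

- The linear mixing assumption ignores particle-size and packing effects
  that make real powder mixtures mildly nonlinear in mass fraction.
- The selection rule among near-tied preprocessing schemes is one
  formalization of a qualitative criterion; a different defensible rule may
  pick a different near-optimal scheme.
- OC-PLS thresholds are asymptotic approximations; at small $n$ or heavily
  skewed training designs the realized false-rejection rate can drift from
  $\alpha$ (see the separability and Gaussianity remarks above).
- Only binary garlic/adulterant mixtures and two adulterant classes are in
  scope; multi-class soft classification (e.g., SIMCA-style families) is
  not implemented.
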