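---
title: "Validating knowledge-based DVH predictions with a reference cohort"
author: "dvhqa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating knowledge-based DVH predictions with a reference cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvhqa)
```

## The problem

Knowledge-based planning (KBP) systems predict the achievable dose-volume
histogram (DVH) of an organ at risk (OAR) for a new radiotherapy patient from
a library of prior treatment plans. Before such predictions can drive
clinical decisions — accept a plan, or push for more sparing — two questions
must be answered for the local practice:

1. **Accuracy.** How far do predictions sit from the clinically accepted
   DVHs, as a function of dose?
2. **Interpretability of the error band.** If a model ships its own
   lower/upper DVH error bounds, what fraction of clinical DVHs actually
   falls inside them — is the band a standard deviation, an interquartile
   range, or something else?

`dvhqa` implements a model-independent answer: compare predicted to clinical
DVHs across a reference cohort, summarize the dosewise errors, and measure
the empirical coverage of any candidate error band.

## The statistics

All DVHs are cumulative and normalized: dose in % of prescription (Rx) dose,
volume in % of OAR volume. For plan $i$ the prediction error at dose $D$ is

$$e_i(D) = V_{\mathrm{clin},i}(D) - V_{\mathrm{pred},i}(D),$$

so $e_i > 0$ means the model *under*predicted the dose to the organ and
$e_i < 0$ means it *over*predicted. Across $N$ plans, per dose point:

* **bias** $\mu(D) = \overline{e_i(D)}$,
* **error variation** $\sigma(D)$, the sample standard deviation
  ($N-1$ denominator),
* **root-mean-square error**
  $\mathrm{RMSE}_{\mathrm{pred}}(D) = \sqrt{\tfrac1N \sum_i e_i(D)^2}
  \simeq \sqrt{\sigma^2 + \mu^2}.$

The quadrature relation is *exact* when the population ($N$ denominator)
standard deviation is used; with the sample SD the deficit is exactly
$\sigma^2/N$, bounded by $\sigma^2/(N-1)$ — hence the $\simeq$. The package
reports both SDs: figures and exports default to the sample SD, while
`quadratureCheck()` verifies the exact identity with the population SD and
bounds the sample-SD residual. For a single-plan cohort $\sigma$ is reported
as missing rather than zero; a silent zero would fake certainty.

When $\mu \approx 0$, $\mathrm{RMSE}_{\mathrm{pred}}$ behaves as a canonical
standard deviation of the prediction error, so the band
$V_{\mathrm{pred}} \pm \mathrm{RMSE}_{\mathrm{pred}}$ should contain about
68% of normally distributed clinical DVHs.

## Band formalisms and their expected coverage

`dvhqa` constructs four bands (all clipped to $[0, 100]$, never
re-monotonized — the coverage tally is pointwise and re-monotonizing would
silently change it):

| kind | construction | scope | Gaussian coverage |
|---|---|---|---|
| `rmse` | $V_{\mathrm{pred},i} \pm \mathrm{RMSE}_{\mathrm{pred}}(D)$ | per plan | $2\Phi(1)-1 = 68.3\%$ |
| `iqr` | 25th–75th percentile of the clinical DVHs | cohort | $50\%$ |
| `median_split` | mean clinical DVH of the [min, median] and [median, max] feature halves | cohort | $2\Phi(\sqrt{2/\pi})-1 = 57.5\%$ |
| `model_provided` | model's own bounds, ingested and integrity-checked | per plan | whatever it is — that is the question |

The median-split band generalizes the construction used by a web-based KBP
platform that splits its training plans at the median of an anatomy feature
and derives one bound DVH from each half. With an odd cohort the median plan
joins *both* halves (the inclusive [min, median] / [median, max] reading),
and the bound orientation is resolved pointwise — at each dose the upper
bound is the larger half-mean — because the feature/DVH correlation can flip
sign along the dose axis. In the self-matching limit (feature = the dosewise
value itself, `pointwise = TRUE`) each half-mean tends to the mean of a
half-normal, $\pm\sqrt{2/\pi}\,\sigma \approx \pm 0.798\sigma$, giving the
$57.5\%$ entry above and placing this formalism strictly between an IQR and
a one-sigma band. The exact construction of the original platform's bound
DVHs is not public; the half-mean is this package's explicit approximation,
not a claimed equivalence.

## The tally rule

A clinical value is tallied as correctly predicted at dose $D$ when it lies
inside the band **or** strictly within 0.5% of OAR volume of the prediction
itself — differences below clinical dose-volume granularity should not count
as failures. Two deliberate details: the comparison is strict (`<`), and the
distance is measured to the *prediction*, not to the nearer band edge. The
tolerance defaults to 0.5% and is set to 0 for calibration experiments so
the closed forms above apply. The per-dose success fractions form the
coverage curve, smoothed by an 11-point centered boxcar; at the series edges
the window shrinks symmetrically rather than padding, so no data are
invented.

The tally is per dose point across plans — the coverage curve is a function
of dose. `coverageSummary()` offers min/max/mean over a dose range; both raw
and smoothed curves are exported since summary ranges can be computed from
either.

## The synthetic cohort generator

No institutional cohort ships with the package, so every claim is tested on
simulated cohorts with known ground truth. Plans are sigmoid DVHs
$V(D) = 100\, s(D)/s(0)$, $s(D) = 1/(1+e^{(D-d_{50})/k})$, normalized so
$V(0)=100$ exactly; each plan draws $d_{50} \sim N(55, 6)$ % Rx with slope
$k = 22$ % Rx, and the drawn $d_{50}$ doubles as the plan's matching
feature. Defaults: 45 plans (a typical validation-set size), grid 0–110% Rx
in 1% steps, zero injected bias, 3% volume spread — the scale of reported
prostate OAR prediction errors.

Two error modes exist because additive pointwise noise breaks DVH
monotonicity:

* **pointwise** (default): clinical = predicted + bias$(D)$ +
  $N(0,\mathrm{spread}(D)^2)$ independently per dose point, clipped to
  $[0,100]$. Dosewise errors are *exactly* Gaussian — the mode in which the
  68%/50%/57.5% calibrations are literally true — at the price of curve
  monotonicity, which is waived and flagged in the cohort metadata. No noise
  is added at dose 0, preserving $V(0)=100$.
* **parametric**: clinical is itself a valid sigmoid with midpoint shifted
  by $N(\mathrm{shiftMean}, \mathrm{shiftSD}^2)$ % Rx; errors are only
  approximately Gaussian mid-dose (checked by a Shapiro–Wilk sanity test in
  `truthReport()` at $\alpha = 0.01$). This mode feeds end-to-end pipeline
  tests with physically valid curves.

The broad sigmoid defaults keep predicted volumes well inside $[0,100]$ over
the 20–90% Rx *interior* range, where clipping probability is negligible;
calibration and parameter-recovery checks are evaluated there, because at
the dose extremes clipping necessarily distorts a Gaussian error
distribution. What passing calibration shows is therefore that the tally,
band constructions and statistics are correct *under the generator's
assumptions* — it does not show that real clinical errors are Gaussian,
independent across dose, or free of the inter-plan correlation structure
real anatomy induces. On real cohorts the coverage curve is the measurement,
not a known constant.

Reproducibility: one named generator discipline (Mersenne-Twister with
inversion normals) seeded explicitly; the same seed reproduces a cohort bit
for bit.

## Numerical and design choices

* **Dose grid**: analysis runs on a common 0–110% Rx grid in 1% steps by
  default; the grid resolution is a free parameter of the method. Curves are
  resampled by linear interpolation (cumulative DVHs are piecewise smooth);
  grid doses beyond a curve's maximum tabulated dose map to volume 0, below
  its minimum to 100.
* **Validation**: curves must be non-increasing, within $[0,100]$, with
  $V(0)=100$ within $10^{-6}$; inputs may be rescaled on request
  (`renormalize = TRUE`). Duplicate doses keep the last tabulated row, with
  a warning.
* **Percentiles**: linear interpolation between order statistics
  (`quantile()` type 7, the common default); the hand-checkable case
  $\{1,2,3,4\} \to Q_1 = 1.75, Q_3 = 3.25$ is frozen in the tests.
* **Degenerate median split**: if all feature values coincide the split is
  formed by stable plan order, with a warning.
* **Simulation sizes**: calibration runs use 2000 plans (Monte-Carlo error
  on a mean interior coverage ≈ 0.1 percentage points, comfortably inside
  the ±2-point acceptance window) and parameter recovery uses 500 plans;
  both complete in seconds.

## A worked calibration

```{r calibration}
cal <- runCalibration(n = 2000, spread = 3, seed = 1)
cal$table
```

The observed mean interior coverages reproduce the closed-form ladder:
IQR ≈ 50% < median-split ≈ 57.5% < one-sigma ≈ 68.3%. An analyst applying
the same machinery to a real cohort would instead read where a *model's*
provided band lands on this ladder, and interpret it accordingly: a band
covering ~50% behaves like an IQR and flags likely attainable sparing more
aggressively than a one-sigma band.

## Limitations

* Dosewise errors on real cohorts are correlated across dose and across
  plans sharing anatomy; the generator's pointwise mode deliberately ignores
  this, and the parametric mode captures only a one-parameter family of
  deformations.
* Differential DVHs, absolute-volume (cc) DVHs and DICOM RT-DOSE/RT-STRUCT
  ingestion are out of scope; input is the long-format table of
  already-computed cumulative DVHs.
* No confidence intervals are attached to $\mu$, $\sigma$ or
  $\mathrm{RMSE}_{\mathrm{pred}}$ themselves, and no formal test compares
  two coverage curves; the methodology is descriptive.
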