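---
title: "Methods: cosinor modelling of seasonal mtDNA abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cosinor modelling of seasonal mtDNA abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcosinor)
```

## The phenomenon and the model

Relative mitochondrial DNA (mtDNA) abundance in blood, proxied by the
off-target mitochondrial coverage of exome sequencing divided by total
mapped reads, oscillates across the calendar year with a winter peak.
Each individual contributes a single measurement taken at recruitment,
so the seasonal signal is identified *across* individuals recruited in
different months — a cross-sectional, not longitudinal, design.

With month $m \in \{1,\dots,12\}$ and $\theta = 2\pi(m-1)/12$, the
single-harmonic cosinor model is

$$y = \beta_0 + \beta_2\cos\theta + \beta_3\sin\theta + \textstyle\sum_i
\beta_i C_i + \varepsilon,$$

whose seasonal part equals $A\cos(\theta-\varphi)$ with amplitude
$A=\sqrt{\beta_2^2+\beta_3^2}$ and acrophase
$\varphi=\operatorname{atan2}(\beta_3,\beta_2)$. January sits at phase
zero, so the peak falls $1 + 12\varphi/2\pi$ months into the year and
the trough half a year later. A wave of amplitude $A$ on a
unit-variance outcome explains $A^2/2$ of the variance — about 0.4% at
$A = 0.092$ SD — so the effect is small and every design choice below
is driven by the need for calibrated inference on small signals.

### Assumptions

* one measurement per person; between-person seasonal comparison;
* a single annual harmonic (no semi-annual term);
* month-level time resolution (a continuous day-of-year mode would be a
  straightforward extension, but month of recruitment is the recorded
  variable, so months are the default and the only mode implemented);
* homoskedastic errors by default (see *Covariance choice*).

## Delta-method inference

SEs for $A$ and $\varphi$ propagate the OLS coefficient covariance
$\Sigma$ through the transforms to first order:
gradients $(\beta_2/A,\ \beta_3/A)$ and $(-\beta_3/A^2,\ \beta_2/A^2)$
over the $2\times2$ sub-covariance. Estimate/SE is treated as a
standard-normal T-score for CIs and P-values; with the sample sizes in
scope ($n$ in the hundreds and above) the normal-vs-$t$ difference is
negligible (at $n=200$, the 97.5% quantiles differ by under 1%).

Two numerical hazards are handled explicitly:

* **Degeneracy at the origin.** $A \mapsto \sqrt{\cdot}$ is
  non-differentiable at 0; near it the delta-method SE is biased. We
  flag results with $A < 3\max(\mathrm{se}_{\beta_2},
  \mathrm{se}_{\beta_3})$ and always report the joint 2-df Wald test of
  $(\beta_2,\beta_3)=(0,0)$, which remains exact-rate under the null.
* **Quadrant ambiguity.** A single-argument $\arctan(\beta_3/\beta_2)$
  cannot distinguish opposite quadrants. We use the four-quadrant
  `atan2`, which agrees with the single-argument form whenever
  $\beta_2>0$ (the winter-peak regime) and is correct elsewhere.

## Marker interactions

Effect modification by a marker $M$ uses

$$y = \beta_0 + \beta_1 M + \beta_2\cos\theta + \beta_3\sin\theta +
\beta_4 M\cos\theta + \beta_5 M\sin\theta + \textstyle\sum_i \beta_i
C_i,$$

with three reported contrasts per marker (binary exposure or per unit of
a linear marker):

* **$\Delta$amplitude** (default, *exact difference*):
  $\sqrt{(\beta_2+\beta_4)^2+(\beta_3+\beta_5)^2} -
  \sqrt{\beta_2^2+\beta_3^2}$. This form is signed — a marker can
  *lower* the amplitude — which the naive unsigned
  $\sqrt{\beta_4^2+\beta_5^2}$ cannot express; that is why the exact
  difference is the default. The first-order projection
  $(\beta_2\beta_4+\beta_3\beta_5)/A$ is available as
  `method = "linearized"`; the two agree to first order in the
  interaction effects (property-tested on a shrinking-effect sequence).
* **$\Delta$acrophase**: wrapped difference of the two `atan2` phases,
  in $(-\pi,\pi]$, reported in months ($\times 12/2\pi$, so wrapped to
  $(-6, 6]$) and as "percent of a month" ($100\times$ the month value).
* **displacement**: the marginal effect $\beta_1$ (the MESOR shift).

All SEs use the full 4-dimensional gradient over the
$(\beta_2,\beta_3,\beta_4,\beta_5)$ sub-covariance; the displacement SE
comes directly from $\beta_1$. The percent-amplitude scale divides by a
reference amplitude: by default the same model's baseline
$\sqrt{\beta_2^2+\beta_3^2}$, or a fixed external value (the overall
maximal amplitude, 0.091 SD, is the conventional reference) supplied
via `reference_amplitude`.

Scans (`run_scan`) fit one model per marker. Multiplicity control is
either Bonferroni over $3m$ tests (three characteristics times $m$
markers — the disease-scan convention: 640 diseases give 1,920 tests)
or a fixed raw-P threshold (the lab-marker and protein conventions,
$0.05/379$ and $0.05/2923$). The blood-cell mode (`mutual_adjust`)
enters all panel markers as main effects while interacting one at a
time. For protein-style panels, the first `marker_pcs` principal
components of the standardized marker matrix are appended as
covariates. `lambda_gc` (median implied $\chi^2_1$ over 0.4549) and
`zscore_correlations` are the calibration diagnostics.

## Abundance quantification and QC

`normalized_mtdna_ratio` is mitochondrial mean coverage over total
mapped reads. QC excludes samples farther than $k\times$IQR from the
median ($k=4$ by default), computed in a **single pass** on the full
input: the median and IQR are not recomputed after exclusion, so
re-running the filter on the kept set is a different (narrower)
operation — tested, not silently iterated. Quartiles use linear
interpolation between order statistics (R type 7); the convention is
recorded because the brute-force test oracle must share it. With
IQR = 0 the rule is applied literally (keep only values equal to the
median) with a warning. Standardization to mean 0 / SD 1 happens
*after* exclusion, so "SD units" always refers to the QC-passed
analysis set; the order is fixed in the pipeline driver and
configurable only by calling the pieces directly.

## Covariate derivation

Binary lifestyle codings put missingness in the reference category
(ever-smoked vs never-or-missing, >3 drinks/week vs less-or-missing,
below the activity recommendation vs meets-or-missing, degree vs
none-or-missing). Pack-years are 0 for never-smokers and group-median
imputed within past/current smokers; BMI and eGFR are median-imputed,
medians taken from the analysis sample before modelling. eGFR uses the
2009 CKD-EPI creatinine equation (µmol/L ÷ 88.42 → mg/dL; female
$\kappa=0.7,\alpha=-0.329$, scale 144; male $\kappa=0.9,\alpha=-0.411$,
scale 141; $0.993^{\text{age}}$; exponent $-1.209$ above $\kappa$) with
the race coefficient fixed at 1, appropriate for the European-ancestry
analysis sets this package targets. The frailty index is
$100\times$ (reported ailments)/(items queried); the item count $Q$ is
a parameter because questionnaires differ. Omics panels are imputed
(per-marker mean by default; an iterative truncated-SVD low-rank
imputer approximates PCA-based imputation without extra dependencies),
log2-transformed and unit-scaled per marker.

## The synthetic cohort: what it emulates, and what not

The generator writes down the stated world explicitly:

$$y_i = \beta_0 + \textstyle\sum_c \beta_c C_{ic} + \sum_m M_{im} d_m +
b_{2,i}\cos\theta_i + b_{3,i}\sin\theta_i + \varepsilon_i,\quad
\varepsilon_i \sim N(0, \sigma^2),$$

with $(b_{2,i}, b_{3,i})$ the baseline $(A\cos\varphi, A\sin\varphi)$
plus, per exposure, the additive shift that carries $(A,\varphi)$ to
exactly $(A+\Delta A, \varphi+\Delta\varphi)$ in the exposed. Because
the shift is additive on the coefficient vector, the data are *exactly*
representable by the interaction regression — noiseless recovery is an
exact test, and the truth record's $\beta$ values are the estimands,
not approximations. Configurations whose exposed-group amplitude would
be negative are rejected at validation time.

Defaults are the stated world, chosen once:

* amplitude 0.092 SD, acrophase −0.14 rad, residual SD 1 — the
  reported overall pattern on a standardized outcome;
* recruitment months uniform (the per-month recruitment distribution is
  not published beyond per-month sample sizes; weights are
  configurable);
* covariate moments from the published cohort table (age 56.92 (8.00),
  BMI 27.41 (4.69), male 46%, ever-smoked 45.6%, risky alcohol 48.7%,
  low activity 14.7%, degree 30.7%, frailty 11.78 (6.70), eGFR
  90.36 (13.28)), with null effects on the outcome so the seasonal
  parameters are the whole signal unless a `beta` is set;
* disease/death status assigned *first*, cases then given a different
  amplitude — mirroring the analysis direction (status as exposure,
  abundance as outcome); the published contrasts (e.g. cardiovascular
  amplitude ratio 0.835, death 0.772) are natural test settings;
* all-cause death rate 6.5% — not published; chosen as a realistic
  middle-aged-cohort mortality over a ~7.8-year median follow-up;
  follow-up uniform on 0.01–15.5 years (the published range);
* coverage: total mapped reads log-normal around $4\times10^7$
  (sd-log 0.15, typical exome depth variation), latent abundance
  $1.65\times10^{-8}\,e^{0.2 z}$ so mean mitochondrial coverage is
  ~0.66X, times log-normal measurement noise (sd-log 0.05).

What the generator does **not** emulate: linkage structure among
genotype dosages, realistic disease co-occurrence, survival-time hazard
structure (death is a Bernoulli label, follow-up is independent),
geography/latitude effects, or batch structure in coverage. A green
recovery test therefore establishes correctness of the estimator under
the model's own assumptions, not robustness to violations of them.

All randomness descends from a single seed through named per-module
sub-streams, so cohort and coverage generation are independently
reproducible.

## Numerical and design choices

* **Covariance choice.** Classical homoskedastic OLS covariance by
  default; HC1 sandwich by `robust = TRUE`. The source analyses do not
  state which was used; the default favours comparability with standard
  `lm` output, and bootstrap agreement is part of the acceptance suite.
* **Rank deficiency** errors immediately, naming the collinear columns:
  a silently dropped interaction column would corrupt the transforms.
* **Wrapping.** Acrophase differences wrap to $(-\pi,\pi]$ (months:
  $(-6,6]$); a marker cannot shift the phase by more than half a year
  by definition of the contrast.
* **Ties / degenerate inputs.** Zero-variance outcomes, constant
  markers, empty marker tables, zero IQR and zero amplitude all raise
  typed errors or flagged results rather than NaNs.
* **Two printed reference amplitudes.** The overall amplitude is
  printed as 0.092 in the text and 0.091 as the normalization constant;
  the package treats the reference as a parameter
  (`reference_amplitude`) rather than adjudicating.

## Limitations

Single harmonic only; month-resolution phase; linear models throughout
(disease and death enter as exposures in a linear model of abundance —
no logistic or Cox layer); no genome-scale optimizations for dosage
scans (the same machinery runs at toy scale); delta-method CIs are
first-order and degrade near zero amplitude, where only the joint test
should be interpreted.
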