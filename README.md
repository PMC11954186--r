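# mtcosinor

Seasonal cosinor analysis of mitochondrial DNA abundance.

## The problem

The amount of mitochondrial DNA (mtDNA) in circulating blood cells — a
proxy for mitochondrial abundance and function — can be quantified from
the off-target reads of exome sequencing: the mean fold-coverage of the
mitochondrial genome divided by the total number of mapped reads. This
relative abundance is not constant across the year: it oscillates with
season, peaking in winter. Ignoring that oscillation confounds
association studies of mtDNA abundance; modelling it opens three distinct
axes along which a lifestyle factor, blood-cell count, disease, mortality
or molecular marker can act:

* **amplitude** — the height of the seasonal wave,
* **acrophase** — the phase angle (when in the year the peak occurs),
* **displacement** — the vertical (baseline, MESOR) shift.

`mtcosinor` is aimed at epidemiologists and statistical geneticists who
want to estimate these three characteristics and scan marker panels for
effect modification of the seasonal pattern, with a synthetic-cohort
generator providing known ground truth for validation.

## The model

With month of recruitment \(m \in \{1..12\}\), the annual harmonic basis
is

    SINW = sin(2π(m − 1)/12),   COSW = cos(2π(m − 1)/12)

and the cosinor regression (OLS) is

    y = β₀ + β₂·COSW + β₃·SINW + Σᵢ βᵢCᵢ + ε .

The seasonal characteristics are nonlinear transforms of the
coefficients,

    amplitude A = √(β₂² + β₃²),   acrophase φ = atan2(β₃, β₂),

with standard errors by the delta method (first-order Taylor propagation
of the coefficient covariance). Estimate/SE gives a T-score, 95% CI and
P-value. Marker effect modification uses the interaction model

    y = β₀ + β₁M + β₂COSW + β₃SINW + β₄M·COSW + β₅M·SINW + Σᵢ βᵢCᵢ ,

from which the change in amplitude is
√((β₂+β₄)² + (β₃+β₅)²) − √(β₂²+β₃²) (signed; reported in SD units and as
a percentage of a reference amplitude), the change in acrophase is the
wrapped difference of the two `atan2` phases (reported in months), and
the displacement effect is the marginal term β₁. Batch scans apply
Bonferroni control over 3 × (number of markers) tests (e.g. 640 diseases
→ 1,920 tests) or a fixed threshold (labWAS/PWAS style), and the
`lambda_gc()` genomic-inflation diagnostic checks calibration.

## Worked example

```r
library(mtcosinor)

# a synthetic cohort in the stated world: amplitude 0.092 SD,
# acrophase -0.14 rad, unit noise, published covariate moments
cfg <- simulation_config(n_individuals = 20000)
sim <- generate_cohort(cfg, seed = 42)

# coverage summaries -> QC'd standardized abundance
cov <- generate_coverage(sim$cohort, seed = 42)
ab  <- mtdna_abundance(cov)           # 4x-IQR-from-median filter, then z-scale
sum(!ab$qc_pass)                      # 1 of 20000 excluded

cohort <- sim$cohort[ab$qc_pass, ]
cohort$outcome <- ab$z_value[ab$qc_pass]
fit <- fit_cosinor(cohort$outcome, cohort$month,
                   covariates = cohort[c("age", "bmi", "male", "ever_smoked")])
seasonal_characteristics(fit)
```

```
Seasonal characteristics (n = 19999 )
              estimate       se   t_score    ci_low  ci_high  p_value
amplitude     0.081052 0.010029  8.081604  0.061395 0.100709 0.000000
acrophase    -0.230112 0.122660 -1.876017 -0.470522 0.010297 0.060653
displacement  0.009554 0.066461  0.143757 -0.120707 0.139816 0.885692
joint seasonality P = 6.57e-15; peak 0.56 / trough 6.56 months into the year
```

The amplitude recovered from the noisy coverage-derived abundance
(0.081 ± 0.010 SD) is consistent with the generating value 0.092 SD
(measurement noise attenuates it slightly), the acrophase CI covers
−0.14, and the trough lands in early summer. At this desk-scale n the
acrophase is only borderline significant — the seasonal signal is small,
which is exactly why the joint 2-df test is reported alongside.

Marker scans and the mortality interaction work on the same cohort:

```r
s <- mortality_interaction(sim$cohort, covariates = c("age", "bmi"),
                           reference_amplitude = 0.091)
attr(s, "delta_amplitude_pct")   # -11.9 (% of 0.091 SD; truth -22.8%, wide CI)

scan <- run_scan(sim$cohort, sim$cohort[c("circulatory", "bmi", "ever_smoked")],
                 scan_settings(covariates = "age", reference_amplitude = 0.091))
attr(scan, "n_tests")            # 9  (3 characteristics x 3 markers)
```

(Those numbers assume `cfg` also declared `disease_specs` /
`death_spec`; see `?simulation_config`. Interaction SEs at n = 20,000
are honest about power: detecting a 20% amplitude change needs
biobank-scale samples.)

A command-line pipeline wraps the same steps:

```sh
Rscript -e 'mtcosinor::mtcosinor_cli()' simulate --out sim --seed 3 --n 2000
Rscript -e 'mtcosinor::mtcosinor_cli()' quantify --coverage-dir sim/coverage --out abundance.tsv
Rscript -e 'mtcosinor::mtcosinor_cli()' fit-season --cohort sim/cohort.tsv --out season.tsv
Rscript -e 'mtcosinor::mtcosinor_cli()' scan --cohort sim/cohort.tsv --markers bmi,ever_smoked --out scan.tsv
```

## Layout

* `R/` — simulator, abundance QC, covariate derivation (CKD-EPI eGFR,
  frailty, lifestyle codings, omics pre-processing), cosinor core,
  interaction scans, file I/O, CLI.
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (brute-force grid search, bootstrap, enumeration).
* `vignettes/mtcosinor-methods.Rmd` — the model, its assumptions,
  parameter choices and limitations.
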