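Package: mtcosinor
Title: Seasonal Cosinor Analysis of Mitochondrial DNA Abundance
Version: 0.1.0
Authors@R:
    person("Open", "Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies mitochondrial DNA abundance from off-target
    sequencing coverage summaries, models its seasonal variation with a
    single-harmonic cosinor (sine-cosine) regression, and derives
    amplitude, acrophase and displacement with delta-method standard
    errors. Marker-by-season interaction models estimate how lifestyle
    factors, blood-cell counts, disease status, mortality and omics
    markers modify the seasonal pattern, with batch scans under
    Bonferroni multiplicity control and genomic-inflation diagnostics.
    Includes a synthetic-cohort generator with known seasonal ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
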