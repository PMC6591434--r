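Package: mousehrv
Title: Heart Rate Variability Analysis for Murine Telemetric RR-Interval Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing heart rate and heart-rate variability from
    telemetric EKG beat annotations in mice. Provides RR-interval ingest and
    segment selection with a two-standard-deviation ectopic-beat rule and a
    stationarity screen, time-domain summaries (mean RR, range, SDRR, CV),
    beat-domain FFT spectral power with very-low-, low- and high-frequency
    bands, Poincare SD1/SD2, sample entropy and multiscale entropy (E1),
    linear mixed-effects genotype-by-drug comparisons with Satterthwaite
    degrees of freedom, a synthetic RR-series generator with genotype and
    autonomic-drug presets, and auxiliary quantifications (corrected total
    cell fluorescence, comparative-Ct relative expression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
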