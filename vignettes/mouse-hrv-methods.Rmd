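---
title: "Heart-rate variability analysis of murine telemetric RR series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate variability analysis of murine telemetric RR series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousehrv)
```

## Overview

`mousehrv` analyses heart rate (HR) and heart-rate variability (HRV) from
telemetric EKG beat annotations in mice, with particular attention to the
comparison of wild-type animals against a cardiac-specific adenylyl-cyclase-8
overexpressing transgenic whose sinoatrial node runs at a high intrinsic rate
with markedly coherent (low-variability) rhythm. The input is a table of beat
occurrence times (or ready-made RR intervals); everything upstream of that —
electrode placement, R-wave detection from the raw voltage trace — is out of
scope and assumed done by the acquisition software.

The pipeline is: ingest → segment selection and cleaning → per-segment
metrics in three families (time domain, frequency domain, nonlinear) →
tidy metric table → genotype × drug mixed-model statistics. A synthetic
RR-series generator with genotype and autonomic-drug presets exercises every
stage without animal data.

## Segment selection and ectopic handling

HRV statistics are only meaningful on stationary, artifact-free stretches.
`select_segments()` partitions a series left-to-right into
`floor(N / min_intervals)` non-overlapping candidate windows (default
`min_intervals = 2048`; the last window absorbs the remainder). Windows are
non-overlapping to avoid pseudo-replicating the same beats into multiple
rows of the downstream mixed model. Each window must pass two gates:

* **Stationarity.** An OLS line of RR against beat index is fitted. The
  window fails only when the slope is significant at
  `stationarity_alpha = 0.05` *and* the fitted drift across the window
  exceeds `max_relative_drift = 5%` of the mean RR. The conjunction matters:
  over thousands of beats a physiologically negligible trend is almost
  always "significant", so a pure significance rule would reject nearly
  every long window, while a pure drift rule would admit short steep ramps.
  Both thresholds are criteria parameters.
* **Ectopic budget.** An interval is ectopic when it deviates from the
  window mean by more than `outlier_sd = 2` standard deviations. Mean and SD
  are computed once on the raw window; the rule is deliberately
  single-pass — no re-masking after removal — because iterating shrinks the
  SD and escalates the flagged fraction unboundedly on heavy-tailed data.
  A window is kept only if at least `min_intervals` intervals survive
  masking.

Kept windows are truncated to exactly `min_intervals` usable intervals from
the window start, under two cleaning modes matched to the metric families:
`remove` (drop ectopics; used for time-domain and nonlinear metrics, which
need a gap-free sample of genuine intervals) and `zero_replace` (overwrite
ectopics with 0 and keep the first 2048 positions; used for the spectral
stage, which needs a fixed-length vector whose beat indexing is not
shifted). The 2-SD rule on a strict 2048-length window means any Gaussian
series has a few percent of beats flagged and exact-size windows are then
rejected; in practice only windows with slack (the remainder window, or
low-noise data) qualify, which mirrors how strict manual segment vetting
behaves on real telemetry.

## Time-domain metrics

`time_domain_summary()` reports mean RR, range, SDRR and CV = SDRR/mean.
The sample (n − 1) variance convention is used everywhere in the package —
SDRR, Poincaré axes, stationarity residuals — so that algebraic identities
across metrics (below) hold exactly rather than up to n/(n − 1) factors.

## Frequency-domain metrics

`rr_power_spectrum()` works in the *beat domain*: the 2048-interval segment
is transformed directly (no resampling onto a time grid). The mean interval
T̄ is computed over non-zero entries, subtracted from them (zeros stay), the
FFT is taken, coefficient magnitudes are squared and divided by T̄, and the
spectrum is folded one-sided (interior bins doubled; DC and Nyquist not).
Bin k is `k/2048` cycles per beat; its frequency label is `(k/2048)/T̄` Hz.
For a mouse at ~10 beats/s the per-beat Nyquist (0.5 cycles/beat) lands near
5 Hz, which is exactly where the HF band closes — the band edges VLF
0–0.4 Hz, LF 0.4–1.5 Hz, HF 1.5–5.0 Hz only make sense for murine data
under this mapping. Bands are half-open `[low, high)` with HF closed at
5.0 Hz, and the DC bin belongs to no band; total power sums all bins in
(0, 5] Hz.

Numerical choices: the mean is removed because an un-centred tachogram puts
essentially all energy into DC and band powers become meaningless; no taper
is applied by default (the band integrals span hundreds of bins, so
rectangular-window leakage is immaterial — verified by the localization
tests), with a Hann option for users who care about narrowband peaks;
zero-replaced ectopics enter the transform literally, with a
mean-over-non-zero convention so a handful of zeros does not bias T̄. The
1/T̄ divisor uses seconds; this is a pure scale choice that cancels in every
genotype or drug ratio.

## Nonlinear metrics

`poincare_summary()` computes the return-map axes from successive sums and
differences: SD1 = √(var(ΔRR)/2) (short-axis, beat-to-beat) and
SD2 = √(var(ΣRR)/2) (long-axis). Descriptions of this computation sometimes
attach "adding" to SD1 and "subtracting" to SD2; that literal reading is
available via `convention = "literal"`, but the default follows the
universal convention in which SD1 is the short-term statistic, and the
identity SD1² + SD2² = 2·SDRR² (exact up to an O(1/n) edge term) is tested
to 1%.

`sample_entropy()` implements SampEn(m, r): −ln of the ratio of
(m+1)-length to m-length template matches under the Chebyshev distance,
self-matches excluded, over the n − m templates that possess an (m+1)-length
continuation. Defaults m = 2, r = 0.2·SD follow the standard SampEn
parameterisation; r is recomputed per segment, making the statistic
scale-free. A constant segment gives r = 0 with every pair matching, so
SampEn is 0 rather than undefined. The optimized counting loop is verified
bit-exactly (match counts A and B) against an exhaustive O(n²) oracle.
`multiscale_entropy_e1()` coarse-grains by non-overlapping means and keeps
the tolerance fixed at the scale-1 value of 0.2·SD — the convention of the
multiscale-entropy literature, under which white noise loses entropy with
scale. The reported E1 is the scale-1 value of that curve (the most common
reading of "E1"; at scale 1 the fixed-r and relative-r conventions
coincide, so nothing downstream depends on the choice).

## Genotype × drug statistics

`fit_genotype_drug_model()` fits, per metric,
`value ~ genotype * phase + (1 | animal_id)` by REML, where `phase` pairs
each post-drug recording with the same day's pre-drug basal. The random
structure is the minimal one supporting repeated pre/post measures — a
random intercept per animal; random slopes are not identifiable from one
pre/post pair per animal. F-tests and pairwise differences of least-squares
means use the Satterthwaite degrees-of-freedom approximation
(via `lmerTest`). Flags follow the conventional annotation: ‡ genotype main
effect, T drug main effect, * interaction (pairwise contrasts examined when
the interaction is significant). Metrics are analysed independently with no
multiplicity correction, matching per-metric reporting practice. If the
animal-level variance is estimated on the boundary (singular fit) the
function warns and falls back to a transparent paired-difference t analysis,
flagged `method = "paired_t"`. `one_way_genotype_anova()` covers the
24-h-average HR design: an independent one-way F-test per time bin.

## The synthetic generator

`generate_rr_series()` draws
`rr_i = mean_rr + lf_amp·sin(2π·lf_freq·i) + hf_amp·sin(2π·hf_freq·i + π/2)
+ trend_slope·i + ε_i`, ε Gaussian, then makes each beat ectopic
(multiplied by `ectopic_scale`) independently with probability
`ectopic_rate`. An additive-sinusoid model was chosen over
integral-pulse-frequency-modulation because it has closed forms for
everything the tests need — expected SDRR is
`sqrt(lf_amp²/2 + hf_amp²/2 + noise_sd²)` and each sinusoid's band power is
predictable — at the cost of realism in phase coupling. Frequencies are in
cycles/beat so the generator composes directly with the beat-domain
spectral analysis; dividing by the mean RR in seconds gives their Hz
location.

Genotype presets live in `inst/extdata/hrv_presets.yaml`, versioned data
rather than code. The calibration logic: WT at mean RR 105 ms with
modulation (3.5, 4.5) ms and noise 1 ms; the transgenic at 85 ms (faster
beating) with amplitudes scaled so the closed-form SDRR ratio is 2.5, the
midpoint of the two- to threefold reduction the phenotype shows. Noise is
kept small relative to the sinusoids — sleep-state mouse tachograms are
modulation-dominated — which also keeps genuine beats inside the 2-SD
ectopic envelope. Modulation frequencies 0.1 and 0.3 cycles/beat map to
~0.9–1.3 Hz (LF) and ~2.7–3.8 Hz (HF) across all preset mean-RR values.
Drug tables are per-genotype multipliers with the observed directions:
atropine and dobutamine shorten RR and damp modulation much more in WT than
in the transgenic; propranolol lengthens RR slightly; dual blockade moves
both genotypes toward the intrinsic state. The numeric values are
calibration artifacts constrained by direction and fold-range, not
measurements.

What the generator does *not* emulate: respiratory-cardiac phase coupling,
circadian nonstationarity, 1/f broadband structure, and the asymmetric
shape of real ectopy (compensatory pauses). Pipeline tests passing on this
model therefore validate the *computational* contracts — normalisation,
counting, identities, recovery of injected effects — not physiological
fidelity.

```{r example}
wt <- generate_rr_series(genotype_preset("WT", n_beats = 10000, seed = 1))
tg <- generate_rr_series(genotype_preset("TGAC8", n_beats = 10000, seed = 2))
metrics <- rbind(hrv_metrics(wt), hrv_metrics(tg))
reshape(metrics[metrics$metric %in% c("mean_rr", "sdrr", "total_power"),
                c("genotype", "segment", "metric", "value")],
        direction = "wide", idvar = c("genotype", "segment"),
        timevar = "metric")
```

## Problem sizes and verification scale

The test suite validates the SampEn implementation against the exhaustive
oracle on 200 random series of up to 60 intervals; the Poincaré identity on
100 series of 2048; generator calibration on 50 000-beat series; and the
mixed model by 200 coverage replicates (95% CI for an injected genotype
offset on SDRR, 6 + 6 animals) plus 500 null replicates for the
interaction's type-I error. These sizes give Monte-Carlo standard errors
comfortably inside the asserted margins (e.g. a binomial SE of ~1% at 500
null replicates against an accepted 1–10% rejection band) while keeping the
whole suite around a minute.

## Known limitations

* The beat-domain spectrum is not directly comparable to time-resampled
  (Welch/Lomb–Scargle) spectra in absolute units; comparisons should stay
  within one convention.
* The stationarity screen only tests linear drift; slow oscillatory
  nonstationarity inside a window is not detected.
* With strict 2048-interval windows, Gaussian-tailed data rarely yields a
  fully clean exact-size window (see above); supply longer recordings and
  rely on the remainder window, or relax `min_intervals`.
* `ddct_rq()` fixes amplification efficiency at 2 (no efficiency
  correction), and averages replicate wells' Ct before ΔCt; both are the
  plain comparative-Ct conventions.
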