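# Synthetic-generator defaults (version 1).
#
# Genotype presets are calibration artifacts chosen so that, via the closed
# form SDRR = sqrt(lf_amp^2/2 + hf_amp^2/2 + noise_sd^2), the WT:TGAC8 SDRR
# ratio is 2.5 (mid "two- to threefold") and the transgenic beats faster
# (shorter mean RR). Modulation frequencies are cycles/beat; at these mean
# RR values lf_freq maps to ~0.9-1.3 Hz (LF band) and hf_freq to ~2.7-3.8 Hz
# (HF band). Amplitudes and noise_sd are ms.
#
# Drug tables are per-genotype multipliers on mean_rr, lf_amp, hf_amp and
# noise_sd, emulating the directions of the pharmacology: atropine and
# dobutamine shorten RR and shrink modulation with larger effects in WT;
# propranolol lengthens RR slightly; dual blockade moves both genotypes
# toward the intrinsic (denervated-like) state.
version: 1
genotypes:
  WT:
    mean_rr: 105.0
    lf_amp: 3.5
    hf_amp: 4.5
    lf_freq: 0.1
    hf_freq: 0.3
    noise_sd: 1.0
    ectopic_rate: 0.003
    ectopic_scale: 1.6
    trend_slope: 0.0
  TGAC8:
    mean_rr: 85.0
    lf_amp: 1.4
    hf_amp: 1.8
    lf_freq: 0.1
    hf_freq: 0.3
    noise_sd: 0.4
    ectopic_rate: 0.003
    ectopic_scale: 1.6
    trend_slope: 0.0
drugs:
  atropine:
    WT:    {mean_rr: 0.80, lf_amp: 0.45, hf_amp: 0.35, noise_sd: 0.70}
    TGAC8: {mean_rr: 0.95, lf_amp: 0.75, hf_amp: 0.70, noise_sd: 0.90}
  propranolol:
    WT:    {mean_rr: 1.06, lf_amp: 0.85, hf_amp: 0.95, noise_sd: 1.00}
    TGAC8: {mean_rr: 1.02, lf_amp: 0.90, hf_amp: 0.95, noise_sd: 1.00}
  dual:
    WT:    {mean_rr: 0.88, lf_amp: 0.40, hf_amp: 0.35, noise_sd: 0.80}
    TGAC8: {mean_rr: 0.98, lf_amp: 0.70, hf_amp: 0.70, noise_sd: 0.90}
  dobutamine:
    WT:    {mean_rr: 0.75, lf_amp: 0.50, hf_amp: 0.45, noise_sd: 0.80}
    TGAC8: {mean_rr: 0.93, lf_amp: 0.80, hf_amp: 0.80, noise_sd: 0.90}
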