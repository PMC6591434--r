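#' Configuration for the synthetic RR-series generator
#'
#' Parameters of the additive-sinusoid tachogram model: a mean interval,
#' low- and high-frequency sinusoidal modulations expressed in cycles per
#' beat (so that, divided by the mean RR in seconds, they land in the LF
#' 0.4-1.5 Hz and HF 1.5-5 Hz bands of a mouse recording), broadband
#' Gaussian noise, an optional linear trend, and sparse multiplicative
#' ectopic intervals.
#'
#' @param mean_rr mean RR interval, ms (> 0).
#' @param lf_amp,hf_amp sinusoidal modulation amplitudes, ms (>= 0).
#' @param lf_freq,hf_freq modulation frequencies in cycles/beat;
#'   `lf_freq < hf_freq < 0.5`.
#' @param noise_sd SD of the additive Gaussian noise, ms (>= 0).
#' @param ectopic_rate per-beat probability of an ectopic interval
#'   (0 <= rate < 0.1).
#' @param ectopic_scale multiplier applied to an interval when it turns
#'   ectopic.
#' @param trend_slope linear drift, ms per beat.
#' @param n_beats number of intervals to generate.
#' @param seed integer RNG seed (generation is deterministic given the seed;
#'   Mersenne-Twister with inversion normals).
#' @param genotype,condition,animal_id metadata carried into the generated
#'   series.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(mean_rr = 105, lf_amp = 3.5, hf_amp = 4.5,
                             lf_freq = 0.1, hf_freq = 0.3, noise_sd = 1,
                             ectopic_rate = 0.003, ectopic_scale = 1.6,
                             trend_slope = 0, n_beats = 20000L, seed = 1L,
                             genotype = "WT", condition = "basal",
                             animal_id = "sim") {
  if (mean_rr <= 0) stop("mean_rr must be > 0")
  if (lf_amp < 0 || hf_amp < 0 || noise_sd < 0) {
    stop("amplitudes and noise_sd must be >= 0")
  }
  if (ectopic_rate < 0 || ectopic_rate >= 0.1) {
    stop("ectopic_rate must lie in [0, 0.1)")
  }
  if (!(lf_freq < hf_freq && hf_freq < 0.5)) {
    stop("need lf_freq < hf_freq < 0.5 cycles/beat")
  }
  structure(list(mean_rr = mean_rr, lf_amp = lf_amp, hf_amp = hf_amp,
                 lf_freq = lf_freq, hf_freq = hf_freq, noise_sd = noise_sd,
                 ectopic_rate = ectopic_rate, ectopic_scale = ectopic_scale,
                 trend_slope = trend_slope, n_beats = as.integer(n_beats),
                 seed = as.integer(seed), genotype = genotype,
                 condition = condition, animal_id = animal_id),
            class = "synthetic_config")
}

#' Generate a synthetic RR-interval series
#'
#' Simulates `rr_i = mean_rr + lf_amp sin(2 pi lf_freq i) +
#' hf_amp sin(2 pi hf_freq i + pi/2) + trend_slope i + e_i` with
#' `e_i ~ N(0, noise_sd^2)`, then independently replaces each interval with
#' `ectopic_scale * rr_i` with probability `ectopic_rate`. The expected SDRR
#' of the ectopic-free process is `sqrt(lf_amp^2/2 + hf_amp^2/2 +
#' noise_sd^2)`.
#'
#' @param cfg a [synthetic_config()].
#' @return An [rr_series()] carrying the config's metadata.
#' @export
generate_rr_series <- function(cfg) {
  if (!inherits(cfg, "synthetic_config")) stop("`cfg` must be a synthetic_config")
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  i <- seq_len(cfg$n_beats) - 1
  rr <- cfg$mean_rr +
    cfg$lf_amp * sin(2 * pi * cfg$lf_freq * i) +
    cfg$hf_amp * sin(2 * pi * cfg$hf_freq * i + pi / 2) +
    cfg$trend_slope * i +
    stats::rnorm(cfg$n_beats, 0, cfg$noise_sd)
  ect <- stats::runif(cfg$n_beats) < cfg$ectopic_rate
  rr[ect] <- cfg$ectopic_scale * rr[ect]
  if (any(rr <= 0)) {
    stop("generated a non-positive RR interval; increase mean_rr or reduce ",
         "amplitudes / noise_sd / trend_slope")
  }
  rr_series(rr, animal_id = cfg$animal_id, genotype = cfg$genotype,
            condition = cfg$condition)
}

read_presets <- function() {
  path <- system.file("extdata", "hrv_presets.yaml", package = "mousehrv",
                      mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Genotype presets for the synthetic generator
#'
#' Returns the generator configuration emulating one genotype's telemetry
#' phenotype: the AC8-overexpressing transgenic (`"TGAC8"`) beats faster
#' (shorter mean RR) with two- to threefold lower RR variability than its
#' wild-type littermate (`"WT"`). The numeric values are calibration
#' artifacts and live in the package's `extdata/hrv_presets.yaml` defaults
#' file, not in code.
#'
#' @param name `"WT"` or `"TGAC8"`.
#' @param n_beats,seed passed through to [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
genotype_preset <- function(name, n_beats = 20000L, seed = 1L) {
  presets <- read_presets()
  if (!name %in% names(presets$genotypes)) {
    stop("unknown genotype preset ", sQuote(name), "; available: ",
         paste(names(presets$genotypes), collapse = ", "))
  }
  p <- presets$genotypes[[name]]
  synthetic_config(mean_rr = p$mean_rr, lf_amp = p$lf_amp, hf_amp = p$hf_amp,
                   lf_freq = p$lf_freq, hf_freq = p$hf_freq,
                   noise_sd = p$noise_sd, ectopic_rate = p$ectopic_rate,
                   ectopic_scale = p$ectopic_scale,
                   trend_slope = p$trend_slope, n_beats = n_beats,
                   seed = seed, genotype = name, condition = "basal",
                   animal_id = paste0("sim_", name))
}

#' Apply a drug preset to a generator configuration
#'
#' Returns a modified copy of `cfg` with mean RR and modulation amplitudes
#' multiplied by the drug's genotype-specific factors from the defaults
#' file; the input is untouched. Drugs emulated: `"atropine"`
#' (parasympathetic blockade: shorter RR, strongly reduced modulation,
#' larger effect in WT), `"propranolol"` (sympathetic blockade: slightly
#' longer RR), `"dual"` (both blockers: the intrinsic, denervated-like
#' state) and `"dobutamine"` (beta-1 agonist: shorter RR, with a larger
#' effect in WT than in the transgenic).
#'
#' @param cfg a [synthetic_config()] whose `genotype` has an entry in the
#'   drug table.
#' @param drug one of `"atropine"`, `"propranolol"`, `"dual"`,
#'   `"dobutamine"`.
#' @return A new [synthetic_config()] with `condition` set to the drug name.
#' @export
drug_effect_transform <- function(cfg, drug) {
  if (!inherits(cfg, "synthetic_config")) stop("`cfg` must be a synthetic_config")
  presets <- read_presets()
  if (!drug %in% names(presets$drugs)) {
    stop("unknown drug ", sQuote(drug), "; available: ",
         paste(names(presets$drugs), collapse = ", "))
  }
  tab <- presets$drugs[[drug]]
  if (!cfg$genotype %in% names(tab)) {
    stop("no ", sQuote(drug), " multipliers for genotype ", sQuote(cfg$genotype))
  }
  mult <- tab[[cfg$genotype]]
  out <- cfg
  out$mean_rr <- cfg$mean_rr * mult$mean_rr
  out$lf_amp <- cfg$lf_amp * mult$lf_amp
  out$hf_amp <- cfg$hf_amp * mult$hf_amp
  out$noise_sd <- cfg$noise_sd * mult$noise_sd
  out$condition <- drug
  out
}

#' Write a synthetic cohort as a beat-annotation table
#'
#' Generates one series per animal and genotype (seeds derived from `seed`),
#' converts intervals to cumulative beat times and writes the CSV beat-table
#' format read by [load_beat_table()]. Convenience wrapper used in examples
#' and end-to-end tests.
#'
#' @param path output CSV path.
#' @param n_per_genotype animals per genotype.
#' @param n_beats beats per animal.
#' @param seed base seed; animal g gets `seed + g`.
#' @return `path`, invisibly.
#' @export
write_synthetic_cohort <- function(path, n_per_genotype = 3L,
                                   n_beats = 5000L, seed = 1L) {
  rows <- list()
  k <- 0L
  for (g in c("WT", "TGAC8")) {
    for (a in seq_len(n_per_genotype)) {
      k <- k + 1L
      cfg <- genotype_preset(g, n_beats = n_beats, seed = seed + k)
      cfg$animal_id <- sprintf("%s_%02d", g, a)
      s <- generate_rr_series(cfg)
      times <- cumsum(c(0, s$rr)) / 1000
      rows[[k]] <- data.frame(animal_id = s$animal_id, genotype = g,
                              condition = "basal", time_s = times,
                              stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
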