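test_that("generator degenerate and determinism contracts hold", {
  cfg <- synthetic_config(mean_rr = 100, lf_amp = 0, hf_amp = 0, noise_sd = 0,
                          ectopic_rate = 0, n_beats = 100, seed = 1)
  expect_equal(generate_rr_series(cfg)$rr, rep(100, 100))

  cfg2 <- synthetic_config(n_beats = 2000, seed = 42)
  expect_identical(generate_rr_series(cfg2)$rr, generate_rr_series(cfg2)$rr)
  cfg3 <- synthetic_config(n_beats = 2000, seed = 43)
  expect_false(identical(generate_rr_series(cfg2)$rr, generate_rr_series(cfg3)$rr))
})

test_that("invalid configurations are refused", {
  expect_error(synthetic_config(mean_rr = -1), "mean_rr")
  expect_error(synthetic_config(ectopic_rate = 0.2), "ectopic_rate")
  expect_error(synthetic_config(lf_freq = 0.4, hf_freq = 0.3), "lf_freq")
  expect_error(synthetic_config(hf_freq = 0.6), "0.5")
  # parameters that drive intervals negative are reported, not silently kept
  bad <- synthetic_config(mean_rr = 5, noise_sd = 10, lf_amp = 0, hf_amp = 0,
                          n_beats = 1000, seed = 2)
  expect_error(generate_rr_series(bad), "non-positive")
})

test_that("generated SDRR matches the closed form within 3% at 50k beats", {
  cfg <- synthetic_config(mean_rr = 105, lf_amp = 3.5, hf_amp = 4.5,
                          noise_sd = 1, ectopic_rate = 0, n_beats = 50000,
                          seed = 11)
  s <- generate_rr_series(cfg)
  expected <- sqrt(3.5^2 / 2 + 4.5^2 / 2 + 1^2)
  expect_equal(sd(s$rr), expected, tolerance = 0.03)
})

test_that("an HF-only configuration puts >= 90% of band power in HF end-to-end", {
  cfg <- synthetic_config(mean_rr = 100, lf_amp = 0, hf_amp = 4,
                          hf_freq = 0.25, noise_sd = 0.3, ectopic_rate = 0.002,
                          n_beats = 4200, seed = 12)
  s <- generate_rr_series(cfg)
  segs <- select_segments(s, mode = "zero_replace")
  expect_gte(length(segs), 1)
  sp <- rr_power_spectrum(segs[[1]])
  expect_gte(sp$hf / (sp$vlf + sp$lf + sp$hf), 0.9)
  # hf_freq / T-bar sits inside the 1.5-5 Hz band
  f_hz <- 0.25 / (100 / 1000)
  expect_true(f_hz > 1.5 && f_hz <= 5)
})

test_that("genotype presets reproduce the phenotype directions and fold range", {
  wt <- genotype_preset("WT", n_beats = 50000, seed = 21)
  tg <- genotype_preset("TGAC8", n_beats = 50000, seed = 22)
  s_wt <- generate_rr_series(wt)
  s_tg <- generate_rr_series(tg)

  m_wt <- hrv_metrics(s_wt)
  m_tg <- hrv_metrics(s_tg)
  sdrr_wt <- mean(m_wt$value[m_wt$metric == "sdrr"])
  sdrr_tg <- mean(m_tg$value[m_tg$metric == "sdrr"])
  mean_wt <- mean(m_wt$value[m_wt$metric == "mean_rr"])
  mean_tg <- mean(m_tg$value[m_tg$metric == "mean_rr"])

  expect_lt(sdrr_tg, sdrr_wt)
  expect_lt(mean_tg, mean_wt)            # TGAC8 beats faster
  expect_gt(60000 / mean_tg, 60000 / mean_wt)  # i.e. higher HR in bpm
  ratio <- sdrr_wt / sdrr_tg
  expect_gte(ratio, 2)
  expect_lte(ratio, 3)

  expect_error(genotype_preset("KO"), "unknown genotype")
})

test_that("drug transforms are pure and move parameters in the reported directions", {
  wt <- genotype_preset("WT", n_beats = 5000, seed = 31)
  wt_before <- unclass(wt)
  atro <- drug_effect_transform(wt, "atropine")
  expect_identical(unclass(wt), wt_before)       # input untouched
  expect_lt(atro$mean_rr, wt$mean_rr)            # atropine shortens RR
  expect_lt(atro$hf_amp, wt$hf_amp)              # and damps modulation
  expect_equal(atro$condition, "atropine")

  dual <- drug_effect_transform(wt, "dual")
  expect_equal(dual$lf_amp, wt$lf_amp * 0.40)    # from the defaults table
  expect_equal(dual$hf_amp, wt$hf_amp * 0.35)

  prop <- drug_effect_transform(wt, "propranolol")
  expect_gt(prop$mean_rr, wt$mean_rr)            # beta-blockade slows HR

  expect_error(drug_effect_transform(wt, "ivabradine"), "unknown drug")
})

test_that("dobutamine shortens RR more in WT than in TGAC8", {
  for (seeds in list(c(41, 42), c(43, 44))) {
    wt <- genotype_preset("WT", n_beats = 6000, seed = seeds[1])
    tg <- genotype_preset("TGAC8", n_beats = 6000, seed = seeds[2])
    drop_of <- function(cfg) {
      pre <- mean(generate_rr_series(cfg)$rr)
      post_cfg <- drug_effect_transform(cfg, "dobutamine")
      post_cfg$seed <- cfg$seed + 100
      post <- mean(generate_rr_series(post_cfg)$rr)
      pre - post
    }
    expect_gt(drop_of(wt), drop_of(tg))
  }
})

test_that("a synthetic cohort round-trips through the beat-table loader", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write_synthetic_cohort(tf, n_per_genotype = 2, n_beats = 300, seed = 51)
  series <- load_beat_table(tf)
  expect_length(series, 4)
  expect_true(all(vapply(series, inherits, logical(1), "beat_series")))
  rr <- beats_to_rr(series[[1]])
  expect_equal(length(rr$rr), 300)
  genos <- vapply(series, function(s) s$genotype, character(1))
  expect_setequal(unique(genos), c("WT", "TGAC8"))
})
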