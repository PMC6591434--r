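test_that("noiseless additive effects are recovered essentially exactly", {
  # both variance components essentially zero: effects are exact constants
  r <- simulate_metric_table(6, genotype_effect = -3, drug_effect = -2,
                             interaction_effect = 1.5, animal_sd = 1e-4,
                             resid_sd = 1e-4, seed = 101)
  res <- suppressWarnings(fit_genotype_drug_model(r, "sdrr", "atropine"))
  # reference level is TGAC8 (alphabetical), so the WT coefficient is +3
  expect_equal(res$genotype_effect$estimate, 3, tolerance = 1e-3)
  fe <- res$fixed_effects
  expect_true(all(c("genotype", "drug", "genotype:drug") %in% fe$term))
  expect_lt(fe$p_value[fe$term == "genotype:drug"], 1e-6)
  expect_equal(res$flags$interaction, "*")
})

test_that("a well-conditioned design is fitted by the mixed model with correct flags", {
  r <- simulate_metric_table(6, genotype_effect = -3, drug_effect = -2,
                             interaction_effect = 1.5, animal_sd = 2,
                             resid_sd = 0.1, seed = 101)
  res <- fit_genotype_drug_model(r, "sdrr", "atropine")
  expect_equal(res$method, "lmm")
  expect_equal(res$genotype_effect$term, "genotypeWT")
  fe <- res$fixed_effects
  expect_lt(fe$p_value[fe$term == "genotype:drug"], 1e-6)
  expect_equal(res$flags$interaction, "*")
  expect_equal(res$flags$drug, "T")
})

test_that("pairwise LS-mean contrasts carry Satterthwaite df", {
  r <- simulate_metric_table(6, genotype_effect = -3, drug_effect = -1,
                             animal_sd = 1, resid_sd = 0.5, seed = 102)
  res <- fit_genotype_drug_model(r, "sdrr", "atropine")
  expect_true(is.data.frame(res$contrasts))
  expect_true(all(res$contrasts$df > 0))
  expect_true(all(res$contrasts$p_value >= 0 & res$contrasts$p_value <= 1))
  # some contrasts use non-integer (approximated) denominator df
  expect_true(any(abs(res$contrasts$df - round(res$contrasts$df)) > 1e-6))
})

test_that("relabeling genotypes flips effect signs but not F or p", {
  r <- simulate_metric_table(5, genotype_effect = -2, drug_effect = -1,
                             animal_sd = 1, resid_sd = 0.5, seed = 103)
  res1 <- fit_genotype_drug_model(r, "sdrr", "atropine")
  r2 <- r
  r2$genotype <- ifelse(r$genotype == "WT", "AWT", "ZTG")  # swap factor order
  res2 <- fit_genotype_drug_model(r2, "sdrr", "atropine")
  expect_equal(res2$genotype_effect$estimate, -res1$genotype_effect$estimate,
               tolerance = 1e-8)
  expect_equal(res2$fixed_effects$F, res1$fixed_effects$F, tolerance = 1e-8)
  expect_equal(res2$fixed_effects$p_value, res1$fixed_effects$p_value,
               tolerance = 1e-8)
})

test_that("adding a constant to all responses leaves every test unchanged", {
  r <- simulate_metric_table(5, genotype_effect = 1, drug_effect = -1,
                             animal_sd = 1, resid_sd = 0.5, seed = 104)
  res1 <- fit_genotype_drug_model(r, "sdrr", "atropine")
  r2 <- r; r2$value <- r2$value + 1000
  res2 <- fit_genotype_drug_model(r2, "sdrr", "atropine")
  expect_equal(res2$fixed_effects$F, res1$fixed_effects$F, tolerance = 1e-6)
  expect_equal(res2$genotype_effect$estimate, res1$genotype_effect$estimate,
               tolerance = 1e-6)
})

test_that("unpaired animals and undersized designs are refused by name", {
  r <- simulate_metric_table(3, seed = 105)
  r <- r[!(r$animal_id == "WT_2" & r$condition == "atropine"), ]
  expect_error(fit_genotype_drug_model(r, "sdrr", "atropine"), "WT_2")

  r2 <- simulate_metric_table(3, seed = 106)
  r2 <- r2[r2$genotype == "WT", ]
  expect_error(fit_genotype_drug_model(r2, "sdrr", "atropine"), "2 genotypes|genotype")
})

test_that("a singular animal-level fit falls back to the paired t analysis", {
  r <- simulate_metric_table(4, animal_sd = 0, resid_sd = 1, seed = 108)
  expect_warning(res <- fit_genotype_drug_model(r, "sdrr", "atropine"),
                 "singular")
  expect_equal(res$method, "paired_t")
  expect_true(all(res$fixed_effects$p_value >= 0 &
                    res$fixed_effects$p_value <= 1))
})

test_that("one-way genotype ANOVA matches closed forms", {
  rec <- data.frame(genotype = rep(c("WT", "TGAC8"), each = 4),
                    value = rep(c(9, 10, 11, 10), 2))  # identical group values
  out <- one_way_genotype_anova(rec)
  expect_equal(out$F, 0)
  expect_equal(out$p_value, 1)

  rec2 <- data.frame(genotype = rep(c("WT", "TGAC8"), each = 4),
                     value = c(10, 10.01, 9.99, 10, 50, 50.01, 49.99, 50))
  expect_lt(one_way_genotype_anova(rec2)$p_value, 1e-6)

  set.seed(108)
  rec3 <- data.frame(genotype = rep(c("WT", "TGAC8"), each = 6),
                     value = rnorm(12, 10, 2))
  f <- one_way_genotype_anova(rec3)$F
  t2 <- t.test(value ~ genotype, data = rec3, var.equal = TRUE)$statistic^2
  expect_equal(f, unname(t2), tolerance = 1e-10)

  expect_error(one_way_genotype_anova(rec3[rec3$genotype == "WT", ]),
               "2 genotypes")
})

test_that("per-bin ANOVA analyses each bin independently", {
  set.seed(109)
  rec <- data.frame(genotype = rep(rep(c("WT", "TGAC8"), each = 5), 3),
                    hour = rep(1:3, each = 10),
                    value = rnorm(30, 10, 1))
  rec$value[rec$hour == 2 & rec$genotype == "TGAC8"] <- 30
  out <- one_way_genotype_anova(rec, bin = "hour")
  expect_equal(nrow(out), 3)
  expect_lt(out$p_value[out$bin == "2"], 1e-6)
  expect_gt(min(out$p_value[out$bin != "2"]), 0.01)
})
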