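test_that("haplotype generator is deterministic and respects its limits", {
  m <- locus_model(n_snps = 12, ld_decay = 0.8)
  a <- simulate_haplotype_panel(m, 200, seed = 42)
  b <- simulate_haplotype_panel(m, 200, seed = 42)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$snps, b$snps)
  expect_error(locus_model(n_snps = 1), class = "tidylocus_validation_error")

  # near-comonotone limit: equal MAFs, decay -> 1 pushes pairwise r2 -> 1
  hi <- simulate_haplotype_panel(
    locus_model(n_snps = 5, ld_decay = 0.9999, maf_range = c(0.3, 0.3)),
    4000, seed = 1)
  r2 <- ld_stats(hi, "snp001", "snp005")$r2
  expect_gt(r2, 0.9)
})

test_that("ld_decay = 0 gives independent loci with E[r2] ~ 1/n_hap", {
  # for independent biallelic loci, sample r2 is asymptotically
  # chi-square(1)/n, so E[r2] ~ 1/n_haplotypes
  n_hap <- 2000
  panel <- simulate_haplotype_panel(
    locus_model(n_snps = 50, ld_decay = 0), n_hap, seed = 7)
  cm <- ld_cor_matrix(panel)^2
  mean_r2 <- mean(cm[upper.tri(cm)])
  expect_lt(abs(mean_r2 - 1 / n_hap), 3 / n_hap)
})

test_that("case/control generator is deterministic and null-centered", {
  panel <- simulate_haplotype_panel(locus_model(n_snps = 4), 1000, seed = 3)
  co1 <- simulate_case_control(panel, effect_model(), c(HRD = 50, nonHRD = 50),
                               100, seed = 5)
  co2 <- simulate_case_control(panel, effect_model(), c(HRD = 50, nonHRD = 50),
                               100, seed = 5)
  expect_identical(co1$phenotype, co2$phenotype)
  expect_identical(co1$genotypes$dosages, co2$genotypes$dosages)

  # under OR = 1 the causal-SNP log-OR estimates center on zero
  null_eff <- effect_model(or_overall = 1, or_subtype = c(all = 1))
  betas <- vapply(1:60, function(r) {
    co <- simulate_case_control(panel, null_eff, c(all = 150), 150, seed = 100 + r)
    fit_additive_logistic(co$genotypes, co$phenotype,
                          snp_ids = co$causal_snp)$beta
  }, double(1))
  expect_lt(abs(mean(betas, na.rm = TRUE)),
            3 * sd(betas, na.rm = TRUE) / sqrt(sum(!is.na(betas))))
})

test_that("expression generator recovers the planted eQTL effect", {
  g <- random_genotypes(500, 3, seed = 6)
  eff <- effect_model(eqtl_beta = 0.5, n_hidden_factors = 0, noise_sd = 1)
  expr <- simulate_expression(g, eff, causal_snp = "rs002", n_studies = 1,
                              seed = 8)
  fit <- lm(expr[[1]]$values["gene01", ] ~ g$dosages[, "rs002"])
  cf <- summary(fit)$coefficients
  expect_lt(abs(cf[2, "Estimate"] - 0.5), 3 * cf[2, "Std. Error"])
})

test_that("studies share the causal architecture but not the noise", {
  g <- random_genotypes(100, 3, seed = 6)
  eff <- effect_model(eqtl_beta = 0.5, n_hidden_factors = 1)
  expr <- simulate_expression(g, eff, causal_snp = "rs002", n_studies = 2,
                              seed = 8)
  expect_equal(attr(expr[[1]], "eqtl_snp"), attr(expr[[2]], "eqtl_snp"))
  expect_false(isTRUE(all.equal(expr[[1]]$values, expr[[2]]$values)))
  again <- simulate_expression(g, eff, causal_snp = "rs002", n_studies = 2,
                               seed = 8)
  expect_identical(expr[[1]]$values, again[[1]]$values)
})

test_that("linkage scenario picks a SNP near the target r2 or errors", {
  panel <- simulate_haplotype_panel(
    locus_model(n_snps = 20, ld_decay = 0.9, maf_range = c(0.25, 0.35)),
    2000, seed = 12)
  co <- simulate_case_control(panel, effect_model(), c(all = 300), 0, seed = 13)
  eff <- effect_model(scenario = "linkage", linkage_r2 = 0.5, eqtl_beta = 0.5)
  expr <- simulate_expression(co$genotypes, eff, causal_snp = "snp010",
                              n_studies = 1, seed = 14)
  eqtl_snp <- attr(expr, "eqtl_snp")
  expect_false(eqtl_snp == "snp010")
  r2 <- cor(co$genotypes$dosages[, eqtl_snp], co$genotypes$dosages[, "snp010"])^2
  expect_lt(abs(r2 - 0.5), 0.15 + 1e-9)

  indep <- random_genotypes(300, 5, seed = 15)
  expect_error(
    simulate_expression(indep, eff, causal_snp = "rs003", n_studies = 1, seed = 16),
    class = "tidylocus_validation_error")
})

test_that("trisomy counts honor the 2:1 copy model and bias plug-in", {
  # unbiased, every tumor risk-amplified, huge depth: fraction -> 2/3
  tab <- simulate_trisomy_counts(50, depth_mean = 10000, p_risk_amplified = 1,
                                 bias_odds = 1, seed = 2)
  frac <- sum(tab$tumor_risk) / sum(tab$tumor_risk + tab$tumor_nonrisk)
  expect_lt(abs(frac - 2 / 3), 0.005)

  # bias 1.5, non-risk amplified: expected fraction b/(b+2) = 0.4286
  tab2 <- simulate_trisomy_counts(200, depth_mean = 200, p_risk_amplified = 0,
                                  bias_odds = 1.5, seed = 3)
  frac2 <- sum(tab2$tumor_risk) / sum(tab2$tumor_risk + tab2$tumor_nonrisk)
  expect_lt(abs(frac2 - 1.5 / 3.5), 0.01)

  expect_identical(simulate_trisomy_counts(10, 50, seed = 9),
                   simulate_trisomy_counts(10, 50, seed = 9))
  expect_error(simulate_trisomy_counts(10, depth_mean = 0.5),
               class = "tidylocus_validation_error")
})
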