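test_that("T_SMR matches its closed form and limiting behavior", {
  # symmetric case: z_gwas = z_eqtl = z gives T = z^2 / 2
  for (z in c(1, 2.5, 6)) {
    s <- smr_test(b_gwas = z * 0.1, se_gwas = 0.1,
                  b_eqtl = z * 0.2, se_eqtl = 0.2)
    expect_equal(s$t_smr, z^2 / 2, tolerance = 1e-12)
  }

  # z_gwas = 4, z_eqtl = 6: T = 576/52 = 11.0769, p ~ 8.75e-4
  s <- smr_test(0.4, 0.1, 1.2, 0.2)
  expect_equal(s$t_smr, 576 / 52, tolerance = 1e-12)
  expect_equal(s$p_smr, pchisq(576 / 52, 1, lower.tail = FALSE))
  expect_equal(s$p_smr, 8.75e-4, tolerance = 1e-2)
  expect_equal(s$b_xy, 0.4 / 1.2)

  # infinitely precise eQTL: T -> z_gwas^2
  s2 <- smr_test(0.4, 0.1, 1e6 * 0.2, 0.2)
  expect_equal(s2$t_smr, 16, tolerance = 1e-6)

  expect_error(smr_test(0.1, 0.05, 0, 0.1), class = "tidylocus_validation_error")
})

test_that("T_SMR is symmetric, flip-invariant, and bounded by min(z^2)", {
  withr::with_seed(71, {
    for (i in 1:25) {
      bg <- rnorm(1); sg <- runif(1, 0.01, 0.5)
      be <- rnorm(1); se <- runif(1, 0.01, 0.5)
      if (be == 0) next
      t1 <- smr_test(bg, sg, be, se)$t_smr
      # swap the roles of the two z-scores
      t2 <- smr_test(be, se, bg, sg)$t_smr
      expect_equal(t1, t2, tolerance = 1e-12)
      # flip both effect alleles
      t3 <- smr_test(-bg, sg, -be, se)$t_smr
      expect_equal(t1, t3, tolerance = 1e-12)
      expect_lte(t1, min((bg / sg)^2, (be / se)^2) + 1e-12)
    }
  })
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 6), 0.05 / 6)
  expect_equal(signif(bonferroni_threshold(0.05, 6), 3), 0.00833)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 100), 5e-4)
  expect_error(bonferroni_threshold(0.05, 0), class = "tidylocus_validation_error")
})

test_that("probe classification applies both filters and never passes NA HEIDI", {
  df <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    p_smr = c(0.001, 0.001, 0.02, 0.001),
    p_heidi = c(0.5, 0.01, 0.9, NA)
  )
  out <- classify_probes(df, alpha = 0.05, m_tests = 6)
  expect_equal(out$passes, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$smr_threshold[1], 0.05 / 6)
})

heidi_inputs <- function(n_snps = 12, seed = 72, linkage = FALSE) {
  panel <- simulate_haplotype_panel(
    locus_model(n_snps = n_snps, ld_decay = 0.9, maf_range = c(0.25, 0.35)),
    2000, seed = seed)
  causal <- panel$snps$id[ceiling(n_snps / 2)]
  co <- simulate_case_control(panel,
                              effect_model(or_subtype = c(all = 1.7)),
                              c(all = 1000), 1000, seed = seed + 1,
                              causal_snp = causal)
  eff <- effect_model(eqtl_beta = 0.6, n_hidden_factors = 0, noise_sd = 1,
                      scenario = if (linkage) "linkage" else "pleiotropy",
                      linkage_r2 = 0.5)
  eg <- simulate_case_control(panel, effect_model(or_overall = 1),
                              c(all = 600), 0, seed = seed + 2)$genotypes
  expr <- simulate_expression(eg, eff, causal_snp = causal, n_studies = 1,
                              seed = seed + 3)[[1]]
  gwas <- assoc_to_summary_stats(
    fit_additive_logistic(co$genotypes, co$phenotype), co$genotypes)
  eqtl <- cis_eqtl_scan(eg, expr, anchor_snp = causal)
  eqtl <- eqtl[eqtl$gene_id == "gene01", ]
  list(panel = panel, gwas = gwas, eqtl = eqtl,
       top = eqtl$snp_id[which.min(eqtl$p)])
}

test_that("HEIDI returns NA when no SNPs are eligible", {
  inp <- heidi_inputs()
  ids <- unique(inp$eqtl$snp_id)
  ld1 <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  h <- heidi_test(inp$gwas, inp$eqtl, ld1, inp$top)
  expect_true(is.na(h$p_heidi))
  expect_match(h$note, "eligible")
})

test_that("Satterthwaite and bootstrap HEIDI p-values agree", {
  inp <- heidi_inputs()
  ld <- ld_cor_matrix(inp$panel)
  hs <- heidi_test(inp$gwas, inp$eqtl, ld, inp$top)
  withr::with_seed(73, {
    hb <- heidi_test(inp$gwas, inp$eqtl, ld, inp$top, method = "bootstrap",
                     n_boot = 20000)
  })
  expect_equal(hs$n_heidi_snps, hb$n_heidi_snps)
  expect_lt(abs(hs$p_heidi - hb$p_heidi), 0.05)
})

test_that("linkage architecture inflates the HEIDI statistic relative to pleiotropy", {
  p_plei <- vapply(1:8, function(r) {
    inp <- heidi_inputs(seed = 900 + 10 * r, linkage = FALSE)
    heidi_test(inp$gwas, inp$eqtl, ld_cor_matrix(inp$panel), inp$top)$p_heidi
  }, double(1))
  p_link <- vapply(1:8, function(r) {
    inp <- heidi_inputs(seed = 900 + 10 * r, linkage = TRUE)
    heidi_test(inp$gwas, inp$eqtl, ld_cor_matrix(inp$panel), inp$top)$p_heidi
  }, double(1))
  expect_gt(mean(p_plei > 0.05, na.rm = TRUE),
            mean(p_link > 0.05, na.rm = TRUE) - 1e-9)
  expect_lt(median(p_link, na.rm = TRUE), median(p_plei, na.rm = TRUE))
})

test_that("smr_scan requires a significant instrument and flags the target gene", {
  inp <- heidi_inputs()
  eqtl <- dplyr::mutate(inp$eqtl, gene_id = "gene01")
  weak <- dplyr::mutate(eqtl, gene_id = "gene02", p = pmax(p, 1e-4))
  res <- smr_scan(inp$gwas, dplyr::bind_rows(eqtl, weak),
                  ld_cor_matrix(inp$panel))
  expect_true(is.na(res$p_smr[res$gene_id == "gene02"]))
  expect_false(res$passes[res$gene_id == "gene02"])
  expect_false(is.na(res$p_smr[res$gene_id == "gene01"]))
})
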