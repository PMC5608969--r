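test_that("Wald fit matches an independently coded IRLS oracle", {
  g <- random_genotypes(200, 1, seed = 31)
  withr::with_seed(32, {
    y <- rbinom(200, 1, plogis(-0.3 + 0.4 * g$dosages[, 1]))
  })
  pheno <- tibble::tibble(sample_id = g$sample_id,
                          status = ifelse(y == 1, "case", "control"))
  fit <- fit_additive_logistic(g, pheno)
  oracle <- irls_logistic(g$dosages[, 1, drop = FALSE], y)
  expect_equal(fit$beta, unname(oracle$beta[2]), tolerance = 1e-8)
  expect_equal(fit$se, unname(oracle$se[2]), tolerance = 1e-8)
  expect_equal(fit$or_, exp(fit$beta))
})

test_that("balanced dosage tables give beta ~ 0 and monomorphic SNPs are skipped", {
  dos <- c(rep(0, 30), rep(1, 40), rep(2, 30), rep(0, 30), rep(1, 40), rep(2, 30))
  snps <- snp_table(c("bal", "mono"), "chr1", c(1L, 2L), c("A", "A"), c("G", "G"))
  gm <- genotype_matrix(snps, cbind(dos, rep(1, 200)), sprintf("s%03d", 1:200))
  pheno <- tibble::tibble(sample_id = gm$sample_id,
                          status = rep(c("case", "control"), each = 100))
  res <- fit_additive_logistic(gm, pheno)
  expect_equal(res$beta[res$snp_id == "bal"], 0, tolerance = 1e-10)
  expect_equal(res$p[res$snp_id == "bal"], 1, tolerance = 1e-8)
  expect_match(res$note[res$snp_id == "mono"], "monomorphic")
  expect_true(is.na(res$p[res$snp_id == "mono"]))
})

test_that("separation is flagged rather than crashing", {
  dos <- c(rep(2, 50), rep(0, 50))
  snps <- snp_table("sep", "chr1", 1L, "A", "G")
  gm <- genotype_matrix(snps, cbind(dos), sprintf("s%03d", 1:100))
  pheno <- tibble::tibble(sample_id = gm$sample_id,
                          status = rep(c("case", "control"), each = 50))
  res <- fit_additive_logistic(gm, pheno)
  expect_true(is.na(res$p))
  expect_match(res$note, "separation|collinear")
})

test_that("conditional scan reports the condition SNP as NA and flags collinearity", {
  g <- random_genotypes(300, 3, seed = 33)
  g$dosages[, 3] <- g$dosages[, 1]          # rs003 collinear with rs001
  withr::with_seed(34, {
    status <- ifelse(rbinom(300, 1, 0.5) == 1, "case", "control")
  })
  pheno <- tibble::tibble(sample_id = g$sample_id, status = status)
  res <- conditional_scan(g, pheno, condition_snp = "rs001")
  expect_true(is.na(res$p[res$snp_id == "rs001"]))
  expect_match(res$note[res$snp_id == "rs001"], "self-conditioning")
  expect_match(res$note[res$snp_id == "rs003"], "collinear")
  expect_false(is.na(res$p[res$snp_id == "rs002"]))
})

test_that("conditioning on an independent SNP barely moves the betas", {
  panel <- simulate_haplotype_panel(locus_model(n_snps = 6, ld_decay = 0),
                                    2000, seed = 35)
  co <- simulate_case_control(panel, effect_model(or_subtype = c(HRD = 1.5)),
                              c(HRD = 400), 600, seed = 36,
                              causal_snp = "snp002")
  plain <- fit_additive_logistic(co$genotypes, co$phenotype)
  cond <- conditional_scan(co$genotypes, co$phenotype, condition_snp = "snp006")
  shared <- setdiff(intersect(plain$snp_id, cond$snp_id), "snp006")
  delta <- abs(plain$beta[match(shared, plain$snp_id)] -
                 cond$beta[match(shared, cond$snp_id)])
  expect_true(all(delta < 2 * plain$se[match(shared, plain$snp_id)]))
})

test_that("case-only test needs both subtypes and flags tiny ones", {
  g <- random_genotypes(120, 1, seed = 37)
  pheno <- tibble::tibble(
    sample_id = g$sample_id, status = "case",
    subtype = rep(c("HRD", "nonHRD"), each = 60)
  )
  res <- case_only_test(g, pheno)
  expect_equal(res$model_tag, "case_only")
  expect_equal(res$n_cases, 60L)

  lone <- pheno
  lone$subtype <- c("HRD", rep("nonHRD", 119))
  expect_warning(res1 <- case_only_test(g, lone), "few cases")
  expect_match(res1$note, "low subtype count")

  none <- pheno
  none$subtype <- "HRD"
  expect_error(case_only_test(g, none), class = "tidylocus_validation_error")
})

test_that("case-only beta centers on the subtype log-OR difference", {
  panel <- simulate_haplotype_panel(locus_model(n_snps = 3), 2000, seed = 38)
  eff <- effect_model(or_subtype = c(HRD = 1.26, nonHRD = 1.0))
  betas <- vapply(1:40, function(r) {
    co <- simulate_case_control(panel, eff, c(HRD = 700, nonHRD = 700), 0,
                                seed = 500 + r, causal_snp = "snp002")
    case_only_test(co$genotypes, co$phenotype, snp_ids = "snp002")$beta
  }, double(1))
  se_mean <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas) - log(1.26)), 3 * se_mean)
})

test_that("association output exports to the COJO dialect and reads back", {
  g <- random_genotypes(200, 2, seed = 39)
  withr::with_seed(40, {
    status <- ifelse(rbinom(200, 1, 0.5) == 1, "case", "control")
  })
  pheno <- tibble::tibble(sample_id = g$sample_id, status = status)
  st <- assoc_to_summary_stats(fit_additive_logistic(g, pheno), g)
  expect_equal(st$a1, g$snps$alt)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(st, f)
  back <- read_summary_stats(f)
  expect_equal(back$b, st$b, tolerance = 1e-9)
})
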