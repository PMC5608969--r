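make_expr <- function(values, n_genes = nrow(values)) {
  genes <- tibble::tibble(gene_id = sprintf("g%02d", seq_len(n_genes)),
                          chrom = "chr5",
                          tss = seq(1e5, by = 1e4, length.out = n_genes))
  expression_matrix(values, genes, sprintf("s%03d", seq_len(ncol(values))))
}

test_that("zero factors returns the centered matrix, with a warning", {
  withr::with_seed(61, { v <- matrix(rnorm(5 * 40), 5, 40) })
  em <- make_expr(v)
  expect_warning(r <- residualize_expression(em, 0), "unchanged")
  expect_equal(r$values, v - rowMeans(v), ignore_attr = TRUE)
  expect_equal(dim(r$values), dim(v))
})

test_that("planted two-factor structure is almost fully removed", {
  withr::with_seed(62, {
    k <- 2; n_genes <- 20; n <- 100
    loadings <- matrix(rnorm(n_genes * k), n_genes, k)
    factors <- matrix(rnorm(k * n), k, n)
    v <- loadings %*% factors + matrix(rnorm(n_genes * n, sd = 0.05), n_genes, n)
  })
  em <- make_expr(v)
  r <- residualize_expression(em, 2)
  centered <- v - rowMeans(v)
  expect_lt(sum(r$values^2) / sum(centered^2), 0.05)
})

test_that("residuals are orthogonal to the removed components", {
  withr::with_seed(63, { v <- matrix(rnorm(8 * 60), 8, 60) })
  em <- make_expr(v)
  r <- residualize_expression(em, 3)
  x <- t(em$values); x <- scale(x, center = TRUE, scale = FALSE)
  u <- svd(x, nu = 3, nv = 0)$u
  expect_lt(max(abs(crossprod(u, t(r$values)))), 1e-8)
})

test_that("leave-one-out residualization does not leak a cis effect across genes", {
  g <- random_genotypes(400, 1, seed = 64)
  withr::with_seed(65, {
    v <- matrix(rnorm(6 * 400, sd = 0.8), 6, 400)
    v[1, ] <- v[1, ] + 0.8 * g$dosages[, 1]      # strong cis gene
  })
  em <- make_expr(v)
  r_joint <- residualize_expression(em, 2)
  r_loo <- residualize_expression(em, 2, exclude_self = TRUE)
  cor_null_joint <- max(abs(cor(t(r_joint$values[-1, ]), g$dosages[, 1])))
  cor_null_loo <- max(abs(cor(t(r_loo$values[-1, ]), g$dosages[, 1])))
  expect_lt(cor_null_loo, cor_null_joint)     # the leak the option removes
  expect_lt(cor_null_loo, 0.2)
  # and the cis gene's own signal survives
  expect_gt(abs(cor(r_loo$values[1, ], g$dosages[, 1])), 0.3)
})

test_that("cis scan recovers a planted effect and respects the window", {
  g <- random_genotypes(500, 5, seed = 66)
  eff <- effect_model(eqtl_beta = 0.5, n_hidden_factors = 0, noise_sd = 1)
  expr <- simulate_expression(g, eff, causal_snp = "rs003", n_studies = 1,
                              seed = 67)[[1]]
  res <- cis_eqtl_scan(g, expr, anchor_snp = "rs003", window_bp = 500000)
  hit <- res[res$snp_id == "rs003" & res$gene_id == "gene01", ]
  expect_lt(abs(hit$beta - 0.5), 3 * hit$se)

  only_anchor <- cis_eqtl_scan(g, expr, anchor_snp = "rs003", window_bp = 0)
  expect_setequal(unique(only_anchor$snp_id), "rs003")

  far <- g
  far$snps$pos <- c(1L, 2e6L, 4e6L, 6e6L, 8e6L)
  far <- genotype_matrix(far$snps, g$dosages, g$sample_id)
  expect_warning(none <- cis_eqtl_scan(far, expr, "rs001", window_bp = 100),
                 NA) # anchor itself is always in window
  expect_setequal(unique(none$snp_id), "rs001")
})

test_that("pooling matches meta_fixed arithmetic and passes single studies through", {
  df <- tibble::tibble(
    gene_id = "g01", snp_id = "rs1",
    beta = c(0.10, 0.20), se = c(0.05, 0.10), p = c(0.5, 0.5),
    n = c(100L, 200L), study_tag = c("a", "b")
  )
  pooled <- pool_eqtl(df)
  oracle <- meta_fixed(dplyr::transmute(df, snp_id, beta, se))
  expect_equal(pooled$beta, oracle$beta_pooled)
  expect_equal(pooled$se, oracle$se_pooled)
  expect_equal(pooled$p, oracle$p_pooled)
  expect_equal(pooled$q, oracle$q)

  single <- df[1, ]
  ps <- pool_eqtl(single)
  expect_equal(ps$beta, single$beta)
  expect_equal(ps$se, single$se)
  expect_equal(ps$p, single$p)
  expect_equal(ps$k_studies, 1L)

  # two equal studies shrink the SE by sqrt(2)
  eq <- dplyr::mutate(df, beta = 0.3, se = 0.1)
  expect_equal(pool_eqtl(eq)$se, 0.1 / sqrt(2))
})

test_that("the causal SNP usually attains the minimum eQTL p under pleiotropy", {
  panel <- simulate_haplotype_panel(locus_model(n_snps = 20, ld_decay = 0.8),
                                    1000, seed = 68)
  eff <- effect_model(eqtl_beta = 0.5, n_hidden_factors = 0, noise_sd = 1)
  wins <- vapply(1:30, function(r) {
    g <- simulate_case_control(panel, effect_model(or_overall = 1),
                               c(all = 500), 0, seed = 700 + r)$genotypes
    expr <- simulate_expression(g, eff, causal_snp = "snp010", n_studies = 1,
                                seed = 800 + r)[[1]]
    res <- cis_eqtl_scan(g, expr, anchor_snp = "snp010")
    res <- res[res$gene_id == "gene01", ]
    res$snp_id[which.min(res$p)] == "snp010"
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
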