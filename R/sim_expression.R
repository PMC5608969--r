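#' Simulate multi-study expression with a planted cis-eQTL
#'
#' For each study, expression of the target gene is
#' `eqtl_beta * dosage(eQTL SNP) + loadings %*% hidden factors + noise`;
#' the remaining genes carry only the hidden-factor structure and noise.
#' Under `scenario = "pleiotropy"` the eQTL SNP is the disease causal SNP
#' itself; under `"linkage"` it is the SNP whose sample `r2` with the
#' disease causal SNP is closest to `linkage_r2` (an error lists the
#' achievable `r2` range when none is within 0.15); under `"null"` the
#' eQTL effect is zero.
#'
#' Hidden factors are per-sample standard Gaussians with N(0, 0.5^2)
#' loadings shared across genes within a study — the broad expression
#' confounders that latent-factor residualization is meant to absorb.
#' Studies share the causal architecture but have independent factors and
#' noise (per-study seeds are derived from `seed` by fixed offsets).
#'
#' @param genotypes A [genotype_matrix()] or a list of them, one per study;
#'   a single matrix is reused for every study.
#' @param effects An [effect_model()].
#' @param causal_snp Id of the disease causal SNP.
#' @param n_studies Number of studies (ignored when `genotypes` is a list).
#' @param seed Integer master seed.
#' @param n_genes Number of genes (gene 1, `"gene01"`, is the cis target).
#' @param tss_spread_bp Genes get deterministic TSS positions within this
#'   window around the causal SNP so a cis window is well defined.
#' @return A list of [expression_matrix()] objects, one per study, each
#'   with attribute `eqtl_snp` naming the expression causal SNP.
#' @export
simulate_expression <- function(genotypes, effects, causal_snp,
                                n_studies = 2, seed = 1, n_genes = 6,
                                tss_spread_bp = 400000) {
  stopifnot(inherits(effects, "effect_model"))
  if (inherits(genotypes, "genotype_matrix")) {
    genotypes <- rep(list(genotypes), n_studies)
  }
  n_studies <- length(genotypes)
  snps <- genotypes[[1]]$snps
  causal_col <- match(causal_snp, snps$id)
  if (is.na(causal_col)) {
    abort(sprintf("causal SNP '%s' not in genotypes", causal_snp),
          class = "tidylocus_lookup_error")
  }

  eqtl_snp <- causal_snp
  if (effects$scenario == "linkage") {
    g <- genotypes[[1]]$dosages
    r2 <- suppressWarnings(cor(g, g[, causal_col])[, 1]^2)
    r2[causal_col] <- NA  # must differ from the disease SNP
    if (all(is.na(r2)) || min(abs(r2 - effects$linkage_r2), na.rm = TRUE) > 0.15) {
      abort(sprintf(
        "no SNP near target r2 = %.2f with the causal SNP; achievable r2 in [%.3f, %.3f]",
        effects$linkage_r2, min(r2, na.rm = TRUE), max(r2, na.rm = TRUE)),
        class = "tidylocus_validation_error")
    }
    eqtl_snp <- snps$id[which.min(abs(r2 - effects$linkage_r2))]
  }
  beta <- if (effects$scenario == "null") 0 else effects$eqtl_beta

  causal_pos <- snps$pos[causal_col]
  genes <- tibble::tibble(
    gene_id = sprintf("gene%02d", seq_len(n_genes)),
    chrom = snps$chrom[1],
    tss = as.integer(causal_pos +
      round(seq(-tss_spread_bp / 2, tss_spread_bp / 2, length.out = n_genes)))
  )
  genes$tss[1] <- causal_pos + 5000L  # target gene sits beside the locus

  k <- effects$n_hidden_factors
  out <- lapply(seq_len(n_studies), function(s) {
    withr::local_seed(derive_seed(seed, 100 + s))
    dos <- genotypes[[s]]$dosages
    n <- nrow(dos)
    values <- matrix(rnorm(n_genes * n, sd = effects$noise_sd), n_genes, n)
    if (k > 0) {
      loadings <- matrix(rnorm(n_genes * k, sd = 0.5), n_genes, k)
      factors <- matrix(rnorm(k * n), k, n)
      values <- values + loadings %*% factors
    }
    values[1, ] <- values[1, ] + beta * dos[, eqtl_snp]
    em <- expression_matrix(values, genes, genotypes[[s]]$sample_id)
    attr(em, "eqtl_snp") <- eqtl_snp
    em
  })
  attr(out, "eqtl_snp") <- eqtl_snp
  out
}
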