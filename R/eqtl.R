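#' Remove broad latent variance components from expression
#'
#' Centers each gene and removes the top `n_factors` principal components
#' of the sample-by-gene matrix, the deterministic counterpart of
#' latent-factor (PEER-style) residualization: broad variance shared by
#' many genes — batch, cell-composition and other hidden determinants of
#' global expression — is absorbed before eQTL scanning, while the local
#' genotype signal of any single gene is essentially untouched for small
#' `n_factors`.
#'
#' With few genes a strong cis effect on one gene can dominate a principal
#' component, and subtracting that component would smear the genotype
#' signal into every other gene's residuals. `exclude_self = TRUE` guards
#' against this by estimating, for each gene in turn, the sample-space
#' components from the remaining genes only and projecting them out of
#' that gene — the leave-one-out analogue of excluding the focal gene
#' from factor estimation.
#'
#' @param expr An [expression_matrix()].
#' @param n_factors Number of components to remove; must be smaller than
#'   `min(n_genes, n_samples)`. `n_factors <= 0` returns the centered
#'   matrix with a warning.
#' @param exclude_self Estimate each gene's removed components from the
#'   other genes only (default `FALSE`: joint components).
#' @return An [expression_matrix()] of residuals, same shape as the input.
#' @export
residualize_expression <- function(expr, n_factors = 2, exclude_self = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  n_genes <- nrow(expr$values); n_samples <- ncol(expr$values)
  x <- t(expr$values)                       # samples x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  if (n_factors <= 0) {
    warn("n_factors <= 0: returning centered expression unchanged")
    return(expression_matrix(t(x), expr$genes, expr$sample_id))
  }
  if (n_factors >= min(n_genes, n_samples) - exclude_self) {
    abort("n_factors must be < min(n_genes, n_samples)",
          class = "tidylocus_validation_error")
  }
  if (!exclude_self) {
    sv <- svd(x, nu = n_factors, nv = n_factors)
    removed <- sv$u %*% (diag(sv$d[seq_len(n_factors)], n_factors) %*% t(sv$v))
    resid <- x - removed
  } else {
    resid <- x
    for (i in seq_len(n_genes)) {
      u <- svd(x[, -i, drop = FALSE], nu = n_factors, nv = 0)$u
      resid[, i] <- x[, i] - u %*% crossprod(u, x[, i])
    }
  }
  expression_matrix(t(resid), expr$genes, expr$sample_id)
}

#' Cis-eQTL scan around an anchor SNP
#'
#' Ordinary least squares of (residualized) expression on dosage, for
#' every SNP within `window_bp` of the anchor SNP and every gene, with a
#' t-based two-sided p-value on `n - 2` degrees of freedom. Missing
#' dosages drop the sample for that SNP only.
#'
#' @param genotypes A [genotype_matrix()].
#' @param expr An [expression_matrix()] (typically the output of
#'   [residualize_expression()]) sharing samples with `genotypes`.
#' @param anchor_snp SNP id anchoring the cis window.
#' @param window_bp Half-window in bp (500 kb either side by default).
#' @param study_tag Label carried into the result.
#' @return Tibble: `snp_id`, `gene_id`, `beta`, `se`, `p`, `n`,
#'   `study_tag`. Empty (with a warning) when no SNP is in the window.
#' @export
cis_eqtl_scan <- function(genotypes, expr, anchor_snp, window_bp = 500000,
                          study_tag = "study1") {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(expr, "expression_matrix"))
  anchor <- match(anchor_snp, genotypes$snps$id)
  if (is.na(anchor)) {
    abort(sprintf("anchor SNP '%s' not in genotypes", anchor_snp),
          class = "tidylocus_lookup_error")
  }
  in_window <- abs(genotypes$snps$pos - genotypes$snps$pos[anchor]) <= window_bp
  snp_ids <- genotypes$snps$id[in_window]
  if (!length(snp_ids)) {
    warn("no SNPs in the cis window")
    return(tibble::tibble(snp_id = character(), gene_id = character(),
                          beta = double(), se = double(), p = double(),
                          n = integer(), study_tag = character()))
  }
  shared <- intersect(expr$sample_id, genotypes$sample_id)
  e <- expr$values[, shared, drop = FALSE]
  d <- genotypes$dosages[shared, , drop = FALSE]
  grid <- tidyr::expand_grid(snp_id = snp_ids, gene_id = expr$genes$gene_id)
  purrr::pmap_dfr(grid, function(snp_id, gene_id) {
    x <- d[, snp_id]; y <- e[gene_id, ]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3 || var(x) == 0) {
      return(tibble::tibble(snp_id = snp_id, gene_id = gene_id,
                            beta = NA_real_, se = NA_real_, p = NA_real_,
                            n = n, study_tag = study_tag))
    }
    fit <- lm(y ~ x)
    cf <- summary(fit)$coefficients
    tibble::tibble(snp_id = snp_id, gene_id = gene_id,
                   beta = cf["x", "Estimate"], se = cf["x", "Std. Error"],
                   p = cf["x", "Pr(>|t|)"], n = n, study_tag = study_tag)
  })
}

#' Pool per-study eQTL results under a fixed-effects model
#'
#' Inverse-variance pooling of each (gene, SNP) pair across studies, with
#' the identical arithmetic to [meta_fixed()]. A pair observed in a single
#' study passes through unchanged.
#'
#' @param per_study A list of per-study eQTL tibbles (or one bound tibble
#'   with a `study_tag` column) as returned by [cis_eqtl_scan()].
#' @return Tibble: `snp_id`, `gene_id`, `beta`, `se`, `p`, `n`,
#'   `k_studies`, `q`, `p_het`; `study_tag = "pooled"`.
#' @export
pool_eqtl <- function(per_study) {
  df <- if (is.data.frame(per_study)) tibble::as_tibble(per_study) else
    dplyr::bind_rows(per_study)
  df <- df[!is.na(df$beta) & !is.na(df$se), , drop = FALSE]
  out <- dplyr::group_by(df, .data$gene_id, .data$snp_id)
  out <- dplyr::group_modify(out, function(g, key) {
    if (nrow(g) == 0) {
      return(tibble::tibble(beta = double(), se = double(), p = double(),
                            n = integer(), k_studies = integer(),
                            q = double(), p_het = double()))
    }
    if (nrow(g) == 1) {
      return(tibble::tibble(beta = g$beta, se = g$se, p = g$p, n = g$n,
                            k_studies = 1L, q = 0, p_het = NA_real_))
    }
    w <- 1 / g$se^2
    beta <- sum(w * g$beta) / sum(w)
    se <- sum(w)^(-0.5)
    q <- sum(w * (g$beta - beta)^2)
    tibble::tibble(
      beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
      n = sum(g$n), k_studies = nrow(g), q = q,
      p_het = pchisq(q, df = nrow(g) - 1, lower.tail = FALSE)
    )
  })
  out <- dplyr::ungroup(out)
  out$study_tag <- "pooled"
  out
}
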