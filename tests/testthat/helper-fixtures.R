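# Shared fixture builders. Everything is generated in code; no stored data.

# panel from explicit two-SNP haplotype counts (AB, Ab, aB, ab), where
# "A"/"B" denote allele 1 at the first/second SNP
panel_from_counts <- function(n_AB, n_Ab, n_aB, n_ab) {
  h <- rbind(
    matrix(rep(c(1L, 1L), n_AB), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 0L), n_Ab), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 1L), n_aB), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 0L), n_ab), ncol = 2, byrow = TRUE)
  )
  if (nrow(h) %% 2L == 1L) h <- rbind(h, h[1, ])  # keep haplotype count even
  haplotype_panel(snp_table(c("sA", "sB"), "chr5", c(100L, 200L),
                            c("A", "C"), c("G", "T")), h)
}

# independently coded IRLS logistic oracle (Newton scoring on the logit),
# returning beta and Wald SE for each design column
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * w, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- 1 / (1 + exp(-drop(X %*% beta)))
  info <- crossprod(X * (mu * (1 - mu)), X)   # information at the optimum
  se <- sqrt(diag(solve(info)))
  list(beta = beta, se = se)
}

# random genotype matrix with independent binomial dosages
random_genotypes <- function(n_samples, n_snps, maf = 0.3, seed = 1) {
  withr::with_seed(seed, {
    d <- matrix(rbinom(n_samples * n_snps, 2, maf), n_samples, n_snps)
    snps <- snp_table(sprintf("rs%03d", seq_len(n_snps)), "chr5",
                      seq(1e5, by = 1000, length.out = n_snps),
                      rep("A", n_snps), rep("G", n_snps))
    genotype_matrix(snps, d, sprintf("ind%04d", seq_len(n_samples)))
  })
}
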