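#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-study effects with weights `w_i = 1/se_i^2`:
#' `beta_pooled = sum(w b) / sum(w)`, `se_pooled = sum(w)^(-1/2)`,
#' Cochran's heterogeneity `Q = sum(w (b - beta_pooled)^2)` with
#' `p_het` from a chi-square on `k - 1` degrees of freedom, and a
#' two-sided normal `p_pooled`. When several SNPs are present the pooling
#' is done per SNP.
#'
#' If the input carries effect-allele columns (`a1`, `a2`), studies
#' reporting opposite alleles for the same SNP are sign-flipped to the
#' first study's orientation; any other allele disagreement is an error.
#'
#' @param results Tibble with one row per study (and per SNP), columns
#'   `beta`/`b` and `se`; optional `snp_id`/`snp`, `a1`, `a2`,
#'   `n_cases`/`n_controls` or `n`.
#' @return Tibble with one row per SNP: `snp_id`, `beta_pooled`,
#'   `se_pooled`, `p_pooled`, `q`, `p_het`, `k_studies`.
#' @examples
#' meta_fixed(tibble::tibble(beta = c(0.10, 0.20), se = c(0.05, 0.10)))
#' @export
meta_fixed <- function(results) {
  results <- tibble::as_tibble(results)
  if (!"beta" %in% names(results) && "b" %in% names(results)) results$beta <- results$b
  if (!"snp_id" %in% names(results)) {
    results$snp_id <- if ("snp" %in% names(results)) results$snp else "(snp)"
  }
  stopifnot(all(c("beta", "se") %in% names(results)))
  results <- results[!is.na(results$beta) & !is.na(results$se), , drop = FALSE]
  out <- dplyr::group_by(results, .data$snp_id)
  empty <- tibble::tibble(beta_pooled = double(), se_pooled = double(),
                          p_pooled = double(), q = double(), p_het = double(),
                          k_studies = integer())
  out <- dplyr::group_modify(out, function(df, key) {
    if (nrow(df) == 0) return(empty)
    if (nrow(df) < 2) {
      abort(sprintf("meta-analysis needs >= 2 studies (snp %s has %d)",
                    key$snp_id, nrow(df)),
            class = "tidylocus_validation_error")
    }
    b <- df$beta
    if (all(c("a1", "a2") %in% names(df))) {
      same <- df$a1 == df$a1[1] & df$a2 == df$a2[1]
      flipped <- df$a1 == df$a2[1] & df$a2 == df$a1[1]
      if (!all(same | flipped)) {
        abort(sprintf("effect-allele mismatch across studies for %s", key$snp_id),
              class = "tidylocus_harmonization_error")
      }
      b <- ifelse(flipped, -b, b)
    }
    w <- 1 / df$se^2
    beta_pooled <- sum(w * b) / sum(w)
    se_pooled <- sum(w)^(-0.5)
    q <- sum(w * (b - beta_pooled)^2)
    tibble::tibble(
      beta_pooled = beta_pooled,
      se_pooled = se_pooled,
      p_pooled = 2 * pnorm(-abs(beta_pooled / se_pooled)),
      q = q,
      p_het = pchisq(q, df = nrow(df) - 1, lower.tail = FALSE),
      k_studies = nrow(df)
    )
  })
  dplyr::ungroup(out)
}
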