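#' Summary-data Mendelian randomization (SMR) test
#'
#' Tests whether a SNP's disease and expression associations are
#' consistent with a single shared signal. With `z_gwas = b_gwas/se_gwas`
#' and `z_eqtl = b_eqtl/se_eqtl`, the Wald-ratio effect of expression on
#' the trait is `b_xy = b_gwas/b_eqtl` and the test statistic is
#'
#'   `T_SMR = z_gwas^2 * z_eqtl^2 / (z_gwas^2 + z_eqtl^2)`
#'
#' referred to a chi-square with 1 df. `T_SMR` is symmetric in the two z
#' scores, bounded by the smaller of them squared, and invariant to
#' flipping both effect alleles together. The standard error of `b_xy`
#' comes from first-order error propagation of the ratio.
#'
#' @param b_gwas,se_gwas GWAS effect (log-odds) and standard error at the
#'   shared SNP, effect allele harmonized with the eQTL.
#' @param b_eqtl,se_eqtl eQTL effect (log2 expression per allele) and
#'   standard error; `b_eqtl` must be nonzero.
#' @return One-row tibble: `b_xy`, `se_xy`, `t_smr`, `p_smr`.
#' @examples
#' smr_test(b_gwas = 0.2, se_gwas = 0.05, b_eqtl = -0.48, se_eqtl = 0.08)
#' @export
smr_test <- function(b_gwas, se_gwas, b_eqtl, se_eqtl) {
  if (se_gwas <= 0 || se_eqtl <= 0) {
    abort("standard errors must be > 0", class = "tidylocus_validation_error")
  }
  if (b_eqtl == 0) {
    abort("b_eqtl = 0: Wald ratio undefined", class = "tidylocus_validation_error")
  }
  z_g <- b_gwas / se_gwas
  z_e <- b_eqtl / se_eqtl
  t_smr <- (z_g^2 * z_e^2) / (z_g^2 + z_e^2)
  b_xy <- b_gwas / b_eqtl
  se_xy <- sqrt(se_gwas^2 / b_eqtl^2 + b_gwas^2 * se_eqtl^2 / b_eqtl^4)
  tibble::tibble(
    b_xy = b_xy, se_xy = se_xy, t_smr = t_smr,
    p_smr = pchisq(t_smr, df = 1, lower.tail = FALSE)
  )
}

#' Bonferroni significance threshold
#'
#' `alpha / m_tests`; with `alpha = 0.05` over six expression probes this
#' is the 0.00833 cutoff conventionally applied to locus-wide SMR scans.
#'
#' @param alpha Family-wise error rate in `(0, 1)`.
#' @param m_tests Number of tests (>= 1).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_tests) {
  if (alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)", class = "tidylocus_validation_error")
  }
  if (m_tests < 1) {
    abort("m_tests must be >= 1", class = "tidylocus_validation_error")
  }
  alpha / m_tests
}

#' Flag probes passing both the SMR and HEIDI criteria
#'
#' A probe passes when `p_smr` beats the Bonferroni threshold over the
#' probes tested AND `p_heidi > heidi_alpha` (no heterogeneity, i.e. the
#' pleiotropy model is not rejected). Probes whose HEIDI p is `NA`
#' (too few eligible SNPs) are reported but never flagged as passing.
#'
#' @param smr_results Tibble with `p_smr` and `p_heidi` columns (one row
#'   per probe/gene).
#' @param alpha Family-wise SMR error rate (default 0.05).
#' @param heidi_alpha HEIDI rejection level (default 0.05).
#' @param m_tests Bonferroni denominator; defaults to the number of probes
#'   actually tested.
#' @return The input with `smr_threshold` and logical `passes` added.
#' @export
classify_probes <- function(smr_results, alpha = 0.05, heidi_alpha = 0.05,
                            m_tests = NULL) {
  smr_results <- tibble::as_tibble(smr_results)
  m_tests <- m_tests %||% nrow(smr_results)
  thr <- bonferroni_threshold(alpha, m_tests)
  dplyr::mutate(smr_results,
    smr_threshold = thr,
    passes = !is.na(.data$p_smr) & .data$p_smr < thr &
      !is.na(.data$p_heidi) & .data$p_heidi > heidi_alpha
  )
}
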