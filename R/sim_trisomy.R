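#' Simulate allele-specific read counts for trisomic heterozygous tumors
#'
#' Each tumor is trisomic and heterozygous at the risk variant, so one
#' allele is present in two copies. The true amplified allele is drawn
#' `Bernoulli(p_risk_amplified)` once per sample and shared by its proxy
#' SNPs (they tag the same haplotype). Tumor risk-read counts are binomial
#' with success probability `2b/(2b + 1)` when the risk allele is amplified
#' and `b/(b + 2)` otherwise, where `b` is the reference-mapping bias odds
#' (`b = 1` means unbiased). Germline counts are binomial around the
#' bias-distorted heterozygote fraction `b/(1 + b)` and carry no copy
#' signal; they are what [estimate_bias()] uses.
#'
#' Read depths are Poisson around their means, floored at 1.
#'
#' @param n_samples Number of tumors.
#' @param depth_mean Mean tumor read depth per proxy SNP (>= 1).
#' @param p_risk_amplified Probability the duplicated homolog carries the
#'   risk allele.
#' @param bias_odds Multiplicative odds distortion toward risk reads
#'   caused by reference mapping bias.
#' @param seed Integer seed.
#' @param n_proxy_snps Proxy SNPs per sample sharing the amplified state.
#' @param germline_depth_mean Mean germline depth (defaults to `depth_mean`).
#' @return Tibble with `sample_id`, `snp_id`, `tumor_risk`,
#'   `tumor_nonrisk`, `germline_risk`, `germline_nonrisk` and the latent
#'   `true_state` (for validation only; the classifier never sees it).
#' @export
simulate_trisomy_counts <- function(n_samples, depth_mean = 60,
                                    p_risk_amplified = 0.5, bias_odds = 1,
                                    seed = 1, n_proxy_snps = 2,
                                    germline_depth_mean = depth_mean) {
  if (depth_mean < 1) abort("depth_mean must be >= 1", class = "tidylocus_validation_error")
  if (bias_odds <= 0) abort("bias_odds must be > 0", class = "tidylocus_validation_error")
  withr::local_seed(seed)
  states <- ifelse(rbinom(n_samples, 1, p_risk_amplified) == 1,
                   "risk_amplified", "nonrisk_amplified")
  p_state <- ifelse(states == "risk_amplified",
                    2 * bias_odds / (2 * bias_odds + 1),
                    bias_odds / (bias_odds + 2))
  p_germ <- bias_odds / (1 + bias_odds)
  rows <- tidyr::expand_grid(
    sample_idx = seq_len(n_samples),
    snp_id = sprintf("proxy%d", seq_len(n_proxy_snps))
  )
  t_depth <- pmax(1L, rpois(nrow(rows), depth_mean))
  g_depth <- pmax(1L, rpois(nrow(rows), germline_depth_mean))
  t_risk <- rbinom(nrow(rows), t_depth, p_state[rows$sample_idx])
  g_risk <- rbinom(nrow(rows), g_depth, p_germ)
  tibble::tibble(
    sample_id = sprintf("tumor%04d", rows$sample_idx),
    snp_id = rows$snp_id,
    tumor_risk = t_risk,
    tumor_nonrisk = t_depth - t_risk,
    germline_risk = g_risk,
    germline_nonrisk = g_depth - g_risk,
    true_state = states[rows$sample_idx]
  )
}
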