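#' Estimate reference-mapping bias from germline heterozygote counts
#'
#' A germline heterozygote has a true 1:1 allele ratio, so any systematic
#' departure in its read counts measures mapping bias. The bias odds is
#' `b = (sum(germline_risk) + c) / (sum(germline_nonrisk) + c)` with
#' pseudo-count `c = 0.5`: the multiplicative distortion of the odds of
#' observing a risk read. Below `min_depth` total germline reads the
#' estimate is unreliable and `b = 1` is returned with a warning.
#'
#' @param records Tibble with `germline_risk` and `germline_nonrisk`
#'   columns (one sample's proxy SNPs, or a whole cohort).
#' @param min_depth Minimum total germline depth (default 10).
#' @param pseudo_count Haldane-style stabilizer (default 0.5).
#' @return The bias odds `b` (scalar).
#' @examples
#' estimate_bias(tibble::tibble(germline_risk = 60, germline_nonrisk = 40))
#' @export
estimate_bias <- function(records, min_depth = 10, pseudo_count = 0.5) {
  risk <- sum(records$germline_risk)
  nonrisk <- sum(records$germline_nonrisk)
  if (risk + nonrisk < min_depth) {
    warn(sprintf("germline depth %d < %d: assuming no mapping bias",
                 risk + nonrisk, min_depth))
    return(1)
  }
  (risk + pseudo_count) / (nonrisk + pseudo_count)
}

#' Call the amplified allele of one trisomic tumor
#'
#' In a trisomic heterozygote one allele is present in two of three
#' copies. With mapping-bias odds `b`, the expected risk-read fraction is
#' `p_R = 2b/(2b + 1)` if the risk allele is amplified and
#' `p_N = b/(b + 2)` if not (both increase monotonically in `b`). Tumor
#' counts at the sample's proxy SNPs — which tag the same haplotype, so
#' share one latent state — contribute additive binomial log-likelihoods,
#' and the call is the maximum-likelihood state; `|llr| <= tie_epsilon`
#' is `"ambiguous"`.
#'
#' @param records Tibble of the sample's proxy-SNP rows with `tumor_risk`
#'   and `tumor_nonrisk` counts.
#' @param bias Bias odds `b` from [estimate_bias()].
#' @param tie_epsilon Log-likelihood margin below which the call is
#'   ambiguous (default 1e-9: machine-level ties only).
#' @return One-row tibble: `state`, `loglik_risk`, `loglik_nonrisk`, `llr`.
#' @examples
#' call_amplification(tibble::tibble(tumor_risk = 40, tumor_nonrisk = 20))
#' @export
call_amplification <- function(records, bias = 1, tie_epsilon = 1e-9) {
  depth <- records$tumor_risk + records$tumor_nonrisk
  if (any(depth < 1)) {
    abort("tumor depth must be >= 1 at every proxy SNP",
          class = "tidylocus_validation_error")
  }
  p_r <- 2 * bias / (2 * bias + 1)
  p_n <- bias / (bias + 2)
  ll_r <- sum(dbinom(records$tumor_risk, depth, p_r, log = TRUE))
  ll_n <- sum(dbinom(records$tumor_risk, depth, p_n, log = TRUE))
  llr <- ll_r - ll_n
  state <- if (llr > tie_epsilon) "risk_amplified"
           else if (llr < -tie_epsilon) "nonrisk_amplified"
           else "ambiguous"
  tibble::tibble(state = state, loglik_risk = ll_r, loglik_nonrisk = ll_n,
                 llr = llr)
}

#' Call every tumor in an allele-count table
#'
#' Groups records by sample, estimates a per-sample bias from that
#' sample's germline counts (falling back to `bias = 1` at low depth) and
#' calls the amplified allele with [call_amplification()].
#'
#' @param counts Tibble with `sample_id`, `snp_id`, `tumor_risk`,
#'   `tumor_nonrisk`, `germline_risk`, `germline_nonrisk` (as produced by
#'   [simulate_trisomy_counts()] or read from TSV).
#' @param tie_epsilon Passed to [call_amplification()].
#' @param min_depth Passed to [estimate_bias()].
#' @return Tibble, one row per sample: `sample_id`, `bias`, `state`,
#'   `loglik_risk`, `loglik_nonrisk`, `llr`.
#' @export
call_amplification_cohort <- function(counts, tie_epsilon = 1e-9,
                                      min_depth = 10) {
  out <- dplyr::group_by(counts, .data$sample_id)
  out <- dplyr::group_modify(out, function(df, key) {
    if (nrow(df) == 0) {
      return(tibble::tibble(bias = double(), state = character(),
                            loglik_risk = double(), loglik_nonrisk = double(),
                            llr = double()))
    }
    b <- suppressWarnings(estimate_bias(df, min_depth = min_depth))
    dplyr::mutate(call_amplification(df, bias = b, tie_epsilon = tie_epsilon),
                  bias = b, .before = 1)
  })
  dplyr::ungroup(out)
}

#' Cohort-level test of preferential risk-allele amplification
#'
#' Exact two-sided binomial test of the number of risk-amplified calls
#' among unambiguous calls against the symmetric expectation of one half.
#' Ambiguous calls are excluded and counted.
#'
#' @param calls Tibble with a `state` column (from
#'   [call_amplification_cohort()]).
#' @return One-row tibble: `k_risk`, `n_unambiguous`, `n_ambiguous`,
#'   `proportion`, `p`.
#' @export
cohort_amplification_test <- function(calls) {
  n_amb <- sum(calls$state == "ambiguous")
  unamb <- calls$state[calls$state != "ambiguous"]
  n <- length(unamb)
  if (n == 0) {
    abort("no unambiguous calls to test", class = "tidylocus_validation_error")
  }
  k <- sum(unamb == "risk_amplified")
  p <- binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
  tibble::tibble(k_risk = k, n_unambiguous = n, n_ambiguous = n_amb,
                 proportion = k / n, p = p)
}
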