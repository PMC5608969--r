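#' Simulate a retrospective case/control cohort from a haplotype panel
#'
#' Individuals are formed by pairing haplotypes drawn with replacement from
#' the panel. Disease follows a logistic model that is additive in the
#' causal-SNP dosage with a subtype-specific log-odds; cases are obtained
#' by rejection sampling with acceptance probability proportional to
#' `exp(beta_s * dosage)` — the retrospective sampling distribution of a
#' rare logistic disease, under which the case-control odds ratio equals
#' the population odds ratio. Controls are drawn directly from the panel
#' and carry no effect.
#'
#' Subtype is assigned before case sampling (each subtype has its own odds
#' ratio), mirroring a subtype-stratified design where tumor class is a
#' property of the case, not a second phenotype.
#'
#' @param panel A [haplotype_panel()].
#' @param effects An [effect_model()]; `or_subtype[s]` is used for subtype
#'   `s`, falling back to `or_overall` for subtypes it does not name.
#' @param n_cases_by_subtype Named integer vector, cases per subtype,
#'   e.g. `c(HRD = 700, nonHRD = 700)`.
#' @param n_controls Number of controls.
#' @param seed Integer seed.
#' @param causal_snp Id of the causal SNP; defaults to the panel's middle SNP.
#' @return A list with `genotypes` (a [genotype_matrix()]) and `phenotype`
#'   (a tibble with `sample_id`, `status`, `subtype`).
#' @examples
#' panel <- simulate_haplotype_panel(locus_model(n_snps = 10), 400, seed = 1)
#' cohort <- simulate_case_control(panel, effect_model(),
#'                                 c(HRD = 50, nonHRD = 50), 100, seed = 2)
#' dplyr::count(cohort$phenotype, status, subtype)
#' @export
simulate_case_control <- function(panel, effects, n_cases_by_subtype,
                                  n_controls, seed = 1, causal_snp = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(effects, "effect_model"))
  if (nrow(panel$haplotypes) == 0) {
    abort("cannot sample from an empty panel", class = "tidylocus_validation_error")
  }
  if (is.null(names(n_cases_by_subtype))) {
    abort("n_cases_by_subtype must be a named vector",
          class = "tidylocus_validation_error")
  }
  causal_snp <- causal_snp %||% panel$snps$id[ceiling(nrow(panel$snps) / 2)]
  causal_col <- match(causal_snp, panel$snps$id)
  if (is.na(causal_col)) {
    abort(sprintf("causal SNP '%s' not in panel", causal_snp),
          class = "tidylocus_lookup_error")
  }
  withr::local_seed(seed)
  n_hap <- nrow(panel$haplotypes)

  draw_genotypes <- function(n) {
    h1 <- sample.int(n_hap, n, replace = TRUE)
    h2 <- sample.int(n_hap, n, replace = TRUE)
    panel$haplotypes[h1, , drop = FALSE] + panel$haplotypes[h2, , drop = FALSE]
  }

  sample_cases <- function(n, beta) {
    out <- matrix(0L, 0L, ncol(panel$haplotypes))
    while (nrow(out) < n) {
      g <- draw_genotypes(max(2L * (n - nrow(out)), 64L))
      # acceptance ~ exp(beta * dosage), normalized by its maximum over 0..2
      acc <- exp(beta * g[, causal_col] - 2 * max(beta, 0))
      keep <- stats::runif(nrow(g)) < acc
      out <- rbind(out, g[keep, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }

  subtype_beta <- function(s) {
    or_s <- if (s %in% names(effects$or_subtype)) effects$or_subtype[[s]] else effects$or_overall
    log(or_s)
  }

  case_blocks <- lapply(names(n_cases_by_subtype), function(s) {
    sample_cases(n_cases_by_subtype[[s]], subtype_beta(s))
  })
  controls <- draw_genotypes(n_controls)
  dosages <- do.call(rbind, c(case_blocks, list(controls)))
  n_cases <- sum(n_cases_by_subtype)
  sample_id <- sprintf("sample%05d", seq_len(n_cases + n_controls))
  phenotype <- tibble::tibble(
    sample_id = sample_id,
    status = rep(c("case", "control"), c(n_cases, n_controls)),
    subtype = c(rep(names(n_cases_by_subtype), n_cases_by_subtype),
                rep(NA_character_, n_controls))
  )
  list(
    genotypes = genotype_matrix(panel$snps, dosages, sample_id),
    phenotype = validate_phenotype(phenotype),
    causal_snp = causal_snp
  )
}
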