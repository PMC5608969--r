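#' Additive logistic association per SNP
#'
#' Maximum-likelihood logistic regression of case status on alternate-
#' allele dosage (plus any covariates), one SNP at a time, reporting the
#' Wald log-odds `beta`, its standard error, the two-sided p-value and the
#' odds ratio `exp(beta)`. Dosages may be fractional (imputation-style).
#' Monomorphic SNPs are skipped with a reason; fits that fail to converge
#' within 25 IRLS iterations (separation) are flagged with `p = NA`, never
#' an error. Missing dosages drop that sample for that SNP only.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype Phenotype tibble (`sample_id`, `status`, optionally
#'   `subtype` and numeric covariate columns).
#' @param covariates Character vector of covariate column names in
#'   `phenotype`.
#' @param subset Optional sample ids to restrict to.
#' @param snp_ids SNPs to test (default: all).
#' @param model_tag Label stored in the result (`"overall"`, `"HRD"`, ...).
#' @return Tibble with one row per SNP: `snp_id`, `beta`, `se`, `p`, `or_`,
#'   `n_cases`, `n_controls`, `model_tag`, `note` (`NA` when clean).
#' @examples
#' panel <- simulate_haplotype_panel(locus_model(n_snps = 6), 400, seed = 1)
#' cohort <- simulate_case_control(panel, effect_model(),
#'                                 c(HRD = 80, nonHRD = 80), 160, seed = 2)
#' fit_additive_logistic(cohort$genotypes, cohort$phenotype)
#' @export
fit_additive_logistic <- function(genotypes, phenotype, covariates = NULL,
                                  subset = NULL, snp_ids = NULL,
                                  model_tag = "overall") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  phenotype <- validate_phenotype(phenotype)
  keep <- phenotype$sample_id %in% genotypes$sample_id
  phenotype <- phenotype[keep, , drop = FALSE]
  if (!is.null(subset)) phenotype <- phenotype[phenotype$sample_id %in% subset, , drop = FALSE]
  idx <- match(phenotype$sample_id, genotypes$sample_id)
  y <- as.integer(phenotype$status == "case")
  if (sum(y) < 1 || sum(1 - y) < 1) {
    abort("need at least one case and one control", class = "tidylocus_validation_error")
  }
  covar_mat <- if (length(covariates)) {
    as.matrix(phenotype[, covariates, drop = FALSE])
  } else NULL
  snp_ids <- snp_ids %||% genotypes$snps$id
  purrr::map_dfr(snp_ids, function(s) {
    dose <- genotypes$dosages[idx, s]
    fit_one_logistic(s, y, dose, covar_mat, model_tag)
  })
}

# single-SNP Wald logistic fit shared by the association entry points;
# extra_covar columns are appended to the design after the dosage
fit_one_logistic <- function(snp_id, y, dose, extra_covar, model_tag,
                             extra_note = NA_character_) {
  ok <- !is.na(dose) & !is.na(y)
  if (!is.null(extra_covar)) ok <- ok & complete.cases(extra_covar)
  y <- y[ok]; dose <- dose[ok]
  n_cases <- sum(y); n_controls <- sum(1 - y)
  row <- function(beta, se, p, note) {
    tibble::tibble(snp_id = snp_id, beta = beta, se = se, p = p,
                   or_ = exp(beta), n_cases = n_cases, n_controls = n_controls,
                   model_tag = model_tag, note = note)
  }
  if (length(unique(dose)) < 2) {
    return(row(NA_real_, NA_real_, NA_real_, "skipped: monomorphic"))
  }
  x <- cbind(dose = dose)
  if (!is.null(extra_covar)) x <- cbind(x, extra_covar[ok, , drop = FALSE])
  fit <- suppressWarnings(
    glm(y ~ x, family = stats::binomial(),
        control = list(maxit = 25, epsilon = 1e-10))
  )
  if (anyNA(coef(fit))) {  # aliased column in the design
    return(row(NA_real_, NA_real_, NA_real_, "flagged: collinear dosage"))
  }
  # Wald SE from the observed information at the converged coefficients
  # (summary.glm reports the penultimate IWLS iteration's weights)
  xx <- stats::model.matrix(fit)
  mu <- fit$fitted.values
  info <- crossprod(xx * (mu * (1 - mu)), xx)
  i <- 2L  # dosage is the first design column after the intercept
  beta <- unname(coef(fit)[i])
  se <- unname(sqrt(diag(solve(info)))[i])
  diverged <- !fit$converged || abs(beta) > 15 || se > 50
  if (diverged) {
    return(row(NA_real_, NA_real_, NA_real_, "flagged: separation/non-convergence"))
  }
  row(beta, se, 2 * pnorm(-abs(beta / se)), extra_note)
}

#' Conditional association scan
#'
#' Refits every SNP's additive logistic model with the condition SNP's
#' dosage added as a covariate. The condition SNP's own row is reported
#' with `p = NA` (self-conditioning); SNPs perfectly collinear with the
#' condition SNP in-sample are flagged rather than fit.
#'
#' @inheritParams fit_additive_logistic
#' @param condition_snp Id of the SNP conditioned on.
#' @return Tibble as [fit_additive_logistic()], `model_tag = "conditional"`.
#' @export
conditional_scan <- function(genotypes, phenotype, condition_snp,
                             covariates = NULL, snp_ids = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!condition_snp %in% genotypes$snps$id) {
    abort(sprintf("condition SNP '%s' not in genotypes", condition_snp),
          class = "tidylocus_lookup_error")
  }
  phenotype <- validate_phenotype(phenotype)
  phenotype <- phenotype[phenotype$sample_id %in% genotypes$sample_id, , drop = FALSE]
  idx <- match(phenotype$sample_id, genotypes$sample_id)
  y <- as.integer(phenotype$status == "case")
  cond_dose <- genotypes$dosages[idx, condition_snp]
  covar_mat <- cbind(cond = cond_dose)
  if (length(covariates)) {
    covar_mat <- cbind(covar_mat, as.matrix(phenotype[, covariates, drop = FALSE]))
  }
  snp_ids <- snp_ids %||% genotypes$snps$id
  purrr::map_dfr(snp_ids, function(s) {
    na_row <- function(note) tibble::tibble(
      snp_id = s, beta = NA_real_, se = NA_real_, p = NA_real_, or_ = NA_real_,
      n_cases = sum(y), n_controls = sum(1 - y),
      model_tag = "conditional", note = note
    )
    if (s == condition_snp) return(na_row("self-conditioning"))
    dose <- genotypes$dosages[idx, s]
    r <- suppressWarnings(cor(dose, cond_dose, use = "complete.obs"))
    if (!is.na(r) && abs(r) > 1 - 1e-12) return(na_row("flagged: collinear with condition SNP"))
    fit_one_logistic(s, y, dose, covar_mat, "conditional")
  })
}

#' Case-only subtype association
#'
#' Among cases only, logistic regression of membership in `subtype_a`
#' (versus `subtype_b`) on dosage. Under a rare disease, the case-only
#' log-odds estimates the difference of the two subtypes' per-allele
#' disease log-odds, so a subtype-specific risk effect shows up directly.
#'
#' @inheritParams fit_additive_logistic
#' @param subtype_a,subtype_b Subtype labels; `beta > 0` means the dosage
#'   is enriched in `subtype_a`.
#' @return Tibble as [fit_additive_logistic()], `model_tag = "case_only"`;
#'   `n_cases`/`n_controls` hold the two subtype counts.
#' @export
case_only_test <- function(genotypes, phenotype, subtype_a = "HRD",
                           subtype_b = "nonHRD", snp_ids = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  phenotype <- validate_phenotype(phenotype)
  cases <- phenotype[phenotype$status == "case", , drop = FALSE]
  cases <- cases[cases$subtype %in% c(subtype_a, subtype_b), , drop = FALSE]
  n_a <- sum(cases$subtype == subtype_a)
  n_b <- sum(cases$subtype == subtype_b)
  if (n_a == 0 || n_b == 0) {
    abort(sprintf("both subtypes must be present among cases (%s: %d, %s: %d)",
                  subtype_a, n_a, subtype_b, n_b),
          class = "tidylocus_validation_error")
  }
  note <- NA_character_
  if (min(n_a, n_b) < 5) {
    warn(sprintf("case-only test with very few cases in one subtype (%d)", min(n_a, n_b)))
    note <- "warning: low subtype count"
  }
  idx <- match(cases$sample_id, genotypes$sample_id)
  y <- as.integer(cases$subtype == subtype_a)
  snp_ids <- snp_ids %||% genotypes$snps$id
  purrr::map_dfr(snp_ids, function(s) {
    out <- fit_one_logistic(s, y, genotypes$dosages[idx, s], NULL, "case_only",
                            extra_note = note)
    out$n_cases <- n_a; out$n_controls <- n_b
    out
  })
}

#' Export association results in the COJO summary-statistics dialect
#'
#' @param assoc Result of an association function.
#' @param genotypes The [genotype_matrix()] used, for allele labels and
#'   effect-allele (ALT) frequencies.
#' @return Summary-statistics tibble (`snp, a1, a2, freq, b, se, p, n`);
#'   rows with `NA` effects are dropped.
#' @export
assoc_to_summary_stats <- function(assoc, genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  m <- match(assoc$snp_id, genotypes$snps$id)
  freq <- colMeans(genotypes$dosages, na.rm = TRUE)[assoc$snp_id] / 2
  out <- tibble::tibble(
    snp = assoc$snp_id,
    a1 = genotypes$snps$alt[m], a2 = genotypes$snps$ref[m],
    freq = unname(freq), b = assoc$beta, se = assoc$se, p = assoc$p,
    n = assoc$n_cases + assoc$n_controls
  )
  validate_summary_stats(out[!is.na(out$b), , drop = FALSE])
}
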