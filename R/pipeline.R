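#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end synthetic locus analysis: the
#' locus and effect models, cohort sizes, and the analysis thresholds.
#' Defaults are a quarter-scale emulation of a two-study myeloma GWAS
#' (two case subtypes with a hyperdiploid-specific odds ratio of 1.26),
#' a two-study eQTL design of 183 + 658 expression samples, and a
#' 107-tumor trisomy series. The configuration round-trips losslessly
#' through YAML via [write_locus_config()] / [read_locus_config()].
#'
#' @param seed Master seed; all stage seeds derive from it by fixed
#'   offsets.
#' @param locus A [locus_model()].
#' @param effects An [effect_model()].
#' @param n_studies Number of GWAS/eQTL studies.
#' @param n_cases_by_subtype,n_controls Per-study GWAS cohort sizes.
#' @param n_expr_samples Per-study expression cohort sizes (length
#'   `n_studies`).
#' @param n_tumors,depth_mean,p_risk_amplified,bias_odds Trisomy series.
#' @param r2_min Proxy-selection threshold.
#' @param window_bp Cis-window half-width.
#' @param n_factors Latent components removed before the eQTL scan.
#' @param alpha,heidi_alpha SMR family-wise level and HEIDI level.
#' @param min_depth,tie_epsilon Amplification-caller settings.
#' @return A `locus_config` list.
#' @export
locus_config <- function(seed = 1,
                         locus = locus_model(),
                         effects = effect_model(),
                         n_studies = 2,
                         n_cases_by_subtype = c(HRD = 340, nonHRD = 335),
                         n_controls = 1825,
                         n_expr_samples = c(183, 658),
                         n_tumors = 107, depth_mean = 60,
                         p_risk_amplified = 0.5, bias_odds = 0.9,
                         r2_min = 0.8, window_bp = 500000, n_factors = 2,
                         alpha = 0.05, heidi_alpha = 0.05,
                         min_depth = 10, tie_epsilon = 1e-9) {
  stopifnot(inherits(locus, "locus_model"), inherits(effects, "effect_model"),
            length(n_expr_samples) == n_studies)
  if (r2_min < 0 || r2_min > 1 || alpha <= 0 || alpha >= 1 ||
      heidi_alpha <= 0 || heidi_alpha >= 1 || window_bp < 0) {
    abort("threshold out of range", class = "tidylocus_validation_error")
  }
  structure(list(
    seed = as.integer(seed), locus = locus, effects = effects,
    n_studies = as.integer(n_studies),
    n_cases_by_subtype = n_cases_by_subtype, n_controls = as.integer(n_controls),
    n_expr_samples = as.integer(n_expr_samples),
    n_tumors = as.integer(n_tumors), depth_mean = depth_mean,
    p_risk_amplified = p_risk_amplified, bias_odds = bias_odds,
    r2_min = r2_min, window_bp = window_bp, n_factors = as.integer(n_factors),
    alpha = alpha, heidi_alpha = heidi_alpha,
    min_depth = min_depth, tie_epsilon = tie_epsilon
  ), class = "locus_config")
}

#' @param config A `locus_config`.
#' @param path YAML file path.
#' @rdname locus_config
#' @export
write_locus_config <- function(config, path) {
  stopifnot(inherits(config, "locus_config"))
  x <- unclass(config)
  x$locus <- unclass(x$locus)
  x$effects <- unclass(x$effects)
  x$effects$or_subtype <- as.list(x$effects$or_subtype)
  x$n_cases_by_subtype <- as.list(x$n_cases_by_subtype)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname locus_config
#' @export
read_locus_config <- function(path) {
  x <- yaml::read_yaml(path)
  locus_config(
    seed = x$seed,
    locus = do.call(locus_model, x$locus[c("n_snps", "ld_decay", "maf_range",
                                           "causal_index", "start_pos",
                                           "spacing_bp", "chrom")]),
    effects = effect_model(
      or_overall = x$effects$or_overall,
      or_subtype = unlist(x$effects$or_subtype),
      eqtl_beta = x$effects$eqtl_beta, scenario = x$effects$scenario,
      linkage_r2 = x$effects$linkage_r2,
      n_hidden_factors = x$effects$n_hidden_factors,
      noise_sd = x$effects$noise_sd
    ),
    n_studies = x$n_studies,
    n_cases_by_subtype = unlist(x$n_cases_by_subtype),
    n_controls = x$n_controls, n_expr_samples = x$n_expr_samples,
    n_tumors = x$n_tumors, depth_mean = x$depth_mean,
    p_risk_amplified = x$p_risk_amplified, bias_odds = x$bias_odds,
    r2_min = x$r2_min, window_bp = x$window_bp, n_factors = x$n_factors,
    alpha = x$alpha, heidi_alpha = x$heidi_alpha,
    min_depth = x$min_depth, tie_epsilon = x$tie_epsilon
  )
}

#' Run the full synthetic locus analysis
#'
#' Executes every stage on synthetic data: haplotype panel, per-study
#' case/control cohorts, per-SNP association (overall and per subtype),
#' fixed-effects meta-analysis with heterogeneity, case-only subtype test
#' and conditional scan at the lead SNP, proxy selection and enhancer
#' annotation, two-study residualized cis-eQTL scan, SMR + HEIDI
#' classification of every gene against the subtype GWAS, the trisomy
#' allele-amplification series with its cohort test, and gene-gene
#' correlations combined by Fisher's method.
#'
#' When `out_dir` is given every intermediate is written in its standard
#' format (VCF panel, phenotype/summary/eQTL/count TSVs, YAML config and
#' manifest); two runs with the same config produce identical files.
#'
#' @param config A [locus_config()].
#' @param out_dir Optional output directory for intermediate files.
#' @return A `locus_report` list with elements `config`, `panel`,
#'   `assoc_by_study`, `meta_overall`, `meta_by_subtype`, `lead_snp`,
#'   `lead_meta`, `case_only`, `conditional`, `proxies`, `annotated`,
#'   `enhancer`, `eqtl_by_study`, `eqtl_pooled`, `smr`, `amp_calls`,
#'   `amp_test`, `correlations`, `manifest`.
#' @examples
#' \donttest{
#' cfg <- locus_config(seed = 7, n_cases_by_subtype = c(HRD = 60, nonHRD = 60),
#'                     n_controls = 150, n_expr_samples = c(60, 80),
#'                     locus = locus_model(n_snps = 12), n_tumors = 20)
#' report <- run_locus_pipeline(cfg)
#' glance(report)
#' }
#' @export
run_locus_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "locus_config"))
  seed <- config$seed
  locus <- config$locus
  effects <- config$effects
  causal_snp_id <- NULL

  panel <- simulate_haplotype_panel(locus, n_haplotypes = 2000,
                                    seed = derive_seed(seed, 1))
  causal_snp_id <- panel$snps$id[locus$causal_index]

  # --- per-study GWAS cohorts and association -------------------------
  cohorts <- lapply(seq_len(config$n_studies), function(s) {
    simulate_case_control(panel, effects, config$n_cases_by_subtype,
                          config$n_controls, seed = derive_seed(seed, 10 + s),
                          causal_snp = causal_snp_id)
  })
  subtypes <- names(config$n_cases_by_subtype)
  assoc_by_study <- purrr::imap_dfr(cohorts, function(co, s) {
    overall <- fit_additive_logistic(co$genotypes, co$phenotype)
    per_sub <- purrr::map_dfr(subtypes, function(st) {
      keep <- co$phenotype$status == "control" |
        (!is.na(co$phenotype$subtype) & co$phenotype$subtype == st)
      fit_additive_logistic(co$genotypes, co$phenotype,
                            subset = co$phenotype$sample_id[keep],
                            model_tag = st)
    })
    dplyr::mutate(dplyr::bind_rows(overall, per_sub), study = paste0("study", s))
  })
  meta_of <- function(tag) {
    meta_fixed(assoc_by_study[assoc_by_study$model_tag == tag, ])
  }
  meta_overall <- meta_of("overall")
  meta_by_subtype <- purrr::map_dfr(subtypes, function(st) {
    dplyr::mutate(meta_of(st), model_tag = st)
  })
  lead_snp <- meta_overall$snp_id[which.min(meta_overall$p_pooled)]
  lead_meta <- meta_overall[meta_overall$snp_id == lead_snp, ]

  case_only <- case_only_test(cohorts[[1]]$genotypes, cohorts[[1]]$phenotype,
                              snp_ids = lead_snp)
  conditional <- conditional_scan(cohorts[[1]]$genotypes, cohorts[[1]]$phenotype,
                                  condition_snp = lead_snp)

  # --- LD, proxies, enhancer annotation -------------------------------
  proxies <- select_proxies(panel, lead_snp, r2_min = config$r2_min)
  causal_pos <- panel$snps$pos[panel$snps$id == causal_snp_id]
  enhancer <- tibble::tibble(
    chrom = locus$chrom,
    start = as.integer(causal_pos - 4501L),  # 0-based; spans ~8.5 kb of the block
    end = as.integer(causal_pos + 4063L),
    name = "enhancer_1"
  )
  annotated <- annotate_intervals(proxies, enhancer)

  # --- two-study eQTL -------------------------------------------------
  expr_genotypes <- lapply(seq_len(config$n_studies), function(s) {
    simulate_case_control(panel, effect_model(or_overall = 1,
                                              or_subtype = c(none = 1)),
                          c(none = config$n_expr_samples[s]), 0,
                          seed = derive_seed(seed, 30 + s),
                          causal_snp = causal_snp_id)$genotypes
  })
  expr_list <- simulate_expression(expr_genotypes, effects, causal_snp_id,
                                   seed = derive_seed(seed, 40))
  eqtl_by_study <- purrr::imap_dfr(expr_list, function(em, s) {
    resid <- if (config$n_factors > 0) {
      residualize_expression(em, config$n_factors, exclude_self = TRUE)
    } else em
    cis_eqtl_scan(expr_genotypes[[s]], resid, anchor_snp = lead_snp,
                  window_bp = config$window_bp,
                  study_tag = paste0("study", s))
  })
  eqtl_pooled <- pool_eqtl(eqtl_by_study)

  # --- SMR + HEIDI against the subtype GWAS ---------------------------
  smr_gwas_tag <- subtypes[1]
  gwas_for_smr <- meta_by_subtype[meta_by_subtype$model_tag == smr_gwas_tag, ]
  gwas_for_smr <- tibble::tibble(snp_id = gwas_for_smr$snp_id,
                                 beta = gwas_for_smr$beta_pooled,
                                 se = gwas_for_smr$se_pooled)
  ld_cor <- ld_cor_matrix(panel)
  withr::with_seed(derive_seed(seed, 50), {
    smr <- smr_scan(gwas_for_smr, eqtl_pooled, ld_cor,
                    alpha = config$alpha, heidi_alpha = config$heidi_alpha)
  })

  # --- trisomy allele-specific amplification --------------------------
  counts <- simulate_trisomy_counts(config$n_tumors, config$depth_mean,
                                    config$p_risk_amplified, config$bias_odds,
                                    seed = derive_seed(seed, 60))
  amp_calls <- call_amplification_cohort(counts, tie_epsilon = config$tie_epsilon,
                                         min_depth = config$min_depth)
  amp_test <- cohort_amplification_test(amp_calls)

  # --- expression correlations ----------------------------------------
  target <- expr_list[[1]]$genes$gene_id[1]
  others <- setdiff(expr_list[[1]]$genes$gene_id, target)
  pairs <- tibble::tibble(gene_a = target, gene_b = others)
  names(expr_list) <- paste0("study", seq_along(expr_list))
  correlations <- correlate_genes(expr_list, pairs)

  report <- structure(list(
    config = config, panel = panel, causal_snp = causal_snp_id,
    assoc_by_study = assoc_by_study, meta_overall = meta_overall,
    meta_by_subtype = meta_by_subtype, lead_snp = lead_snp,
    lead_meta = lead_meta, case_only = case_only, conditional = conditional,
    proxies = proxies, annotated = annotated, enhancer = enhancer,
    eqtl_by_study = eqtl_by_study, eqtl_pooled = eqtl_pooled, smr = smr,
    amp_calls = amp_calls, amp_test = amp_test, correlations = correlations,
    manifest = list(seed = seed,
                    package_version = as.character(utils::packageVersion("tidylocus")))
  ), class = "locus_report")

  if (!is.null(out_dir)) write_report_files(report, out_dir)
  report
}

write_report_files <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_vcf(report$panel, p("panel.vcf"))
  write_locus_config(report$config, p("config.yaml"))
  readr::write_tsv(report$assoc_by_study, p("assoc_by_study.tsv"))
  readr::write_tsv(report$meta_overall, p("meta_overall.tsv"))
  readr::write_tsv(report$meta_by_subtype, p("meta_by_subtype.tsv"))
  readr::write_tsv(report$conditional, p("conditional.tsv"))
  readr::write_tsv(dplyr::select(report$annotated, -"intervals"),
                   p("proxies_annotated.tsv"))
  write_bed(report$enhancer, p("enhancer.bed"))
  readr::write_tsv(report$eqtl_pooled, p("eqtl_pooled.tsv"))
  readr::write_tsv(report$smr, p("smr.tsv"))
  readr::write_tsv(report$amp_calls, p("amp_calls.tsv"))
  readr::write_tsv(report$amp_test, p("amp_test.tsv"))
  readr::write_tsv(report$correlations, p("correlations.tsv"))
  yaml::write_yaml(report$manifest, p("manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.locus_report <- function(x, ...) {
  g <- glance(x)
  cat("<locus_report>\n")
  cat(sprintf("  lead SNP      %s (OR = %.3f, p = %.3g, P_het = %.2f)\n",
              g$lead_snp, g$lead_or, g$lead_p, g$lead_p_het))
  cat(sprintf("  proxies       %d at r2 >= %.2f; %d in enhancer\n",
              g$n_proxies, x$config$r2_min, g$n_proxies_in_enhancer))
  cat(sprintf("  SMR + HEIDI   %d of %d genes pass\n",
              g$n_genes_pass, nrow(x$smr)))
  cat(sprintf("  amplification %d/%d risk-amplified, p = %.3g\n",
              g$amp_k, g$amp_n, g$amp_p))
  invisible(x)
}

#' Broom-style summaries of a pipeline report
#'
#' `tidy()` returns the per-gene SMR + HEIDI table; `glance()` a one-row
#' summary (lead SNP, pooled odds ratio and p, heterogeneity p, proxy and
#' enhancer counts, genes passing SMR + HEIDI, amplification test). Odds
#' ratios are reported for the risk-increasing allele of the lead SNP
#' (the conventional orientation of a headline GWAS effect).
#'
#' @param x A `locus_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy locus_report
#' @export
tidy.locus_report <- function(x, ...) {
  x$smr
}

#' @rdname tidy.locus_report
#' @method glance locus_report
#' @export
glance.locus_report <- function(x, ...) {
  risk_dir <- sign(x$lead_meta$beta_pooled)  # orient ORs to the risk allele
  tibble::tibble(
    lead_snp = x$lead_snp,
    lead_or = exp(risk_dir * x$lead_meta$beta_pooled),
    lead_p = x$lead_meta$p_pooled,
    lead_p_het = x$lead_meta$p_het,
    case_only_p = x$case_only$p[1],
    n_proxies = nrow(x$proxies),
    n_proxies_in_enhancer = sum(x$annotated$n_intervals > 0),
    n_genes_pass = sum(x$smr$passes, na.rm = TRUE),
    amp_k = x$amp_test$k_risk,
    amp_n = x$amp_test$n_unambiguous,
    amp_p = x$amp_test$p
  )
}
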