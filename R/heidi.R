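#' HEIDI heterogeneity-in-dependent-instruments test
#'
#' Under pleiotropy (one shared causal variant) every SNP in LD with the
#' top cis-eQTL SNP estimates the same Wald ratio `b_xy`; under linkage
#' (distinct causal variants) the ratios disagree. HEIDI tests the
#' difference `d_i = b_xy(i) - b_xy(top)` across eligible SNPs, with
#' `se(d_i)` from first-order error propagation of the two Wald ratios
#' including the LD-induced covariance of the summary statistics, and
#' refers `sum(z_d^2)` to the distribution of the correlated quadratic
#' form (an eigenvalue-weighted chi-square sum). A small `p_heidi` rejects
#' the single-shared-variant model; probes are conventionally kept when
#' `p_heidi > 0.05`.
#'
#' Eligible SNPs have `0.05 <= r2(top) <= r2_max` (default 0.9, avoiding
#' near-collinear ratios), are capped at the `max_snps` smallest eQTL
#' p-values, and must number at least `min_snps`, else `p_heidi` is `NA`
#' with a reason.
#'
#' @param gwas Summary-stats tibble (columns `snp`/`snp_id`, `b`/`beta`,
#'   `se`) with the GWAS effects, harmonized to the eQTL effect allele.
#' @param eqtl eQTL tibble for one gene (columns `snp_id`, `beta`, `se`,
#'   `p`).
#' @param ld_cor Signed LD correlation matrix with dimnames covering the
#'   SNPs (from [ld_cor_matrix()]).
#' @param top_snp Id of the top cis-eQTL SNP.
#' @param r2_range Eligibility window for `r2` with the top SNP.
#' @param max_snps Cap on eligible SNPs (most significant eQTL first).
#' @param min_snps Minimum eligible SNPs for a defined test.
#' @param method `"satterthwaite"` (moment-matched scaled chi-square,
#'   default) or `"bootstrap"` (parametric simulation from the LD
#'   correlation matrix, for verification).
#' @param n_boot Bootstrap draws when `method = "bootstrap"`.
#' @return One-row tibble: `p_heidi`, `n_heidi_snps`, `note`.
#' @export
heidi_test <- function(gwas, eqtl, ld_cor, top_snp,
                       r2_range = c(0.05, 0.9), max_snps = 20, min_snps = 3,
                       method = c("satterthwaite", "bootstrap"),
                       n_boot = 10000) {
  method <- match.arg(method)
  gwas <- tibble::as_tibble(gwas)
  if (!"snp_id" %in% names(gwas) && "snp" %in% names(gwas)) gwas$snp_id <- gwas$snp
  if (!"beta" %in% names(gwas) && "b" %in% names(gwas)) gwas$beta <- gwas$b
  eqtl <- tibble::as_tibble(eqtl)

  na_result <- function(note) tibble::tibble(
    p_heidi = NA_real_, n_heidi_snps = 0L, note = note
  )
  shared <- intersect(intersect(gwas$snp_id, eqtl$snp_id), rownames(ld_cor))
  if (!top_snp %in% shared) return(na_result("top SNP missing from inputs"))

  r_top <- ld_cor[shared, top_snp]
  r2_top <- r_top^2
  elig <- shared[shared != top_snp &
                   !is.na(r2_top[shared]) &
                   r2_top[shared] >= r2_range[1] &
                   r2_top[shared] <= r2_range[2]]
  if (length(elig) > max_snps) {
    ep <- eqtl$p[match(elig, eqtl$snp_id)]
    elig <- elig[order(ep)][seq_len(max_snps)]
  }
  if (length(elig) < min_snps) {
    return(na_result(sprintf("only %d eligible SNP(s), need >= %d",
                             length(elig), min_snps)))
  }

  snps <- c(top_snp, elig)                    # index 1 = top
  bg <- gwas$beta[match(snps, gwas$snp_id)]
  sg <- gwas$se[match(snps, gwas$snp_id)]
  be <- eqtl$beta[match(snps, eqtl$snp_id)]
  se <- eqtl$se[match(snps, eqtl$snp_id)]
  if (any(is.na(bg) | is.na(sg) | is.na(be) | is.na(se)) || any(be == 0)) {
    return(na_result("missing or zero effects among eligible SNPs"))
  }
  r <- ld_cor[snps, snps]

  # first-order covariance of the Wald ratios b_xy = bg/be; GWAS and eQTL
  # cohorts are independent, so cross terms vanish
  cov_g <- r * tcrossprod(sg)
  cov_e <- r * tcrossprod(se)
  inv_be <- 1 / be
  ratio <- bg / be
  cov_xy <- tcrossprod(inv_be) * cov_g + tcrossprod(ratio * inv_be) * cov_e

  k <- length(elig)
  idx <- seq_len(k) + 1L
  v_d <- cov_xy[idx, idx, drop = FALSE] -
    matrix(cov_xy[idx, 1], k, k) -
    matrix(cov_xy[1, idx], k, k, byrow = TRUE) +
    cov_xy[1, 1]
  d <- ratio[idx] - ratio[1]
  sd_d <- sqrt(pmax(diag(v_d), .Machine$double.eps))
  z_d <- d / sd_d
  t_obs <- sum(z_d^2)
  corr_d <- v_d / tcrossprod(sd_d)
  ev <- eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)

  if (method == "satterthwaite") {
    s1 <- sum(ev); s2 <- sum(ev^2)
    if (s2 == 0) return(na_result("degenerate covariance"))
    a <- s2 / s1
    nu <- s1^2 / s2
    p <- pchisq(t_obs / a, df = nu, lower.tail = FALSE)
  } else {
    ec <- eigen(corr_d, symmetric = TRUE)
    half <- ec$vectors %*% diag(sqrt(pmax(ec$values, 0)), k)
    z <- half %*% matrix(rnorm(k * n_boot), k, n_boot)
    t_null <- colSums(z^2)
    p <- (1 + sum(t_null >= t_obs)) / (n_boot + 1)
  }
  tibble::tibble(p_heidi = p, n_heidi_snps = k, note = NA_character_)
}

#' Per-gene SMR + HEIDI scan
#'
#' For each gene in a pooled cis-eQTL table: take the smallest-p eQTL SNP
#' shared with the GWAS as instrument, run [smr_test()] and [heidi_test()],
#' then flag probes with [classify_probes()].
#'
#' Genes whose best cis-eQTL does not reach `instrument_p` have no valid
#' instrument: they are reported with `NA` SMR fields and never flagged
#' as passing.
#'
#' @param gwas Summary-stats tibble (COJO dialect columns or
#'   `snp_id`/`beta`/`se`), effect alleles harmonized with the eQTL.
#' @param eqtl Pooled eQTL tibble (`gene_id`, `snp_id`, `beta`, `se`, `p`).
#' @param ld_cor Signed LD correlation matrix (see [ld_cor_matrix()]).
#' @param alpha,heidi_alpha Thresholds passed to [classify_probes()].
#' @param instrument_p Largest top-eQTL p-value accepted as an instrument
#'   (default the conventional 5e-8).
#' @param ... Passed to [heidi_test()].
#' @return Tibble, one row per gene: `gene_id`, `top_eqtl_snp`,
#'   `p_eqtl_top`, `b_xy`, `se_xy`, `t_smr`, `p_smr`, `p_heidi`,
#'   `n_heidi_snps`, `smr_threshold`, `passes`.
#' @export
smr_scan <- function(gwas, eqtl, ld_cor, alpha = 0.05, heidi_alpha = 0.05,
                     instrument_p = 5e-8, ...) {
  gwas <- tibble::as_tibble(gwas)
  if (!"snp_id" %in% names(gwas) && "snp" %in% names(gwas)) gwas$snp_id <- gwas$snp
  if (!"beta" %in% names(gwas) && "b" %in% names(gwas)) gwas$beta <- gwas$b
  genes <- unique(eqtl$gene_id)
  out <- purrr::map_dfr(genes, function(g) {
    eg <- eqtl[eqtl$gene_id == g & !is.na(eqtl$beta) & !is.na(eqtl$p), , drop = FALSE]
    eg <- eg[eg$snp_id %in% gwas$snp_id, , drop = FALSE]
    base <- tibble::tibble(gene_id = g, top_eqtl_snp = NA_character_,
                           p_eqtl_top = NA_real_, b_xy = NA_real_,
                           se_xy = NA_real_, t_smr = NA_real_, p_smr = NA_real_,
                           p_heidi = NA_real_, n_heidi_snps = 0L)
    if (!nrow(eg)) return(base)
    top <- eg[which.min(eg$p), ]
    base$top_eqtl_snp <- top$snp_id
    base$p_eqtl_top <- top$p
    if (top$p > instrument_p) return(base)  # no valid instrument
    gr <- gwas[match(top$snp_id, gwas$snp_id), ]
    if (is.na(gr$beta) || top$beta == 0) return(base)
    s <- smr_test(gr$beta, gr$se, top$beta, top$se)
    h <- heidi_test(gwas, eg, ld_cor, top$snp_id, ...)
    tibble::tibble(gene_id = g, top_eqtl_snp = top$snp_id,
                   p_eqtl_top = top$p, b_xy = s$b_xy, se_xy = s$se_xy,
                   t_smr = s$t_smr, p_smr = s$p_smr,
                   p_heidi = h$p_heidi, n_heidi_snps = h$n_heidi_snps)
  })
  classify_probes(out, alpha = alpha, heidi_alpha = heidi_alpha)
}
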