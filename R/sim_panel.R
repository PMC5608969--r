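#' Locus and effect models for the synthetic-data generator
#'
#' `locus_model()` describes an LD block: number of SNPs, a first-order
#' (Markov) correlation-decay parameter between adjacent SNPs, the range
#' minor-allele fractions are drawn from, and which SNP is causal.
#' `effect_model()` describes the planted effects: the overall and
#' per-subtype disease odds ratios at the causal SNP, the cis-eQTL effect
#' on the target gene, and the genetic architecture linking them —
#' `"pleiotropy"` (one shared causal SNP), `"linkage"` (distinct disease
#' and expression causal SNPs in LD `r2 ~ linkage_r2`) or `"null"`
#' (no eQTL effect).
#'
#' Defaults mirror the study conditions the generator emulates: a ~40 kb
#' haplotype block of common SNPs, a hyperdiploid-subtype-specific odds
#' ratio of 1.26 against 1.0 in the other subtype, and a two-study eQTL
#' design with hidden expression confounders.
#'
#' @param n_snps Number of SNPs in the block (>= 2).
#' @param ld_decay Adjacent-SNP latent correlation in `[0, 1)`; pairwise
#'   latent correlation decays geometrically with distance in SNPs.
#' @param maf_range Two-element range in `(0, 0.5]` for per-SNP MAF.
#' @param causal_index 1-based index of the causal SNP (default: the
#'   middle SNP).
#' @param start_pos,spacing_bp 1-based position of the first SNP and
#'   spacing between adjacent SNPs (defaults span ~40 kb).
#' @param chrom Chromosome label.
#' @return `locus_model()`: a `locus_model` list.
#' @export
locus_model <- function(n_snps = 40, ld_decay = 0.9,
                        maf_range = c(0.1, 0.5), causal_index = NULL,
                        start_pos = 95230000L, spacing_bp = 1000L,
                        chrom = "chr5") {
  if (n_snps < 2) abort("n_snps must be >= 2", class = "tidylocus_validation_error")
  causal_index <- causal_index %||% ceiling(n_snps / 2)
  if (ld_decay < 0 || ld_decay >= 1) {
    abort("ld_decay must lie in [0, 1)", class = "tidylocus_validation_error")
  }
  if (causal_index < 1 || causal_index > n_snps) {
    abort("causal_index out of range", class = "tidylocus_validation_error")
  }
  if (min(maf_range) <= 0 || max(maf_range) > 0.5) {
    abort("maf_range must lie in (0, 0.5]", class = "tidylocus_validation_error")
  }
  structure(list(n_snps = as.integer(n_snps), ld_decay = ld_decay,
                 maf_range = maf_range, causal_index = as.integer(causal_index),
                 start_pos = as.integer(start_pos), spacing_bp = as.integer(spacing_bp),
                 chrom = chrom),
            class = "locus_model")
}

#' @param or_overall Odds ratio at the causal SNP ignoring subtype.
#' @param or_subtype Named numeric vector of per-subtype odds ratios,
#'   e.g. `c(HRD = 1.26, nonHRD = 1.0)`.
#' @param eqtl_beta Expression change (log2 units) per effect allele at the
#'   eQTL causal SNP.
#' @param scenario `"pleiotropy"`, `"linkage"` or `"null"`.
#' @param linkage_r2 Target `r2` between disease and expression causal SNPs
#'   when `scenario = "linkage"`.
#' @param n_hidden_factors Number of latent expression confounders.
#' @param noise_sd Residual expression noise SD (log2 units).
#' @rdname locus_model
#' @return `effect_model()`: an `effect_model` list.
#' @export
effect_model <- function(or_overall = 1.16,
                         or_subtype = c(HRD = 1.26, nonHRD = 1.0),
                         eqtl_beta = -0.5, scenario = "pleiotropy",
                         linkage_r2 = 0.5, n_hidden_factors = 2,
                         noise_sd = 1) {
  scenario <- match.arg(scenario, c("pleiotropy", "linkage", "null"))
  if (or_overall <= 0 || any(or_subtype <= 0)) {
    abort("odds ratios must be > 0", class = "tidylocus_validation_error")
  }
  if (scenario == "linkage" && (linkage_r2 <= 0 || linkage_r2 >= 1)) {
    abort("linkage_r2 must lie in (0, 1)", class = "tidylocus_validation_error")
  }
  if (noise_sd <= 0) abort("noise_sd must be > 0", class = "tidylocus_validation_error")
  structure(list(or_overall = or_overall, or_subtype = or_subtype,
                 eqtl_beta = eqtl_beta, scenario = scenario,
                 linkage_r2 = linkage_r2,
                 n_hidden_factors = as.integer(n_hidden_factors),
                 noise_sd = noise_sd),
            class = "effect_model")
}

#' Simulate a phased haplotype panel with geometric LD decay
#'
#' Haplotypes are drawn from a first-order Gaussian-copula Markov chain:
#' each haplotype is a latent AR(1) Gaussian vector with adjacent-site
#' correlation `ld_decay`, thresholded per SNP at its allele frequency.
#' Pairwise latent correlation between SNPs `j` and `k` is
#' `ld_decay^|j-k|`, so haplotype `r2` decays geometrically along the
#' block, emulating a local LD block without reproducing any real map.
#'
#' @param model A [locus_model()].
#' @param n_haplotypes Even number of haplotypes (phased pairs).
#' @param seed Integer seed; same seed gives a byte-identical panel.
#' @return A [haplotype_panel()]. Allele 1 is the alternate (minor at
#'   generation) allele; `maf` records the generating frequency.
#' @examples
#' panel <- simulate_haplotype_panel(locus_model(n_snps = 10), 200, seed = 1)
#' panel
#' @export
simulate_haplotype_panel <- function(model, n_haplotypes = 2000, seed = 1) {
  stopifnot(inherits(model, "locus_model"))
  if (n_haplotypes %% 2L != 0L || n_haplotypes < 2L) {
    abort("n_haplotypes must be a positive even number",
          class = "tidylocus_validation_error")
  }
  withr::local_seed(seed)
  p <- model$n_snps
  maf <- stats::runif(p, model$maf_range[1], model$maf_range[2])
  rho <- model$ld_decay
  # latent AR(1): z_1 ~ N(0,1); z_j = rho z_{j-1} + sqrt(1-rho^2) e_j
  z <- matrix(rnorm(n_haplotypes * p), n_haplotypes, p)
  if (p > 1 && rho > 0) {
    for (j in 2:p) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  }
  thresh <- qnorm(maf)
  haps <- t(t(z) < thresh) * 1L
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, p, replace = TRUE)
  alt <- vapply(ref, function(a) sample(setdiff(alleles, a), 1), character(1))
  snps <- snp_table(
    id = sprintf("snp%03d", seq_len(p)),
    chrom = model$chrom,
    pos = model$start_pos + (seq_len(p) - 1L) * model$spacing_bp,
    ref = ref, alt = alt, maf = maf
  )
  haplotype_panel(snps, haps)
}

# derive a bounded sub-seed from a master seed and a fixed stage offset
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 16807) %% 2147483647)
}
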