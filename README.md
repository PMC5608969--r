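# tidylocus

Dissecting a single GWAS risk locus, end to end, in tidy R.

`tidylocus` is for statistical geneticists who need the machinery that turns
a locus-level association signal into a candidate causal gene and mechanism:
additive logistic association with tumor-subtype stratification, conditional
and case-only analysis, fixed-effects meta-analysis with Cochran's Q,
linkage-disequilibrium (r², D′) proxy selection and enhancer annotation,
latent-factor-residualized cis-eQTL scanning pooled across studies, the
summary-data Mendelian randomization (SMR) pleiotropy test with the HEIDI
heterogeneity filter, a binomial classifier of allele-specific amplification
in trisomic tumors, and gene–gene expression correlation combined across
studies by Fisher's method.

The package is organized the tidyverse way: analysis functions take data
frames (or the package's light panel/matrix containers) and return tibbles,
results chain with the pipe, fitted pipelines have `tidy()`, `glance()` and
`autoplot()` methods, and every figure is a ggplot. A synthetic-data
generator emulates the statistical structure of a hyperdiploid-myeloma risk
locus — an LD block with one causal variant carrying a subtype-specific odds
ratio, a two-study cis-eQTL design with hidden expression confounders, and
trisomic tumor read counts with reference-mapping bias — so the entire
pipeline runs and is tested without any restricted cohort data.

## The statistics in brief

**Association and meta-analysis.** Per SNP, case status is regressed on
alternate-allele dosage g under the additive logistic model
logit P(case) = α + βg (+ covariates), with Wald tests. Studies are pooled
with inverse-variance weights wᵢ = 1/seᵢ²:
β̂ = Σwᵢβᵢ/Σwᵢ, se = (Σwᵢ)^(−1/2), and heterogeneity
Q = Σwᵢ(βᵢ − β̂)² ~ χ²(k−1). Case-only analysis regresses subtype on dosage
among cases, estimating the difference in subtype-specific log odds ratios.

**LD.** From phased haplotypes, D = p_AB − p_A p_B,
r² = D²/(p_A p_a p_B p_b), D′ = |D|/D_max. Proxies are SNPs with
r² ≥ 0.8 versus the lead.

**SMR + HEIDI.** With z-scores z_gwas, z_eqtl of the SNP's disease and
expression effects, the Wald-ratio effect of expression on disease is
b_xy = b_gwas/b_eqtl and

  T_SMR = z²_gwas z²_eqtl / (z²_gwas + z²_eqtl) ~ χ²₁.

Probes pass when P_SMR beats the Bonferroni threshold α/m (0.05/6 ≈ 0.00833
for a six-probe locus) **and** HEIDI — which tests equality of the Wald
ratios across LD-linked SNPs via an eigenvalue-weighted quadratic form —
does not reject (P_HEIDI > 0.05). Passing indicates pleiotropy (one shared
causal variant); HEIDI rejection indicates linkage of distinct variants.

**Allele-specific amplification.** A trisomic heterozygote carries one
allele in 2 of 3 copies, so risk-read counts are Binomial(n, 2b/(2b+1)) if
the risk allele is amplified and Binomial(n, b/(b+2)) otherwise, where b is
the reference-mapping bias odds estimated from germline heterozygote
counts. Each tumor is assigned its maximum-likelihood state (proxy SNPs
share the state, so their log-likelihoods add), and the cohort is tested
for preferential risk-allele amplification with an exact binomial test.

## Worked example

```r
library(tidylocus)

report <- run_locus_pipeline(locus_config(seed = 42))
report
#> <locus_report>
#>   lead SNP      snp020 (OR = 1.176, p = 0.000473, P_het = 0.61)
#>   proxies       1 at r2 >= 0.80; 1 in enhancer
#>   SMR + HEIDI   1 of 6 genes pass
#>   amplification 56/107 risk-amplified, p = 0.699
```

The default configuration is a quarter-scale, two-study case/control design
(340 hyperdiploid + 335 non-hyperdiploid cases and 1,825 controls per
study) over a 40-SNP LD block whose middle SNP is causal with a
hyperdiploid-specific odds ratio of 1.26. The lead SNP recovered by the
meta-analysis is the causal one; its pooled OR (1.18) sits near the planted
overall effect, and P_het = 0.61 shows the two studies agree.

```r
dplyr::select(tidy(report), gene_id, top_eqtl_snp, p_smr, p_heidi, passes)
#> # A tibble: 6 × 5
#>   gene_id top_eqtl_snp     p_smr p_heidi passes
#> 1 gene01  snp020        0.000266   0.664 TRUE
#> 2 gene02  snp019       NA         NA     FALSE
#> ...
```

Only `gene01` — the gene the generator wired to the causal SNP — has a
significant cis-eQTL instrument; it beats the 0.00833 SMR threshold and
HEIDI finds no heterogeneity (P_HEIDI = 0.66), the signature of pleiotropy
rather than linkage. The amplification series (simulated with no
preferential amplification) gives 56/107 risk-amplified tumors, p = 0.70:
no evidence of preferential duplication, as designed.

```r
report$amp_test
#> # A tibble: 1 × 5
#>   k_risk n_unambiguous n_ambiguous proportion     p
#> 1     56           107           0      0.523 0.699

autoplot(report)          # regional association plot, LD-shaded
plot_smr(tidy(report))    # per-gene SMR/HEIDI summary
```

Individual stages are ordinary functions on tibbles and compose freely:
`simulate_haplotype_panel()` → `simulate_case_control()` →
`fit_additive_logistic()` → `meta_fixed()`; `ld_stats()`,
`select_proxies()`, `annotate_intervals()`; `residualize_expression()` →
`cis_eqtl_scan()` → `pool_eqtl()` → `smr_scan()`;
`simulate_trisomy_counts()` → `call_amplification_cohort()` →
`cohort_amplification_test()`; `correlate_genes()` / `fisher_combine()`.

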