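---
title: "Methods: dissecting a risk locus with tidylocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting a risk locus with tidylocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidylocus)
```

`tidylocus` implements the statistical machinery used to take a single
disease-risk locus from an association signal to a candidate causal gene
and somatic mechanism. This vignette is the package's own account of the
models it fits, the knobs that matter, what the synthetic-data generator
does and does not emulate, and the places where the design was genuinely
open and a choice had to be made.

## The analysis chain

The pipeline mirrors a fine-mapping study of a myeloma risk locus:

1. **Association.** Per-SNP logistic regression of case status on
   alternate-allele dosage (additive model), overall and within tumor
   subtypes (hyperdiploid "HRD" versus non-hyperdiploid), per study.
2. **Meta-analysis.** Fixed-effects inverse-variance pooling across
   studies with Cochran's Q and its p-value for heterogeneity.
3. **Conditional and case-only analysis.** Conditioning every SNP on the
   lead tests for secondary independent signals; regressing subtype on
   dosage among cases tests subtype specificity directly.
4. **LD and annotation.** r²/D′ from phased haplotypes, proxy selection at
   r² ≥ 0.8, and overlap of proxies with regulatory intervals (BED).
5. **cis-eQTL.** Expression residualized for latent factors, then OLS of
   residual expression on dosage for every SNP within ±500 kb of the
   anchor, pooled across studies with the same fixed-effects arithmetic.
6. **SMR + HEIDI.** The Wald-ratio test of pleiotropy between the GWAS and
   eQTL signals, Bonferroni-thresholded across probes, with the HEIDI
   heterogeneity filter separating pleiotropy from linkage.
7. **Allele-specific amplification.** In trisomic heterozygous tumors, a
   binomial maximum-likelihood call of which allele the extra copy
   carries, bias-adjusted from germline counts, plus an exact binomial
   cohort test.
8. **Expression correlation.** Pearson correlation between the target gene
   and companion genes per study, p-values combined by Fisher's method.

## Models and assumptions

**Retrospective disease model.** Cases are simulated by rejection
sampling: an individual with dosage g at the causal SNP is accepted as a
case of subtype s with probability proportional to exp(β_s g), where
β_s = log OR_s. This is the retrospective sampling distribution of a
logistic disease model in the rare-disease limit, where the case-control
odds ratio equals the population odds ratio and controls are
indistinguishable from the population; controls are therefore drawn
directly from the panel. Subtype is assigned before case sampling — tumor
class is a property of the case, each class with its own odds ratio —
mirroring a subtype-stratified retrospective design.

**Wald tests.** Association inference is Wald (estimate/SE from the
observed information at the converged coefficients), not score-based as
some GWAS tools use. At the simulated sample sizes the two are
practically identical, and Wald estimates are directly comparable to the
IRLS oracle used in the tests. Separation or non-convergence within 25
IRLS iterations is flagged (`p = NA`) rather than penalized, keeping
estimates comparable across SNPs.

**SMR.** T_SMR = z²_g z²_e/(z²_g + z²_e) is referred to χ²₁. The statistic
is symmetric in the two z-scores and bounded by the smaller of them
squared, so a probe can never borrow significance from one strong arm.
A probe is only tested when its best cis-eQTL reaches `instrument_p`
(default 5 × 10⁻⁸): a weak instrument makes the Wald ratio unstable, and
— because the top SNP is chosen as the minimum p over the window — an
unthresholded scan would let winner's-curse-inflated null eQTLs produce
spurious SMR hits.

**HEIDI.** For eligible SNPs i (0.05 ≤ r² with the top SNP ≤ 0.9, capped
at the 20 smallest eQTL p-values, minimum 3 — the established defaults of
the method, configurable because the source analyses state none), the
difference of Wald ratios d_i = b_xy(i) − b_xy(top) has covariance
obtained by first-order error propagation of the two ratios, including
the LD-induced covariance r_ij se_i se_j within each summary-statistic
set (GWAS and eQTL cohorts are independent, so cross-terms vanish). The
statistic Σ z²_d is a correlated quadratic form: its null distribution is
the eigenvalue-weighted χ² sum, approximated by Satterthwaite moment
matching (`T/a ~ χ²_ν` with `a = Σλ²/Σλ`, `ν = (Σλ)²/Σλ²`). A parametric
bootstrap from the same correlation matrix (`method = "bootstrap"`) is
provided purely to verify the approximation; the two agree to a few
hundredths on the cases the tests exercise. The upper r² bound avoids
near-collinear ratios whose difference variance is dominated by
cancellation; the lower bound excludes SNPs carrying almost no shared
signal.

**Amplification caller.** With bias odds b (germline risk:non-risk odds,
pseudo-count 0.5 per side), the risk-read probability is 2b/(2b+1) under
risk-allele amplification and b/(b+2) otherwise — both monotone in b, so
a misestimated bias shifts both hypotheses the same way. The two proxy
SNPs of one tumor tag the same haplotype (they are chosen for r² > 0.95
with the risk variant), so a single latent amplified state is assumed and
their binomial log-likelihoods add; the source analyses do not state how
proxy SNPs were combined, and this is the natural choice under that LD.
Ties within `tie_epsilon = 1e-9` (machine-level only) are called
ambiguous, and ambiguous calls are excluded from — but reported alongside
— the exact binomial cohort test. A uniform prior over the two states
makes "most probable state" coincide with maximum likelihood. Tumor
purity is ignored (the upstream sample selection is assumed to have
handled it); a purity parameter is an obvious extension.

**Residualization.** The Bayesian latent-factor approach used on real
expression arrays is replaced by truncated principal-component removal:
deterministic, dependency-light, and equivalent in its role of absorbing
broad variance components. `n_factors` is a configuration knob (default
2, matching the two hidden confounders the generator plants). With only a
handful of genes, a strong cis effect can itself dominate a component, so
removing joint components would smear genotype signal into other genes'
residuals; the pipeline therefore uses `exclude_self = TRUE`, estimating
each gene's removed components from the remaining genes only. With a
transcriptome-scale panel the two are indistinguishable.

## The synthetic-data generator

The generator defines the study conditions; it is not a tuning dial.

* **LD block.** Haplotypes come from a first-order Gaussian-copula Markov
  chain: a latent AR(1) vector with adjacent-site correlation `ld_decay`
  (default 0.9), thresholded per SNP at its allele frequency (drawn from
  `maf_range`, default 0.1–0.5). Latent correlation decays geometrically
  with SNP distance, giving a tunable local LD block. Defaults span ~40 kb
  at 1 kb spacing — the scale of the haplotype block the package emulates.
* **Cohorts.** Two studies, each 340 HRD + 335 non-HRD cases and 1,825
  controls — a quarter-scale rendering of a combined GWAS of ~2,700 typed
  cases and 7,304 controls, chosen so the full pipeline runs in seconds
  while keeping the subtype contrast estimable. The planted odds ratios
  are 1.26 (HRD) and 1.0 (non-HRD); 1.16 is the overall default where no
  subtype is named.
* **Expression.** Two studies of 183 and 658 samples (the sizes of the
  eQTL cohorts emulated), six genes with deterministic TSS positions
  spanning the cis window; gene 1 carries the eQTL
  (`eqtl_beta`, default −0.5 log2 units per allele — the source analyses
  report no effect size in expression units, so this is a configurable
  package choice of a clearly detectable cis effect), all genes load on
  `n_hidden_factors = 2` standard-normal confounders with N(0, 0.5²)
  loadings, plus N(0, 1) noise. Scenarios: *pleiotropy* (eQTL at the
  disease SNP), *linkage* (eQTL at the SNP whose r² with the disease SNP
  is closest to `linkage_r2`; an error reports the achievable range when
  none is within 0.15), *null* (no eQTL).
* **Trisomy series.** 107 tumors (the two emulated series combined),
  Poisson depths around 60 per proxy SNP, two proxy SNPs sharing the
  latent state, `p_risk_amplified = 0.5` (the no-preference null the
  corresponding study reported), bias odds 0.9 (mild reference-mapping
  excess against the risk allele).
* **Seeds.** One master seed; each stage derives its own seed by a fixed
  integer recurrence (`derive_seed`), so stages are independently
  reproducible and the whole pipeline is byte-identical under a repeated
  seed.

What the generator does **not** emulate: real human LD maps (no hotspots,
no MAF-LD coupling), population structure and relatedness, genotyping or
imputation error, array probe effects, expression heavy tails, or tumor
purity. Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under the stated model — not that any biological
conclusion about a real locus follows.

## Numerical choices and degenerate inputs

* Dosages may be fractional in [0, 2]; missing dosages are dropped
  pairwise per SNP. Monomorphic SNPs are skipped with a reason.
* Collinearity with the conditioning SNP (|r| = 1 in sample) and
  self-conditioning yield flagged `NA` rows, never errors.
* Coordinates: VCF/TSV positions are 1-based; BED is 0-based half-open.
  The conversion happens in exactly one place (`annotate_intervals()`):
  a SNP at position p overlaps [start, end) iff start < p ≤ end.
* Allele harmonization aligns effect alleles to the panel ALT; strand-
  ambiguous (A/T, C/G) mismatches are rejected, never guessed.
* HEIDI covariance eigenvalues are clamped at zero before moment
  matching; a degenerate covariance yields `NA` with a reason.
* The summary-statistic writer rounds to 10 significant digits; write →
  read is the identity to that precision (asserted in the tests).

## Problem sizes in the test suite

The suite verifies calibration and recovery at desk scale, chosen to keep
a full run in a few minutes: null-calibration Kolmogorov–Smirnov checks
use 1,000 association replicates (n = 600) and 2,000 SMR replicates;
odds-ratio recovery uses 200 replicates of 500 cases/1,000 controls; the
pleiotropy/linkage/null SMR battery uses 50 seeds per scenario with
strong planted effects (OR 1.7, eQTL β 0.6 at n = 600) so that scenario
separation, not power, is what is being tested; the amplification
classifier is assessed on 1,000 tumors at depth 60. The exact binomial
cohort test has a discrete null, so its calibration is asserted as
bounded type-I error at α = 0.05 rather than strict p-value uniformity.

## Known limitations

* Fixed-effects meta-analysis only; no random-effects or genomic control.
* LD comes from phased haplotypes only (the simulated panel); EM-based
  genotype LD is out of scope.
* Single-SNP SMR; no multi-SNP extensions or colocalization posteriors.
* The case-only estimator interprets its coefficient as a subtype
  log-OR difference only under the rare-disease assumption the generator
  satisfies.
* The trisomy caller assumes exactly one extra copy (2:1); higher-order
  amplifications would need a generalized copy model.
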