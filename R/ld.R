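#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Computes `r2` and `D'` for a pair of SNPs from the 2x2 haplotype
#' frequency table: with allele-1 frequencies `pA`, `pB` and joint
#' frequency `pAB`, `D = pAB - pA pB`, `r2 = D^2 / (pA pa pB pb)` and
#' `D' = |D| / Dmax`, where `Dmax = min(pA pb, pa pB)` if `D > 0` and
#' `min(pA pB, pa pb)` otherwise. Both statistics are invariant to
#' relabeling either SNP's alleles and symmetric in the two SNPs.
#'
#' @param panel A [haplotype_panel()].
#' @param snp_a,snp_b SNP ids.
#' @return One-row tibble: `snp_a`, `snp_b`, `r2`, `d_prime`.
#' @examples
#' panel <- simulate_haplotype_panel(locus_model(n_snps = 5), 1000, seed = 1)
#' ld_stats(panel, "snp001", "snp002")
#' @export
ld_stats <- function(panel, snp_a, snp_b) {
  stopifnot(inherits(panel, "haplotype_panel"))
  for (s in c(snp_a, snp_b)) {
    if (!s %in% panel$snps$id) {
      abort(sprintf("SNP '%s' not in panel", s), class = "tidylocus_lookup_error")
    }
  }
  a <- panel$haplotypes[, snp_a]
  b <- panel$haplotypes[, snp_b]
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    abort(sprintf("LD undefined: monomorphic SNP (%s or %s)", snp_a, snp_b),
          class = "tidylocus_monomorphic_error")
  }
  pAB <- mean(a == 1 & b == 1)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  d_max <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (D == 0) 0 else abs(D) / d_max
  tibble::tibble(snp_a = snp_a, snp_b = snp_b, r2 = r2, d_prime = d_prime)
}

#' Pairwise r2 of every panel SNP against one SNP
#'
#' @param panel A [haplotype_panel()].
#' @param snp_id Reference SNP id.
#' @return Named vector of `r2` (NA for monomorphic SNPs).
#' @export
ld_r2_with <- function(panel, snp_id) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!snp_id %in% panel$snps$id) {
    abort(sprintf("SNP '%s' not in panel", snp_id), class = "tidylocus_lookup_error")
  }
  h <- panel$haplotypes
  suppressWarnings(cor(h, h[, snp_id])[, 1]^2)
}

#' LD correlation matrix (signed r) between panel SNPs
#'
#' @param panel A [haplotype_panel()].
#' @param snp_ids SNP ids (default: all).
#' @return Correlation matrix of haplotype allele indicators.
#' @export
ld_cor_matrix <- function(panel, snp_ids = panel$snps$id) {
  stopifnot(inherits(panel, "haplotype_panel"))
  suppressWarnings(cor(panel$haplotypes[, snp_ids, drop = FALSE]))
}

#' Select LD proxies of a lead SNP
#'
#' Returns every panel SNP with `r2 >= r2_min` versus the lead (the lead
#' itself included), sorted by descending `r2` with position breaking ties.
#'
#' @param panel A [haplotype_panel()].
#' @param lead_snp Lead SNP id (must be polymorphic).
#' @param r2_min Minimum `r2` (0.8 mirrors the usual proxy convention).
#' @return Tibble of proxies: SNP columns plus `r2`.
#' @export
select_proxies <- function(panel, lead_snp, r2_min = 0.8) {
  r2 <- ld_r2_with(panel, lead_snp)
  if (is.na(r2[lead_snp])) {
    abort(sprintf("lead SNP '%s' is monomorphic", lead_snp),
          class = "tidylocus_monomorphic_error")
  }
  out <- dplyr::mutate(panel$snps, r2 = unname(r2))
  out <- dplyr::filter(out, !is.na(.data$r2), .data$r2 >= r2_min)
  dplyr::arrange(out, dplyr::desc(.data$r2), .data$pos)
}

#' Annotate SNPs with the regulatory intervals they fall in
#'
#' BED intervals are 0-based half-open; SNP positions are 1-based. A SNP at
#' 1-based position `p` overlaps `[start, end)` iff `start < p <= end`.
#' This is the single place the two conventions meet.
#'
#' @param snps SNP table (or any tibble with `id`, `chrom`, `pos`).
#' @param intervals Interval tibble as from [read_bed()].
#' @return Tibble `id`, `chrom`, `pos`, `intervals` (list-column of
#'   interval names; empty character for SNPs outside all intervals) and
#'   `n_intervals`.
#' @export
annotate_intervals <- function(snps, intervals) {
  snps <- tibble::as_tibble(snps)
  if (nrow(intervals) > 0 && !any(snps$chrom %in% intervals$chrom)) {
    warn("no shared chromosome names between SNPs and intervals")
  }
  hits <- purrr::map(seq_len(nrow(snps)), function(i) {
    sel <- intervals$chrom == snps$chrom[i] &
      intervals$start < snps$pos[i] & snps$pos[i] <= intervals$end
    nm <- intervals$name[sel]
    nm[is.na(nm)] <- sprintf("%s:%d-%d", intervals$chrom[sel][is.na(nm)],
                             intervals$start[sel][is.na(nm)],
                             intervals$end[sel][is.na(nm)])
    nm
  })
  tibble::tibble(
    id = snps$id, chrom = snps$chrom, pos = snps$pos,
    intervals = hits, n_intervals = lengths(hits)
  )
}
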