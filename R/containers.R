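#' SNP tables
#'
#' A SNP table is an ordinary tibble with one row per biallelic variant and
#' columns `id`, `chrom`, `pos` (1-based), `ref`, `alt` and optionally `maf`.
#' `snp_table()` builds and validates one.
#'
#' @param id Character vector of SNP identifiers (unique).
#' @param chrom Chromosome names.
#' @param pos 1-based integer positions.
#' @param ref,alt Reference / alternate alleles; must differ per SNP.
#' @param maf Optional minor-allele fractions in `[0, 0.5]`.
#' @return A tibble with one row per SNP.
#' @examples
#' snp_table("rs1", "chr5", 95259093L, "C", "G")
#' @export
snp_table <- function(id, chrom, pos, ref, alt, maf = NULL) {
  out <- tibble::tibble(
    id = as.character(id), chrom = as.character(chrom),
    pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt)
  )
  if (!is.null(maf)) out$maf <- as.double(maf)
  validate_snps(out)
}

validate_snps <- function(snps) {
  need <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(snps))
  if (length(missing_cols)) {
    abort(paste0("SNP table lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "tidylocus_format_error")
  }
  if (anyDuplicated(snps$id)) {
    abort("SNP ids must be unique", class = "tidylocus_validation_error")
  }
  if (any(snps$pos < 1L)) {
    abort("SNP positions must be >= 1 (1-based)", class = "tidylocus_validation_error")
  }
  if (any(snps$ref == snps$alt)) {
    abort("ref and alt alleles must differ", class = "tidylocus_validation_error")
  }
  if ("maf" %in% names(snps) && any(!is.na(snps$maf) & (snps$maf < 0 | snps$maf > 0.5))) {
    abort("maf must lie in [0, 0.5]", class = "tidylocus_validation_error")
  }
  tibble::as_tibble(snps)
}

#' Phased haplotype panels
#'
#' A haplotype panel couples a SNP table with a 0/1 allele matrix, one row
#' per haplotype (an even number: phased pairs), one column per SNP. It is
#' the basis for LD computation and for drawing genotypes in simulation.
#'
#' @param snps A SNP table (see [snp_table()]).
#' @param haplotypes Integer matrix of 0/1 alleles, haplotypes in rows,
#'   SNPs in columns (column order matches `snps`).
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(snps, haplotypes) {
  snps <- validate_snps(snps)
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) != nrow(snps)) {
    abort("haplotype matrix must have one column per SNP",
          class = "tidylocus_validation_error")
  }
  if (nrow(haplotypes) %% 2L != 0L) {
    abort("haplotype count must be even (phased pairs)",
          class = "tidylocus_validation_error")
  }
  if (!all(haplotypes %in% c(0L, 1L))) {
    abort("haplotype alleles must be 0/1", class = "tidylocus_validation_error")
  }
  storage.mode(haplotypes) <- "integer"
  colnames(haplotypes) <- snps$id
  structure(list(snps = snps, haplotypes = haplotypes),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d SNPs (%s:%s-%s)\n",
              nrow(x$haplotypes), nrow(x$snps), x$snps$chrom[1],
              format(min(x$snps$pos), big.mark = ","),
              format(max(x$snps$pos), big.mark = ",")))
  invisible(x)
}

#' Genotype dosage matrices
#'
#' Couples a SNP table with a samples-by-SNPs dosage matrix. Dosages count
#' alternate (effect) alleles and may be fractional in `[0, 2]`
#' (imputation-style expected dosages); `NA` marks missing genotypes, which
#' downstream analyses drop pairwise.
#'
#' @param snps A SNP table.
#' @param dosages Numeric matrix in `[0, 2]`, samples in rows.
#' @param sample_id Unique sample identifiers, one per row of `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(snps, dosages, sample_id) {
  snps <- validate_snps(snps)
  dosages <- as.matrix(dosages)
  sample_id <- as.character(sample_id)
  if (ncol(dosages) != nrow(snps)) {
    abort("dosage matrix must have one column per SNP",
          class = "tidylocus_validation_error")
  }
  if (nrow(dosages) != length(sample_id)) {
    abort("one sample id per dosage row required",
          class = "tidylocus_validation_error")
  }
  if (anyDuplicated(sample_id)) {
    abort("sample ids must be unique", class = "tidylocus_validation_error")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    abort("dosages must lie in [0, 2]", class = "tidylocus_validation_error")
  }
  dimnames(dosages) <- list(sample_id, snps$id)
  structure(list(snps = snps, dosages = dosages, sample_id = sample_id),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs\n",
              length(x$sample_id), nrow(x$snps)))
  invisible(x)
}

#' Extract a single SNP's dosage vector
#'
#' @param genotypes A [genotype_matrix()].
#' @param snp_id SNP identifier.
#' @return Named numeric vector of dosages.
#' @export
dosage_of <- function(genotypes, snp_id) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!snp_id %in% genotypes$snps$id) {
    abort(sprintf("SNP '%s' not present in genotype matrix", snp_id),
          class = "tidylocus_lookup_error")
  }
  genotypes$dosages[, snp_id]
}

#' Case/control phenotype tables
#'
#' Validates a phenotype tibble: `sample_id` (unique), `status`
#' (`"case"`/`"control"`), `subtype` (`"HRD"`, `"nonHRD"`, or `NA`;
#' non-`NA` only for cases). Additional numeric columns are treated as
#' covariates by the association functions.
#'
#' @param phenotype A data frame.
#' @return The validated tibble.
#' @export
validate_phenotype <- function(phenotype) {
  need <- c("sample_id", "status")
  missing_cols <- setdiff(need, names(phenotype))
  if (length(missing_cols)) {
    abort(paste0("phenotype lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "tidylocus_format_error")
  }
  if (anyDuplicated(phenotype$sample_id)) {
    abort("phenotype sample ids must be unique", class = "tidylocus_validation_error")
  }
  if (!all(phenotype$status %in% c("case", "control"))) {
    abort("status must be 'case' or 'control'", class = "tidylocus_validation_error")
  }
  if ("subtype" %in% names(phenotype)) {
    bad <- !is.na(phenotype$subtype) & phenotype$status == "control"
    if (any(bad)) {
      abort("subtype must be NA for controls", class = "tidylocus_validation_error")
    }
  }
  tibble::as_tibble(phenotype)
}

#' Expression matrices
#'
#' A light container for log2-scale expression: genes in rows, samples in
#' columns, plus a gene annotation tibble (`gene_id`, `chrom`, `tss`) that
#' anchors each gene for cis-window queries.
#'
#' @param values Numeric matrix, genes x samples, finite, log2 scale.
#' @param genes Tibble with `gene_id` and optionally `chrom`, `tss`.
#' @param sample_id Unique sample ids, one per column.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, genes, sample_id) {
  values <- as.matrix(values)
  genes <- tibble::as_tibble(genes)
  sample_id <- as.character(sample_id)
  if (!"gene_id" %in% names(genes)) {
    abort("genes must have a gene_id column", class = "tidylocus_format_error")
  }
  if (nrow(values) != nrow(genes) || ncol(values) != length(sample_id)) {
    abort("values must be genes x samples", class = "tidylocus_validation_error")
  }
  if (anyDuplicated(genes$gene_id) || anyDuplicated(sample_id)) {
    abort("gene and sample ids must be unique", class = "tidylocus_validation_error")
  }
  if (!all(is.finite(values))) {
    abort("expression values must be finite", class = "tidylocus_validation_error")
  }
  dimnames(values) <- list(genes$gene_id, sample_id)
  structure(list(values = values, genes = genes, sample_id = sample_id),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
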