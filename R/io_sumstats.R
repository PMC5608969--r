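#' Read and write COJO-dialect summary statistics
#'
#' The pipeline exchanges GWAS and eQTL summary statistics as tab-separated
#' text with the exact header `SNP A1 A2 freq b se p n` (the GCTA-COJO
#' dialect): `A1` is the effect allele, `b` the per-A1-allele effect
#' (log-odds for disease, log2-expression units for eQTL), `se` its
#' standard error, `p` the two-sided p-value and `n` the sample size.
#'
#' Records violating the type invariants (`se > 0`, `p` in `(0, 1]`,
#' `freq` in `(0, 1)`) are rejected with the offending row named, never
#' silently coerced.
#'
#' @param path File path.
#' @return `read_summary_stats()`: a tibble with columns
#'   `snp, a1, a2, freq, b, se, p, n`.
#' @export
read_summary_stats <- function(path) {
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "n")
  missing_cols <- setdiff(need, header)
  if (length(missing_cols)) {
    abort(paste0("summary-stat file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tidylocus_format_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    SNP = readr::col_character(), A1 = readr::col_character(),
    A2 = readr::col_character(), freq = readr::col_double(),
    b = readr::col_double(), se = readr::col_double(),
    p = readr::col_double(), n = readr::col_double()
  ))
  out <- tibble::tibble(
    snp = raw$SNP, a1 = raw$A1, a2 = raw$A2, freq = raw$freq,
    b = raw$b, se = raw$se, p = raw$p, n = raw$n
  )
  validate_summary_stats(out)
}

validate_summary_stats <- function(stats) {
  bad_se <- which(!is.na(stats$se) & stats$se <= 0)
  bad_p <- which(!is.na(stats$p) & (stats$p <= 0 | stats$p > 1))
  bad_f <- which(!is.na(stats$freq) & (stats$freq <= 0 | stats$freq >= 1))
  flag <- function(rows, what) {
    if (length(rows)) {
      abort(sprintf("invalid %s in summary-stat row(s) %s (snp %s)",
                    what, paste(head(rows, 5), collapse = ", "),
                    paste(head(stats$snp[rows], 5), collapse = ", ")),
            class = "tidylocus_validation_error")
    }
  }
  flag(bad_se, "se (must be > 0)")
  flag(bad_p, "p (must be in (0,1])")
  flag(bad_f, "freq (must be in (0,1))")
  tibble::as_tibble(stats)
}

#' @param stats A summary-statistics tibble as returned by
#'   [read_summary_stats()] or produced by the association functions.
#' @rdname read_summary_stats
#' @return `write_summary_stats()`: `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  stats <- validate_summary_stats(stats)
  out <- tibble::tibble(
    SNP = stats$snp, A1 = stats$a1, A2 = stats$a2,
    freq = formatC(stats$freq, digits = 10, format = "g"),
    b = formatC(stats$b, digits = 10, format = "g"),
    se = formatC(stats$se, digits = 10, format = "g"),
    p = formatC(stats$p, digits = 10, format = "g"),
    n = stats$n
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Harmonize summary-statistic effect alleles to a panel's ALT allele
#'
#' Aligns each record's effect allele (`a1`) to the designated panel ALT
#' allele: matching records pass through, swapped records get `b` negated
#' and `freq` reflected, and strand-ambiguous SNPs (A/T or C/G) whose
#' alleles do not match the panel verbatim are rejected rather than
#' strand-flipped — silent strand guessing is the classic failure mode of
#' summary-data MR.
#'
#' @param stats Summary-statistics tibble.
#' @param snps SNP table giving the reference orientation (`ref`, `alt`).
#' @return The harmonized tibble (only SNPs present in `snps`).
#' @export
harmonize_alleles <- function(stats, snps) {
  snps <- validate_snps(snps)
  m <- match(stats$snp, snps$id)
  keep <- !is.na(m)
  stats <- stats[keep, , drop = FALSE]
  m <- m[keep]
  ref <- snps$ref[m]; alt <- snps$alt[m]
  same <- stats$a1 == alt & stats$a2 == ref
  swapped <- stats$a1 == ref & stats$a2 == alt
  ambiguous <- paste0(pmin(stats$a1, stats$a2), pmax(stats$a1, stats$a2)) %in% c("AT", "CG")
  unmatched <- !(same | swapped)
  if (any(unmatched & ambiguous)) {
    abort(sprintf("strand-ambiguous SNP(s) with mismatched alleles: %s",
                  paste(head(stats$snp[unmatched & ambiguous], 5), collapse = ", ")),
          class = "tidylocus_harmonization_error")
  }
  if (any(unmatched)) {
    abort(sprintf("allele mismatch versus panel for SNP(s): %s",
                  paste(head(stats$snp[unmatched], 5), collapse = ", ")),
          class = "tidylocus_harmonization_error")
  }
  dplyr::mutate(stats,
    b = ifelse(swapped, -.data$b, .data$b),
    freq = ifelse(swapped, 1 - .data$freq, .data$freq),
    a1 = alt, a2 = ref
  )
}
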