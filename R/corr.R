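#' Pearson product-moment correlation between two genes
#'
#' Sample Pearson `r` with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (via [stats::cor.test()]). Pairs with missing values are dropped.
#'
#' @param x,y Paired numeric vectors (log2 expression), `n >= 3` complete
#'   pairs; zero variance in either is an error.
#' @param gene_a,gene_b Labels carried into the result.
#' @param study_tag Study label.
#' @return One-row tibble: `gene_a`, `gene_b`, `r`, `p`, `n`, `study_tag`.
#' @export
pearson_cor_test <- function(x, y, gene_a = "gene_a", gene_b = "gene_b",
                             study_tag = "study1") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("need at least 3 complete pairs", class = "tidylocus_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance", class = "tidylocus_validation_error")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(gene_a = gene_a, gene_b = gene_b,
                 r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 study_tag = study_tag)
}

#' Combine independent p-values by Fisher's method
#'
#' `X2 = -2 * sum(log(p))` referred to a chi-square with `2k` degrees of
#' freedom. Monotone (any smaller input p gives a smaller combined p) and
#' permutation-invariant; a single p passes through unchanged.
#'
#' @param p_values Vector of p-values, each in `(0, 1]`.
#' @return One-row tibble: `statistic`, `df`, `p_combined`.
#' @examples
#' fisher_combine(c(0.5, 0.5))
#' @export
fisher_combine <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values > 1)) {
    abort("p-values must be in (0, 1]", class = "tidylocus_validation_error")
  }
  if (any(p_values <= 0)) {
    abort("p = 0 gives an infinite Fisher statistic", class = "tidylocus_validation_error")
  }
  x2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  tibble::tibble(statistic = x2, df = df,
                 p_combined = pchisq(x2, df = df, lower.tail = FALSE))
}

#' Gene-gene correlation across studies with Fisher-combined p-values
#'
#' For each requested gene pair, computes the Pearson correlation within
#' every study and appends a `"combined"` row whose p-value is the
#' Fisher combination of the per-study p-values (the correlation shown
#' for the combined row is the sample-size-weighted mean of the per-study
#' `r`, for display only; inference is on the combined p).
#'
#' @param expr_list List of [expression_matrix()] objects, one per study
#'   (names become study tags).
#' @param pairs Two-column data frame (`gene_a`, `gene_b`) of pairs to
#'   test.
#' @return Tibble with per-study rows plus one combined row per pair.
#' @export
correlate_genes <- function(expr_list, pairs) {
  tags <- names(expr_list) %||% sprintf("study%d", seq_along(expr_list))
  if (is.null(names(expr_list))) names(expr_list) <- tags
  per_study <- purrr::map_dfr(tags, function(tag) {
    em <- expr_list[[tag]]
    purrr::pmap_dfr(pairs, function(gene_a, gene_b) {
      pearson_cor_test(em$values[gene_a, ], em$values[gene_b, ],
                       gene_a = gene_a, gene_b = gene_b, study_tag = tag)
    })
  })
  combined <- dplyr::group_by(per_study, .data$gene_a, .data$gene_b)
  combined <- dplyr::group_modify(combined, function(df, key) {
    if (nrow(df) == 0) {
      return(tibble::tibble(r = double(), p = double(), n = integer(),
                            study_tag = character()))
    }
    fc <- fisher_combine(df$p)
    tibble::tibble(r = sum(df$r * df$n) / sum(df$n), p = fc$p_combined,
                   n = sum(df$n), study_tag = "combined")
  })
  dplyr::bind_rows(per_study, dplyr::ungroup(combined))
}
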