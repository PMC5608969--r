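#' Regional association plot
#'
#' The classic locus view: -log10 p against chromosomal position, points
#' shaded by LD (`r2`) with the lead SNP, the lead annotated.
#'
#' @param assoc Association or meta-analysis tibble with `snp_id` and a
#'   p-value column (`p` or `p_pooled`).
#' @param snps SNP table giving positions.
#' @param panel Optional [haplotype_panel()] for LD shading.
#' @param lead_snp Lead SNP id (default: smallest p).
#' @return A ggplot object.
#' @export
plot_regional <- function(assoc, snps, panel = NULL, lead_snp = NULL) {
  p_col <- if ("p_pooled" %in% names(assoc)) "p_pooled" else "p"
  df <- dplyr::inner_join(tibble::as_tibble(assoc),
                          dplyr::select(tibble::as_tibble(snps),
                                        snp_id = "id", "pos"),
                          by = "snp_id")
  df$neglog10p <- -log10(df[[p_col]])
  lead_snp <- lead_snp %||% df$snp_id[which.max(df$neglog10p)]
  df$r2 <- if (!is.null(panel)) unname(ld_r2_with(panel, lead_snp)[df$snp_id]) else NA_real_
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$neglog10p))
  gg <- if (!is.null(panel)) {
    gg + ggplot2::geom_point(ggplot2::aes(fill = .data$r2), shape = 21, size = 2.5) +
      ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                   limits = c(0, 1), name = expression(r^2))
  } else {
    gg + ggplot2::geom_point(size = 2.5)
  }
  gg +
    ggplot2::geom_point(data = df[df$snp_id == lead_snp, ],
                        shape = 23, size = 3.5, fill = "purple") +
    ggplot2::labs(x = "Position (Mb)", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' @param object A `locus_report`.
#' @param ... Unused.
#' @rdname plot_regional
#' @method autoplot locus_report
#' @export
autoplot.locus_report <- function(object, ...) {
  plot_regional(object$meta_overall, object$panel$snps, panel = object$panel,
                lead_snp = object$lead_snp)
}

#' SMR probe plot
#'
#' One point per gene: -log10 SMR p against the gene's TSS-ordered index,
#' shape-coded by HEIDI outcome, with the Bonferroni threshold drawn.
#'
#' @param smr SMR result tibble from [smr_scan()].
#' @return A ggplot object.
#' @export
plot_smr <- function(smr) {
  df <- dplyr::mutate(tibble::as_tibble(smr),
    heidi = dplyr::case_when(
      is.na(.data$p_heidi) ~ "HEIDI undefined",
      .data$p_heidi > 0.05 ~ "HEIDI pass",
      TRUE ~ "HEIDI reject"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = -log10(.data$p_smr),
                                   shape = .data$heidi,
                                   color = .data$passes)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = -log10(df$smr_threshold[1]),
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "red", `FALSE` = "grey30"),
                                name = "passes SMR+HEIDI") +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(P)[SMR]))) +
    ggplot2::theme_minimal()
}

#' Allele-amplification cohort plot
#'
#' Per-tumor log-likelihood ratio for risk- versus non-risk-allele
#' amplification, colored by call.
#'
#' @param calls Calls tibble from [call_amplification_cohort()].
#' @return A ggplot object.
#' @export
plot_amplification <- function(calls) {
  df <- dplyr::arrange(tibble::as_tibble(calls), .data$llr)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$llr,
                                   color = .data$state)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Tumor (ranked)", y = "log-likelihood ratio (risk vs non-risk)") +
    ggplot2::theme_minimal()
}
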