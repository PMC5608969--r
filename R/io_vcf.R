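#' Read genotypes or phased haplotypes from a VCF
#'
#' Reads a VCF v4.2 file (via \pkg{vcfR}) and returns either a
#' [genotype_matrix()] of 0/1/2 alternate-allele dosages, or — when
#' `phased = TRUE` — a [haplotype_panel()] built from the phased GT field.
#' Multi-allelic records are rejected; positions stay 1-based as in the VCF.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param phased If `TRUE`, require `|`-phased genotypes and return the
#'   haplotype panel; otherwise return dosages (missing GT becomes `NA`).
#' @return A [haplotype_panel()] or [genotype_matrix()].
#' @export
read_vcf <- function(path, phased = FALSE) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("malformed VCF: ", conditionMessage(e)),
                              class = "tidylocus_format_error")
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    abort("multi-allelic records are not supported; split them upstream",
          class = "tidylocus_format_error")
  }
  snps <- snp_table(
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = alt
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || nrow(gt) == 0) {
    abort("VCF has no GT field", class = "tidylocus_format_error")
  }
  sample_id <- colnames(gt)

  if (phased) {
    if (any(grepl("/", gt, fixed = TRUE))) {
      abort("unphased genotypes ('/') present but phased haplotypes requested",
            class = "tidylocus_phase_error")
    }
    split_alleles <- function(column) {
      parts <- strsplit(column, "|", fixed = TRUE)
      bad <- lengths(parts) != 2L
      if (any(bad)) {
        abort("GT entries must be diploid 'a|b'", class = "tidylocus_phase_error")
      }
      m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
      m
    }
    # one pair of haplotype rows per sample, SNPs in columns
    haps <- matrix(0L, nrow = 2L * length(sample_id), ncol = nrow(snps))
    for (j in seq_along(sample_id)) {
      m <- split_alleles(gt[, j])
      haps[2L * j - 1L, ] <- m[, 1]
      haps[2L * j, ] <- m[, 2]
    }
    rownames(haps) <- paste0(rep(sample_id, each = 2), c("_h1", "_h2"))
    return(haplotype_panel(snps, haps))
  }

  to_dosage <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[|/]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(as.integer(alleles))
  }
  dos <- apply(gt, c(1, 2), to_dosage)
  genotype_matrix(snps, t(dos), sample_id)
}

#' Write a haplotype panel or genotype matrix as plain-text VCF
#'
#' Emits a minimal VCF v4.2 with a GT-only FORMAT column. Haplotype panels
#' are written phased (`a|b`, consecutive haplotype rows paired); genotype
#' matrices require hard-call dosages 0/1/2 and are written unphased.
#'
#' @param x A [haplotype_panel()] or [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  snps <- x$snps
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  if (inherits(x, "haplotype_panel")) {
    n_sample <- nrow(x$haplotypes) / 2L
    rn <- rownames(x$haplotypes)
    sample_id <- if (is.null(rn)) paste0("S", seq_len(n_sample)) else
      sub("_h1$", "", rn[seq(1, by = 2, length.out = n_sample)])
    gt_cols <- vapply(seq_len(n_sample), function(j) {
      paste0(x$haplotypes[2L * j - 1L, ], "|", x$haplotypes[2L * j, ])
    }, character(nrow(snps)))
  } else if (inherits(x, "genotype_matrix")) {
    if (any(!is.na(x$dosages) & x$dosages != round(x$dosages))) {
      abort("write_vcf needs hard-call dosages 0/1/2",
            class = "tidylocus_validation_error")
    }
    code <- c("0/0", "0/1", "1/1")
    sample_id <- x$sample_id
    gt_cols <- vapply(seq_along(sample_id), function(j) {
      d <- x$dosages[j, ]
      ifelse(is.na(d), "./.", code[d + 1L])
    }, character(nrow(snps)))
  } else {
    abort("write_vcf handles haplotype_panel or genotype_matrix objects",
          class = "tidylocus_validation_error")
  }
  gt_cols <- matrix(gt_cols, nrow = nrow(snps))
  body <- paste(
    snps$chrom, snps$pos, snps$id, snps$ref, snps$alt, ".", "PASS", ".", "GT",
    apply(gt_cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  col_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_id), collapse = "\t")
  writeLines(c(header, col_line, body), path)
  invisible(path)
}
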