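#' Read and write BED interval files
#'
#' BED files are 0-based, half-open `[start, end)`. The convention is kept
#' verbatim in the returned tibble; conversion to 1-based SNP coordinates
#' happens exactly once, inside [annotate_intervals()].
#'
#' @param path File path (BED3 or BED4; further columns ignored).
#' @return `read_bed()`: tibble with `chrom`, `start` (0-based),
#'   `end` (exclusive), `name` (`NA` if absent).
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character()))
  }
  if (ncol(raw) < 3) {
    abort("BED needs at least 3 columns", class = "tidylocus_format_error")
  }
  out <- tibble::tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    name = if (ncol(raw) >= 4) raw[[4]] else NA_character_
  )
  if (any(is.na(out$start)) || any(is.na(out$end))) {
    abort("non-numeric BED coordinates", class = "tidylocus_format_error")
  }
  if (any(out$start >= out$end)) {
    abort("BED intervals require start < end", class = "tidylocus_validation_error")
  }
  out
}

#' @param intervals Interval tibble with `chrom`, `start`, `end` and
#'   optionally `name`.
#' @rdname read_bed
#' @return `write_bed()`: `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (any(intervals$start >= intervals$end)) {
    abort("BED intervals require start < end", class = "tidylocus_validation_error")
  }
  nm <- intervals$name
  if (is.null(nm)) nm <- rep(NA_character_, nrow(intervals))
  lines <- ifelse(
    is.na(nm),
    paste(intervals$chrom, intervals$start, intervals$end, sep = "\t"),
    paste(intervals$chrom, intervals$start, intervals$end, nm, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
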