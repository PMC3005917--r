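#' The 12 one-base-conversion editing patterns
#'
#' Every ordered pair of distinct bases over the RNA alphabet \{A, C, G, U\}
#' defines one editing pattern, written `"X-to-Y"` for a genomic base X read
#' as Y in the transcript. There are exactly 4 x 3 = 12 such patterns; any
#' single-base conversion observed in a tag falls into exactly one of them.
#'
#' @return A character vector of the 12 pattern labels, in fixed
#'   (alphabetical by from-base, then to-base) order.
#' @examples
#' edit_patterns()
#' @export
edit_patterns <- function() {
  out <- character(0)
  for (from in RNA_BASES) {
    for (to in setdiff(RNA_BASES, from)) {
      out <- c(out, paste0(from, "-to-", to))
    }
  }
  out
}

#' Classify a reference/read base pair into an editing pattern
#'
#' @param ref_base Reference (genomic) base, one of A/C/G/U. Vectorised.
#' @param read_base Observed transcript base, one of A/C/G/U, different from
#'   `ref_base` element-wise.
#' @return Character vector of pattern labels, e.g. `"C-to-U"`.
#' @examples
#' classify_pattern("C", "U")
#' classify_pattern(c("A", "G"), c("G", "U"))
#' @export
classify_pattern <- function(ref_base, read_base) {
  ref_base <- toupper(ref_base)
  read_base <- toupper(read_base)
  if (length(ref_base) != length(read_base)) {
    abort("ref_base and read_base must have equal length")
  }
  if (!all(ref_base %in% RNA_BASES) || !all(read_base %in% RNA_BASES)) {
    abort("bases must be one of A, C, G, U")
  }
  if (any(ref_base == read_base)) {
    abort("ref_base and read_base must differ (no pattern for an identical pair)")
  }
  paste0(ref_base, "-to-", read_base)
}

#' Per-pattern sequencing error rate
#'
#' A single-base sequencing error turns the true base into one of the three
#' alternatives, so an overall per-signature error rate spreads uniformly
#' over the 12 ordered conversion patterns. An overall MPSS rate of ~5.00%
#' (20-nt signatures) gives ~0.42% per pattern, 4.25% (17-nt) gives ~0.35%,
#' and a PARE rate of 1.30 +/- 0.90% gives ~0.03--0.18%.
#'
#' @param overall_rate Overall single-base error rate in `[0, 1]`. Vectorised.
#' @param n_patterns Number of conversion patterns the rate is spread over
#'   (default 12).
#' @return `overall_rate / n_patterns`.
#' @examples
#' expected_error_rate_per_pattern(0.05)    # ~0.0042
#' expected_error_rate_per_pattern(0.0425)  # ~0.0035
#' @export
expected_error_rate_per_pattern <- function(overall_rate, n_patterns = 12) {
  if (n_patterns <= 0) abort("n_patterns must be positive")
  if (any(overall_rate < 0 | overall_rate > 1)) {
    abort("overall_rate must lie in [0, 1]")
  }
  overall_rate / n_patterns
}
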