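#' Extract fixed windows around editing sites
#'
#' Returns, for each site, the transcript subsequence from `flank` nt
#' upstream to `flank - 1` nt downstream of the site (a `2 * flank` window
#' with the edited position at relative offset 0; 100 nt for the default
#' flank of 50). Windows running past a transcript end are padded with `N`;
#' padded positions are ignored by the frequency/information computation.
#'
#' @param sites Site table with site_id, target_id, position (and optionally
#'   pattern, carried through).
#' @param transcripts Tibble with transcript_id (or target_id) and sequence.
#' @param flank Nucleotides upstream of the site (>= 1); the window is
#'   `[position - flank, position + flank - 1]`.
#' @return Tibble: site_id, target_id, position, (pattern,) window.
#' @export
extract_windows <- function(sites, transcripts, flank = 50) {
  if (flank < 1) abort("flank must be >= 1")
  if (!"transcript_id" %in% names(transcripts)) {
    transcripts <- dplyr::rename(transcripts, transcript_id = "target_id")
  }
  df <- sites %>%
    dplyr::inner_join(transcripts %>% dplyr::select("transcript_id", "sequence"),
                      by = c(target_id = "transcript_id"))
  win <- purrr::map2_chr(df$sequence, df$position, function(s, p) {
    lo <- p - flank; hi <- p + flank - 1L
    core <- substr(s, max(1L, lo), min(nchar(s), hi))
    paste0(strrep("N", max(0L, 1L - lo)), core,
           strrep("N", max(0L, hi - nchar(s))))
  })
  keep <- intersect(c("site_id", "target_id", "position", "pattern"), names(df))
  dplyr::bind_cols(df[keep], tibble(window = win))
}

#' Position-wise base frequencies and information content
#'
#' Computes, for each window position, the A/C/G/U frequencies (ignoring N
#' padding) and the information content IC = 2 - H bits, where H is the
#' Shannon entropy of the column against a uniform 25% background. With
#' `correction = TRUE` the small-sample correction e_n = 3 / (2 ln 2 n) is
#' subtracted before clipping at 0. Columns with no informative base are
#' reported as NA.
#'
#' @param windows An [extract_windows()] result or a character vector of
#'   equal-length windows.
#' @param flank Offset origin: position labels run `-flank ... flank - 1`.
#'   Defaults to half the window length.
#' @param correction Apply the small-sample entropy correction?
#' @return Tibble of class `context_profile`: position, freq_A, freq_C,
#'   freq_G, freq_U, n, ic.
#' @examples
#' position_information(c("AAG", "AAU", "AAC"), flank = 1)
#' @export
position_information <- function(windows, flank = NULL, correction = FALSE) {
  seqs <- if (is.character(windows)) windows else windows$window
  if (length(seqs) < 1) abort("need at least one window")
  W <- nchar(seqs[1])
  if (!all(nchar(seqs) == W)) abort("windows must have equal length")
  flank <- flank %||% (W %/% 2)
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  rows <- purrr::map(seq_len(W), function(j) {
    col <- chars[, j]
    col <- col[col %in% RNA_BASES]
    n <- length(col)
    if (n == 0) {
      return(tibble(position = j - flank - 1L, freq_A = NA_real_,
                    freq_C = NA_real_, freq_G = NA_real_, freq_U = NA_real_,
                    n = 0L, ic = NA_real_))
    }
    p <- table(factor(col, levels = RNA_BASES)) / n
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    ic <- 2 - h
    if (correction) ic <- ic - 3 / (2 * log(2) * n)
    tibble(position = j - flank - 1L,
           freq_A = p[["A"]], freq_C = p[["C"]], freq_G = p[["G"]],
           freq_U = p[["U"]], n = as.integer(n),
           ic = max(0, min(2, ic)))
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("context_profile", class(out))
  out
}

#' Random-sequence control windows
#'
#' Draws `n` windows of the given length from uniformly sampled transcript
#' positions (not anchored at editing sites), the background against which
#' site-anchored profiles are compared. Deterministic given `seed`.
#'
#' @param transcripts Tibble with transcript_id and sequence.
#' @param n Number of windows (>= 1).
#' @param length Window length (default 100).
#' @param seed Integer seed.
#' @return Tibble: target_id, position (window start), window.
#' @export
random_control <- function(transcripts, n, length = 100, seed = 1) {
  if (n < 1) abort("n must be >= 1")
  ok <- transcripts[nchar(transcripts$sequence) >= length, ]
  if (nrow(ok) == 0) abort("no transcript long enough for the requested window")
  with_seed0(seed, {
    idx <- sample.int(nrow(ok), n, replace = TRUE)
    starts <- purrr::map_int(idx, ~ sample.int(nchar(ok$sequence[.x]) - length + 1L, 1))
    tibble(target_id = ok$transcript_id[idx],
           position = starts,
           window = substring(ok$sequence[idx], starts, starts + length - 1L))
  })
}

#' Plot an information-content profile
#'
#' @param object A `context_profile` from [position_information()].
#' @param ... Unused.
#' @return A ggplot: IC (bits) against position relative to the site.
#' @export
autoplot.context_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$ic)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "position relative to editing site (nt)",
                  y = "information content (bits)") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}
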