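STOP_CODONS <- c("UAA", "UAG", "UGA")

# translate an RNA codon to a 1-letter amino acid ("*" for stop)
codon_aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[rna_to_dna(codon)])
}

#' Annotate the codon consequence of editing sites inside a CDS
#'
#' For each site falling inside the annotated CDS of its transcript, reads
#' the reference codon in frame (frame taken from the annotation, never
#' re-inferred), substitutes the read base at the site's in-codon offset,
#' translates both codons, and flags new start codons (edited codon AUG,
#' reference not AUG) and new stop codons (edited codon a stop, reference
#' not). Sites outside the CDS are silently dropped; transcripts whose CDS
#' length is not a multiple of 3 are skipped with a warning.
#'
#' @param sites Site table with site_id, target_id, position, ref_base,
#'   read_base, pattern.
#' @param transcripts Tibble with transcript_id, cds_start, cds_end,
#'   sequence (e.g. `transcriptome$transcripts`).
#' @return Tibble: site_id, target_id, position, pattern, cds_frame_offset
#'   (0--2), codon_before, codon_after, aa_before, aa_after, creates_start,
#'   creates_stop.
#' @export
annotate_codon_effect <- function(sites, transcripts) {
  tx <- transcripts %>%
    dplyr::select("transcript_id", "cds_start", "cds_end", "sequence")
  bad_cds <- (tx$cds_end - tx$cds_start + 1L) %% 3L != 0L
  if (any(bad_cds)) {
    warn(sprintf("%d transcript(s) with CDS length not divisible by 3 skipped: %s",
                 sum(bad_cds), paste(head(tx$transcript_id[bad_cds], 5), collapse = ", ")))
    tx <- tx[!bad_cds, ]
  }
  df <- sites %>%
    dplyr::inner_join(tx, by = c(target_id = "transcript_id")) %>%
    dplyr::filter(.data$position >= .data$cds_start,
                  .data$position <= .data$cds_end)
  if (nrow(df) == 0) {
    return(tibble(site_id = character(), target_id = character(),
                  position = integer(), pattern = character(),
                  cds_frame_offset = integer(), codon_before = character(),
                  codon_after = character(), aa_before = character(),
                  aa_after = character(), creates_start = logical(),
                  creates_stop = logical()))
  }
  off <- df$position - df$cds_start            # 0-based offset into the CDS
  frame <- off %% 3L
  cstart <- df$cds_start + off - frame
  before <- substring(df$sequence, cstart, cstart + 2L)
  stopifnot(all(substr(before, frame + 1L, frame + 1L) == df$ref_base))
  after <- before
  substr(after, frame + 1L, frame + 1L) <- df$read_base
  tibble(
    site_id = df$site_id,
    target_id = df$target_id,
    position = df$position,
    pattern = df$pattern,
    cds_frame_offset = as.integer(frame),
    codon_before = before,
    codon_after = after,
    aa_before = codon_aa(before),
    aa_after = codon_aa(after),
    creates_start = after == "AUG" & before != "AUG",
    creates_stop = after %in% STOP_CODONS & !(before %in% STOP_CODONS)
  )
}

#' Source codons reachable by a single editing event
#'
#' Enumerates every codon that a single edit of the given pattern converts
#' into `target_codon`. A source exists for each occurrence of the pattern's
#' result base in the target; when the result base is absent the set is
#' empty — the structural zeros of the start/stop-codon generation table.
#'
#' @param target_codon A 3-mer over A/C/G/U (e.g. `"AUG"`).
#' @param pattern An editing pattern label, e.g. `"C-to-U"`.
#' @return Character vector of source codons (possibly empty), sorted.
#' @examples
#' enumerate_feasible_generations("AUG", "C-to-U")  # "ACG"
#' enumerate_feasible_generations("AUG", "U-to-C")  # empty: AUG has no C
#' @export
enumerate_feasible_generations <- function(target_codon, pattern) {
  target_codon <- toupper(target_codon)
  if (nchar(target_codon) != 3) abort("target_codon must be a 3-mer")
  assert_rna(target_codon, "target_codon")
  if (!pattern %in% edit_patterns()) {
    abort(sprintf("unknown pattern '%s'", pattern))
  }
  parts <- strsplit(pattern, "-to-", fixed = TRUE)[[1]]
  from <- parts[1]; to <- parts[2]
  hits <- which(strsplit(target_codon, "")[[1]] == to)
  sources <- vapply(hits, function(i) {
    s <- target_codon
    substr(s, i, i) <- from
    s
  }, character(1))
  sort(unique(sources))
}

#' Tally start/stop codon generation by editing pattern
#'
#' Counts the events in an [annotate_codon_effect()] result that create a
#' new AUG, UAA, UAG or UGA, cross-tabulated against the 12 editing
#' patterns, with per-codon totals. Cells whose pattern's result base does
#' not occur in the codon are structurally zero.
#'
#' @param effects An [annotate_codon_effect()] result.
#' @return Tibble with 4 rows (codon AUG/UAA/UAG/UGA), one count column per
#'   pattern, and a `total` column.
#' @export
summarize_codon_table <- function(effects) {
  codons <- c("AUG", STOP_CODONS)
  pats <- edit_patterns()
  relevant <- effects %>%
    dplyr::filter((.data$creates_start & .data$codon_after == "AUG") |
                    (.data$creates_stop & .data$codon_after %in% STOP_CODONS))
  grid <- tidyr::crossing(codon = codons, pattern = pats)
  counts <- relevant %>%
    dplyr::count(codon = .data$codon_after, pattern = .data$pattern) %>%
    dplyr::right_join(grid, by = c("codon", "pattern")) %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
    tidyr::pivot_wider(names_from = "pattern", values_from = "n") %>%
    dplyr::mutate(codon = factor(.data$codon, levels = codons)) %>%
    dplyr::arrange(.data$codon) %>%
    dplyr::mutate(codon = as.character(.data$codon))
  counts$total <- rowSums(counts[pats])
  counts
}

#' Exon-boundary and translation-border annotation of sites
#'
#' Flags sites lying in the first or last three nucleotides of their exon
#' (positions that can affect splicing of the pre-mRNA) and computes the
#' signed distance to the CDS/3'UTR translation border: negative inside the
#' CDS, 0 at the last CDS base (the stop codon's 3' edge), positive in the
#' 3' UTR.
#'
#' @param sites Site table with site_id, target_id, position.
#' @param transcriptome A `transcriptome` object (exon features and CDS
#'   coordinates), or a list with `$features` and `$transcripts`.
#' @return Tibble: site_id, target_id, position, exon_index,
#'   position_in_exon, exon_length, within_first3, within_last3,
#'   distance_to_cds_end.
#' @export
annotate_boundaries <- function(sites, transcriptome) {
  exons <- transcriptome$features %>%
    dplyr::filter(.data$feature == "exon") %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::mutate(exon_index = dplyr::row_number()) %>%
    dplyr::ungroup()
  cds <- transcriptome$transcripts %>% dplyr::select("transcript_id", "cds_end")
  joined <- sites %>%
    dplyr::select("site_id", "target_id", "position") %>%
    dplyr::inner_join(exons, by = c(target_id = "transcript_id"),
                      relationship = "many-to-many") %>%
    dplyr::filter(.data$position >= .data$start, .data$position <= .data$end)
  missing <- setdiff(sites$site_id, joined$site_id)
  if (length(missing)) {
    abort(sprintf("site(s) outside every exon: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  joined %>%
    dplyr::left_join(cds, by = c(target_id = "transcript_id")) %>%
    dplyr::transmute(
      .data$site_id, .data$target_id, .data$position,
      exon_index = .data$exon_index,
      position_in_exon = .data$position - .data$start + 1L,
      exon_length = .data$end - .data$start + 1L,
      within_first3 = .data$position - .data$start + 1L <= 3L,
      within_last3 = .data$end - .data$position + 1L <= 3L,
      distance_to_cds_end = .data$position - .data$cds_end
    )
}

#' Count sites inside a window around the CDS/3'UTR border
#'
#' Counts how many sites fall within +/- `window_nt` of their transcript's
#' translation border (the last CDS base). Reports counts only: enrichment
#' near the border is a descriptive observation, no formal test is attached.
#'
#' @param sites Site table with target_id and position.
#' @param transcripts Tibble with transcript_id and cds_end.
#' @param window_nt Half-window size in nt (>= 0). Window 0 counts only
#'   sites exactly at the border.
#' @return One-row tibble: n_inside, n_outside, window_nt.
#' @export
border_window_counts <- function(sites, transcripts, window_nt) {
  if (window_nt < 0) abort("window_nt must be >= 0")
  df <- sites %>%
    dplyr::inner_join(transcripts %>% dplyr::select("transcript_id", "cds_end"),
                      by = c(target_id = "transcript_id"))
  inside <- abs(df$position - df$cds_end) <= window_nt
  tibble(n_inside = sum(inside), n_outside = sum(!inside),
         window_nt = as.integer(window_nt))
}
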