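#' Aggregate mismatch records into candidate editing sites
#'
#' Groups one-mismatch alignments by (target, position, pattern). Support is
#' counted in distinct tag sequences, pooled over libraries: the same tag
#' sequence seen in three libraries contributes 1, and two different
#' patterns at one position form two distinct candidate sites.
#'
#' @param alignments A [map_tags()] result (only `status == "mismatch"` rows
#'   are used), or any tibble of mismatch records with target_id,
#'   target_class, position, ref_base, read_base, pattern, tag and
#'   optionally library_id.
#' @return Tibble of candidate sites: site_id, target_id, target_class,
#'   position, ref_base, read_base, pattern, distinct_read_support,
#'   n_libraries, tag_lengths (list of supporting tag lengths).
#' @export
aggregate_sites <- function(alignments) {
  mm <- alignments
  if ("status" %in% names(mm)) mm <- dplyr::filter(mm, .data$status == "mismatch")
  if (!"library_id" %in% names(mm)) mm$library_id <- "lib01"
  mm %>%
    dplyr::group_by(.data$target_id, .data$target_class, .data$position,
                    .data$ref_base, .data$read_base, .data$pattern) %>%
    dplyr::summarise(
      distinct_read_support = dplyr::n_distinct(.data$tag),
      n_libraries = dplyr::n_distinct(.data$library_id),
      tag_lengths = list(sort(unique(nchar(.data$tag)))),
      .groups = "drop"
    ) %>%
    dplyr::mutate(site_id = site_id(.data$target_id, .data$position, .data$pattern),
                  .before = 1) %>%
    dplyr::arrange(.data$target_id, .data$position, .data$pattern)
}

#' Site-calling criteria
#'
#' The prediction criteria for calling editing sites: a protein-coding
#' (including organellar) transcript must carry more than two candidate
#' sites (>= 3) and each site must be supported by more than five distinct
#' short reads (>= 6); a pre-miRNA site must be supported by more than two
#' distinct short reads (>= 3), with no per-hairpin site minimum. The
#' "more than" wording is read strictly.
#'
#' @param min_sites_per_transcript Minimum called sites a protein-coding
#'   transcript must retain (default 3).
#' @param min_reads_per_site Minimum distinct tag sequences per site on
#'   protein-coding transcripts (default 6).
#' @param min_reads_per_premirna_site Minimum distinct tag sequences per
#'   pre-miRNA site (default 3).
#' @param min_ratio_report Minimum editing ratio for reporting (default 0 =
#'   report all).
#' @return A list of class `calling_criteria`.
#' @export
calling_criteria <- function(min_sites_per_transcript = 3,
                             min_reads_per_site = 6,
                             min_reads_per_premirna_site = 3,
                             min_ratio_report = 0) {
  if (min_sites_per_transcript < 1 || min_reads_per_site < 1 ||
      min_reads_per_premirna_site < 1) {
    abort("criteria thresholds must be >= 1")
  }
  structure(list(min_sites_per_transcript = min_sites_per_transcript,
                 min_reads_per_site = min_reads_per_site,
                 min_reads_per_premirna_site = min_reads_per_premirna_site,
                 min_ratio_report = min_ratio_report),
            class = "calling_criteria")
}

#' Apply the calling criteria to candidate sites
#'
#' Protein-coding (and organellar) transcripts: sites with
#' `distinct_read_support >= min_reads_per_site` are kept, then only
#' transcripts retaining at least `min_sites_per_transcript` such sites
#' survive (the per-transcript rule is applied across patterns). Pre-miRNAs:
#' sites with support `>= min_reads_per_premirna_site` are kept, with no
#' per-target minimum.
#'
#' @param sites An [aggregate_sites()] result.
#' @param criteria A [calling_criteria()] object.
#' @return The called subset of `sites`.
#' @export
apply_criteria <- function(sites, criteria = calling_criteria()) {
  stopifnot(inherits(criteria, "calling_criteria"))
  mirna <- sites %>%
    dplyr::filter(.data$target_class == "pre_miRNA",
                  .data$distinct_read_support >= criteria$min_reads_per_premirna_site)
  coding <- sites %>%
    dplyr::filter(.data$target_class != "pre_miRNA",
                  .data$distinct_read_support >= criteria$min_reads_per_site) %>%
    dplyr::group_by(.data$target_id) %>%
    dplyr::filter(dplyr::n() >= criteria$min_sites_per_transcript) %>%
    dplyr::ungroup()
  dplyr::bind_rows(coding, mirna) %>%
    dplyr::arrange(.data$target_id, .data$position, .data$pattern)
}

#' Per-library editing ratios
#'
#' The editing ratio of a site in a library is the TPM of the edited reads
#' divided by the TPM of all reads surrounding the site: numerator = summed
#' TPM of mismatch tags supporting the site (its own pattern by default),
#' denominator = summed TPM of every uniquely aligned tag (perfect or
#' one-mismatch) whose alignment spans the site's position. The ratio is
#' missing (NA) in libraries with no spanning coverage.
#'
#' @param sites Site table (needs site_id, target_id, position, pattern).
#' @param alignments A [map_tags()] result with library_id and tpm columns.
#' @param pattern_mode `"site"` (default): the numerator counts only tags
#'   carrying the site's own pattern; `"all"`: any mismatch at the site's
#'   position counts as edited.
#' @return Long tibble: site_id, library_id, edited_tpm, total_tpm, ratio.
#'   Every (site, library) combination present in `alignments` is reported.
#' @export
editing_ratio <- function(sites, alignments, pattern_mode = c("site", "all")) {
  pattern_mode <- match.arg(pattern_mode)
  if (!"tpm" %in% names(alignments)) abort("alignments must carry a tpm column")
  libs <- sort(unique(alignments$library_id))
  aln <- alignments %>%
    dplyr::filter(.data$status %in% c("perfect", "mismatch")) %>%
    dplyr::mutate(aln_end = .data$start + nchar(.data$tag) - 1L)
  sites_key <- sites %>%
    dplyr::select(site = "site_id", site_target = "target_id",
                  site_pos = "position", site_pattern = "pattern")
  joined <- dplyr::inner_join(aln, sites_key,
                              by = c(target_id = "site_target"),
                              relationship = "many-to-many") %>%
    dplyr::filter(.data$start <= .data$site_pos, .data$aln_end >= .data$site_pos)
  edited <- if (pattern_mode == "site") {
    joined$status == "mismatch" & !is.na(joined$position) &
      joined$position == joined$site_pos & joined$pattern == joined$site_pattern
  } else {
    joined$status == "mismatch" & !is.na(joined$position) &
      joined$position == joined$site_pos
  }
  joined %>%
    dplyr::mutate(.edited = edited) %>%
    dplyr::group_by(site_id = .data$site, .data$library_id) %>%
    dplyr::summarise(edited_tpm = sum(.data$tpm[.data$.edited]),
                     total_tpm = sum(.data$tpm), .groups = "drop") %>%
    tidyr::complete(site_id = sites$site_id, library_id = libs,
                    fill = list(edited_tpm = 0, total_tpm = 0)) %>%
    dplyr::mutate(ratio = dplyr::if_else(.data$total_tpm > 0,
                                         .data$edited_tpm / .data$total_tpm,
                                         NA_real_))
}
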