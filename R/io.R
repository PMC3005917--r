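#' Read sequences from FASTA
#'
#' Sequences are uppercased and converted to the RNA alphabet (T becomes U)
#' on read; [write_fasta()] converts back, so a write/read round trip is the
#' identity.
#'
#' @param path FASTA file.
#' @return Tibble: id (first whitespace-delimited token of the header),
#'   sequence.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  tibble(id = sub("\\s.*$", "", names(ss)),
         sequence = unname(dna_to_rna(as.character(ss))))
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble whose first id-like column (`id`, `transcript_id`,
#'   `premirna_id` or `target_id`) names the records and with a `sequence`
#'   column (RNA alphabet; written as DNA, U becomes T).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  idcol <- intersect(c("id", "transcript_id", "premirna_id", "target_id"),
                     names(seqs))[1]
  if (is.na(idcol)) abort("no id column found")
  ss <- Biostrings::BStringSet(rna_to_dna(seqs$sequence))
  names(ss) <- seqs[[idcol]]
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read transcript structure from GFF3
#'
#' 1-based closed intervals; the seqid is the transcript the feature lives
#' on (spliced mRNA coordinates), and the `compartment` attribute is carried
#' through when present.
#'
#' @param path GFF3 file.
#' @return Tibble: transcript_id, feature, start, end, compartment.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    feature = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    compartment = if (!is.null(gr$compartment)) as.character(gr$compartment)
                  else NA_character_
  )
}

#' Write transcript structure to GFF3
#'
#' @param features Tibble: transcript_id, feature, start, end and optionally
#'   compartment.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$transcript_id,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    type = features$feature,
    source = "editscan"
  )
  if ("compartment" %in% names(features)) gr$compartment <- features$compartment
  # CDS features start in frame 0 on the spliced transcript
  gr$phase <- ifelse(features$feature == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a tag library TSV
#'
#' Expects columns `tag` and `raw_count` (tab-separated, header line).
#' Tags are converted to the RNA alphabet; a tag containing a character
#' outside ACGTU is rejected with its line number.
#'
#' @param path TSV file.
#' @param library_id Library label to attach (default: file name sans
#'   extension).
#' @return Tibble: library_id, tag, raw_count, tpm.
#' @export
read_tag_tsv <- function(path, library_id = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    tag = readr::col_character(), raw_count = readr::col_integer()))
  bad <- grepl("[^ACGTUacgtu]", df$tag)
  if (any(bad)) {
    abort(sprintf("invalid tag character at line %d of %s ('%s')",
                  which(bad)[1] + 1L, path, df$tag[bad][1]))
  }
  df %>%
    dplyr::mutate(tag = dna_to_rna(.data$tag),
                  library_id = library_id %||%
                    sub("\\.[^.]*$", "", basename(path)),
                  .before = 1) %>%
    normalize_tpm()
}

#' Write one tag library per file as TSV
#'
#' @param tags Tibble with library_id, tag, raw_count.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_tag_tsv <- function(tags, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(split(tags, tags$library_id), function(df) {
    p <- file.path(dir, paste0(df$library_id[1], ".tsv"))
    readr::write_tsv(df %>% dplyr::select("tag", "raw_count"), p)
    p
  })
  invisible(paths)
}

#' Write a site table as TSV with a provenance header
#'
#' @param sites Site table (list columns are flattened to comma strings).
#' @param path Output file.
#' @param header Named character vector written as leading `# key=value`
#'   comment lines (e.g. seed and config hash).
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path, header = NULL) {
  # semicolon separator: readr would parse "17,20" as a grouped number
  flat <- sites %>%
    dplyr::mutate(dplyr::across(dplyr::where(is.list),
                                ~ purrr::map_chr(.x, paste, collapse = ";")))
  lines <- if (length(header)) sprintf("# %s=%s", names(header), header) else character(0)
  readr::write_lines(lines, path)
  readr::write_tsv(flat, path, append = length(lines) > 0, col_names = TRUE)
  invisible(path)
}

#' Read a site table written by [write_sites_tsv()]
#'
#' @param path TSV file (leading `#` comment lines are skipped).
#' @return Tibble.
#' @export
read_sites_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Write sites as BED
#'
#' Converts the 1-based site positions to BED's 0-based half-open intervals
#' (a site at position p becomes `[p-1, p)`), with the pattern as name and
#' the distinct-read support as score.
#'
#' @param sites Site table with target_id, position, pattern and
#'   distinct_read_support.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  bed <- sites %>%
    dplyr::transmute(chrom = .data$target_id,
                     chromStart = .data$position - 1L,
                     chromEnd = .data$position,
                     name = .data$pattern,
                     score = .data$distinct_read_support)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
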