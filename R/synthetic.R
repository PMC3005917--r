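#' Configuration for the synthetic tag-library generator
#'
#' Bundles the knobs of the synthetic transcriptome + tag-library generator.
#' Defaults emulate the reference design the analysis assumes: 17 tissue
#' libraries of fixed-length sense-strand signatures, a per-signature
#' single-base substitution error rate of 5.00% for 20-nt signatures (4.25%
#' for 17-nt ones) and 1.30% for degradome (PARE) tags.
#'
#' The error rate is interpreted per signature: with probability
#' `per_signature_error_rate` an emitted tag carries exactly one substituted
#' base (position uniform over the tag, replacement uniform over the three
#' alternative bases), so each of the 12 conversion patterns occurs at
#' rate/12 — the arithmetic behind the ~0.42% / ~0.35% per-pattern rates.
#'
#' @param n_transcripts Number of protein-coding transcripts to simulate.
#' @param transcript_length_range Length range (nt), inclusive.
#' @param compartment_fractions Named proportions over
#'   `c("nuclear", "mitochondrial", "chloroplast")`, summing to 1.
#' @param n_libraries Number of tissue libraries (default 17).
#' @param tag_length Signature length, 17 or 20 nt.
#' @param per_signature_error_rate Probability an emitted tag contains one
#'   erroneous base. Defaults to 0.05 for 20-nt tags, 0.0425 for 17-nt tags.
#' @param pare_error_rate Per-signature error rate for PARE-mode simulation
#'   (default 0.013).
#' @param n_premirnas Number of pre-miRNA hairpins to simulate.
#' @param premirna_length_range Hairpin length range (nt), inclusive.
#' @param n_tags_per_library Tags emitted per library.
#' @param seed Integer seed; every generator call is deterministic given it.
#' @return A list of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(n_transcripts = 5, seed = 1)
#' @export
synthetic_config <- function(n_transcripts = 30,
                             transcript_length_range = c(600, 1500),
                             compartment_fractions = c(nuclear = 0.8,
                                                       mitochondrial = 0.1,
                                                       chloroplast = 0.1),
                             n_libraries = 17,
                             tag_length = 20,
                             per_signature_error_rate = NULL,
                             pare_error_rate = 0.013,
                             n_premirnas = 8,
                             premirna_length_range = c(70, 200),
                             n_tags_per_library = 20000,
                             seed = 1) {
  if (!tag_length %in% c(17L, 20L)) abort("tag_length must be 17 or 20")
  if (n_transcripts < 0) abort("n_transcripts must be >= 0")
  if (transcript_length_range[1] > transcript_length_range[2]) {
    abort("degenerate transcript_length_range: min > max")
  }
  if (premirna_length_range[1] > premirna_length_range[2]) {
    abort("degenerate premirna_length_range: min > max")
  }
  wanted <- c("nuclear", "mitochondrial", "chloroplast")
  if (is.null(names(compartment_fractions)) ||
      !all(names(compartment_fractions) %in% wanted)) {
    abort("compartment_fractions must be named with nuclear/mitochondrial/chloroplast")
  }
  fr <- stats::setNames(rep(0, 3), wanted)
  fr[names(compartment_fractions)] <- compartment_fractions
  if (abs(sum(fr) - 1) > 1e-9) abort("compartment_fractions must sum to 1")
  per_signature_error_rate <- per_signature_error_rate %||%
    (if (tag_length == 20L) 0.05 else 0.0425)
  for (r in c(per_signature_error_rate, pare_error_rate)) {
    if (r < 0 || r > 1) abort("error rates must lie in [0, 1]")
  }
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    transcript_length_range = as.integer(transcript_length_range),
    compartment_fractions = fr,
    n_libraries = as.integer(n_libraries),
    tag_length = as.integer(tag_length),
    per_signature_error_rate = per_signature_error_rate,
    pare_error_rate = pare_error_rate,
    n_premirnas = as.integer(n_premirnas),
    premirna_length_range = as.integer(premirna_length_range),
    n_tags_per_library = as.integer(n_tags_per_library),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "synthetic_config")
}

library_ids <- function(n) sprintf("lib%02d", seq_len(n))

# one protein-coding transcript: 5'UTR | CDS (AUG ... stop, length %% 3 == 0) | 3'UTR
make_coding_sequence <- function(len) {
  utr5 <- max(12L, round(len * 0.12))
  utr3 <- max(30L, round(len * 0.2))
  cds <- len - utr5 - utr3
  cds <- cds - cds %% 3L
  if (cds < 9L) { # very short transcripts: shrink UTRs
    utr5 <- 6L; cds <- (len - 12L) - (len - 12L) %% 3L; utr3 <- len - utr5 - cds
  }
  utr3 <- len - utr5 - cds
  stops <- c("UAA", "UAG", "UGA")
  codons <- apply(expand.grid(RNA_BASES, RNA_BASES, RNA_BASES), 1, paste, collapse = "")
  sense <- setdiff(codons, stops)
  n_inner <- cds / 3L - 2L
  seq <- paste0(
    random_rna(utr5),
    "AUG",
    paste(sample(sense, n_inner, replace = TRUE), collapse = ""),
    sample(stops, 1),
    random_rna(utr3)
  )
  list(sequence = seq, cds_start = utr5 + 1L, cds_end = utr5 + cds)
}

# split 1..len into n_exons contiguous intervals, each >= min_len where possible
make_exons <- function(len, n_exons, min_len = 20L) {
  n_exons <- max(1L, min(n_exons, len %/% min_len))
  if (n_exons == 1L) return(tibble(start = 1L, end = len))
  cuts <- sort(sample(seq(min_len, len - min_len), n_exons - 1L))
  # enforce minimum spacing; fall back to fewer exons when crowded
  keep <- c(TRUE, diff(cuts) >= min_len)
  cuts <- cuts[keep]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, len)
  tibble(start = as.integer(starts), end = as.integer(ends))
}

#' Generate a synthetic transcriptome and pre-miRNA set
#'
#' Produces protein-coding transcripts (spliced, sense-strand mRNA
#' coordinates) with exon/CDS/UTR structure and a compartment label
#' (nuclear, mitochondrial or chloroplast), plus pre-miRNA hairpins with an
#' annotated mature-miRNA interval. Nuclear and organellar transcripts share
#' the same structure; only the compartment label differs. Deterministic
#' given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `transcriptome` with tibbles
#'   `$transcripts` (transcript_id, compartment, length, cds_start, cds_end,
#'   sequence), `$features` (GFF3-like: transcript_id, feature, start, end)
#'   and `$premirnas` (premirna_id, length, mature_start, mature_end,
#'   sequence).
#' @examples
#' tx <- generate_transcriptome(synthetic_config(n_transcripts = 3, seed = 7))
#' tx$transcripts
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed0(config$seed, {
    n <- config$n_transcripts
    if (n > 0) {
      lens <- sample(seq(config$transcript_length_range[1],
                         config$transcript_length_range[2]), n, replace = TRUE)
      comp <- sample(names(config$compartment_fractions), n, replace = TRUE,
                     prob = config$compartment_fractions)
      built <- purrr::map(lens, make_coding_sequence)
      transcripts <- tibble(
        transcript_id = sprintf("TX%04d", seq_len(n)),
        compartment = comp,
        length = as.integer(lens),
        cds_start = purrr::map_int(built, "cds_start"),
        cds_end = purrr::map_int(built, "cds_end"),
        sequence = purrr::map_chr(built, "sequence")
      )
      features <- purrr::pmap(transcripts, function(transcript_id, compartment,
                                                    length, cds_start, cds_end,
                                                    sequence) {
        ex <- make_exons(length, sample(1:4, 1))
        dplyr::bind_rows(
          tibble(feature = "exon", start = ex$start, end = ex$end),
          tibble(feature = "five_prime_UTR", start = 1L, end = cds_start - 1L),
          tibble(feature = "CDS", start = cds_start, end = cds_end),
          tibble(feature = "three_prime_UTR", start = cds_end + 1L, end = length)
        ) %>%
          dplyr::filter(.data$start <= .data$end) %>%
          dplyr::mutate(transcript_id = transcript_id, .before = 1)
      }) %>% purrr::list_rbind()
    } else {
      transcripts <- tibble(transcript_id = character(), compartment = character(),
                            length = integer(), cds_start = integer(),
                            cds_end = integer(), sequence = character())
      features <- tibble(transcript_id = character(), feature = character(),
                         start = integer(), end = integer())
    }
    m <- config$n_premirnas
    if (m > 0) {
      plens <- sample(seq(config$premirna_length_range[1],
                          config$premirna_length_range[2]), m, replace = TRUE)
      mstart <- purrr::map_int(plens, ~ sample(seq_len(.x - 20L), 1))
      premirnas <- tibble(
        premirna_id = sprintf("MIR%03d", seq_len(m)),
        length = as.integer(plens),
        mature_start = mstart,
        mature_end = mstart + 20L,
        sequence = random_rna(plens)
      )
    } else {
      premirnas <- tibble(premirna_id = character(), length = integer(),
                          mature_start = integer(), mature_end = integer(),
                          sequence = character())
    }
    structure(list(transcripts = transcripts, features = features,
                   premirnas = premirnas, config = config),
              class = "transcriptome")
  })
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("<transcriptome> %d transcripts (%s), %d pre-miRNAs\n",
              nrow(x$transcripts),
              paste(sprintf("%s: %d", names(table(x$transcripts$compartment)),
                            table(x$transcripts$compartment)), collapse = ", "),
              nrow(x$premirnas)))
  invisible(x)
}

#' Mapping targets of a transcriptome
#'
#' Flattens a [generate_transcriptome()] result into the target table the
#' mapper consumes: one row per transcript or pre-miRNA with its class
#' (`protein_coding`, `mitochondrial`, `chloroplast`, `pre_miRNA`).
#'
#' @param transcriptome A `transcriptome` object.
#' @return Tibble with columns target_id, target_class, sequence.
#' @export
targets_table <- function(transcriptome) {
  cls <- c(nuclear = "protein_coding", mitochondrial = "mitochondrial",
           chloroplast = "chloroplast")
  dplyr::bind_rows(
    transcriptome$transcripts %>%
      dplyr::transmute(target_id = .data$transcript_id,
                       target_class = unname(cls[.data$compartment]),
                       sequence = .data$sequence),
    transcriptome$premirnas %>%
      dplyr::transmute(target_id = .data$premirna_id,
                       target_class = "pre_miRNA",
                       sequence = .data$sequence)
  )
}

#' Plant editing events into transcripts
#'
#' Given ground-truth editing events (transcript, 1-based position, from/to
#' bases, per-library editing ratio), constructs the edited haplotypes of
#' each transcript and their per-library mixture weights. Sites are treated
#' as independent, so a transcript with k events yields up to 2^k haplotypes
#' whose weights are the product mixture of the per-site ratios. The
#' reference sequence is never modified.
#'
#' @param transcripts Tibble with at least transcript_id and sequence
#'   (e.g. `transcriptome$transcripts` or a [targets_table()] renamed).
#' @param events Tibble with columns transcript_id, position, from, to and
#'   either a single `ratio` column (applied to every library in
#'   `libraries`) or long per-library rows with `library_id` and `ratio`.
#' @param libraries Character vector of library ids; required when `events`
#'   has no library_id column.
#' @return Long tibble of class `haplotype_mix`: transcript_id, haplotype_id
#'   (`"ref"` or a bitmask over the transcript's events), sequence,
#'   library_id, weight. Weights sum to 1 per transcript x library. The
#'   normalised event table is attached as attribute `"events"`.
#' @examples
#' tx <- tibble::tibble(transcript_id = "t1", sequence = "AACGUACGU")
#' ev <- tibble::tibble(transcript_id = "t1", position = 3, from = "C",
#'                      to = "U", ratio = 0.5)
#' plant_events(tx, ev, libraries = "lib01")
#' @export
plant_events <- function(transcripts, events, libraries = NULL) {
  if (!"transcript_id" %in% names(transcripts) && "target_id" %in% names(transcripts)) {
    transcripts <- dplyr::rename(transcripts, transcript_id = "target_id")
  }
  if (!"library_id" %in% names(events)) {
    if (is.null(libraries)) abort("supply `libraries` when events carry a single ratio")
    events <- tidyr::crossing(events, library_id = libraries)
  }
  libraries <- libraries %||% sort(unique(events$library_id))
  if (any(events$ratio < 0 | events$ratio > 1)) abort("ratios must lie in [0, 1]")
  ev_sites <- events %>%
    dplyr::distinct(.data$transcript_id, .data$position, .data$from, .data$to) %>%
    dplyr::left_join(transcripts %>% dplyr::select("transcript_id", "sequence"),
                     by = "transcript_id")
  if (anyNA(ev_sites$sequence)) {
    abort(sprintf("event references unknown transcript '%s'",
                  ev_sites$transcript_id[is.na(ev_sites$sequence)][1]))
  }
  refb <- substr(ev_sites$sequence, ev_sites$position, ev_sites$position)
  bad <- refb != ev_sites$from
  if (any(bad)) {
    abort(sprintf(
      "from-base mismatch for event %s:%d (%s planted, reference is %s)",
      ev_sites$transcript_id[bad][1], ev_sites$position[bad][1],
      ev_sites$from[bad][1], refb[bad][1]))
  }
  if (any(ev_sites$from == ev_sites$to)) abort("events must change the base (from != to)")

  per_tx <- split(ev_sites, ev_sites$transcript_id)
  hap_rows <- purrr::imap(per_tx, function(ev, tx_id) {
    ev <- dplyr::arrange(ev, .data$position)
    k <- nrow(ev)
    if (k > 12) abort(sprintf("transcript %s has %d events; max 12 per transcript", tx_id, k))
    seq0 <- ev$sequence[1]
    masks <- 0:(2^k - 1)
    purrr::map(masks, function(m) {
      edited <- which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
      s <- seq0
      for (i in edited) substr(s, ev$position[i], ev$position[i]) <- ev$to[i]
      tibble(transcript_id = tx_id,
             haplotype_id = if (m == 0) "ref" else
               paste0("h", paste(ifelse(seq_len(k) %in% edited, 1, 0), collapse = "")),
             sequence = s,
             edited_positions = list(ev$position[edited]))
    }) %>% purrr::list_rbind() %>% dplyr::mutate(.mask = masks)
  })

  # per-library weights: product over sites of ratio (edited) or 1 - ratio
  ratio_tbl <- events %>%
    dplyr::select("transcript_id", "position", "library_id", "ratio")
  mix <- purrr::imap(per_tx, function(ev, tx_id) {
    ev <- dplyr::arrange(ev, .data$position)
    haps <- hap_rows[[tx_id]]
    purrr::map(libraries, function(lib) {
      r <- ratio_tbl %>%
        dplyr::filter(.data$transcript_id == tx_id, .data$library_id == lib) %>%
        dplyr::arrange(.data$position)
      rr <- stats::setNames(rep(0, nrow(ev)), ev$position)
      rr[as.character(r$position)] <- r$ratio
      w <- purrr::map_dbl(haps$.mask, function(m) {
        edited <- bitwAnd(m, 2^(seq_len(nrow(ev)) - 1)) > 0
        prod(ifelse(edited, rr, 1 - rr))
      })
      haps %>% dplyr::select(-".mask") %>%
        dplyr::mutate(library_id = lib, weight = w)
    }) %>% purrr::list_rbind()
  }) %>% purrr::list_rbind()

  untouched <- setdiff(transcripts$transcript_id, names(per_tx))
  if (length(untouched)) {
    base <- transcripts %>%
      dplyr::filter(.data$transcript_id %in% untouched) %>%
      dplyr::transmute(.data$transcript_id, haplotype_id = "ref",
                       .data$sequence, edited_positions = list(integer(0)))
    mix <- dplyr::bind_rows(mix, tidyr::crossing(base, library_id = libraries) %>%
                              dplyr::mutate(weight = 1))
  }
  out <- mix %>% dplyr::arrange(.data$transcript_id, .data$haplotype_id, .data$library_id)
  attr(out, "events") <- events
  class(out) <- c("haplotype_mix", class(out))
  out
}

# corrupt a fraction `rate` of tags with exactly one substitution each;
# returns list(tags, pattern) with pattern NA for untouched tags
corrupt_tags <- function(tags, rate) {
  n <- length(tags)
  pattern <- rep(NA_character_, n)
  if (n == 0 || rate <= 0) return(list(tags = tags, pattern = pattern))
  hit <- runif(n) < rate
  idx <- which(hit)
  if (length(idx)) {
    L <- nchar(tags[1])
    pos <- sample.int(L, length(idx), replace = TRUE)
    old <- substr(tags[idx], pos, pos)
    # uniform choice among the 3 alternative bases
    alt <- vapply(old, function(b) sample(setdiff(RNA_BASES, b), 1), character(1),
                  USE.NAMES = FALSE)
    out <- tags
    substr(out[idx], pos, pos) <- alt
    tags <- out
    pattern[idx] <- paste0(old, "-to-", alt)
  }
  list(tags = tags, pattern = pattern)
}

# shared tag-emission engine for MPSS and PARE modes
simulate_tags <- function(haplotypes, tag_length, error_rate, n_tags,
                          start_sampler, libraries, seed, keep_truth,
                          abundance = NULL) {
  with_seed0(seed, {
    hap <- haplotypes %>% dplyr::filter(nchar(.data$sequence) >= tag_length)
    short <- setdiff(unique(haplotypes$transcript_id), unique(hap$transcript_id))
    if (length(short)) {
      warn(sprintf("%d transcript(s) shorter than tag_length skipped: %s",
                   length(short), paste(head(short, 5), collapse = ", ")))
    }
    tx_ids <- unique(hap$transcript_id)
    out <- purrr::map(libraries, function(lib) {
      hl <- hap %>% dplyr::filter(.data$library_id == lib, .data$weight > 0)
      if (nrow(hl) == 0) {
        return(tibble(library_id = character(), tag = character(),
                      raw_count = integer()))
      }
      ab <- abundance %||%
        stats::setNames(rlnorm(length(tx_ids), meanlog = log(100), sdlog = 1), tx_ids)
      p <- ab[hl$transcript_id] * hl$weight
      rows <- sample.int(nrow(hl), n_tags, replace = TRUE, prob = p)
      # start positions per sampled row, grouped by haplotype for speed
      starts <- integer(n_tags)
      for (g in split(seq_len(n_tags), rows)) {
        r <- rows[g[1]]
        st <- start_sampler(hl$sequence[r], length(g), tag_length)
        starts[g] <- st
      }
      src <- substring(hl$sequence[rows], starts, starts + tag_length - 1L)
      cor <- corrupt_tags(src, error_rate)
      emitted <- tibble(tag = cor$tags, source = src, pattern = cor$pattern)
      lib_tbl <- emitted %>%
        dplyr::count(.data$tag, name = "raw_count") %>%
        dplyr::mutate(library_id = lib, .before = 1)
      if (keep_truth) {
        attr(lib_tbl, "truth") <- emitted %>%
          dplyr::count(.data$tag, .data$source, .data$pattern, name = "n") %>%
          dplyr::mutate(library_id = lib, .before = 1)
      }
      lib_tbl
    })
    truth <- purrr::map(out, attr, "truth")
    res <- purrr::list_rbind(out)
    if (nrow(res)) res <- normalize_tpm(res)
    if (keep_truth) attr(res, "truth") <- purrr::list_rbind(purrr::compact(truth))
    res
  })
}

# start positions immediately 3' of a GAUC (DpnII) motif; uniform fallback
gatc_start_sampler <- function(sequence, n, tag_length) {
  hits <- gregexpr("GAUC", sequence, fixed = TRUE)[[1]]
  maxs <- nchar(sequence) - tag_length + 1L
  anchors <- if (hits[1] == -1) integer(0) else as.integer(hits) + 4L
  anchors <- anchors[anchors >= 1L & anchors <= maxs]
  if (length(anchors) == 0) return(sample.int(maxs, n, replace = TRUE))
  anchors[sample.int(length(anchors), n, replace = TRUE)]
}

uniform_start_sampler <- function(sequence, n, tag_length) {
  sample.int(nchar(sequence) - tag_length + 1L, n, replace = TRUE)
}

#' Simulate MPSS-like signature libraries
#'
#' Emits fixed-length sense-strand tags from the haplotype mixture of each
#' transcript. With `anchoring = "gatc"` tags start immediately 3' of a
#' GAUC (DpnII) motif when the haplotype has one (the MPSS protocol's
#' anchoring), falling back to uniform start positions otherwise;
#' `anchoring = "uniform"` samples starts uniformly, which spreads distinct
#' tags across every transcript position. Each emitted tag is independently
#' corrupted with probability `error_rate` by one uniform substitution.
#' Counts are drawn per haplotype proportionally to a per-transcript,
#' per-library log-normal abundance times the haplotype weight; TPM is
#' computed per library. Deterministic given `seed`.
#'
#' @param haplotypes A [plant_events()] result (long haplotype mixture).
#' @param config A [synthetic_config()]; supplies defaults below.
#' @param anchoring `"gatc"` (default) or `"uniform"`.
#' @param n_tags Tags emitted per library.
#' @param tag_length,error_rate,libraries,seed Override the config values.
#' @param abundance Optional named vector of per-transcript abundances; by
#'   default drawn log-normally per library.
#' @param keep_truth If `TRUE`, attach a `"truth"` attribute recording, per
#'   emitted tag, its uncorrupted source substring and the error pattern
#'   applied (`NA` when none) — used for error-model calibration.
#' @return Tibble: library_id, tag, raw_count, tpm.
#' @export
simulate_mpss_library <- function(haplotypes, config,
                                  anchoring = c("gatc", "uniform"),
                                  n_tags = config$n_tags_per_library,
                                  tag_length = config$tag_length,
                                  error_rate = config$per_signature_error_rate,
                                  libraries = NULL,
                                  seed = config$seed,
                                  abundance = NULL,
                                  keep_truth = FALSE) {
  anchoring <- match.arg(anchoring)
  if (!tag_length %in% c(17L, 20L)) abort("tag_length must be 17 or 20")
  libraries <- libraries %||% sort(unique(haplotypes$library_id))
  sampler <- if (anchoring == "gatc") gatc_start_sampler else uniform_start_sampler
  simulate_tags(haplotypes, tag_length, error_rate, n_tags, sampler,
                libraries, seed, keep_truth, abundance)
}

#' Simulate PARE-like degradome libraries
#'
#' As [simulate_mpss_library()], but tags are 20-nt windows whose starts are
#' sampled from annotated cleavage positions when supplied (uniformly over
#' them), otherwise uniformly over transcript positions; the default error
#' rate is the degradome rate (1.3%).
#'
#' @inheritParams simulate_mpss_library
#' @param cleavage_sites Optional tibble (transcript_id, position) of 5'
#'   cleavage positions. An empty tibble yields an empty library.
#' @return Tibble: library_id, tag, raw_count, tpm.
#' @export
simulate_pare_library <- function(haplotypes, config,
                                  cleavage_sites = NULL,
                                  n_tags = config$n_tags_per_library,
                                  error_rate = config$pare_error_rate,
                                  libraries = NULL,
                                  seed = config$seed,
                                  abundance = NULL,
                                  keep_truth = FALSE) {
  libraries <- libraries %||% sort(unique(haplotypes$library_id))
  if (!is.null(cleavage_sites)) {
    if (nrow(cleavage_sites) == 0) {
      return(tibble(library_id = character(), tag = character(),
                    raw_count = integer(), tpm = double()))
    }
    haplotypes <- haplotypes %>%
      dplyr::semi_join(cleavage_sites, by = "transcript_id")
    cl <- split(cleavage_sites$position, cleavage_sites$transcript_id)
    # sampler closes over the transcript's cleavage set via sequence lookup
    seq2tx <- haplotypes %>% dplyr::distinct(.data$sequence, .data$transcript_id)
    lookup <- stats::setNames(seq2tx$transcript_id, seq2tx$sequence)
    sampler <- function(sequence, n, tag_length) {
      pos <- cl[[lookup[[sequence]]]]
      pos <- pos[pos >= 1 & pos + tag_length - 1L <= nchar(sequence)]
      if (!length(pos)) return(uniform_start_sampler(sequence, n, tag_length))
      pos[sample.int(length(pos), n, replace = TRUE)]
    }
  } else {
    sampler <- uniform_start_sampler
  }
  simulate_tags(haplotypes, 20L, error_rate, n_tags, sampler,
                libraries, seed, keep_truth, abundance)
}

#' Normalise raw tag counts to transcripts per million
#'
#' TPM(tag) = raw_count / sum(raw_count) x 1e6, per library, so each
#' library's TPM values sum to 1e6.
#'
#' @param tags Tibble with columns `raw_count` and (optionally) `library_id`;
#'   normalisation is within library when the column is present.
#' @return The input with a `tpm` column added (replaced if present).
#' @examples
#' normalize_tpm(tibble::tibble(tag = c("a", "b"), raw_count = c(3, 1)))
#' @export
normalize_tpm <- function(tags) {
  if (any(tags$raw_count < 0)) abort("raw counts must be >= 0")
  grp <- if ("library_id" %in% names(tags)) "library_id" else character(0)
  out <- tags %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::mutate(tpm = {
      tot <- sum(.data$raw_count)
      if (tot <= 0) abort("all-zero library: cannot normalise to TPM")
      .data$raw_count / tot * 1e6
    }) %>%
    dplyr::ungroup()
  out
}

#' Generate a flat synthetic gene-to-GO map
#'
#' Assigns each term to a random subset of genes (flat map, no GO-graph
#' propagation). Deterministic given `seed`.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param n_terms Number of terms.
#' @param min_frac,max_frac Range of the fraction of genes carrying a term.
#' @param seed Integer seed.
#' @return Tibble: gene_id, term_id (one pair per row).
#' @export
generate_go_map <- function(gene_ids, n_terms = 12, min_frac = 0.05,
                            max_frac = 0.4, seed = 1) {
  with_seed0(seed, {
    purrr::map(seq_len(n_terms), function(i) {
      k <- max(1L, round(runif(1, min_frac, max_frac) * length(gene_ids)))
      tibble(gene_id = sample(gene_ids, k),
             term_id = sprintf("GO:%07d", i))
    }) %>% purrr::list_rbind()
  })
}

#' Enrich the sequence context around planted sites
#'
#' Rewrites the flanks around the given sites so that the probability of an
#' A decays with distance from the site:
#' P(A at offset d) = 0.25 + boost * exp(-|d| / decay), the remaining mass
#' split evenly over C/G/U. The site base itself (offset 0) is untouched.
#' Used to emulate the A-rich gradient observed around A-to-U sites.
#'
#' @param transcripts Tibble with transcript_id and sequence.
#' @param sites Tibble with transcript_id and position.
#' @param flank Half-window rewritten on each side.
#' @param decay Exponential decay length (nt).
#' @param boost Peak excess A probability at |d| = 1 (capped so P <= 1).
#' @param seed Integer seed.
#' @return `transcripts` with modified sequences.
#' @export
enrich_context <- function(transcripts, sites, flank = 50, decay = 12,
                           boost = 0.6, seed = 1) {
  with_seed0(seed, {
    seqs <- stats::setNames(transcripts$sequence, transcripts$transcript_id)
    for (i in seq_len(nrow(sites))) {
      tx <- sites$transcript_id[i]; pos <- sites$position[i]
      s <- seqs[[tx]]
      for (d in c(-(flank:1), 1:flank)) {
        p <- pos + d
        if (p < 1 || p > nchar(s)) next
        pa <- min(1, 0.25 + boost * exp(-abs(d) / decay))
        b <- if (runif(1) < pa) "A" else sample(c("C", "G", "U"), 1)
        substr(s, p, p) <- b
      }
      seqs[[tx]] <- s
    }
    transcripts$sequence <- unname(seqs[transcripts$transcript_id])
    transcripts
  })
}
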