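#' Apply editing events to pre-miRNA sequences
#'
#' Applies all of each hairpin's edits simultaneously (length is unchanged;
#' only substitutions are modelled). Events whose from-base does not match
#' the reference, or conflicting events (two different target bases at one
#' position), raise an error naming the offender. Edits falling inside the
#' annotated mature-miRNA interval are flagged.
#'
#' @param premirnas Tibble with premirna_id, sequence and (optionally)
#'   mature_start, mature_end (e.g. `transcriptome$premirnas`).
#' @param sites Tibble with premirna_id (or target_id), position, from
#'   (or ref_base), to (or read_base).
#' @return Tibble: premirna_id, sequence (edited), n_edits, edits_in_mature.
#'   Hairpins without events are returned unchanged.
#' @export
apply_edits <- function(premirnas, sites) {
  nm <- names(sites)
  if (!"premirna_id" %in% nm && "target_id" %in% nm) {
    sites <- dplyr::rename(sites, premirna_id = "target_id")
  }
  if (!"from" %in% names(sites) && "ref_base" %in% names(sites)) {
    sites <- dplyr::rename(sites, from = "ref_base", to = "read_base")
  }
  dup <- sites %>%
    dplyr::distinct(.data$premirna_id, .data$position, .data$to) %>%
    dplyr::count(.data$premirna_id, .data$position) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("conflicting edits at %s:%d", dup$premirna_id[1], dup$position[1]))
  }
  ed <- sites %>% dplyr::distinct(.data$premirna_id, .data$position, .data$from, .data$to)
  out <- premirnas
  out$n_edits <- 0L
  out$edits_in_mature <- 0L
  has_mature <- all(c("mature_start", "mature_end") %in% names(premirnas))
  for (i in seq_len(nrow(out))) {
    ev <- ed[ed$premirna_id == out$premirna_id[i], ]
    if (nrow(ev) == 0) next
    s <- out$sequence[i]
    refb <- substr(rep(s, nrow(ev)), ev$position, ev$position)
    # a base already equal to `to` is an edit applied before: no-op (idempotent)
    bad <- refb != ev$from & refb != ev$to
    if (any(bad)) {
      abort(sprintf("from-base mismatch for edit %s:%d (%s given, reference is %s)",
                    ev$premirna_id[bad][1], ev$position[bad][1],
                    ev$from[bad][1], refb[bad][1]))
    }
    for (j in seq_len(nrow(ev))) substr(s, ev$position[j], ev$position[j]) <- ev$to[j]
    out$sequence[i] <- s
    out$n_edits[i] <- nrow(ev)
    if (has_mature) {
      out$edits_in_mature[i] <- sum(ev$position >= out$mature_start[i] &
                                      ev$position <= out$mature_end[i])
    }
  }
  out
}

# base-pair set of a dot-bracket string as a 2-column matrix (i < j)
dotbracket_pairs <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  if (!all(chars %in% c("(", ")", "."))) {
    abort("dot-bracket string may contain only '(', ')' and '.'")
  }
  stack <- integer(0)
  pairs <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) abort("unbalanced dot-bracket string: unmatched ')'")
      pairs[[length(pairs) + 1]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) abort("unbalanced dot-bracket string: unmatched '('")
  if (length(pairs) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

#' Compare pre-miRNA secondary structures before and after editing
#'
#' Takes two externally folded dot-bracket strings (e.g. from an MFE folder;
#' folding itself is not performed here), computes their base-pair sets by
#' bracket matching, and reports the pairs lost and gained by editing plus
#' the net change in pairs touching the mature-miRNA interval.
#'
#' @param before,after Dot-bracket strings of equal length.
#' @param mature_interval Optional length-2 vector (1-based closed interval)
#'   of the mature miRNA within the hairpin.
#' @return One-row tibble: n_pairs_before, n_pairs_after, pairs_lost,
#'   pairs_gained, mature_region_pairs_delta (NA without an interval).
#' @examples
#' compare_structures("((..))", "......")
#' @export
compare_structures <- function(before, after, mature_interval = NULL) {
  if (nchar(before) != nchar(after)) {
    abort("before/after structures must have equal length")
  }
  pb <- dotbracket_pairs(before)
  pa <- dotbracket_pairs(after)
  key <- function(m) if (nrow(m)) paste(m[, 1], m[, 2]) else character(0)
  kb <- key(pb); ka <- key(pa)
  delta <- NA_integer_
  if (!is.null(mature_interval)) {
    touches <- function(m) {
      if (!nrow(m)) return(0L)
      sum((m[, 1] >= mature_interval[1] & m[, 1] <= mature_interval[2]) |
            (m[, 2] >= mature_interval[1] & m[, 2] <= mature_interval[2]))
    }
    delta <- touches(pa) - touches(pb)
  }
  tibble(n_pairs_before = length(kb), n_pairs_after = length(ka),
         pairs_lost = length(setdiff(kb, ka)),
         pairs_gained = length(setdiff(ka, kb)),
         mature_region_pairs_delta = delta)
}

#' Read a Vienna-format file (FASTA header, sequence line, structure line)
#'
#' @param path Vienna file: records of `>id`, sequence, dot-bracket
#'   structure (energy annotations after the structure are dropped).
#' @return Tibble: id, sequence (RNA alphabet), structure.
#' @export
read_vienna <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(lines) == 0 || length(lines) %% 3 != 0 ||
      !identical(heads, as.integer(seq(1, length(lines), by = 3)))) {
    abort("malformed Vienna file: expected >id / sequence / structure triplets")
  }
  purrr::map(heads, function(i) {
    struct <- sub("\\s+\\(.*\\)\\s*$", "", lines[i + 2])
    tibble(id = sub("^>\\s*", "", lines[i]),
           sequence = dna_to_rna(lines[i + 1]),
           structure = struct)
  }) %>% purrr::list_rbind()
}
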