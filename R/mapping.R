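#' Build a one-mismatch lookup index over target sequences
#'
#' Indexes every length-`tag_length` window of the targets for exact lookup,
#' plus every half-tag window for seed-and-extend one-mismatch lookup: a tag
#' aligned with a single mismatch matches at least one of its two halves
#' exactly, so the union of the half-seed candidates contains every
#' one-mismatch location, and a Hamming check over the handful of candidates
#' confirms it. Lookup cost is therefore independent of total target length.
#'
#' @param targets Tibble with columns target_id, sequence and (optionally)
#'   target_class; e.g. [targets_table()].
#' @param tag_length Tag length (17 or 20 nt).
#' @return A `tag_index` object.
#' @examples
#' idx <- build_tag_index(
#'   tibble::tibble(target_id = "t1", sequence = "ACGUACGUACGUACGUACGUA"),
#'   tag_length = 17)
#' @export
build_tag_index <- function(targets, tag_length) {
  if (nrow(targets) == 0) abort("empty target set")
  short <- nchar(targets$sequence) < tag_length
  if (any(short)) {
    warn(sprintf("%d target(s) shorter than tag_length dropped from the index",
                 sum(short)))
    targets <- targets[!short, ]
    if (nrow(targets) == 0) abort("empty target set (all targets shorter than tag_length)")
  }
  assert_rna(targets$sequence, "target sequence")
  L <- as.integer(tag_length)
  h1 <- as.integer(ceiling(L / 2))
  seqs <- targets$sequence

  window_table <- function(width, offset = 0L) {
    # all windows of `width` whose implied tag alignment starts in-bounds
    purrr::imap(seqs, function(s, i) {
      n_start <- nchar(s) - L + 1L
      starts <- seq_len(n_start) + offset
      tibble(key = substring(s, starts, starts + width - 1L),
             target = i, start = seq_len(n_start))
    }) %>% purrr::list_rbind()
  }
  to_env <- function(tbl) {
    packed <- split(as.integer(rbind(tbl$target, tbl$start)),
                    rep(tbl$key, each = 2))
    # interleaved (target, start) pairs keyed by window sequence
    list2env(packed, envir = new.env(parent = emptyenv(), size = length(packed)))
  }
  structure(list(
    target_id = targets$target_id,
    target_class = if ("target_class" %in% names(targets)) targets$target_class
                   else rep(NA_character_, nrow(targets)),
    sequence = seqs,
    tag_length = L,
    h1 = h1,
    exact = to_env(window_table(L)),
    seed_a = to_env(window_table(h1)),
    seed_b = to_env(window_table(L - h1, offset = h1))
  ), class = "tag_index")
}

#' @export
print.tag_index <- function(x, ...) {
  cat(sprintf("<tag_index> %d targets, tag length %d nt\n",
              length(x$target_id), x$tag_length))
  invisible(x)
}

# all alignments of one tag against the index: exact hits, else 1-mismatch hits
lookup_tag <- function(tag, index) {
  ex <- get0(tag, envir = index$exact, ifnotfound = NULL)
  if (!is.null(ex)) {
    m <- matrix(ex, ncol = 2, byrow = TRUE)
    return(list(status = "perfect", target = m[, 1], start = m[, 2],
                offset = NA_integer_))
  }
  h1 <- index$h1; L <- index$tag_length
  ca <- get0(substr(tag, 1L, h1), envir = index$seed_a, ifnotfound = NULL)
  cb <- get0(substr(tag, h1 + 1L, L), envir = index$seed_b, ifnotfound = NULL)
  cand <- unique(rbind(
    if (!is.null(ca)) matrix(ca, ncol = 2, byrow = TRUE),
    if (!is.null(cb)) matrix(cb, ncol = 2, byrow = TRUE)
  ))
  if (is.null(cand) || nrow(cand) == 0) {
    return(list(status = "unmapped", target = integer(0), start = integer(0),
                offset = integer(0)))
  }
  hits_t <- integer(0); hits_s <- integer(0); hits_o <- integer(0)
  traw <- charToRaw(tag)
  for (j in seq_len(nrow(cand))) {
    i <- cand[j, 1]; st <- cand[j, 2]
    win <- substr(index$sequence[i], st, st + L - 1L)
    d <- which(charToRaw(win) != traw)
    if (length(d) == 1L) {
      hits_t <- c(hits_t, i); hits_s <- c(hits_s, st); hits_o <- c(hits_o, d - 1L)
    }
  }
  if (length(hits_t) == 0L) {
    list(status = "unmapped", target = integer(0), start = integer(0),
         offset = integer(0))
  } else if (length(hits_t) > 1L) {
    list(status = "ambiguous", target = hits_t, start = hits_s, offset = hits_o)
  } else {
    list(status = "mismatch", target = hits_t, start = hits_s, offset = hits_o)
  }
}

#' Map a tag library against an index
#'
#' Implements the mismatch-pool logic of the editing search: a tag with at
#' least one perfect hit is removed from editing evidence (it only yields
#' `perfect` alignment rows, one per hit); a tag with no perfect hit and a
#' unique one-mismatch location yields one `mismatch` row carrying the
#' mismatched transcript position, reference and read base and the derived
#' editing pattern; one-mismatch tags hitting several distinct locations are
#' `ambiguous` (discarded from evidence, kept for audit); everything else is
#' `unmapped`. Every input tag lands in exactly one category.
#'
#' @param tags Tibble with columns tag and (optionally) library_id,
#'   raw_count, tpm — e.g. a [simulate_mpss_library()] result.
#' @param index A [build_tag_index()] object.
#' @return Tibble: original columns plus status
#'   (`perfect`/`mismatch`/`ambiguous`/`unmapped`), target_id, target_class,
#'   start, mismatch_offset (0-based within the tag), position (1-based
#'   transcript coordinate of the mismatch), ref_base, read_base, pattern.
#'   Perfect tags with several hits occupy several rows; ambiguous and
#'   unmapped tags one row with NA coordinates.
#' @export
map_tags <- function(tags, index) {
  stopifnot(inherits(index, "tag_index"))
  L <- index$tag_length
  if (nrow(tags) && !all(nchar(tags$tag) == L)) {
    abort(sprintf("all tags must have length %d to match the index", L))
  }
  uniq <- unique(tags$tag)
  n_u <- length(uniq)
  status <- character(n_u)
  hit_target <- vector("list", n_u)
  hit_start <- vector("list", n_u)
  hit_offset <- vector("list", n_u)
  for (i in seq_len(n_u)) {
    hit <- lookup_tag(uniq[i], index)
    status[i] <- hit$status
    if (hit$status == "perfect") {
      hit_target[[i]] <- hit$target
      hit_start[[i]] <- hit$start
      hit_offset[[i]] <- rep(NA_integer_, length(hit$target))
    } else if (hit$status == "mismatch") {
      hit_target[[i]] <- hit$target
      hit_start[[i]] <- hit$start
      hit_offset[[i]] <- hit$offset
    } else { # ambiguous / unmapped: one NA row
      hit_target[[i]] <- NA_integer_
      hit_start[[i]] <- NA_integer_
      hit_offset[[i]] <- NA_integer_
    }
  }
  n_rows <- lengths(hit_target)
  ti <- unlist(hit_target)
  st <- as.integer(unlist(hit_start))
  off <- as.integer(unlist(hit_offset))
  tag_rep <- rep(uniq, n_rows)
  status_rep <- rep(status, n_rows)
  is_mm <- status_rep == "mismatch"
  pos <- ifelse(is_mm, st + off, NA_integer_)
  ref <- rep(NA_character_, length(pos))
  read <- rep(NA_character_, length(pos))
  if (any(is_mm)) {
    ref[is_mm] <- substr(index$sequence[ti[is_mm]], pos[is_mm], pos[is_mm])
    read[is_mm] <- substr(tag_rep[is_mm], off[is_mm] + 1L, off[is_mm] + 1L)
  }
  per_tag <- tibble(
    tag = tag_rep, status = status_rep,
    target_id = ifelse(is.na(ti), NA_character_, index$target_id[ti]),
    target_class = ifelse(is.na(ti), NA_character_, index$target_class[ti]),
    start = st, mismatch_offset = off, position = as.integer(pos),
    ref_base = ref, read_base = read,
    pattern = ifelse(is_mm, paste0(ref, "-to-", read), NA_character_)
  )
  n_amb <- sum(per_tag$status == "ambiguous")
  if (n_amb > 0) {
    inform(sprintf("%d tag(s) with multi-locus one-mismatch hits discarded as ambiguous",
                   n_amb))
  }
  dplyr::inner_join(tags, per_tag, by = "tag", relationship = "many-to-many")
}
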