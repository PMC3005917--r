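# shared fixtures and independent oracles, all built in code

# small deterministic transcriptome
tiny_transcriptome <- function(seed = 101, n = 6, n_premirnas = 2,
                               n_libraries = 3) {
  generate_transcriptome(synthetic_config(
    n_transcripts = n, transcript_length_range = c(300, 600),
    n_premirnas = n_premirnas, n_libraries = n_libraries, seed = seed))
}

# a hand-built single-transcript "transcriptome" with known structure:
# 5'UTR 1..6 | CDS 7..15 (AUG ACG UAA) | 3'UTR 16..24, two exons 1..10, 11..24
fixed_transcript <- function() {
  seqn <- paste0("CCCCCC", "AUGACGUAA", "CCCCCCCCC")
  list(
    transcripts = tibble::tibble(
      transcript_id = "FX1", compartment = "nuclear",
      length = nchar(seqn), cds_start = 7L, cds_end = 15L, sequence = seqn),
    features = tibble::tibble(
      transcript_id = "FX1",
      feature = c("exon", "exon", "five_prime_UTR", "CDS", "three_prime_UTR"),
      start = c(1L, 11L, 1L, 7L, 16L),
      end = c(10L, 24L, 6L, 15L, 24L))
  )
}

# brute-force Hamming mapper: every window of every target, exact scan
brute_force_map <- function(tag, targets) {
  L <- nchar(tag)
  traw <- charToRaw(tag)
  hits0 <- list(); hits1 <- list()
  for (i in seq_len(nrow(targets))) {
    s <- targets$sequence[i]
    if (nchar(s) < L) next
    sraw <- charToRaw(s)
    for (st in seq_len(nchar(s) - L + 1L)) {
      d <- sum(sraw[st:(st + L - 1L)] != traw)
      if (d == 0L) hits0[[length(hits0) + 1]] <- c(i, st)
      if (d == 1L) hits1[[length(hits1) + 1]] <- c(i, st)
    }
  }
  list(perfect = do.call(rbind, hits0), mismatch = do.call(rbind, hits1))
}

# naive O(n^3) average-linkage agglomeration over a distance matrix;
# returns the cophenetic distance matrix it implies
naive_average_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  dd <- d
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1L)) {
        if (dd[active[b], active[a]] < bestd) {
          bestd <- dd[active[b], active[a]]
          best <- c(active[b], active[a])
        }
      }
    }
    i <- best[1]; j <- best[2]
    mi <- clusters[[i]]; mj <- clusters[[j]]
    coph[mi, mj] <- bestd; coph[mj, mi] <- bestd
    merged <- c(mi, mj)
    clusters[[i]] <- merged
    active <- setdiff(active, j)
    # average linkage: size-weighted mean of the two merged distances
    for (k in setdiff(active, i)) {
      dik <- dd[i, k]; djk <- dd[j, k]
      dd[i, k] <- dd[k, i] <-
        (length(mi) * dik + length(mj) * djk) / (length(mi) + length(mj))
    }
  }
  coph
}

# exhaustive hypergeometric upper tail by enumerating every draw of size n
enumerated_upper_tail <- function(k, K, N, n) {
  genes <- seq_len(N)
  term <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(draws %in% term, nrow = n))
  mean(hits >= k)
}

# brute-force codon-generation oracle: apply the pattern at every position
# of every codon and record the ones that land on the target
oracle_feasible <- function(target, pattern) {
  bases <- c("A", "C", "G", "U")
  from <- sub("-to-.*", "", pattern)
  to <- sub(".*-to-", "", pattern)
  all_codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  out <- character(0)
  for (cdn in all_codons) {
    for (i in 1:3) {
      if (substr(cdn, i, i) == from) {
        edited <- cdn
        substr(edited, i, i) <- to
        if (edited == target) out <- c(out, cdn)
      }
    }
  }
  sort(unique(out))
}
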