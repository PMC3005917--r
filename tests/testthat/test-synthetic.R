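test_that("transcriptome generation is deterministic and respects the config", {
  cfg <- synthetic_config(n_transcripts = 8, n_premirnas = 3, seed = 1)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$features, b$features)
  expect_identical(a$premirnas, b$premirnas)

  empty <- generate_transcriptome(synthetic_config(n_transcripts = 0,
                                                   n_premirnas = 0, seed = 1))
  expect_identical(nrow(empty$transcripts), 0L)
  expect_identical(nrow(empty$premirnas), 0L)

  nuc <- generate_transcriptome(synthetic_config(
    n_transcripts = 10, compartment_fractions = c(nuclear = 1), seed = 2))
  expect_true(all(nuc$transcripts$compartment == "nuclear"))

  expect_error(synthetic_config(transcript_length_range = c(500, 100)),
               "degenerate")
  expect_error(synthetic_config(tag_length = 19), "17 or 20")
  expect_error(synthetic_config(compartment_fractions = c(nuclear = 0.7)),
               "sum to 1")
})

test_that("generated transcripts have a well-formed CDS and exon cover", {
  tx <- tiny_transcriptome(seed = 3)
  cds_len <- tx$transcripts$cds_end - tx$transcripts$cds_start + 1L
  expect_true(all(cds_len %% 3 == 0))
  starts <- substring(tx$transcripts$sequence, tx$transcripts$cds_start,
                      tx$transcripts$cds_start + 2L)
  stops <- substring(tx$transcripts$sequence, tx$transcripts$cds_end - 2L,
                     tx$transcripts$cds_end)
  expect_true(all(starts == "AUG"))
  expect_true(all(stops %in% c("UAA", "UAG", "UGA")))
  # exons tile the transcript without gaps or overlaps
  exons <- dplyr::filter(tx$features, feature == "exon")
  for (id in tx$transcripts$transcript_id) {
    e <- dplyr::arrange(dplyr::filter(exons, transcript_id == id), start)
    expect_identical(e$start[1], 1L)
    expect_identical(e$end[nrow(e)],
                     tx$transcripts$length[tx$transcripts$transcript_id == id])
    if (nrow(e) > 1) expect_true(all(e$start[-1] == e$end[-nrow(e)] + 1L))
  }
  expect_true(all(tx$premirnas$length >= 70 & tx$premirnas$length <= 200))
  expect_true(all(tx$premirnas$mature_end <= tx$premirnas$length))
})

test_that("planting events yields product-mixture haplotype weights", {
  tx <- tibble::tibble(transcript_id = "t1",
                       sequence = paste(rep("ACGU", 25), collapse = ""))
  # single event, ratio 0.5 -> two haplotypes at 0.5 / 0.5
  ev1 <- tibble::tibble(transcript_id = "t1", position = 2, from = "C",
                        to = "U", ratio = 0.5)
  h1 <- plant_events(tx, ev1, libraries = "libA")
  expect_identical(nrow(h1), 2L)
  expect_equal(sort(h1$weight), c(0.5, 0.5))
  expect_identical(substr(h1$sequence[h1$haplotype_id != "ref"], 2, 2), "U")
  expect_identical(substr(h1$sequence[h1$haplotype_id == "ref"], 2, 2), "C")

  # from-base mismatch names the offending event
  expect_error(plant_events(tx, tibble::tibble(
    transcript_id = "t1", position = 1, from = "C", to = "U", ratio = 0.5),
    libraries = "libA"), "t1:1")

  # three events: weights equal the brute-force product over all 8 subsets
  ev3 <- tibble::tibble(transcript_id = "t1", position = c(2, 6, 10),
                        from = "C", to = "U", ratio = c(0.2, 0.5, 0.9))
  h3 <- plant_events(tx, ev3, libraries = "libA")
  expect_identical(nrow(h3), 8L)
  expect_equal(sum(h3$weight), 1)
  r <- c(0.2, 0.5, 0.9)
  manual <- c()
  for (m in 0:7) {
    on <- as.logical(bitwAnd(m, c(1L, 2L, 4L)))
    manual <- c(manual, prod(ifelse(on, r, 1 - r)))
  }
  expect_equal(sort(h3$weight), sort(manual))
  # weights match the edited bases they describe
  for (i in seq_len(nrow(h3))) {
    edited <- substr(h3$sequence[i], 2, 2) == "U"
    w_ref <- if (edited) 0.2 else 0.8
    expect_true(abs(h3$weight[i] / w_ref -
                      prod(ifelse(c(substr(h3$sequence[i], 6, 6) == "U",
                                    substr(h3$sequence[i], 10, 10) == "U"),
                                  r[2:3], 1 - r[2:3]))) < 1e-12)
  }
})

test_that("tag emission respects the error model at the extremes", {
  cfg <- synthetic_config(n_transcripts = 3, n_libraries = 1,
                          transcript_length_range = c(300, 400),
                          n_premirnas = 0, seed = 4)
  txo <- generate_transcriptome(cfg)
  haps <- plant_events(txo$transcripts,
                       tibble::tibble(transcript_id = character(),
                                      position = integer(), from = character(),
                                      to = character(), ratio = double()),
                       libraries = "lib01")
  # error rate 0: every tag is an exact substring of some haplotype
  t0 <- simulate_mpss_library(haps, cfg, anchoring = "uniform", n_tags = 500,
                              error_rate = 0, seed = 5)
  expect_true(all(vapply(t0$tag, function(tg)
    any(grepl(tg, haps$sequence, fixed = TRUE)), logical(1))))
  expect_true(all(nchar(t0$tag) == cfg$tag_length))

  # error rate 1: every tag differs from its source at exactly one position
  t1 <- simulate_mpss_library(haps, cfg, anchoring = "uniform", n_tags = 500,
                              error_rate = 1, seed = 6, keep_truth = TRUE)
  truth <- attr(t1, "truth")
  d <- mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
              truth$tag, truth$source)
  expect_true(all(d == 1))

  # determinism under a fixed seed
  t0b <- simulate_mpss_library(haps, cfg, anchoring = "uniform", n_tags = 500,
                               error_rate = 0, seed = 5)
  expect_identical(t0, t0b)
})

test_that("GATC anchoring starts tags immediately 3' of the motif", {
  s <- paste0(strrep("A", 40), "GAUC", strrep("CGU", 20), strrep("A", 30))
  tx <- tibble::tibble(transcript_id = "t1", sequence = s)
  haps <- plant_events(tx, tibble::tibble(transcript_id = character(),
                                          position = integer(),
                                          from = character(), to = character(),
                                          ratio = double()),
                       libraries = "lib01")
  cfg <- synthetic_config(n_transcripts = 1, seed = 7)
  tags <- simulate_mpss_library(haps, cfg, anchoring = "gatc", n_tags = 50,
                                error_rate = 0, seed = 7)
  anchor <- substr(s, 45, 45 + 19)
  expect_true(all(tags$tag == anchor))
})

test_that("PARE simulation uses cleavage positions and the empty set", {
  set.seed(81)
  tx <- tibble::tibble(transcript_id = "t1",
                       sequence = paste(sample(c("A", "C", "G", "U"), 200, TRUE),
                                        collapse = ""))
  haps <- plant_events(tx, tibble::tibble(transcript_id = character(),
                                          position = integer(),
                                          from = character(), to = character(),
                                          ratio = double()),
                       libraries = "lib01")
  cfg <- synthetic_config(n_transcripts = 1, seed = 8)
  cl <- tibble::tibble(transcript_id = "t1", position = 17L)
  tags <- simulate_pare_library(haps, cfg, cleavage_sites = cl, n_tags = 30,
                                error_rate = 0, seed = 8)
  expect_true(all(tags$tag == substr(tx$sequence, 17, 36)))
  empty <- simulate_pare_library(haps, cfg,
                                 cleavage_sites = cl[0, ], n_tags = 30)
  expect_identical(nrow(empty), 0L)
})

test_that("TPM normalisation is exact and conserves 1e6 per library", {
  expect_equal(normalize_tpm(tibble::tibble(tag = c("a", "b"),
                                            raw_count = c(3, 1)))$tpm,
               c(750000, 250000))
  expect_equal(normalize_tpm(tibble::tibble(tag = "a", raw_count = 7))$tpm, 1e6)
  expect_equal(normalize_tpm(tibble::tibble(tag = c("a", "b", "c"),
                                            raw_count = c(1, 1, 2)))$tpm,
               c(250000, 250000, 500000))
  expect_error(normalize_tpm(tibble::tibble(tag = "a", raw_count = 0)),
               "all-zero")
  multi <- tibble::tibble(library_id = rep(c("l1", "l2"), each = 3),
                          tag = rep(c("a", "b", "c"), 2),
                          raw_count = c(1, 2, 3, 10, 0, 30))
  tot <- dplyr::summarise(dplyr::group_by(normalize_tpm(multi), library_id),
                          s = sum(tpm))
  expect_true(all(abs(tot$s - 1e6) < 0.5))
})

test_that("with no errors and ratio 1, tags spanning the site carry the edit", {
  set.seed(123)
  tx <- tibble::tibble(transcript_id = "t1",
                       sequence = paste(sample(c("A", "C", "G", "U"), 300, TRUE),
                                        collapse = ""))
  pos <- 150L
  from <- substr(tx$sequence, pos, pos)
  to <- setdiff(c("A", "C", "G", "U"), from)[1]
  haps <- plant_events(tx, tibble::tibble(transcript_id = "t1", position = pos,
                                          from = from, to = to, ratio = 1),
                       libraries = "lib01")
  cfg <- synthetic_config(n_transcripts = 1, seed = 9)
  tags <- simulate_mpss_library(haps, cfg, anchoring = "uniform",
                                n_tags = 2000, error_rate = 0, seed = 9,
                                keep_truth = TRUE)
  # ratio 1 leaves only the edited haplotype in the mixture
  edited_seq <- haps$sequence[haps$haplotype_id != "ref"][1]
  truth <- attr(tags, "truth")
  ok <- vapply(truth$tag, function(tg) {
    st <- regexpr(tg, edited_seq, fixed = TRUE)
    if (st <= 0) return(FALSE)                    # must come from the edited haplotype
    if (st > pos || st + nchar(tg) - 1L < pos) return(TRUE)  # not spanning
    substr(tg, pos - st + 1L, pos - st + 1L) == to
  }, logical(1))
  expect_true(all(ok))
})

test_that("per-pattern corruption frequency matches rate/12 over 1e5 tags", {
  # single long uniform-composition haplotype, one library, no planted edits
  set.seed(10)
  tx <- tibble::tibble(transcript_id = "t1",
                       sequence = paste(sample(c("A", "C", "G", "U"), 10000,
                                               TRUE), collapse = ""))
  haps <- plant_events(tx, tibble::tibble(transcript_id = character(),
                                          position = integer(),
                                          from = character(), to = character(),
                                          ratio = double()),
                       libraries = "lib01")
  cfg <- synthetic_config(n_transcripts = 1, seed = 10)
  rate <- 0.05
  N <- 1e5
  tags <- simulate_mpss_library(haps, cfg, anchoring = "uniform", n_tags = N,
                                error_rate = rate, seed = 10, keep_truth = TRUE)
  truth <- attr(tags, "truth")
  counts <- tapply(truth$n, truth$pattern, sum)
  p <- rate / 12
  sigma <- sqrt(p * (1 - p) / N)
  for (pat in edit_patterns()) {
    obs <- if (pat %in% names(counts)) counts[[pat]] else 0
    expect_lt(abs(obs / N - p), 3 * sigma)
  }
})
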