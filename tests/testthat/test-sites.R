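mm_record <- function(target = "T1", class = "protein_coding", pos = 50,
                      ref = "C", read = "U", tag, lib = "lib01") {
  tibble::tibble(target_id = target, target_class = class,
                 position = as.integer(pos), ref_base = ref, read_base = read,
                 pattern = classify_pattern(ref, read), tag = tag,
                 library_id = lib, status = "mismatch")
}

test_that("sites aggregate by (target, position, pattern) with distinct-tag support", {
  six <- mm_record(tag = sprintf("TAG%02d", 1:6))
  s <- aggregate_sites(six)
  expect_identical(nrow(s), 1L)
  expect_identical(s$distinct_read_support, 6L)

  # the same tag sequence in three libraries counts once
  rep3 <- mm_record(tag = "SAMETAG", lib = "lib01")
  rep3 <- dplyr::bind_rows(rep3, mm_record(tag = "SAMETAG", lib = "lib02"),
                           mm_record(tag = "SAMETAG", lib = "lib03"))
  expect_identical(aggregate_sites(rep3)$distinct_read_support, 1L)

  # two patterns at one position form two sites; grouping matches brute force
  two <- dplyr::bind_rows(mm_record(ref = "C", read = "U", tag = "t1"),
                          mm_record(ref = "C", read = "G", tag = "t2"))
  s2 <- aggregate_sites(two)
  expect_identical(nrow(s2), 2L)
  brute <- unique(paste(two$target_id, two$position, two$pattern))
  expect_setequal(s2$site_id,
                  gsub(" ", "|", brute))
})

test_that("calling criteria follow the strict more-than reading", {
  crit <- calling_criteria()
  # 3 sites with support 6, 6, 7 -> all called
  s3 <- aggregate_sites(dplyr::bind_rows(
    mm_record(pos = 10, tag = sprintf("a%d", 1:6)),
    mm_record(pos = 20, tag = sprintf("b%d", 1:6)),
    mm_record(pos = 30, tag = sprintf("c%d", 1:7))))
  expect_identical(nrow(apply_criteria(s3, crit)), 3L)

  # 2 sites with support 10 each -> none (fails the >2-sites rule)
  s2 <- aggregate_sites(dplyr::bind_rows(
    mm_record(pos = 10, tag = sprintf("a%d", 1:10)),
    mm_record(pos = 20, tag = sprintf("b%d", 1:10))))
  expect_identical(nrow(apply_criteria(s2, crit)), 0L)

  # pre-miRNA site with support 3 -> called, no per-target minimum
  sm <- aggregate_sites(mm_record(target = "MIR1", class = "pre_miRNA",
                                  tag = sprintf("m%d", 1:3)))
  expect_identical(nrow(apply_criteria(sm, crit)), 1L)
  # support 2 is insufficient for a pre-miRNA
  sm2 <- aggregate_sites(mm_record(target = "MIR1", class = "pre_miRNA",
                                   tag = sprintf("m%d", 1:2)))
  expect_identical(nrow(apply_criteria(sm2, crit)), 0L)
})

test_that("calling is monotone in the thresholds", {
  set.seed(31)
  recs <- purrr::map(1:40, function(i) {
    mm_record(target = sample(sprintf("T%d", 1:5), 1),
              pos = sample(c(10, 20, 30, 40), 1),
              tag = paste(sample(letters, 8), collapse = ""))
  }) |> purrr::list_rbind()
  sites <- aggregate_sites(recs)
  base <- apply_criteria(sites, calling_criteria(min_sites_per_transcript = 1,
                                                 min_reads_per_site = 1))
  for (ms in 1:4) {
    for (mr in 1:4) {
      called <- apply_criteria(sites, calling_criteria(
        min_sites_per_transcript = ms, min_reads_per_site = mr))
      expect_true(all(called$site_id %in% base$site_id))
      stricter <- apply_criteria(sites, calling_criteria(
        min_sites_per_transcript = ms + 1, min_reads_per_site = mr))
      expect_true(all(stricter$site_id %in% called$site_id))
    }
  }
})

aln_row <- function(tag, status, start, tpm, pos = NA_integer_,
                    pattern = NA_character_, lib = "lib01", target = "T1") {
  tibble::tibble(library_id = lib, tag = tag, raw_count = 1L, tpm = tpm,
                 status = status, target_id = target,
                 target_class = "protein_coding", start = as.integer(start),
                 mismatch_offset = NA_integer_, position = as.integer(pos),
                 ref_base = NA_character_, read_base = NA_character_,
                 pattern = pattern)
}

test_that("editing ratios are TPM fractions of spanning reads", {
  site <- tibble::tibble(site_id = "T1|50|C-to-U", target_id = "T1",
                         position = 50L, pattern = "C-to-U")
  # edited TPM 5, perfect spanning TPM 95 -> 0.05
  aln <- dplyr::bind_rows(
    aln_row(strrep("A", 20), "mismatch", 40, 5, pos = 50, pattern = "C-to-U"),
    aln_row(strrep("C", 20), "perfect", 45, 95))
  r <- editing_ratio(site, aln)
  expect_equal(r$ratio, 0.05)

  # 1 edited tag among 8 spanning tags at equal TPM -> 0.125
  aln8 <- dplyr::bind_rows(
    aln_row("E", "mismatch", 40, 10, pos = 50, pattern = "C-to-U"),
    purrr::map(1:7, ~ aln_row(paste0("P", .x), "perfect", 35 + .x, 10)) |>
      purrr::list_rbind())
  aln8$tag <- paste0(aln8$tag, strrep("A", 20 - nchar(aln8$tag)))
  expect_equal(editing_ratio(site, aln8)$ratio, 0.125)

  # no spanning unedited tags -> ratio 1
  only_ed <- aln_row(strrep("G", 20), "mismatch", 40, 3, pos = 50,
                     pattern = "C-to-U")
  expect_equal(editing_ratio(site, only_ed)$ratio, 1)

  # non-spanning perfect tags do not enter the denominator
  far <- dplyr::bind_rows(only_ed, aln_row(strrep("U", 20), "perfect", 100, 50))
  expect_equal(editing_ratio(site, far)$ratio, 1)

  # zero coverage in a library is reported missing, not zero
  two_lib <- dplyr::bind_rows(only_ed,
                              aln_row(strrep("U", 20), "perfect", 100, 50,
                                      lib = "lib02"))
  r2 <- editing_ratio(site, two_lib)
  expect_true(is.na(r2$ratio[r2$library_id == "lib02"]))

  # other-pattern mismatches at the site count as edited only in "all" mode
  mixed <- dplyr::bind_rows(
    aln_row(strrep("G", 20), "mismatch", 40, 3, pos = 50, pattern = "C-to-U"),
    aln_row(strrep("U", 20), "mismatch", 42, 1, pos = 50, pattern = "C-to-G"))
  expect_equal(editing_ratio(site, mixed)$ratio, 3 / 4)
  expect_equal(editing_ratio(site, mixed, pattern_mode = "all")$ratio, 1)
})

test_that("ratios are bounded and monotone in edited TPM", {
  site <- tibble::tibble(site_id = "T1|50|C-to-U", target_id = "T1",
                         position = 50L, pattern = "C-to-U")
  last <- -1
  for (etpm in c(0.5, 1, 5, 20, 60)) {
    aln <- dplyr::bind_rows(
      aln_row(strrep("A", 20), "mismatch", 40, etpm, pos = 50,
              pattern = "C-to-U"),
      aln_row(strrep("C", 20), "perfect", 45, 40))
    r <- editing_ratio(site, aln)$ratio
    expect_true(r >= 0 && r <= 1)
    expect_gt(r, last)
    last <- r
  }
})

test_that("planted editing ratios are recovered within 0.05 at deep coverage", {
  set.seed(32)
  tx <- tibble::tibble(transcript_id = "t1",
                       sequence = paste(sample(c("A", "C", "G", "U"), 400, TRUE),
                                        collapse = ""))
  pos <- 200L
  from <- substr(tx$sequence, pos, pos)
  to <- setdiff(c("A", "C", "G", "U"), from)[1]
  planted <- 0.3
  haps <- plant_events(tx, tibble::tibble(transcript_id = "t1", position = pos,
                                          from = from, to = to,
                                          ratio = planted),
                       libraries = "lib01")
  cfg <- synthetic_config(n_transcripts = 1, seed = 33)
  tags <- simulate_mpss_library(haps, cfg, anchoring = "uniform",
                                n_tags = 10000, error_rate = 0, seed = 33)
  idx <- build_tag_index(tibble::tibble(target_id = "t1",
                                        target_class = "protein_coding",
                                        sequence = tx$sequence), 20)
  aln <- suppressMessages(map_tags(tags, idx))
  sites <- aggregate_sites(aln)
  sites <- sites[sites$position == pos, ]
  r <- editing_ratio(sites, aln)
  # condition: at least 200 raw spanning tags at the site
  spanning <- sum(aln$raw_count[aln$status %in% c("perfect", "mismatch") &
                                  !is.na(aln$start) &
                                  aln$start <= pos &
                                  aln$start + 19 >= pos])
  expect_gte(spanning, 200)
  expect_lt(abs(r$ratio - planted), 0.05)
})
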