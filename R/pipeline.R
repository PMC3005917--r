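#' Pipeline configuration
#'
#' Collects every knob of the end-to-end simulate -> map -> call -> cluster
#' -> annotate -> enrich driver.
#'
#' @param synthetic A [synthetic_config()] describing the simulated inputs.
#' @param criteria A [calling_criteria()].
#' @param clustering_threshold Minimum editing ratio for the tissue
#'   clustering filter (default 0.02).
#' @param flank Context-window flank in nt (default 50).
#' @param alpha Corrected-p cutoff for reporting enriched GO terms.
#' @param anchoring Tag anchoring mode for the simulator.
#' @param events Optional planted-event table (transcript_id, position,
#'   from, to, ratio); when `NULL` a small default set is planted.
#' @param outdir Output directory; `NULL` disables file output.
#' @param seed Master seed (overrides `synthetic$seed` when given).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            criteria = calling_criteria(),
                            clustering_threshold = 0.02,
                            flank = 50,
                            alpha = 1e-7,
                            anchoring = "uniform",
                            events = NULL,
                            outdir = NULL,
                            seed = NULL) {
  if (!is.null(seed)) synthetic$seed <- as.integer(seed)
  structure(list(synthetic = synthetic, criteria = criteria,
                 clustering_threshold = clustering_threshold,
                 flank = flank, alpha = alpha, anchoring = anchoring,
                 events = events, outdir = outdir,
                 seed = synthetic$seed),
            class = "pipeline_config")
}

# default planted events: a few C-to-U / A-to-G / U-to-C sites on the first
# transcripts, editable in every library at moderate ratios
default_events <- function(transcriptome, n_transcripts = 3, sites_per_tx = 3,
                           ratio = 0.4) {
  tx <- head(transcriptome$transcripts, n_transcripts)
  purrr::pmap(tx, function(transcript_id, compartment, length, cds_start,
                           cds_end, sequence) {
    pos <- round(seq(cds_start + 10, length - 60, length.out = sites_per_tx))
    from <- substring(sequence, pos, pos)
    to <- vapply(from, function(b) setdiff(RNA_BASES, b)[1], character(1))
    tibble(transcript_id = transcript_id, position = as.integer(pos),
           from = unname(from), to = unname(to), ratio = ratio)
  }) %>% purrr::list_rbind()
}

#' Run the full editing-discovery pipeline on synthetic data
#'
#' Generates a transcriptome, plants editing events, simulates tag
#' libraries, maps tags, calls sites, computes per-library editing ratios,
#' clusters the filtered ratio matrix, annotates codon effects and exon
#' boundaries, and runs GO enrichment against a synthetic gene-to-term map.
#' When `config$outdir` is set, the analogue output tables (sites TSV/BED,
#' ratio matrix, context windows FASTA, codon table, enrichment TSV, Newick
#' tree) and a JSON run manifest (seed, thresholds, config hash, stage-wise
#' counts) are written there. Deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with the intermediate and final
#'   tables and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  result <- tryCatch({
    scfg <- config$synthetic
    txome <- generate_transcriptome(scfg)
    libs <- library_ids(scfg$n_libraries)
    events <- config$events %||% default_events(txome)
    haps <- plant_events(txome$transcripts, events, libraries = libs)
    # pre-miRNA haplotypes: unedited reference hairpins in the tag pool
    mir_haps <- if (nrow(txome$premirnas)) {
      tidyr::crossing(
        txome$premirnas %>%
          dplyr::transmute(transcript_id = .data$premirna_id, .data$sequence,
                          haplotype_id = "ref",
                          edited_positions = list(integer(0))),
        library_id = libs) %>%
        dplyr::mutate(weight = 1)
    } else NULL
    tags <- simulate_mpss_library(dplyr::bind_rows(haps, mir_haps), scfg,
                                  anchoring = config$anchoring)

    stage <- "map"
    targets <- targets_table(txome)
    index <- build_tag_index(targets, scfg$tag_length)
    alignments <- map_tags(tags, index)

    stage <- "call"
    candidates <- aggregate_sites(alignments)
    called <- apply_criteria(candidates, config$criteria)
    ratios <- editing_ratio(called, alignments)

    stage <- "cluster"
    rmat <- filter_for_clustering(ratio_matrix(ratios),
                                  config$clustering_threshold)
    clust <- if (nrow(rmat) >= 2) cluster_sites(rmat) else NULL

    stage <- "annotate"
    effects <- annotate_codon_effect(called, txome$transcripts)
    codon_table <- summarize_codon_table(effects)
    coding_sites <- called %>% dplyr::filter(.data$target_class != "pre_miRNA")
    boundaries <- if (nrow(coding_sites)) {
      annotate_boundaries(coding_sites, txome)
    } else NULL
    windows <- if (nrow(coding_sites)) {
      extract_windows(coding_sites, txome$transcripts, flank = config$flank)
    } else NULL
    profile <- if (!is.null(windows) && nrow(windows)) {
      position_information(windows, flank = config$flank)
    } else NULL

    stage <- "enrich"
    go_map <- generate_go_map(txome$transcripts$transcript_id, seed = scfg$seed)
    edited_genes <- unique(coding_sites$target_id)
    enrichment <- if (length(edited_genes)) {
      hypergeom_enrich(edited_genes, txome$transcripts$transcript_id, go_map)
    } else NULL

    manifest <- list(
      package_version = as.character(utils::packageVersion("editscan")),
      seed = config$seed,
      config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
      tag_length = scfg$tag_length,
      per_signature_error_rate = scfg$per_signature_error_rate,
      clustering_threshold = config$clustering_threshold,
      alpha = config$alpha,
      criteria = unclass(config$criteria),
      counts = list(
        transcripts = nrow(txome$transcripts),
        premirnas = nrow(txome$premirnas),
        planted_events = nrow(events),
        tags = nrow(tags),
        perfect_tags = dplyr::n_distinct(alignments$tag[alignments$status == "perfect"]),
        mismatch_tags = sum(alignments$status == "mismatch"),
        ambiguous_tags = sum(alignments$status == "ambiguous"),
        unmapped_tags = sum(alignments$status == "unmapped"),
        candidate_sites = nrow(candidates),
        called_sites = nrow(called),
        clustered_sites = nrow(rmat)
      )
    )
    list(transcriptome = txome, events = events, tags = tags,
         alignments = alignments, candidates = candidates, sites = called,
         ratios = ratios, ratio_matrix = rmat, clustering = clust,
         codon_effects = effects, codon_table = codon_table,
         boundaries = boundaries, context_profile = profile,
         enrichment = enrichment, significant = if (!is.null(enrichment))
           flag_significant(enrichment, config$alpha) else NULL,
         manifest = manifest)
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })

  if (!is.null(config$outdir)) {
    dir <- config$outdir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(seed = as.character(config$seed),
             config_hash = result$manifest$config_hash)
    write_fasta(result$transcriptome$transcripts, file.path(dir, "transcripts.fasta"))
    if (nrow(result$transcriptome$premirnas)) {
      write_fasta(result$transcriptome$premirnas, file.path(dir, "premirnas.fasta"))
    }
    feats <- result$transcriptome$features %>%
      dplyr::left_join(result$transcriptome$transcripts %>%
                         dplyr::select("transcript_id", "compartment"),
                       by = "transcript_id")
    write_gff3(feats, file.path(dir, "transcripts.gff3"))
    write_tag_tsv(result$tags, file.path(dir, "tags"))
    write_sites_tsv(result$events, file.path(dir, "planted_events.tsv"), hdr)
    write_sites_tsv(result$sites, file.path(dir, "sites.tsv"), hdr)
    write_bed(result$sites, file.path(dir, "sites.bed"))
    write_sites_tsv(ratio_matrix(result$ratios), file.path(dir, "ratio_matrix.tsv"), hdr)
    write_sites_tsv(result$codon_table, file.path(dir, "codon_table.tsv"), hdr)
    if (!is.null(result$enrichment)) {
      write_sites_tsv(result$enrichment, file.path(dir, "enrichment.tsv"), hdr)
    }
    if (!is.null(result$clustering)) {
      write_newick(result$clustering, file.path(dir, "clustering.nwk"))
    }
    jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(result, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("<pipeline_result>\n")
  cat(sprintf("  transcripts: %d (+%d pre-miRNAs), planted events: %d\n",
              cnt$transcripts, cnt$premirnas, cnt$planted_events))
  cat(sprintf("  tags: %d rows; perfect %d, mismatch %d, ambiguous %d, unmapped %d\n",
              cnt$tags, cnt$perfect_tags, cnt$mismatch_tags,
              cnt$ambiguous_tags, cnt$unmapped_tags))
  cat(sprintf("  sites: %d candidates -> %d called -> %d clustered\n",
              cnt$candidate_sites, cnt$called_sites, cnt$clustered_sites))
  invisible(x)
}

#' Heat-map style plot of a clustered ratio matrix
#'
#' @param object An `edit_clust` object.
#' @param ... Unused.
#' @return A ggplot tile plot of the leaf-ordered ratio matrix.
#' @export
autoplot.edit_clust <- function(object, ...) {
  long <- as_tibble(object$matrix, rownames = "site_id") %>%
    dplyr::mutate(site_id = factor(.data$site_id, levels = rev(rownames(object$matrix)))) %>%
    tidyr::pivot_longer(-"site_id", names_to = "library_id", values_to = "ratio")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$library_id, y = .data$site_id,
                                     fill = .data$ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "editing ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Bar plot of called sites per editing pattern
#'
#' @param sites A site table with a `pattern` column.
#' @return A ggplot: number of sites per pattern over the 12 patterns.
#' @export
plot_pattern_counts <- function(sites) {
  counts <- sites %>%
    dplyr::count(pattern = factor(.data$pattern, levels = edit_patterns()),
                 .drop = FALSE)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$pattern, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "editing pattern", y = "called sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
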