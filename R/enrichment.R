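#' GO term enrichment of edited genes (hypergeometric test)
#'
#' For every term annotating at least one edited gene, computes the
#' one-sided hypergeometric upper-tail probability of drawing at least the
#' observed number of term-annotated genes when sampling the edited set from
#' the background, then corrects over the number of tested terms
#' (Bonferroni by default, Benjamini-Hochberg as an option). Also reports
#' the percentage of background/edited genes carrying the term.
#'
#' @param edited_genes Character vector of edited gene ids (must be a subset
#'   of `background_genes`, non-empty).
#' @param background_genes Character vector: the gene universe.
#' @param go_map Tibble with columns gene_id, term_id (flat map; no GO-graph
#'   propagation is applied).
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @return Tibble sorted by corrected p: term_id, n_background,
#'   n_background_with_term, n_edited, n_edited_with_term, pct_all,
#'   pct_edited, p_raw, p_corrected.
#' @examples
#' bg <- sprintf("g%02d", 1:20)
#' gm <- tibble::tibble(gene_id = bg[1:5], term_id = "GO:0000001")
#' hypergeom_enrich(bg[1:5], bg, gm)
#' @export
hypergeom_enrich <- function(edited_genes, background_genes, go_map,
                             correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  edited_genes <- unique(edited_genes)
  background_genes <- unique(background_genes)
  if (length(edited_genes) == 0) abort("empty edited gene set")
  if (!all(edited_genes %in% background_genes)) {
    abort("edited_genes must be a subset of background_genes")
  }
  gm <- go_map %>%
    dplyr::filter(.data$gene_id %in% background_genes) %>%
    dplyr::distinct(.data$gene_id, .data$term_id)
  N <- length(background_genes)
  n <- length(edited_genes)
  per_term <- gm %>%
    dplyr::group_by(.data$term_id) %>%
    dplyr::summarise(n_background_with_term = dplyr::n(),
                     n_edited_with_term = sum(.data$gene_id %in% edited_genes),
                     .groups = "drop") %>%
    dplyr::filter(.data$n_edited_with_term >= 1)
  if (nrow(per_term) == 0) {
    return(tibble(term_id = character(), n_background = integer(),
                  n_background_with_term = integer(), n_edited = integer(),
                  n_edited_with_term = integer(), pct_all = double(),
                  pct_edited = double(), p_raw = double(),
                  p_corrected = double()))
  }
  p_raw <- phyper(per_term$n_edited_with_term - 1,
                  per_term$n_background_with_term,
                  N - per_term$n_background_with_term,
                  n, lower.tail = FALSE)
  p_corr <- if (correction == "bonferroni") {
    pmin(1, p_raw * nrow(per_term))
  } else {
    p.adjust(p_raw, method = "BH")
  }
  per_term %>%
    dplyr::mutate(n_background = N, n_edited = n,
                  pct_all = .data$n_background_with_term / N,
                  pct_edited = .data$n_edited_with_term / n,
                  p_raw = p_raw, p_corrected = p_corr) %>%
    dplyr::select("term_id", "n_background", "n_background_with_term",
                  "n_edited", "n_edited_with_term", "pct_all", "pct_edited",
                  "p_raw", "p_corrected") %>%
    dplyr::arrange(.data$p_corrected, .data$p_raw)
}

#' Keep significantly enriched terms
#'
#' Retains results with corrected p strictly below `alpha` (default 1e-7,
#' the stringent cutoff used for reporting enriched GO terms).
#'
#' @param results A [hypergeom_enrich()] result.
#' @param alpha Significance threshold (strict <).
#' @return The significant subset of `results`.
#' @export
flag_significant <- function(results, alpha = 1.0e-7) {
  dplyr::filter(results, .data$p_corrected < alpha)
}

#' Plot enrichment percentages
#'
#' @param object A [hypergeom_enrich()] result (tibble); pass through
#'   [flag_significant()] first to restrict to significant terms.
#' @param ... Unused.
#' @return A ggplot comparing the per-term percentage of edited vs all genes.
#' @export
plot_enrichment <- function(object, ...) {
  long <- object %>%
    dplyr::select("term_id", "pct_all", "pct_edited") %>%
    tidyr::pivot_longer(c("pct_all", "pct_edited"),
                        names_to = "set", values_to = "pct") %>%
    dplyr::mutate(set = dplyr::recode(.data$set, pct_all = "all genes",
                                      pct_edited = "edited genes"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$term_id, y = .data$pct,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "genes with term", fill = NULL) +
    ggplot2::theme_minimal()
}
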