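#' Site x library editing-ratio matrix
#'
#' Pivots the long per-library ratios into a wide matrix-like tibble (one
#' row per site, one column per library) for filtering and clustering.
#'
#' @param ratios An [editing_ratio()] result.
#' @return Tibble: site_id plus one numeric column per library (NA where the
#'   site had no spanning coverage in that library).
#' @export
ratio_matrix <- function(ratios) {
  ratios %>%
    dplyr::select("site_id", "library_id", "ratio") %>%
    tidyr::pivot_wider(names_from = "library_id", values_from = "ratio") %>%
    dplyr::arrange(.data$site_id)
}

#' Filter sites for clustering by minimum editing ratio
#'
#' Keeps the rows whose editing ratio exceeds `threshold` in at least one
#' library (strict >, so a row whose maximum is exactly the threshold is
#' dropped). The 2% default suppresses rows compatible with sequencing
#' error alone. The filter is idempotent.
#'
#' @param matrix A [ratio_matrix()] tibble.
#' @param threshold Ratio cutoff in `[0, 1]` (default 0.02).
#' @return The retained rows of `matrix`.
#' @export
filter_for_clustering <- function(matrix, threshold = 0.02) {
  if (threshold < 0 || threshold > 1) abort("threshold must lie in [0, 1]")
  vals <- as.matrix(matrix[setdiff(names(matrix), "site_id")])
  keep <- apply(vals, 1, function(r) any(r > threshold, na.rm = TRUE))
  matrix[keep, , drop = FALSE]
}

# pairwise-complete correlation distance; degenerate rows get distance 1
correlation_distance <- function(m, metric) {
  if (metric == "pearson") {
    r <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  } else { # uncentered correlation (Cluster 3.0's default similarity)
    n <- nrow(m)
    r <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
      for (j in i:n) {
        ok <- !is.na(m[i, ]) & !is.na(m[j, ])
        den <- sqrt(sum(m[i, ok]^2) * sum(m[j, ok]^2))
        r[i, j] <- r[j, i] <- if (any(ok) && den > 0)
          sum(m[i, ok] * m[j, ok]) / den else NA_real_
      }
    }
  }
  d <- 1 - r
  degenerate <- !is.finite(d)
  if (any(degenerate[upper.tri(degenerate)])) {
    inform(sprintf(
      "%d site pair(s) with undefined correlation (zero variance or no shared coverage) set to distance 1",
      sum(degenerate[upper.tri(degenerate)])))
    d[degenerate] <- 1
  }
  diag(d) <- 0
  d
}

#' Hierarchically cluster editing sites across libraries
#'
#' Agglomerative clustering of the filtered ratio matrix with distance
#' 1 - correlation (centred Pearson by default; uncentred correlation is
#' the alternative) and average linkage. Correlations use pairwise-complete
#' observations; rows with undefined correlation to a partner (zero
#' variance, no shared coverage) get distance 1 to it.
#'
#' @param matrix A [ratio_matrix()] tibble with >= 2 rows.
#' @param metric `"pearson"` (default) or `"uncentered"`.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return An object of class `edit_clust`: the [stats::hclust()] tree, the
#'   row-reordered matrix, leaf order and labels. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
cluster_sites <- function(matrix, metric = c("pearson", "uncentered"),
                          linkage = "average") {
  metric <- match.arg(metric)
  m <- as.matrix(matrix[setdiff(names(matrix), "site_id")])
  rownames(m) <- matrix$site_id
  if (nrow(m) < 2) abort("need at least 2 sites to cluster")
  d <- correlation_distance(m, metric)
  hc <- hclust(as.dist(d), method = linkage)
  structure(list(
    hclust = hc,
    matrix = m[hc$order, , drop = FALSE],
    leaf_order = rownames(m)[hc$order],
    labels = rownames(m),
    metric = metric,
    linkage = linkage
  ), class = "edit_clust")
}

#' @export
print.edit_clust <- function(x, ...) {
  cat(sprintf("<edit_clust> %d sites x %d libraries, 1 - %s correlation, %s linkage\n",
              nrow(x$matrix), ncol(x$matrix), x$metric, x$linkage))
  invisible(x)
}

#' @rdname cluster_sites
#' @param x,object An `edit_clust` object.
#' @param ... Unused.
#' @export
tidy.edit_clust <- function(x, ...) {
  hc <- x$hclust
  tibble(merge_step = seq_len(nrow(hc$merge)),
         height = hc$height,
         left = hc$merge[, 1],
         right = hc$merge[, 2])
}

#' @rdname cluster_sites
#' @export
glance.edit_clust <- function(x, ...) {
  tibble(n_sites = nrow(x$matrix),
         n_libraries = ncol(x$matrix),
         min_height = min(x$hclust$height),
         max_height = max(x$hclust$height),
         metric = x$metric,
         linkage = x$linkage)
}

#' Cut an editing-site tree into k clusters
#'
#' @param clust An `edit_clust` object.
#' @param k Number of clusters.
#' @return Tibble: site_id, cluster.
#' @export
cut_clusters <- function(clust, k) {
  cl <- stats::cutree(clust$hclust, k = k)
  tibble(site_id = names(cl), cluster = unname(cl))
}

#' Split sites into 17-nt and 20-nt evidence matrices
#'
#' The signature pool mixes 17-nt and 20-nt tags; the tissue analysis is run
#' separately per length. Sites are assigned to a length by the lengths of
#' their supporting tags (from [aggregate_sites()]); a site supported by
#' both lengths appears in both matrices (logged).
#'
#' @param sites An [aggregate_sites()] result with the `tag_lengths` column.
#' @param ratios An [editing_ratio()] result for the same sites.
#' @return Named list of [ratio_matrix()] tibbles, one per observed tag
#'   length (names `"17"`, `"20"`, ...).
#' @export
split_by_tag_length <- function(sites, ratios) {
  lens <- sort(unique(unlist(sites$tag_lengths)))
  both <- sum(lengths(sites$tag_lengths) > 1)
  if (both > 0) {
    inform(sprintf("%d site(s) supported by several tag lengths appear in every matrix",
                   both))
  }
  out <- purrr::map(lens, function(L) {
    ids <- sites$site_id[purrr::map_lgl(sites$tag_lengths, ~ L %in% .x)]
    ratio_matrix(ratios %>% dplyr::filter(.data$site_id %in% ids))
  })
  stats::setNames(out, as.character(lens))
}

#' Export a clustering tree as Newick
#'
#' @param clust An `edit_clust` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(clust, path) {
  phy <- ape::as.phylo(clust$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
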