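#' Hierarchical clustering of samples on correlation distance
#'
#' Agglomerative clustering of samples on the `1 - Pearson` distance
#' between species-level abundance profiles (all species, no prevalence
#' filter), cut to exactly `k` clusters.  Cluster ids are relabelled as
#' contiguous integers ordered by decreasing cluster size, so cluster 1
#' is always the largest.
#'
#' @param data Relative-abundance tibble.
#' @param k Number of clusters, `2 <= k <= n_samples`.
#' @param linkage Agglomeration method passed to [stats::hclust];
#'   `"average"` (UPGMA) by default.
#' @return Tibble with columns `sample_id`, `cluster`.
#' @export
hcl_cluster <- function(data, k, linkage = c("average", "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  data <- validate_abundance(data)
  n <- nrow(data)
  if (k < 2 || k > n) abort("k must be between 2 and the number of samples")
  d <- distance_matrix(data, "pearson")
  tree <- hclust(d, method = linkage)
  labels <- relabel_by_size(cutree(tree, k = k))
  tibble(sample_id = data$sample_id, cluster = labels)
}

# Internal: map cluster ids to 1..k by decreasing size (ties: first seen).
relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- setNames(seq_along(tab), names(tab))
  as.integer(map[as.character(labels)])
}

#' Mean silhouette width of a clustering
#'
#' Standard silhouette: for sample `i` with mean within-cluster distance
#' `a(i)` and smallest mean distance to another cluster `b(i)`,
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`; singleton clusters get
#' `s(i) = 0`, as does the degenerate `a = b = 0` case.  Returns the mean
#' over all samples.
#'
#' @param d [stats::dist] or symmetric dissimilarity matrix.
#' @param labels Cluster assignment per sample (>= 2 nonempty clusters).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
mean_silhouette <- function(d, labels) {
  dm <- as.matrix(as.dist(d))
  n <- nrow(dm)
  labels <- as.integer(as.factor(labels))
  if (length(labels) != n) abort("labels must have one entry per sample")
  k <- max(labels)
  if (k < 2) abort("silhouette needs at least 2 clusters")
  sizes <- tabulate(labels, k)
  # mean distance from each sample to each cluster
  member <- matrix(0, n, k)
  member[cbind(seq_len(n), labels)] <- 1
  sums <- dm %*% member                       # n x k: total distance to cluster
  own <- sizes[labels]
  a <- ifelse(own > 1, sums[cbind(seq_len(n), labels)] / (own - 1), 0)
  means_other <- sweep(sums, 2, sizes, "/")
  means_other[cbind(seq_len(n), labels)] <- Inf
  b <- apply(means_other, 1, min)
  s <- ifelse(own == 1, 0, {
    denom <- pmax(a, b)
    ifelse(denom == 0, 0, (b - a) / denom)
  })
  mean(s)
}

#' Select the number of community state types by silhouette
#'
#' Fits a single dendrogram (hierarchical clustering on `1 - Pearson`
#' distances, see [hcl_cluster()]) and cuts it at every `k` in `k_range`,
#' scoring each partition by its mean silhouette width on the same
#' distances.  The selected `k` maximizes the mean silhouette; ties break
#' toward the smaller `k`.  The returned clusters at the selected `k` are
#' the community state types (CSTs).
#'
#' @param data Relative-abundance tibble.
#' @param k_range Candidate cluster counts, within `[2, n_samples - 1]`.
#' @param linkage Agglomeration method (default `"average"`).
#' @return `cst_result`: list with `labels` (tibble `sample_id`,
#'   `cluster`), selected `k`, `silhouette_by_k` (tibble `k`,
#'   `mean_silhouette`), the fitted `tree`, and the `dist` used.
#' @export
select_k <- function(data, k_range = 2:15, linkage = c("average", "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  data <- validate_abundance(data)
  n <- nrow(data)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) abort("k_range must not be empty")
  if (min(k_range) < 2 || max(k_range) > n - 1) {
    abort("k_range must lie within [2, n_samples - 1]")
  }
  d <- distance_matrix(data, "pearson")
  tree <- hclust(d, method = linkage)
  cuts <- cutree(tree, k = k_range)           # n x length(k_range)
  sil <- vapply(seq_along(k_range),
                function(i) mean_silhouette(d, cuts[, i]),
                numeric(1))
  best <- k_range[which.max(sil)]             # which.max takes the first max
  labels <- relabel_by_size(cuts[, match(best, k_range)])
  structure(
    list(
      labels = tibble(sample_id = data$sample_id, cluster = labels),
      k = best,
      silhouette_by_k = tibble(k = k_range, mean_silhouette = sil),
      tree = tree,
      dist = d,
      hpc = NULL,
      group_composition = NULL
    ),
    class = "cst_result"
  )
}

#' Flag high prevalence clusters (HPCs)
#'
#' A community state type is a high prevalence cluster when it contains at
#' least `min_prevalence` of all samples (inclusive threshold).  Adds the
#' per-cluster prevalence table, the HPC ids, and the collective coverage
#' (summed prevalence over HPCs) to the result.
#'
#' @param result A `cst_result` from [select_k()], or any list with a
#'   `labels` tibble.
#' @param min_prevalence Minimum fraction of samples (default 0.15).
#' @return The `cst_result` with `hpc` populated: tibble
#'   (`cluster`, `n`, `prevalence`, `is_hpc`) plus attributes via
#'   `hpc_ids` and `collective_coverage` elements.
#' @export
identify_hpcs <- function(result, min_prevalence = 0.15) {
  labels <- cst_labels(result)
  if (is.data.frame(result)) {
    result <- structure(list(labels = labels), class = "cst_result")
  }
  n <- nrow(labels)
  prev <- labels |>
    dplyr::count(.data$cluster) |>
    dplyr::mutate(prevalence = .data$n / !!n,
                  is_hpc = .data$prevalence >= min_prevalence) |>
    dplyr::arrange(dplyr::desc(.data$prevalence))
  result$hpc <- prev
  result$hpc_ids <- prev$cluster[prev$is_hpc]
  result$collective_coverage <- sum(prev$prevalence[prev$is_hpc])
  result$min_prevalence <- min_prevalence
  result
}

#' Group composition of each cluster
#'
#' For every cluster, the fraction of member samples carrying each
#' metadata group label (fractions sum to 1 within cluster).
#'
#' @param result A `cst_result` (or list with a `labels` tibble).
#' @param metadata Metadata tibble with `sample_id` and `group`; every
#'   clustered sample must be present.
#' @return The `cst_result` with `group_composition` populated: tibble
#'   (`cluster`, `group`, `n`, `fraction`).
#' @export
group_composition <- function(result, metadata) {
  labels <- cst_labels(result)
  if (is.data.frame(result)) {
    result <- structure(list(labels = labels), class = "cst_result")
  }
  md <- align_metadata(labels$sample_id, metadata)
  comp <- tibble(cluster = labels$cluster, group = md$group) |>
    dplyr::count(.data$cluster, .data$group) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  result$group_composition <- comp
  result
}

# Internal: extract a labels tibble from a cst_result or plain tibble.
cst_labels <- function(result) {
  if (is.data.frame(result)) {
    if (!all(c("sample_id", "cluster") %in% names(result))) {
      abort("labels need sample_id and cluster columns")
    }
    return(as_tibble(result))
  }
  if (is.list(result) && !is.null(result$labels)) return(result$labels)
  abort("expected a cst_result or a sample_id/cluster tibble")
}

#' @export
print.cst_result <- function(x, ...) {
  cat("Community state typing\n")
  cat("  samples:", nrow(x$labels), "  selected k:", x$k, "\n")
  cat(sprintf("  mean silhouette at k: %.3f\n",
              x$silhouette_by_k$mean_silhouette[match(x$k, x$silhouette_by_k$k)]))
  if (!is.null(x$hpc)) {
    cat("  HPCs:", paste(x$hpc_ids, collapse = ", "),
        sprintf(" (collective coverage %.1f%%)\n", 100 * x$collective_coverage))
  }
  invisible(x)
}
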