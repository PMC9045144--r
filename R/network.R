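#' Kendall's tau-b rank correlation with significance
#'
#' Tie-corrected Kendall rank correlation
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))`, where `C`/`D` count
#' concordant/discordant pairs, `n0 = n(n-1)/2` and `n1`, `n2` are the
#' tied-pair counts of each vector.  The p-value is two-sided: exact (from
#' the null distribution of `C - D` over all permutations) for `n <= 10`
#' with no ties, otherwise the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Tibble with columns `tau`, `p`, `method` (`"exact"` or
#'   `"normal"`).  If either vector is constant (all pairs tied) tau is
#'   undefined and `NA` is returned.
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  if (n < 3) abort("kendall_tau needs at least 3 observations")
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  cd <- sum(sx[upper.tri(sx)] * sy[upper.tri(sy)])   # C - D
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(table(x), 2))
  n2 <- sum(choose(table(y), 2))
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) {
    return(tibble(tau = NA_real_, p = NA_real_, method = NA_character_))
  }
  tau <- cd / denom
  if (n <= 10 && n1 == 0 && n2 == 0) {
    p <- kendall_exact_p(cd, n)
    method <- "exact"
  } else {
    v <- kendall_var(n, table(x), table(y))
    z <- (cd - sign(cd) * (cd != 0)) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  tibble(tau = tau, p = min(p, 1), method = method)
}

# Internal: exact two-sided P(|C - D| >= |cd|) under the no-ties null,
# from the Mahonian (inversion-count) distribution computed by dynamic
# programming.
kendall_exact_p <- function(cd, n) {
  n0 <- n * (n - 1) / 2
  counts <- 1                                  # permutations of 1 element
  for (m in 2:n) {
    # inserting element m adds 0..(m-1) inversions
    new <- numeric(length(counts) + m - 1)
    for (j in 0:(m - 1)) {
      idx <- (1 + j):(j + length(counts))
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  d_vals <- 0:n0
  t_vals <- n0 - 2 * d_vals                    # C - D per inversion count
  sum(counts[abs(t_vals) >= abs(cd)]) / sum(counts)
}

# Internal: tie-corrected variance of C - D under the null.
kendall_var <- function(n, tx, ty) {
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  (v0 - vt - vu) / 18 + v1 + v2
}

# Internal: all-pairs Kendall tau-b and normal-approximation p-values for
# the columns of a matrix.  C - D for every pair comes from one crossprod
# of the per-column pairwise sign vectors, so the count is exact and the
# cost is a single BLAS call rather than a per-pair scan.
kendall_all <- function(m) {
  n <- nrow(m)
  p <- ncol(m)
  ut <- which(upper.tri(matrix(0, n, n)))
  ii <- ((ut - 1) %% n) + 1
  ll <- ((ut - 1) %/% n) + 1
  S <- sign(m[ii, , drop = FALSE] - m[ll, , drop = FALSE])
  CD <- crossprod(S)
  n0 <- n * (n - 1) / 2
  tie_stats <- apply(m, 2, function(x) {
    t <- table(x)
    c(n1 = sum(t * (t - 1)) / 2,
      vt = sum(t * (t - 1) * (2 * t + 5)),
      s1 = sum(t * (t - 1)),
      s2 = sum(t * (t - 1) * (t - 2)))
  })
  n1 <- tie_stats["n1", ]
  denom <- sqrt(outer(n0 - n1, n0 - n1))
  tau <- CD / denom
  tau[denom == 0] <- NA_real_
  v0 <- n * (n - 1) * (2 * n + 5)
  v <- (v0 - outer(tie_stats["vt", ], tie_stats["vt", ], "+")) / 18 +
    outer(tie_stats["s1", ], tie_stats["s1", ]) / (2 * n * (n - 1)) +
    outer(tie_stats["s2", ], tie_stats["s2", ]) / (9 * n * (n - 1) * (n - 2))
  z <- (CD - sign(CD)) / sqrt(pmax(v, 0))
  pmat <- 2 * pnorm(-abs(z))
  pmat[denom == 0] <- NA_real_
  list(tau = tau, p = pmin(pmat, 1))
}

#' Build a signed co-occurrence network
#'
#' Tests every pair of sufficiently prevalent species for rank correlation
#' across samples, adjusts the p-values across all tested pairs, and keeps
#' the pairs whose adjusted p-value is at or below `alpha` as signed
#' edges.  Nodes carry the species' mean relative abundance and degree;
#' module ids are filled in by [modularity_clusters()].
#'
#' @param data Relative-abundance tibble with >= 10 samples.
#' @param min_prevalence Species must be present (abundance > 0) in at
#'   least this fraction of samples to enter the network (default 0.2,
#'   which avoids tie-degenerate correlations on sparse taxa).
#' @param alpha Significance level on the (adjusted) p-value.
#' @param correction `"bh"` (Benjamini-Hochberg, default) or `"none"`.
#' @param method `"kendall"` (tau-b, default) or `"spearman"`.
#' @return `cooccur_network`: list with `nodes` (tibble `species`,
#'   `mean_abundance`, `degree`, `module`), `edges` (tibble `taxon_a`,
#'   `taxon_b`, `tau`, `p`, `q`, `sign`), and the build parameters.
#' @export
build_network <- function(data, min_prevalence = 0.2, alpha = 0.05,
                          correction = c("bh", "none"),
                          method = c("kendall", "spearman")) {
  correction <- match.arg(correction)
  method <- match.arg(method)
  data <- validate_abundance(data)
  m <- abundance_matrix(data)
  n <- nrow(m)
  if (n < 10) abort("co-occurrence networks need at least 10 samples")
  prev <- colMeans(m > 0)
  keep <- prev >= min_prevalence
  if (sum(keep) < 2) abort("fewer than 2 species pass the prevalence filter")
  m <- m[, keep, drop = FALSE]
  sp <- colnames(m)

  if (method == "kendall") {
    res <- kendall_all(m)
    tau <- res$tau
    pmat <- res$p
  } else {
    tau <- cor(m, method = "spearman")
    tstat <- tau * sqrt((n - 2) / pmax(1 - tau^2, .Machine$double.eps))
    pmat <- 2 * pt(-abs(tstat), df = n - 2)
    const <- apply(m, 2, function(x) length(unique(x)) == 1)
    tau[const, ] <- NA_real_; tau[, const] <- NA_real_
    pmat[const, ] <- NA_real_; pmat[, const] <- NA_real_
  }

  pairs <- which(upper.tri(tau), arr.ind = TRUE)
  edge_tbl <- tibble(
    taxon_a = sp[pairs[, 1]],
    taxon_b = sp[pairs[, 2]],
    tau = tau[pairs],
    p = pmat[pairs]
  ) |>
    dplyr::filter(!is.na(.data$tau))           # all-tied vectors drop out
  edge_tbl$q <- if (correction == "bh") p.adjust(edge_tbl$p, method = "BH") else edge_tbl$p
  n_tested <- nrow(edge_tbl)
  edges <- edge_tbl |>
    dplyr::filter(.data$q <= alpha, .data$tau != 0) |>
    dplyr::mutate(sign = ifelse(.data$tau > 0, "positive", "negative"))

  deg <- table(factor(c(edges$taxon_a, edges$taxon_b), levels = sp))
  nodes <- tibble(
    species = sp,
    mean_abundance = unname(colMeans(m)),
    degree = as.integer(deg),
    module = NA_integer_
  )
  structure(
    list(nodes = nodes, edges = edges, n_samples = n, method = method,
         alpha = alpha, correction = correction,
         min_prevalence = min_prevalence, n_tested = n_tested,
         modularity = NA_real_),
    class = "cooccur_network"
  )
}

#' Detect modularity clusters in a co-occurrence network
#'
#' Greedy modularity maximization (fast-greedy agglomeration) on the
#' undirected network weighted by `|tau|`; the sign stays an edge
#' attribute and does not enter the weights.  Isolated nodes each form
#' their own module; an edgeless network gets `Q = 0`.
#'
#' @param net `cooccur_network`.
#' @param seed Integer seed (the greedy algorithm is deterministic; the
#'   seed pins any library-internal tie-breaking).
#' @return The network with `nodes$module` filled and element
#'   `modularity` set to the partition's Q.
#' @export
modularity_clusters <- function(net, seed = 1L) {
  stopifnot(inherits(net, "cooccur_network"))
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) {
    net$nodes$module <- seq_len(nrow(net$nodes))
    net$modularity <- 0
    return(net)
  }
  w <- abs(igraph::E(g)$tau)
  comm <- withr::with_seed(seed, igraph::cluster_fast_greedy(g, weights = w))
  member <- igraph::membership(comm)
  q <- igraph::modularity(g, member, weights = w)
  # the greedy merge path can end at a locally optimal split worse than the
  # connected-components partition (whose Q is always >= 0); never return it
  comp <- igraph::components(g)$membership
  q_comp <- igraph::modularity(g, comp, weights = w)
  if (q < q_comp) {
    member <- comp
    q <- q_comp
  }
  net$nodes$module <- as.integer(member[net$nodes$species])
  net$modularity <- q
  net
}

#' Summarise a co-occurrence network
#'
#' @param net `cooccur_network`.
#' @param top_n How many top-degree taxa to list (default 5).
#' @return One-row tibble: `n_nodes`, `n_edges`, `n_positive`,
#'   `n_negative`, `pct_positive` (0 for an empty network), `n_modules`
#'   (`NA` until [modularity_clusters()] has run), `modularity`, and a
#'   `top_degree_taxa` list-column.
#' @export
network_summary <- function(net, top_n = 5) {
  stopifnot(inherits(net, "cooccur_network"))
  n_pos <- sum(net$edges$sign == "positive")
  n_neg <- sum(net$edges$sign == "negative")
  n_edges <- nrow(net$edges)
  tibble(
    n_nodes = nrow(net$nodes),
    n_edges = n_edges,
    n_positive = n_pos,
    n_negative = n_neg,
    pct_positive = if (n_edges == 0) 0 else 100 * n_pos / n_edges,
    n_modules = if (all(is.na(net$nodes$module))) NA_integer_ else
      length(unique(net$nodes$module)),
    modularity = net$modularity,
    top_degree_taxa = list(keystone_taxa(net, min(top_n, nrow(net$nodes)))$species)
  )
}

#' Rank keystone taxa by connectivity
#'
#' Orders nodes by degree; ties break by higher mean abundance, then
#' alphabetically by species name.
#'
#' @param net `cooccur_network`.
#' @param top_n Number of taxa to return; if larger than the node count
#'   the full ordering is returned with a warning.
#' @return Tibble of the top rows of `nodes`, in keystone order.
#' @export
keystone_taxa <- function(net, top_n = 5) {
  stopifnot(inherits(net, "cooccur_network"))
  if (top_n > nrow(net$nodes)) {
    warn("top_n exceeds the node count; returning the full ordering")
    top_n <- nrow(net$nodes)
  }
  net$nodes |>
    dplyr::arrange(dplyr::desc(.data$degree),
                   dplyr::desc(.data$mean_abundance),
                   .data$species) |>
    head(top_n)
}

# Internal: igraph view of a network, nodes and attributes included.
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("taxon_a", "taxon_b", "tau", "p", "q", "sign")],
    directed = FALSE,
    vertices = net$nodes[, c("species", "mean_abundance", "degree", "module")]
  )
  g
}

#' @export
print.cooccur_network <- function(x, ...) {
  cat("Co-occurrence network (", x$method, ", ",
      x$correction, " q <= ", x$alpha, ")\n", sep = "")
  cat("  nodes:", nrow(x$nodes), "  edges:", nrow(x$edges),
      " (", sum(x$edges$sign == "positive"), "positive /",
      sum(x$edges$sign == "negative"), "negative )\n")
  if (!is.na(x$modularity)) {
    cat(sprintf("  modules: %d  Q = %.3f\n",
                length(unique(x$nodes$module)), x$modularity))
  }
  invisible(x)
}
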