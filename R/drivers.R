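#' Variance in each species explained by cluster structure
#'
#' For every species, fits a linear model of its relative abundance on the
#' cluster assignment and reports the adjusted R-squared,
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)` with `p` predictors.  Two designs
#' are available:
#'
#' * `"categorical"` (default): indicator-coded cluster membership, i.e. a
#'   one-way ANOVA design with `p = k - 1`; this measures how much of a
#'   species' inter-sample variability the community state types account
#'   for.
#' * `"pcoa_poly"`: abundance regressed on powers `1..degree` of the first
#'   principal coordinate of the Bray-Curtis distances, a continuous-axis
#'   reading of "variance explained".
#'
#' Species with zero variance across samples get an adjusted R-squared of
#' 0 (with an informational message), not an error.
#'
#' @param data Relative-abundance tibble.
#' @param labels Cluster assignment: a `sample_id`/`cluster` tibble (as
#'   from [hcl_cluster()] or `select_k()$labels`) or a vector in table
#'   order.  Ignored for `mode = "pcoa_poly"`.
#' @param mode `"categorical"` or `"pcoa_poly"`.
#' @param degree Polynomial degree for `"pcoa_poly"` (default 2).
#' @return Tibble with columns `species`, `adj_r2`, `r2`.
#' @export
variance_explained <- function(data, labels = NULL,
                               mode = c("categorical", "pcoa_poly"),
                               degree = 2) {
  mode <- match.arg(mode)
  data <- validate_abundance(data)
  m <- abundance_matrix(data)
  n <- nrow(m)

  if (mode == "categorical") {
    f <- as.factor(labels_vector(labels, data$sample_id))
    k <- nlevels(f)
    if (k < 2) abort("need at least 2 clusters")
    if (any(table(f) < 2)) abort("every cluster needs at least 2 samples")
    p <- k - 1
    grp_mean <- rowsum(m, f) / as.vector(table(f))
    fitted <- grp_mean[as.integer(f), , drop = FALSE]
  } else {
    ord <- pcoa(distance_matrix(data, "bray_curtis"), n_axes = 1)
    x <- ord$coordinates$Axis1
    X <- stats::poly(x, degree = degree, raw = TRUE)
    p <- ncol(X)
    fit <- stats::lm.fit(cbind(1, X), m)
    fitted <- m - fit$residuals
  }

  sst <- colSums(sweep(m, 2, colMeans(m))^2)
  sse <- colSums((m - fitted)^2)
  r2 <- ifelse(sst > 0, 1 - sse / sst, 0)
  adj <- ifelse(sst > 0, 1 - (1 - r2) * (n - 1) / (n - p - 1), 0)
  if (any(sst == 0)) {
    inform(paste0(sum(sst == 0), " zero-variance species reported with adj_r2 = 0"))
  }
  tibble(species = colnames(m), adj_r2 = unname(adj), r2 = unname(r2))
}

#' Select driver taxa by adjusted R-squared
#'
#' Driver taxa are the species whose adjusted R-squared against the
#' cluster structure is strictly greater than the threshold (0.15 by
#' default), sorted by decreasing adjusted R-squared.
#'
#' @param var_exp Tibble from [variance_explained()] (columns `species`,
#'   `adj_r2`).
#' @param threshold Strict lower cutoff on `adj_r2`.
#' @return Tibble of the selected rows, ordered by descending `adj_r2`.
#' @export
select_drivers <- function(var_exp, threshold = 0.15) {
  if (!all(c("species", "adj_r2") %in% names(var_exp))) {
    abort("var_exp must have species and adj_r2 columns")
  }
  var_exp |>
    dplyr::filter(.data$adj_r2 > threshold) |>
    dplyr::arrange(dplyr::desc(.data$adj_r2))
}

#' Share of each cluster's composition covered by driver taxa
#'
#' For every cluster, the percent of total abundance contributed by the
#' driver species: by default the mean over member samples of the summed
#' relative abundance of the drivers (`"sample_mean"`); the `"pooled"`
#' variant instead takes the ratio of pooled driver abundance to pooled
#' total abundance across the cluster (identical for normalized rows up
#' to weighting).
#'
#' @param data Relative-abundance tibble.
#' @param labels Cluster assignment (tibble or vector, as in
#'   [variance_explained()]).
#' @param drivers Character vector of species names (or a tibble with a
#'   `species` column); must be a subset of the table's species.
#' @param mode `"sample_mean"` or `"pooled"`.
#' @return Tibble with columns `cluster`, `coverage_pct` in `[0, 100]`.
#' @export
driver_coverage <- function(data, labels, drivers,
                            mode = c("sample_mean", "pooled")) {
  mode <- match.arg(mode)
  data <- validate_abundance(data)
  if (is.data.frame(drivers)) drivers <- drivers$species
  drivers <- as.character(drivers)
  m <- abundance_matrix(data)
  unknown <- setdiff(drivers, colnames(m))
  if (length(unknown) > 0) {
    abort(paste0("unknown driver species: ", paste(unknown, collapse = ", ")))
  }
  f <- as.factor(labels_vector(labels, data$sample_id))
  driver_sum <- if (length(drivers) == 0) rep(0, nrow(m)) else
    rowSums(m[, drivers, drop = FALSE])
  if (mode == "sample_mean") {
    cov <- tapply(driver_sum, f, mean)
  } else {
    cov <- tapply(driver_sum, f, sum) / tapply(rowSums(m), f, sum)
  }
  tibble(cluster = type.convert(names(cov), as.is = TRUE),
         coverage_pct = 100 * as.numeric(cov))
}

#' Per-species group difference tests
#'
#' Welch two-sample t-test of each species' relative abundance between the
#' two metadata groups, with optional Benjamini-Hochberg adjustment.
#' Species with zero variance in both groups are reported with `p = 1`.
#'
#' @param data Relative-abundance tibble.
#' @param metadata Metadata tibble (`sample_id`, `group`); both groups
#'   need >= 2 samples.
#' @param correction `"none"` (default, mirroring per-taxon reporting) or
#'   `"bh"` to add `q` values.
#' @return Tibble with columns `species`, `statistic`, `p`, and `q` when
#'   corrected.
#' @export
taxon_group_test <- function(data, metadata, correction = c("none", "bh")) {
  correction <- match.arg(correction)
  data <- validate_abundance(data)
  md <- align_metadata(data$sample_id, metadata)
  g <- as.factor(md$group)
  if (nlevels(g) != 2) abort("taxon_group_test needs exactly 2 groups")
  if (any(table(g) < 2)) abort("both groups need at least 2 samples")
  m <- abundance_matrix(data)
  res <- purrr::map(seq_len(ncol(m)), function(j) {
    x <- m[g == levels(g)[1], j]
    y <- m[g == levels(g)[2], j]
    if (var(x) == 0 && var(y) == 0) {
      list(statistic = 0, p = 1)
    } else {
      tt <- t.test(x, y, var.equal = FALSE)
      list(statistic = unname(tt$statistic), p = tt$p.value)
    }
  })
  out <- tibble(species = colnames(m),
                statistic = purrr::map_dbl(res, "statistic"),
                p = purrr::map_dbl(res, "p"))
  if (correction == "bh") out$q <- p.adjust(out$p, method = "BH")
  out
}

# Internal: coerce a labels tibble or vector to a per-sample vector
# aligned with sample_ids.
labels_vector <- function(labels, sample_ids) {
  if (is.null(labels)) abort("cluster labels are required")
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "cluster") %in% names(labels))) {
      abort("labels tibble needs sample_id and cluster columns")
    }
    idx <- match(sample_ids, labels$sample_id)
    if (anyNA(idx)) {
      abort(paste0("samples without a cluster label: ",
                   paste(sample_ids[is.na(idx)], collapse = ", ")))
    }
    return(labels$cluster[idx])
  }
  if (length(labels) != length(sample_ids)) {
    abort("labels vector must have one entry per sample")
  }
  labels
}
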