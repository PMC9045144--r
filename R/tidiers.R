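#' Tidy a PERMANOVA result
#'
#' @param x `permanova_result`.
#' @param ... Unused.
#' @return One-row tibble: `pseudo_F`, `df_between`, `df_within`,
#'   `p_value`, `n_permutations`.
#' @method tidy permanova_result
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F,
         df_between = unname(x$df["between"]),
         df_within = unname(x$df["within"]),
         p_value = x$p_value,
         n_permutations = x$n_permutations)
}

#' @rdname tidy.permanova_result
#' @method glance permanova_result
#' @export
glance.permanova_result <- function(x, ...) tidy(x, ...)

#' Tidy a community state typing result
#'
#' `tidy()` returns the per-sample assignment (with an `is_hpc` flag once
#' [identify_hpcs()] has run); `glance()` the one-row model summary.
#'
#' @param x `cst_result`.
#' @param ... Unused.
#' @method tidy cst_result
#' @export
tidy.cst_result <- function(x, ...) {
  out <- x$labels
  if (!is.null(x$hpc)) {
    out <- dplyr::left_join(out, x$hpc[, c("cluster", "is_hpc")], by = "cluster")
  }
  out
}

#' @rdname tidy.cst_result
#' @method glance cst_result
#' @export
glance.cst_result <- function(x, ...) {
  tibble(
    n_samples = nrow(x$labels),
    k = x$k,
    mean_silhouette = x$silhouette_by_k$mean_silhouette[
      match(x$k, x$silhouette_by_k$k)],
    n_hpcs = if (is.null(x$hpc)) NA_integer_ else length(x$hpc_ids),
    collective_coverage = if (is.null(x$hpc)) NA_real_ else x$collective_coverage
  )
}

#' Tidy an ordination
#'
#' @param x `pcoa_result`.
#' @param ... Unused.
#' @return `tidy()`: the sample coordinates; `glance()`: one row per axis
#'   with eigenvalue and proportion explained.
#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) x$coordinates

#' @rdname tidy.pcoa_result
#' @method glance pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble(axis = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         proportion_explained = x$proportion_explained)
}

#' Tidy a co-occurrence network
#'
#' @param x `cooccur_network`.
#' @param ... Unused.
#' @return `tidy()`: the edge tibble; `glance()`: the one-row
#'   [network_summary()].
#' @method tidy cooccur_network
#' @export
tidy.cooccur_network <- function(x, ...) x$edges

#' @rdname tidy.cooccur_network
#' @method glance cooccur_network
#' @export
glance.cooccur_network <- function(x, ...) network_summary(x)
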