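#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same
#' samples: 1 for identical partitions (up to relabelling), ~0 for
#' independent ones.  Computed from the contingency table via the
#' Hubert-Arabie formula.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
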