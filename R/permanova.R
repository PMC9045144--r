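#' Permutational multivariate analysis of variance (one factor)
#'
#' Distance-based pseudo-F in Anderson's formulation.  With `N` samples in
#' `a` groups,
#' `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`, and
#' `F = ((SS_total - SS_within)/(a-1)) / (SS_within/(N-a))`.
#' Significance comes from permuting group labels across samples
#' (unstratified by default); the permutation p-value uses the `+1/+1`
#' convention `p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1)`, counting
#' ties as exceedances.  `permutations = "all"` enumerates every label
#' ordering (feasible for ~8 samples or fewer) and reports the exact
#' proportion `#\{F_perm >= F_obs\} / n!`, with the identity ordering
#' included.
#'
#' @param d [stats::dist] or symmetric dissimilarity matrix.
#' @param groups Group label per sample, in the order of `d`'s ids; at
#'   least 2 groups each of size >= 2.
#' @param permutations Number of random permutations (default 1000), or
#'   `"all"` for exhaustive enumeration.
#' @param seed Integer seed controlling the random permutations; ignored
#'   for `"all"`.  `NULL` uses the session RNG stream.
#' @param strata Optional factor; when given, labels are permuted only
#'   within its levels (e.g. within study of origin).
#' @return `permanova_result`: list with `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`, `df`, and the sums of squares.
#' @export
permanova <- function(d, groups, permutations = 1000, seed = NULL,
                      strata = NULL) {
  dm <- as.matrix(as.dist(d))
  n <- nrow(dm)
  groups <- as.factor(groups)
  if (length(groups) != n) abort("groups must have one label per sample")
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) {
    abort(paste0("every group needs >= 2 samples; too small: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  D2 <- dm^2
  obs <- permanova_F(D2, groups)

  exhaustive <- identical(permutations, "all")
  if (exhaustive) {
    if (n > 8) abort("exhaustive enumeration is limited to 8 samples")
    perms <- all_permutations(n)
    f_perm <- vapply(seq_len(ncol(perms)),
                     function(i) permanova_F(D2, groups[perms[, i]])$F,
                     numeric(1))
    p <- mean(f_perm >= obs$F - 1e-12)
    n_perm <- ncol(perms)
  } else {
    n_perm <- as.integer(permutations)
    if (is.na(n_perm) || n_perm < 1) abort("permutations must be >= 1 or \"all\"")
    draw <- function() {
      f_perm <- numeric(n_perm)
      for (b in seq_len(n_perm)) {
        idx <- permute_indices(n, strata)
        f_perm[b] <- permanova_F(D2, groups[idx])$F
      }
      f_perm
    }
    f_perm <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    p <- (1 + sum(f_perm >= obs$F - 1e-12)) / (n_perm + 1)
  }

  structure(
    list(pseudo_F = obs$F, p_value = p, n_permutations = n_perm,
         seed = if (exhaustive) NA_integer_ else seed,
         df = c(between = length(sizes) - 1L, within = n - length(sizes)),
         ss_total = obs$ss_total, ss_within = obs$ss_within,
         exhaustive = exhaustive),
    class = "permanova_result"
  )
}

# Internal: pseudo-F for one labelling, from the squared distance matrix.
permanova_F <- function(D2, groups) {
  n <- nrow(D2)
  a <- nlevels(droplevels(as.factor(groups)))
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (g in levels(droplevels(as.factor(groups)))) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  Fval <- ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  list(F = Fval, ss_total = ss_total, ss_within = ss_within)
}

# Internal: one random permutation of 1..n, optionally within strata.
permute_indices <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  idx <- seq_len(n)
  for (lev in unique(strata)) {
    w <- which(strata == lev)
    idx[w] <- w[sample.int(length(w))]
  }
  idx
}

# Internal: matrix whose columns are all n! permutations of 1..n, built by
# inserting the value n at every position of each (n-1)-permutation.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (i in seq_len(ncol(sub))) {
    for (pos in seq_len(n)) {
      col <- col + 1L
      out[, col] <- append(sub[, i], n, after = pos - 1L)
    }
  }
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (", if (x$exhaustive) "exhaustive" else
    paste0(x$n_permutations, " permutations"), ")\n", sep = "")
  cat(sprintf("  pseudo-F = %.4f  (df %d, %d)\n", x$pseudo_F,
              x$df["between"], x$df["within"]))
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}
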