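# Independent reference implementations, deliberately written as plain
# double loops so they share no code path with the package.

# Silhouette: literal per-sample a/b computation.
brute_silhouette <- function(dm, labels) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(dm[i, labels == cl]))
    }
    denom <- max(a, b)
    s[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  mean(s)
}

# Kendall tau-b by exhaustive pair counting.
brute_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - tx) * (n0 - ty))
  if (denom == 0) return(NA_real_)
  (conc - disc) / denom
}

# PERMANOVA pseudo-F by literal pair sums.
brute_permanova_F <- function(dm, labels) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  groups <- unique(labels)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + dm[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in groups) {
    idx <- which(labels == g)
    acc <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        acc <- acc + dm[idx[a], idx[b]]^2
      }
    }
    ss_within <- ss_within + acc / length(idx)
  }
  a <- length(groups)
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# All permutations of 1..n, built by a different recursion than the
# package's (prepend each element to permutations of the rest).
brute_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (sub in brute_permutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(first, rest[sub])
    }
  }
  out
}

# Tiny relative-abundance tibble from a matrix of rows-summing-to-1.
abund_tbl <- function(m, ids = NULL, species = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_len(nrow(m)))
  species <- species %||% sprintf("sp%02d", seq_len(ncol(m)))
  colnames(m) <- species
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(m))
}

# Well-separated three-mode cohort used by several clustering tests:
# each mode concentrates its mass on a distinct block of species.
three_mode_cohort <- function(n_per = 10, n_species = 30, seed = 1) {
  withr::with_seed(seed, {
    states <- rep(1:3, each = n_per)
    shape <- matrix(0.1, 3 * n_per, n_species)
    for (s in 1:3) {
      block <- ((s - 1) * 5 + 1):(s * 5)
      shape[states == s, block] <- 5
    }
    g <- matrix(rgamma(length(shape), shape = as.vector(shape)), nrow(shape))
    list(table = abund_tbl(g / rowSums(g)), states = states)
  })
}

# Hand-built cooccur_network for graph-level tests.
make_network <- function(edges, species = NULL, mean_abundance = NULL) {
  species <- species %||% sort(unique(c(edges$taxon_a, edges$taxon_b)))
  deg <- table(factor(c(edges$taxon_a, edges$taxon_b), levels = species))
  if (is.null(mean_abundance)) mean_abundance <- rep(0.01, length(species))
  structure(
    list(
      nodes = tibble::tibble(species = species,
                             mean_abundance = mean_abundance,
                             degree = as.integer(deg),
                             module = NA_integer_),
      edges = edges,
      n_samples = NA_integer_, method = "kendall", alpha = 0.05,
      correction = "bh", min_prevalence = 0, n_tested = nrow(edges),
      modularity = NA_real_
    ),
    class = "cooccur_network"
  )
}

# Edge tibble with the columns build_network() produces.
edge_tbl <- function(a, b, tau, p = rep(1e-4, length(a)), q = p) {
  tibble::tibble(taxon_a = a, taxon_b = b, tau = tau, p = p, q = q,
                 sign = ifelse(tau > 0, "positive", "negative"))
}

`%||%` <- rlang::`%||%`
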