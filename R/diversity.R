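#' Threshold species richness per sample
#'
#' Alpha diversity as the number of species whose relative abundance is
#' strictly greater than a threshold.  The default threshold is 0.5%
#' (0.005); 0.05% (`5e-4`) is a common alternative convention and can be
#' passed explicitly.
#'
#' @param data Relative-abundance tibble (`sample_id` + species columns).
#' @param threshold Abundance fraction in `[0, 1)`; species strictly above
#'   it count towards richness.
#' @return Tibble with columns `sample_id`, `richness`.
#' @export
species_richness <- function(data, threshold = 0.005) {
  data <- validate_abundance(data)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold >= 1) {
    abort("threshold must be a single fraction in [0, 1)")
  }
  m <- abundance_matrix(data)
  tibble(sample_id = data$sample_id,
         richness = as.integer(rowSums(m > threshold)))
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' For relative-abundance profiles `p` and `q` this equals
#' `1 - sum(pmin(p, q))`: 0 for identical profiles, 1 for disjoint ones.
#' The general two-vector form `sum(|p - q|) / sum(p + q)` is used so the
#' value is well defined even if the inputs are only approximately
#' normalized.
#'
#' @param p,q Numeric abundance vectors over the same species set (if
#'   named, names must agree).
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(p, q) {
  if (length(p) != length(q)) abort("profiles must cover the same species set")
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q))) {
    abort("profiles must cover the same species set (names differ)")
  }
  s <- sum(p) + sum(q)
  if (s == 0) return(0)
  sum(abs(p - q)) / s
}

#' Pairwise sample distance matrix
#'
#' Bray-Curtis dissimilarity for beta diversity, or the correlation
#' distance `1 - r` (Pearson correlation across species of the two
#' samples' abundance profiles) used for community-state clustering.
#'
#' @param data Relative-abundance tibble.
#' @param metric `"bray_curtis"` or `"pearson"`.
#' @return A [stats::dist] object labelled by sample id.
#' @export
distance_matrix <- function(data, metric = c("bray_curtis", "pearson")) {
  metric <- match.arg(metric)
  data <- validate_abundance(data)
  if (nrow(data) < 2) abort("need at least 2 samples")
  m <- abundance_matrix(data)
  if (metric == "bray_curtis") {
    vegan::vegdist(m, method = "bray")
  } else {
    sds <- apply(m, 1, sd)
    if (any(sds == 0)) {
      abort(paste0("zero-variance sample(s) under the pearson metric: ",
                   paste(rownames(m)[sds == 0], collapse = ", ")))
    }
    as.dist(1 - cor(t(m)))
  }
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: Gower double-centering
#' of `-d^2/2` followed by eigendecomposition.  Axes with eigenvalue at or
#' below `1e-10` are dropped; negative eigenvalues are excluded from the
#' variance-explained denominator (no Lingoes/Cailliez correction).  Each
#' axis is oriented so that its first nonzero coordinate is positive.
#'
#' @param d A [stats::dist] or symmetric matrix of dissimilarities.
#' @param n_axes Number of axes requested; if fewer positive eigenvalues
#'   exist, all available axes are returned with a warning.
#' @return An object of class `pcoa_result`: list with `coordinates`
#'   (tibble: `sample_id`, `Axis1`, ...), `eigenvalues` and
#'   `proportion_explained` (per returned axis).
#' @export
pcoa <- function(d, n_axes = 3) {
  dm <- as.matrix(as.dist(d))
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(nrow(dm)))
  n <- nrow(dm)
  if (n_axes < 1) abort("n_axes must be at least 1")
  # cmdscale warns whenever a non-Euclidean matrix (e.g. Bray-Curtis) has
  # negative eigenvalues; we handle those explicitly below
  mds <- suppressWarnings(cmdscale(as.dist(dm), k = n - 1, eig = TRUE))
  eig <- mds$eig
  keep <- which(eig > 1e-10)
  if (length(keep) == 0) {
    # all points coincide: a single all-zero axis
    coords <- matrix(0, n, 1)
    out_eig <- 0
    prop <- 0
  } else {
    if (n_axes > length(keep)) {
      warn(paste0("requested ", n_axes, " axes but only ", length(keep),
                  " positive eigenvalues; returning ", length(keep)))
      n_axes <- length(keep)
    }
    keep <- keep[seq_len(n_axes)]
    coords <- mds$points[, keep, drop = FALSE]
    out_eig <- eig[keep]
    prop <- out_eig / sum(eig[eig > 1e-10])
  }
  # orient: first nonzero loading of each axis positive
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) > 0 && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(
    list(
      coordinates = dplyr::bind_cols(tibble(sample_id = ids), as_tibble(coords)),
      eigenvalues = unname(out_eig),
      proportion_explained = unname(prop)
    ),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("Principal coordinates analysis\n")
  cat("  samples:", nrow(x$coordinates), " axes retained:", length(x$eigenvalues), "\n")
  cat("  proportion explained:",
      paste(sprintf("%.3f", x$proportion_explained), collapse = " "), "\n")
  invisible(x)
}
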