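#' Configuration for a synthetic gut-microbiome cohort
#'
#' Describes a cohort with a small number of recurrent community states
#' (dominance patterns), a group label statistically associated with state
#' membership, and planted taxon-taxon rank correlations.  The defaults
#' emulate a ~200-sample athlete/non-athlete fecal cohort profiled to
#' species level: 207 samples over 330 species in 3 states — a
#' Prevotella-like state dominated by one taxon at ~44% mean abundance, a
#' Bacteroides-like state (17.5% + 5.9% dominants) and a
#' Faecalibacterium/Eubacterium-like state (15.2% + 14.4% + 7.1%
#' dominants) — with athlete-label probabilities 0.52, 0.18 and 0.87 per
#' state and six planted correlations (three positive, three negative) of
#' copula strength 0.8.
#'
#' @param n_samples,n_species Cohort dimensions.
#' @param state_weights Probability of each state; must sum to 1.
#' @param dominant_targets List (one element per state) of named numeric
#'   vectors: taxon index -> target mean relative abundance in that state.
#'   Converted internally to Dirichlet concentration boosts.
#' @param dirichlet_base Symmetric Dirichlet concentration of the
#'   non-dominant background (default 0.1: sparse, strongly
#'   individual profiles typical of stool metagenomes).
#' @param group_assoc Per-state probability that a sample is labelled
#'   `athlete`.
#' @param planted_edges Tibble/data frame with columns `taxon_a`,
#'   `taxon_b` (indices), `sign` (`"positive"`/`"negative"`), `strength`
#'   in `[0, 1]` (Gaussian-copula correlation magnitude).  A taxon may
#'   appear in at most one edge.
#' @param depth Reads per sample; 0 (default) returns exact Dirichlet
#'   fractions, a positive depth draws multinomial counts and
#'   renormalizes.
#' @param seed Integer seed; the cohort is a deterministic function of
#'   the config.
#' @return `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 207,
                          n_species = 330,
                          state_weights = c(0.30, 0.40, 0.30),
                          dominant_targets = list(
                            c("1" = 0.439),
                            c("2" = 0.175, "3" = 0.059),
                            c("4" = 0.152, "5" = 0.144, "6" = 0.071)
                          ),
                          dirichlet_base = 0.1,
                          group_assoc = c(0.52, 0.18, 0.87),
                          planted_edges = default_planted_edges(),
                          depth = 0,
                          seed = 1L) {
  n_states <- length(state_weights)
  if (abs(sum(state_weights) - 1) > 1e-8) abort("state_weights must sum to 1")
  if (length(dominant_targets) != n_states) {
    abort("dominant_targets needs one element per state")
  }
  if (length(group_assoc) != n_states) abort("group_assoc needs one entry per state")
  if (any(group_assoc < 0 | group_assoc > 1)) abort("group_assoc entries must lie in [0, 1]")
  if (dirichlet_base <= 0) abort("dirichlet_base must be positive")

  dom <- purrr::imap(dominant_targets, function(targets, state) {
    idx <- as.integer(names(targets))
    if (anyNA(idx) || any(idx < 1 | idx > n_species)) {
      abort("dominant taxon index out of range")
    }
    if (sum(targets) >= 1) abort("dominant target abundances must sum to < 1")
    # choose boosts so the expected relative abundance hits the target:
    # total concentration implied by the background plus the dominants
    total <- (n_species - length(idx)) * dirichlet_base / (1 - sum(targets))
    tibble(state = as.integer(state), taxon = idx,
           boost = unname(targets) * total / dirichlet_base)
  }) |> purrr::list_rbind()

  pe <- as_tibble(planted_edges)
  if (nrow(pe) > 0) {
    need <- c("taxon_a", "taxon_b", "sign", "strength")
    if (!all(need %in% names(pe))) {
      abort("planted_edges needs columns taxon_a, taxon_b, sign, strength")
    }
    idx <- c(pe$taxon_a, pe$taxon_b)
    if (any(idx < 1 | idx > n_species)) abort("planted edge taxon index out of range")
    if (anyDuplicated(idx)) abort("each taxon may appear in at most one planted edge")
    if (any(pe$strength < 0 | pe$strength > 1)) abort("edge strengths must lie in [0, 1]")
    if (!all(pe$sign %in% c("positive", "negative"))) {
      abort("edge sign must be \"positive\" or \"negative\"")
    }
  }

  structure(
    list(n_samples = n_samples, n_species = n_species, n_states = n_states,
         state_weights = state_weights, dominant_taxa = dom,
         dirichlet_base = dirichlet_base, group_assoc = group_assoc,
         planted_edges = pe, depth = depth, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Default planted correlation structure: three positive and three negative
# couplings among moderately ranked background taxa.
default_planted_edges <- function() {
  tibble(
    taxon_a = c(7L, 9L, 11L, 13L, 15L, 17L),
    taxon_b = c(8L, 10L, 12L, 14L, 16L, 18L),
    sign = rep(c("positive", "negative"), each = 3),
    strength = 0.8
  )
}

#' Generate a synthetic cohort with planted structure
#'
#' Each sample draws a community state from `state_weights`; its profile
#' is a Dirichlet draw whose concentration is `dirichlet_base` everywhere
#' except the state's dominant taxa, which are boosted to hit their target
#' mean abundances.  Planted taxon pairs are coupled through a Gaussian
#' copula on the Dirichlet's latent gamma variates, giving positive or
#' negative rank dependence of the configured strength without disturbing
#' the marginals.  Group labels are drawn per state from `group_assoc`.
#' With `depth > 0`, multinomial read counts are drawn and renormalized.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed` when given.
#' @return List with `abundance` (relative-abundance tibble), `metadata`
#'   (tibble `sample_id`, `group`) and `truth` — the planted structure:
#'   `states` (tibble `sample_id`, `state`), `drivers` (species names of
#'   all dominant taxa), `planted_edges` (with species names), and the
#'   config.
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  n <- config$n_samples
  p <- config$n_species
  species <- sprintf("sp%03d", seq_len(p))
  sample_ids <- sprintf("sample_%03d", seq_len(n))

  out <- withr::with_seed(seed, {
    states <- sample.int(config$n_states, n, replace = TRUE,
                         prob = config$state_weights)
    shape <- matrix(config$dirichlet_base, n, p)
    for (r in seq_len(nrow(config$dominant_taxa))) {
      row <- config$dominant_taxa[r, ]
      in_state <- states == row$state
      shape[in_state, row$taxon] <- config$dirichlet_base * row$boost
    }
    g <- matrix(rgamma(n * p, shape = as.vector(shape)), n, p)
    if (nrow(config$planted_edges) > 0) {
      for (r in seq_len(nrow(config$planted_edges))) {
        e <- config$planted_edges[r, ]
        rho <- e$strength * if (e$sign == "positive") 1 else -1
        za <- rnorm(n)
        zb <- rho * za + sqrt(1 - rho^2) * rnorm(n)
        g[, e$taxon_a] <- qgamma(pnorm(za), shape = shape[, e$taxon_a])
        g[, e$taxon_b] <- qgamma(pnorm(zb), shape = shape[, e$taxon_b])
      }
    }
    rel <- g / rowSums(g)
    if (config$depth > 0) {
      counts <- t(vapply(seq_len(n),
                         function(i) rmultinom(1, config$depth, rel[i, ])[, 1],
                         numeric(p)))
      rel <- counts / rowSums(counts)
    }
    group <- ifelse(stats::runif(n) < config$group_assoc[states],
                    "athlete", "non_athlete")
    list(rel = rel, states = states, group = group)
  })

  colnames(out$rel) <- species
  abundance <- dplyr::bind_cols(tibble(sample_id = sample_ids),
                                as_tibble(out$rel))
  truth_edges <- config$planted_edges
  if (nrow(truth_edges) > 0) {
    truth_edges$taxon_a <- species[truth_edges$taxon_a]
    truth_edges$taxon_b <- species[truth_edges$taxon_b]
  }
  list(
    abundance = abundance,
    metadata = tibble(sample_id = sample_ids, group = out$group),
    truth = list(
      states = tibble(sample_id = sample_ids, state = out$states),
      drivers = species[sort(unique(config$dominant_taxa$taxon))],
      planted_edges = truth_edges,
      config = config
    )
  )
}

#' Generate a structure-free null cohort
#'
#' Exchangeable samples from one symmetric Dirichlet: no community
#' states, no group effect, no planted correlations.  Used to calibrate
#' tests and to check that the pipeline finds nothing where nothing was
#' planted.
#'
#' @param n_samples,n_species Cohort dimensions (`n_samples >= 2`).
#' @param seed Integer seed.
#' @param dirichlet_base Symmetric concentration (default 1).
#' @return Relative-abundance tibble.
#' @export
generate_null_cohort <- function(n_samples, n_species, seed = 1L,
                                 dirichlet_base = 1) {
  if (n_samples < 2) abort("need at least 2 samples")
  rel <- withr::with_seed(seed, {
    g <- matrix(rgamma(n_samples * n_species, shape = dirichlet_base),
                n_samples, n_species)
    g / rowSums(g)
  })
  colnames(rel) <- sprintf("sp%03d", seq_len(n_species))
  dplyr::bind_cols(tibble(sample_id = sprintf("sample_%03d", seq_len(n_samples))),
                   as_tibble(rel))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$n_samples, "samples x", x$n_species,
      "species,", x$n_states, "states\n")
  cat("  state weights:", paste(x$state_weights, collapse = ", "), "\n")
  cat("  athlete probability by state:",
      paste(x$group_assoc, collapse = ", "), "\n")
  cat("  planted edges:", nrow(x$planted_edges),
      " depth:", x$depth, " seed:", x$seed, "\n")
  invisible(x)
}
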