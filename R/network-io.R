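#' Write a co-occurrence network to disk
#'
#' `"graphml"` serializes the full network (node attributes
#' `mean_abundance`, `degree`, `module`; edge attributes `tau`, `p`, `q`,
#' `sign`) and round-trips through [read_network()].  `"edge_tsv"` writes
#' a flat edge list with columns `taxon_a`, `taxon_b`, `tau`, `p`, `q`,
#' `sign` (header only for an empty network).
#'
#' @param net `cooccur_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cooccur_network"))
  if (format == "edge_tsv") {
    readr::write_tsv(net$edges[, c("taxon_a", "taxon_b", "tau", "p", "q", "sign")],
                     path, progress = FALSE)
  } else {
    g <- as_igraph(net)
    # igraph cannot write logical NA module ids; use -1 sentinel
    mod <- igraph::V(g)$module
    igraph::V(g)$module <- ifelse(is.na(mod), -1L, mod)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a co-occurrence network written by [write_network()]
#'
#' @param path File path.
#' @param format `"graphml"` (full round trip) or `"edge_tsv"` (edges
#'   only; node attributes are reconstructed as far as the edge list
#'   allows: degree from the edges, mean abundance unknown).
#' @return `cooccur_network`.
#' @export
read_network <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                             col_types = readr::cols(
                               taxon_a = readr::col_character(),
                               taxon_b = readr::col_character(),
                               tau = readr::col_double(),
                               p = readr::col_double(),
                               q = readr::col_double(),
                               sign = readr::col_character()))
    sp <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
    deg <- table(factor(c(edges$taxon_a, edges$taxon_b), levels = sp))
    nodes <- tibble(species = sp, mean_abundance = NA_real_,
                    degree = as.integer(deg), module = NA_integer_)
    net <- list(nodes = nodes, edges = edges, n_samples = NA_integer_,
                method = NA_character_, alpha = NA_real_,
                correction = NA_character_, min_prevalence = NA_real_,
                n_tested = NA_integer_, modularity = NA_real_)
    return(structure(net, class = "cooccur_network"))
  }
  g <- igraph::read_graph(path, format = "graphml")
  mod <- igraph::V(g)$module
  nodes <- tibble(
    species = igraph::V(g)$name,
    mean_abundance = igraph::V(g)$mean_abundance,
    degree = as.integer(igraph::V(g)$degree),
    module = ifelse(mod < 0, NA_integer_, as.integer(mod))
  )
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble(taxon_a = el$from, taxon_b = el$to, tau = el$tau,
                    p = el$p, q = el$q, sign = el$sign)
  } else {
    edges <- tibble(taxon_a = character(), taxon_b = character(),
                    tau = double(), p = double(), q = double(),
                    sign = character())
  }
  structure(
    list(nodes = nodes, edges = edges, n_samples = NA_integer_,
         method = NA_character_, alpha = NA_real_,
         correction = NA_character_, min_prevalence = NA_real_,
         n_tested = NA_integer_, modularity = NA_real_),
    class = "cooccur_network"
  )
}
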