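#' Classical centrality baselines
#'
#' The seven topology-only centralities the LDS ranking is compared against.
#' Each takes the edge tibble first and returns a tibble with columns
#' `protein`, `score` covering every network node; [centrality_scores()]
#' stacks any subset into one long table. Conventions (the field uses
#' several; these are fixed and documented here):
#'
#' * **DC** — node degree.
#' * **BC** — unnormalized shortest-path betweenness, each unordered pair
#'   counted once.
#' * **CloseC** — component-local closeness `(n_comp - 1) / sum of
#'   distances` within the node's component; 0 for isolated nodes.
#' * **ClusterC** — local clustering coefficient
#'   `2 e_N / (deg (deg - 1))`; 0 when degree < 2.
#' * **SC** — subgraph centrality, the diagonal of `exp(A)` (closed
#'   walk-count series `sum_k (A^k)_vv / k!`), via eigendecomposition.
#' * **LAC** — local average connectivity: the mean, over a node's
#'   neighbors, of their degree within the induced neighborhood subgraph;
#'   0 for degree-0 nodes.
#' * **LID** — local interaction density, read as the count of interactions
#'   among a node's neighbors.
#'
#' @inheritParams network_nodes
#' @return Tibble `protein`, `score` sorted by identifier.
#' @name baselines
#' @examples
#' degree_centrality(kite_network())
NULL

baseline_tbl <- function(g, score) {
  tibble(protein = igraph::V(g)$name, score = unname(score)) |>
    arrange(.data$protein)
}

#' @rdname baselines
#' @export
degree_centrality <- function(edges, nodes = NULL) {
  g <- as_ppi_igraph(edges, nodes)
  baseline_tbl(g, as.numeric(igraph::degree(g)))
}

#' @rdname baselines
#' @export
betweenness_centrality <- function(edges, nodes = NULL) {
  g <- as_ppi_igraph(edges, nodes)
  baseline_tbl(g, igraph::betweenness(g, directed = FALSE, normalized = FALSE))
}

#' @rdname baselines
#' @export
closeness_centrality <- function(edges, nodes = NULL) {
  g <- as_ppi_igraph(edges, nodes)
  dmat <- igraph::distances(g)
  score <- apply(dmat, 1, function(drow) {
    d <- drow[is.finite(drow)]
    tot <- sum(d)
    if (tot == 0) 0 else (length(d) - 1) / tot
  })
  baseline_tbl(g, score)
}

#' @rdname baselines
#' @export
clustering_coefficient <- function(edges, nodes = NULL) {
  g <- as_ppi_igraph(edges, nodes)
  baseline_tbl(g, igraph::transitivity(g, type = "local", isolates = "zero"))
}

#' @rdname baselines
#' @export
subgraph_centrality <- function(edges, nodes = NULL) {
  g <- as_ppi_igraph(edges, nodes)
  A <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = TRUE))
  if (nrow(A) == 0L) return(baseline_tbl(g, numeric()))
  eig <- eigen(A, symmetric = TRUE)
  score <- as.numeric((eig$vectors^2) %*% exp(eig$values))
  baseline_tbl(g, score)
}

# edges among each node's neighbors; shared by LAC and LID
neighborhood_edge_counts <- function(g) {
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  vapply(adj, function(nb) {
    if (length(nb) < 2L) return(0)
    as.numeric(igraph::ecount(igraph::induced_subgraph(g, nb)))
  }, numeric(1))
}

#' @rdname baselines
#' @export
lac <- function(edges, nodes = NULL) {
  g <- as_ppi_igraph(edges, nodes)
  deg <- igraph::degree(g)
  e_n <- neighborhood_edge_counts(g)
  # mean within-neighborhood degree of the neighbors = 2 e_N / deg
  baseline_tbl(g, ifelse(deg == 0, 0, 2 * e_n / deg))
}

#' @rdname baselines
#' @export
lid <- function(edges, nodes = NULL) {
  g <- as_ppi_igraph(edges, nodes)
  baseline_tbl(g, neighborhood_edge_counts(g))
}

#' @rdname baselines
#' @param methods Which baselines to compute, a subset of
#'   `c("DC", "BC", "CloseC", "ClusterC", "SC", "LAC", "LID")`.
#' @return For `centrality_scores()`: long tibble `method`, `protein`,
#'   `score`.
#' @export
centrality_scores <- function(edges, methods = names(baseline_methods),
                              nodes = NULL) {
  unknown <- setdiff(methods, names(baseline_methods))
  if (length(unknown) > 0) {
    abort(sprintf("unknown method %s; available: %s", shQuote(unknown[1]),
                  paste(names(baseline_methods), collapse = ", ")))
  }
  purrr::map(methods, function(m) {
    baseline_methods[[m]](edges, nodes = nodes) |>
      mutate(method = m, .before = 1)
  }) |>
    bind_rows()
}

baseline_methods <- list(
  DC = degree_centrality,
  BC = betweenness_centrality,
  CloseC = closeness_centrality,
  ClusterC = clustering_coefficient,
  SC = subgraph_centrality,
  LAC = lac,
  LID = lid
)
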