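#' Read and clean a PPI edge list
#'
#' Reads a two-column, delimiter-separated edge list of protein identifiers
#' (the flat format DIP/MIPS-style dumps export), drops self-interactions and
#' repeated interactions (an edge and its reverse count as one), and returns
#' a tidy edge table. Extra columns beyond the first two are ignored; lines
#' starting with `#` are skipped. Identifiers are case-sensitive opaque
#' strings; no normalization is applied.
#'
#' @param file Path to a text file, or a character vector of lines.
#' @param delim Field delimiter (default tab).
#' @param quiet Suppress the cleaning summary message.
#'
#' @return A tibble with columns `protein_a` and `protein_b`, one row per
#'   unique undirected interaction. The full node set (identical to the union
#'   of the two columns for files, which cannot carry isolated nodes) is
#'   attached as attribute `"nodes"`.
#'
#' @examples
#' edges <- read_edge_list(c("A\tB", "B\tA", "A\tA", "B\tC"))
#' edges
#' @export
read_edge_list <- function(file, delim = "\t", quiet = FALSE) {
  lines <- if (length(file) == 1L && !grepl("[\t\n]", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    as.character(file)
  }
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(new_ppi_edges(tibble(protein_a = character(), protein_b = character()),
                         nodes = character()))
  }
  fields <- strsplit(lines, delim, fixed = TRUE)
  bad <- which(lengths(fields) < 2L | vapply(fields, function(f) {
    !nzchar(f[1]) || !nzchar(f[2])
  }, logical(1)))
  if (length(bad) > 0L) {
    abort(sprintf("malformed edge-list line %d: need at least 2 non-empty fields, got %s",
                  lineno[bad[1]], shQuote(lines[bad[1]])))
  }
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  n_raw <- length(a)
  self <- a == b
  a <- a[!self]; b <- b[!self]
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dup <- duplicated(key)
  edges <- tibble(protein_a = a[!dup], protein_b = b[!dup])
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b,
                         vapply(fields, `[`, character(1), 1L),
                         vapply(fields, `[`, character(1), 2L))))
  if (!quiet) {
    inform(sprintf(
      "read %d interaction records: dropped %d self-interaction(s), %d repeated interaction(s); %d nodes, %d edges",
      n_raw, sum(self), sum(dup), length(nodes), nrow(edges)))
  }
  new_ppi_edges(edges, nodes = nodes)
}

#' Write an edge list back to TSV
#'
#' @param edges Edge tibble as returned by [read_edge_list()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_edge_list <- function(edges, file) {
  readr::write_tsv(edges[c("protein_a", "protein_b")], file, col_names = FALSE)
  invisible(file)
}

new_ppi_edges <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  attr(edges, "nodes") <- nodes
  edges
}

#' All node identifiers of an edge table
#'
#' Returns the attached node set when present (which may include isolated
#' nodes), otherwise the union of the two endpoint columns.
#'
#' @param edges Edge tibble.
#' @param nodes Optional explicit node set overriding both.
#' @return Character vector of protein identifiers.
#' @export
network_nodes <- function(edges, nodes = NULL) {
  if (!is.null(nodes)) return(as.character(nodes))
  n <- attr(edges, "nodes")
  if (!is.null(n)) return(n)
  sort(unique(c(edges$protein_a, edges$protein_b)))
}

# igraph view of the edge table; isolated nodes carried via `nodes`
as_ppi_igraph <- function(edges, nodes = NULL) {
  nodes <- network_nodes(edges, nodes)
  el <- as.matrix(edges[c("protein_a", "protein_b")])
  storage.mode(el) <- "character"
  igraph::graph_from_edgelist(el, directed = FALSE) |>
    igraph::add_vertices(length(setdiff(nodes, c(el))),
                         name = setdiff(nodes, c(el)))
}

check_node <- function(nodes, v) {
  if (!v %in% nodes) abort(sprintf("node %s is not in the network", shQuote(v)))
}

#' Shortest-path distance profile of one protein
#'
#' Breadth-first-search hop distances from `node` to every protein in its
#' connected component. The source itself appears with distance 0;
#' unreachable proteins are absent.
#'
#' @inheritParams network_nodes
#' @param node Source protein identifier; must be in the network.
#' @return Tibble with columns `protein`, `distance` (integer hops),
#'   sorted by increasing distance then identifier.
#' @export
single_source_distances <- function(edges, node, nodes = NULL) {
  nodes <- network_nodes(edges, nodes)
  check_node(nodes, node)
  g <- as_ppi_igraph(edges, nodes)
  d <- igraph::distances(g, v = node)[1, ]
  d <- d[is.finite(d)]
  tibble(protein = names(d), distance = as.integer(d)) |>
    arrange(.data$distance, .data$protein)
}

#' Eccentricity of a protein within its component
#'
#' Maximum shortest-path distance from `node` to any protein in its connected
#' component; 0 for an isolated node.
#'
#' @inheritParams single_source_distances
#' @return Integer eccentricity.
#' @export
node_eccentricity <- function(edges, node, nodes = NULL) {
  max(single_source_distances(edges, node, nodes)$distance)
}

#' Induced neighborhood subgraph
#'
#' The subgraph on a protein's direct interaction partners (the protein itself
#' excluded) with all interactions among them — the local structure LAC, LID
#' and the clustering coefficient are built on.
#'
#' @inheritParams single_source_distances
#' @return Edge tibble over the neighbor set, with the neighbor identifiers
#'   (including any that end up isolated) attached as attribute `"nodes"`.
#' @export
induced_neighborhood <- function(edges, node, nodes = NULL) {
  all_nodes <- network_nodes(edges, nodes)
  check_node(all_nodes, node)
  nb <- unique(c(edges$protein_b[edges$protein_a == node],
                 edges$protein_a[edges$protein_b == node]))
  sub <- edges |>
    filter(.data$protein_a %in% nb, .data$protein_b %in% nb)
  new_ppi_edges(sub[c("protein_a", "protein_b")], nodes = sort(nb))
}

#' Summarise a PPI network
#'
#' @inheritParams network_nodes
#' @return One-row tibble: `n_nodes`, `n_edges`, `n_components`,
#'   `largest_component`.
#' @export
network_summary <- function(edges, nodes = NULL) {
  g <- as_ppi_igraph(edges, nodes)
  comp <- igraph::components(g)
  tibble(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
         n_components = comp$no,
         largest_component = if (comp$no > 0) max(comp$csize) else 0L)
}
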