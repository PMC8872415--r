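#' The Krackhardt kite network
#'
#' The classic 10-node, 18-edge kite: nodes labeled "1".."10" with node 7
#' the degree-6 hub and 8–9–10 the tail, so distances from node 7 are six
#' nodes at 1 hop and one node each at 2, 3 and 4 hops. The standard small
#' worked example for local (fuzzy) fractal dimensions.
#'
#' @return Edge tibble (`protein_a`, `protein_b`).
#' @examples
#' node_eccentricity(kite_network(), "7")
#' @export
kite_network <- function() {
  el <- matrix(c(1,2, 1,3, 1,5, 1,7, 2,4, 2,6, 2,7, 3,5, 3,7, 4,6, 4,7,
                 5,6, 5,7, 5,8, 6,7, 6,8, 8,9, 9,10),
               ncol = 2, byrow = TRUE)
  new_ppi_edges(tibble(protein_a = as.character(el[, 1]),
                       protein_b = as.character(el[, 2])))
}

#' A layered tree with sphere counts 6, 11, 15, 19
#'
#' A fixed 19-node tree whose center "v" sees 5 nodes at distance 1, 5 at
#' distance 2, 4 at distance 3 and 4 at distance 4 — cumulative sphere
#' counts `B(r) = 6, 11, 15, 19` — the canonical small example for the
#' local fractal dimension (OLS slope 0.8295). Any tree realizing these
#' counts gives the same LFD; this one chains one extra child under each of
#' the first branches.
#'
#' @return Edge tibble; the designated center node is `"v"`.
#' @export
layered_tree_network <- function() {
  edges <- c(
    paste0("v\ta", 1:5),
    paste0("a", 1:5, "\tb", 1:5),
    paste0("b", 1:4, "\tc", 1:4),
    paste0("c", 1:4, "\td", 1:4)
  )
  parts <- strsplit(edges, "\t", fixed = TRUE)
  new_ppi_edges(tibble(protein_a = vapply(parts, `[`, character(1), 1),
                       protein_b = vapply(parts, `[`, character(1), 2)))
}

#' Simulate a scale-free PPI network
#'
#' Preferential attachment (Barabási–Albert): start from a complete graph on
#' `m + 1` nodes; each subsequent node attaches `m` edges to distinct
#' existing nodes chosen with probability proportional to their current
#' degree. Yields the connected, heavy-tailed degree structure typical of
#' cleaned yeast interactomes. Bit-for-bit reproducible from `seed`.
#'
#' @param n Number of proteins (`n >= m + 1`).
#' @param m Edges added per new node (`m >= 1`).
#' @param seed Integer seed; all randomness flows through it.
#' @return Edge tibble over proteins "P0001".."P<n>", with
#'   `choose(m + 1, 2) + (n - m - 1) * m` edges.
#' @export
simulate_ppi <- function(n, m = 3, seed = 1) {
  if (!(m >= 1 && n >= m + 1)) abort("need n >= m + 1 >= 2")
  ids <- sprintf("P%04d", seq_len(n))
  withr::with_seed(seed, {
    init <- t(utils::combn(m + 1, 2))
    from <- init[, 1]; to <- init[, 2]
    deg <- integer(n)
    deg[seq_len(m + 1)] <- m
    for (v in seq(m + 2, length.out = n - m - 1)) {
      existing <- seq_len(v - 1)
      targets <- sample(existing, size = m, prob = deg[existing])
      from <- c(from, rep(v, m)); to <- c(to, targets)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
    }
  })
  new_ppi_edges(tibble(protein_a = ids[from], protein_b = ids[to]),
                nodes = ids)
}

#' Plant essential proteins with a degree bias
#'
#' Samples `ceiling(fraction * n)` proteins without replacement with
#' probability proportional to `degree^degree_bias`, emulating the
#' centrality–lethality structure of real interactomes (hubs are more often
#' essential). `degree_bias = 0` is a uniform draw.
#'
#' @inheritParams network_nodes
#' @param fraction Essential fraction, in (0, 1).
#' @param degree_bias Exponent on degree (>= 0).
#' @param seed Integer seed.
#' @return Sorted character vector of essential protein identifiers.
#' @export
plant_essentials <- function(edges, fraction = 0.23, degree_bias = 2,
                             seed = 1, nodes = NULL) {
  if (!(fraction > 0 && fraction < 1)) abort("fraction must be in (0, 1)")
  if (degree_bias < 0) abort("degree_bias must be >= 0")
  g <- as_ppi_igraph(edges, nodes)
  ids <- igraph::V(g)$name
  deg <- as.numeric(igraph::degree(g))
  w <- deg^degree_bias
  if (all(w == 0)) w <- rep(1, length(w))
  n_ess <- ceiling(fraction * length(ids))
  withr::with_seed(seed, sort(sample(ids, n_ess, prob = w)))
}

#' Plant compartment annotations with essential enrichment
#'
#' Assigns each protein 1–3 of the 11 compartments; a designated
#' essential-rich trio (Nucleus, Mitochondrion, Cytosol — the compartments
#' where essential yeast proteins concentrate) has its sampling weight
#' multiplied by `enrichment` for essential proteins, so compartment scores
#' carry real signal when `enrichment > 1` and none when it equals 1. About
#' 5% of proteins are left unannotated (SCS 0 downstream).
#'
#' @inheritParams plant_essentials
#' @param essentials Character vector of essential protein identifiers.
#' @param enrichment Multiplicative weight (>= 1) on the essential-rich
#'   compartments for essential proteins.
#' @param compartments Compartment vocabulary; the first three of
#'   `rich` must belong to it.
#' @param rich The essential-rich compartment names.
#' @param p_unannotated Fraction of proteins with no annotation.
#' @return Annotation tibble (`protein`, `compartment`; `NA` compartment for
#'   unannotated proteins).
#' @export
plant_annotations <- function(edges, essentials, enrichment = 5, seed = 1,
                              compartments = yeast_compartments,
                              rich = c("Nucleus", "Mitochondrion", "Cytosol"),
                              p_unannotated = 0.05, nodes = NULL) {
  if (enrichment < 1) abort("enrichment must be >= 1")
  stopifnot(all(rich %in% compartments))
  ids <- network_nodes(edges, nodes)
  withr::with_seed(seed, {
    rows <- purrr::map(ids, function(p) {
      if (stats::runif(1) < p_unannotated) {
        return(tibble(protein = p, compartment = NA_character_))
      }
      w <- rep(1, length(compartments))
      if (p %in% essentials) w[compartments %in% rich] <- enrichment
      k <- sample(1:3, 1)
      tibble(protein = p, compartment = sort(sample(compartments, k, prob = w)))
    })
  })
  bind_rows(rows)
}

#' Simulate a complete benchmark dataset
#'
#' One call bundling network, planted essentials, the complementary
#' non-essential set, and enriched annotations. Defaults emulate a
#' scaled-down cleaned yeast interactome: 1000 proteins at mean degree ~6,
#' essential fraction 0.23, strong hub bias and strong compartment
#' enrichment.
#'
#' @inheritParams simulate_ppi
#' @inheritParams plant_essentials
#' @inheritParams plant_annotations
#' @return List with `edges`, `essentials`, `nonessentials`, `annotations`,
#'   `params`.
#' @export
simulate_ppi_dataset <- function(n = 1000, m = 3, fraction = 0.23,
                                 degree_bias = 2, enrichment = 5, seed = 1) {
  edges <- simulate_ppi(n, m, seed = seed)
  essentials <- plant_essentials(edges, fraction, degree_bias, seed = seed + 1)
  annotations <- plant_annotations(edges, essentials, enrichment, seed = seed + 2)
  list(edges = edges,
       essentials = essentials,
       nonessentials = setdiff(network_nodes(edges), essentials),
       annotations = annotations,
       params = list(n = n, m = m, fraction = fraction,
                     degree_bias = degree_bias, enrichment = enrichment,
                     seed = seed))
}
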