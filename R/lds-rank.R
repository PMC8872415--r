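#' Min-max normalization
#'
#' Rescales values to `[0, 1]` as `(x - min) / (max - min)`. A constant
#' vector maps to all zeros (the degenerate case where no value stands out).
#'
#' @param x Non-empty numeric vector (names preserved).
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0L) abort("cannot min-max normalize an empty vector")
  rng <- range(x)
  if (rng[1] == rng[2]) return(setNames(rep(0, length(x)), names(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Deterministic descending ranking of proteins
#'
#' Orders proteins by decreasing score. Ties — common for the compartment
#' score, which takes few distinct values — are broken by decreasing network
#' degree, then increasing identifier, so the ranking is fully reproducible.
#'
#' @param scores Tibble with columns `protein`, `score`, and optionally
#'   `degree` (missing degrees count as 0).
#' @return Character vector of protein identifiers, best first.
#' @export
rank_proteins <- function(scores) {
  stopifnot(nrow(scores) >= 1)
  deg <- if ("degree" %in% names(scores)) scores$degree else rep(0, nrow(scores))
  scores$protein[order(-scores$score, -deg, scores$protein)]
}

#' Fuse topology and localization into the LDS score and rank
#'
#' Computes, per protein, the convex combination
#' `LDS(v) = alpha * ND_f(v) + (1 - alpha) * SCS(v)`, where `ND_f` is the
#' min-max-normalized local fuzzy fractal dimension and SCS the subcellular
#' compartment score. `alpha = 1` ranks on topology alone, `alpha = 0` on
#' localization alone. Proteins missing from the SCS table get SCS 0 (the
#' null-annotation rule).
#'
#' @param fractal Tibble with columns `protein` and `lffd`, e.g. from
#'   [fractal_dimensions()]; defines the ranked universe.
#' @param scs Tibble with columns `protein` and `scs`, e.g. from
#'   [protein_scs()].
#' @param alpha Weight on topology, in `[0, 1]`.
#' @param edges Optional edge tibble used to attach degrees for
#'   deterministic tie-breaking.
#' @return An `lds_ranking` tibble with columns `rank`, `protein`, `lffd`,
#'   `nd_f`, `scs`, `lds`, `degree`, sorted by rank; `alpha` is attached as
#'   an attribute and reported by [glance()].
#' @examples
#' net <- kite_network()
#' fd <- suppressWarnings(fractal_dimensions(net))
#' scs <- tibble::tibble(protein = as.character(1:10), scs = 0)
#' lds_scores(fd, scs, alpha = 1, edges = net)
#' @export
lds_scores <- function(fractal, scs, alpha = 0.5, edges = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    abort("alpha must be a single number in [0, 1]")
  }
  stopifnot(nrow(fractal) >= 1)
  deg <- if (is.null(edges)) {
    tibble(protein = fractal$protein, degree = 0L)
  } else {
    g <- as_ppi_igraph(edges, nodes = network_nodes(edges))
    tibble(protein = igraph::V(g)$name, degree = as.integer(igraph::degree(g)))
  }
  out <- fractal[c("protein", "lffd")] |>
    left_join(scs[c("protein", "scs")], by = "protein") |>
    left_join(deg, by = "protein") |>
    mutate(
      scs = ifelse(is.na(.data$scs), 0, .data$scs),
      degree = ifelse(is.na(.data$degree), 0L, .data$degree),
      nd_f = minmax_normalize(.data$lffd),
      lds = alpha * .data$nd_f + (1 - alpha) * .data$scs
    )
  ord <- order(-out$lds, -out$degree, out$protein)
  out <- out[ord, ] |>
    mutate(rank = row_number()) |>
    select("rank", "protein", "lffd", "nd_f", "scs", "lds", "degree")
  structure(out, class = c("lds_ranking", class(out)), alpha = alpha)
}

#' @rdname lds_scores
#' @param x An `lds_ranking`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lds_ranking <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname lds_scores
#' @exportS3Method generics::glance
glance.lds_ranking <- function(x, ...) {
  tibble(alpha = attr(x, "alpha"), n_proteins = nrow(x),
         mean_lds = mean(x$lds), n_unannotated = sum(x$scs == 0))
}

#' Sweep the topology weight alpha
#'
#' Recomputes the LDS ranking over a grid of `alpha` values and counts true
#' essentials among the top `k` for each cutoff — the standard way to see
#' how much each information source contributes on a given network.
#'
#' @inheritParams lds_scores
#' @param essentials Character vector of known essential proteins.
#' @param alphas Grid of weights in `[0, 1]` (duplicates are dropped with a
#'   warning).
#' @param ks Top-k cutoffs to evaluate.
#' @return An `alpha_sweep` tibble: one row per (alpha, k) with
#'   `essential_count`.
#' @export
alpha_sweep <- function(fractal, scs, essentials, edges = NULL,
                        alphas = seq(0, 1, by = 0.1),
                        ks = seq(1000, 1500, by = 100)) {
  if (any(alphas < 0 | alphas > 1)) abort("all alpha values must lie in [0, 1]")
  if (anyDuplicated(alphas)) {
    warn("duplicate alpha values dropped")
    alphas <- unique(alphas)
  }
  rows <- purrr::map(alphas, function(a) {
    ranking <- lds_scores(fractal, scs, alpha = a, edges = edges)
    tibble(alpha = a, k = as.integer(ks),
           essential_count = vapply(ks, function(k) {
             topk_essential_count(ranking$protein, essentials, k)
           }, integer(1)))
  })
  out <- bind_rows(rows)
  structure(out, class = c("alpha_sweep", class(out)))
}

#' @rdname alpha_sweep
#' @param object An `alpha_sweep` result.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.alpha_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$alpha, .data$essential_count,
                                       colour = factor(.data$k))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(alpha), y = "essential proteins in top k",
                  colour = "k")
}
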