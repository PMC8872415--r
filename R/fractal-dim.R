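#' Gaussian membership of a node at hop distance d and radius r
#'
#' The fuzzy-set weight `exp(-d^2 / (2 r^2))` that grades how much a node at
#' shortest-path distance `d` contributes to a sphere of topological radius
#' `r`: 1 at the center, decaying with distance. Vectorized over both
#' arguments.
#'
#' @param d Non-negative hop distance(s).
#' @param r Positive integer radius (zero is undefined and raises an error).
#' @return Membership value(s) in (0, 1].
#' @examples
#' gaussian_membership(1, 1)   # exp(-1/2)
#' @export
gaussian_membership <- function(d, r) {
  if (any(r <= 0)) abort("gaussian_membership is undefined for radius r = 0")
  if (any(d < 0)) abort("hop distance d must be non-negative")
  exp(-d^2 / (2 * r^2))
}

#' Cumulative sphere counts around one protein
#'
#' `B(r)`, the total number of nodes (center included) within hop distance
#' `r` of the source, for `r = 1` up to the source's eccentricity. These are
#' the counts whose log-log slope against `r` is the local fractal dimension.
#'
#' @param profile Distance tibble from [single_source_distances()].
#' @return Tibble with columns `r` and `count`; zero rows for an isolated
#'   node (eccentricity 0).
#' @export
sphere_counts <- function(profile) {
  stopifnot(nrow(profile) >= 1)
  ecc <- max(profile$distance)
  if (ecc == 0L) return(tibble(r = integer(), count = integer()))
  tibble(
    r = seq_len(ecc),
    count = vapply(seq_len(ecc), function(r) sum(profile$distance <= r), integer(1))
  )
}

#' Fuzzy sphere values around one protein
#'
#' `N(r)`: the mean Gaussian membership [gaussian_membership()] over all
#' nodes at distance at most `r` from the source (center included, its
#' `e^0 = 1` term always present), for `r = 1` up to the eccentricity.
#'
#' @inheritParams sphere_counts
#' @return Tibble with columns `r` and `value` (each in (0, 1]).
#' @export
fuzzy_sphere_values <- function(profile) {
  stopifnot(nrow(profile) >= 1)
  ecc <- max(profile$distance)
  if (ecc == 0L) return(tibble(r = integer(), value = numeric()))
  tibble(
    r = seq_len(ecc),
    value = vapply(seq_len(ecc), function(r) {
      d <- profile$distance[profile$distance <= r]
      mean(gaussian_membership(d, r))
    }, numeric(1))
  )
}

#' Fuzzy sphere value at a single radius
#'
#' @inheritParams sphere_counts
#' @param r Radius (>= 1).
#' @return The mean membership over nodes with distance <= r.
#' @export
fuzzy_sphere_value <- function(profile, r) {
  stopifnot(r >= 1)
  d <- profile$distance[profile$distance <= r]
  mean(gaussian_membership(d, r))
}

#' Log-log least-squares fit
#'
#' Ordinary least squares of `ln y` on `ln r` over all supplied points — the
#' fit convention behind both the local fractal dimension and its fuzzy
#' variant. The `r = 1` point participates (contributing `ln r = 0`); no
#' point is dropped or weighted.
#'
#' @param r Radii (positive, at least two distinct values for a fit).
#' @param y Positive response values, same length as `r`.
#' @return A `fractal_fit` object: list with `points` (tibble `r`, `y`),
#'   `slope`, `intercept` (of `ln y` vs `ln r`, natural logs), `n_points`.
#'   With fewer than two distinct radii the fit is unfittable: `slope` and
#'   `intercept` are `NA`.
#' @examples
#' loglog_fit(1:3, c(1, 4, 9))$slope   # exactly 2
#' @export
loglog_fit <- function(r, y) {
  stopifnot(length(r) == length(y))
  if (any(y <= 0)) abort("log-log fit requires strictly positive y values")
  if (any(r <= 0)) abort("log-log fit requires strictly positive radii")
  ord <- order(r)
  r <- r[ord]; y <- y[ord]
  out <- list(points = tibble(r = r, y = y), slope = NA_real_,
              intercept = NA_real_, n_points = length(r))
  if (length(unique(r)) >= 2L) {
    fit <- lm(log(y) ~ log(r))
    out$slope <- unname(coef(fit)[2])
    out$intercept <- unname(coef(fit)[1])
  }
  structure(out, class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> %d points; slope %s, intercept %s\n", x$n_points,
              format(x$slope, digits = 6), format(x$intercept, digits = 6)))
  invisible(x)
}

#' @rdname loglog_fit
#' @param x A `fractal_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fractal_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"), estimate = c(x$intercept, x$slope))
}

#' @rdname loglog_fit
#' @exportS3Method generics::glance
glance.fractal_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, n_points = x$n_points,
         fittable = !is.na(x$slope))
}

#' @rdname loglog_fit
#' @param object A `fractal_fit` object.
#' @exportS3Method ggplot2::autoplot
autoplot.fractal_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(log(.data$r), log(.data$y))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "ln r", y = "ln y",
                  subtitle = sprintf("slope = %.4f", object$slope))
  }

# shared per-node driver over a precomputed distance matrix
fractal_node <- function(drow) {
  d <- drow[is.finite(drow)]
  ecc <- max(d)
  if (ecc < 2) {
    return(list(eccentricity = as.integer(ecc), n_fit_points = as.integer(ecc),
                lfd = NA_real_, lffd = NA_real_))
  }
  rs <- seq_len(ecc)
  counts <- vapply(rs, function(r) sum(d <= r), numeric(1))
  fuzzy <- vapply(rs, function(r) mean(exp(-d[d <= r]^2 / (2 * r^2))), numeric(1))
  list(eccentricity = as.integer(ecc), n_fit_points = length(rs),
       lfd = loglog_fit(rs, counts)$slope,
       lffd = loglog_fit(rs, fuzzy)$slope)
}

#' Local fractal dimensions of every protein
#'
#' For each node `v` the package fits, by ordinary least squares on natural
#' log-log axes over radii `r = 1` to the node's own eccentricity:
#' * **LFD**: slope of `ln B_v(r)` vs `ln r`, where `B_v(r)` counts nodes
#'   within distance `r` (center included);
#' * **LFFD**: slope of `ln N_v(r)` vs `ln r`, where `N_v(r)` is the mean
#'   Gaussian membership over those nodes — nearer nodes weigh more, so the
#'   fuzzy variant discriminates hubs from peripheral nodes more sharply.
#'
#' Nodes with eccentricity below 2 (isolated nodes and nodes whose component
#' is a single edge) have fewer than two fit points; their dimensions are
#' defined as 0 so they rank lowest on topology, and a single warning reports
#' how many were affected.
#'
#' @inheritParams network_nodes
#' @return Tibble with columns `protein`, `eccentricity`, `n_fit_points`,
#'   `lfd`, `lffd`, one row per node, ordered by identifier.
#' @examples
#' fractal_dimensions(kite_network())
#' @export
fractal_dimensions <- function(edges, nodes = NULL) {
  nodes <- network_nodes(edges, nodes)
  if (length(nodes) == 0L) {
    return(tibble(protein = character(), eccentricity = integer(),
                  n_fit_points = integer(), lfd = numeric(), lffd = numeric()))
  }
  g <- as_ppi_igraph(edges, nodes)
  dmat <- igraph::distances(g)
  rows <- lapply(rownames(dmat), function(v) {
    res <- fractal_node(dmat[v, ])
    tibble(protein = v, eccentricity = res$eccentricity,
           n_fit_points = res$n_fit_points, lfd = res$lfd, lffd = res$lffd)
  })
  out <- bind_rows(rows) |> arrange(.data$protein)
  n_deg <- sum(is.na(out$lfd))
  if (n_deg > 0) {
    warn(sprintf("%d node(s) with eccentricity < 2 are unfittable; LFD/LFFD set to 0", n_deg))
    out$lfd[is.na(out$lfd)] <- 0
    out$lffd[is.na(out$lffd)] <- 0
  }
  out
}

#' Local fractal dimension of one protein
#'
#' @inheritParams single_source_distances
#' @return The LFD slope (0, with a warning, when the node's eccentricity is
#'   below 2 and no line can be fitted).
#' @seealso [fractal_dimensions()] for the batch driver and the definition.
#' @export
lfd <- function(edges, node, nodes = NULL) {
  profile <- single_source_distances(edges, node, nodes)
  sc <- sphere_counts(profile)
  if (nrow(sc) < 2L) {
    warn(sprintf("node %s has eccentricity < 2; LFD set to 0", shQuote(node)))
    return(0)
  }
  loglog_fit(sc$r, sc$count)$slope
}

#' Local fuzzy fractal dimension of one protein
#'
#' @inheritParams lfd
#' @return The LFFD slope (0, with a warning, for eccentricity below 2).
#' @seealso [fractal_dimensions()]
#' @export
lffd <- function(edges, node, nodes = NULL) {
  profile <- single_source_distances(edges, node, nodes)
  fv <- fuzzy_sphere_values(profile)
  if (nrow(fv) < 2L) {
    warn(sprintf("node %s has eccentricity < 2; LFFD set to 0", shQuote(node)))
    return(0)
  }
  loglog_fit(fv$r, fv$value)$slope
}
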