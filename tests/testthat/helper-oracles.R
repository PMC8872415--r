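# Independent brute-force oracles, all working from a plain adjacency matrix.
# They deliberately share no code with the package internals.

# random simple graph as an adjacency matrix with node names
random_adjacency <- function(n, p = 0.4, seed = 1, connected = FALSE) {
  withr::with_seed(seed, {
    repeat {
      A <- matrix(0L, n, n)
      A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
      A <- A + t(A)
      rownames(A) <- colnames(A) <- sprintf("n%02d", seq_len(n))
      if (!connected) break
      if (all(is.finite(fw_distances(A)))) break
    }
    A
  })
}

adjacency_to_edges <- function(A) {
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  structure(
    tibble::tibble(protein_a = rownames(A)[idx[, 1]],
                   protein_b = rownames(A)[idx[, 2]]),
    nodes = rownames(A))
}

# Floyd-Warshall all-pairs shortest paths
fw_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# shortest-path counts: for hop distance d, walks of length d are exactly paths
path_counts <- function(A, D) {
  n <- nrow(A)
  maxd <- max(D[is.finite(D)])
  powers <- vector("list", maxd + 1)
  powers[[1]] <- diag(n)
  for (k in seq_len(maxd)) powers[[k + 1]] <- powers[[k]] %*% A
  S <- matrix(0, n, n, dimnames = dimnames(A))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (is.finite(D[i, j])) S[i, j] <- powers[[D[i, j] + 1]][i, j]
  }
  S
}

oracle_betweenness <- function(A) {
  D <- fw_distances(A)
  S <- path_counts(A, D)
  n <- nrow(A)
  bc <- setNames(numeric(n), rownames(A))
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    if (!is.finite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  bc
}

oracle_closeness <- function(A) {
  D <- fw_distances(A)
  apply(D, 1, function(drow) {
    d <- drow[is.finite(drow)]
    if (sum(d) == 0) 0 else (length(d) - 1) / sum(d)
  })
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }) |> setNames(rownames(A))
}

oracle_subgraph_centrality <- function(A, terms = 60) {
  n <- nrow(A)
  acc <- diag(n)
  Ak <- diag(n)
  for (k in seq_len(terms)) {
    Ak <- Ak %*% A
    acc <- acc + Ak / factorial(k)
  }
  setNames(diag(acc), rownames(A))
}

oracle_neighborhood_edges <- function(A, v) {
  nb <- which(A[v, ] == 1)
  if (length(nb) < 2) return(0)
  sum(A[nb, nb]) / 2
}

oracle_lid <- function(A) {
  sapply(seq_len(nrow(A)), oracle_neighborhood_edges, A = A) |>
    setNames(rownames(A))
}

oracle_lac <- function(A) {
  sapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] == 1)
    if (length(nb) == 0) return(0)
    mean(colSums(A[nb, nb, drop = FALSE]))
  }) |> setNames(rownames(A))
}

# LFD/LFFD recomputed straight from the distance matrix with stats::lm
oracle_dimensions <- function(A, v) {
  D <- fw_distances(A)
  d <- D[v, is.finite(D[v, ])]
  ecc <- max(d)
  if (ecc < 2) return(c(lfd = 0, lffd = 0))
  rs <- seq_len(ecc)
  B <- sapply(rs, function(r) sum(d <= r))
  N <- sapply(rs, function(r) mean(exp(-d[d <= r]^2 / (2 * r^2))))
  c(lfd = unname(coef(lm(log(B) ~ log(rs)))[2]),
    lffd = unname(coef(lm(log(N) ~ log(rs)))[2]))
}

# random reference universe + annotation table for Bayes-identity checks
random_annotation_case <- function(seed) {
  withr::with_seed(seed, {
    n_e <- sample(3:30, 1)
    n_ne <- sample(3:60, 1)
    ess <- sprintf("E%03d", seq_len(n_e))
    non <- sprintf("N%03d", seq_len(n_ne))
    ann <- dplyr::bind_rows(lapply(c(ess, non), function(p) {
      k <- sample(0:3, 1)
      if (k == 0) return(tibble::tibble(protein = p, compartment = NA_character_))
      tibble::tibble(protein = p,
                     compartment = sample(ldsrank::yeast_compartments, k))
    }))
    list(annotations = ann, essential = ess, nonessential = non)
  })
}

kite_adjacency <- function() {
  edges <- ldsrank::kite_network()
  ids <- as.character(1:10)
  A <- matrix(0, 10, 10, dimnames = list(ids, ids))
  A[cbind(edges$protein_a, edges$protein_b)] <- 1
  A + t(A)
}

cycle_edges <- function(n) {
  ids <- sprintf("c%03d", seq_len(n))
  structure(
    tibble::tibble(protein_a = ids, protein_b = ids[c(2:n, 1)]),
    nodes = ids)
}

path_edges <- function(ids) {
  structure(
    tibble::tibble(protein_a = ids[-length(ids)], protein_b = ids[-1]),
    nodes = ids)
}
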