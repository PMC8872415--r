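test_that("edge-list reading drops self-interactions and repeated interactions", {
  net <- suppressMessages(read_edge_list(c("A\tB", "B\tA", "A\tA", "B\tC")))
  expect_setequal(network_nodes(net), c("A", "B", "C"))
  expect_equal(nrow(net), 2)
  key <- paste(pmin(net$protein_a, net$protein_b),
               pmax(net$protein_a, net$protein_b))
  expect_setequal(key, c("A B", "B C"))

  empty <- suppressMessages(read_edge_list(character()))
  expect_equal(nrow(empty), 0)
  expect_length(network_nodes(empty), 0)

  # comment lines and extra columns are tolerated
  net2 <- suppressMessages(read_edge_list(c("# header", "A\tB\t0.9", "C\tD")))
  expect_equal(nrow(net2), 2)
})

test_that("malformed lines fail with their line number", {
  expect_error(suppressMessages(read_edge_list(c("A\tB", "oops"))), "line 2")
  expect_error(suppressMessages(read_edge_list(c("A\tB", "X\t"))), "line 2")
})

test_that("the kite edge list round-trips and re-reading is idempotent", {
  kite <- kite_network()
  expect_equal(nrow(kite), 18)
  expect_length(network_nodes(kite), 10)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(kite, path)
  again <- suppressMessages(read_edge_list(path))
  norm <- function(e) {
    sort(paste(pmin(e$protein_a, e$protein_b), pmax(e$protein_a, e$protein_b)))
  }
  expect_identical(norm(again), norm(kite))
  expect_identical(network_nodes(again), sort(network_nodes(kite)))
})

test_that("single-source distances match the worked profiles", {
  kite <- kite_network()
  prof <- single_source_distances(kite, "7")
  expect_equal(sum(prof$distance == 1), 6)
  expect_equal(sum(prof$distance == 2), 1)
  expect_equal(sum(prof$distance == 3), 1)
  expect_equal(sum(prof$distance == 4), 1)
  expect_equal(prof$distance[prof$protein == "7"], 0)

  abc <- path_edges(c("A", "B", "C"))
  prof_a <- single_source_distances(abc, "A")
  expect_equal(setNames(prof_a$distance, prof_a$protein),
               c(A = 0L, B = 1L, C = 2L))

  # disconnected components are omitted from the profile
  two_k2 <- structure(tibble::tibble(protein_a = c("a", "x"),
                                     protein_b = c("b", "y")),
                      nodes = c("a", "b", "x", "y"))
  expect_setequal(single_source_distances(two_k2, "a")$protein, c("a", "b"))

  expect_error(single_source_distances(kite, "Z"), "'Z'")
})

test_that("eccentricity covers hub, isolated and cycle cases", {
  expect_equal(node_eccentricity(kite_network(), "7"), 4)
  iso <- structure(tibble::tibble(protein_a = "a", protein_b = "b"),
                   nodes = c("a", "b", "lonely"))
  expect_equal(node_eccentricity(iso, "lonely"), 0)
  c9 <- cycle_edges(9)
  A <- matrix(0L, 9, 9, dimnames = list(network_nodes(c9), network_nodes(c9)))
  A[cbind(c9$protein_a, c9$protein_b)] <- 1L
  A <- A | t(A)
  expect_equal(node_eccentricity(c9, "c001"), max(fw_distances(A * 1)[1, ]))
  expect_equal(node_eccentricity(c9, "c005"), 4)
})

test_that("induced neighborhoods exclude the center and keep internal edges", {
  tri <- structure(tibble::tibble(protein_a = c("v", "v", "a"),
                                  protein_b = c("a", "b", "b")),
                   nodes = c("v", "a", "b"))
  nb <- induced_neighborhood(tri, "v")
  expect_setequal(network_nodes(nb), c("a", "b"))
  expect_equal(nrow(nb), 1)

  star <- structure(tibble::tibble(protein_a = rep("hub", 3),
                                   protein_b = c("l1", "l2", "l3")),
                    nodes = c("hub", "l1", "l2", "l3"))
  nb2 <- induced_neighborhood(star, "hub")
  expect_length(network_nodes(nb2), 3)
  expect_equal(nrow(nb2), 0)

  kite <- kite_network()
  nb7 <- induced_neighborhood(kite, "7")
  expect_length(network_nodes(nb7), 6)
  # brute-force enumeration of pairs of neighbors against the edge set
  nbs <- network_nodes(nb7)
  key <- paste(pmin(kite$protein_a, kite$protein_b),
               pmax(kite$protein_a, kite$protein_b))
  pairs <- t(combn(sort(nbs), 2))
  expect_equal(nrow(nb7), sum(paste(pairs[, 1], pairs[, 2]) %in% key))
})

test_that("BFS distances agree with Floyd-Warshall and are symmetric on random graphs", {
  for (seed in 1:10) {
    A <- random_adjacency(n = sample(5:50, 1), p = 0.15, seed = seed)
    edges <- adjacency_to_edges(A)
    D <- fw_distances(A)
    for (v in sample(rownames(A), 3)) {
      prof <- single_source_distances(edges, v)
      dv <- D[v, ]
      expected <- dv[is.finite(dv)]
      expect_identical(setNames(prof$distance, prof$protein)[names(expected)],
                       setNames(as.integer(expected), names(expected)))
    }
    # symmetry on sampled pairs
    uv <- sample(rownames(A), 2)
    d_uv <- single_source_distances(edges, uv[1])
    d_vu <- single_source_distances(edges, uv[2])
    if (uv[2] %in% d_uv$protein) {
      expect_equal(d_uv$distance[d_uv$protein == uv[2]],
                   d_vu$distance[d_vu$protein == uv[1]])
    }
  }
})
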