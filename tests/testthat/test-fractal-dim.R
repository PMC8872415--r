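test_that("sphere counts reproduce the layered-tree, path and cycle cases", {
  tree <- layered_tree_network()
  expect_equal(sphere_counts(single_source_distances(tree, "v"))$count,
               c(6, 11, 15, 19))
  expect_length(network_nodes(tree), 19)

  abc <- path_edges(c("A", "B", "C"))
  expect_equal(sphere_counts(single_source_distances(abc, "A"))$count, c(2, 3))

  c9 <- cycle_edges(9)
  expect_equal(sphere_counts(single_source_distances(c9, "c003"))$count,
               c(3, 5, 7, 9))
})

test_that("Gaussian membership matches its closed form and rejects r = 0", {
  expect_equal(gaussian_membership(0, 5), 1.0)
  expect_equal(gaussian_membership(1, 1), exp(-1 / 2))
  expect_equal(gaussian_membership(3, 3), exp(-1 / 2))
  expect_error(gaussian_membership(1, 0), "r = 0")
  expect_error(gaussian_membership(-1, 1), "non-negative")
})

test_that("fuzzy sphere values reproduce the kite hub to 4 decimal places", {
  prof <- single_source_distances(kite_network(), "7")
  expect_equal(round(fuzzy_sphere_value(prof, 1), 4), 0.6627)
  expect_equal(round(fuzzy_sphere_value(prof, 2), 4), 0.8627)
  expect_equal(round(fuzzy_sphere_value(prof, 3), 4), 0.8981)
  expect_equal(round(fuzzy_sphere_value(prof, 4), 4), 0.9059)
  expect_equal(fuzzy_sphere_values(prof)$value,
               sapply(1:4, fuzzy_sphere_value, profile = prof))

  iso <- tibble::tibble(protein = "x", distance = 0L)
  expect_equal(fuzzy_sphere_value(iso, 1), 1.0)
})

test_that("log-log OLS reproduces the two printed slopes and exact power laws", {
  expect_equal(round(loglog_fit(1:4, c(6, 11, 15, 19))$slope, 4), 0.8295)
  expect_equal(loglog_fit(1:3, c(1, 4, 9))$slope, 2.0, tolerance = 1e-12)
  expect_equal(round(loglog_fit(1:4, c(0.6627, 0.8627, 0.8981, 0.9059))$slope, 4),
               0.2312)
  expect_error(loglog_fit(1:2, c(1, -1)), "positive")
  unfit <- loglog_fit(1, 5)
  expect_true(is.na(unfit$slope))
  expect_equal(glance(unfit)$fittable, FALSE)
  expect_equal(tidy(loglog_fit(1:3, c(1, 4, 9)))$estimate[2], 2, tolerance = 1e-12)
})

test_that("LFD and LFFD reproduce the worked examples and degenerate fallbacks", {
  tree <- layered_tree_network()
  expect_equal(round(lfd(tree, "v"), 4), 0.8295)

  kite <- kite_network()
  expect_equal(round(lffd(kite, "7"), 4), 0.2312)

  # eccentricity < 2: dimension defined as 0, with a warning
  k2 <- structure(tibble::tibble(protein_a = "a", protein_b = "b"),
                  nodes = c("a", "b", "iso"))
  expect_warning(v1 <- lfd(k2, "a"), "eccentricity")
  expect_identical(v1, 0)
  expect_warning(v2 <- lffd(k2, "iso"), "eccentricity")
  expect_identical(v2, 0)
  expect_error(lfd(kite, "nope"), "'nope'")
})

test_that("batch dimensions equal per-node calls and the distance-matrix oracle", {
  A <- random_adjacency(30, p = 0.12, seed = 7)
  edges <- adjacency_to_edges(A)
  batch <- suppressWarnings(fractal_dimensions(edges))
  expect_setequal(batch$protein, rownames(A))
  for (v in sample(rownames(A), 6)) {
    orc <- oracle_dimensions(A, v)
    row <- batch[batch$protein == v, ]
    expect_equal(row$lfd, unname(orc["lfd"]), tolerance = 1e-10)
    expect_equal(row$lffd, unname(orc["lffd"]), tolerance = 1e-10)
    if (row$eccentricity >= 2) {
      expect_equal(suppressWarnings(lffd(edges, v)), row$lffd, tolerance = 1e-12)
    }
  }
  # degenerate nodes are exactly 0 in the batch table
  expect_true(all(batch$lfd[batch$eccentricity < 2] == 0))
})

test_that("large odd cycles approach dimension 1 and match the closed-form OLS oracle", {
  c101 <- cycle_edges(101)
  got <- lfd(c101, "c001")
  rs <- 1:50
  oracle <- unname(coef(lm(log(2 * rs + 1) ~ log(rs)))[2])
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_gt(got, 0.85)
  expect_lt(got, 1.0)
})

test_that("sphere counts are cumulative and memberships stay in (0, 1]", {
  for (seed in 1:5) {
    A <- random_adjacency(25, p = 0.15, seed = seed)
    edges <- adjacency_to_edges(A)
    for (v in sample(rownames(A), 4)) {
      prof <- single_source_distances(edges, v)
      sc <- sphere_counts(prof)
      if (nrow(sc) > 1) expect_true(all(diff(sc$count) >= 0))
      if (nrow(sc) > 0) expect_equal(sc$count[nrow(sc)], nrow(prof))
      fv <- fuzzy_sphere_values(prof)
      expect_true(all(fv$value > 0 & fv$value <= 1))
    }
  }
})
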