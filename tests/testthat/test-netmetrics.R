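test_that("density-matched binarization keeps exactly the top K edges with a deterministic tie rule", {
  vals <- matrix(0, 4, 4)
  ut <- c(0.9, 0.1, 0.8, 0.5, 0.3, 0.7)  # (1,2) (1,3) (2,3) (1,4) (2,4) (3,4)
  vals[upper.tri(vals)] <- ut
  vals <- vals + t(vals)
  diag(vals) <- 1
  net <- binarize_to_density(fc_matrix(vals, "correlation"), 0.5)
  expect_equal(net$m, 3)
  expect_equal(net$a[1, 2], 1)  # 0.9
  expect_equal(net$a[2, 3], 1)  # 0.8
  expect_equal(net$a[3, 4], 1)  # 0.7
  expect_equal(net$a[1, 3], 0)
  expect_equal(net$a[1, 4], 0)
  # binary input at its own density reproduces itself
  a <- net$a
  diag(a) <- 1
  again <- binarize_to_density(fc_matrix(a, "correlation"), 0.5)
  expect_identical(again$a, net$a)
  # all-equal values: lexicographically first K pairs, reproducibly
  flat <- matrix(0.5, 4, 4)
  diag(flat) <- 1
  tie1 <- binarize_to_density(fc_matrix(flat, "correlation"), 1 / 3)
  tie2 <- binarize_to_density(fc_matrix(flat, "correlation"), 1 / 3)
  expect_identical(tie1$a, tie2$a)
  expect_equal(which(tie1$a[upper.tri(tie1$a)] == 1), c(1, 2))
  expect_error(binarize_to_density(fc_matrix(flat, "correlation"), 0.01),
               "nothing to threshold")
})

test_that("path length matches hand-counted values including disconnected graphs", {
  full <- binary_network(1 - diag(4))
  expect_equal(average_path_length(full)$L, 1)
  ring4 <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; ring4[i, j] <- 1; ring4[j, i] <- 1 }
  expect_equal(average_path_length(binary_network(ring4))$L, 4 / 3)
  # two disjoint triangles: L = 1 over connected pairs, 60% of pairs disconnected
  tri2 <- matrix(0, 6, 6)
  tri2[1:3, 1:3] <- 1; tri2[4:6, 4:6] <- 1
  diag(tri2) <- 0
  pl <- average_path_length(binary_network(tri2))
  expect_equal(pl$L, 1)
  expect_equal(pl$disconnected_pair_fraction, 0.6)
  expect_error(average_path_length(binary_network(matrix(0, 3, 3))),
               "edgeless")
})

test_that("clustering matches exhaustive triangle counting", {
  tri <- binary_network(1 - diag(3))
  expect_equal(clustering_coefficient(tri), 1)
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- 1; star[2:5, 1] <- 1
  expect_equal(clustering_coefficient(binary_network(star)), 0)
  # 4-cycle plus one diagonal: local c = (2/3, 1, 2/3, 1)
  g <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3))) {
    g[e[1], e[2]] <- 1; g[e[2], e[1]] <- 1
  }
  expect_equal(clustering_coefficient(binary_network(g)), 5 / 6)
  expect_equal(clustering_coefficient(binary_network(g)), oracle_clustering(g))
})

test_that("L and C agree with Floyd-Warshall and triangle oracles on random graphs", {
  set.seed(14)
  for (k in 1:40) {
    n <- sample(4:7, 1)
    a <- random_undirected(n, runif(1, 0.2, 0.8))
    if (sum(a) == 0) next
    net <- binary_network(a)
    pl <- average_path_length(net)
    want <- oracle_path_length(a)
    expect_equal(pl$L, want$L, tolerance = 1e-12)
    expect_equal(pl$disconnected_pair_fraction, want$frac_disconnected)
    expect_equal(clustering_coefficient(net), oracle_clustering(a),
                 tolerance = 1e-12)
  }
})

test_that("Erdos-Renyi reference behaves like its ensemble and is seeded", {
  ref <- random_reference(12, 66, n_samples = 10, seed = 1)   # complete graph
  expect_equal(ref$L_rand, 1)
  expect_equal(ref$C_rand, 1)
  ref1 <- random_reference(20, 60, n_samples = 30, seed = 5)
  ref2 <- random_reference(20, 60, n_samples = 30, seed = 5)
  expect_equal(ref1$L_rand, ref2$L_rand)
  # C_rand ~ density for G(n, m)
  n <- 40; m <- 156  # density 0.2
  ref3 <- random_reference(n, m, n_samples = 60, seed = 2)
  se <- sd(ref3$C_draws) / sqrt(60)
  expect_lt(abs(ref3$C_rand - 0.2), 3 * se + 0.01)
  expect_error(random_reference(5, 100), "out of range")
  expect_error(random_reference(5, 4, n_samples = 5), "n_samples")
})

test_that("small-world index is ~1 for random graphs and >> 1 for ring lattices with shortcuts", {
  set.seed(6)
  n <- 24; m <- 72
  ref <- random_reference(n, m, n_samples = 100, seed = 3)
  g <- igraph::sample_gnm(n, m)
  net <- binary_network(as.matrix(igraph::as_adjacency_matrix(g)))
  sw <- small_world_index(net, ref)
  expect_gt(sw$sw_index, 0.6)
  expect_lt(sw$sw_index, 1.5)
  # ring lattice with k = 3 neighbours per side and a couple of shortcuts
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in 1:3) {
    j <- (i + d - 1) %% n + 1
    a[i, j] <- 1; a[j, i] <- 1
  }
  a[1, 12] <- a[12, 1] <- 1
  a[5, 18] <- a[18, 5] <- 1
  net_ws <- binary_network(a)
  ref_ws <- random_reference(n, net_ws$m, n_samples = 100, seed = 4)
  sw_ws <- small_world_index(net_ws, ref_ws)
  expect_gt(sw_ws$sw_index, 1.5)
  expect_gt(sw_ws$sw_index, 1.5 * sw$sw_index)
  # complete graph: all three relative coefficients are 1
  full <- binary_network(1 - diag(6))
  ref_full <- random_reference(6, 15, n_samples = 10, seed = 1)
  sw_full <- small_world_index(full, ref_full)
  expect_equal(sw_full$lambda, 1)
  expect_equal(sw_full$gamma, 1)
  expect_equal(sw_full$sw_index, 1)
})

test_that("Jaccard similarity counts shared links over the union and is symmetric", {
  a <- matrix(0, 3, 3); a[2, 1] <- a[1, 2] <- 1; a[3, 1] <- 1
  b <- matrix(0, 3, 3); b[2, 1] <- b[1, 2] <- 1; b[3, 2] <- 1
  expect_equal(jaccard_similarity(a, b), 0.5)   # 2 shared of 4 total
  expect_equal(jaccard_similarity(b, a), 0.5)
  expect_equal(jaccard_similarity(a, a), 1)
  d1 <- matrix(0, 3, 3); d1[1, 2] <- 1
  d2 <- matrix(0, 3, 3); d2[2, 3] <- 1
  expect_equal(jaccard_similarity(d1, d2), 0)
  expect_error(jaccard_similarity(matrix(0, 3, 3), matrix(0, 4, 4)),
               "size mismatch")
  expect_warning(j0 <- jaccard_similarity(matrix(0, 3, 3), matrix(0, 3, 3)),
                 "undefined")
  expect_true(is.nan(j0))
})

test_that("agreement decays in expectation as one network is rewired away from the other", {
  sc <- modular_sc(3, 4)
  base <- sc_to_binary(sc)
  js <- vapply(c(1, 5, 20), function(spe) {
    mean(vapply(1:10, function(s) {
      rw <- sc_to_binary(rewire_degree_preserving(sc, spe, seed = s))
      jaccard_similarity(base, rw)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(js) <= 0.05))  # non-increasing in expectation
  expect_lt(js[3], 1)
})
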