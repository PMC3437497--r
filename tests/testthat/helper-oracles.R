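# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: exhaustive graph algorithms, brute-force
# root scans, direct formula evaluation.

# All-pairs shortest paths by Floyd-Warshall on a dense matrix.
oracle_floyd_warshall <- function(a) {
  n <- nrow(a)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[a == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_path_length <- function(a) {
  D <- oracle_floyd_warshall(a)
  off <- D[row(D) != col(D)]
  list(L = mean(off[is.finite(off)]), frac_disconnected = mean(!is.finite(off)))
}

# Average local clustering by brute-force neighbour-pair enumeration.
oracle_clustering <- function(a) {
  n <- nrow(a)
  cs <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (p in seq_len(k - 1)) {
      for (q in (p + 1):k) links <- links + a[nb[p], nb[q]]
    }
    links / (k * (k - 1) / 2)
  }, numeric(1))
  mean(cs)
}

# Random symmetric binary adjacency on n nodes with edge probability p.
random_undirected <- function(n, p) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  a[up] <- as.numeric(runif(sum(up)) < p)
  a + t(a)
}

# Fixed points of the node by an independent route: for each u on a dense
# grid solve the v-nullcline with uniroot (dv/dt is strictly decreasing in
# v), then bracket sign changes of du/dt along the nullcline.
oracle_fixed_points <- function(params, n_grid = 4001) {
  v_null <- function(u) {
    uniroot(function(v) -v + firing_rate(params$c3 * u - params$c4 * v + params$Q),
            c(-1, 2), tol = 1e-13)$root
  }
  g <- function(u) {
    v <- v_null(u)
    -u + firing_rate(params$c1 * u - params$c2 * v + params$P)
  }
  ug <- seq(-0.25, 1.25, length.out = n_grid)
  gv <- vapply(ug, g, numeric(1))
  roots <- c()
  for (i in which(gv[-n_grid] * gv[-1] < 0)) {
    roots <- c(roots, uniroot(g, c(ug[i], ug[i + 1]), tol = 1e-13)$root)
  }
  lapply(sort(roots), function(u) c(u = u, v = v_null(u)))
}

# Slow direct mean phase coherence of two phase series.
oracle_mpc <- function(phi1, phi2) {
  Mod(mean(exp(1i * (phi1 - phi2))))
}

# Reference two-node reciprocal structural connectivity.
pair_sc <- function() {
  structural_connectivity(matrix(c(0, 1, 1, 0), 2, 2), label = "pair")
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
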