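#' Binary undirected network container
#'
#' @param a symmetric binary matrix with zero diagonal.
#' @return An object of class \code{binary_network} with fields \code{n},
#'   \code{a}, \code{m} (undirected edge count).
#' @export
binary_network <- function(a) {
  a <- as.matrix(a)
  stopifnot(nrow(a) == ncol(a), all(a %in% c(0, 1)))
  if (max(abs(a - t(a))) != 0) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(a) != 0)) stop("diagonal must be zero", call. = FALSE)
  structure(list(n = nrow(a), a = a, m = sum(a) / 2), class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (density %.3f)\n",
              x$n, x$m, x$m / (x$n * (x$n - 1) / 2)))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$a, mode = "undirected")
}

#' Undirected binary view of a structural connectivity
#'
#' Symmetrizes the directed anatomical adjacency for comparison with the
#' intrinsically symmetric functional connectivity. "or" keeps a link if
#' either direction exists (the weakest assumption); "and" requires both.
#'
#' @param sc a \code{structural_connectivity}.
#' @param rule "or" (default) or "and".
#' @return A \code{binary_network}.
#' @export
sc_to_binary <- function(sc, rule = c("or", "and")) {
  stopifnot(inherits(sc, "structural_connectivity"))
  rule <- match.arg(rule)
  a <- if (rule == "or") pmax(sc$b, t(sc$b)) else pmin(sc$b, t(sc$b))
  binary_network(a)
}

#' Binarize a functional-connectivity matrix at a matched density
#'
#' Keeps the K largest off-diagonal upper-triangle values, where
#' \code{K = round(target_density * n (n - 1) / 2)}, reproducing the
#' protocol of thresholding the FC so that its density equals that of the
#' structural network. Ties are broken by (i, j) lexicographic order, so the
#' result is deterministic.
#'
#' @param fc an \code{fc_matrix} (or plain symmetric matrix).
#' @param target_density desired edge density in (0, 1).
#' @return A \code{binary_network} with exactly K edges.
#' @export
binarize_to_density <- function(fc, target_density) {
  vals <- if (inherits(fc, "fc_matrix")) fc$values else as.matrix(fc)
  n <- nrow(vals)
  if (target_density <= 0 || target_density >= 1) {
    stop("target_density must be in (0, 1)", call. = FALSE)
  }
  n_pairs <- n * (n - 1) / 2
  K <- round(target_density * n_pairs)
  if (K == 0 || K == n_pairs) {
    stop(sprintf("target density %.3f keeps %d of %d edges; nothing to threshold",
                 target_density, K, n_pairs), call. = FALSE)
  }
  idx <- which(upper.tri(vals), arr.ind = TRUE)
  ord <- order(-vals[idx], idx[, 1], idx[, 2])
  keep <- idx[ord[seq_len(K)], , drop = FALSE]
  a <- matrix(0, n, n)
  a[keep] <- 1
  a <- a + t(a)
  binary_network(a)
}

#' Average shortest-path length
#'
#' Breadth-first-search distances between all node pairs; L is the mean over
#' connected ordered pairs (disconnected pairs are excluded from the mean
#' and their fraction reported, never silently treated as infinite).
#'
#' @param net a \code{binary_network} with at least one edge.
#' @return A list with \code{L}, \code{distances} (matrix, \code{Inf} for
#'   disconnected pairs) and \code{disconnected_pair_fraction}.
#' @export
average_path_length <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  if (net$n < 2) stop("need at least 2 nodes", call. = FALSE)
  if (net$m == 0) stop("edgeless graph has no path length", call. = FALSE)
  D <- igraph::distances(as_igraph(net), algorithm = "unweighted")
  off <- D[row(D) != col(D)]
  connected <- is.finite(off)
  list(L = mean(off[connected]),
       distances = D,
       disconnected_pair_fraction = mean(!connected))
}

#' Global clustering coefficient
#'
#' Average of the local clustering coefficient (existing links among a
#' node's neighbours over the possible ones) across all nodes; nodes with
#' degree below 2 contribute 0.
#'
#' @param net a \code{binary_network} with at least 3 nodes.
#' @return Scalar C in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  if (net$n < 3) stop("need at least 3 nodes", call. = FALSE)
  ci <- igraph::transitivity(as_igraph(net), type = "local", isolates = "zero")
  ci[!is.finite(ci)] <- 0
  mean(ci)
}

#' Erdos-Renyi reference for path length and clustering
#'
#' Means of L and C over a seeded ensemble of G(n, m) uniform random graphs
#' with exactly the same node and edge counts, using the same
#' connected-pairs convention as [average_path_length()]. A sampled
#' ensemble is used rather than closed-form approximations because the
#' networks of interest are small.
#'
#' @param n,m node and edge counts.
#' @param n_samples ensemble size (>= 10; default 100).
#' @param seed RNG seed.
#' @return A list with \code{L_rand}, \code{C_rand}, \code{n}, \code{m},
#'   and the per-draw vectors \code{L_draws}, \code{C_draws}.
#' @export
random_reference <- function(n, m, n_samples = 100, seed = NULL) {
  if (n_samples < 10) stop("n_samples must be >= 10", call. = FALSE)
  if (m < 1 || m > n * (n - 1) / 2) stop("m out of range", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Ls <- numeric(n_samples); Cs <- numeric(n_samples)
  for (k in seq_len(n_samples)) {
    g <- igraph::sample_gnm(n, m)
    D <- igraph::distances(g, algorithm = "unweighted")
    off <- D[row(D) != col(D)]
    Ls[k] <- mean(off[is.finite(off)])
    ci <- igraph::transitivity(g, type = "local", isolates = "zero")
    ci[!is.finite(ci)] <- 0
    Cs[k] <- mean(ci)
  }
  list(L_rand = mean(Ls), C_rand = mean(Cs), n = n, m = m,
       L_draws = Ls, C_draws = Cs)
}

#' Small-world characterization of a binary network
#'
#' Combines the network's L and C with their random-graph references into
#' the relative coefficients \code{lambda = L / L_rand},
#' \code{gamma = C / C_rand} and the small-world index
#' \code{sw = gamma / lambda}: a small-world network has a path length close
#' to random (\code{lambda} near 1) but markedly increased clustering
#' (\code{gamma} well above 1).
#'
#' @param net a \code{binary_network}.
#' @param reference output of [random_reference()] with matching n and m.
#' @param label provenance string carried into the output row.
#' @return A one-row tibble: \code{label}, \code{L}, \code{C},
#'   \code{L_rand}, \code{C_rand}, \code{lambda}, \code{gamma},
#'   \code{sw_index}, \code{disconnected_pair_fraction}.
#' @export
small_world_index <- function(net, reference = NULL, label = "") {
  stopifnot(inherits(net, "binary_network"))
  if (is.null(reference)) {
    reference <- random_reference(net$n, net$m)
  }
  if (reference$n != net$n || reference$m != net$m) {
    stop("reference must match the network's node and edge counts",
         call. = FALSE)
  }
  pl <- average_path_length(net)
  C <- clustering_coefficient(net)
  lam <- pl$L / reference$L_rand
  gam <- if (reference$C_rand > 0) C / reference$C_rand else NA_real_
  if (!is.finite(gam)) {
    warning("C_rand is zero: gamma and the small-world index are undefined",
            call. = FALSE)
  }
  tibble::tibble(label = label, L = pl$L, C = C,
                 L_rand = reference$L_rand, C_rand = reference$C_rand,
                 lambda = lam, gamma = gam, sw_index = gam / lam,
                 disconnected_pair_fraction = pl$disconnected_pair_fraction)
}

#' Jaccard similarity of two binary networks
#'
#' Shared links divided by the union of links, over off-diagonal entries:
#' 1 for identical link sets, 0 for disjoint ones. The standard measure of
#' structure-function overlap for binarized connectivity matrices.
#'
#' @param a,b \code{binary_network}s (or binary matrices) on the same nodes.
#' @return Scalar in [0, 1]; \code{NaN} (with a warning) if both networks
#'   are empty.
#' @export
jaccard_similarity <- function(a, b) {
  ma <- if (inherits(a, "binary_network")) a$a else as.matrix(a)
  mb <- if (inherits(b, "binary_network")) b$a else as.matrix(b)
  if (!all(dim(ma) == dim(mb))) stop("size mismatch", call. = FALSE)
  off <- row(ma) != col(ma)
  inter <- sum(ma[off] & mb[off])
  union <- sum(ma[off] | mb[off])
  if (union == 0) {
    warning("both networks are empty: Jaccard similarity undefined",
            call. = FALSE)
    return(NaN)
  }
  inter / union
}

#' Chance-level Jaccard similarity by edge-position permutation
#'
#' Estimates the agreement expected between a reference network and a
#' random network of equal density by repeatedly redrawing the comparison
#' network's edge positions uniformly at random (seeded), and returns the
#' permutation mean and standard deviation.
#'
#' @param ref a \code{binary_network} (the structural side).
#' @param m_edges edge count of the permuted network (default: same as ref).
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed.
#' @return A list with \code{mean}, \code{sd}, and the vector \code{draws}.
#' @export
chance_jaccard <- function(ref, m_edges = NULL, n_perm = 100, seed = NULL) {
  stopifnot(inherits(ref, "binary_network"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(m_edges)) m_edges <- ref$m
  n <- ref$n
  idx <- which(upper.tri(matrix(0, n, n)))
  draws <- vapply(seq_len(n_perm), function(k) {
    a <- matrix(0, n, n)
    a[sample(idx, m_edges)] <- 1
    jaccard_similarity(ref, binary_network(a + t(a)))
  }, numeric(1))
  list(mean = mean(draws), sd = sd(draws), draws = draws)
}
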