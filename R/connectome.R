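#' Structural connectivity container
#'
#' A directed anatomical network over \code{n} nodes. The binary adjacency
#' \code{b} uses the convention \code{b[i, j] = 1} iff there is an anatomical
#' link from node \code{j} to node \code{i} (column = source), so the input
#' to node \code{i} is \code{sum_j w[i, j] * u[j]}. The weight matrix
#' \code{w} is the row-normalized adjacency: each row with positive
#' in-degree sums to one, so every node receives unit total input.
#'
#' @param b square binary matrix with zero diagonal.
#' @param label provenance string.
#' @param directed logical flag (kept as metadata; the model consumes the
#'   matrix as-is).
#' @return An object of class \code{structural_connectivity} with fields
#'   \code{n}, \code{b}, \code{w}, \code{directed}, \code{label}.
#' @export
structural_connectivity <- function(b, label = "custom", directed = TRUE) {
  b <- as.matrix(b)
  validate_binary_adjacency(b)
  sc <- normalize_rows(b)
  sc$label <- label
  sc$directed <- directed
  sc
}

validate_binary_adjacency <- function(b) {
  if (nrow(b) != ncol(b)) {
    stop(sprintf("adjacency must be square (got %d x %d)", nrow(b), ncol(b)),
         call. = FALSE)
  }
  if (!all(b %in% c(0, 1))) {
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  }
  bad <- which(diag(b) != 0)
  if (length(bad)) {
    stop(sprintf("nonzero diagonal entry at node %d (self-loops not allowed)",
                 bad[1]), call. = FALSE)
  }
  invisible(b)
}

#' @export
print.structural_connectivity <- function(x, ...) {
  cat(sprintf("<structural_connectivity> %s: %d nodes, %d directed links (density %.3f)\n",
              x$label, x$n, sum(x$b), sum(x$b) / (x$n * (x$n - 1))))
  invisible(x)
}

#' Row-normalize a binary adjacency matrix
#'
#' Divides each row of \code{b} by its sum so that the input to every node is
#' normalized: \code{w[i, j] = b[i, j] / sum_k b[i, k]}. Rows with zero
#' in-degree stay all-zero (with a warning naming the nodes).
#'
#' @param b square binary matrix, zero diagonal.
#' @return A \code{structural_connectivity} object (label "normalized").
#' @export
normalize_rows <- function(b) {
  b <- as.matrix(b)
  validate_binary_adjacency(b)
  rs <- rowSums(b)
  empty <- which(rs == 0)
  if (length(empty)) {
    warning(sprintf("node(s) %s have zero in-degree; their rows stay zero",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  w <- b / ifelse(rs == 0, 1, rs)
  structure(list(n = nrow(b), b = b, w = w, directed = TRUE,
                 label = "normalized"),
            class = "structural_connectivity")
}

#' Modular structural connectivity
#'
#' Builds the idealized modular connectome: \code{n_modules} modules, each
#' fully connected inside (all-to-all, no self-loops) and with no links
#' between modules.
#'
#' @param n_modules number of modules (>= 1).
#' @param module_size nodes per module (>= 2; an isolated node has no
#'   within-module partner).
#' @return A \code{structural_connectivity} on
#'   \code{n_modules * module_size} nodes.
#' @examples
#' modular_sc(3, 4)
#' @export
modular_sc <- function(n_modules, module_size) {
  if (n_modules < 1) stop("n_modules must be >= 1", call. = FALSE)
  if (module_size < 2) stop("module_size must be >= 2", call. = FALSE)
  n <- n_modules * module_size
  b <- matrix(0, n, n)
  for (m in seq_len(n_modules)) {
    idx <- ((m - 1) * module_size + 1):(m * module_size)
    b[idx, idx] <- 1
  }
  diag(b) <- 0
  sc <- structural_connectivity(b, label = sprintf("modular-%dx%d",
                                                   n_modules, module_size))
  sc$modules <- rep(seq_len(n_modules), each = module_size)
  sc
}

#' Degree-preserving randomization (Maslov-Sneppen rewiring)
#'
#' Randomizes a binary directed network by repeated edge-pair swaps
#' \code{(a -> b, c -> d) => (a -> d, c -> b)}, rejecting swaps that would
#' create a self-loop or a duplicate edge. Every node's in-degree and
#' out-degree (and hence the overall density) are preserved exactly.
#'
#' @param sc a \code{structural_connectivity}.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @param seed RNG seed for reproducibility (optional).
#' @return A rewired \code{structural_connectivity}.
#' @export
rewire_degree_preserving <- function(sc, swaps_per_edge = 10, seed = NULL) {
  stopifnot(inherits(sc, "structural_connectivity"))
  if (!is.null(seed)) set.seed(seed)
  b <- sc$b
  # directed edges as (source, target): b[target, source] = 1
  idx <- which(b == 1, arr.ind = TRUE)
  edges <- cbind(src = idx[, "col"], dst = idx[, "row"])
  m <- nrow(edges)
  if (m < 2) stop("need at least 2 edges to rewire", call. = FALSE)
  n_attempts <- swaps_per_edge * m
  n_done <- 0L
  for (k in seq_len(n_attempts)) {
    pick <- sample.int(m, 2)
    e1 <- edges[pick[1], ]; e2 <- edges[pick[2], ]
    # proposed: e1$src -> e2$dst, e2$src -> e1$dst
    if (e1["src"] == e2["dst"] || e2["src"] == e1["dst"]) next
    if (b[e2["dst"], e1["src"]] == 1 || b[e1["dst"], e2["src"]] == 1) next
    b[e1["dst"], e1["src"]] <- 0; b[e2["dst"], e2["src"]] <- 0
    b[e2["dst"], e1["src"]] <- 1; b[e1["dst"], e2["src"]] <- 1
    edges[pick[1], "dst"] <- e2["dst"]
    edges[pick[2], "dst"] <- e1["dst"]
    n_done <- n_done + 1L
  }
  if (n_done == 0L) {
    warning("no legal swap found within the attempt budget; returned unchanged",
            call. = FALSE)
  }
  out <- structural_connectivity(b, label = paste0(sc$label, "-rewired"),
                                 directed = sc$directed)
  out$n_swaps <- n_done
  out
}

#' Synthetic cortex-like structural connectivity (stand-in fixture)
#'
#' Generates a seeded random directed network emulating the size and gross
#' organization of a macaque cortical connectome (47 areas, moderate density,
#' modular tendency). This is a synthetic stand-in: it plants 5 communities
#' with a high within-community and low between-community link probability,
#' resamples until the undirected version is connected, and is fully
#' reproducible under a fixed seed. It carries no empirical tract-tracing
#' information.
#'
#' @param n node count (>= 8; default 47).
#' @param seed RNG seed (default 1).
#' @param p_within,p_between link probabilities (defaults 0.6 / 0.08 give
#'   density about 0.18).
#' @return A \code{structural_connectivity} labelled "synthetic-cortex".
#' @export
synthetic_cortex_fixture <- function(n = 47, seed = 1,
                                     p_within = 0.6, p_between = 0.08) {
  if (n < 8) stop("n must be >= 8", call. = FALSE)
  set.seed(seed)
  k <- 5
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  comm <- rep(seq_len(k), times = sizes)
  for (try in 1:100) {
    same <- outer(comm, comm, "==")
    p <- ifelse(same, p_within, p_between)
    diag(p) <- 0
    b <- matrix(as.numeric(runif(n * n) < p), n, n)
    diag(b) <- 0
    g <- igraph::graph_from_adjacency_matrix(b, mode = "max")
    if (igraph::is_connected(g) && all(rowSums(b) > 0)) break
  }
  sc <- structural_connectivity(b, label = "synthetic-cortex")
  sc$modules <- comm
  sc
}

#' Read / write structural connectivity as plain text
#'
#' Two interchangeable formats: a dense numeric matrix (comma or whitespace
#' separated, one row per line) or a two-column directed edge list
#' ("source target", 0-based node indices, one edge per line, canonical
#' header comment \code{# source target}). Lines starting with \code{#} are
#' comments. A write-then-read round trip reproduces the binary adjacency
#' exactly.
#'
#' @param path file path.
#' @param n_nodes for edge lists, the node count (default: 1 + max index).
#' @return \code{read_adjacency} returns a \code{structural_connectivity};
#'   \code{write_adjacency} returns \code{path} invisibly.
#' @export
read_adjacency <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0) stop("no data lines in ", path, call. = FALSE)
  is_edgelist_header <- any(grepl("^\\s*#\\s*source\\s+target", lines))
  fields <- strsplit(trimws(body), "[,[:space:]]+")
  ncols <- lengths(fields)
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(bad)) {
    stop(sprintf("parse error at line %d of %s: non-numeric field",
                 lineno[bad[1]], path), call. = FALSE)
  }
  edgelist <- is_edgelist_header ||
    (all(ncols == 2) && length(body) != 2) ||
    (all(ncols == 2) && any(unlist(vals) > 1))
  if (edgelist) {
    if (any(ncols != 2)) {
      stop(sprintf("parse error at line %d of %s: edge list rows need 2 fields",
                   lineno[which(ncols != 2)[1]], path), call. = FALSE)
    }
    m <- do.call(rbind, vals)
    if (any(m != round(m)) || any(m < 0)) {
      stop("edge list indices must be nonnegative integers (0-based)",
           call. = FALSE)
    }
    n <- if (is.null(n_nodes)) max(m) + 1 else n_nodes
    if (any(m >= n)) {
      bad <- which(apply(m, 1, max) >= n)[1]
      stop(sprintf("parse error at line %d of %s: node index out of range",
                   lineno[bad], path), call. = FALSE)
    }
    b <- matrix(0, n, n)
    # file rows are "source target": link source -> target, i.e. b[target+1, source+1]
    b[cbind(m[, 2] + 1, m[, 1] + 1)] <- 1
  } else {
    if (length(unique(ncols)) != 1 || ncols[1] != length(body)) {
      stop(sprintf("dense matrix in %s is not square (%d rows, %d columns)",
                   path, length(body), ncols[1]), call. = FALSE)
    }
    b <- do.call(rbind, vals)
    bad <- which(diag(b) != 0)
    if (length(bad)) {
      stop(sprintf("nonzero diagonal entry at (%d, %d) in %s",
                   bad[1], bad[1], path), call. = FALSE)
    }
  }
  structural_connectivity(b, label = basename(path))
}

#' @rdname read_adjacency
#' @param sc a \code{structural_connectivity}.
#' @param format "dense" (CSV matrix) or "edgelist" ("source target",
#'   0-based).
#' @export
write_adjacency <- function(sc, path, format = c("dense", "edgelist")) {
  stopifnot(inherits(sc, "structural_connectivity"))
  format <- match.arg(format)
  if (format == "dense") {
    con <- file(path, "w")
    writeLines(sprintf("# dense binary adjacency, %d nodes (b[i,j]=1: link j -> i)",
                       sc$n), con)
    write.table(sc$b, con, row.names = FALSE, col.names = FALSE, sep = ",")
    close(con)
  } else {
    idx <- which(sc$b == 1, arr.ind = TRUE)
    # b[i, j] = 1 means link j -> i: source = j, target = i (0-based on disk)
    con <- file(path, "w")
    writeLines("# source target", con)
    if (nrow(idx)) {
      writeLines(sprintf("%d %d", idx[, "col"] - 1, idx[, "row"] - 1), con)
    }
    close(con)
  }
  invisible(path)
}
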