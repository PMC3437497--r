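#' Simulation protocol configuration
#'
#' Collects the stochastic-integration protocol: Euler-Maruyama with step
#' \code{dt = 0.1}, run length \code{t_total = 10000} time units, the first
#' \code{t_transient = 1000} time units discarded before analysis, coupling
#' strength \code{epsilon = 1}, and a small amount of additive white
#' Gaussian noise applied to the u-variable of every node to ease the
#' detection of stable solutions. \code{noise_sigma} is the diffusion
#' amplitude multiplying \code{sqrt(dt) * xi} in the update, so the noise
#' accumulates variance \code{noise_sigma^2} per unit time; the default
#' 0.1 corresponds to a white-noise variance of 0.01 per unit time.
#' Optional quenched per-node jitter of \code{P} (drawn once per run,
#' uniform on \code{p_jitter_range}) models mild node heterogeneity.
#'
#' @param epsilon coupling strength (default 1).
#' @param noise_sigma noise diffusion amplitude (>= 0; default 0.1, i.e.
#'   variance 0.01 per unit time).
#' @param dt integration step (default 0.1).
#' @param t_total run length in time units (default 10000).
#' @param t_transient discarded prefix in time units (default 1000).
#' @param seed RNG seed (optional; set for reproducibility).
#' @param p_jitter_range optional length-2 interval for per-node P offsets,
#'   e.g. \code{c(0, 0.01)}; \code{NULL} (default) disables jitter.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(epsilon = 1, noise_sigma = 0.1, dt = 0.1,
                       t_total = 10000, t_transient = 1000, seed = NULL,
                       p_jitter_range = NULL) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (t_transient >= t_total) {
    stop("t_transient must be smaller than t_total", call. = FALSE)
  }
  if (!is.null(p_jitter_range) && length(p_jitter_range) != 2) {
    stop("p_jitter_range must be NULL or a length-2 interval", call. = FALSE)
  }
  structure(list(epsilon = epsilon, noise_sigma = noise_sigma, dt = dt,
                 t_total = t_total, t_transient = t_transient, seed = seed,
                 p_jitter_range = p_jitter_range),
            class = "sim_config")
}

#' Simulate the coupled Wilson-Cowan network
#'
#' Integrates the full network by the Euler-Maruyama scheme:
#' \code{u <- u + dt * du + noise_sigma * sqrt(dt) * xi} with standard-normal
#' \code{xi} independent per node and step (noise on u only); \code{v} is
#' updated deterministically. The coupling enters the u-equation inside the
#' firing-rate argument as \code{epsilon * sum_j w[i, j] * u[j]}. Initial
#' conditions are uniform on (0, 1) for every node. Fully reproducible under
#' a fixed seed.
#'
#' @param sc a \code{structural_connectivity} (rows of \code{w} normalized).
#' @param params a [wc_params()] object.
#' @param config a [sim_config()] object.
#' @return An object of class \code{wc_sim} with fields \code{u}, \code{v}
#'   (node x time matrices including the initial condition), \code{dt},
#'   \code{t0} (time of the first retained sample, 0 here), \code{params},
#'   \code{config}, \code{sc_label}.
#' @examples
#' sc <- modular_sc(2, 3)
#' ts <- simulate_network(sc, wc_params(-1.5, -6),
#'                        sim_config(t_total = 100, t_transient = 10, seed = 1))
#' dim(ts$u)
#' @export
simulate_network <- function(sc, params, config = sim_config()) {
  stopifnot(inherits(sc, "structural_connectivity"),
            inherits(params, "wc_params"),
            inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- sc$n
  u0 <- runif(n); v0 <- runif(n)
  Pvec <- rep(params$P, n)
  if (!is.null(config$p_jitter_range)) {
    Pvec <- Pvec + runif(n, config$p_jitter_range[1], config$p_jitter_range[2])
  }
  n_steps <- round(config$t_total / config$dt)
  res <- em_integrate_cpp(sc$w, u0, v0, Pvec, params$Q,
                          params$c1, params$c2, params$c3, params$c4,
                          config$epsilon, config$noise_sigma, config$dt,
                          n_steps)
  if (!isTRUE(res$ok)) {
    stop(sprintf(
      "numerical blow-up at step %d (node %d): |state| > 10 at (P, Q) = (%g, %g)",
      res$step, res$node, params$P, params$Q), call. = FALSE)
  }
  structure(list(u = res$u, v = res$v, dt = config$dt, t0 = 0,
                 params = params, config = config, sc_label = sc$label),
            class = "wc_sim")
}

#' @export
print.wc_sim <- function(x, ...) {
  cat(sprintf(
    "<wc_sim> %d nodes x %d samples (dt = %g, t0 = %g), sc = %s, (P, Q) = (%g, %g)\n",
    nrow(x$u), ncol(x$u), x$dt, x$t0, x$sc_label, x$params$P, x$params$Q))
  invisible(x)
}

#' Discard the initial transient of a simulation
#'
#' Drops all samples before \code{t_transient} so that analyses see only the
#' settled dynamics. The retained record starts at \code{t0 = t_transient}.
#'
#' @param ts a \code{wc_sim}.
#' @param t_transient length of prefix to discard, in time units (default:
#'   the value in the simulation's config).
#' @return A \code{wc_sim} starting at \code{t0 = t_transient}.
#' @export
drop_transient <- function(ts, t_transient = ts$config$t_transient) {
  stopifnot(inherits(ts, "wc_sim"))
  duration <- (ncol(ts$u) - 1) * ts$dt
  if (t_transient >= duration + ts$t0) {
    stop(sprintf("t_transient (%g) must be below the record end (%g)",
                 t_transient, duration + ts$t0), call. = FALSE)
  }
  if (t_transient <= ts$t0) return(ts)
  first <- floor((t_transient - ts$t0) / ts$dt) + 1
  ts$u <- ts$u[, -seq_len(first - 1), drop = FALSE]
  ts$v <- ts$v[, -seq_len(first - 1), drop = FALSE]
  ts$t0 <- ts$t0 + (first - 1) * ts$dt
  ts
}

#' Export simulated trajectories as plain text
#'
#' Writes the u (and optionally v) trajectories as a whitespace-separated
#' table, one column per node, with a metadata header comment.
#'
#' @param ts a \code{wc_sim}.
#' @param path output file.
#' @param variables which variables to write ("u", "v", or both).
#' @return \code{path}, invisibly.
#' @export
write_timeseries <- function(ts, path, variables = "u") {
  stopifnot(inherits(ts, "wc_sim"))
  con <- file(path, "w")
  writeLines(sprintf("# wc_sim sc=%s P=%g Q=%g dt=%g t0=%g vars=%s",
                     ts$sc_label, ts$params$P, ts$params$Q, ts$dt, ts$t0,
                     paste(variables, collapse = "+")), con)
  mats <- lapply(variables, function(v) t(ts[[v]]))
  write.table(do.call(cbind, mats), con, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}
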