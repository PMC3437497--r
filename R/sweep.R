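#' Parameter-plane sweep configuration
#'
#' Describes a full (P, Q)-plane experiment: the structural network, the
#' parameter grid, the simulation protocol per grid point, and the FC
#' measures to compute. The default grid is the test-scale preset (13 x 13
#' over the canonical window P in (-6, 6), Q in (-12, 0), i.e. increment
#' 1.0, with runs of 3000 time units and a 300 time-unit transient); the
#' full-scale experiment (increment 0.25, 49 x 49, runs of 10000 with a
#' 1000 transient) is available as \code{preset = "paper"}.
#'
#' @param sc a \code{structural_connectivity}.
#' @param P_seq,Q_seq grid vectors (defaults set by \code{preset}).
#' @param sim a [sim_config()] (its seed is ignored; per-point seeds are
#'   derived from \code{base_seed}).
#' @param measures FC measures to compute (subset of
#'   \code{c("correlation", "mean_phase_coherence")}).
#' @param base_seed integer; per-point seeds are deterministic functions of
#'   \code{base_seed} and the grid index, so any single point can be
#'   reproduced standalone.
#' @param preset "test" (default) or "paper".
#' @return An object of class \code{sweep_config}.
#' @export
sweep_config <- function(sc, P_seq = NULL, Q_seq = NULL, sim = NULL,
                         measures = c("correlation", "mean_phase_coherence"),
                         base_seed = 1, preset = c("test", "paper")) {
  stopifnot(inherits(sc, "structural_connectivity"))
  preset <- match.arg(preset)
  measures <- match.arg(measures, several.ok = TRUE)
  if (preset == "test") {
    if (is.null(P_seq)) P_seq <- seq(-6, 6, by = 1)
    if (is.null(Q_seq)) Q_seq <- seq(-12, 0, by = 1)
    if (is.null(sim)) sim <- sim_config(t_total = 3000, t_transient = 300)
  } else {
    if (is.null(P_seq)) P_seq <- seq(-6, 6, by = 0.25)
    if (is.null(Q_seq)) Q_seq <- seq(-12, 0, by = 0.25)
    if (is.null(sim)) sim <- sim_config()
  }
  if (length(P_seq) == 0 || length(Q_seq) == 0) {
    stop("empty parameter grid", call. = FALSE)
  }
  structure(list(sc = sc, P_seq = P_seq, Q_seq = Q_seq, sim = sim,
                 measures = measures, base_seed = as.integer(base_seed)),
            class = "sweep_config")
}

# deterministic per-grid-point seed, kept inside 32-bit integer range
point_seed <- function(base_seed, index) {
  as.integer((as.double(base_seed) + 104729 * as.double(index)) %% 2147483647)
}

#' Evaluate one (P, Q) grid point of a sweep
#'
#' Simulates the network at one parameter pair with the sweep's derived
#' seed, estimates FC with each configured measure, binarizes at the
#' structural density, and computes the graph metrics and the SC-FC Jaccard
#' agreement. Used by [run_sweep()]; calling it standalone with the same
#' config and grid index reproduces the sweep's record exactly.
#'
#' @param cfg a \code{sweep_config}.
#' @param P,Q node parameters for this point.
#' @param index grid index (row-major) used for seed derivation.
#' @param reference shared Erdos-Renyi reference from [random_reference()].
#' @return A tibble with one row per FC measure.
#' @export
sweep_point <- function(cfg, P, Q, index, reference) {
  sc_bin <- sc_to_binary(cfg$sc)
  density <- sc_bin$m / (sc_bin$n * (sc_bin$n - 1) / 2)
  sim <- cfg$sim
  sim$seed <- point_seed(cfg$base_seed, index)
  run <- function() {
    ts <- simulate_network(cfg$sc, wc_params(P, Q), sim)
    ts <- drop_transient(ts)
    rows <- lapply(cfg$measures, function(meas) {
      fc <- switch(meas,
                   correlation = pearson_fc(ts),
                   mean_phase_coherence = mean_phase_coherence_fc(ts))
      net <- binarize_to_density(fc, density)
      met <- small_world_index(net, reference, label = meas)
      dplyr::mutate(met,
                    jaccard = jaccard_similarity(sc_bin, net),
                    measure = meas, .before = 1)
    })
    dplyr::bind_rows(rows)
  }
  out <- tryCatch(run(), error = function(e) {
    tibble::tibble(measure = cfg$measures, jaccard = NA_real_,
                   label = cfg$measures, L = NA_real_, C = NA_real_,
                   L_rand = reference$L_rand, C_rand = reference$C_rand,
                   lambda = NA_real_, gamma = NA_real_, sw_index = NA_real_,
                   disconnected_pair_fraction = NA_real_,
                   point_status = paste0("error: ", conditionMessage(e)))
  })
  if (!"point_status" %in% names(out)) out$point_status <- "ok"
  dplyr::mutate(out, P = P, Q = Q, seed = sim$seed, .before = 1)
}

#' Run a full parameter-plane sweep
#'
#' For every (P, Q) grid point: simulate the network (seeded
#' deterministically from the base seed and the grid index), discard the
#' transient, estimate FC with each configured measure, binarize at the
#' structural density, compute graph metrics against a shared Erdos-Renyi
#' reference, and record the SC-FC Jaccard agreement. The theoretical
#' H'(0) map over the same grid is attached so simulation and theory can be
#' compared point by point. Failed points carry an error status and never
#' abort the sweep; results are independent of execution order.
#'
#' @param cfg a [sweep_config()].
#' @param with_theory attach the H'(0) column (default TRUE).
#' @param n_reference Erdos-Renyi ensemble size for the shared reference.
#' @return A tibble of class \code{sweep_result}: one row per grid point
#'   and measure with columns \code{P}, \code{Q}, \code{seed},
#'   \code{measure}, \code{jaccard}, \code{L}, \code{C}, \code{L_rand},
#'   \code{C_rand}, \code{lambda}, \code{gamma}, \code{sw_index},
#'   \code{disconnected_pair_fraction}, \code{point_status}, and (with
#'   theory) \code{hprime0}, \code{period}, \code{status}.
#' @export
run_sweep <- function(cfg, with_theory = TRUE, n_reference = 100) {
  stopifnot(inherits(cfg, "sweep_config"))
  sc_bin <- sc_to_binary(cfg$sc)
  reference <- random_reference(sc_bin$n, sc_bin$m, n_samples = n_reference,
                                seed = point_seed(cfg$base_seed, 0))
  grid <- tidyr::expand_grid(P = cfg$P_seq, Q = cfg$Q_seq)
  rows <- purrr::pmap(
    list(grid$P, grid$Q, seq_len(nrow(grid))),
    function(P, Q, index) sweep_point(cfg, P, Q, index, reference))
  out <- dplyr::bind_rows(rows)
  if (with_theory) {
    theory <- hprime_map(P_seq = cfg$P_seq, Q_seq = cfg$Q_seq)
    out <- dplyr::left_join(out, theory, by = c("P", "Q"))
  }
  attr(out, "sc_label") <- cfg$sc$label
  class(out) <- c("sweep_result", class(out))
  out
}

#' Compare simulated structure-function agreement with the theory map
#'
#' Splits the sweep's oscillatory grid points by the sign of H'(0) and
#' reports, per FC measure: the mean Jaccard agreement over points with
#' stable synchrony (H'(0) > 0) versus unstable (H'(0) < 0), the
#' point-biserial correlation between the stability indicator and the
#' Jaccard values, and the same for the small-world index. Under the
#' weak-coupling prediction, agreement should concentrate where
#' H'(0) > 0.
#'
#' @param result a \code{sweep_result} containing the theory columns.
#' @param min_points minimum number of oscillatory points required
#'   (default 10).
#' @return A tibble with one row per measure: \code{measure},
#'   \code{n_stable}, \code{n_unstable}, \code{jaccard_stable},
#'   \code{jaccard_unstable}, \code{jaccard_assoc}, \code{sw_stable},
#'   \code{sw_unstable}, \code{sw_assoc}.
#' @export
compare_with_theory <- function(result, min_points = 10) {
  if (!"hprime0" %in% names(result)) {
    stop("result carries no theory column; run the sweep with_theory = TRUE",
         call. = FALSE)
  }
  osc <- dplyr::filter(result, is.finite(.data$hprime0),
                       is.finite(.data$jaccard))
  if (nrow(osc) < min_points) {
    stop(sprintf("only %d oscillatory points (need >= %d)",
                 nrow(osc), min_points), call. = FALSE)
  }
  assoc <- function(flag, value) {
    if (length(unique(flag)) < 2 || sd(value) == 0) return(NA_real_)
    cor(as.numeric(flag), value)
  }
  osc |>
    dplyr::mutate(stable = .data$hprime0 > 0) |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(
      n_stable = sum(.data$stable),
      n_unstable = sum(!.data$stable),
      jaccard_stable = mean(.data$jaccard[.data$stable]),
      jaccard_unstable = mean(.data$jaccard[!.data$stable]),
      jaccard_assoc = assoc(.data$stable, .data$jaccard),
      sw_stable = mean(.data$sw_index[.data$stable], na.rm = TRUE),
      sw_unstable = mean(.data$sw_index[!.data$stable], na.rm = TRUE),
      sw_assoc = assoc(.data$stable[is.finite(.data$sw_index)],
                       .data$sw_index[is.finite(.data$sw_index)]),
      .groups = "drop")
}

#' Write sweep records as tabular text
#'
#' @param result a \code{sweep_result}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_sweep <- function(result, path) {
  write.table(as.data.frame(result), path, row.names = FALSE, quote = FALSE,
              sep = "\t")
  invisible(path)
}
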