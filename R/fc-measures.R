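#' Functional connectivity matrix container
#'
#' Symmetric node-by-node matrix of pairwise dependence values with unit
#' diagonal. Correlation entries lie in \[-1, 1\]; mean-phase-coherence
#' entries in \[0, 1\].
#'
#' @param values symmetric numeric matrix.
#' @param measure "correlation" or "mean_phase_coherence".
#' @param source provenance string.
#' @return An object of class \code{fc_matrix}.
#' @export
fc_matrix <- function(values, measure, source = "") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            max(abs(values - t(values))) < 1e-10)
  structure(list(values = values, measure = measure, source = source,
                 n = nrow(values)),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<fc_matrix> %s, %d nodes, off-diagonal range [%.3f, %.3f]\n",
              x$measure, x$n, min(off), max(off)))
  invisible(x)
}

#' Pearson-correlation functional connectivity
#'
#' Product-moment correlation of every pair of u-trajectories. Constant
#' series yield undefined correlations; those entries are set to 0 with a
#' warning.
#'
#' @param ts a \code{wc_sim} (transient already discarded by the caller).
#' @param variable which state variable to correlate (default "u").
#' @return An \code{fc_matrix} with \code{measure = "correlation"}.
#' @export
pearson_fc <- function(ts, variable = "u") {
  stopifnot(inherits(ts, "wc_sim"))
  x <- ts[[variable]]
  if (ncol(x) < 2) stop("need at least 2 time points", call. = FALSE)
  const <- apply(x, 1, function(r) max(r) - min(r) == 0)
  if (any(const)) {
    warning(sprintf("constant series for node(s) %s: correlations set to 0",
                    paste(which(const), collapse = ", ")), call. = FALSE)
  }
  vals <- suppressWarnings(cor(t(x)))
  vals[!is.finite(vals)] <- 0
  diag(vals) <- 1
  fc_matrix(vals, "correlation", source = ts$sc_label)
}

#' Instantaneous phase via the analytic signal
#'
#' Computes the phase of the analytic signal of a mean-centred series: the
#' negative-frequency half of the spectrum is zeroed (FFT method) and the
#' angle of the resulting complex signal is returned, wrapped to
#' \code{(-pi, pi]}.
#'
#' @param x numeric series (length >= 16, non-constant).
#' @return Phase series in radians, same length as \code{x}.
#' @examples
#' t <- seq(0, 20, by = 0.05)
#' ph <- instantaneous_phase(cos(2 * pi * t))
#' @export
instantaneous_phase <- function(x) {
  n <- length(x)
  if (n < 16) stop("need at least 16 samples", call. = FALSE)
  if (max(x) - min(x) == 0) stop("constant input has no phase", call. = FALSE)
  Arg(analytic_signal(x - mean(x)))
}

# Analytic signal by the FFT half-spectrum method.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Mean-phase-coherence functional connectivity
#'
#' For every node pair (i, j) computes the modulus of the time average of
#' the unit phasor of the instantaneous phase difference,
#' \deqn{R_{ij} = | \langle e^{i (\phi_i(t) - \phi_j(t))} \rangle_t |,}
#' which is 1 for perfectly phase-locked signals (at any fixed lag) and
#' near 0 for independent phases. Phases come from the analytic signal of
#' each mean-centred u-series; the first and last \code{edge_frac} of the
#' samples are excluded from the average to suppress boundary ringing of
#' the analytic signal.
#'
#' @param ts a \code{wc_sim}.
#' @param variable state variable to use (default "u").
#' @param edge_frac fraction of samples trimmed at each end (default 0.05).
#' @return An \code{fc_matrix} with \code{measure = "mean_phase_coherence"}.
#' @export
mean_phase_coherence_fc <- function(ts, variable = "u", edge_frac = 0.05) {
  stopifnot(inherits(ts, "wc_sim"))
  x <- ts[[variable]]
  phi <- phase_matrix(x)
  nt <- ncol(phi)
  trim <- floor(edge_frac * nt)
  keep <- seq.int(trim + 1, nt - trim)
  E <- exp(1i * phi[, keep, drop = FALSE])
  R <- Mod(E %*% Conj(t(E))) / length(keep)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  fc_matrix(R, "mean_phase_coherence", source = ts$sc_label)
}

# node x time matrix of instantaneous phases
phase_matrix <- function(x) {
  t(apply(x, 1, instantaneous_phase))
}

#' Export a functional-connectivity matrix as plain text
#'
#' @param fc an \code{fc_matrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fc <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  con <- file(path, "w")
  writeLines(sprintf("# fc_matrix measure=%s source=%s", fc$measure, fc$source),
             con)
  write.table(fc$values, con, row.names = FALSE, col.names = FALSE, sep = ",")
  close(con)
  invisible(path)
}

#' @export
tidy.fc_matrix <- function(x, ...) {
  n <- x$n
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(node_i = idx[, 1], node_j = idx[, 2],
                 value = x$values[idx], measure = x$measure)
}
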