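#' Tidy a limit cycle into a tibble of orbit samples
#'
#' @param x a \code{limit_cycle}.
#' @param ... unused.
#' @return A tibble with \code{t}, \code{theta}, \code{x}, \code{y}.
#' @export
tidy.limit_cycle <- function(x, ...) {
  xs <- x$x
  ys <- x$y
  tibble::tibble(t = x$t, theta = x$t / x$period, x = xs, y = ys)
}

#' @export
glance.limit_cycle <- function(x, ...) {
  tibble::tibble(P = x$params$P, Q = x$params$Q, period = x$period,
                 n_samples = x$M, closure = x$closure)
}

#' Tidy an adjoint orbit into a tibble of phase-response samples
#'
#' @param x an \code{adjoint_orbit}.
#' @param ... unused.
#' @return A tibble with \code{t}, \code{theta}, \code{Zx}, \code{Zy}.
#' @export
tidy.adjoint_orbit <- function(x, ...) {
  Zx <- x$Zx
  Zy <- x$Zy
  tibble::tibble(t = x$t, theta = x$t / x$period, Zx = Zx, Zy = Zy)
}

#' @export
glance.adjoint_orbit <- function(x, ...) {
  tibble::tibble(P = x$params$P, Q = x$params$Q, period = x$period,
                 zf_spread = x$zf_spread, n_periods = x$n_periods)
}

#' Tidy a phase interaction function into (theta, H) samples
#'
#' @param x a \code{phase_interaction}.
#' @param ... unused.
#' @return A tibble with \code{theta}, \code{H}.
#' @export
tidy.phase_interaction <- function(x, ...) {
  tibble::tibble(theta = x$theta, H = x$H)
}

#' One-row summary of a phase interaction function
#'
#' @param x a \code{phase_interaction}.
#' @param ... unused.
#' @return A tibble with the parameters, period, H'(0) (direct quadrature
#'   and spectral cross-check) and the synchrony verdict.
#' @export
glance.phase_interaction <- function(x, ...) {
  tibble::tibble(P = x$params$P, Q = x$params$Q, period = x$period,
                 H_prime_0 = x$H_prime_0,
                 H_prime_0_spectral = x$H_prime_0_spectral,
                 synchrony_stable = x$H_prime_0 > 0)
}

#' @export
tidy.phase_lock_jacobian <- function(x, ...) {
  tibble::tibble(eigenvalue_re = Re(x$eigenvalues),
                 eigenvalue_im = Im(x$eigenvalues))
}

#' @export
glance.phase_lock_jacobian <- function(x, ...) {
  tibble::tibble(n = nrow(x$matrix), units = x$units, epsilon = x$epsilon,
                 h_prime_0 = x$h_prime_0, stable = x$stable,
                 max_nonzero_re = max(Re(x$eigenvalues)[-1]))
}

#' Tidy a simulated run into long format
#'
#' @param x a \code{wc_sim}.
#' @param ... unused.
#' @return A tibble with \code{time}, \code{node}, \code{u}, \code{v}.
#' @export
tidy.wc_sim <- function(x, ...) {
  nt <- ncol(x$u)
  n <- nrow(x$u)
  tibble::tibble(
    time = rep(x$t0 + (seq_len(nt) - 1) * x$dt, each = n),
    node = rep(seq_len(n), times = nt),
    u = as.vector(x$u), v = as.vector(x$v))
}

#' @export
glance.wc_sim <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$u), n_samples = ncol(x$u), dt = x$dt,
                 t0 = x$t0, P = x$params$P, Q = x$params$Q,
                 epsilon = x$config$epsilon, noise_sigma = x$config$noise_sigma,
                 sc_label = x$sc_label)
}
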