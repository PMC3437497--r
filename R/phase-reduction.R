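#' Transformed Wilson-Cowan node field
#'
#' The linear change of variables \code{x = c1 u - c2 v + P},
#' \code{y = c3 u - c4 v + Q} maps the node equations to a form in which the
#' network coupling appears additively in the x-equation:
#' \deqn{\dot x = -x + P + c_1 f(x) - c_2 f(y), \quad
#'       \dot y = -y + Q + c_3 f(x) - c_4 f(y),}
#' with the coupling perturbation to node i being
#' \code{epsilon * sum_j w[i, j] * f(x_j)}. This is the convenient form for
#' phase reduction: the phase response to coupling needs only the
#' x-component of the adjoint vector.
#'
#' @param x,y transformed state (vectors allowed).
#' @param params a [wc_params()] object.
#' @return A list with \code{dx}, \code{dy}.
#' @export
transformed_field <- function(x, y, params) {
  stopifnot(inherits(params, "wc_params"))
  list(dx = -x + params$P + params$c1 * firing_rate(x) - params$c2 * firing_rate(y),
       dy = -y + params$Q + params$c3 * firing_rate(x) - params$c4 * firing_rate(y))
}

# transformed coordinates of an original-variables state
to_transformed <- function(u, v, params) {
  list(x = params$c1 * u - params$c2 * v + params$P,
       y = params$c3 * u - params$c4 * v + params$Q)
}

transformed_jacobian <- function(x, y, params) {
  matrix(c(-1 + params$c1 * firing_rate_deriv(x), -params$c2 * firing_rate_deriv(y),
           params$c3 * firing_rate_deriv(x), -1 - params$c4 * firing_rate_deriv(y)),
         nrow = 2, byrow = TRUE)
}

transformed_rhs_desolve <- function(t, st, p) {
  fld <- transformed_field(st[1], st[2], p)
  list(c(fld$dx, fld$dy))
}

# lsoda on the compiled right-hand side (registered in the package DLL)
ode_node <- function(st, times, params, rtol, atol) {
  deSolve::ode(st, times, func = "scfc_node_deriv",
               parms = c(params$P, params$Q, params$c1, params$c2,
                         params$c3, params$c4),
               dllname = "scfc", initfunc = "scfc_node_init",
               method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000)
}

#' Locate the attracting limit cycle of the transformed node
#'
#' Integrates the transformed node from a generic initial state through a
#' long transient, detects the period by upward crossings of x through its
#' orbit mean (Poincare section, crossing times refined by linear
#' interpolation), and resamples one period at M uniform points. If the
#' trajectory settles to a fixed point (amplitude below \code{amp_tol}) an
#' explicit no-limit-cycle outcome is returned instead of an error, since
#' large parts of the (P, Q) plane are non-oscillatory.
#'
#' @param params a [wc_params()] object.
#' @param M samples per period (>= 256; default 2048).
#' @param transient settling time before period detection (default 500).
#' @param t_observe observation window for crossing detection (default 300).
#' @param amp_tol amplitude below which the node is declared quiescent.
#' @return An object of class \code{limit_cycle} with fields \code{period},
#'   \code{t} (M + 1 uniform times spanning one period), \code{x}, \code{y},
#'   \code{params}, \code{closure} (endpoint mismatch), or an object of
#'   class \code{no_limit_cycle} carrying the parameters and the observed
#'   amplitude.
#' @examples
#' \donttest{
#' lc <- find_limit_cycle(wc_params(-1.5, -6))
#' lc$period
#' }
#' @export
find_limit_cycle <- function(params, M = 2048, transient = 500,
                             t_observe = 300, amp_tol = 1e-4) {
  stopifnot(inherits(params, "wc_params"))
  if (M < 256) stop("M must be >= 256", call. = FALSE)
  st <- c(x = params$P, y = params$Q + 4)
  no_lc <- function(amp) structure(list(params = params, amplitude = amp),
                                   class = "no_limit_cycle")
  out <- ode_node(st, c(0, transient), params, rtol = 1e-10, atol = 1e-10)
  st <- out[nrow(out), 2:3]
  h_obs <- 0.02
  tt <- seq(0, t_observe, by = h_obs)
  out <- ode_node(st, tt, params, rtol = 1e-11, atol = 1e-11)
  x <- out[, 2]
  amp <- diff(range(x[tt > t_observe / 2]))
  if (amp < amp_tol) return(no_lc(amp))
  xm <- mean(range(x))
  i <- which(x[-length(x)] < xm & x[-1] >= xm)
  if (length(i) < 4) return(no_lc(amp))
  tc <- tt[i] + h_obs * (xm - x[i]) / (x[i + 1] - x[i])
  tc <- tc[tc > t_observe / 4]
  if (length(tc) < 3) return(no_lc(amp))
  period <- (tc[length(tc)] - tc[1]) / (length(tc) - 1)
  s0 <- ode_node(st, c(0, tc[1]), params, rtol = 1e-12, atol = 1e-12)
  s0 <- s0[nrow(s0), 2:3]
  ts <- seq(0, period, length.out = M + 1)
  orb <- ode_node(s0, ts, params, rtol = 1e-12, atol = 1e-12)
  structure(list(period = period, t = ts, x = orb[, 2], y = orb[, 3],
                 params = params, M = M,
                 closure = sqrt(sum((orb[1, 2:3] - orb[M + 1, 2:3])^2))),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf("<limit_cycle> (P, Q) = (%g, %g): period %.4f, %d samples, closure %.2e\n",
              x$params$P, x$params$Q, x$period, x$M, x$closure))
  invisible(x)
}

#' @export
print.no_limit_cycle <- function(x, ...) {
  cat(sprintf("<no_limit_cycle> (P, Q) = (%g, %g): amplitude %.2e below threshold\n",
              x$params$P, x$params$Q, x$amplitude))
  invisible(x)
}

# field along the stored orbit samples
orbit_field <- function(lc) {
  fld <- transformed_field(lc$x, lc$y, lc$params)
  list(Fx = fld$dx, Fy = fld$dy)
}

#' Phase-response vector by the adjoint method
#'
#' Solves the adjoint equation \code{Z' = -J(t)^T Z} along the limit cycle.
#' The periodic initial direction is obtained from the monodromy matrix of
#' the variational equation (the adjoint's periodic solution is the left
#' eigenvector for the trivial Floquet multiplier 1); a few backward passes
#' with per-period renormalization polish it, and the samples over one
#' period are then normalized pointwise so that \code{Z(t) . F(t) = 1/T}
#' at every sample (phase measured in fractions of a cycle, so the
#' intrinsic drift is \code{1/T}). All linear integrations use fixed-step
#' RK4 on the orbit's uniform grid with the Jacobian from periodic spline
#' interpolants. The nontrivial Floquet multiplier and the relative spread
#' of \code{Z . F} before normalization are reported as diagnostics.
#'
#' @param lc a \code{limit_cycle}.
#' @param max_periods maximum backward polish periods (default 25).
#' @param tol direction-convergence tolerance between successive periods.
#' @return An object of class \code{adjoint_orbit} with \code{Zx}, \code{Zy}
#'   aligned with the limit-cycle samples, plus \code{zf_spread},
#'   \code{floquet_multiplier} and \code{n_periods} diagnostics.
#' @export
adjoint_solve <- function(lc, max_periods = 25, tol = 1e-10) {
  stopifnot(inherits(lc, "limit_cycle"))
  p <- lc$params
  Tper <- lc$period
  M <- lc$M
  h <- Tper / M
  # closure mismatch is ~1e-8; pin the endpoint for the periodic spline
  sx <- splinefun(lc$t, c(lc$x[1:M], lc$x[1]), method = "periodic")
  sy <- splinefun(lc$t, c(lc$y[1:M], lc$y[1]), method = "periodic")
  # orbit on the half-grid so every RK4 stage lands on a sample
  t_half <- seq(0, Tper, length.out = 2 * M + 1)
  fpx <- firing_rate_deriv(sx(t_half))
  fpy <- firing_rate_deriv(sy(t_half))
  Mon <- monodromy_cpp(fpx, fpy, p$c1, p$c2, p$c3, p$c4, h, M)
  # left eigenvector for the Floquet multiplier closest to 1
  ed <- eigen(t(Mon))
  i1 <- which.min(abs(ed$values - 1))
  mu <- Re(ed$values[-i1][1])
  z0 <- Re(ed$vectors[, i1])
  res <- adjoint_backward_cpp(fpx, fpy, p$c1, p$c2, p$c3, p$c4,
                              h, M, max_periods, tol, z0)
  if (!isTRUE(res$converged)) {
    warning(sprintf(
      paste("adjoint direction not converged to %g after %d periods at",
            "(P, Q) = (%g, %g); Floquet multiplier %.6f"),
      tol, max_periods, p$P, p$Q, mu), call. = FALSE)
  }
  Zg <- res$Z
  fld <- orbit_field(lc)
  dot <- Zg[, 1] * fld$Fx + Zg[, 2] * fld$Fy
  spread <- diff(range(dot)) / abs(mean(dot))
  scale <- dot * Tper
  structure(list(Zx = Zg[, 1] / scale, Zy = Zg[, 2] / scale,
                 t = lc$t, period = Tper, M = M, params = p,
                 zf_spread = spread, floquet_multiplier = mu,
                 n_periods = res$n_periods),
            class = "adjoint_orbit")
}

#' Phase interaction function H and its slope at zero lag
#'
#' The pairwise phase interaction function of two weakly coupled identical
#' oscillators is the one-period average of the product of the phase
#' response (x-component, since coupling enters the x-equation) and the
#' incoming signal \code{f(x)} shifted by the phase difference:
#' \deqn{H(\theta) = \frac{1}{T}\int_0^T Z_x(s)\, f(x(s + \theta T))\, ds.}
#' H is 1-periodic in \code{theta}. Its slope at zero,
#' \deqn{H'(0) = \int_0^T Z_x(s)\, f'(x(s))\, \dot x(s)\, ds,}
#' is computed by direct trapezoidal quadrature (no differentiation of
#' sampled data); a spectral derivative of the sampled H is stored as an
#' independent cross-check. \code{H'(0) > 0} means the in-phase state of a
#' coupled pair (and of a globally coupled network) is stable.
#'
#' @param lc a \code{limit_cycle}.
#' @param adj the matching \code{adjoint_orbit}.
#' @param K number of theta samples (>= 256; default 512).
#' @return An object of class \code{phase_interaction} with \code{theta}
#'   (K + 1 points on \[0, 1\]), \code{H}, \code{H_prime_0},
#'   \code{H_prime_0_spectral}, \code{period}.
#' @export
interaction_function <- function(lc, adj, K = 512) {
  stopifnot(inherits(lc, "limit_cycle"), inherits(adj, "adjoint_orbit"))
  if (adj$M != lc$M || abs(adj$period - lc$period) > 1e-10) {
    stop("adjoint samples are not aligned with the limit cycle", call. = FALSE)
  }
  if (K < 256) stop("K must be >= 256", call. = FALSE)
  M <- lc$M
  h <- lc$period / M
  fld <- orbit_field(lc)
  integrand <- adj$Zx * firing_rate_deriv(lc$x) * fld$Fx
  H_prime_0 <- sum((integrand[-1] + integrand[-(M + 1)]) / 2) * h
  fx <- firing_rate(lc$x)[1:M]
  Zx <- adj$Zx[1:M]
  theta <- seq(0, 1, length.out = K + 1)
  shifts <- round(theta * M) %% M
  H <- vapply(shifts, function(s) {
    mean(Zx * fx[((seq_len(M) - 1 + s) %% M) + 1])
  }, numeric(1))
  # spectral cross-check of H'(0) from the sampled H
  Hk <- fft(H[1:K]) / K
  kk <- c(0:(K / 2 - 1), 0, (-K / 2 + 1):(-1))
  dH <- Re(fft(Hk * 2i * pi * kk, inverse = TRUE))
  structure(list(theta = theta, H = H, H_prime_0 = H_prime_0,
                 H_prime_0_spectral = dH[1], period = lc$period,
                 params = lc$params),
            class = "phase_interaction")
}

#' @export
print.phase_interaction <- function(x, ...) {
  cat(sprintf("<phase_interaction> (P, Q) = (%g, %g): T = %.4f, H'(0) = %.6g (%s)\n",
              x$params$P, x$params$Q, x$period, x$H_prime_0,
              if (x$H_prime_0 > 0) "synchrony stable" else "synchrony unstable"))
  invisible(x)
}

#' Phase reduction of a Wilson-Cowan node in one call
#'
#' Convenience wrapper: limit cycle, adjoint, interaction function.
#'
#' @param params a [wc_params()] object.
#' @param ... passed to [find_limit_cycle()].
#' @return A \code{phase_interaction}, or a \code{no_limit_cycle} if the
#'   node does not oscillate at these parameters.
#' @export
phase_reduction <- function(params, ...) {
  lc <- find_limit_cycle(params, ...)
  if (inherits(lc, "no_limit_cycle")) return(lc)
  interaction_function(lc, adjoint_solve(lc))
}

#' Jacobian of the phase-locked synchronous state
#'
#' At synchrony the linearization of the phase equations has entries
#' \code{epsilon * H'(0) * (w[i, j] - delta_ij * sum_k w[i, k])}. Every row
#' sums to zero, so one eigenvalue is always 0 (the free common phase); the
#' synchronous state is stable when all remaining eigenvalues have negative
#' real part. With \code{units = "scaled"} the matrix is reported in units
#' of \code{epsilon * H'(0)} so algebraic spectra (e.g. the -1 eigenvalue of
#' uniform global coupling with \code{w_ij = 1/N}) can be checked
#' scale-free.
#'
#' @param sc a \code{structural_connectivity} or a plain nonnegative weight
#'   matrix with zero diagonal.
#' @param h_prime_0 slope of the interaction function at zero lag.
#' @param epsilon coupling strength (default 1).
#' @param units "natural" (multiply by \code{epsilon * H'(0)}) or "scaled".
#' @return An object of class \code{phase_lock_jacobian} with the matrix,
#'   eigenvalues sorted by decreasing real part, and a stability verdict
#'   (\code{TRUE} if all nonzero-real-part eigenvalues are negative).
#' @export
sync_jacobian <- function(sc, h_prime_0, epsilon = 1,
                          units = c("natural", "scaled")) {
  units <- match.arg(units)
  w <- if (inherits(sc, "structural_connectivity")) sc$w else as.matrix(sc)
  if (any(w < 0) || any(diag(w) != 0)) {
    stop("weights must be nonnegative with zero diagonal", call. = FALSE)
  }
  A <- w - diag(rowSums(w))
  scale <- if (units == "natural") epsilon * h_prime_0 else 1
  mat <- scale * A
  ev <- eigen(mat, only.values = TRUE)$values
  ev <- ev[order(Re(ev), decreasing = TRUE)]
  nonzero <- ev[abs(Re(ev)) > 1e-10 | abs(Im(ev)) > 1e-10]
  structure(list(matrix = mat, eigenvalues = ev,
                 stable = all(Re(nonzero) < 0),
                 units = units, epsilon = epsilon, h_prime_0 = h_prime_0),
            class = "phase_lock_jacobian")
}

#' @export
print.phase_lock_jacobian <- function(x, ...) {
  cat(sprintf("<phase_lock_jacobian> %d x %d (%s units): leading eigenvalues %s; %s\n",
              nrow(x$matrix), ncol(x$matrix), x$units,
              paste(sprintf("%.4g", Re(x$eigenvalues[seq_len(min(3, length(x$eigenvalues)))])),
                    collapse = ", "),
              if (x$stable) "synchrony stable" else "synchrony unstable"))
  invisible(x)
}

#' Map of H'(0) over the (P, Q) plane
#'
#' Runs the full phase-reduction pipeline at every grid point and records
#' H'(0) where a limit cycle exists, an explicit no-limit-cycle status
#' elsewhere. Individual failures are caught and logged in the status
#' column, never fatal.
#'
#' @param P_range,Q_range length-2 windows (or explicit grids via
#'   \code{P_seq}/\code{Q_seq}).
#' @param resolution grid points per axis (>= 8).
#' @param P_seq,Q_seq explicit grid vectors overriding range/resolution.
#' @param M orbit samples per period (default 1024 for map work).
#' @return A tibble with columns \code{P}, \code{Q}, \code{hprime0}
#'   (NA where no cycle), \code{period}, \code{status} ("ok",
#'   "no_limit_cycle" or "error: ...").
#' @export
hprime_map <- function(P_range = c(-6, 6), Q_range = c(-12, 0),
                       resolution = 13, P_seq = NULL, Q_seq = NULL,
                       M = 1024) {
  if (is.null(P_seq)) {
    if (resolution < 8) stop("resolution must be >= 8", call. = FALSE)
    P_seq <- seq(P_range[1], P_range[2], length.out = resolution)
  }
  if (is.null(Q_seq)) {
    Q_seq <- seq(Q_range[1], Q_range[2], length.out = resolution)
  }
  grid <- tidyr::expand_grid(P = P_seq, Q = Q_seq)
  rows <- purrr::pmap(grid, function(P, Q) {
    res <- tryCatch({
      pr <- phase_reduction(wc_params(P, Q), M = M)
      if (inherits(pr, "no_limit_cycle")) {
        tibble::tibble(hprime0 = NA_real_, period = NA_real_,
                       status = "no_limit_cycle")
      } else {
        tibble::tibble(hprime0 = pr$H_prime_0, period = pr$period,
                       status = "ok")
      }
    }, error = function(e) {
      tibble::tibble(hprime0 = NA_real_, period = NA_real_,
                     status = paste0("error: ", conditionMessage(e)))
    })
    res
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(rows))
  class(out) <- c("hprime_map", class(out))
  out
}
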