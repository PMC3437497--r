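#' Wilson-Cowan node parameters
#'
#' Bundles the intra-node coupling constants and background inputs of a
#' Wilson-Cowan population pair. The node equations are
#' \deqn{\dot u = -u + f(c_1 u - c_2 v + P), \quad
#'       \dot v = -v + f(c_3 u - c_4 v + Q),}
#' with the logistic firing-rate function \code{f(x) = 1/(1 + exp(-x))}.
#' The default constants are \code{c1 = c2 = c3 = 10}, \code{c4 = -2}, the
#' classic choice for which the node oscillates via a Hopf bifurcation in
#' part of the \code{(P, Q)} plane. \code{P} and \code{Q} are dimensionless
#' background drives to the excitatory-like (\code{u}) and inhibitory-like
#' (\code{v}) populations; the canonical exploration window is
#' \code{P} in (-6, 6) and \code{Q} in (-12, 0).
#'
#' @param P,Q background inputs to the u- and v-populations.
#' @param c1,c2,c3,c4 intra-node coupling constants.
#' @return An object of class \code{wc_params}.
#' @examples
#' wc_params(P = -1.5, Q = -6)
#' @export
wc_params <- function(P, Q, c1 = 10, c2 = 10, c3 = 10, c4 = -2) {
  vals <- c(P = P, Q = Q, c1 = c1, c2 = c2, c3 = c3, c4 = c4)
  if (!all(is.finite(vals))) {
    stop("all Wilson-Cowan parameters must be finite", call. = FALSE)
  }
  structure(as.list(vals), class = "wc_params")
}

#' @export
print.wc_params <- function(x, ...) {
  cat(sprintf(
    "<wc_params> P = %g, Q = %g (c1 = %g, c2 = %g, c3 = %g, c4 = %g)\n",
    x$P, x$Q, x$c1, x$c2, x$c3, x$c4))
  invisible(x)
}

#' Logistic firing-rate function
#'
#' The population firing-rate nonlinearity \code{f(x) = 1/(1 + exp(-x))},
#' bounded in (0, 1), with derivative \code{f'(x) = f(x) (1 - f(x))}.
#' Saturates without overflow at extreme arguments.
#'
#' @param x numeric vector.
#' @return Firing rates in (0, 1), same shape as \code{x}.
#' @examples
#' firing_rate(0)      # 0.5
#' firing_rate(c(-2, 2))
#' @export
firing_rate <- function(x) 1 / (1 + exp(-x))

#' Derivative of the firing-rate function
#'
#' @param x numeric vector.
#' @return \code{f(x) * (1 - f(x))}, maximal value 1/4 at \code{x = 0}.
#' @export
firing_rate_deriv <- function(x) {
  s <- firing_rate(x)
  s * (1 - s)
}

#' Vector field of an uncoupled Wilson-Cowan node
#'
#' Evaluates the right-hand side of the node equations, optionally with an
#' additive input inside the u-population firing-rate argument (the form the
#' network coupling takes).
#'
#' @param u,v activities (numeric, may be vectors of equal length).
#' @param params a [wc_params()] object.
#' @param coupling additive input to the u firing-rate argument (default 0).
#' @return A list with components \code{du} and \code{dv}.
#' @examples
#' p <- wc_params(P = 0, Q = 0)
#' node_field(0, 0, p)   # (0.5, 0.5)
#' @export
node_field <- function(u, v, params, coupling = 0) {
  stopifnot(inherits(params, "wc_params"))
  du <- -u + firing_rate(params$c1 * u - params$c2 * v + params$P + coupling)
  dv <- -v + firing_rate(params$c3 * u - params$c4 * v + params$Q)
  list(du = du, dv = dv)
}

# Jacobian of the node field at (u, v); entries use f' = f(1-f).
node_jacobian <- function(u, v, params) {
  au <- params$c1 * u - params$c2 * v + params$P
  av <- params$c3 * u - params$c4 * v + params$Q
  fpu <- firing_rate_deriv(au)
  fpv <- firing_rate_deriv(av)
  matrix(c(-1 + params$c1 * fpu, -params$c2 * fpu,
           params$c3 * fpv, -1 - params$c4 * fpv),
         nrow = 2, byrow = TRUE)
}

# Solve v = f(c3 u - c4 v + Q) for each u by fixed-point iteration.
# Contraction: |c4| * max f' = 0.5 < 1 at the default constants.
solve_v_branch <- function(u, params, iter = 80) {
  v <- rep(0.5, length(u))
  for (k in seq_len(iter)) {
    v_new <- firing_rate(params$c3 * u - params$c4 * v + params$Q)
    if (max(abs(v_new - v)) < 1e-14) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v
}

classify_fixed_point <- function(tr, det) {
  if (det < 0) return("saddle")
  disc <- tr^2 - 4 * det
  if (tr < 0) {
    if (disc < 0) "stable-focus" else "stable-node"
  } else {
    if (disc < 0) "unstable-focus" else "unstable-node"
  }
}

#' Rest states of an uncoupled Wilson-Cowan node
#'
#' Finds all fixed points by a one-dimensional reduction: for each candidate
#' \code{u} the v-nullcline equation \code{v = f(c3 u - c4 v + Q)} is solved
#' by fixed-point iteration (a contraction at the default constants), then
#' sign changes of the residual \code{u - f(c1 u - c2 v(u) + P)} are
#' bracketed on a dense grid over the invariant box and polished by
#' bisection. The node has either one or three rest states (two exactly at a
#' saddle-node bifurcation).
#'
#' @param params a [wc_params()] object.
#' @param n_grid number of bracketing samples over \code{u} in
#'   \code{[-0.25, 1.25]} (default 2001).
#' @param tol bisection tolerance on \code{u} (default 1e-12).
#' @param merge_tol roots closer than this in \code{u} are reported once.
#' @return A tibble with one row per fixed point, sorted by \code{u_star}:
#'   columns \code{u_star}, \code{v_star}, \code{trace}, \code{det},
#'   \code{re1}, \code{im1}, \code{re2}, \code{im2} (eigenvalues of the
#'   Jacobian), \code{classification} and \code{residual}.
#' @examples
#' find_fixed_points(wc_params(P = -1.5, Q = -6))
#' @export
find_fixed_points <- function(params, n_grid = 2001, tol = 1e-12,
                              merge_tol = 1e-8) {
  stopifnot(inherits(params, "wc_params"))
  ug <- seq(-0.25, 1.25, length.out = n_grid)
  resid <- function(u) {
    v <- solve_v_branch(u, params)
    u - firing_rate(params$c1 * u - params$c2 * v + params$P)
  }
  r <- resid(ug)
  roots <- ug[r == 0]
  sw <- which(r[-n_grid] * r[-1] < 0)
  for (i in sw) {
    lo <- ug[i]; hi <- ug[i + 1]
    root <- uniroot(resid, c(lo, hi), tol = tol)$root
    roots <- c(roots, root)
  }
  roots <- sort(roots)
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > merge_tol)
    roots <- roots[keep]
  }
  if (length(roots) == 0) {
    stop(sprintf("no fixed point found at (P, Q) = (%g, %g)",
                 params$P, params$Q), call. = FALSE)
  }
  rows <- lapply(roots, function(u) {
    v <- solve_v_branch(u, params)
    linear_stability(u, v, params)
  })
  dplyr::bind_rows(rows)
}

#' Linear stability of a Wilson-Cowan rest state
#'
#' Evaluates the analytic 2x2 Jacobian at a fixed point, returns its
#' eigenvalues and the trace/determinant classification.
#'
#' @param u_star,v_star fixed-point coordinates (must satisfy the fixed-point
#'   equations to \code{residual_tol}).
#' @param params a [wc_params()] object.
#' @param residual_tol maximum allowed fixed-point residual (default 1e-6).
#' @return One-row tibble as described in [find_fixed_points()].
#' @export
linear_stability <- function(u_star, v_star, params, residual_tol = 1e-6) {
  fld <- node_field(u_star, v_star, params)
  res <- max(abs(fld$du), abs(fld$dv))
  if (res > residual_tol) {
    stop(sprintf("(%.6g, %.6g) is not a fixed point (residual %.3g)",
                 u_star, v_star, res), call. = FALSE)
  }
  J <- node_jacobian(u_star, v_star, params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(Re(ev), decreasing = TRUE)]
  tr <- sum(diag(J))
  dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  tibble::tibble(
    u_star = u_star, v_star = v_star,
    trace = tr, det = dt,
    re1 = Re(ev[1]), im1 = Im(ev[1]),
    re2 = Re(ev[2]), im2 = Im(ev[2]),
    classification = classify_fixed_point(tr, dt),
    residual = res)
}

# Trace / det / count summary used by the bifurcation scan.
fp_summary <- function(P, Q, base) {
  params <- wc_params(P, Q, base$c1, base$c2, base$c3, base$c4)
  fps <- find_fixed_points(params, n_grid = 601)
  fps
}

#' Hopf and saddle-node loci of the isolated node
#'
#' Scans the \code{(P, Q)} plane on a uniform grid and locates the skeleton
#' of the node's bifurcation diagram. Hopf points are found by bisection
#' along grid edges where the trace of the Jacobian at a tracked focus
#' changes sign while its determinant stays positive; saddle-node points by
#' bisection on changes of the fixed-point count. Loci are returned as
#' unordered point sets (curve ordering is a plotting concern).
#'
#' @param P_range,Q_range length-2 numeric windows.
#' @param resolution grid points per axis (minimum 8).
#' @param params_base a [wc_params()] giving the constants \code{c1..c4}
#'   (its P, Q are ignored).
#' @return A tibble with columns \code{kind} ("HB" or "SN"), \code{P},
#'   \code{Q}. Empty (zero rows) when no bifurcation lies in the window.
#' @examples
#' \donttest{
#' loci <- bifurcation_scan(c(-6, 6), c(-12, 0), resolution = 16)
#' table(loci$kind)
#' }
#' @export
bifurcation_scan <- function(P_range, Q_range, resolution = 25,
                             params_base = wc_params(0, 0)) {
  stopifnot(length(P_range) == 2, length(Q_range) == 2,
            all(is.finite(c(P_range, Q_range))))
  if (resolution < 8) stop("resolution must be >= 8 per axis", call. = FALSE)
  Ps <- seq(P_range[1], P_range[2], length.out = resolution)
  Qs <- seq(Q_range[1], Q_range[2], length.out = resolution)

  # per-grid-point fixed-point tables
  grid <- vector("list", resolution * resolution)
  dim(grid) <- c(resolution, resolution)
  for (i in seq_along(Ps)) {
    for (j in seq_along(Qs)) {
      grid[[i, j]] <- fp_summary(Ps[i], Qs[j], params_base)
    }
  }
  # trace of the fixed point with det > 0 nearest in u to a reference;
  # returns NA when no such point exists
  focus_trace <- function(fps, u_ref) {
    cand <- fps[fps$det > 0, , drop = FALSE]
    if (nrow(cand) == 0) return(NA_real_)
    cand$trace[which.min(abs(cand$u_star - u_ref))]
  }
  hb <- list(); sn <- list()
  edges <- list()
  for (i in seq_len(resolution)) {
    for (j in seq_len(resolution)) {
      if (i < resolution) edges[[length(edges) + 1]] <- c(i, j, i + 1, j)
      if (j < resolution) edges[[length(edges) + 1]] <- c(i, j, i, j + 1)
    }
  }
  for (e in edges) {
    a <- grid[[e[1], e[2]]]; b <- grid[[e[3], e[4]]]
    p1 <- c(Ps[e[1]], Qs[e[2]]); p2 <- c(Ps[e[3]], Qs[e[4]])
    # --- Hopf: trace sign change at a tracked det>0 fixed point
    u_ref <- a$u_star[which.max(a$det)]
    ta <- focus_trace(a, u_ref); tb <- focus_trace(b, u_ref)
    if (is.finite(ta) && is.finite(tb) && ta * tb < 0) {
      f <- function(s) {
        pq <- (1 - s) * p1 + s * p2
        focus_trace(fp_summary(pq[1], pq[2], params_base), u_ref)
      }
      s <- tryCatch(uniroot(f, c(0, 1), tol = 1e-6)$root, error = function(e) NA)
      if (is.finite(s)) {
        pq <- (1 - s) * p1 + s * p2
        fps <- fp_summary(pq[1], pq[2], params_base)
        tr <- focus_trace(fps, u_ref)
        cand <- fps[fps$det > 0, , drop = FALSE]
        dt <- if (nrow(cand)) cand$det[which.min(abs(cand$trace))] else NA_real_
        if (is.finite(tr) && abs(tr) < 1e-3 && is.finite(dt) && dt > 0) {
          hb[[length(hb) + 1]] <- pq
        }
      }
    }
    # --- saddle-node: fixed-point count change
    if (nrow(a) != nrow(b)) {
      lo <- 0; hi <- 1; n_lo <- nrow(a)
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        pq <- (1 - mid) * p1 + mid * p2
        n_mid <- nrow(fp_summary(pq[1], pq[2], params_base))
        if (n_mid == n_lo) lo <- mid else hi <- mid
      }
      pq <- (1 - (lo + hi) / 2) * p1 + ((lo + hi) / 2) * p2
      sn[[length(sn) + 1]] <- pq
    }
  }
  pts <- function(lst, kind) {
    if (length(lst) == 0) {
      return(tibble::tibble(kind = character(), P = numeric(), Q = numeric()))
    }
    m <- do.call(rbind, lst)
    tibble::tibble(kind = kind, P = m[, 1], Q = m[, 2])
  }
  out <- dplyr::bind_rows(pts(hb, "HB"), pts(sn, "SN"))
  class(out) <- c("bifurcation_loci", class(out))
  attr(out, "grid_resolution") <- resolution
  out
}

#' Write bifurcation loci as plain text
#'
#' @param loci tibble from [bifurcation_scan()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_loci <- function(loci, path) {
  write.table(loci, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
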