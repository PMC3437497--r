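pt_a <- wc_params(-2.5, -8.5)
pt_b <- wc_params(-1.5, -6)
pt_c <- wc_params(2.5, -3.5)

test_that("the transformed field is conjugate to the node field", {
  params <- pt_b
  # a fixed point of the node maps to a fixed point of the transformed field
  fps <- find_fixed_points(params)
  tr <- to_transformed(fps$u_star[1], fps$v_star[1], params)
  fld <- transformed_field(tr$x, tr$y, params)
  expect_lt(max(abs(c(fld$dx, fld$dy))), 1e-8)
  # a transformed trajectory mapped back through the inverse linear change
  # of variables satisfies the node equations (chain rule residual)
  lc <- find_limit_cycle(params, M = 512)
  W <- matrix(c(params$c1, -params$c2, params$c3, -params$c4), 2, byrow = TRUE)
  uv <- solve(W, rbind(lc$x - params$P, lc$y - params$Q))
  fld <- transformed_field(lc$x, lc$y, params)
  nf <- node_field(uv[1, ], uv[2, ], params)
  expect_lt(max(abs(fld$dx - (params$c1 * nf$du - params$c2 * nf$dv))), 1e-8)
  expect_lt(max(abs(fld$dy - (params$c3 * nf$du - params$c4 * nf$dv))), 1e-8)
})

test_that("limit cycles exist at the three reference points and close up", {
  for (p in list(pt_a, pt_b, pt_c)) {
    lc <- find_limit_cycle(p, M = 512)
    expect_s3_class(lc, "limit_cycle")
    expect_lt(lc$closure, 1e-5)
    expect_gt(lc$period, 1)
  }
  # deep quiescence gives the explicit no-limit-cycle outcome
  expect_s3_class(find_limit_cycle(wc_params(-6, -12), M = 256),
                  "no_limit_cycle")
})

test_that("the adjoint satisfies its normalization and periodicity and predicts impulse phase shifts", {
  lc <- find_limit_cycle(pt_b, M = 1024)
  adj <- adjoint_solve(lc)
  fld <- scfc:::orbit_field(lc)
  dot <- adj$Zx * fld$Fx + adj$Zy * fld$Fy
  expect_equal(dot, rep(1 / lc$period, lc$M + 1), tolerance = 1e-9)
  expect_lt(adj$zf_spread, 1e-6)
  # periodic endpoints
  expect_equal(adj$Zx[1], adj$Zx[lc$M + 1], tolerance = 1e-6)
  # brute-force oracle: impulse delta on x at phase theta shifts the
  # asymptotic phase by delta * Zx(theta T) (in cycles: delta * Zx * T... the
  # normalization Z.F = 1/T makes Z the gradient of phase in cycles)
  delta <- 1e-4
  for (idx in c(1, round(lc$M / 3))) {
    base <- c(lc$x[idx], lc$y[idx])
    pert <- base + c(delta, 0)
    horizon <- 40 * lc$period
    tt <- seq(0, horizon, length.out = 2001)
    o1 <- scfc:::ode_node(base, tt, pt_b, rtol = 1e-12, atol = 1e-12)
    o2 <- scfc:::ode_node(pert, tt, pt_b, rtol = 1e-12, atol = 1e-12)
    # phase shift from the final-time displacement along the cycle:
    # project the difference on the field direction
    f_end <- scfc:::orbit_field(list(x = o1[2001, 2], y = o1[2001, 3],
                                     params = pt_b))
    fvec <- c(f_end$Fx, f_end$Fy)
    dstate <- o2[2001, 2:3] - o1[2001, 2:3]
    shift_cycles <- sum(dstate * fvec) / sum(fvec^2) / lc$period
    expect_equal(shift_cycles, delta * adj$Zx[idx], tolerance = 0.03,
                 ignore_attr = TRUE)
  }
})

test_that("H is 1-periodic with the printed signs at the three reference points and consistent derivatives", {
  signs <- c(-1, 1, -1)
  pts <- list(pt_a, pt_b, pt_c)
  for (k in 1:3) {
    pr <- phase_reduction(pts[[k]], M = 1024)
    expect_s3_class(pr, "phase_interaction")
    expect_equal(pr$H[1], pr$H[length(pr$H)], tolerance = 1e-10)
    expect_equal(sign(pr$H_prime_0), signs[k])
    # direct quadrature vs spectral differentiation of sampled H
    expect_lt(abs(pr$H_prime_0 - pr$H_prime_0_spectral) /
                abs(pr$H_prime_0), 1e-4)
  }
})

test_that("H'(0) sign is invariant to the orbit sampling resolution", {
  for (M in c(256, 1024)) {
    pr <- phase_reduction(pt_a, M = M)
    expect_lt(pr$H_prime_0, 0)
  }
  pr1 <- phase_reduction(pt_b, M = 256)
  pr2 <- phase_reduction(pt_b, M = 1024)
  expect_gt(pr1$H_prime_0, 0)
  expect_equal(pr1$H_prime_0, pr2$H_prime_0, tolerance = 1e-4)
})

test_that("the synchrony Jacobian has the analytic spectrum and scaling", {
  # row sums vanish => one zero eigenvalue, any connected sc
  sc <- synthetic_cortex_fixture(20, seed = 3)
  J <- sync_jacobian(sc, h_prime_0 = 0.05, epsilon = 1)
  expect_lt(min(abs(J$eigenvalues)), 1e-12)
  # all-to-all w_ij = 1/N: nonzero eigenvalues all -1 (N-1 fold) in scaled units
  N <- 10
  w <- matrix(1 / N, N, N); diag(w) <- 0
  Js <- sync_jacobian(w, h_prime_0 = 0.05, units = "scaled")
  nz <- Js$eigenvalues[abs(Js$eigenvalues) > 1e-10]
  expect_equal(length(nz), N - 1)
  expect_equal(Re(nz), rep(-1, N - 1), tolerance = 1e-12)
  # two-node reciprocal row-normalized pair: eigenvalues {0, -2} scaled
  J2 <- sync_jacobian(pair_sc(), h_prime_0 = 1, units = "scaled")
  expect_equal(sort(Re(J2$eigenvalues)), c(-2, 0), tolerance = 1e-12)
  # eigenvalues scale linearly in epsilon and H'(0)
  Ja <- sync_jacobian(pair_sc(), h_prime_0 = 0.05, epsilon = 0.3)
  Jb <- sync_jacobian(pair_sc(), h_prime_0 = 0.1, epsilon = 0.6)
  expect_equal(Re(Jb$eigenvalues), 4 * Re(Ja$eigenvalues), tolerance = 1e-12)
  # trace criterion: H'(0) < 0 makes the trace positive (instability)
  Jneg <- sync_jacobian(pair_sc(), h_prime_0 = -0.08)
  expect_gt(sum(diag(Jneg$matrix)), 0)
  expect_false(Jneg$stable)
})

test_that("the H'(0) map reproduces the reference-point signs and flags quiescent regions", {
  map <- hprime_map(P_seq = c(-2.5, -1.5, 2.5, -6),
                    Q_seq = c(-8.5, -6, -3.5, -12), M = 512)
  at <- function(P, Q) map[map$P == P & map$Q == Q, ]
  expect_lt(at(-2.5, -8.5)$hprime0, 0)
  expect_gt(at(-1.5, -6)$hprime0, 0)
  expect_lt(at(2.5, -3.5)$hprime0, 0)
  expect_equal(at(-6, -12)$status, "no_limit_cycle")
})

test_that("weak-coupling prediction matches full two-node simulations at the reference points", {
  # central scientific consistency check: with a reciprocal pair at small
  # epsilon and no noise, H'(0) > 0 predicts in-phase locking and
  # H'(0) < 0 predicts locking away from in-phase
  lock <- function(params) {
    cfg <- sim_config(epsilon = 0.05, noise_sigma = 0, t_total = 6000,
                      t_transient = 4000, seed = 5)
    ts <- drop_transient(simulate_network(pair_sc(), params, cfg))
    ph1 <- instantaneous_phase(ts$u[1, ])
    ph2 <- instantaneous_phase(ts$u[2, ])
    abs(Arg(mean(exp(1i * (ph1 - ph2))))) / (2 * pi)
  }
  expect_lt(lock(pt_b), 0.02)
  expect_gt(lock(pt_a), 0.1)
  expect_gt(lock(pt_c), 0.1)
})
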