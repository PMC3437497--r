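test_that("firing rate is the logistic function with its exact identities", {
  expect_equal(firing_rate(0), 0.5)
  expect_equal(firing_rate(2), 0.8807970779778823)
  x <- seq(-30, 30, length.out = 501)
  expect_equal(firing_rate(x) + firing_rate(-x), rep(1, 501))
  r <- firing_rate(x)
  expect_true(all(r > 0 & r < 1))
  expect_true(all(diff(r) > 0))
  expect_equal(firing_rate_deriv(x), r * (1 - r))
  expect_lte(max(firing_rate_deriv(x)), 0.25)
  # no overflow at extremes
  expect_equal(firing_rate(c(-1000, 1000)), c(0, 1))
})

test_that("node field matches direct formula evaluation and vanishes at fixed points", {
  p <- wc_params(P = 0, Q = 0)
  expect_equal(node_field(0, 0, p), list(du = 0.5, dv = 0.5))
  p2 <- wc_params(P = -1.5, Q = -6)
  fld <- node_field(0.5, 0.5, p2)
  # frozen from high-precision evaluation of f(c1 u - c2 v + P), f(c3 u - c4 v + Q)
  expect_equal(fld$du, -0.31757447619364365, tolerance = 1e-14)
  expect_equal(fld$dv, 0.0, tolerance = 1e-14)
  fps <- find_fixed_points(p2)
  for (k in seq_len(nrow(fps))) {
    fld <- node_field(fps$u_star[k], fps$v_star[k], p2)
    expect_lt(max(abs(c(fld$du, fld$dv))), 1e-9)
  }
})

test_that("fixed points match an independent nullcline-intersection oracle", {
  for (pq in list(c(-1.5, -6), c(0, -3), c(3, -1), c(-4, -10))) {
    params <- wc_params(pq[1], pq[2])
    got <- find_fixed_points(params)
    want <- oracle_fixed_points(params)
    expect_equal(nrow(got), length(want))
    expect_true(nrow(got) %in% c(1, 2, 3))
    for (k in seq_along(want)) {
      expect_equal(got$u_star[k], want[[k]]["u"], tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_equal(got$v_star[k], want[[k]]["v"], tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
    expect_true(all(got$u_star >= -0.25 & got$u_star <= 1.25))
    expect_true(all(got$v_star >= -0.25 & got$v_star <= 1.25))
    expect_false(is.unsorted(got$u_star))
  }
})

test_that("linear stability classifies by trace and determinant and rejects non-fixed points", {
  params <- wc_params(-1.5, -6)
  fps <- find_fixed_points(params)
  for (k in seq_len(nrow(fps))) {
    # product of eigenvalues equals the determinant
    ev1 <- complex(real = fps$re1[k], imaginary = fps$im1[k])
    ev2 <- complex(real = fps$re2[k], imaginary = fps$im2[k])
    expect_equal(Re(ev1 * ev2), fps$det[k], tolerance = 1e-10)
    expect_equal(fps$re1[k] + fps$re2[k], fps$trace[k], tolerance = 1e-10)
    cls <- fps$classification[k]
    if (fps$det[k] < 0) expect_identical(cls, "saddle")
    if (fps$det[k] > 0 && fps$trace[k] < 0 &&
        fps$trace[k]^2 < 4 * fps$det[k]) {
      expect_identical(cls, "stable-focus")
    }
  }
  expect_error(linear_stability(0.9, 0.9, params), "not a fixed point")
})

test_that("forward flow points into the invariant box on its faces", {
  params <- wc_params(-1.5, -6)
  s <- seq(-0.25, 1.25, length.out = 41)
  right <- node_field(rep(1.25, 41), s, params)
  left <- node_field(rep(-0.25, 41), s, params)
  top <- node_field(s, rep(1.25, 41), params)
  bottom <- node_field(s, rep(-0.25, 41), params)
  expect_true(all(right$du < 0))
  expect_true(all(left$du > 0))
  expect_true(all(top$dv < 0))
  expect_true(all(bottom$dv > 0))
})

test_that("bifurcation scan finds a Hopf locus in the canonical window and verifies its points", {
  loci <- bifurcation_scan(c(-6, 6), c(-12, 0), resolution = 12)
  hb <- dplyr::filter(loci, kind == "HB")
  expect_gt(nrow(hb), 0)
  # every reported Hopf point satisfies trace ~ 0 with det > 0 at a fixed point
  for (k in seq_len(min(nrow(hb), 6))) {
    fps <- find_fixed_points(wc_params(hb$P[k], hb$Q[k]))
    cand <- dplyr::filter(fps, det > 0)
    expect_gt(nrow(cand), 0)
    expect_lt(min(abs(cand$trace)), 1e-3)
  }
  # eigenvalue real part ~ 0 at a Hopf point (cross-check with linear_stability)
  fps <- find_fixed_points(wc_params(hb$P[1], hb$Q[1]))
  cand <- dplyr::filter(fps, det > 0)
  expect_lt(min(abs(cand$re1)), 1e-3)
})

test_that("fixed-point count changes only across SN loci and far windows are quiet", {
  loci_far <- bifurcation_scan(c(50, 60), c(-12, 0), resolution = 8)
  expect_equal(nrow(loci_far), 0)
  # scan Q at fixed P: count changes must bracket an SN point from the scan
  loci <- bifurcation_scan(c(-6, 6), c(-12, 0), resolution = 12)
  sn <- dplyr::filter(loci, kind == "SN")
  if (nrow(sn) > 0) {
    P0 <- sn$P[1]
    Qs <- seq(-12, 0, length.out = 60)
    counts <- vapply(Qs, function(q) {
      nrow(find_fixed_points(wc_params(P0, q)))
    }, numeric(1))
    changes <- Qs[which(diff(counts) != 0)]
    # every count change along this line lies within the scanned window
    expect_true(all(changes >= -12 & changes <= 0))
  }
})

test_that("oscillation onset: points a, b, c all lie inside the limit-cycle region", {
  for (pq in list(c(-2.5, -8.5), c(-1.5, -6), c(2.5, -3.5))) {
    lc <- find_limit_cycle(wc_params(pq[1], pq[2]), M = 256)
    expect_s3_class(lc, "limit_cycle")
    expect_gt(lc$period, 0)
  }
})
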