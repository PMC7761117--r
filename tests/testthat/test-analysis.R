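test_that("f(s) vanishes at the ends, is symmetric, and peaks at sqrt(s1)", {
  ps <- 0.7; eps <- 0.1; s1 <- 0.02
  expect_error(f_curve(0.01, s1, ps, eps), "s1 < s < 1")
  expect_error(f_curve(1, s1, ps, eps), "s1 < s < 1")
  # one-sided limits at both ends of the domain
  expect_lt(abs(f_curve(s1 + 1e-9, s1, ps, eps)), 1e-6)
  expect_lt(abs(f_curve(1 - 1e-9, s1, ps, eps)), 1e-6)
  for (s in c(0.05, 0.1, 0.3, 0.7)) {
    expect_equal(f_curve(s1 / s, s1, ps, eps), f_curve(s, s1, ps, eps),
                 tolerance = 1e-12)
  }
  expect_equal(f_curve(sqrt(s1), s1, ps, eps), g_fn(s1, ps, eps), tolerance = 1e-15)
})

test_that("g has the known endpoint behavior and equals the symmetric phi-eff", {
  ps <- 0.6; eps <- 0.1
  expect_equal(g_fn(0, ps, eps), -i0(ps, eps), tolerance = 1e-15)
  g_near1 <- g_fn(1 - 10^-(4:7), ps, eps)
  expect_true(all(g_near1 > 0))          # approaches 0 from above
  expect_true(all(diff(abs(g_near1)) < 0))
  # N = 6 equal-node model: g(s1) is the symmetric-bipartition phi_eff
  for (s1 in c(0.02, 0.1, 0.3, 0.7)) {
    m <- equal_model(6, s1, ps, eps)
    expect_equal(effective_information(m, bipartition(1:3, 6)),
                 g_fn(s1, ps, eps), tolerance = 1e-12)
  }
})

test_that("the exact threshold brackets the sign change of g", {
  root <- s1min_exact(0.6, 0.1)
  expect_lt(g_fn(root - 1e-6, 0.6, 0.1), 0)
  expect_gt(g_fn(root + 1e-6, 0.6, 0.1), 0)
  expect_lt(abs(g_fn(root, 0.6, 0.1)), 1e-11)
  # threshold is non-increasing in ps at fixed eps
  th <- vapply(seq(0.1, 0.9, by = 0.1), s1min_exact, 0, eps = 0.1)
  expect_true(all(diff(th) < 0))
  expect_true(all(th > 0 & th < 1))
  expect_error(s1min_exact(0.6, 0), "eps > 0")
})

test_that("weak-correlation approximation of I0 converges to the exact value", {
  for (ps in c(0.3, 0.5, 0.7)) {
    ratios <- vapply(c(0.1, 0.05, 0.025), function(e) {
      i0(ps, e) / i0_approx(ps, e)$value
    }, 0)
    expect_true(all(diff(abs(ratios - 1)) < 0))  # monotone approach to 1
    expect_lt(abs(ratios[3] - 1), 0.05)
  }
  expect_equal(i0_approx(0.5, 0)$value, 0)
  # validity flag false on the boundary ps = 1/(1+eps)
  expect_false(i0_approx(1 / 1.1, 0.1)$valid)
  expect_true(i0_approx(0.5, 0.1)$valid)
})

test_that("asymptotic threshold has the correct limits and monotonicity", {
  # ps -> 0 supremum: 3 - 2 sqrt(2) ~ 0.1716, the universal 0.17 bound
  expect_equal(s1min_asymptotic(1e-6), 3 - 2 * sqrt(2), tolerance = 1e-5)
  # frozen root of the asymptotic quadratic at ps = 0.5
  expect_equal(s1min_asymptotic(0.5), 0.0470219, tolerance = 1e-6)
  ps_grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(s1min_asymptotic(ps_grid)) < 0))
  # agreement with the exact root at small eps
  for (ps in c(0.3, 0.5, 0.7)) {
    expect_equal(s1min_exact(ps, 0.01), s1min_asymptotic(ps), tolerance = 0.05)
  }
})

test_that("the sign verdict is a property of the process, not the parameterization", {
  # under the invariance scaling every subsystem satisfies
  # (1 - sA') ps' = (1 - sA) ps, so Ixy and phi_eff per bipartition -- and
  # with them the positivity verdict -- are unchanged
  ps <- 0.5; eps <- 0.2; s1 <- 0.1; alpha <- 1.2
  s1p <- 1 - (1 - s1) / alpha
  expect_equal(i_xy(s1, ps, eps), i_xy(s1p, alpha * ps, eps), tolerance = 1e-12)
  m <- equal_model(4, s1, ps, eps)
  mt <- scaling_transform(m, alpha)
  for (bp in bipartitions(4)) {
    expect_equal(effective_information(m, bp), effective_information(mt, bp),
                 tolerance = 1e-12)
  }
  expect_equal(mib_phi(m)$phi, mib_phi(mt)$phi, tolerance = 1e-12)
})

test_that("positivity verdicts agree with the sign of the MIB phi", {
  ps <- 0.6; eps <- 0.2
  th <- s1min_exact(ps, eps)
  m_hi <- equal_model(6, th * 2, ps, eps)
  v_hi <- positivity_conditions(m_hi)
  expect_true(v_hi$necessary_sufficient)
  expect_true(v_hi$sufficient)
  expect_true(v_hi$symmetric_exists)
  expect_gt(mib_phi(m_hi)$phi, 0)
  m_lo <- equal_model(6, th / 2, ps, eps)
  v_lo <- positivity_conditions(m_lo)
  expect_false(v_lo$necessary_sufficient)
  expect_false(v_lo$sufficient)
  expect_lt(mib_phi(m_lo)$phi, 0)
  # verdicts (27) and (30a) coincide when a symmetric bipartition exists
  expect_equal(v_hi$necessary_sufficient, v_hi$sufficient)
  expect_equal(v_lo$necessary_sufficient, v_lo$sufficient)
  # degenerate eps = 0
  v0 <- positivity_conditions(equal_model(4, 0.3, 0.6, 0))
  expect_true(v0$degenerate)
  # correlated table: directional mode engages
  probs <- independent_spike_table(rep(0.4, 3))$probs
  probs[8] <- probs[8] + 0.05; probs[1] <- probs[1] - 0.05
  m_corr <- spiking_bursting_model(spike_table(probs), ps, eps)
  v_corr <- positivity_conditions(m_corr)
  expect_equal(v_corr$mode, "directional")
  expect_equal(v_corr$correlation, "positive")
})

test_that("phi-eff scales as eps^2 in the weak-correlation regime", {
  bp <- bipartition(1:3, 6)
  for (s1 in c(0.1, 0.3)) {
    scaled <- vapply(c(0.0125, 0.025, 0.05), function(e) {
      effective_information(equal_model(6, s1, 0.6, e), bp) / e^2
    }, 0)
    expect_lt(diff(range(scaled)) / abs(mean(scaled)), 0.10)
  }
  # the sign verdict is eps-independent at small eps
  for (ps in c(0.3, 0.5, 0.7)) {
    for (s1 in c(0.02, 0.05, 0.2)) {
      expect_equal(g_fn(s1, ps, 0.01) > 0, g_fn(s1, ps, 0.02) > 0)
    }
  }
})

test_that("threshold curves evaluate on grids and export as CSV", {
  csv <- tempfile(fileext = ".csv")
  tc <- threshold_curve(c(0.3, 0.5, 0.7), c(0.1, 0.5), path = csv)
  expect_true(all(tc$s1min > 0 & tc$s1min < 1))
  expect_equal(nrow(read.csv(csv)), nrow(tc))
  ta <- threshold_curve(c(0.3, 0.5, 0.7), 0.1, method = "asymptotic")
  expect_equal(ta$s1min, s1min_asymptotic(c(0.3, 0.5, 0.7)), tolerance = 1e-12)
  # invalid grid points (eps > eps_max) are dropped
  tb <- threshold_curve(c(0.5, 0.9), c(0.5, 2))
  expect_false(any(tb$eps > (1 - tb$ps) / tb$ps + 1e-12))
})
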