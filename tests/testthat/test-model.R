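test_that("dichotomous parameter validation enforces the probability constraints", {
  # boundary ps = 1/(1+eps) is admissible and gives a perfectly persistent chain
  d <- dichotomous_params(0.5, 1)
  expect_equal(d$ps_max, 0.5)
  expect_equal(d$eps_max, 1)
  expect_error(dichotomous_params(0.6, 1), "ps <= 1/\\(1\\+eps\\)")
  expect_error(dichotomous_params(0.5, -0.1), "eps >= 0")
  expect_error(dichotomous_params(0, 0.1), "strictly in \\(0, 1\\)")
  expect_error(dichotomous_params(1, 0.1), "strictly in \\(0, 1\\)")
  d2 <- dichotomous_params(0.6, 0.5)
  expect_equal(d2$eps_max, 2 / 3)
  expect_equal(d2$rho, 0.5 * 0.6 / 0.4)
})

test_that("dichotomous two-time table matches the closed cells and marginals", {
  j <- dichotomous_joint(dichotomous_params(0.5, 1))
  expect_equal(unname(j), diag(2) / 2, tolerance = 1e-15)
  # eps = 0 factorizes as the outer product of the marginals
  j0 <- dichotomous_joint(dichotomous_params(0.35, 0))
  expect_equal(unname(j0), outer(c(0.35, 0.65), c(0.35, 0.65)), tolerance = 1e-15)
  j1 <- dichotomous_joint(dichotomous_params(0.7, 0.1))
  expect_equal(sum(j1), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(j1)), c(0.7, 0.3), tolerance = 1e-12)
  expect_equal(unname(colSums(j1)), c(0.7, 0.3), tolerance = 1e-12)
  expect_equal(j1["s", "b"], j1["b", "s"])
  # boundary eps = eps_max: off-diagonal vanishes
  jm <- dichotomous_joint(dichotomous_params(0.4, 1.5))
  expect_equal(jm["s", "b"], 0)
})

test_that("rho <-> eps conversion is proportional and invertible", {
  expect_equal(rho_to_eps(0.3, 0), 0)
  expect_equal(rho_to_eps(0.6, 1), 2 / 3, tolerance = 1e-15)  # rho = 1 gives eps_max
  expect_equal(eps_to_rho(0.7, rho_to_eps(0.7, 0.1)), 0.1, tolerance = 1e-15)
  expect_equal(rho_to_eps(0.7, eps_to_rho(0.7, 0.1)), 0.1, tolerance = 1e-15)
})

test_that("independent spike tables are product distributions", {
  st <- independent_spike_table(c(0.5, 0.5))
  expect_equal(st$probs, rep(0.25, 4))
  # target s1 with equal nodes: P = s1^(1/N)
  st6 <- independent_spike_table(rep(0.1^(1 / 6), 6))
  expect_equal(st6$s1, 0.1, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:5) {
    p <- runif(4)
    sti <- independent_spike_table(p)
    expect_equal(sum(sti$probs), 1, tolerance = 1e-12)
    expect_true(all(sti$probs >= 0))
    expect_equal(sti$s1, prod(p), tolerance = 1e-12)
    # word probability = product over nodes
    b <- word_bits(4)
    expect_equal(sti$probs,
                 apply(b, 1, function(x) prod(ifelse(x == 1, p, 1 - p))),
                 tolerance = 1e-14)
  }
})

test_that("subsystem marginal tables match brute-force summation", {
  set.seed(7)
  p <- c(0.2, 0.5, 0.35, 0.6)
  st <- independent_spike_table(p)
  expect_identical(subsystem_spike_table(st, 1:4), st)
  expect_error(subsystem_spike_table(st, integer(0)), "non-empty")
  sub <- subsystem_spike_table(st, c(2, 4))
  b <- word_bits(4)
  brute <- vapply(0:3, function(k) {
    sum(st$probs[b[, 2] == k %% 2 & b[, 4] == k %/% 2])
  }, 0)
  expect_equal(sub$probs, brute, tolerance = 1e-14)
  # independent spiking: sA * sB = s1 across every bipartition
  for (bp in bipartitions(4)) {
    sa <- subsystem_spike_table(st, bp$a)$s1
    sb <- subsystem_spike_table(st, bp$b)$s1
    expect_equal(sa * sb, st$s1, tolerance = 1e-14)
  }
})

test_that("one-time distribution follows p(x) = ps sx with p1 = ps s1 + pb", {
  m <- equal_model(3, 0.3^3, 0.7, 0.1)  # P = 0.3 each
  p <- one_time_dist(m)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(attr(p, "p1"), 0.7 * m$spikes$s1 + 0.3, tolerance = 1e-14)
  # spot-check a non-all-ones word: proportional to sx with factor ps
  expect_equal(p[3], 0.7 * m$spikes$probs[3], tolerance = 1e-14)
  # s1 = 0 model: the all-ones word occurs only through bursts
  st0 <- spike_table(c(0.4, 0.3, 0.3, 0))
  m0 <- spiking_bursting_model(st0, 0.7, 0.1)
  expect_equal(unname(one_time_dist(m0)[4]), 0.3, tolerance = 1e-14)
})

test_that("two-time joint has the closed pi/p11 cells, symmetry and marginals", {
  m <- spiking_bursting_model(independent_spike_table(c(0.4, 0.4)), 0.6, 0.2)
  j <- two_time_joint(m)
  ps <- 0.6; pb <- 0.4; eps <- 0.2; s1 <- 0.16
  pss <- ps^2 * (1 + eps); psb <- ps * pb - eps * ps^2
  pbb <- pb^2 + eps * ps^2
  expect_equal(attr(j, "pi"), pss * s1 + psb, tolerance = 1e-14)
  expect_equal(attr(j, "p11"), pss * s1^2 + 2 * psb * s1 + pbb, tolerance = 1e-14)
  expect_equal(sum(j), 1, tolerance = 1e-12)
  expect_equal(unclass(j), t(unclass(j)), tolerance = 1e-15)
  expect_equal(as.numeric(rowSums(j)), as.numeric(one_time_dist(m)),
               tolerance = 1e-12)
  # eps = 0: the joint factorizes
  m0 <- spiking_bursting_model(independent_spike_table(c(0.4, 0.4)), 0.6, 0)
  j0 <- two_time_joint(m0)
  p0 <- as.numeric(one_time_dist(m0))
  expect_equal(unclass(j0), outer(p0, p0), tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("scaling transform leaves the observable process invariant", {
  m <- spiking_bursting_model(independent_spike_table(c(0.4, 0.4)), 0.6, 0.2)
  expect_equal(two_time_joint(scaling_transform(m, 1)), two_time_joint(m),
               tolerance = 1e-15)
  mt <- scaling_transform(m, 0.9)
  expect_lt(max(abs(two_time_joint(mt) - two_time_joint(m))), 1e-12)
  expect_equal(mt$dichotomous$eps, 0.2)  # eps is scaling-invariant
  # property: random admissible (model, alpha)
  set.seed(21)
  for (i in 1:10) {
    mi <- random_model(3)
    rng <- admissible_alpha(mi)
    a <- runif(1, rng[1], min(rng[2], 2))
    mti <- scaling_transform(mi, a)
    expect_lt(max(abs(two_time_joint(mti) - two_time_joint(mi))), 1e-12)
    expect_lt(max(abs(one_time_dist(mti) - one_time_dist(mi))), 1e-12)
    expect_equal(mti$dichotomous$eps, mi$dichotomous$eps, tolerance = 1e-12)
  }
  expect_error(scaling_transform(m, 100), "admissible interval")
})

test_that("model configs load from JSON and YAML with either parameterization", {
  js <- tempfile(fileext = ".json")
  writeLines(paste0('{"n_nodes": 3, "spike": {"mode": "independent", "p": [0.3, 0.3, 0.3]},',
                    ' "dichotomous": {"pb": 0.3, "rho": 0.3}}'), js)
  m <- read_model_config(js)
  expect_equal(m$dichotomous$ps, 0.7)
  expect_equal(m$dichotomous$eps, rho_to_eps(0.7, 0.3), tolerance = 1e-14)
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("n_nodes: 2", "spike:", "  mode: table",
               "  probs: [0.4, 0.3, 0.2, 0.1]",
               "dichotomous: {ps: 0.6, eps: 0.1}"), yml)
  m2 <- read_model_config(yml)
  expect_equal(m2$spikes$probs, c(0.4, 0.3, 0.2, 0.1))
  expect_equal(m2$dichotomous$eps, 0.1)
  # CSV export carries binary word labels
  csv <- tempfile(fileext = ".csv")
  df <- write_prob_csv(m2$spikes, csv)
  expect_equal(df$word, c("00", "10", "01", "11"))
  expect_true(file.exists(csv))
})

test_that("generated probability tables are valid distributions", {
  set.seed(33)
  for (i in 1:8) {
    m <- random_model(sample(2:5, 1))
    p1 <- one_time_dist(m)
    j <- two_time_joint(m)
    expect_true(all(p1 >= 0) && all(j >= 0))
    expect_equal(sum(p1), 1, tolerance = 1e-12)
    expect_equal(sum(j), 1, tolerance = 1e-12)
    expect_equal(unclass(j), t(unclass(j)), tolerance = 1e-14)
  }
})
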