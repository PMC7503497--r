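test_that("Zwanzig increments handle degenerate and constant perturbations", {
  set.seed(11)
  mk <- function(lambda, eps1, eps2)
    window_sample(lambda, eps1, eps2, replica = 1L)

  # identical mapping energies at every lambda -> all increments zero
  v <- stats::rnorm(200, sd = 5)
  same <- lapply(seq(1, 0, by = -0.25), function(l) mk(l, v, v))
  inc <- zwanzig_increments(same, 300)
  expect_equal(inc$dG, rep(0, 5), tolerance = 1e-12)
  expect_equal(attr(inc, "hysteresis"), 0, tolerance = 1e-12)

  # constant gap g: eps_m changes by exactly (lambda' - lambda) g per step
  g <- 7.5
  const <- lapply(seq(1, 0, by = -0.25),
                  function(l) mk(l, v, v - g))
  inc2 <- zwanzig_increments(const, 300)
  # walking reactant (lambda 1) -> product (lambda 0): total = -g
  expect_equal(inc2$dG[inc2$lambda == 0], -g, tolerance = 1e-10)
  expect_equal(inc2$dG_avg[inc2$lambda == 0], -g, tolerance = 1e-10)
  expect_error(zwanzig_increments(const[1], 300),
               class = "evbfep_protocol_error")
})

test_that("Gaussian windows reproduce the linear-response closed form", {
  s <- harmonic_surrogate(curvature = 2, lambda_reorg = 40, dg0 = 5)
  smp <- surrogate_samples(s, lambdas = seq(1, 0, length.out = 21), n = 5000,
                           replicas = 2, seed = 14)
  inc <- zwanzig_increments(smp, 300)
  beta <- 1 / (R_GAS * 300)
  lam <- vapply(smp, function(w) w$lambda, 0)
  # increment m -> m+1 equals mean(dE) - beta var(dE)/2 for Gaussian dE
  lams <- sort(unique(lam), decreasing = TRUE)
  for (m in c(1, 10, 19)) {
    x <- unlist(lapply(smp[lam == lams[m]], function(w) w$eps1 - w$eps2))
    dE <- (lams[m + 1] - lams[m]) * x
    pred <- mean(dE) - beta * stats::var(dE) / 2
    got <- inc$dG[inc$lambda == lams[m + 1]] - inc$dG[inc$lambda == lams[m]]
    se <- stats::sd(dE) / sqrt(length(dE) / 4)  # conservative
    expect_lt(abs(got - pred), 3 * se + 1e-3)
  }
})

test_that("the full estimator reproduces the Marcus closed form", {
  # zero coupling: cusped crossing at (Lambda + dG0)^2 / (4 Lambda); the
  # histogram apex underestimates a cusp by at most slope*w/2 = w/4 here
  w <- 0.25
  s0 <- harmonic_surrogate(curvature = 2, lambda_reorg = 40, dg0 = 0)
  smp <- surrogate_samples(s0, n = 3000, replicas = 3, seed = 5)
  b <- extract_barriers(us_assemble(smp, h_ij = 0, temperature = 300,
                                    bin_width = w))
  expect_lt(abs(b$dg_act - 10), 3 * max(b$se_act, 0.02) + w / 4)
  expect_lt(abs(b$dg_rxn), 3 * max(b$se_rxn, 0.02))
  expect_lt(abs(b$x_ts), 1)

  # asymmetric case: dG0 = 10 -> barrier 15.625, reaction free energy 10
  s10 <- harmonic_surrogate(curvature = 2, lambda_reorg = 40, dg0 = 10)
  smp10 <- surrogate_samples(s10, n = 3000, replicas = 3, seed = 6)
  b10 <- extract_barriers(us_assemble(smp10, h_ij = 0, temperature = 300,
                                      bin_width = w))
  expect_lt(abs(b10$dg_act - marcus_barrier(s10)),
            3 * max(b10$se_act, 0.02) + w / 4)
  expect_lt(abs(b10$dg_rxn - 10), 3 * max(b10$se_rxn, 0.02))

  # constant coupling h = 4 cuts the crossing by ~h with an O(h^2/Lambda)
  # well-deepening correction
  s4 <- harmonic_surrogate(curvature = 2, lambda_reorg = 40, dg0 = 0,
                           h_ij = 4)
  smp4 <- surrogate_samples(s4, n = 3000, replicas = 3, seed = 7)
  b4 <- extract_barriers(us_assemble(smp4, h_ij = 4, temperature = 300,
                                     bin_width = 0.5))
  expect_lt(abs(b4$dg_act - 6), 3 * max(b4$se_act, 0.02) + 16 / 40)
})

test_that("barrier extraction reads stationary points off binned profiles", {
  # reference-table values used as a hand-built synthetic profile
  p <- free_energy_profile(x = c(-50, 0, 50), dg = c(0, 30.60, 19.18),
                           n = c(100, 100, 100))
  b <- extract_barriers(p)
  expect_equal(b$dg_act, 30.60)
  expect_equal(b$dg_rxn, 19.18)
  expect_equal(b$x_ts, 0)

  # symmetric double well
  xs <- seq(-40, 40, by = 2)
  ps <- free_energy_profile(xs, 10 * (1 - (xs / 40)^2)^2)
  bs <- extract_barriers(ps)
  expect_equal(bs$dg_rxn, 0, tolerance = 1e-12)
  expect_equal(bs$x_ts, 0)

  # monotone profile has no barrier
  pm <- free_energy_profile(xs, 0.3 * xs)
  expect_error(extract_barriers(pm), class = "evbfep_no_barrier_error")
})

test_that("disjoint adjacent windows raise a coverage error", {
  set.seed(2)
  near <- window_sample(1, stats::rnorm(100), stats::rnorm(100) + 60)
  far <- window_sample(0, stats::rnorm(100) + 200, stats::rnorm(100))
  expect_error(us_assemble(list(near, far), h_ij = 0),
               class = "evbfep_coverage_error")
})

test_that("profile is gauge invariant and monotone in the coupling", {
  sys <- toy_system(alpha = 20, h_ij = 5)
  sched <- fast_schedule(n_steps = 2000, replicas = 2)
  smp <- run_protocol(sys, sched, seed = 21)

  shifted <- toy_system(alpha = 20, h_ij = 5)
  shifted$state1$shift <- shifted$state1$shift + 55
  shifted$state2$shift <- shifted$state2$shift + 55
  smp_s <- run_protocol(shifted, sched, seed = 21)
  p1 <- us_assemble(smp, h_ij = 5, temperature = 300)
  p2 <- us_assemble(smp_s, h_ij = 5, temperature = 300)
  expect_equal(p1$dg, p2$dg, tolerance = 1e-9)
  expect_equal(p1$x, p2$x)

  # increasing h_ij strictly lowers the barrier (same samples re-analysed)
  acts <- vapply(c(0, 10, 20, 40), function(h)
    extract_barriers(us_assemble(smp, h_ij = h, temperature = 300))$dg_act, 0)
  expect_true(all(diff(acts) < 0))
})

test_that("pipeline is deterministic and robust to binning and schedule density", {
  sys <- toy_system(alpha = 39, h_ij = 13.7)
  sched <- fast_schedule(n_windows = 51, n_steps = 2500, replicas = 2)
  r1 <- profile_pipeline(sys, sched, seed = 10)
  r2 <- profile_pipeline(sys, sched, seed = 10)
  expect_identical(r1$barriers$dg_act, r2$barriers$dg_act)
  expect_identical(r1$profile$dg, r2$profile$dg)

  # doubling the bin width moves the (smooth) barrier by < 0.2 kcal/mol
  smp <- run_protocol(sys, sched, seed = 10)
  a2 <- extract_barriers(us_assemble(smp, h_ij = 13.7, bin_width = 2))$dg_act
  a4 <- extract_barriers(us_assemble(smp, h_ij = 13.7, bin_width = 4))$dg_act
  expect_lt(abs(a2 - a4), 0.2)

  # halving the schedule density agrees within pooled errors
  r26 <- profile_pipeline(sys, fast_schedule(n_windows = 26, n_steps = 2500,
                                             replicas = 2), seed = 12)
  pooled <- sqrt(max(r1$barriers$se_act, 0.1)^2 +
                 max(r26$barriers$se_act, 0.1)^2)
  expect_lt(abs(r1$barriers$dg_act - r26$barriers$dg_act), 3 * pooled)
})
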