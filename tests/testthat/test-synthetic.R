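test_that("toy builder realises the requested reorganization energy", {
  sys <- toy_system(lambda_reorg = 40, n_bath = 10, k_bath = 2)
  bath2 <- sys$state2$harmonic
  bath2 <- bath2[is.na(bath2$j) | bath2$j < 1, ]
  expect_equal(nrow(bath2), 10)
  lam <- sum(0.5 * bath2$k * bath2$r0^2)
  expect_equal(lam, 40, tolerance = 1e-6)
  # generator bookkeeping at other settings
  sys2 <- toy_system(lambda_reorg = 17.3, n_bath = 7, k_bath = 3.5)
  b2 <- sys2$state2$harmonic
  b2 <- b2[is.na(b2$j) | b2$j < 1, ]
  expect_equal(sum(0.5 * b2$k * b2$r0^2), 17.3, tolerance = 1e-6)
  # state 1 bath sits at the origin
  b1 <- sys$state1$harmonic
  expect_true(all(b1$r0[is.na(b1$j) | b1$j < 1] == 0))
  expect_error(toy_system(lambda_reorg = -5), class = "evbfep_parameter_error")
  expect_error(toy_system(lambda_reorg = 10, n_bath = 0),
               class = "evbfep_parameter_error")
})

test_that("toy builder wires the reacting bonds per state", {
  sys <- toy_system()
  expect_equal(unlist(sys$state1$morse[1, c("i", "j")], use.names = FALSE),
               c(1, 2))  # C-H in reactants
  expect_equal(unlist(sys$state2$morse[1, c("i", "j")], use.names = FALSE),
               c(2, 3))  # H-N in products
  expect_equal(sys$particles$role[1:3], c("donor-C", "hydride-H", "acceptor-N"))
})

test_that("a symmetrised toy gives a thermoneutral profile", {
  sym <- toy_system(alpha = 0, h_ij = 0,
                    morse_nh = c(D = 100, b = 2.0, r0 = 1.09),
                    buck_cn = c(A = 20000, B = 3.8, C = 120),
                    charges1 = c(C = -0.1, H = 0.1, N = 0),
                    charges2 = c(C = 0, H = 0.1, N = -0.1))
  res <- profile_pipeline(sym, fast_schedule(n_steps = 4000, replicas = 3),
                          seed = 31)
  tol <- 3 * max(res$barriers$se_rxn, 0.15, na.rm = TRUE)
  expect_lt(abs(res$barriers$dg_rxn), tol)
})

test_that("surrogate windows are exact Gaussians with the closed-form variance", {
  s <- harmonic_surrogate(curvature = 2, lambda_reorg = 40, dg0 = 3, h_ij = 0)
  expect_equal(s$lambda_reorg, 0.5 * s$curvature * s$d^2)
  smp <- surrogate_samples(s, lambdas = c(1, 0.5, 0), n = 4000, replicas = 1,
                           seed = 2)
  kT <- R_GAS * 300
  var_gap <- (s$curvature * s$d)^2 * kT / s$curvature  # = 2*Lambda*kT
  for (w in smp) {
    x <- w$eps1 - w$eps2
    se_var <- var_gap * sqrt(2 / (length(x) - 1))
    expect_lt(abs(stats::var(x) - var_gap), 3 * se_var)
    # mean gap: E[X] = k d ((1-lambda) d) - k d^2/2 - dg0
    mu <- s$curvature * s$d^2 * (1 - w$lambda) - s$curvature * s$d^2 / 2 - s$dg0
    expect_lt(abs(mean(x) - mu), 3 * sqrt(var_gap / length(x)))
    # normality of the linear-response window (documented check:
    # Shapiro-Wilk at n = 1500, alpha = 0.01)
    expect_gt(stats::shapiro.test(x[1:1500])$p.value, 0.01)
  }
})

test_that("surrogate sampling is deterministic and window-stable", {
  s <- harmonic_surrogate(curvature = 2, lambda_reorg = 30, dg0 = 0)
  a <- surrogate_samples(s, lambdas = c(1, 0.5, 0), n = 50, seed = 9)
  b <- surrogate_samples(s, lambdas = c(1, 0.5, 0), n = 50, seed = 9)
  expect_identical(lapply(a, `[[`, "eps1"), lapply(b, `[[`, "eps1"))
  # adding windows must not perturb existing ones
  wide <- surrogate_samples(s, lambdas = c(1, 0.75, 0.5, 0.25, 0), n = 50,
                            seed = 9)
  expect_identical(a[[2]]$eps1, wide[[3]]$eps1)
  # T -> 0 limit collapses onto the mapping-potential minimum
  cold <- surrogate_samples(s, lambdas = 0.5, n = 20, temperature = 1e-6,
                            replicas = 1, seed = 4)[[1]]
  x_min <- 0.5 * s$d
  x_back <- (cold$eps1 * 2 / s$curvature)^0.5  # invert eps1 = k x^2/2
  expect_lt(max(abs(x_back - x_min)), 1e-3)
})

test_that("toy per-window gap distributions are near-Gaussian", {
  smp <- run_protocol(toy_system(),
                      evb_schedule(n_windows = 5, n_steps = 8000,
                                   replicas = 2), seed = 5)
  lam <- vapply(smp, function(w) w$lambda, 0)
  for (lv in c(0.25, 0.5, 0.75)) {
    x <- unlist(lapply(smp[lam == lv], function(w) w$eps1 - w$eps2))
    kurt <- mean((x - mean(x))^4) / stats::var(x)^2 - 3
    expect_lt(abs(kurt), 0.5)
  }
})

test_that("fixtures round-trip and regenerate deterministically", {
  s <- harmonic_surrogate(curvature = 2, lambda_reorg = 40, dg0 = 0)
  smp <- surrogate_samples(s, lambdas = c(1, 0.5, 0), n = 40, replicas = 2,
                           seed = 20200826)
  d <- file.path(tempfile(), "wins")
  write_fixture(smp, d)
  back <- read_window_files(d)
  expect_equal(length(back), length(smp))
  ord <- order(vapply(smp, function(w) w$lambda * 10 + w$replica, 0))
  bord <- order(vapply(back, function(w) w$lambda * 10 + w$replica, 0))
  for (i in seq_along(ord)) {
    expect_lt(max(abs(back[[bord[i]]]$eps1 - smp[[ord[i]]]$eps1)), 1e-9)
    expect_lt(max(abs(back[[bord[i]]]$eps2 - smp[[ord[i]]]$eps2)), 1e-9)
  }
  expect_error(write_fixture(list(), tempfile()),
               class = "evbfep_parameter_error")
  # full fixture regeneration under the documented seed is byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  regenerate_fixtures(d1); regenerate_fixtures(d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
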