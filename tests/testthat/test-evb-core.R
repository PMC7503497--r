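test_that("diabatic energies reproduce term-by-term arithmetic", {
  # Morse well minimum: single bond at r0, everything else zero -> -D
  sys <- mini_system(morse1 = morse_term(1, 2, 100, 2, 1.09),
                     morse2 = morse_term(2, 3, 105, 2.2, 1.01))
  e <- diabatic_energies(sys, c(0, 1.09, 1.09 + 1.01))
  expect_equal(unname(e["eps1"]), -100)
  expect_equal(unname(e["eps2"]), -105)

  # product-shift linearity: raising state2's shift by the reference
  # alpha_0 magnitude raises eps2 by exactly that amount
  sys80 <- mini_system(shift2 = 80.40)
  x <- c(0, 1.2, 2.5)
  expect_equal(diabatic_energies(sys80, x)[["eps2"]] -
                 diabatic_energies(sys, x)[["eps2"]], 80.40)
  expect_equal(diabatic_energies(sys80, x)[["eps1"]],
               diabatic_energies(sys, x)[["eps1"]])

  # Buckingham pair at r = 2 with A = 1e4, B = 3, C = 100: independent
  # hand computation of A*exp(-B*r) - C/r^6
  sysb <- mini_system(buck1 = buckingham_term(1, 3, 1e4, 3, 100))
  r_ch <- 1.09
  base <- diabatic_energies(mini_system(), c(0, r_ch, 2))[["eps1"]]
  withb <- diabatic_energies(sysb, c(0, r_ch, 2))[["eps1"]]
  expect_equal(withb - base, 1e4 * exp(-3 * 2) - 100 / 2^6, tolerance = 1e-12)

  # Coulomb: two unit-ish charges at 2 A
  sysq <- mini_system(charges1 = c(0.3, 0, -0.2))
  withq <- diabatic_energies(sysq, c(0, r_ch, 2))[["eps1"]]
  expect_equal(withq - base, 332.0636 * 0.3 * (-0.2) / 2, tolerance = 1e-12)
})

test_that("configuration validation errors are raised", {
  sys <- mini_system()
  expect_error(diabatic_energies(sys, c(0, 1)), class = "evbfep_shape_error")
  expect_error(diabatic_energies(sys, c(0, NaN, 2)),
               class = "evbfep_configuration_error")
  expect_error(mini_system(morse1 = morse_term(1, 2, -5, 2, 1)),
               class = "evbfep_parameter_error")
  bad_particles <- data.frame(label = c("a", "b"), mass = c(1, 1),
                              role = c("donor-C", "bath"))
  st <- evb_state(charges = c(0, 0))
  expect_error(evb_system(st, st, 0, bad_particles, c(0, 1)),
               class = "evbfep_parameter_error")
  expect_error(evb_system(st, st, -1,
                          data.frame(label = c("C", "H", "N"),
                                     mass = c(12, 1, 14),
                                     role = c("donor-C", "hydride-H",
                                              "acceptor-N")),
                          c(0, 1, 2)),
               class = "evbfep_parameter_error")
})

test_that("mapping energy follows the linear lambda blend", {
  expect_identical(mapping_energy(10, 20, 1), 10)
  expect_identical(mapping_energy(10, 20, 0), 20)
  expect_identical(mapping_energy(10, 20, 0.5), 15)
  expect_error(mapping_energy(10, 20, 1.2), class = "evbfep_domain_error")
  expect_error(mapping_energy(10, 20, -0.1), class = "evbfep_domain_error")
  # midpoint equals the arithmetic mean to machine precision
  set.seed(1)
  for (i in 1:20) {
    e <- stats::rnorm(2, sd = 100)
    expect_identical(mapping_energy(e[1], e[2], 0.5), mean(e))
  }
})

test_that("ground-state energy is the lower 2x2 eigenvalue", {
  expect_equal(ground_state_energy(0, 0, 44.34), -44.34)
  expect_equal(ground_state_energy(0, 100, 0), 0)
  # independent eigenvalue oracle
  eig <- function(e1, e2, h) min(eigen(matrix(c(e1, h, h, e2), 2))$values)
  expect_equal(ground_state_energy(10, 20, 5), eig(10, 20, 5),
               tolerance = 1e-12)
  expect_equal(round(ground_state_energy(10, 20, 5), 4), 7.9289)
  set.seed(7)
  for (i in 1:25) {
    e1 <- stats::rnorm(1, sd = 50); e2 <- stats::rnorm(1, sd = 50)
    h <- stats::runif(1, 0, 30)
    Eg <- ground_state_energy(e1, e2, h)
    expect_equal(Eg, eig(e1, e2, h), tolerance = 1e-10)
    # symmetry, bound, and coupling monotonicity
    expect_equal(Eg, ground_state_energy(e2, e1, h))
    expect_lte(Eg, min(e1, e2))
    expect_lt(ground_state_energy(e1, e2, h + 1), Eg)
    # gauge: shifting both diabats shifts E_g by the same constant
    cst <- stats::rnorm(1, sd = 20)
    expect_equal(ground_state_energy(e1 + cst, e2 + cst, h), Eg + cst,
                 tolerance = 1e-10)
  }
  expect_identical(ground_state_energy(3, 9, 0), 3)
  expect_error(ground_state_energy(1, 2, -0.5), class = "evbfep_domain_error")
})

test_that("system serialization round-trips", {
  sys <- toy_system(alpha = 12.5, h_ij = 7.25)
  f <- tempfile(fileext = ".json")
  write_evb_system(sys, f)
  back <- read_evb_system(f)
  set.seed(3)
  for (i in 1:5) {
    x <- sys$x0 + stats::rnorm(length(sys$x0), sd = 0.05)
    expect_equal(diabatic_energies(back, x), diabatic_energies(sys, x),
                 tolerance = 1e-12)
  }
  expect_equal(back$h_ij, sys$h_ij)
  expect_equal(back$state2$shift, sys$state2$shift)
  expect_equal(back$particles$role, sys$particles$role)
  expect_error(read_evb_system(tempfile()), class = "evbfep_io_error")
})
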