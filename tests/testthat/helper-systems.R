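# Shared builders for small test systems.

R_GAS <- 1.987204e-3  # kcal/mol/K, package-wide convention

# Minimal three-particle system: one Morse bond per state, no nonbonded
# terms unless supplied.  Useful for term-level arithmetic checks.
mini_system <- function(morse1 = morse_term(1, 2, 100, 2, 1.09),
                        morse2 = morse_term(2, 3, 105, 2.2, 1.01),
                        buck1 = NULL, buck2 = NULL,
                        charges1 = rep(0, 3), charges2 = rep(0, 3),
                        shift1 = 0, shift2 = 0, h_ij = 0) {
  particles <- data.frame(label = c("C", "H", "N"),
                          mass = c(12.011, 1.008, 14.007),
                          role = c("donor-C", "hydride-H", "acceptor-N"))
  evb_system(
    evb_state(morse = morse1, buckingham = buck1, charges = charges1,
              shift = shift1),
    evb_state(morse = morse2, buckingham = buck2, charges = charges2,
              shift = shift2),
    h_ij, particles, x0 = c(0, 1.09, 2.8))
}

# A single tethered harmonic degree of freedom (in state-1 form), used for
# thermostat checks.  The triad particles carry no forces.
oscillator_system <- function(k = 10, mass = 12) {
  particles <- data.frame(label = c("C", "H", "N", "osc"),
                          mass = c(12.011, 1.008, 14.007, mass),
                          role = c("donor-C", "hydride-H", "acceptor-N", "bath"))
  st <- evb_state(harmonic = harmonic_term(4, NA, k, 0), charges = rep(0, 4))
  evb_system(st, st, 0, particles, x0 = c(0, 1.09, 2.8, 0))
}

# Fast toy schedule for unit tests (acceptance tests use the defaults).
fast_schedule <- function(n_windows = 26L, n_steps = 3000L, replicas = 2L, ...)
  evb_schedule(n_windows = n_windows, n_steps = n_steps, replicas = replicas, ...)

expect_barrier_close <- function(b, act, rxn, tol) {
  expect_lt(abs(b$dg_act - act), tol)
  expect_lt(abs(b$dg_rxn - rxn), tol)
}
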