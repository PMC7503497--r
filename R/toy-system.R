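# Synthetic reacting systems: a collinear donor/hydride/acceptor triad with
# a displaced harmonic bath (tunable reorganization energy), and an exactly
# solvable harmonic surrogate used as a Marcus oracle.

#' Build the default toy hydride-transfer system
#'
#' A 1-D collinear model of hydride abstraction: a donor carbon, the
#' transferring hydride and an acceptor nitrogen, plus `n_bath` harmonic
#' bath oscillators whose equilibrium positions differ between the two
#' diabatic states so that the realised reorganization energy equals
#' `lambda_reorg` (each oscillator displaced by
#' `d = sqrt(2 * lambda_reorg / (n_bath * k_bath))`, giving
#' `sum(k_bath * d^2 / 2) = lambda_reorg` exactly).
#'
#' State 1 (reactants) carries a C--H Morse bond; state 2 (products) an
#' H--N Morse bond plus the calibratable shift `alpha`.  Both states share
#' a flat-bottom donor--acceptor distance restraint active beyond
#' `restraint_r`.  Nonbonded pairs among the reacting triad use Buckingham
#' exponential-6 terms with a softened dispersion, and state-dependent
#' point charges model the charge separation of the hydride transfer.
#'
#' @param lambda_reorg target bath reorganization energy, kcal/mol (>= 0).
#' @param n_bath number of bath oscillators (>= 1 unless `lambda_reorg = 0`).
#' @param k_bath bath force constant, kcal/mol/A^2.
#' @param bath_mass bath particle mass, amu.
#' @param alpha product-state shift, kcal/mol.
#' @param h_ij constant off-diagonal coupling, kcal/mol.
#' @param morse_ch,morse_nh named vectors `c(D, b, r0)` for the C--H and
#'   N--H Morse bonds.
#' @param restraint_k,restraint_r flat-bottom donor--acceptor restraint
#'   force constant (kcal/mol/A^2) and onset distance (A).
#' @param buck_hn,buck_ch,buck_cn named vectors `c(A, B, C)` for the
#'   nonbonded Buckingham pairs (H..N and C..N in state 1; C..H and C..N in
#'   state 2).
#' @param rsoft dispersion softening radius for toy Buckingham terms (A).
#' @param charges1,charges2 named triad charges `c(C, H, N)` per state.
#' @param temperature default temperature, K.
#' @return an `evb_system`.
#' @export
toy_system <- function(lambda_reorg = 40, n_bath = 10L, k_bath = 2,
                       bath_mass = 10,
                       alpha = 0, h_ij = 0,
                       morse_ch = c(D = 100, b = 2.0, r0 = 1.09),
                       morse_nh = c(D = 105, b = 2.2, r0 = 1.01),
                       restraint_k = 5, restraint_r = 3,
                       buck_hn = c(A = 2000, B = 3.8, C = 20),
                       buck_ch = c(A = 2000, B = 3.8, C = 20),
                       buck_cn = c(A = 20000, B = 3.8, C = 120),
                       rsoft = 1.0,
                       charges1 = c(C = -0.10, H = 0.10, N = 0.00),
                       charges2 = c(C = 0.40, H = 0.00, N = -0.40),
                       temperature = 300) {
  if (!is.finite(lambda_reorg) || lambda_reorg < 0)
    .stopf("unrealizable reorganization energy: lambda_reorg = %s",
           lambda_reorg, class = "evbfep_parameter_error")
  n_bath <- as.integer(n_bath)
  if (lambda_reorg > 0 && (n_bath < 1L || k_bath <= 0))
    .stopf("need n_bath >= 1 and k_bath > 0 to realise lambda_reorg > 0",
           class = "evbfep_parameter_error")
  if (n_bath < 0L) .stopf("n_bath must be >= 0", class = "evbfep_parameter_error")

  d <- if (n_bath > 0L) sqrt(2 * lambda_reorg / (n_bath * k_bath)) else numeric(0)

  n <- 3L + n_bath
  particles <- data.frame(
    label = c("C", "H", "N", if (n_bath > 0) paste0("b", seq_len(n_bath))),
    mass = c(12.011, 1.008, 14.007, rep(bath_mass, n_bath)),
    role = c("donor-C", "hydride-H", "acceptor-N", rep("bath", n_bath)),
    stringsAsFactors = FALSE)
  bath_idx <- if (n_bath > 0) 3L + seq_len(n_bath) else integer(0)

  restr <- harmonic_term(1L, 3L, restraint_k, restraint_r, flat = TRUE)
  bath1 <- if (n_bath > 0)
    harmonic_term(bath_idx, NA, k_bath, 0) else NULL
  bath2 <- if (n_bath > 0)
    harmonic_term(bath_idx, NA, k_bath, rep(d, n_bath)) else NULL

  q1 <- c(charges1[["C"]], charges1[["H"]], charges1[["N"]], rep(0, n_bath))
  q2 <- c(charges2[["C"]], charges2[["H"]], charges2[["N"]], rep(0, n_bath))

  st1 <- evb_state(
    morse = morse_term(1L, 2L, morse_ch[["D"]], morse_ch[["b"]], morse_ch[["r0"]]),
    harmonic = rbind(restr, bath1),
    buckingham = rbind(
      buckingham_term(2L, 3L, buck_hn[["A"]], buck_hn[["B"]], buck_hn[["C"]], rsoft),
      buckingham_term(1L, 3L, buck_cn[["A"]], buck_cn[["B"]], buck_cn[["C"]], rsoft)),
    charges = q1, shift = 0)
  st2 <- evb_state(
    morse = morse_term(2L, 3L, morse_nh[["D"]], morse_nh[["b"]], morse_nh[["r0"]]),
    harmonic = rbind(restr, bath2),
    buckingham = rbind(
      buckingham_term(1L, 2L, buck_ch[["A"]], buck_ch[["B"]], buck_ch[["C"]], rsoft),
      buckingham_term(1L, 3L, buck_cn[["A"]], buck_cn[["B"]], buck_cn[["C"]], rsoft)),
    charges = q2, shift = alpha)

  x0 <- c(0, morse_ch[["r0"]], 2.8, rep(0, n_bath))
  sys <- evb_system(st1, st2, h_ij, particles, x0, temperature)
  sys$lambda_reorg <- lambda_reorg
  sys
}

#' Analytic harmonic surrogate (Marcus model)
#'
#' Two 1-D harmonic diabats of equal curvature `k` with minima separated by
#' `d` and a product offset `dg0`:
#' `eps1 = k x^2 / 2`, `eps2 = k (x - d)^2 / 2 + dg0`.  The implied
#' reorganization energy is `lambda_reorg = k d^2 / 2` and, at `h_ij = 0`,
#' the diabatic crossing height is `(lambda_reorg + dg0)^2 / (4
#' lambda_reorg)` exactly — the Marcus closed form used as an independent
#' oracle for the FEP/US estimator.
#'
#' Specify either `d` or `lambda_reorg` (the other is derived).
#'
#' @param curvature shared force constant `k`, kcal/mol/A^2.
#' @param d diabat minima separation, A.
#' @param dg0 product-minus-reactant free energy offset, kcal/mol.
#' @param h_ij constant coupling, kcal/mol.
#' @param lambda_reorg reorganization energy, kcal/mol (alternative to `d`).
#' @return an object of class `harmonic_surrogate`.
#' @export
harmonic_surrogate <- function(curvature = 2, d = NULL, dg0 = 0, h_ij = 0,
                               lambda_reorg = NULL) {
  if (is.null(d) && is.null(lambda_reorg))
    .stopf("supply d or lambda_reorg", class = "evbfep_parameter_error")
  if (is.null(d)) {
    if (lambda_reorg <= 0)
      .stopf("unrealizable reorganization energy: %s", lambda_reorg,
             class = "evbfep_parameter_error")
    d <- sqrt(2 * lambda_reorg / curvature)
  }
  if (curvature <= 0)
    .stopf("curvature must be positive", class = "evbfep_parameter_error")
  if (h_ij < 0) .stopf("h_ij must be >= 0", class = "evbfep_parameter_error")
  structure(list(curvature = curvature, d = d, dg0 = dg0, h_ij = h_ij,
                 lambda_reorg = 0.5 * curvature * d^2),
            class = "harmonic_surrogate")
}

#' Exact Gaussian window samples from the harmonic surrogate
#'
#' On the mapping potential `eps_m = lambda eps1 + (1 - lambda) eps2` the
#' surrogate coordinate is exactly Gaussian with mean `(1 - lambda) d` and
#' variance `kB T / k`; samples are drawn from that stationary distribution
#' directly (no integrator error) and converted to per-frame
#' `(eps1, eps2)` pairs.  Each (window, replica) uses a sub-seed derived
#' from `seed`, so extending the schedule never perturbs existing windows.
#'
#' @param s a `harmonic_surrogate`.
#' @param lambdas mapping schedule (values in `[0, 1]`).
#' @param n frames per window per replica (>= 1).
#' @param temperature K (> 0).
#' @param replicas number of independent replicas.
#' @param seed base seed.
#' @return list of `window_sample` objects.
#' @export
surrogate_samples <- function(s, lambdas = seq(1, 0, length.out = 51),
                              n = 2000, temperature = 300, replicas = 3,
                              seed = 1) {
  stopifnot(inherits(s, "harmonic_surrogate"))
  if (n < 1) .stopf("n must be >= 1", class = "evbfep_parameter_error")
  if (temperature <= 0)
    .stopf("temperature must be > 0", class = "evbfep_parameter_error")
  k <- s$curvature; d <- s$d
  sd_x <- sqrt(.GAS_R * temperature / k)
  out <- list()
  for (r in seq_len(replicas)) {
    for (w in seq_along(lambdas)) {
      lam <- lambdas[w]
      sub <- derive_seed(seed, round(lam * 1e6), r)
      set.seed(sub)
      x <- (1 - lam) * d + sd_x * stats::rnorm(n)
      e1 <- 0.5 * k * x^2
      e2 <- 0.5 * k * (x - d)^2 + s$dg0
      out[[length(out) + 1L]] <- window_sample(
        lambda = lam, eps1 = e1, eps2 = e2, replica = r,
        temperature = temperature, seed = sub, n_equil = 0L, dt = NA_real_)
    }
  }
  out
}

#' Closed-form Marcus barrier of a harmonic surrogate
#'
#' `(lambda_reorg + dg0)^2 / (4 lambda_reorg)` — the diabatic crossing
#' height at zero coupling.
#'
#' @param s a `harmonic_surrogate`.
#' @return barrier in kcal/mol.
#' @export
marcus_barrier <- function(s) {
  (s$lambda_reorg + s$dg0)^2 / (4 * s$lambda_reorg)
}
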