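# Calibration of the two free EVB parameters: the off-diagonal coupling
# h_ij (controls the activation free energy) and the product-state shift
# alpha (controls the reaction free energy), fitted so the simulated
# FEP/US profile reproduces reference activation and reaction free
# energies.
#
# Key structural fact exploited here: neither h_ij nor alpha changes the
# forces on the mapping potential (alpha enters eps_m only as a
# configuration-independent constant, h_ij not at all), so trajectories
# depend on neither parameter.  Within one outer iteration the same
# window samples are therefore re-analysed at trial (h_ij, alpha) values
# — exact common random numbers, which makes the damped alternating
# secant updates noise-free.  Each outer iteration redraws samples under
# a fresh derived sub-seed, and convergence is judged on fresh samples.

#' Calibration target
#'
#' @param dg_act reference activation free energy, kcal/mol.
#' @param dg_rxn reference reaction free energy, kcal/mol.
#' @param tolerance per-observable convergence tolerance, kcal/mol.
#' @param label inhibitor / target id.
#' @return object of class `calibration_target`.
#' @export
calibration_target <- function(dg_act, dg_rxn, tolerance = 0.3,
                               label = "custom") {
  if (!is.finite(dg_act) || !is.finite(dg_rxn))
    .stopf("targets must be finite", class = "evbfep_parameter_error")
  if (dg_act < max(0, dg_rxn))
    .stopf("dg_act must be >= max(0, dg_rxn) (got %.3f < %.3f)",
           dg_act, max(0, dg_rxn), class = "evbfep_parameter_error")
  if (tolerance <= 0)
    .stopf("tolerance must be positive", class = "evbfep_parameter_error")
  structure(list(dg_act = dg_act, dg_rxn = dg_rxn, tolerance = tolerance,
                 label = label),
            class = "calibration_target")
}

# Observables at (h, dalpha) by re-analysis of collated samples.
.observe <- function(col, h, dalpha, temperature, bin_width, min_count) {
  prof <- .profile_from_col(col, h, temperature, bin_width, min_count,
                            dalpha = dalpha)
  extract_barriers(prof)
}

# On fixed samples, solve the two-target system by alternating damped
# secant: alpha against dg_rxn (near-unit sensitivity) first, then h_ij
# against dg_act (monotone decreasing), a few cycles.
.inner_fit <- function(col, h, dalpha, target, temperature, bin_width,
                       min_count, damping = 0.8, cycles = 4L) {
  obs <- .observe(col, h, dalpha, temperature, bin_width, min_count)
  for (cyc in seq_len(cycles)) {
    # alpha step: slope of dg_rxn in alpha is ~1; refine by secant
    slope <- 1
    r0 <- obs$dg_rxn - target$dg_rxn
    if (abs(r0) > 1e-3) {
      step0 <- -damping * r0 / slope
      obs1 <- .observe(col, h, dalpha + step0, temperature, bin_width, min_count)
      s_emp <- (obs1$dg_rxn - obs$dg_rxn) / step0
      if (is.finite(s_emp) && s_emp > 0.2) {
        dalpha <- dalpha + step0 - damping * (obs1$dg_rxn - target$dg_rxn) / s_emp
      } else {
        dalpha <- dalpha + step0
      }
      obs <- .observe(col, h, dalpha, temperature, bin_width, min_count)
    }
    # h step: secant on dg_act, slope ~ -1, h kept non-negative
    r0 <- obs$dg_act - target$dg_act
    if (abs(r0) > 1e-3) {
      step0 <- damping * r0            # slope -1 guess
      h1 <- max(0, h + step0)
      if (h1 != h) {
        obs1 <- .observe(col, h1, dalpha, temperature, bin_width, min_count)
        s_emp <- (obs1$dg_act - obs$dg_act) / (h1 - h)
        if (is.finite(s_emp) && s_emp < -0.2) {
          h <- max(0, h1 - damping * (obs1$dg_act - target$dg_act) / s_emp)
        } else {
          h <- h1
        }
        obs <- .observe(col, h, dalpha, temperature, bin_width, min_count)
      }
    }
  }
  list(h = h, dalpha = dalpha, obs = obs)
}

#' Calibrate (h_ij, alpha) against reference energetics
#'
#' Iteratively fits the coupling and product shift of `system` so the
#' FEP/US profile reproduces `target$dg_act` and `target$dg_rxn` within
#' `target$tolerance`.  Each outer iteration draws fresh window samples
#' under a derived sub-seed, solves the two-parameter system on those
#' samples by damped alternating secant (alpha against the reaction free
#' energy first, then h_ij against the barrier), and convergence is
#' declared only when a fresh evaluation meets both tolerances.  Returns
#' the last iterate with an honest `converged` flag; an unreachable
#' barrier (target above the h_ij = 0 barrier) raises an infeasibility
#' error.
#'
#' @param system template `evb_system`; its `h_ij` and `state2$shift` are
#'   the free parameters (current values are the starting guess).
#' @param target a [calibration_target()], or a label accepted by
#'   [reference_energetics()] (`"rasagiline"`, `"selegiline"`).
#' @param schedule an `evb_schedule`.
#' @param seed base seed; iteration i samples under `derive_seed(seed, i)`.
#' @param max_iter maximum outer iterations.
#' @param bin_width,min_count umbrella binning controls.
#' @return object of class `calibration_result`: fitted `h_ij`, `alpha`,
#'   achieved observables with standard errors, iteration trace,
#'   `converged` flag, and the calibrated system (`$system`).
#' @export
calibrate_evb <- function(system, target, schedule = evb_schedule(),
                          seed = 1, max_iter = 30L, bin_width = 2,
                          min_count = 20) {
  stopifnot(inherits(system, "evb_system"))
  if (is.character(target)) {
    ref <- reference_energetics(target)
    target <- calibration_target(ref$dg_ts, ref$dg_intermediate,
                                 label = ref$inhibitor)
  }
  stopifnot(inherits(target, "calibration_target"))
  alpha0 <- system$state2$shift
  h <- system$h_ij
  dalpha <- 0
  trace <- list()
  converged <- FALSE
  obs <- NULL
  for (it in seq_len(max_iter)) {
    sub <- derive_seed(seed, it)
    samples <- run_protocol(system, schedule, sub)
    col <- .collate_samples(samples)
    # fresh-sample evaluation at the current iterate
    obs <- .observe(col, h, dalpha, schedule$temperature, bin_width, min_count)
    trace[[it]] <- data.frame(iter = it, h_ij = h, alpha = alpha0 + dalpha,
                              dg_act = obs$dg_act, dg_rxn = obs$dg_rxn,
                              seed = sub)
    if (abs(obs$dg_act - target$dg_act) <= target$tolerance &&
        abs(obs$dg_rxn - target$dg_rxn) <= target$tolerance) {
      converged <- TRUE
      break
    }
    if (it == 1L) {
      # feasibility: the h_ij = 0 barrier at the rxn-matched alpha is the
      # largest achievable activation free energy
      da0 <- dalpha + (target$dg_rxn - obs$dg_rxn)
      ob0 <- .observe(col, 0, da0, schedule$temperature, bin_width, min_count)
      if (ob0$dg_act < target$dg_act - target$tolerance)
        .stopf(paste("infeasible target: dg_act = %.2f exceeds the h_ij = 0",
                     "barrier %.2f at the matching alpha"),
               target$dg_act, ob0$dg_act, class = "evbfep_infeasible_error")
    }
    fit <- .inner_fit(col, h, dalpha, target, schedule$temperature,
                      bin_width, min_count)
    h <- fit$h; dalpha <- fit$dalpha
  }
  fitted <- system
  fitted$h_ij <- h
  fitted$state2$shift <- alpha0 + dalpha
  structure(list(h_ij = h, alpha = alpha0 + dalpha,
                 dg_act = obs$dg_act, dg_rxn = obs$dg_rxn,
                 se_act = obs$se_act, se_rxn = obs$se_rxn,
                 iterations = length(trace), converged = converged,
                 target = target, seed = seed,
                 trace = do.call(rbind, trace), system = fitted),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration [%s]: %s after %d iteration(s)\n",
              x$target$label, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  h_ij = %.3f, alpha = %.3f kcal/mol\n", x$h_ij, x$alpha))
  cat(sprintf("  dg_act = %.2f (target %.2f), dg_rxn = %.2f (target %.2f)\n",
              x$dg_act, x$target$dg_act, x$dg_rxn, x$target$dg_rxn))
  invisible(x)
}

#' Transfer calibrated parameters to another system
#'
#' Overwrites `h_ij` and the product shift of `other` with the fitted
#' values — the EVB transferability step (parameters fitted against the
#' reference reaction are applied unchanged to a perturbed environment).
#' Refuses unconverged results.
#'
#' @param result a converged `calibration_result`.
#' @param other the target `evb_system`.
#' @return `other` with `h_ij` and `state2$shift` replaced; everything
#'   else untouched.
#' @export
transfer_parameters <- function(result, other) {
  stopifnot(inherits(result, "calibration_result"),
            inherits(other, "evb_system"))
  if (!isTRUE(result$converged))
    .stopf("refusing to transfer parameters from an unconverged calibration",
           class = "evbfep_unconverged_error")
  other$h_ij <- result$h_ij
  other$state2$shift <- result$alpha
  other
}
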