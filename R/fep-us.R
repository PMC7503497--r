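# FEP/US estimator: Zwanzig increments over the lambda schedule, umbrella
# binning on the diabatic energy-gap coordinate X = eps1 - eps2, assembly of
# the adiabatic ground-state free-energy profile, and barrier extraction.
#
# Sign convention: reactants (state 1 low) sit at negative X, products at
# positive X.  The reactant endpoint of the mapping is lambda = 1.

# --- internal collated representation -------------------------------------
# Everything the estimator needs is the per-frame gap X per window: with
# S = eps1 + eps2,  eps_m = S/2 + (lambda - 1/2) X  and
# E_g = S/2 - sqrt(X^2 + 4 h^2)/2, so E_g - eps_m and all FEP increments
# are functions of X alone.  A constant added to the product shift enters
# as X -> X - dalpha.

.collate_samples <- function(samples) {
  if (length(samples) < 2)
    .stopf("need at least 2 windows", class = "evbfep_protocol_error")
  lam <- vapply(samples, function(s) s$lambda, 0)
  ulam <- sort(unique(lam))
  if (length(ulam) < 2)
    .stopf("need at least 2 distinct lambda windows",
           class = "evbfep_protocol_error")
  X <- vector("list", length(ulam))
  rp <- vector("list", length(ulam))
  for (m in seq_along(ulam)) {
    idx <- which(lam == ulam[m])
    X[[m]] <- unlist(lapply(idx, function(i) samples[[i]]$eps1 - samples[[i]]$eps2),
                     use.names = FALSE)
    rp[[m]] <- unlist(lapply(idx, function(i)
      rep.int(samples[[i]]$replica, length(samples[[i]]$eps1))),
      use.names = FALSE)
  }
  list(lambda = ulam, X = X, rep = rp,
       replicas = sort(unique(unlist(rp, use.names = FALSE))),
       temperature = samples[[1]]$temperature,
       n_frames = sum(lengths(X)))
}

# Cumulative mapping free energies (ascending-lambda order, anchored 0 at
# the reactant endpoint lambda = 1), plus the reverse-direction estimate.
.increments_core <- function(col, beta, dalpha = 0, keep = NULL) {
  M <- length(col$lambda)
  kT <- 1 / beta
  xw <- function(m) {
    x <- col$X[[m]] - dalpha
    if (!is.null(keep)) x <- x[col$rep[[m]] == keep]
    x
  }
  G <- numeric(M); G[M] <- 0
  for (m in seq(M - 1, 1)) {
    dl <- col$lambda[m] - col$lambda[m + 1]
    G[m] <- G[m + 1] - kT * .logmeanexp(-beta * dl * xw(m + 1))
  }
  Grev <- numeric(M); Grev[1] <- 0
  for (m in seq(2, M)) {
    dl <- col$lambda[m] - col$lambda[m - 1]
    Grev[m] <- Grev[m - 1] - kT * .logmeanexp(-beta * dl * xw(m - 1))
  }
  # G[1]: forward reactant->product total; -Grev[M]: same total, reverse walk.
  # The working estimate averages the two walks (halves the accumulated
  # random-walk variance); their mismatch is the reported hysteresis.
  Gavg <- 0.5 * (G + (Grev - Grev[M]))
  list(G = Gavg, G_fwd = G, G_rev = Grev, hysteresis = abs(G[1] + Grev[M]))
}

# Umbrella assembly on the gap coordinate for one frame subset.
# Returns bins (integer codes), dg, counts.
.us_core <- function(col, G, h_ij, beta, dalpha, bin_width, min_count,
                     keep = NULL) {
  kT <- 1 / beta
  acc_num <- new.env(parent = emptyenv())
  vals <- list(); cnts <- list(); bins <- list()
  M <- length(col$lambda)
  for (m in seq_len(M)) {
    x <- col$X[[m]] - dalpha
    if (!is.null(keep)) x <- x[col$rep[[m]] == keep]
    if (length(x) == 0) next
    lam <- col$lambda[m]
    # E_g - eps_m as a function of the gap
    w <- -beta * (-(lam - 0.5) * x - 0.5 * sqrt(x^2 + 4 * h_ij^2))
    b <- as.integer(floor(x / bin_width))
    sp <- split(w, b)
    n_m <- length(x)
    lv <- vapply(sp, function(v) {
      mx <- max(v); mx + log(sum(exp(v - mx)))
    }, 0)
    vals[[m]] <- G[m] - kT * (lv - log(n_m))
    cnts[[m]] <- lengths(sp)
    bins[[m]] <- as.integer(names(sp))
  }
  b_all <- unlist(bins, use.names = FALSE)
  v_all <- unlist(vals, use.names = FALSE)
  n_all <- unlist(cnts, use.names = FALSE)
  if (length(b_all) == 0)
    .stopf("no umbrella bins could be formed", class = "evbfep_coverage_error")
  ub <- sort(unique(b_all))
  f <- factor(b_all, levels = ub)
  ntot <- as.numeric(tapply(n_all, f, sum))
  dg <- as.numeric(tapply(v_all * n_all, f, sum)) / ntot
  keep_b <- ntot >= min_count
  list(bin = ub[keep_b], dg = dg[keep_b], n = ntot[keep_b])
}

# Stationary-point location on a binned profile (ascending X order).
# Returns NULL when no interior maximum flanked by lower bins exists.
.locate_stationary <- function(dg) {
  M <- length(dg)
  if (M < 3) return(NULL)
  best <- 0; jbest <- NA_integer_
  lmin <- cummin(dg)
  rmin <- rev(cummin(rev(dg)))
  for (j in 2:(M - 1)) {
    depth <- min(dg[j] - lmin[j - 1], dg[j] - rmin[j + 1])
    if (depth > best) { best <- depth; jbest <- j }
  }
  if (is.na(jbest) || best <= 0) return(NULL)
  i_react <- which.min(dg[seq_len(jbest - 1)])
  i_prod <- jbest + which.min(dg[seq(jbest + 1, M)])
  list(ts = jbest, react = i_react, prod = i_prod)
}

.profile_from_col <- function(col, h_ij, temperature, bin_width, min_count,
                              dalpha = 0) {
  beta <- 1 / (.GAS_R * temperature)
  # adjacent windows must overlap on the gap coordinate, or the stitched
  # profile has an unsupported seam
  rng <- vapply(col$X, range, numeric(2))
  for (m in seq_len(ncol(rng) - 1)) {
    if (rng[1, m + 1] > rng[2, m] + bin_width ||
        rng[1, m] > rng[2, m + 1] + bin_width)
      .stopf("no gap-coordinate overlap between windows lambda = %.3f and %.3f",
             col$lambda[m], col$lambda[m + 1], class = "evbfep_coverage_error")
  }
  inc <- .increments_core(col, beta, dalpha)
  pooled <- .us_core(col, inc$G, h_ij, beta, dalpha, bin_width, min_count)

  reps <- col$replicas
  rep_profiles <- NULL
  if (length(reps) >= 2) {
    mc_rep <- max(1, ceiling(min_count / length(reps)))
    rep_profiles <- lapply(reps, function(r) {
      gr <- .increments_core(col, beta, dalpha, keep = r)
      us <- .us_core(col, gr$G, h_ij, beta, dalpha, bin_width, mc_rep, keep = r)
      loc <- .locate_stationary(us$dg)
      if (!is.null(loc)) us$dg <- us$dg - us$dg[loc$react]
      us
    })
  }

  loc <- .locate_stationary(pooled$dg)
  gauge <- if (is.null(loc)) min(pooled$dg) else pooled$dg[loc$react]
  dg <- pooled$dg - gauge

  se <- rep(NA_real_, length(pooled$bin))
  if (!is.null(rep_profiles)) {
    for (i in seq_along(pooled$bin)) {
      v <- unlist(lapply(rep_profiles, function(p) p$dg[match(pooled$bin[i], p$bin)]))
      v <- v[!is.na(v)]
      if (length(v) >= 2) se[i] <- stats::sd(v) / sqrt(length(v))
    }
  }

  prof <- free_energy_profile(
    x = (pooled$bin + 0.5) * bin_width, dg = dg, n = pooled$n, se = se,
    h_ij = h_ij, temperature = temperature, bin_width = bin_width,
    min_count = min_count)
  attr(prof, "replica_profiles") <- rep_profiles
  attr(prof, "replica_bin_width") <- bin_width
  attr(prof, "hysteresis") <- inc$hysteresis
  attr(prof, "increments") <- data.frame(lambda = col$lambda, dG = inc$G_fwd,
                                         dG_rev = inc$G_rev, dG_avg = inc$G)
  prof
}

# --- public API ------------------------------------------------------------

#' Construct a free-energy profile object
#'
#' Binned ground-state free energy versus the diabatic energy-gap
#' coordinate `X = eps1 - eps2`, gauged so the reactant-region minimum is
#' 0.  Normally produced by [us_assemble()] or [profile_pipeline()]; the
#' constructor is exported so externally computed profiles (e.g. read from
#' disk) can use [extract_barriers()].
#'
#' @param x bin centers of the gap coordinate, kcal/mol.
#' @param dg free energy per bin, kcal/mol.
#' @param n per-bin sample counts.
#' @param se per-bin standard errors (between-replica scatter).
#' @param h_ij,temperature,bin_width,min_count metadata.
#' @return object of class `free_energy_profile` (a data frame).
#' @export
free_energy_profile <- function(x, dg, n = rep(NA_real_, length(x)),
                                se = rep(NA_real_, length(x)),
                                h_ij = NA_real_, temperature = 300,
                                bin_width = NA_real_, min_count = NA_integer_) {
  ord <- order(x)
  out <- data.frame(x = x[ord], dg = dg[ord], n = n[ord], se = se[ord])
  class(out) <- c("free_energy_profile", "data.frame")
  attr(out, "h_ij") <- h_ij
  attr(out, "temperature") <- temperature
  attr(out, "bin_width") <- bin_width
  attr(out, "min_count") <- min_count
  out
}

#' Zwanzig free-energy increments over the mapping schedule
#'
#' Free energy perturbation between adjacent mapping windows:
#' `dG(lambda_{m+1}) = dG(lambda_m) - kT ln < exp(-beta (eps_{m+1} -
#' eps_m)) >_{lambda_m}`, walking from the reactant endpoint
#' (`lambda = 1`, anchored at 0) to the product endpoint, with frames
#' pooled across replicas.  The reverse-direction walk is retained for
#' hysteresis reporting.
#'
#' @param samples list of `window_sample` (any order; at least two distinct
#'   lambdas).
#' @param temperature K.
#' @return data frame with columns `lambda`, `dG` (forward, anchored at
#'   the reactant endpoint) and `dG_rev` (reverse walk, anchored at the
#'   product endpoint), ascending lambda; attribute `hysteresis` holds the
#'   absolute forward/reverse mismatch of the total, in kcal/mol.
#' @export
zwanzig_increments <- function(samples, temperature = 300) {
  col <- .collate_samples(samples)
  beta <- 1 / (.GAS_R * temperature)
  inc <- .increments_core(col, beta)
  out <- data.frame(lambda = col$lambda, dG = inc$G_fwd, dG_rev = inc$G_rev,
                    dG_avg = inc$G)
  attr(out, "hysteresis") <- inc$hysteresis
  out
}

#' Umbrella-sampling assembly of the ground-state free-energy profile
#'
#' For each gap bin X, `dg(X) = dG(lambda_m) - kT ln < delta(X' - X)
#' exp(-beta (E_g - eps_m)) >_{lambda_m}`, with per-bin estimates from
#' different windows combined by sample-count weighting, bins below the
#' minimum count omitted, and the gauge fixed to the reactant-region
#' minimum.  Standard errors come from between-replica scatter.
#'
#' @param samples list of `window_sample`.
#' @param increments result of [zwanzig_increments()] on the same samples
#'   (recomputed internally when `NULL`).
#' @param h_ij coupling of the system the samples came from, kcal/mol.
#' @param temperature K.
#' @param bin_width gap bin width, kcal/mol (default 2).
#' @param min_count minimum pooled samples per reported bin (default 20).
#' @return a [free_energy_profile()].
#' @export
us_assemble <- function(samples, increments = NULL, h_ij, temperature = 300,
                        bin_width = 2, min_count = 20) {
  col <- .collate_samples(samples)
  .profile_from_col(col, h_ij, temperature, bin_width, min_count)
}

#' Barrier extraction from a free-energy profile
#'
#' Locates the reactant minimum (negative-X side), the interior maximum
#' (transition state) and the product minimum, and reports the activation
#' free energy `dG_act = g(TS) - g(reactant)` and reaction free energy
#' `dG_rxn = g(product) - g(reactant)`.  Standard errors are propagated
#' from per-replica profiles when available.
#'
#' @param profile a `free_energy_profile`.
#' @return object of class `barrier_summary`: list with `dg_act`, `dg_rxn`,
#'   `x_react`, `x_ts`, `x_prod`, `se_act`, `se_rxn`.
#' @export
extract_barriers <- function(profile) {
  stopifnot(inherits(profile, "free_energy_profile"))
  loc <- .locate_stationary(profile$dg)
  if (is.null(loc))
    .stopf("no interior barrier found in profile (monotone or single-well)",
           class = "evbfep_no_barrier_error")
  dg_act <- profile$dg[loc$ts] - profile$dg[loc$react]
  dg_rxn <- profile$dg[loc$prod] - profile$dg[loc$react]
  se_act <- NA_real_; se_rxn <- NA_real_
  reps <- attr(profile, "replica_profiles")
  if (!is.null(reps)) {
    ba <- vapply(reps, function(p) {
      l <- .locate_stationary(p$dg)
      if (is.null(l)) return(c(NA_real_, NA_real_))
      c(p$dg[l$ts] - p$dg[l$react], p$dg[l$prod] - p$dg[l$react])
    }, numeric(2))
    a <- ba[1, ]; rx <- ba[2, ]
    a <- a[!is.na(a)]; rx <- rx[!is.na(rx)]
    if (length(a) >= 2) se_act <- stats::sd(a) / sqrt(length(a))
    if (length(rx) >= 2) se_rxn <- stats::sd(rx) / sqrt(length(rx))
  }
  structure(list(dg_act = dg_act, dg_rxn = dg_rxn,
                 x_react = profile$x[loc$react], x_ts = profile$x[loc$ts],
                 x_prod = profile$x[loc$prod],
                 se_act = se_act, se_rxn = se_rxn),
            class = "barrier_summary")
}

#' @export
print.barrier_summary <- function(x, ...) {
  cat(sprintf("dG_act = %.2f (+/- %s) kcal/mol, dG_rxn = %.2f (+/- %s) kcal/mol\n",
              x$dg_act, format(x$se_act, digits = 2),
              x$dg_rxn, format(x$se_rxn, digits = 2)))
  cat(sprintf("stationary X: reactant %.1f, TS %.1f, product %.1f kcal/mol\n",
              x$x_react, x$x_ts, x$x_prod))
  invisible(x)
}

#' Full sampling + FEP/US pipeline
#'
#' Runs the window protocol, computes Zwanzig increments, assembles the
#' umbrella profile and extracts the barrier summary.  Single entry point
#' used by calibration and the command line.
#'
#' @param system an `evb_system`.
#' @param schedule an `evb_schedule`.
#' @param seed base seed.
#' @param bin_width,min_count umbrella binning controls.
#' @param samples optional pre-generated window samples (skips sampling).
#' @return list with elements `profile` (a `free_energy_profile`, carrying
#'   the increments and hysteresis as attributes) and `barriers` (a
#'   `barrier_summary`).
#' @export
profile_pipeline <- function(system, schedule = evb_schedule(), seed = 1,
                             bin_width = 2, min_count = 20, samples = NULL) {
  if (is.null(samples)) samples <- run_protocol(system, schedule, seed)
  col <- .collate_samples(samples)
  prof <- .profile_from_col(col, system$h_ij, schedule$temperature,
                            bin_width, min_count)
  list(profile = prof, barriers = extract_barriers(prof))
}
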