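# Two-state EVB energetics: diabatic states, mapping potential, adiabatic
# ground state.

#' Construct a diabatic valence state
#'
#' A diabatic state is a fixed-bonding-pattern force field: Morse bonds for
#' the reactive bonds, harmonic terms (pairwise, optionally flat-bottom, or
#' absolute-coordinate tethers for bath oscillators), Buckingham
#' exponential-6 nonbonded terms, point-charge Coulomb interactions, and a
#' constant energy shift.  The shift of the product state houses the
#' calibratable gas/solution-phase offset alpha.
#'
#' Term functional forms (r is the 1-D interparticle distance):
#' \itemize{
#'   \item Morse: \eqn{D[(1 - e^{-b(r - r_0)})^2 - 1]} — minimum \eqn{-D} at
#'     \eqn{r_0}, dissociating to 0.
#'   \item Harmonic pair: \eqn{\frac{1}{2} k (r - r_0)^2}; with
#'     \code{flat = TRUE} the term applies only for \eqn{r > r_0}
#'     (flat-bottom distance restraint).
#'   \item Site harmonic (\code{j = NA}): \eqn{\frac{1}{2} k (x_i - x_0)^2}
#'     on the absolute coordinate — the bath tether.
#'   \item Buckingham: \eqn{A e^{-B r} - C/(r^6 + r_s^6)}; \code{rsoft}
#'     (\eqn{r_s}) defaults to 0, giving the textbook \eqn{A e^{-Br} - C/r^6};
#'     a positive \code{rsoft} bounds the dispersion singularity in the toy
#'     system.
#'   \item Coulomb: \eqn{332.0636\, q_i q_j / r} over every pair with nonzero
#'     charge product, no cutoff.
#' }
#'
#' @param morse data frame with columns `i, j, D, b, r0` (well depth
#'   kcal/mol, range 1/A, equilibrium A), or `NULL`.
#' @param harmonic data frame with columns `i, j, k, r0, flat`; `j = NA`
#'   marks an absolute-coordinate term; or `NULL`.
#' @param buckingham data frame with columns `i, j, A, B, C, rsoft`, or
#'   `NULL`.
#' @param charges numeric vector of per-particle partial charges (e).
#' @param shift constant energy offset in kcal/mol.
#' @return an object of class `evb_state`.
#' @seealso [morse_term()], [harmonic_term()], [buckingham_term()]
#' @export
evb_state <- function(morse = NULL, harmonic = NULL, buckingham = NULL,
                      charges, shift = 0) {
  if (!is.null(morse)) {
    if (any(morse$D <= 0) || any(morse$b <= 0) || any(morse$r0 <= 0))
      .stopf("Morse terms require D > 0, b > 0, r0 > 0",
             class = "evbfep_parameter_error")
  }
  if (!is.numeric(charges))
    .stopf("charges must be numeric", class = "evbfep_parameter_error")
  structure(list(morse = morse, harmonic = harmonic, buckingham = buckingham,
                 charges = as.numeric(charges), shift = as.numeric(shift)),
            class = "evb_state")
}

#' @rdname evb_state
#' @param i,j 1-based particle indices.
#' @param D,b,r0 Morse well depth, range and equilibrium distance.
#' @export
morse_term <- function(i, j, D, b, r0) data.frame(i = i, j = j, D = D, b = b, r0 = r0)

#' @rdname evb_state
#' @param k harmonic force constant (kcal/mol/A^2); energy is k/2 (r - r0)^2.
#' @param flat logical; one-sided (penalise only r > r0)?
#' @export
harmonic_term <- function(i, j = NA, k, r0, flat = FALSE)
  data.frame(i = i, j = j, k = k, r0 = r0, flat = flat)

#' @rdname evb_state
#' @param A,B,C Buckingham repulsion amplitude (kcal/mol), range (1/A) and
#'   dispersion coefficient (kcal A^6/mol).
#' @param rsoft dispersion softening radius (A); 0 = plain exp-6.
#' @export
buckingham_term <- function(i, j, A, B, C, rsoft = 0)
  data.frame(i = i, j = j, A = A, B = B, C = C, rsoft = rsoft)

#' Assemble a two-state EVB system
#'
#' Couples a reactant-like and a product-like diabatic state through a
#' constant off-diagonal term `h_ij`.  The particle table must contain the
#' three reacting roles `donor-C`, `hydride-H`, `acceptor-N` exactly once
#' each; remaining particles are `bath`.
#'
#' @param state1 reactant diabatic state (`evb_state`), C--H bonded.
#' @param state2 product diabatic state (`evb_state`), N--H bonded; its
#'   `shift` carries the calibratable alpha.
#' @param h_ij constant coupling, kcal/mol, `>= 0`.
#' @param particles data frame with columns `label`, `mass` (amu), `role`.
#' @param x0 default starting coordinates (A), one per particle.
#' @param temperature default temperature in K.
#' @return an object of class `evb_system`.
#' @export
evb_system <- function(state1, state2, h_ij, particles, x0,
                       temperature = 300) {
  stopifnot(inherits(state1, "evb_state"), inherits(state2, "evb_state"))
  if (!is.finite(h_ij) || h_ij < 0)
    .stopf("h_ij must be a finite non-negative coupling (got %s)", h_ij,
           class = "evbfep_parameter_error")
  need <- c("donor-C", "hydride-H", "acceptor-N")
  cnt <- table(factor(particles$role, levels = c(need, "bath")))
  if (any(cnt[need] != 1L))
    .stopf("roles donor-C, hydride-H, acceptor-N must each appear exactly once",
           class = "evbfep_parameter_error")
  n <- nrow(particles)
  if (length(state1$charges) != n || length(state2$charges) != n)
    .stopf("charge vectors must have one entry per particle",
           class = "evbfep_parameter_error")
  if (length(x0) != n)
    .stopf("x0 must supply one coordinate per particle",
           class = "evbfep_parameter_error")
  structure(list(state1 = state1, state2 = state2, h_ij = as.numeric(h_ij),
                 particles = particles, x0 = as.numeric(x0),
                 temperature = temperature),
            class = "evb_system")
}

# --- packing for the compiled backend -------------------------------------

.pack_terms <- function(df, cols) {
  if (is.null(df) || nrow(df) == 0)
    return(matrix(0, nrow = 0, ncol = length(cols)))
  m <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0     # j = NA -> 0 marks site terms
  m
}

.pack_state <- function(st) {
  list(morse = .pack_terms(st$morse, c("i", "j", "D", "b", "r0")),
       harmonic = .pack_terms(
         if (is.null(st$harmonic)) NULL else
           transform(st$harmonic, flat = as.numeric(flat)),
         c("i", "j", "k", "r0", "flat")),
       buckingham = .pack_terms(st$buckingham, c("i", "j", "A", "B", "C", "rsoft")),
       charges = st$charges, shift = st$shift)
}

.pack_system <- function(sys) {
  list(state1 = .pack_state(sys$state1), state2 = .pack_state(sys$state2),
       n = nrow(sys$particles))
}

# --- energetics ------------------------------------------------------------

#' Diabatic energies of a configuration
#'
#' @param system an `evb_system`.
#' @param coords numeric vector of 1-D particle positions (A), one per
#'   particle.
#' @return named numeric vector `c(eps1, eps2)` in kcal/mol.
#' @export
diabatic_energies <- function(system, coords) {
  stopifnot(inherits(system, "evb_system"))
  n <- nrow(system$particles)
  if (length(coords) != n)
    .stopf("coords has %d entries but the system has %d particles",
           length(coords), n, class = "evbfep_shape_error")
  if (any(!is.finite(coords)))
    .stopf("invalid configuration: non-finite coordinate",
           class = "evbfep_configuration_error")
  e <- cpp_diabatic(.pack_system(system), as.numeric(coords))
  c(eps1 = e[1], eps2 = e[2])
}

#' Mapping potential
#'
#' The lambda-weighted blend of the two diabats used to drag sampling from
#' reactants to products: `eps_m = lambda * eps1 + (1 - lambda) * eps2`.
#' `lambda = 1` is the pure reactant state, `lambda = 0` the pure product
#' state.
#'
#' @param eps1,eps2 diabatic energies, kcal/mol.
#' @param lambda mapping parameter in `[0, 1]`.
#' @return mapping energy in kcal/mol.
#' @export
mapping_energy <- function(eps1, eps2, lambda) {
  if (any(lambda < 0 | lambda > 1))
    .stopf("lambda must lie in [0, 1]", class = "evbfep_domain_error")
  lambda * eps1 + (1 - lambda) * eps2
}

#' Adiabatic ground-state energy of the two-state Hamiltonian
#'
#' Lowest eigenvalue of the 2x2 EVB Hamiltonian with constant coupling:
#' `E_g = (eps1 + eps2)/2 - sqrt((eps1 - eps2)^2 + 4 h_ij^2)/2`.
#'
#' @param eps1,eps2 diabatic energies, kcal/mol.
#' @param h_ij constant off-diagonal coupling, kcal/mol, `>= 0`.
#' @return ground-state energy in kcal/mol; `<= min(eps1, eps2)` with
#'   equality iff `h_ij = 0`.
#' @export
ground_state_energy <- function(eps1, eps2, h_ij) {
  if (any(h_ij < 0))
    .stopf("h_ij must be non-negative", class = "evbfep_domain_error")
  0.5 * (eps1 + eps2) - 0.5 * sqrt((eps1 - eps2)^2 + 4 * h_ij^2)
}

#' @export
print.evb_system <- function(x, ...) {
  cat("<evb_system> ", nrow(x$particles), " particles, h_ij = ",
      format(x$h_ij), " kcal/mol, alpha (state2 shift) = ",
      format(x$state2$shift), " kcal/mol\n", sep = "")
  invisible(x)
}
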