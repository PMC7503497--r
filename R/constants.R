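# Unit system: energy kcal/mol, length Angstrom, time fs, mass amu,
# temperature K.  Gas constant per the package-wide convention.
.GAS_R <- 1.987204e-3    # kcal mol^-1 K^-1
.ACC   <- 4.184e-4       # (A/fs^2) per (kcal/mol/A / amu)

# CODATA constants, used only by the TST prefactor (computed at call time)
.KB_SI <- 1.380649e-23   # J/K
.H_SI  <- 6.62607015e-34 # J s

#' Derive a reproducible sub-seed from a base seed
#'
#' Mixes a base seed with one or more integer tags through a
#' Lehmer-style recurrence, keeping the result inside the 32-bit signed
#' integer range R requires of `set.seed()`.  Used throughout the package
#' so that replicas, windows and calibration iterations draw from
#' independent but fully determined streams.
#'
#' @param base integer base seed.
#' @param ... integer tags (window index, replica id, iteration, ...).
#' @return a single integer seed.
#' @export
derive_seed <- function(base, ...) {
  tags <- c(...)
  s <- as.double(abs(as.integer(base))) %% 2147483647
  for (k in tags) {
    s <- (s * 48271 + abs(as.double(k)) + 1) %% 2147483647
  }
  as.integer(s)
}

# Stable hex digest of an R object (via its canonical JSON serialisation).
.digest_of <- function(obj) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

.logmeanexp <- function(v) {
  m <- max(v)
  m + log(mean(exp(v - m)))
}

.stopf <- function(fmt, ..., class = "evbfep_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
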