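# Readers/writers: window-energy TSV dialect, system JSON, profile TSV,
# manifests.  All formats are plain text and round-trip stable.

#' Serialize / read an EVB system (JSON)
#'
#' The system configuration file is a JSON document (the one structured
#' dialect used throughout the package) listing particles, per-state
#' terms, the coupling and the shifts.  Round-trip stable at full double
#' precision.
#'
#' @param system an `evb_system`.
#' @param path file path.
#' @return `read_evb_system` returns an `evb_system`;
#'   `write_evb_system` returns `path` invisibly.
#' @export
write_evb_system <- function(system, path) {
  stopifnot(inherits(system, "evb_system"))
  obj <- list(
    particles = system$particles, x0 = system$x0, h_ij = system$h_ij,
    temperature = system$temperature,
    state1 = unclass(system$state1), state2 = unclass(system$state2))
  ok <- try(jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                                 null = "null"), silent = TRUE)
  if (inherits(ok, "try-error"))
    .stopf("failed to write system file '%s'", path, class = "evbfep_io_error")
  invisible(path)
}

.df_or_null <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0)
    return(NULL)
  as.data.frame(x)
}

#' @rdname write_evb_system
#' @export
read_evb_system <- function(path) {
  if (!file.exists(path))
    .stopf("system file not found: '%s'", path, class = "evbfep_io_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- function(s) evb_state(
    morse = .df_or_null(s$morse), harmonic = .df_or_null(s$harmonic),
    buckingham = .df_or_null(s$buckingham),
    charges = as.numeric(s$charges), shift = s$shift)
  evb_system(st(obj$state1), st(obj$state2), obj$h_ij,
             as.data.frame(obj$particles), as.numeric(obj$x0),
             obj$temperature)
}

#' Write window-energy files
#'
#' One tab-separated file per (window, replica), named
#' `win_<lambda index>_rep<replica>.tsv`, with header and columns
#' `frame`, `lambda`, `eps1_kcal`, `eps2_kcal`.  Energies are written with
#' 12 significant digits (round trip well under 1e-9 kcal/mol at the
#' magnitudes involved).
#'
#' @param samples non-empty list of `window_sample`.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_window_files <- function(samples, dir) {
  if (length(samples) == 0)
    .stopf("refusing to write an empty sample list",
           class = "evbfep_parameter_error")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) .stopf("cannot create directory '%s'", dir,
                    class = "evbfep_io_error")
  }
  lam <- vapply(samples, function(s) s$lambda, 0)
  ulam <- sort(unique(lam))
  files <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    w <- match(s$lambda, ulam) - 1L
    f <- file.path(dir, sprintf("win_%02d_rep%d.tsv", w, s$replica))
    con <- file(f, "w")
    writeLines("frame\tlambda\teps1_kcal\teps2_kcal", con)
    writeLines(sprintf("%d\t%.10g\t%.12g\t%.12g",
                       seq_along(s$eps1), s$lambda, s$eps1, s$eps2), con)
    close(con)
    files[i] <- f
  }
  invisible(files)
}

#' Read window-energy files
#'
#' Reads every `win_*.tsv` in `dir` (or an explicit vector of paths) in
#' the dialect written by [write_window_files()].  Malformed rows raise a
#' parse error naming file and line; an empty directory is an explicit
#' error.
#'
#' @param dir directory containing window files, or a character vector of
#'   file paths.
#' @param temperature temperature to record on the samples, K.
#' @return list of `window_sample`.
#' @export
read_window_files <- function(dir, temperature = 300) {
  files <- if (length(dir) == 1 && dir.exists(dir))
    list.files(dir, pattern = "^win_.*\\.tsv$", full.names = TRUE)
  else dir
  if (length(files) == 0)
    .stopf("no window files found in '%s'", dir[1], class = "evbfep_io_error")
  lapply(sort(files), function(f) {
    if (!file.exists(f))
      .stopf("window file not found: '%s'", f, class = "evbfep_io_error")
    lines <- readLines(f)
    if (length(lines) < 2)
      .stopf("parse error in '%s': no data rows", f, class = "evbfep_parse_error")
    if (!identical(lines[1], "frame\tlambda\teps1_kcal\teps2_kcal"))
      .stopf("parse error in '%s', line 1: unexpected header", f,
             class = "evbfep_parse_error")
    parts <- strsplit(lines[-1], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 4L)
    if (length(bad))
      .stopf("parse error in '%s', line %d: expected 4 fields", f, bad[1] + 1L,
             class = "evbfep_parse_error")
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 4,
                byrow = TRUE)
    if (anyNA(m)) {
      bad <- which(apply(is.na(m), 1, any))[1]
      .stopf("parse error in '%s', line %d: non-numeric field", f, bad + 1L,
             class = "evbfep_parse_error")
    }
    rep_id <- as.integer(sub(".*_rep([0-9]+)\\.tsv$", "\\1", basename(f)))
    if (is.na(rep_id)) rep_id <- 1L
    window_sample(lambda = m[1, 2], eps1 = m[, 3], eps2 = m[, 4],
                  replica = rep_id, temperature = temperature)
  })
}

#' Write / read a free-energy profile (TSV)
#'
#' Columns `X_center_kcal`, `dG_kcal`, `n_samples`, `se_kcal`.
#'
#' @param profile a `free_energy_profile`.
#' @param path file path.
#' @return `read_profile_tsv` returns a `free_energy_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "free_energy_profile"))
  con <- file(path, "w")
  writeLines("X_center_kcal\tdG_kcal\tn_samples\tse_kcal", con)
  writeLines(sprintf("%.12g\t%.12g\t%g\t%.12g",
                     profile$x, profile$dg, profile$n, profile$se), con)
  close(con)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  if (!file.exists(path))
    .stopf("profile file not found: '%s'", path, class = "evbfep_io_error")
  d <- utils::read.delim(path)
  free_energy_profile(d$X_center_kcal, d$dG_kcal, d$n_samples, d$se_kcal)
}

#' Write generated objects as plain-text fixtures
#'
#' Dispatches on type: a list of `window_sample` is written as a directory
#' of window TSV files, an `evb_system` as a JSON config.
#'
#' @param x object to write.
#' @param path destination (directory for samples, file for a system).
#' @return the path(s) written, invisibly.
#' @export
write_fixture <- function(x, path) {
  if (inherits(x, "evb_system")) return(write_evb_system(x, path))
  if (is.list(x)) {
    if (length(x) == 0)
      .stopf("refusing to write an empty sample list",
             class = "evbfep_parameter_error")
    if (all(vapply(x, inherits, TRUE, "window_sample")))
      return(write_window_files(x, path))
  }
  .stopf("don't know how to write an object of class '%s'", class(x)[1],
         class = "evbfep_parameter_error")
}

# Run manifest: every knob needed to reproduce a run, no timestamps (so
# reruns are byte-identical).
.write_manifest <- function(path, schedule, seed, extra = list()) {
  sched <- unclass(schedule)
  obj <- c(list(schedule = sched, seed = seed,
                schedule_digest = .digest_of(sched)), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
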