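#' Sampled electrophysiology trace
#'
#' A `trace` is the carrier for every recorded or simulated signal in the
#' package: an evenly sampled time series with a sampling interval in
#' milliseconds and a unit of either millivolts (current clamp) or picoamperes
#' (voltage clamp). The time of sample `i` (0-based) is `t0 + i * dt`;
#' every operation in the package reconstructs time this way.
#'
#' @param samples numeric vector of sampled values (>= 2 samples).
#' @param dt sampling interval, ms (> 0).
#' @param unit `"mV"` or `"pA"`.
#' @param t0 time of the first sample, ms. Default 0.
#' @return An object of class `trace`.
#' @examples
#' tr <- trace(rep(-65, 1000), dt = 0.1)
#' trace_times(tr)[1:3]
#' @export
trace <- function(samples, dt, unit = c("mV", "pA"), t0 = 0) {
  unit <- match.arg(unit)
  samples <- as.numeric(samples)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (ms)")
  if (length(samples) < 2L)
    stop("a trace needs at least 2 samples")
  structure(
    list(samples = samples, dt = dt, unit = unit, t0 = as.numeric(t0)),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ dt = %g ms (%s), span %.6g ms\n",
              length(x$samples), x$dt, x$unit, trace_span(x)))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param x a `trace`.
#' @return Numeric vector `t0 + (0:(n-1)) * dt`, ms.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$samples) - 1) * x$dt
}

#' Total span of a trace in ms (first to last sample)
#' @param x a `trace`.
#' @export
trace_span <- function(x) (length(x$samples) - 1) * x$dt

#' Index of the sample at or just after time `t_ms`
#' @param x a `trace`.
#' @param t_ms time, ms.
#' @keywords internal
trace_index <- function(x, t_ms) {
  i <- ceiling((t_ms - x$t0) / x$dt - 1e-9) + 1
  max(1L, min(length(x$samples), as.integer(i)))
}

#' Extract the samples of a trace between two times (inclusive)
#' @param x a `trace`.
#' @param from,to window bounds, ms.
#' @keywords internal
trace_window <- function(x, from, to) {
  if (to <= from) stop("empty window [", from, ", ", to, ")")
  tt <- trace_times(x)
  keep <- tt >= from - 1e-9 & tt <= to + 1e-9
  if (!any(keep)) stop("window [", from, ", ", to, "] outside trace")
  x$samples[keep]
}

#' Rectangular current step stimulus
#'
#' @param amplitude step amplitude, pA.
#' @param onset step onset, ms (>= 0).
#' @param duration step duration, ms (> 0).
#' @return An object of class `stimulus_step`.
#' @export
stimulus_step <- function(amplitude, onset, duration) {
  if (onset < 0) stop("onset must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(amplitude = as.numeric(amplitude), onset = as.numeric(onset),
                 duration = as.numeric(duration)),
            class = "stimulus_step")
}

#' One stimulus-aligned sweep (trace + step stimulus)
#'
#' @param tr a `trace`.
#' @param stim a `stimulus_step`; its window must lie inside the trace.
#' @param sweep_id label for the sweep.
#' @return An object of class `sweep_rec`.
#' @export
sweep_rec <- function(tr, stim, sweep_id = NULL) {
  stopifnot(inherits(tr, "trace"), inherits(stim, "stimulus_step"))
  t_end <- tr$t0 + trace_span(tr)
  if (stim$onset < tr$t0 - 1e-9 || stim$onset + stim$duration > t_end + 1e-9)
    stop("stimulus window [", stim$onset, ", ", stim$onset + stim$duration,
         "] lies outside the trace [", tr$t0, ", ", t_end, "]")
  if (is.null(sweep_id)) sweep_id <- sprintf("%gpA", stim$amplitude)
  structure(list(trace = tr, stimulus = stim, sweep_id = as.character(sweep_id)),
            class = "sweep_rec")
}

#' A family of sweeps from one cell
#'
#' The unit of analysis: an ordered family of stimulus-aligned sweeps sharing
#' sampling interval and unit, recorded in a single clamp mode. Stimulus
#' amplitudes must be unique within the set.
#'
#' @param cell_id cell label.
#' @param sweeps list of `sweep_rec` objects.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param metadata free-form named list, preserved verbatim by I/O.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(cell_id, sweeps, mode = c("current_clamp", "voltage_clamp"),
                      metadata = list()) {
  mode <- match.arg(mode)
  if (length(sweeps) == 0L) stop("a sweep_set needs at least one sweep")
  if (!all(vapply(sweeps, inherits, logical(1), "sweep_rec")))
    stop("sweeps must all be sweep_rec objects")
  dts <- vapply(sweeps, function(s) s$trace$dt, numeric(1))
  if (max(dts) - min(dts) > 1e-12 * max(dts))
    stop("inconsistent sampling: dt differs across sweeps")
  units <- vapply(sweeps, function(s) s$trace$unit, character(1))
  if (length(unique(units)) != 1L)
    stop("inconsistent units across sweeps")
  amps <- vapply(sweeps, function(s) s$stimulus$amplitude, numeric(1))
  if (anyDuplicated(amps)) stop("stimulus amplitudes must be unique within a sweep_set")
  structure(list(cell_id = as.character(cell_id), sweeps = sweeps, mode = mode,
                 metadata = metadata),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  amps <- sweep_amplitudes(x)
  cat(sprintf("<sweep_set> cell %s: %d sweeps (%s), %g..%g pA, dt = %g ms\n",
              x$cell_id, length(x$sweeps), x$mode, min(amps), max(amps),
              x$sweeps[[1]]$trace$dt))
  invisible(x)
}

#' Stimulus amplitudes of a sweep set, in sweep order
#' @param s a `sweep_set`.
#' @export
sweep_amplitudes <- function(s) {
  vapply(s$sweeps, function(sw) sw$stimulus$amplitude, numeric(1))
}

#' Get the sweep with a given stimulus amplitude
#' @param s a `sweep_set`.
#' @param amplitude stimulus amplitude, pA.
#' @keywords internal
sweep_at <- function(s, amplitude) {
  i <- which(abs(sweep_amplitudes(s) - amplitude) < 1e-9)
  if (length(i) != 1L) stop("no sweep at ", amplitude, " pA")
  s$sweeps[[i]]
}

unit_long <- c(mV = "millivolt", pA = "picoampere")
unit_short <- function(u) {
  if (u %in% names(unit_long)) return(u)
  i <- match(u, unit_long)
  if (is.na(i)) stop("unknown unit string: '", u, "'")
  names(unit_long)[i]
}

#' Write a sweep set to disk in the native dialect
#'
#' The native on-disk form is one two-column CSV per sweep (`time_ms`,
#' `value`) plus one JSON sidecar (`sweepset.json`) holding the cell id,
#' clamp mode, unit, sampling interval and the stimulus table. Extra
#' metadata keys are preserved verbatim. The representation round-trips
#' through [read_sweep_set()] to full printed precision (17 significant
#' digits).
#'
#' @param s a `sweep_set`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_sweep_set()]
#' @export
write_sweep_set <- function(s, path) {
  stopifnot(inherits(s, "sweep_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  files <- character(length(s$sweeps))
  for (i in seq_along(s$sweeps)) {
    sw <- s$sweeps[[i]]
    files[i] <- sprintf("sweep_%03d.csv", i)
    df <- data.frame(time_ms = trace_times(sw$trace), value = sw$trace$samples)
    con <- file(file.path(path, files[i]), "w")
    writeLines("time_ms,value", con)
    writeLines(paste(sprintf("%.17g", df$time_ms),
                     sprintf("%.17g", df$value), sep = ","), con)
    close(con)
  }
  stim <- data.frame(
    file = files,
    sweep_id = vapply(s$sweeps, `[[`, character(1), "sweep_id"),
    amplitude_pA = sweep_amplitudes(s),
    onset_ms = vapply(s$sweeps, function(sw) sw$stimulus$onset, numeric(1)),
    duration_ms = vapply(s$sweeps, function(sw) sw$stimulus$duration, numeric(1))
  )
  side <- list(
    cell_id = s$cell_id,
    mode = s$mode,
    unit = unname(unit_long[s$sweeps[[1]]$trace$unit]),
    dt_ms = s$sweeps[[1]]$trace$dt,
    t0_ms = vapply(s$sweeps, function(sw) sw$trace$t0, numeric(1)),
    sweeps = stim,
    metadata = s$metadata
  )
  jsonlite::write_json(side, file.path(path, "sweepset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a sweep set from disk
#'
#' Reads the native dialect written by [write_sweep_set()]: a directory with
#' per-sweep CSV trace tables and a `sweepset.json` sidecar. Units are taken
#' from the sidecar, never guessed; a missing sidecar or unknown unit string
#' is an error, as is an inconsistent sampling interval across sweeps.
#'
#' @param path directory containing the sweep set.
#' @param format_hint unused placeholder for alternative formats; only the
#'   native dialect is currently recognized, and any other value errors.
#' @return A `sweep_set`.
#' @export
read_sweep_set <- function(path, format_hint = "native") {
  if (!identical(format_hint, "native"))
    stop("no reader available for format '", format_hint,
         "'; only the native CSV+JSON dialect is supported")
  side_path <- file.path(path, "sweepset.json")
  if (!file.exists(side_path)) stop("missing sidecar metadata: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  for (k in c("cell_id", "mode", "unit", "dt_ms", "sweeps"))
    if (is.null(side[[k]])) stop("sidecar missing required field '", k, "'")
  u <- unit_short(side$unit)
  stim <- side$sweeps
  t0s <- side$t0_ms
  if (is.null(t0s)) t0s <- rep(0, nrow(stim))
  sweeps <- vector("list", nrow(stim))
  for (i in seq_len(nrow(stim))) {
    df <- utils::read.csv(file.path(path, stim$file[i]))
    if (nrow(df) >= 2) {
      dt_obs <- (df$time_ms[nrow(df)] - df$time_ms[1]) / (nrow(df) - 1)
      if (abs(dt_obs - side$dt_ms) > 1e-6 * side$dt_ms)
        stop("inconsistent sampling in ", stim$file[i],
             ": observed dt ", dt_obs, " vs declared ", side$dt_ms)
    }
    tr <- trace(df$value, dt = side$dt_ms, unit = u, t0 = t0s[i])
    sweeps[[i]] <- sweep_rec(
      tr,
      stimulus_step(stim$amplitude_pA[i], stim$onset_ms[i], stim$duration_ms[i]),
      sweep_id = stim$sweep_id[i]
    )
  }
  md <- side$metadata
  if (is.null(md)) md <- list()
  sweep_set(side$cell_id, sweeps, mode = side$mode, metadata = md)
}
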