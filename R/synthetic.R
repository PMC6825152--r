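#' Cohort generation specification
#'
#' Describes a synthetic patch-clamp cohort: each cell is a reduced
#' conductance-based model drawn from its class's parameter distribution,
#' run through the standard current-clamp protocol, with Gaussian recording
#' noise added. Class parameter ranges are read from a YAML profile
#' (default: the package's `cohort_profile.yaml`), never hard-coded.
#'
#' @param n_cells number of cells.
#' @param fs_fraction probability a cell is drawn from the fast-spiking
#'   class, in `[0, 1]`.
#' @param noise_sd recording noise SD, mV. Default 0.2.
#' @param seed integer seed; identical seed gives an identical cohort.
#' @param profile path to the class-parameter YAML profile.
#' @param dt integration step, ms.
#' @param record_dt recorded sampling interval, ms.
#' @param sub_currents subthreshold family, pA.
#' @param dep_currents depolarizing family, pA.
#' @param step_duration step duration, ms.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cells, fs_fraction, noise_sd = 0.2, seed = 1,
                        profile = NULL, dt = 0.025, record_dt = 0.05,
                        sub_currents = seq(-50, 20, by = 10),
                        dep_currents = seq(25, 500, by = 25),
                        step_duration = 800) {
  if (fs_fraction < 0 || fs_fraction > 1) stop("fs_fraction must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(profile))
    profile <- system.file("extdata", "cohort_profile.yaml", package = "cinphys")
  structure(list(n_cells = as.integer(n_cells), fs_fraction = fs_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 profile = profile, dt = dt, record_dt = record_dt,
                 sub_currents = sub_currents, dep_currents = dep_currents,
                 step_duration = step_duration),
            class = "cohort_spec")
}

draw_in <- function(range) stats::runif(1, range[[1]], range[[2]])

# build one model by drawing from a class's parameter ranges
draw_model <- function(class_cfg, name) {
  reg <- channel_registry()
  chans <- list()
  for (nm in names(class_cfg$gbar)) {
    ch <- reg[[nm]]
    if (is.null(ch)) stop("unknown channel in profile: ", nm)
    ch$gbar <- draw_in(class_cfg$gbar[[nm]])
    chans[[nm]] <- ch
  }
  neuron_model(chans,
               cm = if (is.null(class_cfg$cm)) 1 else draw_in(class_cfg$cm),
               area = if (is.null(class_cfg$area)) 1e-4 else draw_in(class_cfg$area),
               g_leak = draw_in(class_cfg$g_leak),
               e_leak = draw_in(class_cfg$e_leak),
               v_init = -70, name = name)
}

#' Generate a synthetic current-clamp cohort with known ground truth
#'
#' For each cell, a class (`FS`/`RS`) is drawn with probability
#' `fs_fraction`, a model is drawn from the class parameter ranges, and the
#' standard protocol (subthreshold family plus depolarizing steps) is
#' simulated, with Gaussian noise added to the recorded voltage. Cells whose
#' simulation diverges are redrawn (count reported). Sub-streams per cell
#' are derived from the base seed by counter, so the cohort is reproducible
#' cell-by-cell.
#'
#' @param spec a `cohort_spec`.
#' @param progress print a dot per cell.
#' @return List of class `cohort`: `cells` (list of `sweep_set`), `truth`
#'   (data frame: `cell_id`, `true_class`, drawn parameters), `n_redrawn`,
#'   `spec`.
#' @export
generate_cohort <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  prof <- yaml::read_yaml(spec$profile)
  p <- sim_protocol(dt = spec$dt,
                    step_currents = c(spec$sub_currents, spec$dep_currents),
                    step_duration = spec$step_duration,
                    onset = 100, tail = 100, settle = 500,
                    record_dt = spec$record_dt)
  cells <- vector("list", spec$n_cells)
  truth <- vector("list", spec$n_cells)
  n_redrawn <- 0L
  for (i in seq_len(spec$n_cells)) {
    set.seed(spec$seed + i)
    done <- FALSE
    for (attempt in 1:6) {
      cls <- if (stats::runif(1) < spec$fs_fraction) "FS" else "RS"
      m <- draw_model(prof$classes[[cls]], sprintf("cell_%03d", i))
      s <- tryCatch(run_protocol(m, p, cell_id = m$name),
                    error = function(e) NULL)
      if (!is.null(s)) { done <- TRUE; break }
      n_redrawn <- n_redrawn + 1L
    }
    if (!done) stop("cell ", i, " diverged repeatedly")
    if (spec$noise_sd > 0) {
      s$sweeps <- lapply(s$sweeps, function(sw) {
        sw$trace$samples <- sw$trace$samples +
          stats::rnorm(length(sw$trace$samples), 0, spec$noise_sd)
        sw
      })
    }
    gb <- lapply(m$channels, `[[`, "gbar")
    truth[[i]] <- data.frame(cell_id = m$name, true_class = cls,
                             g_leak = m$g_leak, e_leak = m$e_leak,
                             as.data.frame(gb), stringsAsFactors = FALSE)
    cells[[i]] <- s
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(cells = cells, truth = do.call(rbind, truth),
                 n_redrawn = n_redrawn, spec = spec),
            class = "cohort")
}

#' Synaptic recording scenario
#'
#' Generative parameters for synthetic inhibitory postsynaptic current
#' recordings: Poisson event timing, log-normal amplitudes, biexponential
#' (difference-of-exponentials) kinetics, Gaussian noise, and a
#' Tsodyks-Markram short-term plasticity block for evoked trains.
#'
#' @param rate_hz spontaneous event rate, Hz.
#' @param amp_meanlog,amp_sdlog log-normal amplitude parameters (pA scale).
#' @param tau_rise,tau_decay event kinetics, ms (`tau_rise < tau_decay`).
#' @param noise_sd recording noise SD, pA.
#' @param duration_s recording length, s.
#' @param dt sampling interval, ms.
#' @param U release probability parameter of the plasticity recursion,
#'   in (0, 1].
#' @param tau_rec,tau_fac recovery / facilitation time constants, ms
#'   (`tau_fac = 0` disables facilitation).
#' @param base_amp_pA first-pulse evoked amplitude, pA.
#' @param seed integer seed.
#' @return List of class `synaptic_scenario`.
#' @export
synaptic_scenario <- function(rate_hz = 5, amp_meanlog = log(40),
                              amp_sdlog = 0.3, tau_rise = 1, tau_decay = 15,
                              noise_sd = 2, duration_s = 60, dt = 0.1,
                              U = 0.5, tau_rec = 200, tau_fac = 0,
                              base_amp_pA = 100, seed = 1) {
  if (tau_rise >= tau_decay) stop("tau_rise must be < tau_decay")
  if (tau_rise <= 0 || tau_decay <= 0 || rate_hz < 0) stop("rates/taus must be positive")
  if (U <= 0 || U > 1) stop("U must be in (0, 1]")
  structure(as.list(environment()), class = "synaptic_scenario")
}

# biexponential event waveform, unit peak amplitude, sampled at times tt >= 0
biexp_waveform <- function(tt, tau_rise, tau_decay) {
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  peak <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  (exp(-tt / tau_decay) - exp(-tt / tau_rise)) / peak
}

#' Generate a spontaneous IPSC recording with ground truth
#'
#' Event onsets are a homogeneous Poisson process; each event is a
#' difference-of-exponentials waveform
#' `a * (exp(-t/tau_decay) - exp(-t/tau_rise))` normalized so its nominal
#' peak is the drawn amplitude; Gaussian noise is added. Events are positive
#' (outward, as recorded at a +10 mV holding potential).
#'
#' @param s a `synaptic_scenario`.
#' @return List: `trace` (current `trace`), `truth` (data frame `onset_ms`,
#'   `amplitude_pA`).
#' @export
generate_ipsc_recording <- function(s) {
  stopifnot(inherits(s, "synaptic_scenario"))
  set.seed(s$seed)
  span_ms <- s$duration_s * 1000
  n_ev <- stats::rpois(1, s$rate_hz * s$duration_s)
  onsets <- sort(stats::runif(n_ev, 0, span_ms - 100))
  amps <- stats::rlnorm(n_ev, s$amp_meanlog, s$amp_sdlog)
  n <- as.integer(round(span_ms / s$dt)) + 1L
  v <- numeric(n)
  wf_len <- as.integer(round(min(8 * s$tau_decay, 400) / s$dt))
  wf <- biexp_waveform((0:wf_len) * s$dt, s$tau_rise, s$tau_decay)
  for (k in seq_len(n_ev)) {
    i0 <- as.integer(round(onsets[k] / s$dt)) + 1L
    idx <- i0:min(n, i0 + wf_len)
    v[idx] <- v[idx] + amps[k] * wf[seq_along(idx)]
  }
  if (s$noise_sd > 0) v <- v + stats::rnorm(n, 0, s$noise_sd)
  list(trace = trace(v, dt = s$dt, unit = "pA"),
       truth = data.frame(onset_ms = onsets, amplitude_pA = amps))
}

#' Tsodyks-Markram per-pulse relative amplitudes
#'
#' Resources `R` and utilization `u` evolve over a pulse train as
#' `R_{n+1} = 1 - (1 - R_n (1 - u_n)) exp(-dt/tau_rec)` and, with
#' facilitation, `u_{n+1} = U + u_n (1 - U) exp(-dt/tau_fac)` (otherwise
#' `u_n = U`). The pulse-n amplitude is proportional to `u_n R_n`, reported
#' relative to pulse 1.
#'
#' @param pulse_times pulse times, ms (strictly increasing).
#' @param U release probability parameter, (0, 1].
#' @param tau_rec recovery time constant, ms.
#' @param tau_fac facilitation time constant, ms; 0 disables facilitation.
#' @return Numeric vector of relative amplitudes (first = 1).
#' @export
tm_relative_amplitudes <- function(pulse_times, U, tau_rec, tau_fac = 0) {
  if (any(diff(pulse_times) <= 0)) stop("pulse times must be increasing")
  np <- length(pulse_times)
  u <- numeric(np); R <- numeric(np)
  u[1] <- U; R[1] <- 1
  if (np > 1) for (k in 2:np) {
    dtk <- pulse_times[k] - pulse_times[k - 1]
    R[k] <- 1 - (1 - R[k - 1] * (1 - u[k - 1])) * exp(-dtk / tau_rec)
    u[k] <- if (tau_fac > 0) U + u[k - 1] * (1 - U) * exp(-dtk / tau_fac) else U
  }
  rel <- u * R
  rel / rel[1]
}

#' Generate an evoked IPSC train with known per-pulse amplitudes
#'
#' Pulse amplitudes follow the Tsodyks-Markram recursion
#' ([tm_relative_amplitudes()]) scaled by `base_amp_pA`; waveforms are the
#' same normalized difference-of-exponentials used for spontaneous events,
#' summed over pulses, plus Gaussian noise.
#'
#' @param s a `synaptic_scenario`.
#' @param pulse_times pulse times, ms (>= 1, strictly increasing).
#' @param pre_ms,post_ms trace padding before the first / after the last
#'   pulse, ms.
#' @return List: `trace`, `truth` (data frame `pulse_time_ms`,
#'   `amplitude_pA`, `relative`).
#' @export
generate_evoked_train <- function(s, pulse_times, pre_ms = 50, post_ms = 200) {
  stopifnot(inherits(s, "synaptic_scenario"))
  if (length(pulse_times) < 1L) stop("need >= 1 pulse")
  if (length(pulse_times) > 1L && any(diff(pulse_times) <= 0))
    stop("pulse times must be increasing")
  set.seed(s$seed)
  rel <- tm_relative_amplitudes(pulse_times, s$U, s$tau_rec, s$tau_fac)
  amps <- s$base_amp_pA * rel
  t_end <- max(pulse_times) + post_ms
  n <- as.integer(round((t_end + pre_ms) / s$dt)) + 1L
  t0 <- min(pulse_times) - pre_ms
  v <- numeric(n)
  wf_len <- as.integer(round(min(8 * s$tau_decay, 400) / s$dt))
  wf <- biexp_waveform((0:wf_len) * s$dt, s$tau_rise, s$tau_decay)
  for (k in seq_along(pulse_times)) {
    i0 <- as.integer(round((pulse_times[k] - t0) / s$dt)) + 1L
    idx <- i0:min(n, i0 + wf_len)
    v[idx] <- v[idx] + amps[k] * wf[seq_along(idx)]
  }
  if (s$noise_sd > 0) v <- v + stats::rnorm(n, 0, s$noise_sd)
  list(trace = trace(v, dt = s$dt, unit = "pA", t0 = t0),
       truth = data.frame(pulse_time_ms = pulse_times, amplitude_pA = amps,
                          relative = rel))
}
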