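#' Single-compartment neuron model
#'
#' A reduced conductance-based model: membrane capacitance and area, a leak,
#' and a set of voltage-gated channels from the registry with per-model
#' maximal conductance densities.
#'
#' @param channels named list of `channel_spec` (with `gbar` set, S/cm^2).
#' @param cm specific capacitance, uF/cm^2.
#' @param area membrane area, cm^2 (sets the pA -> uA/cm^2 conversion).
#' @param g_leak leak conductance density, S/cm^2.
#' @param e_leak leak reversal, mV.
#' @param v_init initial voltage, mV.
#' @param name model label.
#' @return List of class `neuron_model`.
#' @export
neuron_model <- function(channels, cm = 1, area = 1e-4, g_leak = 1e-4,
                         e_leak = -67, v_init = -70, name = "model") {
  if (cm <= 0) stop("capacitance must be > 0")
  if (area <= 0) stop("area must be > 0")
  if (!all(vapply(channels, inherits, logical(1), "channel_spec")))
    stop("channels must be channel_spec objects")
  structure(list(name = name, cm = cm, area = area, g_leak = g_leak,
                 e_leak = e_leak, v_init = v_init, channels = channels),
            class = "neuron_model")
}

#' Set a channel's maximal conductance density
#' @param m a `neuron_model`.
#' @param channel channel name.
#' @param gbar new density, S/cm^2.
#' @return The modified model.
#' @export
set_gbar <- function(m, channel, gbar) {
  stopifnot(inherits(m, "neuron_model"))
  if (!channel %in% names(m$channels)) stop("no channel '", channel, "' in model")
  if (gbar < 0) stop("gbar must be >= 0")
  m$channels[[channel]]$gbar <- gbar
  m
}

#' Simulation protocol for current steps
#'
#' @param dt integration step, ms.
#' @param step_currents injected step amplitudes, pA.
#' @param step_duration step duration, ms.
#' @param onset time from recording start to step onset, ms.
#' @param tail recorded time after step offset, ms.
#' @param settle unrecorded settling time before the recording, ms.
#' @param record_dt recording interval, ms (a multiple of `dt`).
#' @return List of class `sim_protocol`.
#' @export
sim_protocol <- function(dt = 0.025, step_currents = seq(50, 350, by = 50),
                         step_duration = 1000, onset = 100, tail = 100,
                         settle = 500, record_dt = dt) {
  if (dt <= 0 || step_duration <= 0) stop("dt and step_duration must be > 0")
  re <- as.integer(round(record_dt / dt))
  if (abs(re * dt - record_dt) > 1e-9) stop("record_dt must be a multiple of dt")
  structure(list(dt = dt, step_currents = step_currents,
                 step_duration = step_duration, onset = onset, tail = tail,
                 settle = settle, record_every = max(1L, re)),
            class = "sim_protocol")
}

# tabulate gate steady states and per-step decay factors on a voltage grid
tabulate_channels <- function(m, dt, grid_min = -120, grid_max = 80,
                              grid_step = 0.1, v_ss = NULL) {
  vv <- seq(grid_min, grid_max, by = grid_step)
  lapply(m$channels, function(ch) {
    ng <- length(ch$gates)
    xinf <- matrix(0, length(vv), ng)
    efac <- matrix(0, length(vv), ng)
    x0 <- numeric(ng)
    vi <- if (is.null(v_ss)) m$v_init else v_ss
    for (g in seq_len(ng)) {
      gate <- ch$gates[[g]]
      xinf[, g] <- eval_gate_law(gate$inf, vv, "inf")
      efac[, g] <- exp(-dt / eval_gate_law(gate$tau, vv, "tau"))
      x0[g] <- eval_gate_law(gate$inf, vi, "inf")
    }
    list(gbar = ch$gbar * 1000,  # S/cm^2 -> mS/cm^2
         e = ch$reversal,
         powers = vapply(ch$gates, `[[`, numeric(1), "power"),
         xinf = xinf, efac = efac, x0 = x0)
  })
}

#' Run one current step through the model
#'
#' Integrates `C dV/dt = I/A - sum g_i(V, x)(V - E_i) - g_L (V - E_L)` with
#' Rush-Larsen gate updates and an exponential voltage update at fixed step
#' `dt`. The model is first settled at zero current for `p$settle` ms; a
#' non-settled rest (|dV/dt| > 0.01 mV/ms at the end of the settle) is
#' reported as a warning. Fully deterministic.
#'
#' @param m a `neuron_model`.
#' @param I step amplitude, pA.
#' @param p a `sim_protocol`.
#' @return A `sweep_rec` (voltage trace in mV plus the step stimulus).
#' @export
run_current_step <- function(m, I, p = sim_protocol()) {
  stopifnot(inherits(m, "neuron_model"), inherits(p, "sim_protocol"))
  tabs <- tabulate_channels(m, p$dt)
  g_leak_mS <- m$g_leak * 1000
  # settle at I = 0
  n_settle <- as.integer(round(p$settle / p$dt))
  v0 <- m$v_init
  if (n_settle > 0) {
    rec_settle <- max(1L, n_settle %/% 16L)
    st <- hh_run_cpp(v0, p$dt, n_settle, 0, m$cm, g_leak_mS, m$e_leak,
                     tabs, -120, 0.1, rec_settle)
    if (!isTRUE(st$ok))
      stop("numerical divergence during settle (V = ", st$v_last, " mV)")
    vs <- st$v
    v0 <- st$v_last
    for (c in seq_along(tabs)) tabs[[c]]$x0 <- as.numeric(st$gates[[c]])
    # terminal drift rate over the last 1/16th of the settle period
    nv <- length(vs)
    if (nv >= 2 && abs(vs[nv] - vs[nv - 1]) / (rec_settle * p$dt) > 0.01)
      warning("model may not have settled to rest (terminal drift ",
              signif(abs(vs[nv] - vs[nv - 1]) / (rec_settle * p$dt), 2),
              " mV/ms)")
  }
  total_ms <- p$onset + p$step_duration + p$tail
  n_steps <- as.integer(round(total_ms / p$dt))
  i_dens <- numeric(n_steps)
  on_i <- as.integer(round(p$onset / p$dt))
  off_i <- as.integer(round((p$onset + p$step_duration) / p$dt))
  i_dens[(on_i + 1):off_i] <- I * 1e-6 / m$area  # pA -> uA/cm^2
  out <- hh_run_cpp(v0, p$dt, n_steps, i_dens, m$cm, g_leak_mS, m$e_leak,
                    tabs, -120, 0.1, p$record_every)
  if (!isTRUE(out$ok))
    stop("numerical divergence at I = ", I, " pA, step ", out$step,
         " (V = ", out$v_last, " mV)")
  tr <- trace(out$v, dt = p$dt * p$record_every, unit = "mV", t0 = 0)
  sweep_rec(tr, stimulus_step(I, p$onset, p$step_duration))
}

#' Run a full step family and return a sweep set
#'
#' @param m a `neuron_model`.
#' @param p a `sim_protocol`; one sweep per entry of `p$step_currents`.
#' @param cell_id label for the resulting `sweep_set`.
#' @return A current-clamp `sweep_set`.
#' @export
run_protocol <- function(m, p = sim_protocol(), cell_id = m$name) {
  sweeps <- lapply(p$step_currents, function(I) run_current_step(m, I, p))
  sweep_set(cell_id, sweeps, mode = "current_clamp",
            metadata = list(model = m$name))
}

#' Instantaneous firing frequency
#'
#' `1000 / ISI` for each consecutive spike pair, Hz.
#'
#' @param spike_times ordered spike times, ms (>= 2).
#' @return Numeric vector, one entry per inter-spike interval.
#' @export
instantaneous_frequency <- function(spike_times) {
  if (length(spike_times) < 2L) stop("need >= 2 spikes")
  1000 / diff(spike_times)
}

#' Kv3.1 conductance-density sweep
#'
#' For each Kv3.1 density, runs the full step protocol and extracts features
#' through the same [intrinsic_profile()] code path used for recordings,
#' then classifies the result. Reports maximal firing frequency, SFA, AP
#' half-width and fAHP per density.
#'
#' @param m a `neuron_model` containing a `kv31` channel.
#' @param gbar_values Kv3.1 densities to test, S/cm^2.
#' @param p a `sim_protocol`.
#' @param ... passed to [intrinsic_profile()].
#' @return Data frame: `gbar_kv31`, `max_freq_Hz`, `sfa`, `half_width_ms`,
#'   `fahp_mV`, `rheobase_pA`, `label`.
#' @export
kv31_sweep <- function(m, gbar_values, p = sim_protocol(), ...) {
  stopifnot(inherits(m, "neuron_model"))
  if (!"kv31" %in% names(m$channels)) stop("model has no kv31 channel")
  rows <- lapply(gbar_values, function(g) {
    mi <- set_gbar(m, "kv31", g)
    s <- run_protocol(mi, p, cell_id = sprintf("%s_g%.4g", m$name, g))
    prof <- intrinsic_profile(s, ...)
    cls <- classify_phys(prof)
    data.frame(
      gbar_kv31 = g,
      max_freq_Hz = prof$max_freq,
      sfa = prof$sfa,
      half_width_ms = if (is.null(prof$ap)) NA_real_ else prof$ap$half_width,
      fahp_mV = if (is.null(prof$ap)) NA_real_ else prof$ap$fahp,
      rheobase_pA = prof$rheobase,
      label = cls$label,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Shipped regular-spiking model configurations
#'
#' Reduced single-compartment stand-ins for layer 5 somatostatin-positive
#' interneurons: fast sodium + delayed rectifier for spike generation, an
#' M-type slow potassium conductance for spike-frequency accommodation, and
#' a Kv3.1 conductance at a low baseline density. Densities are read from
#' the package's model configuration file (`inst/extdata/rs_models.yaml`),
#' which documents every value.
#'
#' @param path optional alternative YAML configuration file.
#' @return Named list of `neuron_model`.
#' @export
rs_models <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rs_models.yaml", package = "cinphys")
  cfg <- yaml::read_yaml(path)
  reg <- channel_registry()
  out <- lapply(cfg$models, function(mc) {
    chans <- list()
    for (nm in names(mc$gbar)) {
      if (!nm %in% names(reg)) stop("unknown channel in config: ", nm)
      ch <- reg[[nm]]
      ch$gbar <- mc$gbar[[nm]]
      chans[[nm]] <- ch
    }
    neuron_model(chans, cm = mc$cm, area = mc$area, g_leak = mc$g_leak,
                 e_leak = mc$e_leak, v_init = mc$v_init, name = mc$name)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write a model configuration to YAML
#' @param models named list of `neuron_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(models, path) {
  cfg <- list(models = lapply(models, function(m) {
    list(name = m$name, cm = m$cm, area = m$area, g_leak = m$g_leak,
         e_leak = m$e_leak, v_init = m$v_init,
         gbar = lapply(m$channels, `[[`, "gbar"))
  }))
  names(cfg$models) <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}
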