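# Analytic test waveforms with closed-form ground truth.

# triangular AP: linear rise base -> peak over rise_ms, linear fall back,
# optional afterhyperpolarizing dip
triangle_ap_trace <- function(base = -40, peak = 30, rise_ms = 0.6,
                              dip = NULL, dip_ms = 2, dt = 0.01,
                              pre_ms = 10, post_ms = 10) {
  t_up <- seq(0, rise_ms, by = dt)
  up <- base + (peak - base) * t_up / rise_ms
  dn <- rev(up)[-1]
  v <- c(rep(base, round(pre_ms / dt)), up, dn)
  if (!is.null(dip)) {
    t_d <- seq(dt, dip_ms, by = dt)
    half <- dip_ms / 2
    dipseg <- base + (dip - base) * (1 - abs(t_d - half) / half)
    v <- c(v, dipseg)
  }
  v <- c(v, rep(base, round(post_ms / dt)))
  trace(v, dt = dt, unit = "mV")
}

# membrane charging of a passive RC cell for a current step
rc_response <- function(I_pA, R_MOhm, tau_ms, e_rest = -65, onset = 100,
                        duration = 800, total = 1000, dt = 0.1) {
  tt <- seq(0, total, by = dt)
  dv_ss <- I_pA * R_MOhm / 1000   # mV
  v <- rep(e_rest, length(tt))
  on_idx <- tt >= onset & tt < onset + duration
  v[on_idx] <- e_rest + dv_ss * (1 - exp(-(tt[on_idx] - onset) / tau_ms))
  off <- tt >= onset + duration
  v_end <- e_rest + dv_ss * (1 - exp(-duration / tau_ms))
  v[off] <- e_rest + (v_end - e_rest) * exp(-(tt[off] - onset - duration) / tau_ms)
  sweep_rec(trace(v, dt = dt, unit = "mV"),
            stimulus_step(I_pA, onset, duration))
}

rc_sweep_set <- function(amps = seq(-50, 20, by = 10), R_MOhm = 150,
                         tau_ms = 20, ...) {
  sweep_set("rc_cell", lapply(amps, rc_response, R_MOhm = R_MOhm,
                              tau_ms = tau_ms, ...),
            mode = "current_clamp")
}

# brute-force spike finder: scans every sample for a dV/dt crossing of the
# criterion, then takes the next local maximum (independent oracle for
# detect_spikes)
brute_spikes <- function(tr, thr = 20, min_isi = 1) {
  v <- tr$samples
  dt <- tr$dt
  dv <- diff(v) / dt
  out <- numeric(0)
  i <- 2L
  n <- length(v)
  while (i <= length(dv)) {
    if (dv[i] >= thr && dv[i - 1] < thr) {
      j <- i
      while (j < n - 1 && v[j + 1] >= v[j]) j <- j + 1L
      tm <- (j - 1) * dt + tr$t0
      if (!length(out) || tm - out[length(out)] >= min_isi) out <- c(out, tm)
      i <- j
    }
    i <- i + 1L
  }
  out
}

# small two-channel spiking model for fast simulator tests
tiny_model <- function(kv31 = 0.009, km = 5e-3, na = 0.15, kdr = 0.004,
                       gl = 5e-4, el = -67, area = 1e-5) {
  reg <- channel_registry()
  ch <- reg[c("na_t", "kdr", "km", "kv31")]
  ch$na_t$gbar <- na; ch$kdr$gbar <- kdr; ch$km$gbar <- km
  ch$kv31$gbar <- kv31
  neuron_model(ch, area = area, g_leak = gl, e_leak = el, v_init = -70,
               name = "tiny")
}
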