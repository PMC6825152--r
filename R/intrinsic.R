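#' Resting membrane potential
#'
#' Mean voltage over a pre-stimulus baseline window, averaged across the
#' sweeps of a current-clamp family. The window must precede stimulus onset
#' in every sweep.
#'
#' @param s a current-clamp `sweep_set`.
#' @param baseline_window numeric length-2, ms interval `[from, to)` relative
#'   to trace time. Default: the 100 ms (or all available time) before the
#'   earliest stimulus onset.
#' @return RMP in mV.
#' @export
compute_rmp <- function(s, baseline_window = NULL) {
  stopifnot(inherits(s, "sweep_set"))
  if (s$mode != "current_clamp") stop("RMP requires a current-clamp sweep_set")
  onset <- min(vapply(s$sweeps, function(sw) sw$stimulus$onset, numeric(1)))
  t0 <- s$sweeps[[1]]$trace$t0
  if (onset <= t0) stop("no pre-stimulus segment: stimulus starts at trace start")
  if (is.null(baseline_window)) baseline_window <- c(max(t0, onset - 100), onset)
  if (baseline_window[2] <= baseline_window[1])
    stop("empty baseline window")
  if (baseline_window[2] > onset + 1e-9)
    stop("baseline window must precede stimulus onset (", onset, " ms)")
  v <- unlist(lapply(s$sweeps, function(sw)
    trace_window(sw$trace, baseline_window[1], baseline_window[2])))
  mean(v)
}

#' Input resistance from subthreshold current steps
#'
#' Slope of the least-squares linear fit of steady-state voltage deflection
#' against injected current, over subthreshold sweeps (sweeps containing
#' spikes are excluded). Steady state is the mean over the final fraction of
#' the step; the baseline is the mean over the pre-stimulus segment of each
#' sweep. A slope in mV/pA is a resistance in GOhm, reported here in MOhm.
#'
#' @param s a current-clamp `sweep_set` with >= 3 subthreshold sweeps of
#'   distinct amplitudes.
#' @param steady_frac fraction of the step, at its end, used as the
#'   steady-state window. Default 0.25.
#' @return Input resistance, MOhm.
#' @export
input_resistance <- function(s, steady_frac = 0.25) {
  stopifnot(inherits(s, "sweep_set"))
  keep <- vapply(s$sweeps, function(sw)
    length(detect_spikes(sw$trace)) == 0L, logical(1))
  sweeps <- s$sweeps[keep]
  if (length(sweeps) < 3L) stop("need >= 3 spike-free sweeps for input resistance")
  amps <- vapply(sweeps, function(sw) sw$stimulus$amplitude, numeric(1))
  if (length(unique(amps)) < 2L) stop("all stimulus amplitudes equal")
  dv <- vapply(sweeps, function(sw) {
    st <- sw$stimulus
    base <- mean(trace_window(sw$trace, sw$trace$t0, st$onset))
    ss_from <- st$onset + (1 - steady_frac) * st$duration
    ss <- mean(trace_window(sw$trace, ss_from, st$onset + st$duration))
    ss - base
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, amps), dv)
  unname(fit$coefficients[2]) * 1000  # mV/pA -> MOhm
}

#' Detect action potential peak times in a voltage trace
#'
#' Spikes are located where dV/dt first exceeds an upstroke criterion
#' (default 20 mV/ms); each detection is assigned to the next local voltage
#' maximum, and detections closer than a refractory merge window are fused.
#' Deterministic for a fixed trace.
#'
#' @param t a voltage `trace`.
#' @param dvdt_threshold upstroke criterion, mV/ms.
#' @param min_isi refractory merge window, ms.
#' @param deriv_span_ms span of the centered finite difference used for
#'   dV/dt, ms; widening it suppresses sample-to-sample recording noise
#'   without touching the much faster AP upstroke.
#' @return Numeric vector of AP peak times, ms (possibly empty).
#' @export
detect_spikes <- function(t, dvdt_threshold = 20, min_isi = 1,
                          deriv_span_ms = 0.2) {
  stopifnot(inherits(t, "trace"))
  v <- t$samples
  n <- length(v)
  span <- max(1L, as.integer(round(deriv_span_ms / t$dt / 2)))
  if (n < 2L * span + 2L) return(numeric(0))
  dv <- (v[(1L + 2L * span):n] - v[1:(n - 2L * span)]) / (2 * span * t$dt)
  above <- dv >= dvdt_threshold
  up <- which(above[-1] & !above[-length(above)]) + 1L
  if (above[1]) up <- c(1L, up)
  if (length(up) == 0L) return(numeric(0))
  peaks <- integer(0)
  for (j in up) {
    i <- j + span  # center of the finite difference
    repeat {       # climb to the local maximum, looking `span` samples ahead
      seg_end <- min(n, i + max(span, 1L))
      nxt <- which.max(v[i:seg_end]) + i - 1L
      if (nxt == i) break
      i <- nxt
    }
    peaks <- c(peaks, i)
  }
  peaks <- unique(peaks)
  tt <- t$t0 + (peaks - 1) * t$dt
  if (length(tt) > 1L) {
    keep <- c(TRUE, diff(tt) >= min_isi)
    # merging must be iterative: a run of close detections collapses to first
    out <- tt[1]
    for (k in tt[-1]) if (k - out[length(out)] >= min_isi) out <- c(out, k)
    tt <- out
  }
  tt
}

#' Spike counts per stimulus amplitude
#'
#' Counts action potentials fired within the stimulus window of each
#' depolarizing sweep.
#'
#' @param s a current-clamp `sweep_set`.
#' @param ... passed to [detect_spikes()].
#' @return Data frame with columns `amplitude_pA`, `n_spikes`,
#'   `frequency_Hz` (count / stimulus duration in s), ordered by amplitude.
#' @export
firing_curve <- function(s, ...) {
  stopifnot(inherits(s, "sweep_set"))
  dep <- s$sweeps[vapply(s$sweeps, function(sw) sw$stimulus$amplitude > 0,
                         logical(1))]
  if (length(dep) == 0L) stop("no depolarizing sweeps")
  rows <- lapply(dep, function(sw) {
    st <- sw$stimulus
    sp <- detect_spikes(sw$trace, ...)
    sp <- sp[sp >= st$onset & sp <= st$onset + st$duration]
    data.frame(amplitude_pA = st$amplitude, n_spikes = length(sp),
               frequency_Hz = length(sp) / (st$duration / 1000))
  })
  out <- do.call(rbind, rows)
  out[order(out$amplitude_pA), , drop = FALSE]
}

#' Maximum firing frequency over a step family
#'
#' @param s a current-clamp `sweep_set`.
#' @param ... passed to [detect_spikes()].
#' @return Maximum of spike count / stimulus duration across sweeps, Hz.
#' @export
max_firing_frequency <- function(s, ...) {
  max(firing_curve(s, ...)$frequency_Hz)
}

#' Rheobase: minimum step current eliciting at least one spike
#'
#' @param s a current-clamp `sweep_set`.
#' @param ... passed to [detect_spikes()].
#' @return Rheobase, pA. Resolution is limited to the tested amplitude grid.
#' @export
rheobase <- function(s, ...) {
  fc <- firing_curve(s, ...)
  i <- which(fc$n_spikes >= 1L)
  if (length(i) == 0L) stop("rheobase undefined: no sweep spikes")
  fc$amplitude_pA[min(i)]
}

#' Single action-potential waveform features
#'
#' Measures the first AP of the sweep 50 pA above rheobase (or the nearest
#' tested suprathreshold amplitude, recorded in the result). Threshold is the
#' voltage at the maximum of the third time-derivative of voltage within a
#' pre-peak search window, after Savitzky-Golay smoothing; amplitude is
#' threshold to peak; half-width is the waveform width at threshold +
#' amplitude/2, linearly interpolated between samples; `max_dvdt` is the
#' maximal first derivative on the upstroke; fAHP is threshold minus the
#' voltage minimum after the peak (a non-negative magnitude).
#'
#' @param s a current-clamp `sweep_set`.
#' @param delta_pA target increment above rheobase, pA. Default 50.
#' @param search_pre_ms pre-peak window searched for the threshold, ms.
#' @param fahp_window_ms post-peak window searched for the fAHP trough, ms
#'   (truncated at the next spike's upstroke).
#' @param smooth_ms Savitzky-Golay smoothing window for the third
#'   derivative, ms (order 3; widened to >= 5 samples).
#' @param ... passed to [detect_spikes()].
#' @return List of class `ap_features`: `peak_time`, `threshold_v`,
#'   `amplitude`, `half_width`, `max_dvdt`, `fahp`, `sweep_amplitude_pA`.
#' @export
ap_features <- function(s, delta_pA = 50, search_pre_ms = 3,
                        fahp_window_ms = 10, smooth_ms = 0.5, ...) {
  rb <- rheobase(s, ...)
  amps <- sweep_amplitudes(s)
  target <- rb + delta_pA
  cand <- amps[amps >= rb]
  a_sel <- cand[which.min(abs(cand - target))]
  sw <- sweep_at(s, a_sel)
  sp <- detect_spikes(sw$trace, ...)
  st <- sw$stimulus
  sp <- sp[sp >= st$onset & sp <= st$onset + st$duration]
  if (length(sp) == 0L) stop("no AP in selected sweep (", a_sel, " pA)")
  f <- measure_ap(sw$trace, sp[1],
                  next_spike = if (length(sp) > 1) sp[2] else NA_real_,
                  search_pre_ms = search_pre_ms,
                  fahp_window_ms = fahp_window_ms, smooth_ms = smooth_ms)
  f$sweep_amplitude_pA <- a_sel
  f
}

#' Measure one AP at a known peak time
#' @param t voltage `trace`; `peak_time` from [detect_spikes()].
#' @param peak_time AP peak time, ms.
#' @param next_spike peak time of the following spike, ms, or `NA`.
#' @inheritParams ap_features
#' @return List of class `ap_features` (without `sweep_amplitude_pA`).
#' @export
measure_ap <- function(t, peak_time, next_spike = NA_real_,
                       search_pre_ms = 3, fahp_window_ms = 10,
                       smooth_ms = 0.5) {
  v <- t$samples
  dt <- t$dt
  ip <- trace_index(t, peak_time)
  n <- length(v)
  i_from <- max(1L, ip - as.integer(ceiling(search_pre_ms / dt)))
  if (ip - i_from < 4L) stop("peak window truncated by trace start")
  # third derivative of the smoothed pre-peak segment
  seg_to <- min(n, ip + 5L)
  seg <- v[i_from:seg_to]
  w <- max(5L, as.integer(round(smooth_ms / dt)))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- if (length(seg) > w) signal::sgolayfilt(seg, p = 3, n = w) else seg
  d3 <- diff(sm, differences = 3) / dt^3
  # d3[k] is centered near sample k+1..k+2 of seg; attribute to k+1 (earliest
  # tie wins via which.max). The search stops at the sample where dV/dt first
  # reaches the spike upstroke criterion: past that point the third
  # derivative of a conductance-model upstroke keeps growing almost to the
  # peak, which would put the "threshold" halfway up the spike.
  upto <- ip - i_from - 1L          # stay strictly before the peak
  if (upto < 1L) stop("peak too close to window start")
  d1 <- diff(seg) / dt   # raw: smoothing smears a narrow upstroke backwards
  j <- min(ip - i_from, length(d1))
  while (j >= 1L && d1[j] < 20) j <- j - 1L   # skip the peak turnover
  while (j >= 1L && d1[j] >= 20) j <- j - 1L  # traverse the fast upstroke
  if (j >= 1L) upto <- min(upto, j)
  upto <- min(upto, length(d3))
  # the first filter-window samples carry Savitzky-Golay edge artifacts
  lo <- min(w, upto)
  k <- lo - 1L + which.max(d3[lo:upto])
  i_thr <- i_from + k
  thr <- v[i_thr]
  peak_v <- v[ip]
  amp <- peak_v - thr
  if (amp <= 0) stop("non-positive AP amplitude; bad threshold or peak")
  # half-width at thr + amp/2, linear interpolation on the raw samples
  half <- thr + amp / 2
  i_up <- i_thr
  while (i_up < ip && v[i_up + 1] < half) i_up <- i_up + 1L
  t_up <- cross_time(t, i_up, half, rising = TRUE)
  i_dn <- ip
  i_end_hw <- if (is.na(next_spike)) n else trace_index(t, next_spike)
  while (i_dn < i_end_hw && v[i_dn + 1] > half) i_dn <- i_dn + 1L
  if (i_dn >= n) stop("peak window truncated by trace end")
  t_dn <- cross_time(t, i_dn, half, rising = FALSE)
  # max dV/dt on the upstroke (threshold to peak)
  max_dvdt <- max(diff(v[i_thr:ip]) / dt)
  # fAHP trough: peak -> min(fahp window, next spike upstroke)
  t_stop <- peak_time + fahp_window_ms
  if (!is.na(next_spike)) t_stop <- min(t_stop, next_spike - 0.5)
  i_stop <- min(n, trace_index(t, t_stop))
  if (i_stop <= ip) stop("no post-peak samples for fAHP")
  v_min <- min(v[(ip + 1L):i_stop])
  structure(list(
    peak_time = peak_time, threshold_v = thr, amplitude = amp,
    half_width = t_dn - t_up, max_dvdt = max_dvdt,
    fahp = max(0, thr - v_min)
  ), class = "ap_features")
}

# linear interpolation of the time where v crosses `level` between sample i
# and i+1 (rising) or i and i+1 (falling)
cross_time <- function(t, i, level, rising) {
  v <- t$samples
  t_i <- t$t0 + (i - 1) * t$dt
  v1 <- v[i]; v2 <- v[min(length(v), i + 1L)]
  if (v2 == v1) return(t_i)
  frac <- (level - v1) / (v2 - v1)
  frac <- min(1, max(0, frac))
  t_i + frac * t$dt
}

#' Spike-frequency accommodation index
#'
#' Ratio of the last inter-spike interval to the first.
#'
#' @param spike_times ordered spike times, ms (>= 3 spikes).
#' @return SFA ratio (dimensionless).
#' @export
sfa <- function(spike_times) {
  if (length(spike_times) < 3L) stop("SFA undefined: need >= 3 spikes")
  isi <- diff(spike_times)
  isi[length(isi)] / isi[1]
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector, >= 2 values, nonzero mean.
#' @return CV (dimensionless).
#' @export
cv_ratio <- function(values) {
  if (length(values) < 2L) stop("CV undefined: need >= 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero")
  stats::sd(values) / m
}

#' Sag ratio and rebound from a hyperpolarizing step
#'
#' `sag_ratio = (V_ss - V_baseline) / (V_min - V_baseline)`, the ratio of
#' the steady-state to the peak hyperpolarizing deflection: 1 for a pure RC
#' response, < 1 when an HCN-type conductance relaxes the voltage back from
#' its early trough. `rebound` is the post-stimulus peak voltage minus
#' baseline, mV.
#'
#' @param s a current-clamp `sweep_set` containing a hyperpolarizing sweep.
#' @param amplitude which hyperpolarizing amplitude to use, pA. Default: the
#'   most negative tested.
#' @param steady_frac end fraction of the step used for V_ss.
#' @return List with `sag_ratio` and `rebound_mV`.
#' @export
sag_rebound <- function(s, amplitude = NULL, steady_frac = 0.25) {
  amps <- sweep_amplitudes(s)
  hyp <- amps[amps < 0]
  if (length(hyp) == 0L) stop("no hyperpolarizing sweep")
  if (is.null(amplitude)) amplitude <- min(hyp)
  sw <- sweep_at(s, amplitude)
  st <- sw$stimulus
  base <- mean(trace_window(sw$trace, sw$trace$t0, st$onset))
  step_v <- trace_window(sw$trace, st$onset, st$onset + st$duration)
  v_min <- min(step_v)
  ss_from <- st$onset + (1 - steady_frac) * st$duration
  v_ss <- mean(trace_window(sw$trace, ss_from, st$onset + st$duration))
  denom <- v_min - base
  sag <- if (abs(denom) < 1e-12) 1 else (v_ss - base) / denom
  t_end <- sw$trace$t0 + trace_span(sw$trace)
  post <- trace_window(sw$trace, st$onset + st$duration, t_end)
  list(sag_ratio = sag, rebound_mV = max(post) - base)
}

#' Full intrinsic profile of one cell
#'
#' Runs every intrinsic and single-AP measurement on a current-clamp sweep
#' family and returns them in one record consumable by [classify_phys()].
#' The SFA/CV sweep is the lowest amplitude eliciting at least `min_spikes`
#' spikes (falling back to the sweep with the most spikes).
#'
#' @param s a current-clamp `sweep_set`.
#' @param min_spikes minimum spike count for the SFA/CV sweep. Default 10.
#' @param ... passed to [ap_features()] / [detect_spikes()].
#' @return List of class `intrinsic_profile` with fields `cell_id`, `rmp`,
#'   `r_in`, `rheobase`, `firing_curve`, `max_freq`, `sfa`, `cv_isi`,
#'   `sag_ratio`, `rebound`, `ap` (an `ap_features`). Features that cannot
#'   be computed (e.g. SFA with < 3 spikes) are `NA`.
#' @export
intrinsic_profile <- function(s, min_spikes = 10, ...) {
  fc <- firing_curve(s)
  rb <- tryCatch(rheobase(s), error = function(e) NA_real_)
  ap <- if (is.na(rb)) NULL else
    tryCatch(ap_features(s, ...), error = function(e) NULL)
  # SFA / CV sweep selection
  sfa_v <- NA_real_; cv_v <- NA_real_
  cand <- fc$amplitude_pA[fc$n_spikes >= min_spikes]
  a_sfa <- if (length(cand)) min(cand) else
    fc$amplitude_pA[which.max(fc$n_spikes)]
  sw <- tryCatch(sweep_at(s, a_sfa), error = function(e) NULL)
  if (!is.null(sw)) {
    st <- sw$stimulus
    sp <- detect_spikes(sw$trace)
    sp <- sp[sp >= st$onset & sp <= st$onset + st$duration]
    if (length(sp) >= 3L) {
      sfa_v <- sfa(sp)
      cv_v <- cv_ratio(diff(sp))
    }
  }
  sag <- tryCatch(sag_rebound(s), error = function(e)
    list(sag_ratio = NA_real_, rebound_mV = NA_real_))
  structure(list(
    cell_id = s$cell_id,
    rmp = tryCatch(compute_rmp(s), error = function(e) NA_real_),
    r_in = tryCatch(input_resistance(s), error = function(e) NA_real_),
    rheobase = rb,
    firing_curve = fc,
    max_freq = max(fc$frequency_Hz),
    sfa = sfa_v,
    cv_isi = cv_v,
    sag_ratio = sag$sag_ratio,
    rebound = sag$rebound_mV,
    ap = ap
  ), class = "intrinsic_profile")
}

#' One-row data frame view of an intrinsic profile
#' @param p an `intrinsic_profile`.
#' @return A one-row data frame (firing curve omitted).
#' @export
profile_row <- function(p) {
  stopifnot(inherits(p, "intrinsic_profile"))
  ap <- p$ap
  data.frame(
    cell_id = p$cell_id, rmp_mV = p$rmp, r_in_MOhm = p$r_in,
    rheobase_pA = p$rheobase, max_freq_Hz = p$max_freq, sfa = p$sfa,
    cv_isi = p$cv_isi, sag_ratio = p$sag_ratio, rebound_mV = p$rebound,
    ap_threshold_mV = if (is.null(ap)) NA_real_ else ap$threshold_v,
    ap_amplitude_mV = if (is.null(ap)) NA_real_ else ap$amplitude,
    ap_half_width_ms = if (is.null(ap)) NA_real_ else ap$half_width,
    ap_max_dvdt = if (is.null(ap)) NA_real_ else ap$max_dvdt,
    fahp_mV = if (is.null(ap)) NA_real_ else ap$fahp,
    stringsAsFactors = FALSE
  )
}
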