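#' Robust noise SD of a current trace
#'
#' Median absolute deviation (scaled to the normal) of a first-difference
#' high-pass residual, which is insensitive to the slow event waveforms.
#'
#' @param t a current `trace`.
#' @return Noise SD in the trace's unit.
#' @export
noise_sd <- function(t) {
  stopifnot(inherits(t, "trace"))
  stats::mad(diff(t$samples)) / sqrt(2)
}

#' Detect postsynaptic current events
#'
#' Detects outward (positive) synaptic events on a voltage-clamp current
#' trace: the trace is baseline-corrected with a running-median baseline and
#' lightly smoothed, candidate samples exceeding `k` times the robust noise
#' SD are grouped into excursions, excursions closer than `merge_ms` are
#' fused, and each excursion's onset is the time the corrected trace last
#' rose through 10% of that excursion's peak. Deterministic given the trace
#' and settings.
#'
#' @param t a current `trace` (events positive).
#' @param noise_sd robust noise SD, pA; estimated with [noise_sd()] when
#'   `NULL`.
#' @param k detection threshold in noise SDs. Default 4.
#' @param merge_ms merge window, ms: excursions closer than this are one
#'   event. Default 5.
#' @param baseline_ms running-median baseline window, ms. Default 200.
#' @param smooth_ms moving-average pre-smoothing, ms. Default 0.3.
#' @return Numeric vector of event onset times, ms (possibly empty).
#' @export
detect_events <- function(t, noise_sd = NULL, k = 4, merge_ms = 5,
                          baseline_ms = 200, smooth_ms = 0.3) {
  stopifnot(inherits(t, "trace"))
  v <- t$samples
  dt <- t$dt
  if (is.null(noise_sd)) noise_sd <- cinphys::noise_sd(t)
  nb <- as.integer(round(baseline_ms / dt))
  if (nb %% 2L == 0L) nb <- nb + 1L
  base <- if (nb >= 3 && length(v) > nb) stats::runmed(v, nb, endrule = "median")
          else rep(stats::median(v), length(v))
  x <- v - base
  ns <- max(1L, as.integer(round(smooth_ms / dt)))
  if (ns > 1L) x <- stats::filter(x, rep(1 / ns, ns), sides = 2)
  x[is.na(x)] <- 0
  x <- as.numeric(x)
  if (noise_sd <= 0) noise_sd <- 1e-12
  n <- length(x)
  thr <- k * noise_sd
  # candidate event crests: local maxima of the conditioned trace above
  # threshold; candidates closer than the merge window collapse to the
  # largest (so two events 4 ms apart with a 5 ms window are one detection)
  cand <- which(x > thr &
                x >= c(-Inf, x[-n]) &
                x > c(x[-1], -Inf))
  if (length(cand) == 0L) return(numeric(0))
  gap <- merge_ms / dt
  peaks <- integer(0)
  cur <- cand[1]
  for (i in cand[-1]) {
    if (i - cur < gap) {
      if (x[i] > x[cur]) cur <- i
    } else {
      peaks <- c(peaks, cur)
      cur <- i
    }
  }
  peaks <- c(peaks, cur)
  # prominence filter: a crest must rise at least the detection threshold
  # above the local minimum since the previous accepted event, which rejects
  # noise maxima sitting on an event's decay while keeping genuine events
  # riding on it
  look_back <- as.integer(round(30 / dt))
  acc <- integer(0)
  last <- 1L
  for (pk in peaks) {
    j0 <- max(last, pk - look_back, 1L)
    if (x[pk] - min(x[j0:pk]) >= thr) { acc <- c(acc, pk); last <- pk }
  }
  if (length(acc) == 0L) return(numeric(0))
  peaks <- acc
  # onset: 10% rise above the local pre-peak minimum (so an event riding on
  # the decay of the previous one is measured from its own foot)
  prev <- c(1L, peaks[-length(peaks)])
  onsets <- vapply(seq_along(peaks), function(ii) {
    pk <- peaks[ii]
    j0 <- max(prev[ii], pk - look_back, 1L)
    jmin <- j0 + which.min(x[j0:pk]) - 1L
    lev <- x[jmin] + 0.1 * (x[pk] - x[jmin])
    j <- pk
    while (j > jmin && x[j - 1] > lev) j <- j - 1L
    t$t0 + (j - 1) * dt
  }, numeric(1))
  as.numeric(onsets)
}

#' Measure one synaptic event
#'
#' Baseline is the mean over a short window ending at onset; amplitude is
#' baseline to peak; rise time is the 10-90% interval on the rising phase
#' (linearly interpolated); decay tau comes from a single-exponential fit
#' from the peak down to 10% of the amplitude; charge is the trapezoidal
#' integral of the baseline-subtracted current from onset until the trace
#' first returns within `return_frac` noise SDs of baseline after the peak
#' (capped at `max_integrate_ms`). pA x ms = femtocoulombs; charge is
#' reported in pC.
#'
#' @param t a current `trace`.
#' @param onset event onset, ms.
#' @param baseline_ms pre-onset baseline window, ms. Default 2.
#' @param peak_window_ms window after onset searched for the peak, ms.
#' @param return_frac baseline-return criterion, in noise SDs. Default 0.5.
#' @param max_integrate_ms cap on the integration window, ms. Default 200.
#' @param next_onset onset of the following event, ms, or `NA`; when given,
#'   the peak search, decay fit and charge integration stop just before it,
#'   so overlapping events do not contaminate each other.
#' @return List of class `event_measure`: `onset`, `amplitude_pA`,
#'   `rise_time_10_90_ms`, `decay_tau_ms`, `charge_pC`, `peak_time`,
#'   `decay_fit_ok`.
#' @export
measure_event <- function(t, onset, baseline_ms = 2, peak_window_ms = 20,
                          return_frac = 0.5, max_integrate_ms = 200,
                          next_onset = NA_real_) {
  stopifnot(inherits(t, "trace"))
  v <- t$samples
  dt <- t$dt
  n <- length(v)
  i_next <- if (is.na(next_onset)) n else
    max(trace_index(t, next_onset) - 1L, 1L)
  i_on <- trace_index(t, onset)
  i_b0 <- max(1L, i_on - as.integer(round(baseline_ms / dt)))
  base <- mean(v[i_b0:max(i_b0, i_on - 1L)])  # exclude the onset sample
  i_pk_end <- min(n, i_next, i_on + as.integer(round(peak_window_ms / dt)))
  if (i_pk_end <= i_on) stop("peak window empty")
  # locate the peak on a lightly smoothed copy and average raw samples
  # around it: taking a raw maximum over the crest would be biased upward
  # by roughly the largest noise excursion
  seg <- v[(i_on + 1L):i_pk_end]
  ns <- max(1L, as.integer(round(1 / dt)))
  if (ns > 1L && length(seg) > 2L * ns) {
    segs <- as.numeric(stats::filter(seg, rep(1 / ns, ns), sides = 2))
    segs[is.na(segs)] <- -Inf
  } else segs <- seg
  ipk <- i_on + which.max(segs)
  if (ipk >= n) stop("event peak at trace boundary")
  w_avg <- max(0L, as.integer(round(0.25 / dt)))
  amp <- mean(v[max(1L, ipk - w_avg):min(n, ipk + w_avg)]) - base
  if (amp <= 0) stop("non-positive event amplitude")
  # 10-90% rise, interpolated
  l10 <- base + 0.1 * amp; l90 <- base + 0.9 * amp
  i <- ipk; while (i > i_on && v[i - 1] > l90) i <- i - 1L
  t90 <- cross_time(t, max(i - 1L, 1L), l90, rising = TRUE)
  j <- i; while (j > i_on && v[j - 1] > l10) j <- j - 1L
  t10 <- cross_time(t, max(j - 1L, 1L), l10, rising = TRUE)
  rise <- max(t90 - t10, dt * 1e-3)
  # single-exponential decay fit, peak -> 10% of amplitude
  i_end_fit <- ipk
  lim <- min(n, i_next, ipk + as.integer(round(max_integrate_ms / dt)))
  while (i_end_fit < lim && v[i_end_fit + 1] - base > 0.1 * amp)
    i_end_fit <- i_end_fit + 1L
  fit_ok <- FALSE
  tau <- NA_real_
  if (i_end_fit - ipk >= 3L) {
    td <- (seq.int(ipk, i_end_fit) - ipk) * dt
    yd <- v[ipk:i_end_fit] - base
    # log-linear start then refine by nonlinear least squares
    pos <- yd > 0
    tau0 <- if (sum(pos) >= 2)
      unname(-1 / stats::coef(stats::lm(log(yd[pos]) ~ td[pos]))[2]) else rise * 3
    if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(rise * 3, dt * 5)
    fit <- tryCatch(
      minpack.lm::nlsLM(yd ~ A_fit * exp(-td / tau_fit),
                        start = list(A_fit = amp, tau_fit = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      tau <- stats::coef(fit)[["tau_fit"]]
      fit_ok <- is.finite(tau) && tau > 0
      if (!fit_ok) tau <- NA_real_
    }
  }
  # charge: onset -> first return to baseline after the peak
  nsd <- noise_sd(t)
  thr_ret <- base + return_frac * max(nsd, 1e-9)
  i_ret <- ipk
  while (i_ret < lim && v[i_ret + 1] > thr_ret) i_ret <- i_ret + 1L
  i_ret <- min(i_ret + 1L, n)
  y <- v[i_on:i_ret] - base
  charge_fC <- sum((y[-1] + y[-length(y)]) / 2) * dt  # pA*ms = fC
  structure(list(
    onset = onset, amplitude_pA = amp, rise_time_10_90_ms = rise,
    decay_tau_ms = tau, charge_pC = charge_fC / 1000,
    peak_time = t$t0 + (ipk - 1) * dt, decay_fit_ok = fit_ok
  ), class = "event_measure")
}

#' Rising slope of an event (10-90% linear fit)
#'
#' Least-squares slope of current against time over the samples between the
#' 10% and 90% amplitude crossings on the rising phase.
#'
#' @inheritParams measure_event
#' @return Slope, pA/ms.
#' @export
rising_slope <- function(t, onset, baseline_ms = 2, peak_window_ms = 20) {
  v <- t$samples
  dt <- t$dt
  i_on <- trace_index(t, onset)
  i_b0 <- max(1L, i_on - as.integer(round(baseline_ms / dt)))
  base <- mean(v[i_b0:max(i_b0, i_on - 1L)])
  i_pk_end <- min(length(v), i_on + as.integer(round(peak_window_ms / dt)))
  ipk <- i_on + which.max(v[(i_on + 1L):i_pk_end])
  amp <- v[ipk] - base
  if (amp <= 0) stop("non-positive event amplitude")
  l10 <- base + 0.1 * amp; l90 <- base + 0.9 * amp
  idx <- i_on:ipk
  sel <- idx[v[idx] >= l10 & v[idx] <= l90]
  if (length(sel) < 2L)
    stop("fewer than 2 samples between 10% and 90% crossings; ",
         "need dt below ", signif(dt / 2, 3), " ms for this event")
  tt <- (sel - 1) * dt + t$t0
  unname(stats::coef(stats::lm(v[sel] ~ tt))[2])
}

#' Onset-aligned average of events
#'
#' @param t a current `trace`.
#' @param onsets >= 2 event onset times, ms.
#' @param pre_ms,post_ms peri-event window, ms.
#' @return List: `average` (a `trace` with `t0 = -pre_ms`), `n_used`,
#'   `n_dropped` (windows extending past the trace bounds).
#' @export
average_events <- function(t, onsets, pre_ms = 5, post_ms = 50) {
  if (length(onsets) < 2L) stop("need >= 2 onsets to average")
  dt <- t$dt
  n <- length(t$samples)
  npre <- as.integer(round(pre_ms / dt))
  npost <- as.integer(round(post_ms / dt))
  mats <- list(); dropped <- 0L
  for (on in onsets) {
    i <- trace_index(t, on)
    if (i - npre < 1L || i + npost > n) { dropped <- dropped + 1L; next }
    mats[[length(mats) + 1L]] <- t$samples[(i - npre):(i + npost)]
  }
  if (length(mats) < 2L) stop("fewer than 2 usable event windows")
  avg <- Reduce(`+`, mats) / length(mats)
  list(average = trace(avg, dt = dt, unit = t$unit, t0 = -npre * dt),
       n_used = length(mats), n_dropped = dropped)
}

#' Per-pulse amplitudes, normalized series and paired-pulse ratio
#'
#' For each pulse time, the amplitude is measured from a local pre-pulse
#' baseline to the peak within the pulse's measurement window (the
#' inter-pulse interval, capped at `window_ms`). Overlapping measurement
#' windows (inter-pulse interval shorter than the decay) are permitted but
#' flagged.
#'
#' @param t a current `trace`.
#' @param pulse_times stimulus pulse times, ms (>= 2, strictly increasing).
#' @param window_ms cap on the per-pulse measurement window, ms. Default 45.
#' @param baseline_ms local pre-pulse baseline window, ms. Default 2.
#' @return List of class `train_measure`: `pulse_amplitudes_pA`,
#'   `normalized`, `ppr` (amplitude 2 / amplitude 1),
#'   `inter_pulse_interval_ms`, `overlap_flag`.
#' @export
train_analysis <- function(t, pulse_times, window_ms = 45, baseline_ms = 2) {
  if (length(pulse_times) < 2L) stop("need >= 2 pulse times")
  if (any(diff(pulse_times) <= 0)) stop("pulse times must be increasing")
  dt <- t$dt
  v <- t$samples
  ipi <- diff(pulse_times)
  amps <- numeric(length(pulse_times))
  for (p in seq_along(pulse_times)) {
    win <- if (p < length(pulse_times)) min(ipi[p], window_ms) else window_ms
    i_on <- trace_index(t, pulse_times[p])
    i_b0 <- max(1L, i_on - as.integer(round(baseline_ms / dt)))
    base <- mean(v[i_b0:i_on])
    i_end <- min(length(v), i_on + as.integer(round(win / dt)))
    amps[p] <- max(v[(i_on + 1L):i_end]) - base
  }
  if (amps[1] <= 0) stop("first pulse has non-positive amplitude")
  structure(list(
    pulse_amplitudes_pA = amps,
    normalized = amps / amps[1],
    ppr = amps[2] / amps[1],
    inter_pulse_interval_ms = ipi[1],
    overlap_flag = any(ipi < window_ms)
  ), class = "train_measure")
}

#' Event frequency and mean amplitude over a recording
#'
#' @param t a current `trace`.
#' @param onsets event onsets, ms; detected with [detect_events()] when
#'   `NULL`.
#' @param ... passed to [detect_events()].
#' @return List of class `event_train_stats`: `frequency_Hz`,
#'   `mean_amplitude_pA` (NA when no events), `n_events`,
#'   `recording_span_s`.
#' @export
event_train_stats <- function(t, onsets = NULL, ...) {
  span_s <- trace_span(t) / 1000
  if (span_s <= 0) stop("zero-length recording")
  if (is.null(onsets)) onsets <- detect_events(t, ...)
  nxt <- c(onsets[-1], NA_real_)
  amp <- if (length(onsets)) {
    vapply(seq_along(onsets), function(i)
      tryCatch(measure_event(t, onsets[i], next_onset = nxt[i])$amplitude_pA,
               error = function(e) NA_real_),
      numeric(1))
  } else numeric(0)
  structure(list(
    frequency_Hz = length(onsets) / span_s,
    mean_amplitude_pA = if (length(amp)) mean(amp, na.rm = TRUE) else NA_real_,
    n_events = length(onsets),
    recording_span_s = span_s
  ), class = "event_train_stats")
}
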