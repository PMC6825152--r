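test_that("rectangular and exponential events give closed-form charge and tau", {
  dt <- 0.1
  # rectangular 100 pA x 10 ms: charge 1 pC
  v <- c(rep(0, 100), rep(100, 100), rep(0, 400))
  tr <- trace(v, dt = dt, unit = "pA")
  m <- measure_event(tr, onset = 10)
  expect_equal(m$amplitude_pA, 100, tolerance = 0.01)
  expect_equal(m$charge_pC, 1, tolerance = 0.01)
  # single-exponential decay, A = 100 pA, tau = 15 ms: charge ~ 1.5 pC
  tt <- seq(0, 150, by = dt)
  v2 <- c(rep(0, 100), 100 * exp(-tt / 15))
  tr2 <- trace(v2, dt = dt, unit = "pA")
  m2 <- measure_event(tr2, onset = 10, max_integrate_ms = 150)
  expect_equal(m2$decay_tau_ms, 15, tolerance = 0.02)
  expect_equal(m2$charge_pC, 1.5, tolerance = 0.02)
  expect_true(m2$decay_fit_ok)
})

test_that("biexponential amplitude matches the analytic peak within 1%", {
  dt <- 0.02
  tau_r <- 1; tau_d <- 15; A <- 80
  tt <- seq(0, 200, by = dt)
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  peak <- exp(-tp / tau_d) - exp(-tp / tau_r)
  v <- c(rep(0, 500), A / peak * (exp(-tt / tau_d) - exp(-tt / tau_r)))
  tr <- trace(v, dt = dt, unit = "pA")
  m <- measure_event(tr, onset = 10)
  expect_equal(m$amplitude_pA, A, tolerance = 0.01)
  expect_gt(m$rise_time_10_90_ms, 0)
  expect_equal(m$decay_tau_ms, tau_d, tolerance = 0.1)
})

test_that("rising slope: linear case, sampling invariance, dense-grid oracle", {
  mk <- function(dt) {
    tt <- seq(dt, 2, by = dt)
    trace(c(rep(0, round(5 / dt)), tt * 50, rep(100, round(20 / dt))),
          dt = dt, unit = "pA")
  }
  expect_equal(rising_slope(mk(0.1), onset = 5), 50, tolerance = 0.01)
  # doubling the sampling rate leaves the slope unchanged within 1%
  expect_equal(rising_slope(mk(0.05), onset = 5), rising_slope(mk(0.1), 5),
               tolerance = 0.01)
  # biexponential: compare against the 10-90% least-squares slope computed
  # on a 50x denser grid
  tau_r <- 1.2; tau_d <- 18
  f <- function(t) {
    tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
    pk <- exp(-tp / tau_d) - exp(-tp / tau_r)
    100 / pk * ifelse(t < 0, 0, exp(-t / tau_d) - exp(-t / tau_r))
  }
  dt <- 0.05
  tr <- trace(f(seq(-5, 50, by = dt)), dt = dt, unit = "pA", t0 = -5)
  got <- rising_slope(tr, onset = 0)
  td <- seq(0, 10, by = dt / 50)
  vd <- f(td)
  pk_v <- max(vd)
  sel <- vd >= 0.1 * pk_v & vd <= 0.9 * pk_v & td < td[which.max(vd)]
  oracle <- unname(coef(lm(vd[sel] ~ td[sel]))[2])
  expect_equal(got, oracle, tolerance = 0.02)
  # too-coarse sampling is a clear error
  tr_coarse <- trace(c(0, 0, 100, 100, 100, 100), dt = 2, unit = "pA")
  expect_error(rising_slope(tr_coarse, onset = 2), "dt")
})

test_that("event averaging reduces noise like 1/sqrt(n) and is exact without noise", {
  dt <- 0.1
  wf <- c(rep(0, 50), 60 * (exp(-seq(0, 40, by = dt) / 12) -
                            exp(-seq(0, 40, by = dt) / 1)))
  n_ev <- 25
  onsets <- seq(100, by = 100, length.out = n_ev)
  n <- round((max(onsets) + 100) / dt)
  clean <- numeric(n)
  for (o in onsets) {
    i0 <- round(o / dt) + 1 - 50
    clean[i0:(i0 + length(wf) - 1)] <- clean[i0:(i0 + length(wf) - 1)] + wf
  }
  # exact recovery without noise
  tr0 <- trace(clean, dt = dt, unit = "pA")
  av0 <- average_events(tr0, onsets, pre_ms = 5, post_ms = 40)
  expect_equal(av0$n_used, n_ev)
  expect_lt(max(abs(av0$average$samples - wf[1:length(av0$average$samples)])), 1e-9)
  # with noise: residual shrinks like sigma/sqrt(n)
  set.seed(21)
  sigma <- 4
  tr1 <- trace(clean + rnorm(n, 0, sigma), dt = dt, unit = "pA")
  av1 <- average_events(tr1, onsets, pre_ms = 5, post_ms = 40)
  resid <- av1$average$samples - wf[1:length(av1$average$samples)]
  expect_lt(sd(resid), 2 * sigma / sqrt(n_ev))
  expect_error(average_events(tr1, onsets[1]), ">= 2")
  # out-of-bounds windows are dropped and counted
  av2 <- average_events(tr1, c(2, onsets), pre_ms = 5, post_ms = 40)
  expect_equal(av2$n_dropped, 1)
})

test_that("event detection recovers generator ground truth", {
  sc <- synaptic_scenario(rate_hz = 5, duration_s = 60, noise_sd = 2,
                          seed = 7)
  rec <- generate_ipsc_recording(sc)
  on <- detect_events(rec$trace)
  hit <- vapply(rec$truth$onset_ms, function(o) any(abs(on - o) < 5),
                logical(1))
  expect_gte(mean(hit), 0.95)
  st <- event_train_stats(rec$trace, onsets = on)
  expect_equal(st$frequency_Hz, 5, tolerance = 0.1)
  expect_equal(st$mean_amplitude_pA, mean(rec$truth$amplitude_pA),
               tolerance = 0.05)
  # flat noise-free trace: nothing detected
  expect_length(detect_events(trace(rep(0, 5000), dt = 0.1, unit = "pA")), 0)
})

test_that("two events closer than the merge window are one detection", {
  dt <- 0.1
  wf <- 50 * (exp(-seq(0, 60, by = dt) / 10) - exp(-seq(0, 60, by = dt) / 0.8))
  wf <- wf / max(wf) * 50
  v <- numeric(3000)
  for (o in c(100, 104)) {  # 4 ms apart
    i0 <- round(o / dt) + 1
    v[i0:(i0 + length(wf) - 1)] <- v[i0:(i0 + length(wf) - 1)] + wf
  }
  tr <- trace(v, dt = dt, unit = "pA")
  expect_length(detect_events(tr, noise_sd = 1, merge_ms = 5), 1)
})

test_that("charge is additive for non-overlapping events", {
  dt <- 0.1
  wf <- 60 * (exp(-seq(0, 80, by = dt) / 12) - exp(-seq(0, 80, by = dt) / 1))
  v <- numeric(6000)
  for (o in c(100, 400)) {
    i0 <- round(o / dt) + 1
    v[i0:(i0 + length(wf) - 1)] <- v[i0:(i0 + length(wf) - 1)] + wf
  }
  tr <- trace(v, dt = dt, unit = "pA")
  c1 <- measure_event(tr, 100, max_integrate_ms = 150)$charge_pC
  c2 <- measure_event(tr, 400, max_integrate_ms = 150)$charge_pC
  # the same two waveforms in isolation
  tr1 <- trace(c(numeric(1000), wf, numeric(1000)), dt = dt, unit = "pA")
  c_single <- measure_event(tr1, 100, max_integrate_ms = 150)$charge_pC
  expect_equal(c1 + c2, 2 * c_single, tolerance = 0.01)
})

test_that("train analysis: constants, ratios, and agreement with measure_event", {
  sc <- synaptic_scenario(U = 0.5, tau_rec = 200, tau_fac = 0, noise_sd = 0,
                          seed = 1)
  # constant amplitudes -> normalized 1, ppr 1
  ev_c <- generate_evoked_train(synaptic_scenario(U = 1, tau_rec = 1e-6,
                                                  noise_sd = 0, seed = 1),
                                c(0, 100, 200))
  ta_c <- train_analysis(ev_c$trace, c(0, 100, 200))
  expect_equal(ta_c$normalized, c(1, 1, 1), tolerance = 1e-3)
  expect_equal(ta_c$ppr, 1, tolerance = 1e-3)
  # explicit amplitudes 100 then 150 -> ppr 1.5
  dt <- 0.1
  wf <- exp(-seq(0, 60, by = dt) / 12) - exp(-seq(0, 60, by = dt) / 1)
  wf <- wf / max(wf)
  v <- numeric(4000)
  for (k in 1:2) {
    i0 <- round(c(50, 150)[k] / dt) + 1
    v[i0:(i0 + length(wf) - 1)] <- v[i0:(i0 + length(wf) - 1)] +
      c(100, 150)[k] * wf
  }
  tr <- trace(v, dt = dt, unit = "pA")
  expect_equal(train_analysis(tr, c(50, 150))$ppr, 1.5, tolerance = 0.01)
  # ppr equals the measure_event amplitude ratio on a clean two-pulse trace
  ev <- generate_evoked_train(sc, c(0, 100))
  ta <- train_analysis(ev$trace, c(0, 100))
  m1 <- measure_event(ev$trace, 0, next_onset = 100)
  m2 <- measure_event(ev$trace, 100)
  expect_equal(ta$ppr, m2$amplitude_pA / m1$amplitude_pA, tolerance = 2e-3)
  expect_error(train_analysis(ev$trace, 50), ">= 2")
  expect_error(train_analysis(ev$trace, c(100, 50)), "increasing")
})

test_that("paired-pulse depression matches the closed-form recursion within 1%", {
  # U = 0.5, tau_rec = 200 ms, dt = 100 ms:
  # R2 = 1 - (1 - R1(1-U)) exp(-100/200) = 0.6967
  sc <- synaptic_scenario(U = 0.5, tau_rec = 200, tau_fac = 0, noise_sd = 0,
                          seed = 1)
  ev <- generate_evoked_train(sc, c(0, 100))
  ta <- train_analysis(ev$trace, c(0, 100))
  r2 <- 1 - (1 - 1 * (1 - 0.5)) * exp(-100 / 200)
  expect_equal(ta$ppr, r2, tolerance = 0.01)
  expect_equal(tm_relative_amplitudes(c(0, 100), 0.5, 200)[2], r2,
               tolerance = 1e-12)
})

test_that("event train statistics definitions", {
  v <- numeric(600001)  # 60 s at 0.1 ms
  on <- seq(100, 59000, length.out = 300)
  for (o in on) {
    i0 <- round(o / 0.1) + 1
    v[i0:(i0 + 50)] <- v[i0:(i0 + 50)] + 40
  }
  tr <- trace(v, dt = 0.1, unit = "pA")
  st <- event_train_stats(tr, onsets = on)
  expect_equal(st$frequency_Hz, 5)
  st0 <- event_train_stats(tr, onsets = numeric(0))
  expect_equal(st0$frequency_Hz, 0)
  expect_true(is.na(st0$mean_amplitude_pA))
})
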