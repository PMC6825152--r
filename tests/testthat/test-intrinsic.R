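test_that("RMP recovers the baseline mean", {
  # constant trace
  s <- sweep_set("c", list(sweep_rec(trace(rep(-65, 10001), dt = 0.1),
                                     stimulus_step(100, 500, 400))))
  expect_equal(compute_rmp(s), -65)
  # noisy baseline: matches the mean of the very samples that were generated
  set.seed(11)
  v <- c(rnorm(5000, -70, 0.2), rep(-50, 5001))
  s2 <- sweep_set("c", list(sweep_rec(trace(v, dt = 0.1),
                                      stimulus_step(100, 500, 400))))
  expect_equal(compute_rmp(s2, c(0, 500)), mean(v[1:5000]), tolerance = 1e-3)
  expect_lt(abs(compute_rmp(s2, c(0, 500)) + 70), 0.05)
  expect_error(compute_rmp(s2, c(0, 0)), "empty")
})

test_that("input resistance matches the RC closed form within 1%", {
  s <- rc_sweep_set(R_MOhm = 150, tau_ms = 20)
  expect_equal(input_resistance(s), 150, tolerance = 0.01)
  # ideal ohmic cell, instantaneous settling
  s2 <- rc_sweep_set(R_MOhm = 100, tau_ms = 1e-6)
  expect_equal(input_resistance(s2), 100, tolerance = 1e-6)
  # flat responses -> 0 MOhm
  flat <- sweep_set("f", lapply(c(-50, -25, 25), function(a)
    sweep_rec(trace(rep(-65, 5001), dt = 0.2), stimulus_step(a, 100, 800))))
  expect_equal(input_resistance(flat), 0)
  # fewer than 3 usable sweeps
  expect_error(input_resistance(sweep_set("g", list(
    sweep_rec(trace(rep(-65, 5001), dt = 0.2), stimulus_step(-50, 100, 800)),
    sweep_rec(trace(rep(-64, 5001), dt = 0.2), stimulus_step(-25, 100, 800))
  ))), ">= 3")
})

test_that("spike detection finds peaks at known times and ignores subthreshold traces", {
  dt <- 0.01
  one_ap <- function(at_ms, total = 400) {
    v <- rep(-65, round(total / dt) + 1)
    i0 <- round(at_ms / dt) + 1
    shape <- c(seq(-65, 30, length.out = 41), seq(30, -65, length.out = 41)[-1])
    v[(i0 - 40):(i0 + 40)] <- shape
    v
  }
  v <- rep(-65, 40001)
  for (at in c(100, 200, 300)) {
    w <- one_ap(at)
    v <- pmax(v, w)
  }
  tr <- trace(v, dt = dt, unit = "mV")
  expect_equal(detect_spikes(tr), c(100, 200, 300))
  expect_length(detect_spikes(trace(rep(-65, 1000) + sin(1:1000 / 50),
                                    dt = 0.1)), 0)
})

test_that("spike detection agrees with a brute-force oracle on simulator output", {
  m <- tiny_model()
  sw <- run_current_step(m, 300, sim_protocol(step_currents = 300,
                                              step_duration = 500))
  got <- detect_spikes(sw$trace)
  oracle <- brute_spikes(sw$trace)
  expect_equal(length(got), length(oracle))
  expect_lt(max(abs(got - oracle)), 0.3)
  # count is invariant to 0.2 mV Gaussian noise
  set.seed(5)
  noisy <- sw$trace
  noisy$samples <- noisy$samples + rnorm(length(noisy$samples), 0, 0.2)
  expect_equal(length(detect_spikes(noisy)), length(got))
})

test_that("firing curve, frequency and rheobase follow spike counts", {
  dt <- 0.05
  mk_sweep <- function(amp, n_spikes) {
    v <- rep(-65, round(1000 / dt) + 1)
    if (n_spikes > 0) {
      at <- seq(150, 850, length.out = n_spikes)
      for (a in at) {
        i0 <- round(a / dt) + 1
        v[i0:(i0 + 8)] <- c(seq(-65, 30, length.out = 5),
                            seq(30, -65, length.out = 5)[-1])
      }
    }
    sweep_rec(trace(v, dt = dt), stimulus_step(amp, 100, 800))
  }
  s <- sweep_set("c", list(mk_sweep(25, 0), mk_sweep(50, 0), mk_sweep(75, 2),
                           mk_sweep(100, 10), mk_sweep(200, 44),
                           mk_sweep(300, 30)))
  fc <- firing_curve(s)
  expect_equal(fc$n_spikes, c(0, 0, 2, 10, 44, 30))
  expect_equal(fc$frequency_Hz[fc$amplitude_pA == 200], 55)  # 44 / 0.8 s
  expect_equal(max_firing_frequency(s), 55)
  expect_equal(rheobase(s), 75)
  none <- sweep_set("n", list(mk_sweep(100, 0), mk_sweep(200, 0)))
  expect_error(rheobase(none), "rheobase undefined")
})

test_that("AP features match triangle geometry", {
  # triangle from -40 to +30 over 0.6 ms: amplitude 70, half-width 0.6
  tr <- triangle_ap_trace(base = -40, peak = 30, rise_ms = 0.6,
                          dip = -55, dip_ms = 4)
  pk <- detect_spikes(tr)
  expect_length(pk, 1)
  f <- measure_ap(tr, pk[1])
  expect_equal(f$amplitude, 70, tolerance = 0.01)
  expect_equal(f$half_width, 0.6, tolerance = 0.02)
  expect_equal(f$threshold_v, -40, tolerance = 0.5)
  # fAHP from threshold to post-spike minimum: -40 - (-55) = 15
  expect_equal(f$fahp, 15, tolerance = 0.5)
  expect_equal(f$max_dvdt, 70 / 0.6, tolerance = 0.05)
})

test_that("threshold agrees with a dense finite-difference d3 oracle on a sigmoid upstroke", {
  # smooth AP built from a sigmoidal upstroke and a slower sigmoidal
  # repolarization (max slope < 20 mV/ms so no upstroke cap applies);
  # oracle = third-derivative maximum on a 100x denser grid over the same
  # pre-peak window
  base <- -60; A <- 45
  f <- function(t) base + A * (1 / (1 + exp(-(t - 10) / 0.7)) -
                               1 / (1 + exp(-(t - 16) / 2.0)))
  dt <- 0.025
  tt <- seq(0, 30, by = dt)
  tr <- trace(f(tt), dt = dt, unit = "mV")
  pk_time <- tt[which.max(tr$samples)]
  got <- measure_ap(tr, pk_time, search_pre_ms = 12)
  td <- seq(pk_time - 12, pk_time, by = dt / 100)
  vd <- f(td)
  d3 <- diff(vd, differences = 3)
  oracle_v <- vd[1 + which.max(d3)]
  expect_lt(abs(got$threshold_v - oracle_v), 0.5)
})

test_that("SFA and CV definitions", {
  expect_equal(sfa(c(0, 10, 20, 30)), 1.0)
  expect_equal(sfa(c(0, 10, 25, 55)), 3.0)
  expect_error(sfa(c(0, 10)), "SFA undefined")
  expect_equal(cv_ratio(rep(12, 5)), 0)
  expect_equal(cv_ratio(c(1, 3)), sqrt(2) / 2, tolerance = 1e-10)
  expect_error(cv_ratio(5), ">= 2")
  expect_error(cv_ratio(c(-1, 1)), "mean is zero")
  # Poisson-process property: exponential ISIs have CV ~ 1
  set.seed(3)
  expect_equal(cv_ratio(rexp(1000, 1 / 20)), 1, tolerance = 0.1)
})

test_that("sag ratio is 1 for a pure RC response and < 1 with an h-conductance", {
  s <- rc_sweep_set(R_MOhm = 150, tau_ms = 20)
  sr <- sag_rebound(s)
  expect_equal(sr$sag_ratio, 1, tolerance = 0.01)
  expect_lt(abs(sr$rebound_mV), 0.5)
  # arithmetic case: V_min -80, V_ss -75, baseline -65 ->
  # steady-state deflection / peak deflection = 10 / 15
  dt <- 0.1
  v <- c(rep(-65, 1000), seq(-65, -80, length.out = 500),
         seq(-80, -75, length.out = 1500), rep(-75, 6000),
         rep(-65, 1001))
  s2 <- sweep_set("c", list(sweep_rec(trace(v, dt = dt),
                                      stimulus_step(-50, 100, 800))))
  expect_equal(sag_rebound(s2)$sag_ratio, 2 / 3, tolerance = 0.01)
  # simulator with an h-conductance shows sag
  reg <- channel_registry()
  ch <- reg[c("na_t", "kdr", "h")]
  ch$na_t$gbar <- 0.15; ch$kdr$gbar <- 0.004; ch$h$gbar <- 3e-4
  mh <- neuron_model(ch, area = 1e-5, g_leak = 5e-4, e_leak = -67,
                     v_init = -70, name = "h")
  sh <- run_protocol(mh, sim_protocol(step_currents = -50,
                                      step_duration = 800, settle = 2000))
  expect_lt(sag_rebound(sh)$sag_ratio, 0.98)
  expect_error(sag_rebound(rc_sweep_set(amps = c(10, 20, 30))), "hyperpolarizing")
})

test_that("feature extraction is deterministic", {
  m <- tiny_model()
  p <- sim_protocol(step_currents = c(-50, 100, 150, 200),
                    step_duration = 500)
  s <- run_protocol(m, p)
  p1 <- profile_row(intrinsic_profile(s))
  p2 <- profile_row(intrinsic_profile(s))
  expect_identical(p1, p2)
})
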