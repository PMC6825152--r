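test_that("zero current settles to a fixed point independent of initial voltage", {
  for (v0 in c(-90, -70, -40)) {
    m <- tiny_model()
    m$v_init <- v0
    sw <- run_current_step(m, 0, sim_protocol(step_currents = 0,
                                              step_duration = 200,
                                              settle = 1500, tail = 0))
    v <- sw$trace$samples
    n <- length(v)
    # terminal |dV/dt| < 0.01 mV/ms
    expect_lt(abs(v[n] - v[n - 1]) / sw$trace$dt, 0.01)
    if (v0 == -90) v_ref <- v[n] else expect_equal(v[n], v_ref,
                                                   tolerance = 1e-3)
  }
})

test_that("a passive membrane obeys the RC closed form within 1%", {
  reg <- channel_registry()
  ch <- reg["kv31"]
  ch$kv31$gbar <- 0  # all active conductances off
  m <- neuron_model(ch, area = 1e-5, g_leak = 5e-4, e_leak = -65,
                    v_init = -65, name = "passive")
  # R = 1 / (g_leak * area) = 1 / (5e-4 * 1e-5) S = 200 MOhm
  sw <- run_current_step(m, 100, sim_protocol(step_currents = 100,
                                              step_duration = 800))
  st <- sw$stimulus
  v_ss <- mean(trace_window(sw$trace, st$onset + 600, st$onset + 800))
  expect_equal(v_ss - (-65), 100 * 200 / 1000, tolerance = 0.01)
})

test_that("spike counts converge: halving dt leaves them unchanged", {
  m <- tiny_model()
  for (I in c(150, 300)) {
    s1 <- run_current_step(m, I, sim_protocol(dt = 0.025, step_currents = I,
                                              step_duration = 500))
    s2 <- run_current_step(m, I, sim_protocol(dt = 0.0125, step_currents = I,
                                              step_duration = 500))
    n1 <- length(detect_spikes(s1$trace))
    n2 <- length(detect_spikes(s2$trace))
    expect_equal(n1, n2)
  }
})

test_that("spike times agree with a half-step reference within 0.5 ms per spike", {
  m <- tiny_model()
  s1 <- run_current_step(m, 250, sim_protocol(dt = 0.025, step_currents = 250,
                                              step_duration = 500))
  s2 <- run_current_step(m, 250, sim_protocol(dt = 0.0125,
                                              step_currents = 250,
                                              step_duration = 500))
  t1 <- detect_spikes(s1$trace)
  t2 <- detect_spikes(s2$trace)
  expect_equal(length(t1), length(t2))
  expect_lt(max(abs(t1 - t2)), 0.5)
})

test_that("instantaneous frequency is 1000/ISI", {
  expect_equal(instantaneous_frequency(c(0, 20, 40, 60)), rep(50, 3))
  expect_equal(instantaneous_frequency(c(0, 10, 30)), c(100, 50))
  expect_error(instantaneous_frequency(5), ">= 2")
  # regular-spiking model output adapts: instantaneous frequency decreases
  m <- tiny_model()
  sw <- run_current_step(m, 250, sim_protocol(step_currents = 250))
  sp <- detect_spikes(sw$trace)
  fr <- instantaneous_frequency(sp)
  expect_gt(fr[1], fr[length(fr)])
})

test_that("repeating a conductance value reproduces identical profiles", {
  m <- tiny_model()
  p <- sim_protocol(step_currents = c(100, 200), step_duration = 400)
  tab <- kv31_sweep(m, c(0.05, 0.05), p)
  expect_identical(tab[1, -1], structure(tab[2, -1], row.names = 1L))
})

test_that("raising the Kv3.1 density reproduces the fast-spiking sign pattern", {
  m <- rs_models()[["rs_a"]]
  p <- sim_protocol(step_currents = seq(50, 350, by = 100))
  tab <- kv31_sweep(m, c(m$channels$kv31$gbar, 1.5), p)
  expect_gt(tab$max_freq_Hz[2], tab$max_freq_Hz[1])
  expect_lt(tab$sfa[2], tab$sfa[1])
  expect_lt(tab$half_width_ms[2], tab$half_width_ms[1])
  expect_gt(tab$fahp_mV[2], tab$fahp_mV[1])
  expect_equal(tab$label, c("RS", "FS"))
})

test_that("fAHP is monotone non-decreasing along a Kv3.1 density grid", {
  m <- rs_models()[["rs_a"]]
  p <- sim_protocol(step_currents = seq(50, 350, by = 50),
                    step_duration = 1000)
  tab <- kv31_sweep(m, c(0.1, 0.45, 0.8, 1.15, 1.5), p)
  expect_true(all(diff(tab$fahp_mV) > -0.5))
})

test_that("model configurations round-trip through YAML", {
  ms <- rs_models()
  f <- tempfile(fileext = ".yaml")
  write_model_config(ms, f)
  ms2 <- rs_models(f)
  expect_equal(names(ms2), names(ms))
  expect_equal(ms2$rs_b$channels$kv31$gbar, ms$rs_b$channels$kv31$gbar)
  expect_equal(ms2$rs_c$g_leak, ms$rs_c$g_leak)
  unlink(f)
})

test_that("invalid channel and model parameters are rejected", {
  reg <- channel_registry()
  expect_error(channel_spec("bad", -1, -90, reg$kv31$gates), ">= 0")
  expect_error(neuron_model(reg["kv31"], cm = 0), "capacitance")
  m <- tiny_model()
  expect_error(set_gbar(m, "nope", 0.1), "no channel")
  expect_error(kv31_sweep(neuron_model(reg["kdr"], name = "x"), 1,
                          sim_protocol()), "kv31")
})
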