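#!/usr/bin/env Rscript
# Inhibitory synaptic transmission experiment on synthetic recordings:
# (i) spontaneous IPSC detection and kinetics at known generative
#     parameters;
# (ii) evoked paired pulses and 20 Hz trains under two release-probability
#      regimes (high U = control-like, low U = mutant-like), where the
#      Tsodyks-Markram recursion provides the exact expected paired-pulse
#      ratio and train attenuation.
#
# Writes results/sipsc_stats.csv, results/ppr.csv and
# results/train_attenuation.csv.

suppressPackageStartupMessages(library(cinphys))
dir.create("results", showWarnings = FALSE)

## spontaneous recordings ------------------------------------------------------
scenarios <- list(
  control = synaptic_scenario(rate_hz = 8, amp_meanlog = log(45),
                              duration_s = 60, noise_sd = 2, seed = 501),
  mutant  = synaptic_scenario(rate_hz = 4, amp_meanlog = log(32),
                              duration_s = 60, noise_sd = 2, seed = 502))
rows <- list()
for (g in names(scenarios)) {
  sc <- scenarios[[g]]
  rec <- generate_ipsc_recording(sc)
  tab <- synaptic_table(list(rec$trace))
  tab$group <- g
  tab$true_rate_Hz <- sc$rate_hz
  tab$true_mean_amp_pA <- exp(sc$amp_meanlog + sc$amp_sdlog^2 / 2)
  rows[[g]] <- tab
  cat(sprintf("%s sIPSC: %.2f Hz (true %.0f), %.1f pA (true %.1f), tau %.1f ms (true %.0f)\n",
              g, tab$frequency_Hz, sc$rate_hz, tab$mean_amplitude_pA,
              tab$true_mean_amp_pA, tab$median_decay_tau_ms, sc$tau_decay))
}
write.csv(do.call(rbind, rows), "results/sipsc_stats.csv", row.names = FALSE)

## evoked: paired pulses and 20 Hz trains --------------------------------------
U_by_group <- c(control = 0.6, mutant = 0.3)
ppr_rows <- list(); train_rows <- list()
for (g in names(U_by_group)) {
  U <- U_by_group[[g]]
  sc <- synaptic_scenario(U = U, tau_rec = 200, tau_fac = 0, noise_sd = 1,
                          seed = 600 + round(100 * U))
  for (ipi in c(50, 100)) {
    ev <- generate_evoked_train(sc, c(0, ipi))
    ta <- train_analysis(ev$trace, c(0, ipi))
    ppr_rows[[paste(g, ipi)]] <- data.frame(
      group = g, U = U, inter_pulse_ms = ipi, ppr = ta$ppr,
      ppr_expected = tm_relative_amplitudes(c(0, ipi), U, 200)[2])
  }
  pulses <- seq(0, 450, by = 50)  # 10 pulses at 20 Hz
  ev <- generate_evoked_train(sc, pulses)
  ta <- train_analysis(ev$trace, pulses)
  train_rows[[g]] <- data.frame(group = g, U = U, pulse = seq_along(pulses),
                                normalized = ta$normalized,
                                expected = tm_relative_amplitudes(pulses, U, 200))
}
ppr <- do.call(rbind, ppr_rows)
write.csv(ppr, "results/ppr.csv", row.names = FALSE)
tr <- do.call(rbind, train_rows)
write.csv(tr, "results/train_attenuation.csv", row.names = FALSE)

cat("\nPaired-pulse ratios (measured vs Tsodyks-Markram closed form):\n")
print(ppr, row.names = FALSE)
cat(sprintf("\nSteady-state 20 Hz attenuation: control %.2f, mutant %.2f.\n",
            tail(tr$normalized[tr$group == "control"], 1),
            tail(tr$normalized[tr$group == "mutant"], 1)))
cat("Lowering the release-probability parameter raises the paired-pulse\n",
    "ratio and softens train depression - the signature used to infer a\n",
    "presynaptic release deficit.\n")
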