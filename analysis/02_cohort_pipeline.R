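#!/usr/bin/env Rscript
# Synthetic cohort experiment: two simulated genotypes differing only in the
# fraction of cells drawn from the fast-spiking class (a control-like cohort
# with a small FS fraction, and a mutant-like cohort in which ~30% of
# somatostatin-lineage cells have switched to FS properties). Every cell is
# run through the same intrinsic-feature extraction and four-criterion
# classification used for analytic waveforms, and the recovered FS fractions
# are compared with the generative truth.
#
# Writes results/cohort_profiles.csv and results/cohort_summary.csv, and one
# example cell in the native on-disk sweep dialect under
# results/example_cell/.

suppressPackageStartupMessages(library(cinphys))
dir.create("results", showWarnings = FALSE)

groups <- list(control = list(fs = 0.05, seed = 401),
               mutant = list(fs = 0.30, seed = 402))
n_per_group <- 40

all_tabs <- list()
for (g in names(groups)) {
  spec <- cohort_spec(n_cells = n_per_group, fs_fraction = groups[[g]]$fs,
                      seed = groups[[g]]$seed)
  co <- generate_cohort(spec)
  tab <- extract_profiles(co)
  tab$group <- g
  tab$true_class <- co$truth$true_class
  all_tabs[[g]] <- tab
  cat(sprintf("%s cohort (n=%d, generative FS fraction %.2f): %d FS, %d RS recovered\n",
              g, n_per_group, groups[[g]]$fs,
              sum(tab$label == "FS"), sum(tab$label == "RS")))
  if (g == "control")
    write_sweep_set(co$cells[[1]], "results/example_cell")
}
prof <- do.call(rbind, all_tabs)
write.csv(prof, "results/cohort_profiles.csv", row.names = FALSE)

cls <- lapply(prof$label, function(l) structure(list(label = l),
                                                class = "phys_class"))
summ <- cohort_summary(cls, prof$group)
write.csv(summ, "results/cohort_summary.csv", row.names = FALSE)
print(summ, row.names = FALSE)

acc <- mean(prof$label == prof$true_class, na.rm = TRUE)
cat(sprintf("\nPer-cell agreement between generative class and pipeline label: %.1f%%\n",
            100 * acc))
cat("Mutant-like cells also show the expected shifts in rheobase and input\n",
    "resistance that accompany the added Kv3.1 conductance load:\n")
agg <- aggregate(cbind(r_in_MOhm, rheobase_pA, max_freq_Hz) ~ group + label,
                 prof, median)
print(agg, row.names = FALSE)
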