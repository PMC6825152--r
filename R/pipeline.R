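#' Pipeline configuration
#'
#' One serializable object holding every analysis knob: spike-detection
#' criterion, AP-feature windows, classifier thresholds, event-detector
#' settings and the simulation protocol. Unknown keys are rejected by name.
#'
#' @param ... overrides of the defaults (see [pipeline_defaults()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Default pipeline configuration values
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    dvdt_threshold = 20,     # spike upstroke criterion, mV/ms
    min_isi = 1,             # spike merge window, ms
    ap_delta_pA = 50,        # AP-feature sweep: rheobase + this
    ap_search_pre_ms = 3,    # threshold search window before peak, ms
    ap_fahp_window_ms = 10,  # fAHP trough search window, ms
    ap_smooth_ms = 0.5,      # Savitzky-Golay window for d3V/dt3, ms
    sfa_min_spikes = 10,     # SFA/CV sweep: lowest amplitude with >= this
    rin_steady_frac = 0.25,  # steady-state window, fraction of step
    classifier = fs_thresholds(),
    det_k = 4,               # event detector threshold, noise SDs
    det_merge_ms = 5,        # event merge window, ms
    seed = 1
  )
}

#' Write a configuration next to results
#' @param cfg a `pipeline_config`.
#' @param path output YAML file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Extract intrinsic profiles and classifications for a cohort
#'
#' Runs [intrinsic_profile()] and [classify_phys()] on every cell of a
#' generated cohort (or a list of `sweep_set`s, or a directory of sweep sets
#' in the native dialect). Per-cell failures are recorded and the run
#' continues.
#'
#' @param x a `cohort`, a list of `sweep_set`, or a directory path whose
#'   subdirectories are sweep sets.
#' @param cfg a `pipeline_config`.
#' @return Data frame: one row per cell ([profile_row()] columns plus
#'   `label` and per-criterion booleans); failed cells get `label`
#'   `"failed"` and an `error` message.
#' @export
extract_profiles <- function(x, cfg = pipeline_config()) {
  cells <- if (inherits(x, "cohort")) x$cells
    else if (is.character(x) && length(x) == 1L) {
      if (!dir.exists(x)) stop("no readable inputs: ", x, " is not a directory")
      dirs <- list.dirs(x, recursive = FALSE)
      if (length(dirs) == 0L) stop("no readable inputs under ", x)
      lapply(dirs, function(d)
        tryCatch(read_sweep_set(d), error = function(e) e$message))
    } else x
  if (length(cells) == 0L) stop("no readable inputs")
  rows <- lapply(seq_along(cells), function(i) {
    s <- cells[[i]]
    if (!inherits(s, "sweep_set"))
      return(data.frame(cell_id = sprintf("input_%03d", i), label = "failed",
                        error = as.character(s), stringsAsFactors = FALSE))
    res <- tryCatch({
      prof <- intrinsic_profile(
        s, min_spikes = cfg$sfa_min_spikes,
        delta_pA = cfg$ap_delta_pA, search_pre_ms = cfg$ap_search_pre_ms,
        fahp_window_ms = cfg$ap_fahp_window_ms, smooth_ms = cfg$ap_smooth_ms,
        dvdt_threshold = cfg$dvdt_threshold, min_isi = cfg$min_isi)
      cls <- classify_phys(prof, cfg$classifier)
      row <- profile_row(prof)
      row$label <- cls$label
      row$error <- NA_character_
      row
    }, error = function(e)
      data.frame(cell_id = s$cell_id, label = "failed",
                 error = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  do.call(rbind, rows)
}

#' Spontaneous-recording analysis table
#'
#' Detects events on each recording and summarizes frequency, amplitude and
#' kinetics of the averaged event.
#'
#' @param traces list of current `trace`s.
#' @param cfg a `pipeline_config`.
#' @return Data frame: `recording`, `n_events`, `frequency_Hz`,
#'   `mean_amplitude_pA`, `median_decay_tau_ms` (the median is robust to the
#'   occasional distorted fit on overlapping events).
#' @export
synaptic_table <- function(traces, cfg = pipeline_config()) {
  rows <- lapply(seq_along(traces), function(i) {
    t <- traces[[i]]
    on <- detect_events(t, k = cfg$det_k, merge_ms = cfg$det_merge_ms)
    st <- event_train_stats(t, onsets = on)
    nxt <- c(on[-1], NA_real_)
    taus <- vapply(seq_along(on), function(j)
      tryCatch(measure_event(t, on[j], next_onset = nxt[j])$decay_tau_ms,
               error = function(e) NA_real_),
      numeric(1))
    data.frame(recording = i, n_events = st$n_events,
               frequency_Hz = st$frequency_Hz,
               mean_amplitude_pA = st$mean_amplitude_pA,
               median_decay_tau_ms = stats::median(taus, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
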