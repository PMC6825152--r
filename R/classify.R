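#' Default fast-spiking classification thresholds
#'
#' A cell is fast-spiking when all four hold (strict inequalities):
#' AP half-width < 0.5 ms, maximum firing frequency > 50 Hz, fAHP amplitude
#' > 14 mV, and spike-frequency accommodation < 2.
#'
#' @return Named list `half_width_ms`, `max_freq_Hz`, `fahp_mV`, `sfa`.
#' @export
fs_thresholds <- function() {
  list(half_width_ms = 0.5, max_freq_Hz = 50, fahp_mV = 14, sfa = 2)
}

#' Classify a cell as fast-spiking or regular-spiking
#'
#' Applies the conjunctive rule: FS iff half-width < 0.5 ms AND maximum
#' firing frequency > 50 Hz AND fAHP > 14 mV AND SFA < 2, with strict
#' inequalities (a cell exactly at any boundary is RS). A cell missing any
#' required feature is `"unclassifiable"`, never silently RS.
#'
#' @param p an `intrinsic_profile`, or a list/one-row data frame with fields
#'   `half_width`/`ap_half_width_ms`, `max_freq`/`max_freq_Hz`,
#'   `fahp`/`fahp_mV`, `sfa`.
#' @param thresholds optional overrides, as from [fs_thresholds()].
#' @return List of class `phys_class`: `label` (`"FS"`, `"RS"` or
#'   `"unclassifiable"`), `criteria` (named logical vector) and
#'   `thresholds_used`.
#' @export
classify_phys <- function(p, thresholds = fs_thresholds()) {
  th <- utils::modifyList(fs_thresholds(), thresholds)
  get1 <- function(obj, keys) {
    for (k in keys) {
      v <- obj[[k]]
      if (!is.null(v) && length(v) == 1L) return(as.numeric(v))
    }
    NA_real_
  }
  if (inherits(p, "intrinsic_profile")) {
    hw <- if (is.null(p$ap)) NA_real_ else p$ap$half_width
    fa <- if (is.null(p$ap)) NA_real_ else p$ap$fahp
    mf <- p$max_freq
    sf <- p$sfa
  } else {
    hw <- get1(p, c("half_width", "ap_half_width_ms", "half_width_ms"))
    fa <- get1(p, c("fahp", "fahp_mV"))
    mf <- get1(p, c("max_freq", "max_freq_Hz"))
    sf <- get1(p, "sfa")
  }
  feats <- c(half_width = hw, max_freq = mf, fahp = fa, sfa = sf)
  if (anyNA(feats)) {
    return(structure(list(label = "unclassifiable",
                          criteria = is.na(feats) * NA,
                          thresholds_used = th),
                     class = "phys_class"))
  }
  crit <- c(
    half_width = hw < th$half_width_ms,
    max_freq   = mf > th$max_freq_Hz,
    fahp       = fa > th$fahp_mV,
    sfa        = sf < th$sfa
  )
  structure(list(label = if (all(crit)) "FS" else "RS",
                 criteria = crit, thresholds_used = th),
            class = "phys_class")
}

#' @export
print.phys_class <- function(x, ...) {
  cat("<phys_class>", x$label, "\n")
  if (!anyNA(x$criteria))
    cat("  criteria:", paste(names(x$criteria), x$criteria, sep = "=",
                             collapse = " "), "\n")
  invisible(x)
}

#' Cohort summary of FS/RS proportions per group
#'
#' @param classes list of `phys_class` objects (or character labels).
#' @param group_labels factor/character of the same length assigning each
#'   cell to a group.
#' @return Data frame with one row per group: `group`, `n_classified`,
#'   `n_fs`, `n_rs`, `n_unclassifiable`, `fs_fraction` (FS / classified).
#' @export
cohort_summary <- function(classes, group_labels = rep("all", length(classes))) {
  if (length(classes) == 0L) stop("empty cohort")
  if (length(group_labels) != length(classes))
    stop("group_labels must match classes in length")
  labels <- vapply(classes, function(x)
    if (inherits(x, "phys_class")) x$label else as.character(x), character(1))
  groups <- unique(as.character(group_labels))
  rows <- lapply(groups, function(g) {
    l <- labels[group_labels == g]
    if (length(l) == 0L) stop("empty group: ", g)
    n_fs <- sum(l == "FS"); n_rs <- sum(l == "RS")
    n_un <- sum(l == "unclassifiable")
    if (n_fs + n_rs == 0L) stop("no classified cell in group: ", g)
    data.frame(group = g, n_classified = n_fs + n_rs, n_fs = n_fs,
               n_rs = n_rs, n_unclassifiable = n_un,
               fs_fraction = n_fs / (n_fs + n_rs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
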