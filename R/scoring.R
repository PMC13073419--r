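#' Estimate the synchronization offset between two recordings
#'
#' Device clocks are aligned on the prominent artifact produced by a
#' standardized brisk arm maneuver at the start of the session: the offset is
#' the lag maximizing the normalized cross-correlation of the (demeaned)
#' vector-magnitude signals within the search window.
#'
#' @param rec A [triaxial_recording()] to align.
#' @param reference A [triaxial_recording()] (or a numeric magnitude/event
#'   channel at the same rate) serving as the time reference.
#' @param search_window_s Maximum absolute lag searched, in seconds.
#' @param min_peak Minimum acceptable peak correlation coefficient; below it a
#'   warning is raised and offset 0 returned.
#' @return Offset in seconds (positive when `rec` lags the reference, i.e.
#'   subtracting the offset from `rec`'s timeline aligns it), with attribute
#'   `peak_correlation`.
#' @export
estimate_sync_offset <- function(rec, reference, search_window_s = 30,
                                 min_peak = 0.5) {
  m1 <- if (inherits(rec, "triaxial_recording")) vector_magnitude(rec) else as.numeric(rec)
  rate <- if (inherits(rec, "triaxial_recording")) rec$rate else
    stop("rec must be a triaxial_recording")
  m2 <- if (inherits(reference, "triaxial_recording")) {
    if (abs(reference$rate - rate) > 1e-9) {
      reference <- resample_recording(reference, rate)
    }
    vector_magnitude(reference)
  } else as.numeric(reference)
  n <- min(length(m1), length(m2))
  m1 <- m1[seq_len(n)] - mean(m1[seq_len(n)])
  m2 <- m2[seq_len(n)] - mean(m2[seq_len(n)])
  maxlag <- min(n - 1, round(search_window_s * rate))
  lags <- -maxlag:maxlag
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      a <- m1[(k + 1):n]; b <- m2[1:(n - k)]
    } else {
      a <- m1[1:(n + k)]; b <- m2[(1 - k):n]
    }
    sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
    if (sa == 0 || sb == 0) return(0)
    sum(a * b) / (sa * sb)
  }, numeric(1))
  peak <- max(cc)
  if (peak < min_peak) {
    warning(sprintf(
      "no prominent synchronization artifact found (peak correlation %.2f < %.2f); using offset 0",
      peak, min_peak))
    return(structure(0, peak_correlation = peak))
  }
  structure(lags[which.max(cc)] / rate, peak_correlation = peak)
}

#' Score an EMG envelope into 3 s mini-epochs
#'
#' Rule-based binary scoring of REM motor activity from a rectified EMG
#' envelope. Within each REM period the atonia baseline is the lowest envelope
#' amplitude observed during that period, or, if lower, during the preceding
#' non-REM segment (by default the full interval since the previous REM period
#' or the recording start). A suprathreshold run -- envelope at least
#' `multiple` (2) times the atonia baseline -- is a phasic activity burst when
#' its duration lies in `[min_burst, max_burst]` seconds; a mini-epoch is
#' active when it overlaps at least one qualifying burst. Suprathreshold runs
#' longer than `max_burst` are not scored but are reported in the `sustained`
#' attribute ("sustained activity, unscored").
#'
#' @param env An [emg_envelope()] covering all periods (and, for the baseline
#'   look-back, the preceding NREM segments).
#' @param periods A `rem_periods` data.frame.
#' @param grid Optional [mini_epoch_grid()] (defaults to tiling `periods`).
#' @param multiple Threshold as a multiple of the atonia baseline (default 2).
#' @param min_burst,max_burst Qualifying burst duration bounds in seconds
#'   (defaults 0.1 and 5.0).
#' @param use_preceding_nrem Include the preceding non-REM segment in the
#'   atonia baseline search (default `TRUE`).
#' @return A [modality_labels()] (`modality = "emg"`, the envelope's side)
#'   with attributes `atonia` (per-period baselines) and `sustained`
#'   (data.frame of unscored suprathreshold runs > `max_burst`).
#' @export
score_emg_mini_epochs <- function(env, periods, grid = NULL, multiple = 2,
                                  min_burst = 0.1, max_burst = 5.0,
                                  use_preceding_nrem = TRUE) {
  if (is.null(grid)) grid <- mini_epoch_grid(periods)
  rate <- env$rate
  t0 <- env$start_time
  nsamp <- length(env$values)
  sample_idx <- function(a, b) {
    i0 <- floor((a - t0) * rate) + 1
    i1 <- ceiling((b - t0) * rate)
    i0 <- max(1L, i0); i1 <- min(nsamp, i1)
    if (i0 > i1) integer(0) else i0:i1
  }
  labels <- rep(FALSE, nrow(grid))
  atonia <- numeric(nrow(periods))
  sustained <- list()
  for (p in seq_len(nrow(periods))) {
    idx <- sample_idx(periods$start[p], periods$end[p])
    if (length(idx) == 0) stopf("EMG envelope does not cover REM period %d", p)
    base <- min(env$values[idx])
    if (use_preceding_nrem) {
      prev_end <- if (p == 1) t0 else periods$end[p - 1]
      pre <- sample_idx(prev_end, periods$start[p])
      if (length(pre) > 0) base <- min(base, min(env$values[pre]))
    }
    if (base <= 0) {
      stopf(paste0("atonia baseline is zero in REM period %d; the relative ",
                   "threshold is undefined -- supply an envelope floor"), p)
    }
    atonia[p] <- base
    runs <- logical_runs(env$values[idx] >= multiple * base)
    if (nrow(runs) == 0) next
    runs$dur <- runs$length / rate
    runs$t_start <- t0 + (idx[1] - 1 + runs$start - 1) / rate
    runs$t_end <- runs$t_start + runs$dur
    over <- runs[runs$dur > max_burst, , drop = FALSE]
    if (nrow(over) > 0) {
      sustained[[length(sustained) + 1]] <-
        data.frame(period = p, start = over$t_start, duration = over$dur)
    }
    ok <- runs[runs$dur >= min_burst & runs$dur <= max_burst, , drop = FALSE]
    for (r in seq_len(nrow(ok))) {
      hit <- grid$period == p & grid$start < ok$t_end[r] & grid$end > ok$t_start[r]
      labels[hit] <- TRUE
    }
  }
  out <- modality_labels(labels, "emg", side = env$side)
  attr(out, "atonia") <- atonia
  attr(out, "sustained") <- if (length(sustained)) do.call(rbind, sustained) else
    data.frame(period = integer(0), start = numeric(0), duration = numeric(0))
  out
}

#' Merge left- and right-side labels
#'
#' Element-wise OR: an epoch is active when activity was detected on either
#' side. Commutative, associative, and idempotent.
#'
#' @param left,right [modality_labels()] on the same grid and modality.
#' @return A side-merged [modality_labels()].
#' @export
merge_bilateral <- function(left, right) {
  if (length(left) != length(right)) {
    stopf("label vectors differ in length (%d vs %d): not the same grid",
          length(left), length(right))
  }
  if (inherits(left, "modality_labels") && inherits(right, "modality_labels") &&
      left$modality != right$modality) {
    stopf("cannot merge labels from different modalities (%s vs %s)",
          left$modality, right$modality)
  }
  modality <- if (inherits(left, "modality_labels")) left$modality else "acti"
  modality_labels(as_label_vector(left) | as_label_vector(right),
                  modality, side = "merged")
}
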