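#' Hypnogram of 30 s sleep-stage epochs
#'
#' @param stages Character vector of stage labels from `W, N1, N2, N3, R`.
#' @param epoch_len Epoch length in seconds (30 by convention).
#' @param start_time Start, seconds from the session origin.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_len = 30, start_time = 0) {
  stages <- as.character(stages)
  if (length(stages) == 0) stopf("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(stages), sleep_stages())
  if (length(bad) > 0) {
    stopf("unknown stage label(s): %s", paste(bad, collapse = ", "))
  }
  structure(list(stages = stages, epoch_len = epoch_len, start_time = start_time),
            class = "hypnogram")
}

#' Canonical sleep-stage alphabet
#' @return `c("W", "N1", "N2", "N3", "R")`.
#' @export
sleep_stages <- function() c("W", "N1", "N2", "N3", "R")

#' @export
length.hypnogram <- function(x) length(x$stages)

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = sleep_stages()))
  cat(sprintf("<hypnogram> %d x %g s epochs (%.1f min): %s\n",
              length(x), x$epoch_len, length(x) * x$epoch_len / 60,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

# Contiguous same-stage bouts: data.frame(stage, start, end) in seconds.
stage_bouts <- function(hyp) {
  r <- rle(hyp$stages)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(
    stage = r$values,
    start = hyp$start_time + starts * hyp$epoch_len,
    end = hyp$start_time + ends * hyp$epoch_len,
    stringsAsFactors = FALSE
  )
}

# Stage of the hypnogram at time t (seconds); NA outside the span.
stage_at <- function(hyp, t) {
  idx <- floor((t - hyp$start_time) / hyp$epoch_len) + 1
  out <- rep(NA_character_, length(t))
  ok <- idx >= 1 & idx <= length(hyp$stages)
  out[ok] <- hyp$stages[idx[ok]]
  out
}

#' REM periods of a hypnogram
#'
#' Maximal runs of consecutive R-staged epochs converted to time intervals,
#' with short periods excluded. The exclusion rule is strict "shorter than":
#' a period of exactly `min_duration` seconds is kept. A single non-R epoch
#' splits a period.
#'
#' @param hyp A [hypnogram()].
#' @param min_duration Minimum period duration in seconds (default 300 s,
#'   i.e. 5 min, the standard exclusion used in RBD scoring guidelines).
#' @return A data.frame of class `rem_periods` with columns `start`, `end`
#'   (seconds, half-open intervals `[start, end)`), sorted and disjoint.
#' @export
rem_periods <- function(hyp, min_duration = 300) {
  b <- stage_bouts(hyp)
  b <- b[b$stage == "R" & (b$end - b$start) >= min_duration, , drop = FALSE]
  out <- data.frame(start = b$start, end = b$end)
  class(out) <- c("rem_periods", "data.frame")
  out
}

#' Construct REM periods directly from intervals
#'
#' For analyses driven by reported per-period durations rather than a full
#' hypnogram (e.g. tiling reference-cohort REM totals).
#'
#' @param start,end Numeric vectors of period bounds in seconds.
#' @return A `rem_periods` data.frame.
#' @export
rem_periods_from_intervals <- function(start, end) {
  if (any(end <= start)) stopf("each period must have end > start")
  o <- order(start)
  out <- data.frame(start = start[o], end = end[o])
  if (nrow(out) > 1 && any(out$start[-1] < out$end[-nrow(out)])) {
    stopf("REM periods must be disjoint")
  }
  class(out) <- c("rem_periods", "data.frame")
  out
}

#' 3 s mini-epoch grid over REM periods
#'
#' Tiles each REM period from its onset with contiguous, non-overlapping bins
#' of `epoch_s` seconds; a partial tail bin (possible only when period
#' durations are not multiples of `epoch_s`) is dropped, never padded.
#'
#' @param periods A `rem_periods` data.frame.
#' @param epoch_s Mini-epoch length in seconds (3 by convention).
#' @return A data.frame of class `mini_epoch_grid` with columns `start`, `end`
#'   (seconds, half-open) and `period` (1-based period index).
#' @export
mini_epoch_grid <- function(periods, epoch_s = 3) {
  rows <- lapply(seq_len(nrow(periods)), function(i) {
    n <- floor((periods$end[i] - periods$start[i]) / epoch_s)
    if (n == 0) return(NULL)
    s <- periods$start[i] + epoch_s * (0:(n - 1))
    data.frame(start = s, end = s + epoch_s, period = i)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(start = numeric(0), end = numeric(0),
                                      period = integer(0))
  class(out) <- c("mini_epoch_grid", "data.frame")
  out
}
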