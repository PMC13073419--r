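#' Tri-axial wrist accelerometer recording
#'
#' Container for raw acceleration along three orthogonal axes, in units of g,
#' sampled uniformly. This is the input to the activity-count pipeline
#' ([compute_activity_counts()]).
#'
#' @param x,y,z Numeric vectors of equal length: acceleration in g.
#' @param rate Sampling rate in Hz (> 0).
#' @param start_time Recording start, seconds from the session origin.
#' @param side Wrist: `"L"` or `"R"`.
#' @param dynamic_range Device dynamic range in g (values must lie within
#'   `c(-dynamic_range, dynamic_range)`); wrist actigraphs in RBD protocols
#'   are typically configured at +/- 8 g.
#' @param resolution_bits Optional ADC resolution; when set, values are assumed
#'   already quantized by the device (see [quantize_recording()]).
#'
#' @return An object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(x, y, z, rate, start_time = 0, side = "L",
                               dynamic_range = 8, resolution_bits = NULL) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    stopf("axes must have equal length (got %d, %d, %d)", n, length(y), length(z))
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stopf("sampling rate must be a single positive number")
  }
  side <- match.arg(side, c("L", "R"))
  if (n > 0 && max(abs(c(x, y, z)), na.rm = TRUE) > dynamic_range + 1e-9) {
    stopf("acceleration exceeds the stated dynamic range of %g g", dynamic_range)
  }
  structure(
    list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         rate = rate, start_time = start_time, side = side,
         dynamic_range = dynamic_range, resolution_bits = resolution_bits),
    class = "triaxial_recording"
  )
}

#' @export
length.triaxial_recording <- function(x) length(x$x)

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf(
    "<triaxial_recording> side=%s, %d samples @ %g Hz (%.1f s), range +/-%g g\n",
    x$side, length(x), x$rate, length(x) / x$rate, x$dynamic_range))
  invisible(x)
}

#' Vector magnitude of a tri-axial recording
#'
#' @param rec A [triaxial_recording()].
#' @return Numeric vector `sqrt(x^2 + y^2 + z^2)` in g.
#' @export
vector_magnitude <- function(rec) {
  sqrt(rec$x^2 + rec$y^2 + rec$z^2)
}

#' Emulate finite ADC resolution
#'
#' Rounds each axis to the grid of a `bits`-bit converter spanning the
#' recording's dynamic range. Off by default throughout the package; useful to
#' emulate 12-bit vs. 16-bit devices.
#'
#' @param rec A [triaxial_recording()].
#' @param bits Integer resolution in bits.
#' @return The quantized recording with `resolution_bits` set.
#' @export
quantize_recording <- function(rec, bits) {
  step <- 2 * rec$dynamic_range / (2^bits)
  q <- function(v) round(v / step) * step
  out <- rec
  out$x <- q(rec$x); out$y <- q(rec$y); out$z <- q(rec$z)
  out$resolution_bits <- as.integer(bits)
  out
}

#' 1 Hz activity-count series
#'
#' Non-negative activity counts (in g units) produced by the activity-count
#' pipeline; one value per second. After zero-rounding no value lies in the
#' open interval (0, threshold).
#'
#' @param values Numeric vector of counts, one per second.
#' @param start_time Series start, seconds from the session origin.
#' @param side Wrist the series came from (`"L"`, `"R"`, or `"merged"`).
#' @return An object of class `activity_counts` (rate fixed at 1 Hz).
#' @export
activity_counts <- function(values, start_time = 0, side = "L") {
  if (any(values < 0, na.rm = TRUE)) stopf("activity counts must be non-negative")
  structure(
    list(values = as.numeric(values), rate = 1, start_time = start_time,
         side = side),
    class = "activity_counts"
  )
}

#' @export
length.activity_counts <- function(x) length(x$values)

#' @export
print.activity_counts <- function(x, ...) {
  cat(sprintf("<activity_counts> side=%s, %d s, %d active (>0)\n",
              x$side, length(x), sum(x$values > 0)))
  invisible(x)
}

#' Rectified EMG envelope
#'
#' Non-negative rectified EMG amplitude (microvolts) at a fixed rate, used by
#' the rule-based mini-epoch scorer [score_emg_mini_epochs()].
#'
#' @param values Non-negative numeric amplitude series.
#' @param rate Sampling rate in Hz.
#' @param start_time Start, seconds from the session origin.
#' @param side `"L"` or `"R"`.
#' @return An object of class `emg_envelope`.
#' @export
emg_envelope <- function(values, rate, start_time = 0, side = "L") {
  if (any(values < 0, na.rm = TRUE)) stopf("EMG envelope values must be non-negative")
  structure(
    list(values = as.numeric(values), rate = rate, start_time = start_time,
         side = match.arg(side, c("L", "R"))),
    class = "emg_envelope"
  )
}

#' Binary per-mini-epoch modality labels
#'
#' One 0/1 label per mini-epoch of a [mini_epoch_grid()], for one modality and
#' one side (or the side-merged combination).
#'
#' @param labels Vector coercible to 0/1, one element per grid epoch.
#' @param modality `"emg"`, `"acti"`, or `"video"`.
#' @param side `"L"`, `"R"`, or `"merged"`.
#' @return An object of class `modality_labels`.
#' @export
modality_labels <- function(labels, modality, side = "merged") {
  modality <- match.arg(modality, c("emg", "acti", "video"))
  side <- match.arg(side, c("L", "R", "merged"))
  lab <- as.integer(as.logical(labels))
  if (any(is.na(lab))) stopf("labels must be binary (0/1)")
  structure(list(labels = lab, modality = modality, side = side),
            class = "modality_labels")
}

#' @export
length.modality_labels <- function(x) length(x$labels)

#' @export
print.modality_labels <- function(x, ...) {
  cat(sprintf("<modality_labels> %s/%s: %d epochs, %d active (%.1f%%)\n",
              x$modality, x$side, length(x), sum(x$labels),
              100 * mean(x$labels)))
  invisible(x)
}

# Accept either a modality_labels object or a bare binary vector.
as_label_vector <- function(x) {
  if (inherits(x, "modality_labels")) x$labels else as.integer(as.logical(x))
}
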