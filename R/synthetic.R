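#' Simulation configuration for synthetic multimodal recordings
#'
#' Parameters of the generative model used to emulate overnight multimodal
#' recordings with known ground truth: stage-dependent Poisson motor-event
#' processes, log-normal event durations and burst amplitudes, per-event side
#' involvement, per-modality detection probabilities and false-positive rates,
#' accelerometer noise, and an EMG atonia baseline.
#'
#' Defaults emulate an RBD-like night: motor events are far more frequent in
#' REM (2/min) than in NREM sleep, bursts are sub-second to a few seconds
#' with peak accelerations around 1 g (median), and modalities detect events
#' with the asymmetric sensitivities seen clinically (actigraphy and EMG
#' comparable and most sensitive, manually scored video lowest).
#'
#' @param stage_event_rates Named events/min per stage `W, N1, N2, N3, R`.
#' @param duration_meanlog,duration_sdlog Log-normal parameters of event
#'   duration in seconds.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal parameters of burst
#'   peak acceleration in g.
#' @param side_probs Probabilities of `left`, `right`, `bilateral`
#'   involvement (must sum to 1).
#' @param detect_probs Per-modality per-event detection probabilities
#'   (`emg`, `acti`, `video`).
#' @param fp_rates Per-modality false-positive epochs per hour.
#' @param noise_sd Accelerometer noise SD in g.
#' @param emg_atonia Baseline rectified-EMG envelope amplitude in microvolts.
#' @param emg_burst_gain Peak envelope of a detected EMG burst, as a multiple
#'   of the atonia baseline (default 3).
#' @param emg_rate EMG envelope sampling rate in Hz.
#' @param burst_freq Oscillation frequency of accelerometry bursts in Hz
#'   (band-limited 2-4 Hz; default 3).
#' @param device_rate Accelerometer sampling rate in Hz.
#' @param device_range Accelerometer dynamic range in g.
#' @param resolution_bits Optional ADC resolution to emulate.
#' @param seed Default seed used by generators when none is supplied.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(stage_event_rates = c(W = 6, N1 = 0.5, N2 = 0.2, N3 = 0.1, R = 2),
                       duration_meanlog = log(1.0), duration_sdlog = 0.6,
                       amplitude_meanlog = log(1.0), amplitude_sdlog = 0.7,
                       side_probs = c(left = 0.35, right = 0.35, bilateral = 0.3),
                       detect_probs = c(emg = 0.6, acti = 0.85, video = 0.5),
                       fp_rates = c(emg = 2, acti = 2, video = 0.5),
                       noise_sd = 0.005, emg_atonia = 2, emg_burst_gain = 3,
                       emg_rate = 25, burst_freq = 3,
                       device_rate = 25, device_range = 8,
                       resolution_bits = NULL, seed = 1L) {
  cfg <- list(stage_event_rates = stage_event_rates,
              duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
              amplitude_meanlog = amplitude_meanlog, amplitude_sdlog = amplitude_sdlog,
              side_probs = side_probs, detect_probs = detect_probs,
              fp_rates = fp_rates, noise_sd = noise_sd,
              emg_atonia = emg_atonia, emg_burst_gain = emg_burst_gain,
              emg_rate = emg_rate, burst_freq = burst_freq,
              device_rate = device_rate, device_range = device_range,
              resolution_bits = resolution_bits, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (any(cfg$stage_event_rates < 0)) stopf("stage event rates must be >= 0")
  if (!all(sleep_stages() %in% names(cfg$stage_event_rates))) {
    stopf("stage_event_rates must name all stages %s",
          paste(sleep_stages(), collapse = ", "))
  }
  probs <- c(cfg$side_probs, cfg$detect_probs)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$side_probs) - 1) > 1e-8) stopf("side_probs must sum to 1")
  if (any(cfg$fp_rates < 0)) stopf("false-positive rates must be >= 0")
  if (cfg$device_rate <= 0) stopf("device_rate must be positive")
  if (cfg$emg_atonia <= 0) stopf("emg_atonia must be positive")
  if (cfg$noise_sd < 0) stopf("noise_sd must be >= 0")
  invisible(cfg)
}

#' Plausible overnight stage-transition matrix
#'
#' Row-stochastic 30 s epoch-to-epoch transition matrix over
#' `W, N1, N2, N3, R` with realistic bout structure (sticky stages, REM
#' reachable through N2), plus a start-of-night initial distribution.
#'
#' @return List with `matrix` (5x5, row-stochastic) and `init` (named
#'   probability vector).
#' @export
sleep_transition_spec <- function() {
  s <- sleep_stages()
  m <- matrix(c(
    0.85, 0.12, 0.03, 0.00, 0.00,   # W
    0.10, 0.60, 0.28, 0.00, 0.02,   # N1
    0.03, 0.05, 0.80, 0.09, 0.03,   # N2
    0.01, 0.02, 0.12, 0.84, 0.01,   # N3
    0.03, 0.05, 0.05, 0.00, 0.87    # R
  ), nrow = 5, byrow = TRUE, dimnames = list(s, s))
  list(matrix = m, init = c(W = 1, N1 = 0, N2 = 0, N3 = 0, R = 0))
}

#' Generate a synthetic hypnogram
#'
#' First-order Markov chain over the 30 s stage alphabet.
#'
#' @param n_epochs Number of 30 s epochs (>= 1).
#' @param transition Transition spec: a list with a row-stochastic `matrix`
#'   (rows/columns named by stage) and an initial distribution `init`.
#'   Defaults to [sleep_transition_spec()].
#' @param seed RNG seed.
#' @return A [hypnogram()].
#' @export
generate_hypnogram <- function(n_epochs, transition = sleep_transition_spec(),
                               seed = 1L) {
  if (n_epochs < 1) stopf("n_epochs must be >= 1")
  m <- transition$matrix
  init <- transition$init
  s <- sleep_stages()
  if (!identical(dim(m), c(5L, 5L)) || !all(rownames(m) == s)) {
    stopf("transition matrix must be 5x5 with rows/columns %s",
          paste(s, collapse = ", "))
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
    stopf("transition matrix must be row-stochastic (non-negative rows summing to 1)")
  }
  if (any(init < 0) || abs(sum(init) - 1) > 1e-8) {
    stopf("initial distribution must be a probability vector")
  }
  stages <- with_seed(derive_seed(seed, "hypnogram"), {
    out <- character(n_epochs)
    out[1] <- sample(s, 1, prob = init[s])
    for (i in seq_len(n_epochs - 1)) {
      out[i + 1] <- sample(s, 1, prob = m[out[i], ])
    }
    out
  })
  hypnogram(stages)
}

#' Generate latent motor events from a hypnogram
#'
#' Homogeneous Poisson event onsets within each same-stage bout at that
#' stage's rate; durations and peak amplitudes are log-normal; side
#' involvement is drawn from `side_probs`. Events are truncated at the end of
#' their bout so they never straddle a stage boundary, keeping stage
#' attribution unambiguous.
#'
#' @param hyp A [hypnogram()].
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A data.frame of class `latent_events` with columns `onset`,
#'   `duration`, `amplitude`, `side` (`L`, `R`, `both`), `stage`, sorted by
#'   onset.
#' @export
generate_latent_events <- function(hyp, config, seed = config$seed) {
  bouts <- stage_bouts(hyp)
  ev <- with_seed(derive_seed(seed, "events"), {
    rows <- lapply(seq_len(nrow(bouts)), function(i) {
      rate_s <- config$stage_event_rates[[bouts$stage[i]]] / 60
      span <- bouts$end[i] - bouts$start[i]
      n <- stats::rpois(1, rate_s * span)
      if (n == 0) return(NULL)
      onset <- sort(stats::runif(n, bouts$start[i], bouts$end[i]))
      dur <- stats::rlnorm(n, config$duration_meanlog, config$duration_sdlog)
      dur <- pmin(dur, bouts$end[i] - onset)  # never straddle a stage boundary
      amp <- stats::rlnorm(n, config$amplitude_meanlog, config$amplitude_sdlog)
      side <- sample(c("L", "R", "both"), n, replace = TRUE,
                     prob = config$side_probs)
      data.frame(onset = onset, duration = dur, amplitude = amp,
                 side = side, stage = bouts$stage[i], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  if (is.null(ev)) {
    ev <- data.frame(onset = numeric(0), duration = numeric(0),
                     amplitude = numeric(0), side = character(0),
                     stage = character(0), stringsAsFactors = FALSE)
  }
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("latent_events", "data.frame")
  ev
}

# Events involving one wrist ("both" counts for either side).
events_for_side <- function(events, side) {
  if (side == "merged") return(events)
  events[events$side == side | events$side == "both", , drop = FALSE]
}

#' Render a synthetic accelerometer signal
#'
#' Signal model: a fixed unit gravity vector along z, plus zero-mean Gaussian
#' noise of SD `noise_sd` on each axis, plus -- for every latent event
#' involving this side -- a smooth burst: a raised-cosine envelope of the
#' event's duration times a rectified band-limited oscillation (`burst_freq`
#' Hz), scaled to the event's peak amplitude and directed along the gravity
#' axis so that the vector-magnitude deviation (hence ENMO) responds linearly
#' to the peak amplitude. Values are clipped to the device range. Bilateral
#' events render with identical onset on both sides.
#'
#' @param events A `latent_events` data.frame.
#' @param hyp The [hypnogram()] defining the recording span.
#' @param config A [sim_config()].
#' @param side `"L"` or `"R"`.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A [triaxial_recording()] at `config$device_rate`.
#' @export
render_accelerometry <- function(events, hyp, config, side, seed = config$seed) {
  side <- match.arg(side, c("L", "R"))
  span <- length(hyp) * hyp$epoch_len
  if (nrow(events) > 0 &&
      (min(events$onset) < hyp$start_time ||
       max(events$onset + events$duration) > hyp$start_time + span + 1e-9)) {
    stopf("events lie outside the recording span")
  }
  rate <- config$device_rate
  n <- round(span * rate)
  noise <- with_seed(derive_seed(seed, paste0("noise_", side)), {
    matrix(stats::rnorm(3 * n, 0, config$noise_sd), ncol = 3)
  })
  x <- noise[, 1]; y <- noise[, 2]; z <- 1 + noise[, 3]
  ev <- events_for_side(events, side)
  t0 <- hyp$start_time
  for (i in seq_len(nrow(ev))) {
    i0 <- floor((ev$onset[i] - t0) * rate) + 1
    i1 <- min(n, ceiling((ev$onset[i] + ev$duration[i] - t0) * rate))
    if (i1 < i0) next
    tt <- ((i0:i1) - 1) / rate + t0
    u <- (tt - ev$onset[i]) / ev$duration[i]
    w <- ev$amplitude[i] * raised_cosine(u) *
      abs(sin(2 * pi * config$burst_freq * (tt - ev$onset[i])))
    z[i0:i1] <- z[i0:i1] + w
  }
  r <- config$device_range
  rec <- triaxial_recording(pmin(pmax(x, -r), r), pmin(pmax(y, -r), r),
                            pmin(pmax(z, -r), r), rate = rate,
                            start_time = t0, side = side, dynamic_range = r)
  if (!is.null(config$resolution_bits)) {
    rec <- quantize_recording(rec, config$resolution_bits)
  }
  rec
}

#' Render a synthetic rectified EMG envelope
#'
#' Envelope = atonia baseline plus, for each event involving this side that
#' passes the per-event EMG detection draw (`detect_probs["emg"]`), a
#' raised-cosine bump peaking at `emg_burst_gain` times the atonia baseline.
#' Missed events render no burst.
#'
#' @param events A `latent_events` data.frame.
#' @param config A [sim_config()].
#' @param side `"L"` or `"R"`.
#' @param n_seconds Envelope span in seconds (e.g. the recording span).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return An [emg_envelope()] at `config$emg_rate`, with attribute
#'   `detected` (logical per event of this side).
#' @export
render_emg_envelope <- function(events, config, side, n_seconds,
                                seed = config$seed) {
  side <- match.arg(side, c("L", "R"))
  rate <- config$emg_rate
  n <- round(n_seconds * rate)
  v <- rep(config$emg_atonia, n)
  ev <- events_for_side(events, side)
  detected <- with_seed(derive_seed(seed, paste0("emg_", side)), {
    stats::runif(nrow(ev)) < config$detect_probs[["emg"]]
  })
  peak <- config$emg_atonia * (config$emg_burst_gain - 1)
  for (i in which(detected)) {
    i0 <- floor(ev$onset[i] * rate) + 1
    i1 <- min(n, ceiling((ev$onset[i] + ev$duration[i]) * rate))
    if (i1 < i0) next
    tt <- ((i0:i1) - 1) / rate
    u <- (tt - ev$onset[i]) / ev$duration[i]
    v[i0:i1] <- v[i0:i1] + peak * raised_cosine(u)
  }
  out <- emg_envelope(v, rate = rate, side = side)
  attr(out, "detected") <- detected
  out
}

#' Render probabilistic per-mini-epoch modality annotations
#'
#' Observation model for binary per-epoch labels: each latent event is
#' detected with the modality's per-event probability, in which case all grid
#' mini-epochs it overlaps are set active; false-positive epochs are added as
#' a Poisson draw at the modality's rate per hour of gridded time.
#'
#' @param events A `latent_events` data.frame.
#' @param grid A [mini_epoch_grid()].
#' @param config A [sim_config()].
#' @param modality `"emg"`, `"acti"`, or `"video"`.
#' @param side `"L"`, `"R"`, or `"merged"` (default): which events can be
#'   seen. Video is scored side-merged by design.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A [modality_labels()] with attribute `detected` (logical per
#'   considered event).
#' @export
render_modality_annotations <- function(events, grid, config, modality,
                                        side = "merged", seed = config$seed) {
  modality <- match.arg(modality, c("emg", "acti", "video"))
  ev <- events_for_side(events, side)
  p <- config$detect_probs[[modality]]
  fp_rate <- config$fp_rates[[modality]]
  hours <- sum(grid$end - grid$start) / 3600
  res <- with_seed(derive_seed(seed, paste0("detect_", modality)), {
    detected <- stats::runif(nrow(ev)) < p
    n_fp <- stats::rpois(1, fp_rate * hours)
    fp_idx <- if (n_fp > 0 && nrow(grid) > 0) {
      sample.int(nrow(grid), min(n_fp, nrow(grid)))
    } else integer(0)
    list(detected = detected, fp_idx = fp_idx)
  })
  labels <- rep(FALSE, nrow(grid))
  for (i in which(res$detected)) {
    labels[grid$start < ev$onset[i] + ev$duration[i] & grid$end > ev$onset[i]] <- TRUE
  }
  labels[res$fp_idx] <- TRUE
  out <- modality_labels(labels, modality, side = side)
  attr(out, "detected") <- res$detected
  out
}

#' Ground-truth event occupancy of a grid
#'
#' Mini-epochs overlapped by at least one latent event (optionally of one
#' side); the noiseless reference against which detections are compared.
#'
#' @param events A `latent_events` data.frame.
#' @param grid A [mini_epoch_grid()].
#' @param side `"L"`, `"R"`, or `"merged"`.
#' @return Logical vector per grid epoch.
#' @export
event_occupancy <- function(events, grid, side = "merged") {
  ev <- events_for_side(events, side)
  occ <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(ev))) {
    occ[grid$start < ev$onset[i] + ev$duration[i] & grid$end > ev$onset[i]] <- TRUE
  }
  occ
}

#' Simulate one participant's multimodal night
#'
#' Convenience wrapper chaining the generators: hypnogram, latent events,
#' bilateral accelerometry, bilateral EMG envelopes, and per-epoch video
#' annotations on the REM mini-epoch grid.
#'
#' @param config A [sim_config()].
#' @param n_epochs Number of 30 s epochs.
#' @param transition Stage-transition spec (see [generate_hypnogram()]).
#' @param seed RNG seed (defaults to `config$seed`).
#' @param hyp Optional fixed [hypnogram()]; when supplied, `n_epochs` and
#'   `transition` are ignored (useful for designs with a prescribed stage
#'   structure).
#' @return List with `config`, `seed`, `hypnogram`, `events`, `periods`,
#'   `grid`, `accel` (list `L`, `R`), `emg` (list `L`, `R` envelopes), and
#'   `video` (merged [modality_labels()]).
#' @export
simulate_participant <- function(config = sim_config(), n_epochs = 960,
                                 transition = sleep_transition_spec(),
                                 seed = config$seed, hyp = NULL) {
  if (is.null(hyp)) hyp <- generate_hypnogram(n_epochs, transition, seed = seed)
  n_epochs <- length(hyp)
  events <- generate_latent_events(hyp, config, seed = seed)
  periods <- rem_periods(hyp)
  grid <- mini_epoch_grid(periods)
  span <- n_epochs * hyp$epoch_len
  list(
    config = config, seed = seed, hypnogram = hyp, events = events,
    periods = periods, grid = grid,
    accel = list(L = render_accelerometry(events, hyp, config, "L", seed),
                 R = render_accelerometry(events, hyp, config, "R", seed)),
    emg = list(L = render_emg_envelope(events, config, "L", span, seed),
               R = render_emg_envelope(events, config, "R", span, seed)),
    video = render_modality_annotations(events, grid, config, "video",
                                        side = "merged", seed = seed)
  )
}
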