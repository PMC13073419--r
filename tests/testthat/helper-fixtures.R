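# Shared builders for test fixtures (all generated in code).

# Recording with constant gravity (optionally scaled) plus optional z bursts.
gravity_recording <- function(n_seconds, rate = 25, scale = 1, side = "L") {
  n <- n_seconds * rate
  triaxial_recording(rep(0, n), rep(0, n), rep(scale, n), rate = rate,
                     side = side)
}

# Add a pure 3 Hz oscillation of given peak (g) along z over [onset, onset+dur).
add_z_burst <- function(rec, onset, duration, peak, freq = 3) {
  t <- (seq_len(length(rec)) - 1) / rec$rate
  idx <- t >= onset & t < onset + duration
  rec$z[idx] <- rec$z[idx] + peak * sin(2 * pi * freq * (t[idx] - onset))
  rec
}

# Latent-event data.frame with the class the generators produce.
make_events <- function(onset, duration, amplitude, side = "L", stage = "R") {
  ev <- data.frame(onset = onset, duration = duration, amplitude = amplitude,
                   side = rep_len(side, length(onset)),
                   stage = rep_len(stage, length(onset)),
                   stringsAsFactors = FALSE)
  class(ev) <- c("latent_events", "data.frame")
  ev
}

# Degenerate transition spec: absorbing single stage.
absorbing_spec <- function(stage) {
  s <- sleep_stages()
  m <- diag(5)
  dimnames(m) <- list(s, s)
  init <- stats::setNames(as.numeric(s == stage), s)
  list(matrix = m, init = init)
}

# Block hypnogram with guaranteed >=5 min REM bouts (one per cycle).
block_hypnogram <- function(cycles = 2) {
  hypnogram(rep(c(rep("W", 2), rep("N1", 4), rep("N2", 16), rep("N3", 10),
                  rep("R", 12)), cycles))
}

# Random binary label vector.
rand_labels <- function(n, p = 0.3) as.integer(stats::runif(n) < p)

# Brute-force kappa from two binary vectors (independent of contingency path).
kappa_brute <- function(f, s) {
  n <- length(f)
  po <- mean(f == s)
  pe <- mean(f == 1) * mean(s == 1) + mean(f == 0) * mean(s == 0)
  if (abs(1 - pe) < 1e-14) return(NA_real_)
  (po - pe) / (1 - pe)
}
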