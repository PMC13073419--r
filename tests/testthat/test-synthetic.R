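# Synthetic multimodal generator: determinism, stage structure, event
# statistics, rendering contracts.

test_that("hypnogram generator respects absorbing states and determinism", {
  h <- generate_hypnogram(10, absorbing_spec("N2"), seed = 3)
  expect_identical(h$stages, rep("N2", 10))

  h1 <- generate_hypnogram(200, seed = 42)
  h2 <- generate_hypnogram(200, seed = 42)
  expect_identical(h1$stages, h2$stages)
  h3 <- generate_hypnogram(200, seed = 43)
  expect_false(identical(h1$stages, h3$stages))
})

test_that("forced REM entry with self-transition 1 survives the 5 min filter", {
  s <- sleep_stages()
  m <- diag(5); dimnames(m) <- list(s, s)
  m["N2", ] <- c(0, 0, 0, 0, 1)  # N2 always enters REM; REM absorbs
  h <- generate_hypnogram(20, list(matrix = m, init = c(W = 0, N1 = 0, N2 = 1,
                                                        N3 = 0, R = 0)),
                          seed = 1)
  expect_identical(h$stages[-1], rep("R", 19))
  p <- rem_periods(h)
  expect_equal(nrow(p), 1)
  expect_gte(p$end[1] - p$start[1], 300)
})

test_that("hypnogram generator rejects non-stochastic transition input", {
  s <- sleep_stages()
  m <- diag(5) * 2; dimnames(m) <- list(s, s)
  expect_error(
    generate_hypnogram(5, list(matrix = m, init = c(W = 1, N1 = 0, N2 = 0,
                                                    N3 = 0, R = 0))),
    "row-stochastic")
})

test_that("latent events follow the stage-wise Poisson model", {
  cfg0 <- sim_config(stage_event_rates = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0))
  h <- generate_hypnogram(120, absorbing_spec("R"), seed = 1)
  expect_equal(nrow(generate_latent_events(h, cfg0, seed = 1)), 0)

  # rate 2/min over 60 min of REM: mean count over seeds within 3 sigma/sqrt(k)
  cfg <- sim_config(stage_event_rates = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 2))
  counts <- vapply(1:20, function(s) {
    nrow(generate_latent_events(h, cfg, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 120), 3 * sqrt(120 / 20))

  ev <- generate_latent_events(h, cfg, seed = 5)
  expect_true(all(diff(ev$onset) >= 0))
  expect_true(all(ev$duration > 0))
  expect_true(all(ev$onset + ev$duration <= 120 * 30 + 1e-9))
  expect_identical(ev, generate_latent_events(h, cfg, seed = 5))
})

test_that("REM-dominant rates produce REM-dominant event density", {
  cfg <- sim_config(stage_event_rates = c(W = 0, N1 = 0, N2 = 0, N3 = 0.2, R = 4))
  stages <- rep(c("R", "N3"), each = 60)  # 30 min each
  h <- hypnogram(stages)
  ev <- generate_latent_events(h, cfg, seed = 11)
  per_min <- table(factor(ev$stage, levels = c("R", "N3"))) / 30
  expect_gt(per_min[["R"]], per_min[["N3"]])
})

test_that("accelerometry rendering is 1 g at rest, bursty at events, deterministic", {
  h <- hypnogram(rep("R", 2))
  cfg <- sim_config(noise_sd = 0,
                    stage_event_rates = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0))
  rec0 <- render_accelerometry(make_events(numeric(0), numeric(0), numeric(0)),
                               h, cfg, "L")
  expect_equal(vector_magnitude(rec0), rep(1, length(rec0)), tolerance = 1e-12)
  cnt0 <- compute_activity_counts(rec0)
  expect_true(all(cnt0$values == 0))

  ev <- make_events(20, 1, 0.5)
  rec <- render_accelerometry(ev, h, cfg, "L")
  e <- enmo(rec)
  in_window <- seq(20 * rec$rate + 1, 21 * rec$rate)
  expect_gt(max(e[in_window]), 0.1)  # survives zero-rounding per-sample

  cfg_n <- sim_config(noise_sd = 0.01)
  r1 <- render_accelerometry(ev, h, cfg_n, "L", seed = 9)
  r2 <- render_accelerometry(ev, h, cfg_n, "L", seed = 9)
  expect_identical(r1$x, r2$x); expect_identical(r1$z, r2$z)

  expect_error(render_accelerometry(make_events(100, 5, 1), h, cfg, "L"),
               "outside the recording span")
})

test_that("burst count per side matches latent events involving that side", {
  h <- hypnogram(rep("R", 10))
  cfg <- sim_config(noise_sd = 0)
  ev <- make_events(onset = c(10, 50, 100, 170, 230),
                    duration = rep(2, 5), amplitude = rep(1, 5),
                    side = c("L", "R", "both", "L", "R"))
  for (side in c("L", "R")) {
    rec <- render_accelerometry(ev, h, cfg, side)
    t <- (seq_len(length(rec)) - 1) / rec$rate
    dev <- abs(vector_magnitude(rec) - 1)
    involved <- ev$side %in% c(side, "both")
    for (i in seq_len(nrow(ev))) {
      win <- t >= ev$onset[i] & t < ev$onset[i] + ev$duration[i]
      if (involved[i]) {
        expect_gt(max(dev[win]), 0.05)  # every involved event leaves a burst
      } else {
        expect_lt(max(dev[win]), 1e-9)  # uninvolved events leave nothing
      }
    }
    outside <- !logical(length(t))
    for (i in which(involved)) {
      outside[t >= ev$onset[i] & t < ev$onset[i] + ev$duration[i]] <- FALSE
    }
    expect_lt(max(dev[outside]), 1e-9)  # no spurious bursts elsewhere
  }
})

test_that("EMG envelope renders detected bursts over a flat atonia baseline", {
  cfg <- sim_config(detect_probs = c(emg = 1, acti = 1, video = 1),
                    fp_rates = c(emg = 0, acti = 0, video = 0))
  env0 <- render_emg_envelope(make_events(numeric(0), numeric(0), numeric(0)),
                              cfg, "L", n_seconds = 60)
  expect_equal(env0$values, rep(cfg$emg_atonia, 60 * cfg$emg_rate))
  periods <- rem_periods_from_intervals(0, 60)
  lab0 <- score_emg_mini_epochs(env0, periods)
  expect_equal(sum(lab0$labels), 0)

  # one 3x-atonia burst of 0.5 s at t=30: only the covering mini-epoch fires
  ev <- make_events(30.1, 0.5, 1)
  env <- render_emg_envelope(ev, cfg, "L", n_seconds = 60)
  lab <- score_emg_mini_epochs(env, periods)
  expect_equal(which(lab$labels == 1), 11L)  # epoch [30, 33)

  # a burst peaking at 1.5x atonia never reaches the 2x threshold
  cfg_low <- sim_config(detect_probs = c(emg = 1, acti = 1, video = 1),
                        emg_burst_gain = 1.5)
  env_low <- render_emg_envelope(ev, cfg_low, "L", n_seconds = 60)
  lab_low <- score_emg_mini_epochs(env_low, periods)
  expect_equal(sum(lab_low$labels), 0)
})

test_that("annotation model reduces to occupancy at p=1 and to silence at p=0", {
  h <- generate_hypnogram(100, absorbing_spec("R"), seed = 2)
  cfg1 <- sim_config(detect_probs = c(emg = 1, acti = 1, video = 1),
                     fp_rates = c(emg = 0, acti = 0, video = 0))
  ev <- generate_latent_events(h, cfg1, seed = 2)
  grid <- mini_epoch_grid(rem_periods(h))
  lab <- render_modality_annotations(ev, grid, cfg1, "video", seed = 2)
  expect_equal(lab$labels, as.integer(event_occupancy(ev, grid)))

  cfg0 <- sim_config(detect_probs = c(emg = 0, acti = 0, video = 0),
                     fp_rates = c(emg = 0, acti = 0, video = 0))
  lab0 <- render_modality_annotations(ev, grid, cfg0, "video", seed = 2)
  expect_equal(sum(lab0$labels), 0)
})

test_that("per-event detection frequency matches the configured probability", {
  h <- generate_hypnogram(300, absorbing_spec("R"), seed = 4)
  cfg <- sim_config(stage_event_rates = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 4),
                    detect_probs = c(emg = 0.7, acti = 0.7, video = 0.7),
                    fp_rates = c(emg = 0, acti = 0, video = 0))
  ev <- generate_latent_events(h, cfg, seed = 4)
  expect_gt(nrow(ev), 500)
  grid <- mini_epoch_grid(rem_periods(h))
  fracs <- vapply(1:20, function(s) {
    lab <- render_modality_annotations(ev, grid, cfg, "video", seed = s)
    mean(attr(lab, "detected"))
  }, numeric(1))
  sigma <- sqrt(0.7 * 0.3 / nrow(ev))
  expect_lt(abs(mean(fracs) - 0.7), 3 * sigma)
})

test_that("simulation config validates rates and probabilities", {
  expect_error(sim_config(side_probs = c(left = 0.5, right = 0.5, bilateral = 0.5)),
               "sum to 1")
  expect_error(sim_config(detect_probs = c(emg = 1.2, acti = 0.5, video = 0.5)),
               "\\[0, 1\\]")
  expect_error(sim_config(device_rate = 0), "positive")
  expect_error(sim_config(stage_event_rates = c(W = -1, N1 = 0, N2 = 0,
                                                N3 = 0, R = 0)),
               ">= 0")
})
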