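# Cross-modality agreement: overlap decomposition, kappa, conditional
# probabilities, pooled odds ratios, burden, stratified counts, bootstrap.

test_that("overlap decomposition matches hand enumeration and conserves totals", {
  emg <- c(1, 1, 1); acti <- c(1, 0, 0); video <- c(0, 1, 0)
  ov <- overlap_regions(emg, acti, video)
  expect_equal(unname(ov$regions["all_three"]), 0)
  expect_equal(unname(ov$regions["emg_acti"]), 1)
  expect_equal(unname(ov$regions["emg_video"]), 1)
  expect_equal(unname(ov$regions["emg_only"]), 1)
  expect_equal(ov$union_active, 3)

  ov0 <- overlap_regions(rep(0, 7), rep(0, 7), rep(0, 7))
  expect_equal(ov0$none_active, 7)

  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:200, 1)
    ov2 <- overlap_regions(rand_labels(n), rand_labels(n), rand_labels(n))
    expect_equal(sum(ov2$regions) + ov2$none_active, n)
    expect_equal(ov2$union_active, sum(ov2$regions))
    for (m in c("emg", "acti", "video")) {
      in_m <- grepl(m, names(ov2$regions)) | names(ov2$regions) == "all_three"
      expect_equal(unname(ov2$marginals[m]), sum(ov2$regions[in_m]))
    }
  }
})

test_that("pair tables collapse the seven regions consistently", {
  ov <- overlap_regions(c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 1), c(0, 1, 1, 0, 1))
  t_ea <- pair_table(ov, "emg", "acti")
  direct <- contingency_2x2(c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 1))
  expect_equal(t_ea$a, direct$a); expect_equal(t_ea$b, direct$b)
  expect_equal(t_ea$c, direct$c); expect_equal(t_ea$d, direct$d)
})

test_that("kappa matches the closed form, the oracle, and is symmetric", {
  x <- c(1, 0, 1, 0, 1)
  expect_equal(cohens_kappa(contingency_2x2(x, x)), 1)
  expect_equal(cohens_kappa(contingency_2x2(a = 1, b = 1, c = 1, d = 1)), 0)

  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    f <- rand_labels(n, 0.5); s <- rand_labels(n, 0.5)
    t <- contingency_2x2(f, s)
    k <- suppressWarnings(cohens_kappa(t))
    expect_equal(k, kappa_brute(f, s), tolerance = 1e-12)
    tt <- contingency_2x2(a = t$a, b = t$c, c = t$b, d = t$d)
    expect_equal(suppressWarnings(cohens_kappa(tt)), k, tolerance = 1e-12)
  }

  expect_warning(k0 <- cohens_kappa(contingency_2x2(a = 5, b = 0, c = 0, d = 0)),
                 "undefined")
  expect_true(is.na(k0))
})

test_that("conditional probabilities follow the orientation convention", {
  t_perfect <- contingency_2x2(c(1, 1, 0), c(1, 1, 0))
  expect_equal(unname(conditional_probs(t_perfect)), rep(1, 4))

  t0 <- contingency_2x2(a = 0, b = 2, c = 3, d = 5)
  expect_equal(unname(conditional_probs(t0)["p_first1_given_second1"]), 0)

  # zero conditioning margin yields NA, not division by zero
  t_na <- contingency_2x2(a = 0, b = 0, c = 0, d = 5)
  p <- conditional_probs(t_na)
  expect_true(is.na(p["p_first1_given_second1"]))

  # consistency: P(A=1|B=1) * margin(B) = a, exactly
  set.seed(19)
  for (i in 1:10) {
    n <- sample(4:20, 1)
    t <- contingency_2x2(rand_labels(n, 0.5), rand_labels(n, 0.5))
    p <- conditional_probs(t)
    if (!is.na(p["p_first1_given_second1"])) {
      expect_equal(p[["p_first1_given_second1"]] * (t$a + t$c), t$a)
    }
  }
})

test_that("pooled odds ratio matches single-table and corrected hand values", {
  or1 <- pooled_odds_ratio(list(contingency_2x2(a = 10, b = 5, c = 2, d = 20)))
  expect_equal(or1$or, 20)

  or2 <- pooled_odds_ratio(list(contingency_2x2(a = 5, b = 0, c = 3, d = 10)))
  expect_equal(or2$or, (5.5 * 10.5) / (0.5 * 3.5))  # Haldane-Anscombe 0.5

  t <- contingency_2x2(a = 10, b = 5, c = 2, d = 20)
  expect_equal(pooled_odds_ratio(list(t, t))$or, 20)  # MH invariance

  expect_error(pooled_odds_ratio(list()), "at least one")
  expect_error(pooled_odds_ratio(list(contingency_2x2(a = 3, b = 0, c = 0, d = 7)),
                                 correction = FALSE),
               "degenerate")
})

test_that("pooled odds ratio agrees with an independent meta-analysis oracle", {
  skip_if_not_installed("metafor")
  tabs <- list(contingency_2x2(a = 12, b = 5, c = 7, d = 30),
               contingency_2x2(a = 8, b = 9, c = 4, d = 22),
               contingency_2x2(a = 20, b = 3, c = 11, d = 41))
  ours <- pooled_odds_ratio(tabs)
  ref <- metafor::rma.mh(ai = c(12, 8, 20), bi = c(5, 9, 3),
                         ci = c(7, 4, 11), di = c(30, 22, 41),
                         measure = "OR")
  expect_equal(ours$log_or, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$ci[1], exp(ref$ci.lb), tolerance = 1e-6)
  expect_equal(ours$ci[2], exp(ref$ci.ub), tolerance = 1e-6)
})

test_that("activity ratio and rate follow their definitions", {
  expect_equal(activity_ratio(c(rep(1, 4), rep(0, 46))), 8)
  expect_equal(activity_ratio(rep(0, 10)), 0)

  grid1 <- mini_epoch_grid(rem_periods_from_intervals(0, 12))
  r <- activity_rate(c(1, 1, 0, 1), grid1)
  expect_equal(attr(r, "n_events"), 2)

  # 2 events in 12 min of REM -> 10 events/h
  grid2 <- mini_epoch_grid(rem_periods_from_intervals(0, 720))
  lab <- rep(0, 240); lab[10] <- 1; lab[100] <- 1
  expect_equal(as.numeric(activity_rate(lab, grid2)), 10)

  # an all-active period is one event regardless of length
  expect_equal(attr(activity_rate(rep(1, 240), grid2), "n_events"), 1)

  # runs never span period boundaries
  grid3 <- mini_epoch_grid(rem_periods_from_intervals(c(0, 600), c(6, 606)))
  expect_equal(attr(activity_rate(c(1, 1, 1, 1), grid3), "n_events"), 2)
})

test_that("consensus stratification averages the right epochs", {
  grid <- mini_epoch_grid(rem_periods_from_intervals(0, 18))  # 6 epochs
  vals <- c(0, 0, 0, 0.1, 0, 0, 0.3, 0, 0, 0.5, 0, 0, 0.2, 0, 0, 0, 0, 0)
  cnt <- activity_counts(vals)
  acti <- c(0, 1, 1, 1, 1, 0)
  emg <- c(0, 0, 1, 1, 0, 0)
  video <- c(0, 0, 0, 1, 1, 0)
  s <- stratified_activity_counts(cnt, emg, acti, video, grid)
  expect_equal(unname(s["acti_only"]), 0.1)
  expect_equal(unname(s["emg_acti"]), 0.3)
  expect_equal(unname(s["all_three"]), 0.5)
  expect_equal(unname(s["acti_video"]), 0.2)

  # empty categories are NA-flagged
  s2 <- stratified_activity_counts(cnt, rep(0, 6), acti, rep(0, 6), grid)
  expect_true(is.na(s2["all_three"]))
  expect_false(is.na(s2["acti_only"]))

  # two acti-only epochs with maxima 0.1 and 0.3 average to 0.2
  s3 <- stratified_activity_counts(cnt, rep(0, 6), c(0, 1, 1, 0, 0, 0),
                                   rep(0, 6), grid)
  expect_equal(unname(s3["acti_only"]), 0.2)
})

test_that("stronger multimodal events carry larger stratified counts", {
  # construction: all-three events get 5x the burst amplitude of acti-only ones
  base <- gravity_recording(300)
  strong_onsets <- c(30, 90, 150)   # seen by all three
  weak_onsets <- c(60, 120, 210)    # actigraphy only
  for (o in strong_onsets) base <- add_z_burst(base, o + 0.2, 1, 5)
  for (o in weak_onsets) base <- add_z_burst(base, o + 0.2, 1, 1)
  grid <- mini_epoch_grid(rem_periods_from_intervals(0, 300))
  cnt <- compute_activity_counts(base)
  acti <- epoch_activity(cnt, grid)
  in_epoch <- function(onsets) as.integer(grid$start %in% onsets)
  emg <- in_epoch(strong_onsets); video <- in_epoch(strong_onsets)
  s <- stratified_activity_counts(cnt, emg, acti, video, grid)
  expect_gt(s["all_three"], s["acti_only"])
})

test_that("participant bootstrap is percentile-based, seeded, and collapses on ties", {
  ci_const <- bootstrap_group_ci(rep(3.3, 5), B = 200, seed = 1)
  expect_equal(ci_const$lower, 3.3)
  expect_equal(ci_const$upper, 3.3)

  v <- c(0.25, 0.08, 0.40, 0.34, 0.27, 0.39, 0.24, 0.19, 0.27)
  c1 <- bootstrap_group_ci(v, B = 2000, seed = 7)
  c2 <- bootstrap_group_ci(v, B = 2000, seed = 7)
  expect_identical(c1, c2)
  c3 <- bootstrap_group_ci(v, B = 2000, seed = 8)
  expect_false(identical(c1$lower, c3$lower))
  expect_lte(c1$lower, c1$estimate); expect_gte(c1$upper, c1$estimate)

  expect_error(bootstrap_group_ci(c(1, NA)), "at least two")
})
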