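#' 2x2 contingency table of two binary label vectors
#'
#' Orientation convention: the first modality indexes rows, the second
#' columns; `a` = both active, `b` = first only, `c` = second only, `d` =
#' neither.
#'
#' @param first,second Binary vectors (or [modality_labels()]) on one grid;
#'   alternatively supply counts via `a`, `b`, `c`, `d`.
#' @param a,b,c,d Cell counts (used when `first` is missing).
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(first = NULL, second = NULL,
                            a = NULL, b = NULL, c = NULL, d = NULL) {
  if (!is.null(first)) {
    f <- as_label_vector(first); s <- as_label_vector(second)
    if (length(f) != length(s)) {
      stopf("label vectors differ in length (%d vs %d)", length(f), length(s))
    }
    a <- sum(f == 1 & s == 1); b <- sum(f == 1 & s == 0)
    c <- sum(f == 0 & s == 1); d <- sum(f == 0 & s == 0)
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stopf("cell counts must be non-negative")
  structure(as.list(cells), n = sum(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<2x2> a=%g b=%g c=%g d=%g (n=%g)\n", x$a, x$b, x$c, x$d,
              attr(x, "n")))
  invisible(x)
}

transpose_2x2 <- function(t) contingency_2x2(a = t$a, b = t$c, c = t$b, d = t$d)

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (a + d)/n` and chance agreement
#' `p_e = [(a+b)(a+c) + (c+d)(b+d)] / n^2`. When both raters are constant
#' (`p_e = 1`) kappa is undefined and `NA` is returned with a warning.
#'
#' @param t A [contingency_2x2()].
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohens_kappa <- function(t) {
  n <- attr(t, "n")
  if (n == 0) stopf("empty table")
  po <- (t$a + t$d) / n
  pe <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    warning("both raters are constant; kappa is undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Directional conditional probabilities of co-detection
#'
#' For a table with first modality A (rows) and second modality B (columns):
#' `P(A=1|B=1) = a/(a+c)`, `P(B=1|A=1) = a/(a+b)`, `P(A=0|B=0) = d/(b+d)`,
#' `P(B=0|A=0) = d/(c+d)`. A probability whose conditioning margin is zero is
#' returned as `NA`, never as a division by zero.
#'
#' @param t A [contingency_2x2()].
#' @return Named numeric vector
#'   `c(p_first1_given_second1, p_second1_given_first1,
#'      p_first0_given_second0, p_second0_given_first0)`.
#' @export
conditional_probs <- function(t) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(p_first1_given_second1 = safe(t$a, t$a + t$c),
    p_second1_given_first1 = safe(t$a, t$a + t$b),
    p_first0_given_second0 = safe(t$d, t$b + t$d),
    p_second0_given_first0 = safe(t$d, t$c + t$d))
}

#' Mantel-Haenszel pooled odds ratio across participants
#'
#' Pools per-participant 2x2 tables with the Mantel-Haenszel estimator. Any
#' table containing a zero cell receives the Haldane-Anscombe 0.5 continuity
#' correction (added to all four of its cells). The confidence interval comes
#' from the Robins-Breslow-Greenland variance of the log odds ratio.
#'
#' @param tables List of [contingency_2x2()] tables (one per participant).
#' @param conf Confidence level (default 0.95).
#' @param correction Apply the Haldane-Anscombe correction to zero-cell
#'   tables (default `TRUE`).
#' @return List with `or`, `log_or`, `se_log_or`, `ci` (length-2), `conf`,
#'   `n_tables`.
#' @export
pooled_odds_ratio <- function(tables, conf = 0.95, correction = TRUE) {
  if (length(tables) == 0) stopf("need at least one table")
  cells <- lapply(tables, function(t) {
    v <- c(t$a, t$b, t$c, t$d)
    if (correction && any(v == 0)) v <- v + 0.5
    v
  })
  m <- do.call(rbind, cells)
  n <- rowSums(m)
  ok <- n > 0
  if (!any(ok)) stopf("all tables are empty")
  m <- m[ok, , drop = FALSE]; n <- n[ok]
  a <- m[, 1]; b <- m[, 2]; c <- m[, 3]; d <- m[, 4]
  R <- a * d / n; S <- b * c / n
  if (sum(R) == 0 || sum(S) == 0) {
    stopf("all tables are degenerate; the pooled odds ratio is undefined")
  }
  or <- sum(R) / sum(S)
  P <- (a + d) / n; Q <- (b + c) / n
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  se <- sqrt(var_log)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, log_or = log(or), se_log_or = se,
       ci = exp(log(or) + c(-1, 1) * z * se), conf = conf,
       n_tables = length(tables))
}

#' Three-modality overlap decomposition
#'
#' Exclusive region counts of mini-epochs with activity detected by exactly
#' one modality, each pair, or all three, plus marginals, the active union,
#' and the count with no activity. Conservation (regions + none = n) is
#' asserted on every call.
#'
#' @param emg,acti,video Binary vectors or [modality_labels()] on one grid.
#' @return An object of class `overlap_counts`: list with `n_total`,
#'   `regions` (named: `emg_only`, `acti_only`, `video_only`, `emg_acti`,
#'   `emg_video`, `acti_video`, `all_three`), `none_active`, `marginals`,
#'   `union_active`.
#' @export
overlap_regions <- function(emg, acti, video) {
  e <- as_label_vector(emg); a <- as_label_vector(acti); v <- as_label_vector(video)
  n <- length(e)
  if (length(a) != n || length(v) != n) {
    stopf("label vectors differ in length (%d, %d, %d)", n, length(a), length(v))
  }
  regions <- c(
    emg_only   = sum(e & !a & !v),
    acti_only  = sum(!e & a & !v),
    video_only = sum(!e & !a & v),
    emg_acti   = sum(e & a & !v),
    emg_video  = sum(e & !a & v),
    acti_video = sum(!e & a & v),
    all_three  = sum(e & a & v)
  )
  none <- sum(!e & !a & !v)
  stopifnot(sum(regions) + none == n)
  out <- list(
    n_total = n, regions = regions, none_active = none,
    marginals = c(emg = sum(e), acti = sum(a), video = sum(v)),
    union_active = sum(e | a | v)
  )
  stopifnot(out$union_active == sum(regions))
  structure(out, class = "overlap_counts")
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat(sprintf("<overlap_counts> n=%d, union=%d (EMG=%d, Acti=%d, Video=%d)\n",
              x$n_total, x$union_active, x$marginals["emg"],
              x$marginals["acti"], x$marginals["video"]))
  print(x$regions)
  invisible(x)
}

#' Pairwise 2x2 table from an overlap decomposition
#'
#' Collapses the seven-region decomposition to the 2x2 table of one modality
#' pair (first = rows).
#'
#' @param overlap An [overlap_regions()] result.
#' @param first,second Modality names among `"emg"`, `"acti"`, `"video"`.
#' @return A [contingency_2x2()].
#' @export
pair_table <- function(overlap, first, second) {
  r <- overlap$regions
  act <- function(m, e, a, v) switch(m, emg = e, acti = a, video = v)
  reg <- rbind(
    emg_only = c(1, 0, 0), acti_only = c(0, 1, 0), video_only = c(0, 0, 1),
    emg_acti = c(1, 1, 0), emg_video = c(1, 0, 1), acti_video = c(0, 1, 1),
    all_three = c(1, 1, 1))
  f <- reg[, match(first, c("emg", "acti", "video"))]
  s <- reg[, match(second, c("emg", "acti", "video"))]
  a <- sum(r[f == 1 & s == 1]); b <- sum(r[f == 1 & s == 0])
  c_ <- sum(r[f == 0 & s == 1])
  d <- overlap$none_active + sum(r[f == 0 & s == 0])
  contingency_2x2(a = a, b = b, c = c_, d = d)
}

#' Activity ratio
#'
#' Percentage of REM mini-epochs containing any detected activity.
#'
#' @param labels Binary vector or [modality_labels()].
#' @return Percentage in `[0, 100]`.
#' @export
activity_ratio <- function(labels) {
  l <- as_label_vector(labels)
  if (length(l) == 0) stopf("empty grid")
  100 * mean(l)
}

#' Activity rate (distinct motor events per REM hour)
#'
#' A motor event is a maximal run of consecutive active mini-epochs within a
#' single REM period (onset to offset, counted once regardless of duration);
#' runs never span periods. The rate divides the event count by the total
#' gridded REM time in hours.
#'
#' @param labels Binary vector or [modality_labels()] on the grid.
#' @param grid The [mini_epoch_grid()] the labels live on.
#' @return Events per hour, with attribute `n_events`.
#' @export
activity_rate <- function(labels, grid) {
  l <- as_label_vector(labels)
  if (length(l) != nrow(grid)) stopf("labels do not match the grid")
  hours <- sum(grid$end - grid$start) / 3600
  if (hours <= 0) stopf("zero REM duration")
  n_events <- sum(vapply(split(l, grid$period), function(v) {
    nrow(logical_runs(v == 1))
  }, numeric(1)))
  structure(n_events / hours, n_events = n_events)
}

#' Mean actigraphy counts stratified by multimodal consensus
#'
#' Splits actigraphy-active mini-epochs into the four mutually exclusive
#' consensus categories -- detected by all three modalities, by EMG and
#' actigraphy (no video), by actigraphy and video (no EMG), or by actigraphy
#' alone -- and returns the mean per-epoch actigraphy magnitude in each. An
#' empty category yields `NA`.
#'
#' @param counts An [activity_counts()] series (one wrist, or merged).
#' @param emg,acti,video Binary vectors or [modality_labels()] on `grid`.
#' @param grid The [mini_epoch_grid()].
#' @param summary Per-epoch magnitude: `"max"` (default) or `"mean"` of the
#'   epoch's 1 Hz counts.
#' @return Named numeric vector over `all_three`, `emg_acti`, `acti_video`,
#'   `acti_only`, with attribute `n_epochs` (per-category counts).
#' @export
stratified_activity_counts <- function(counts, emg, acti, video, grid,
                                       summary = c("max", "mean")) {
  e <- as_label_vector(emg) == 1
  a <- as_label_vector(acti) == 1
  v <- as_label_vector(video) == 1
  if (!any(a)) stopf("no actigraphy-active epochs to stratify")
  mag <- epoch_count_magnitude(counts, grid, summary = match.arg(summary))
  cats <- list(all_three = e & a & v, emg_acti = e & a & !v,
               acti_video = !e & a & v, acti_only = !e & a & !v)
  out <- vapply(cats, function(idx) if (any(idx)) mean(mag[idx]) else NA_real_,
                numeric(1))
  attr(out, "n_epochs") <- vapply(cats, sum, numeric(1))
  out
}

#' Participant-level bootstrap confidence interval
#'
#' Nonparametric bootstrap across participants: resamples the per-participant
#' values with replacement `B` times and returns the percentile interval of
#' the statistic. Deterministic for a fixed seed.
#'
#' @param values Per-participant numeric values (`NA`s dropped; at least two
#'   non-missing values required).
#' @param statistic Function of a numeric vector (default `mean`).
#' @param B Number of bootstrap resamples (default 10000).
#' @param seed RNG seed (default 1).
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`, `B`, `conf`, `n`.
#' @export
bootstrap_group_ci <- function(values, statistic = mean, B = 10000, seed = 1L,
                               conf = 0.95) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 2) stopf("need at least two non-missing values")
  stats_b <- with_seed(derive_seed(seed, "bootstrap"), {
    vapply(seq_len(B), function(i) statistic(v[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - conf) / 2
  q <- stats::quantile(stats_b, c(alpha, 1 - alpha), names = FALSE)
  list(estimate = statistic(v), lower = q[1], upper = q[2], B = B,
       conf = conf, n = n)
}
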