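#' Per-stage movement load for one participant
#'
#' Movement load is the sum of left and right wrist activity counts per
#' minute, within each sleep stage: the 1 Hz counts are attributed to 30 s
#' hypnogram epochs, summed over all epochs of a stage, and divided by the
#' stage's total minutes. A stage absent from the hypnogram yields `NA`
#' (never 0). With a single wrist the load is computed from that side alone
#' and the result carries attribute `unilateral = TRUE`.
#'
#' @param left,right [activity_counts()] series covering the hypnogram span
#'   (either may be `NULL`).
#' @param hyp A [hypnogram()].
#' @param stages Stages to report (default `N1, N2, N3, R`, plus `W` when
#'   `include_wake`).
#' @param include_wake Also report wake (default `TRUE`; wake is reported but
#'   conventionally excluded from hypothesis testing).
#' @return Named numeric vector of counts/min per stage.
#' @export
movement_load <- function(left, right, hyp,
                          stages = c("N1", "N2", "N3", "R"),
                          include_wake = TRUE) {
  if (is.null(left) && is.null(right)) stopf("at least one wrist is required")
  if (include_wake) stages <- unique(c(stages, "W"))
  n_sec <- length(hyp) * hyp$epoch_len
  total <- numeric(n_sec)
  for (cnt in list(left, right)) {
    if (is.null(cnt)) next
    if (length(cnt) < n_sec) stopf("counts do not cover the hypnogram span")
    total <- total + cnt$values[seq_len(n_sec)]
  }
  sec_stage <- rep(hyp$stages, each = hyp$epoch_len)
  out <- vapply(stages, function(s) {
    idx <- sec_stage == s
    if (!any(idx)) return(NA_real_)
    sum(total[idx]) / (sum(idx) / 60)
  }, numeric(1))
  attr(out, "unilateral") <- is.null(left) || is.null(right)
  out
}

#' Build a participants-by-stages movement-load table
#'
#' @param loads List of per-participant named load vectors from
#'   [movement_load()].
#' @return Numeric matrix, rows = participants, columns = stages.
#' @export
movement_load_table <- function(loads) {
  stages <- unique(unlist(lapply(loads, names)))
  m <- t(vapply(loads, function(l) l[stages], numeric(length(stages))))
  colnames(m) <- stages
  rownames(m) <- names(loads) %||% seq_along(loads)
  m
}

# Exact-friendly paired Wilcoxon signed-rank p value; zeros dropped.
paired_wilcoxon_p <- function(x, y, exact_max_n = 25) {
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (length(d) == 0) return(list(statistic = NA_real_, p = 1))
  exact <- length(d) <= exact_max_n && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Pairwise stage comparisons of movement load (Wilcoxon + Holm)
#'
#' Within-participant paired comparisons of movement load between sleep
#' stages using Wilcoxon signed-rank tests (exact distribution for small
#' samples without ties; zero differences dropped), with Holm step-down
#' adjustment across the tested pairs.
#'
#' @param load_table Matrix from [movement_load_table()] (rows =
#'   participants).
#' @param stage_pairs List of length-2 character vectors; default: all 6
#'   pairwise combinations of `N1, N2, N3, R` present in the table.
#' @param method Adjustment method, `"holm"` (default) or `"BH"`.
#' @return data.frame of class `stat_results` with columns `comparison`,
#'   `stage_a`, `stage_b`, `n`, `statistic`, `p`, `p_adj`, `method`.
#' @export
wilcoxon_holm <- function(load_table, stage_pairs = NULL, method = "holm") {
  if (is.null(stage_pairs)) {
    st <- intersect(c("N1", "N2", "N3", "R"), colnames(load_table))
    stage_pairs <- utils::combn(st, 2, simplify = FALSE)
  }
  rows <- lapply(stage_pairs, function(pr) {
    x <- load_table[, pr[1]]; y <- load_table[, pr[2]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) stopf("fewer than two participants with both %s and %s",
                           pr[1], pr[2])
    w <- paired_wilcoxon_p(x[ok], y[ok])
    data.frame(comparison = paste(pr[1], "vs", pr[2]),
               stage_a = pr[1], stage_b = pr[2], n = sum(ok),
               statistic = w$statistic, p = w$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = method)
  out$method <- method
  class(out) <- c("stat_results", "data.frame")
  out
}

#' Mann-Whitney U test with Cliff's delta
#'
#' Two-sided between-group comparison (exact for small samples without ties,
#' tie-corrected normal approximation otherwise) with the nonparametric
#' effect size `delta = [#(a > b) - #(a < b)] / (n_a * n_b)`.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `statistic` (U for `group_a`), `p`, `delta`, `n_a`,
#'   `n_b`.
#' @export
mannwhitney_cliffs <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) == 0 || length(b) == 0) stopf("both groups must be non-empty")
  exact <- (length(a) + length(b)) <= 50 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
  cmp <- sign(outer(a, b, "-"))
  delta <- sum(cmp) / (length(a) * length(b))
  list(statistic = unname(wt$statistic), p = wt$p.value, delta = delta,
       n_a = length(a), n_b = length(b))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values with monotonicity enforcement.
#'
#' @param p Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
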