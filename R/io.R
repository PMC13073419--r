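#' Read a tri-axial accelerometer CSV
#'
#' Expected header `time_s,x_g,y_g,z_g` with monotone time. The sampling rate
#' is inferred from the median time step; visibly non-uniform input is
#' resampled onto a uniform grid with a warning.
#'
#' @param path CSV file path.
#' @param side `"L"` or `"R"`.
#' @param dynamic_range Device range in g.
#' @return A [triaxial_recording()].
#' @export
read_accel_csv <- function(path, side = "L", dynamic_range = 8) {
  df <- utils::read.csv(path)
  need <- c("time_s", "x_g", "y_g", "z_g")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stopf("%s: missing column(s) %s", path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stopf("%s: empty recording", path)
  dt <- diff(df$time_s)
  if (length(dt) > 0 && any(dt <= 0)) {
    stopf("%s: time is not strictly increasing at line %d", path,
          which(dt <= 0)[1] + 2L)  # +1 header, +1 for the second point
  }
  rate <- if (length(dt) > 0) 1 / stats::median(dt) else 1
  # snap to an integer rate when the written timestamps round-trip imprecisely
  if (abs(rate - round(rate)) / rate < 1e-4) rate <- round(rate)
  vals <- df[, c("x_g", "y_g", "z_g")]
  if (length(dt) > 0 && (max(dt) - min(dt)) > 1e-6 / rate + 1e-9) {
    warning(sprintf("%s: non-uniform sampling; resampling to %.6g Hz", path, rate))
    grid <- seq(df$time_s[1], df$time_s[nrow(df)], by = 1 / rate)
    vals <- as.data.frame(lapply(vals, function(v) {
      stats::approx(df$time_s, v, xout = grid, rule = 2)$y
    }))
  }
  triaxial_recording(vals$x_g, vals$y_g, vals$z_g, rate = rate,
                     start_time = df$time_s[1], side = side,
                     dynamic_range = dynamic_range)
}

#' Write a tri-axial recording as CSV
#' @param rec A [triaxial_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(rec, path) {
  t <- rec$start_time + (seq_len(length(rec)) - 1) / rec$rate
  df <- data.frame(time_s = t, x_g = rec$x, y_g = rec$y, z_g = rec$z)
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.stage_aliases <- c(W = "W", WAKE = "W", N1 = "N1", N2 = "N2", N3 = "N3",
                    SWS = "N3", R = "R", REM = "R")

#' Read a hypnogram TSV
#'
#' Two tab-separated columns `epoch_index` and `stage`; stages from
#' `W, N1, N2, N3, R` with the aliases `REM` (R), `SWS` (N3) and `Wake` (W)
#' accepted.
#'
#' @param path TSV file path.
#' @return A [hypnogram()] of 30 s epochs.
#' @export
read_hypnogram_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stopf("%s: expected columns epoch_index and stage", path)
  }
  df <- df[order(df$epoch_index), , drop = FALSE]
  lab <- toupper(trimws(df$stage))
  unknown <- setdiff(unique(lab), names(.stage_aliases))
  if (length(unknown) > 0) {
    stopf("%s: unknown stage label(s): %s", path, paste(unknown, collapse = ", "))
  }
  hypnogram(unname(.stage_aliases[lab]))
}

#' Write a hypnogram TSV
#' @param hyp A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_tsv <- function(hyp, path) {
  utils::write.table(
    data.frame(epoch_index = seq_along(hyp$stages) - 1L, stage = hyp$stages),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-mini-epoch annotation labels
#'
#' Tab-separated columns `epoch_start_s` and `label` (0/1), one row per grid
#' mini-epoch.
#'
#' @param path TSV file path.
#' @param grid The [mini_epoch_grid()] the labels belong to.
#' @param modality,side Passed to [modality_labels()].
#' @return A [modality_labels()].
#' @export
read_labels_tsv <- function(path, grid, modality, side = "merged") {
  df <- utils::read.delim(path)
  if (!all(c("epoch_start_s", "label") %in% names(df))) {
    stopf("%s: expected columns epoch_start_s and label", path)
  }
  if (nrow(df) != nrow(grid)) {
    stopf("%s: %d rows but the grid has %d mini-epochs", path, nrow(df), nrow(grid))
  }
  df <- df[order(df$epoch_start_s), , drop = FALSE]
  if (nrow(df) > 0 && max(abs(df$epoch_start_s - grid$start)) > 1e-6) {
    stopf("%s: epoch start times do not match the grid", path)
  }
  modality_labels(df$label, modality, side)
}

#' Write per-mini-epoch annotation labels
#' @param labels A [modality_labels()].
#' @param grid The matching [mini_epoch_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, grid, path) {
  utils::write.table(
    data.frame(epoch_start_s = grid$start, label = as_label_vector(labels)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated participant to disk
#'
#' Writes per-side accelerometer CSVs, the hypnogram TSV, EMG envelope CSVs,
#' video annotation TSV, the latent-event truth TSV, and a JSON manifest
#' naming all files together with the device rate, range and seed.
#'
#' @param sim Result of [simulate_participant()].
#' @param dir Output directory (created if needed).
#' @param participant Participant identifier used in the manifest.
#' @return Path to the manifest JSON, invisibly.
#' @export
write_simulation <- function(sim, dir, participant = "sim01") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(dir, name)
  write_accel_csv(sim$accel$L, p("accel_L.csv"))
  write_accel_csv(sim$accel$R, p("accel_R.csv"))
  write_hypnogram_tsv(sim$hypnogram, p("hypnogram.tsv"))
  for (s in c("L", "R")) {
    env <- sim$emg[[s]]
    utils::write.table(
      data.frame(time_s = (seq_along(env$values) - 1) / env$rate,
                 amplitude_uv = env$values),
      p(sprintf("emg_envelope_%s.csv", s)), sep = ",", row.names = FALSE,
      quote = FALSE)
  }
  write_labels_tsv(sim$video, sim$grid, p("video_labels.tsv"))
  utils::write.table(sim$events, p("latent_events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(
    participant = participant,
    device_rate = sim$config$device_rate,
    device_range = sim$config$device_range,
    emg_rate = sim$config$emg_rate,
    seed = sim$seed,
    sync_offsets = list(accel_L = 0, accel_R = 0),
    files = list(
      accel_L = "accel_L.csv", accel_R = "accel_R.csv",
      hypnogram = "hypnogram.tsv",
      emg_envelope_L = "emg_envelope_L.csv",
      emg_envelope_R = "emg_envelope_R.csv",
      video_labels = "video_labels.tsv",
      latent_events = "latent_events.tsv"
    )
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(p("manifest.json"))
}

#' Read a recording manifest
#'
#' @param path Manifest JSON path; file paths inside are resolved relative to
#'   the manifest's directory and checked for existence.
#' @return Manifest list with an added `dir` element.
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  man$dir <- dirname(path)
  for (f in unlist(man$files)) {
    fp <- file.path(man$dir, f)
    if (!file.exists(fp)) stopf("manifest references a missing file: %s", fp)
  }
  man
}

#' Run the full per-participant analysis
#'
#' Executes the whole pipeline for one manifest: activity counts per wrist,
#' REM-period selection and mini-epoch gridding, per-modality labels
#' (actigraphy from counts, EMG from envelope scoring or annotations, video
#' from annotations), side merging, cross-modality concordance, activity
#' burden, consensus-stratified counts, and per-stage movement load. Streams
#' absent from the manifest degrade gracefully: pairs involving a missing
#' modality are `NA`-flagged rather than computed.
#'
#' @param manifest A manifest list from [read_manifest()].
#' @param spec A [filter_spec()].
#' @param target_rate Harmonized accelerometer rate (Hz).
#' @param calibrate Autocalibrate recordings (default `TRUE`).
#' @return A list bundle: `participant`, `periods`, `grid`, `labels` (merged
#'   per modality), `overlap`, `pairs` (per-pair kappa, conditional
#'   probabilities, 2x2 tables), `burden` (ratio/rate per modality),
#'   `stratified`, `movement_load`, `provenance`.
#' @export
run_full_analysis <- function(manifest, spec = filter_spec(), target_rate = 25,
                              calibrate = TRUE) {
  dir <- manifest$dir %||% "."
  fp <- function(name) {
    f <- manifest$files[[name]]
    if (is.null(f)) NULL else file.path(dir, f)
  }
  hyp <- read_hypnogram_tsv(fp("hypnogram"))
  periods <- rem_periods(hyp)
  grid <- mini_epoch_grid(periods)

  counts <- list()
  acti_labels <- list()
  for (s in c("L", "R")) {
    f <- fp(paste0("accel_", s))
    if (is.null(f)) next
    rec <- read_accel_csv(f, side = s,
                          dynamic_range = manifest$device_range %||% 8)
    off <- manifest$sync_offsets[[paste0("accel_", s)]] %||% 0
    rec$start_time <- rec$start_time - off
    counts[[s]] <- compute_activity_counts(rec, spec, target_rate,
                                           calibrate = calibrate)
    acti_labels[[s]] <- epoch_activity(counts[[s]], grid)
  }
  labels <- list()
  if (length(acti_labels) == 2) {
    labels$acti <- merge_bilateral(acti_labels$L, acti_labels$R)
  } else if (length(acti_labels) == 1) {
    labels$acti <- acti_labels[[1]]
  }

  emg_sides <- list()
  for (s in c("L", "R")) {
    f <- fp(paste0("emg_envelope_", s))
    if (is.null(f)) next
    df <- utils::read.csv(f)
    rate <- manifest$emg_rate %||% (1 / stats::median(diff(df$time_s)))
    env <- emg_envelope(df$amplitude_uv, rate = rate, side = s)
    emg_sides[[s]] <- score_emg_mini_epochs(env, periods, grid)
  }
  if (length(emg_sides) == 2) {
    labels$emg <- merge_bilateral(emg_sides$L, emg_sides$R)
  } else if (length(emg_sides) == 1) {
    labels$emg <- emg_sides[[1]]
  } else if (!is.null(fp("emg_labels"))) {
    labels$emg <- read_labels_tsv(fp("emg_labels"), grid, "emg")
  }
  if (!is.null(fp("video_labels"))) {
    labels$video <- read_labels_tsv(fp("video_labels"), grid, "video")
  }

  modalities <- intersect(c("emg", "acti", "video"), names(labels))
  overlap <- if (length(modalities) == 3) {
    overlap_regions(labels$emg, labels$acti, labels$video)
  } else NULL

  pair_names <- list(c("emg", "acti"), c("emg", "video"), c("acti", "video"))
  pairs <- lapply(pair_names, function(pr) {
    nm <- paste(pr, collapse = "_")
    if (!all(pr %in% modalities) || nrow(grid) == 0) {
      return(list(pair = nm, available = FALSE, kappa = NA_real_,
                  probs = NULL, table = NULL))
    }
    t <- contingency_2x2(labels[[pr[1]]], labels[[pr[2]]])
    list(pair = nm, available = TRUE, kappa = cohens_kappa(t),
         probs = conditional_probs(t), table = t)
  })
  names(pairs) <- vapply(pairs, `[[`, character(1), "pair")

  burden <- lapply(labels, function(l) {
    if (nrow(grid) == 0) {
      return(list(ratio = NA_real_, rate = NA_real_))  # night without usable REM
    }
    list(ratio = activity_ratio(l),
         rate = as.numeric(activity_rate(l, grid)))
  })

  stratified <- if (length(modalities) == 3 && length(counts) > 0 &&
                    sum(as_label_vector(labels$acti)) > 0) {
    cmerged <- if (length(counts) == 2) sum_counts(counts$L, counts$R) else counts[[1]]
    stratified_activity_counts(cmerged, labels$emg, labels$acti, labels$video, grid)
  } else NULL

  load <- if (length(counts) > 0) {
    movement_load(counts$L %||% NULL, counts$R %||% NULL, hyp)
  } else NULL

  list(
    participant = manifest$participant %||% NA_character_,
    periods = periods, grid = grid, labels = labels, overlap = overlap,
    pairs = pairs, burden = burden, stratified = stratified,
    movement_load = load,
    provenance = list(
      package_version = as.character(utils::packageVersion("remmotor")),
      target_rate = target_rate, calibrated = calibrate,
      filter_spec = unclass(spec), seed = manifest$seed %||% NA,
      n_mini_epochs = nrow(grid))
  )
}

#' Write an analysis bundle to disk
#'
#' Tidy TSV tables (overlap regions, pairwise agreement, burden, movement
#' load) plus a JSON summary carrying the provenance block. Rerunning with an
#' identical bundle reproduces byte-identical output.
#'
#' @param bundle Result of [run_full_analysis()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$overlap)) {
    utils::write.table(
      data.frame(region = c(names(bundle$overlap$regions), "none_active"),
                 count = c(unname(bundle$overlap$regions),
                           bundle$overlap$none_active)),
      file.path(dir, "overlap_regions.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  pair_df <- do.call(rbind, lapply(bundle$pairs, function(p) {
    data.frame(pair = p$pair, available = p$available, kappa = p$kappa,
               p_first1_given_second1 = p$probs[["p_first1_given_second1"]] %||% NA,
               p_second1_given_first1 = p$probs[["p_second1_given_first1"]] %||% NA)
  }))
  utils::write.table(pair_df, file.path(dir, "pairwise_agreement.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (length(bundle$burden) > 0) {
    bd <- do.call(rbind, lapply(names(bundle$burden), function(m) {
      data.frame(modality = m, activity_ratio_pct = bundle$burden[[m]]$ratio,
                 activity_rate_per_h = bundle$burden[[m]]$rate)
    }))
    utils::write.table(bd, file.path(dir, "activity_burden.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(bundle$movement_load)) {
    utils::write.table(
      data.frame(stage = names(bundle$movement_load),
                 load_counts_per_min = unname(bundle$movement_load)),
      file.path(dir, "movement_load.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  summary <- list(
    participant = bundle$participant,
    n_mini_epochs = nrow(bundle$grid),
    n_rem_periods = nrow(bundle$periods),
    kappa = lapply(bundle$pairs, `[[`, "kappa"),
    burden = bundle$burden,
    stratified = as.list(bundle$stratified),
    movement_load = as.list(bundle$movement_load),
    provenance = bundle$provenance
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       na = "null")
  invisible(dir)
}

#' Reference cohort summary tables
#'
#' Per-participant summary statistics of a nine-participant RBD reference
#' cohort with synchronized EMG, actigraphy, and video: sleep architecture
#' (total sleep and REM minutes, REM period counts), pairwise Cohen's kappa,
#' activity ratio/rate per modality, and the pooled three-modality overlap
#' region counts. Shipped as plain CSV under `inst/extdata/` and used by the
#' worked examples and the acceptance script.
#'
#' @return Named list of data.frames: `sleep`, `kappa`, `burden`, `overlap`.
#' @export
reference_cohort <- function() {
  p <- function(f) system.file("extdata", f, package = "remmotor", mustWork = TRUE)
  list(
    sleep = utils::read.csv(p("cohort_sleep_architecture.csv")),
    kappa = utils::read.csv(p("cohort_kappa.csv")),
    burden = utils::read.csv(p("cohort_activity_burden.csv")),
    overlap = utils::read.csv(p("cohort_overlap_regions.csv"))
  )
}
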