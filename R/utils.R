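# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Named sub-streams so one global seed expands into independently reproducible
# per-stream seeds (hypnogram, events, noise, detections, ...). Kept < 2^31.
.stream_ids <- c(
  hypnogram = 1L, events = 2L, noise_L = 3L, noise_R = 4L,
  emg_L = 5L, emg_R = 6L, detect_emg = 7L, detect_acti = 8L,
  detect_video = 9L, bootstrap = 10L
)

derive_seed <- function(seed, stream) {
  id <- .stream_ids[[stream]]
  if (is.null(id)) stop("unknown RNG stream: ", stream)
  ((as.integer(seed) %% 599479L) * 3581L + id * 7919L + 17L) %% 2147483629L
}

# Maximal runs of TRUE in a logical vector: data.frame(start_idx, end_idx, length)
logical_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

# Raised-cosine (Hann) envelope on [0, 1], peak 1 at the midpoint.
raised_cosine <- function(u) {
  out <- numeric(length(u))
  inside <- u >= 0 & u <= 1
  out[inside] <- 0.5 * (1 - cos(2 * pi * u[inside]))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
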