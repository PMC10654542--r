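# Threshold-based vocalization detection: a clip is flagged voiced when the
# time its rectified amplitude spends above a volume threshold exceeds a
# time threshold. Calibration is a constrained grid search (miss rate at
# most 5% in-sample, then fewest false alarms), evaluated by Monte Carlo
# cross-validation.

#' Construct an audio clip
#'
#' @param samples Numeric amplitude sequence, arbitrary units.
#' @param sample_rate Sampling rate, Hz, > 0.
#' @param label `"voiced"`, `"unvoiced"`, or `"unknown"`.
#' @return Object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate,
                       label = c("unknown", "voiced", "unvoiced")) {
  label <- match.arg(label)
  stopifnot(sample_rate > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 label = label), class = "audio_clip")
}

#' Detection threshold pair
#'
#' @param volume_threshold Amplitude threshold, arbitrary units, > 0.
#' @param time_threshold Duration threshold, seconds, > 0.
#' @return Object of class `detection_thresholds`.
#' @export
detection_thresholds <- function(volume_threshold, time_threshold) {
  stopifnot(volume_threshold > 0, time_threshold > 0)
  structure(list(volume_threshold = volume_threshold,
                 time_threshold = time_threshold),
            class = "detection_thresholds")
}

supra_duration <- function(clip, volume_threshold) {
  sum(abs(clip$samples) > volume_threshold) / clip$sample_rate
}

#' Detect a voiced event in a clip
#'
#' Counts samples whose rectified amplitude strictly exceeds the volume
#' threshold; the clip is retained when that count, converted to seconds,
#' strictly exceeds the time threshold. An empty clip is never detected.
#'
#' @param clip An [audio_clip()].
#' @param thresholds A [detection_thresholds()].
#' @return Logical.
#' @export
detect_event <- function(clip, thresholds) {
  if (length(clip$samples) == 0L) return(FALSE)
  supra_duration(clip, thresholds$volume_threshold) >
    thresholds$time_threshold
}

#' Miss and false-alarm rates of the detector
#'
#' @param clips List of [audio_clip()]s.
#' @param labels Character vector, `"voiced"`/`"unvoiced"`, one per clip;
#'   defaults to the clips' own labels.
#' @param thresholds A [detection_thresholds()].
#' @return List with `miss_rate` (voiced clips not detected) and
#'   `false_alarm_rate` (unvoiced clips detected).
#' @export
confusion_rates <- function(clips, labels = NULL, thresholds) {
  if (is.null(labels)) labels <- vapply(clips, `[[`, "", "label")
  if (any(!labels %in% c("voiced", "unvoiced"))) {
    stop("labels must be 'voiced' or 'unvoiced'")
  }
  if (!any(labels == "voiced") || !any(labels == "unvoiced")) {
    stop("need at least one voiced and one unvoiced clip")
  }
  det <- vapply(clips, detect_event, logical(1), thresholds = thresholds)
  list(miss_rate = mean(!det[labels == "voiced"]),
       false_alarm_rate = mean(det[labels == "unvoiced"]))
}

#' Default volume-threshold grid
#'
#' 20 log-spaced points spanning the clips' rectified amplitude range.
#'
#' @param clips List of [audio_clip()]s.
#' @param n Number of grid points.
#' @return Numeric vector.
#' @export
default_volume_grid <- function(clips, n = 20L) {
  amps <- unlist(lapply(clips, function(c) max(abs(c$samples))))
  lo <- max(min(amps) * 0.05, 1e-6)
  hi <- max(amps)
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Default time-threshold grid
#'
#' @return 0.01 to 0.2 s in 0.01 s steps.
#' @export
default_time_grid <- function() seq(0.01, 0.2, by = 0.01)

# n_clips x n_volumes matrix of supra-threshold durations; detection for a
# tuple (v, t) is D[, v] > t, making grid evaluation a matrix comparison.
supra_duration_matrix <- function(clips, volume_grid) {
  vapply(volume_grid,
         function(v) vapply(clips, supra_duration, numeric(1),
                            volume_threshold = v),
         numeric(length(clips)))
}

grid_rates <- function(D, labels, volume_grid, time_grid) {
  pos <- labels == "voiced"
  grid <- expand.grid(vi = seq_along(volume_grid), ti = seq_along(time_grid))
  miss <- fa <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    det <- D[, grid$vi[g]] > time_grid[grid$ti[g]]
    miss[g] <- mean(!det[pos])
    fa[g] <- mean(det[!pos])
  }
  cbind(grid, miss = miss, fa = fa)
}

#' Constrained grid-search calibration of the detector
#'
#' Among all threshold tuples on the grid whose in-sample miss rate is at
#' most `max_miss`, returns the tuple with the lowest false-alarm rate. Ties
#' are broken deterministically in favor of the highest volume threshold,
#' then the highest time threshold (the more conservative detector).
#'
#' @param clips List of [audio_clip()]s.
#' @param labels Labels (see [confusion_rates()]); defaults to clip labels.
#' @param volume_grid Volume thresholds to search; default
#'   [default_volume_grid()].
#' @param time_grid Time thresholds to search; default [default_time_grid()].
#' @param max_miss Maximum admissible in-sample miss rate (default 0.05).
#' @return A [detection_thresholds()] with attributes `miss_rate` and
#'   `false_alarm_rate` (in-sample).
#' @export
grid_search_calibrate <- function(clips, labels = NULL,
                                  volume_grid = default_volume_grid(clips),
                                  time_grid = default_time_grid(),
                                  max_miss = 0.05) {
  stopifnot(length(volume_grid) > 0, length(time_grid) > 0)
  if (is.null(labels)) labels <- vapply(clips, `[[`, "", "label")
  D <- supra_duration_matrix(clips, volume_grid)
  rates <- grid_rates(D, labels, volume_grid, time_grid)
  feas <- rates[rates$miss <= max_miss, , drop = FALSE]
  if (nrow(feas) == 0L) {
    stop("infeasible-calibration: no threshold tuple achieves miss rate <= ",
         max_miss)
  }
  best <- feas[feas$fa == min(feas$fa), , drop = FALSE]
  best <- best[order(-volume_grid[best$vi], -time_grid[best$ti]), ,
               drop = FALSE][1L, ]
  out <- detection_thresholds(volume_grid[best$vi], time_grid[best$ti])
  attr(out, "miss_rate") <- best$miss
  attr(out, "false_alarm_rate") <- best$fa
  out
}

#' Monte Carlo cross-validation of the calibrated detector
#'
#' Per repetition, a random `1/k` of the clips is held out, the grid search
#' is calibrated on the remainder, and miss/false-alarm rates are evaluated
#' on the holdout. When a repetition's training split admits no feasible
#' tuple, the least-miss tuple is used and the repetition is logged.
#'
#' @param clips List of [audio_clip()]s.
#' @param labels Labels; defaults to clip labels.
#' @param k Fold divisor: holdout fraction is exactly `1/k`.
#' @param reps Number of Monte Carlo repetitions.
#' @param max_miss Miss-rate constraint for the grid search.
#' @param volume_grid,time_grid Search grids; defaults as in
#'   [grid_search_calibrate()] (the volume grid is built on the full set).
#' @param seed Optional integer seed.
#' @return List of class `cv_result`: `mean_miss_rate`,
#'   `mean_false_alarm_rate`, per-repetition `miss_rates` and
#'   `false_alarm_rates`, and `infeasible_reps`.
#' @export
monte_carlo_cv <- function(clips, labels = NULL, k = 5L, reps = 1000L,
                           max_miss = 0.05,
                           volume_grid = default_volume_grid(clips),
                           time_grid = default_time_grid(),
                           seed = NULL) {
  if (is.null(labels)) labels <- vapply(clips, `[[`, "", "label")
  n <- length(clips)
  pos_n <- sum(labels == "voiced"); neg_n <- sum(labels == "unvoiced")
  if (pos_n < k || neg_n < k) {
    stop("need at least k clips of each label")
  }
  if (!is.null(seed)) set.seed(seed)
  D <- supra_duration_matrix(clips, volume_grid)
  n_hold <- max(1L, floor(n / k))
  miss <- fa <- numeric(reps)
  infeasible <- integer(0)
  pos <- labels == "voiced"
  for (r in seq_len(reps)) {
    hold <- sample.int(n, n_hold)
    train <- setdiff(seq_len(n), hold)
    # guard: both classes must appear in train and holdout
    if (!any(pos[train]) || !any(!pos[train]) ||
        !any(pos[hold]) || !any(!pos[hold])) {
      miss[r] <- NA; fa[r] <- NA
      next
    }
    rates <- grid_rates(D[train, , drop = FALSE], labels[train],
                        volume_grid, time_grid)
    feas <- rates[rates$miss <= max_miss, , drop = FALSE]
    if (nrow(feas) == 0L) {
      infeasible <- c(infeasible, r)
      feas <- rates[rates$miss == min(rates$miss), , drop = FALSE]
    }
    best <- feas[feas$fa == min(feas$fa), , drop = FALSE]
    best <- best[order(-volume_grid[best$vi], -time_grid[best$ti]), ,
                 drop = FALSE][1L, ]
    det <- D[hold, best$vi] > time_grid[best$ti]
    hp <- pos[hold]
    miss[r] <- mean(!det[hp])
    fa[r] <- mean(det[!hp])
  }
  structure(list(mean_miss_rate = mean(miss, na.rm = TRUE),
                 mean_false_alarm_rate = mean(fa, na.rm = TRUE),
                 miss_rates = miss, false_alarm_rates = fa,
                 infeasible_reps = infeasible),
            class = "cv_result")
}

#' Generate synthetic labeled audio clips
#'
#' Unvoiced clips are Gaussian background noise; voiced clips add one or
#' more vocalization bursts (amplitude-modulated tone segments) of random
#' duration and placement. Labels are exact by construction.
#'
#' @param n Number of clips (> 0); half voiced by default.
#' @param prop_voiced Proportion of voiced clips.
#' @param burst_amp Burst peak amplitude, arbitrary units.
#' @param burst_dur Range `c(min, max)` of burst duration, seconds.
#' @param noise_sd Background noise standard deviation, arbitrary units.
#' @param duration Clip duration, seconds.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Optional integer seed.
#' @return List of [audio_clip()]s.
#' @export
synth_audio <- function(n, prop_voiced = 0.5, burst_amp = 500,
                        burst_dur = c(0.1, 0.3), noise_sd = 100,
                        duration = 1, sample_rate = 4000, seed = NULL) {
  stopifnot(n > 0)
  if (!is.null(seed)) set.seed(seed)
  n_samp <- round(duration * sample_rate)
  n_voiced <- round(n * prop_voiced)
  voiced <- c(rep(TRUE, n_voiced), rep(FALSE, n - n_voiced))
  lapply(seq_len(n), function(i) {
    x <- stats::rnorm(n_samp, 0, noise_sd)
    if (voiced[i]) {
      dur <- stats::runif(1, burst_dur[1], burst_dur[2])
      len <- max(2L, round(dur * sample_rate))
      start <- sample.int(max(1L, n_samp - len), 1L)
      env <- sin(pi * seq_len(len) / len)   # smooth on/offset
      tone <- sin(2 * pi * 400 * seq_len(len) / sample_rate +
                    stats::runif(1, 0, 2 * pi))
      x[start:(start + len - 1L)] <- x[start:(start + len - 1L)] +
        burst_amp * env * tone
    }
    audio_clip(x, sample_rate, if (voiced[i]) "voiced" else "unvoiced")
  })
}

#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for 16-bit PCM and 32-bit float mono files (the
#' formats this package writes).
#'
#' @param path File path.
#' @return An [audio_clip()] with label `"unknown"`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("parse error: not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("parse error: not a WAVE file: ", path)
  fmt_code <- NA_integer_; n_chan <- NA_integer_; sr <- NA_integer_
  bits <- NA_integer_; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", 1, 2, endian = "little",
                          signed = FALSE)
      n_chan <- readBin(con, "integer", 1, 2, endian = "little",
                        signed = FALSE)
      sr <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))  # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little"))  # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little",
                      signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16L))
    } else if (identical(id, "data")) {
      if (is.na(fmt_code)) stop("parse error: data chunk before fmt chunk")
      if (fmt_code == 1L && bits == 16L) {
        samples <- readBin(con, "integer", size / 2L, 2, endian = "little",
                           signed = TRUE)
      } else if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, "double", size / 4L, 4, endian = "little")
      } else {
        stop("unsupported WAV format: code ", fmt_code, ", ", bits, " bits")
      }
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(samples)) stop("parse error: no data chunk in ", path)
  if (!is.na(n_chan) && n_chan != 1L) {
    samples <- samples[seq(1L, length(samples), by = n_chan)]
  }
  audio_clip(samples, sr, "unknown")
}

#' Write a mono WAV file
#'
#' @param clip An [audio_clip()].
#' @param path Output path.
#' @param format `"pcm16"` (samples rounded and clipped to the 16-bit
#'   integer range) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(clip$samples)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(clip$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * bytes_per), con, 4,
           endian = "little")
  writeBin(bytes_per, con, 2, endian = "little")
  writeBin(8L * bytes_per, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "pcm16") {
    x <- as.integer(pmin(32767, pmax(-32768, round(clip$samples))))
    writeBin(x, con, 2, endian = "little")
  } else {
    writeBin(as.numeric(clip$samples), con, 4, endian = "little")
  }
  invisible(path)
}
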