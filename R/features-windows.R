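WINDOW_METRICS <- c(
  "time_stamp", "elapsed_time", "elapsed_from_midnight",
  "event_code", "bad_data_value",
  "avg_activity_count", "avg_temp",
  "avg_eda_level", "avg_eda_level_diff", "avg_eda_level_z",
  "eda_slope_20s", "eda_slope_120s",
  "rms_eda", "rms_eda_diff", "rms_eda_z",
  "n_peaks_high", "avg_peak_height_high",
  "n_peaks_low", "avg_peak_height_low"
)
EDA_METRICS <- WINDOW_METRICS[8:19]

#' Per-window time bookkeeping
#'
#' Window `k` (0-based) starts at `session_start + 20k`; its time stamp is
#' that start, its elapsed time `20k` seconds, and its elapsed time from
#' midnight the seconds since the most recent midnight of the time stamp in
#' the configured timezone (a fixed UTC offset; shifts routinely span
#' midnight, where the value resets toward zero).
#'
#' @param session_start session start, UNIX seconds.
#' @param n_windows number of 20-second windows.
#' @param width window width in seconds.
#' @param tz_offset timezone offset from UTC in seconds (default 0 = UTC).
#' @return data frame with columns `time_stamp`, `elapsed_time`,
#'   `elapsed_from_midnight`.
#' @export
window_time_metrics <- function(session_start, n_windows, width = 20,
                                tz_offset = 0) {
  stopifnot(n_windows >= 0)
  k <- seq_len(n_windows) - 1
  ts <- session_start + width * k
  data.frame(
    time_stamp = ts,
    elapsed_time = width * k,
    elapsed_from_midnight = (ts + tz_offset) %% 86400
  )
}

#' Detect skin-conductance-response peaks in a phasic segment
#'
#' Local maxima of the band-passed EDA segment whose sample value meets the
#' height threshold, thinned so retained peaks are separated by at least
#' `min_separation` seconds: among maxima closer than that, the larger is
#' kept (ties resolved toward the earlier one). Height is the sample value
#' at the maximum, not prominence.
#'
#' @param segment numeric vector of band-passed EDA samples.
#' @param rate_hz sampling rate, Hz.
#' @param height_threshold minimum peak height, microsiemens.
#' @param min_separation minimum separation between retained peaks, seconds.
#' @return data frame with `time` (seconds from segment start) and `height`.
#' @export
detect_peaks <- function(segment, rate_hz = 4, height_threshold = 0.15,
                         min_separation = 1) {
  n <- length(segment)
  empty <- data.frame(time = numeric(0), height = numeric(0))
  if (n < 3) return(empty)
  mid <- 2:(n - 1)
  cand <- mid[segment[mid] > segment[mid - 1] & segment[mid] >= segment[mid + 1]]
  cand <- cand[segment[cand] >= height_threshold]
  if (!length(cand)) return(empty)
  o <- order(-segment[cand], cand)
  cand <- cand[o]
  kept <- integer(0)
  min_gap <- min_separation * rate_hz
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(time = (kept - 1) / rate_hz, height = segment[kept])
}

# reshape the first n_win*per samples into a per-window matrix (per x n_win)
win_matrix <- function(x, per, n_win) {
  matrix(x[seq_len(per * n_win)], nrow = per)
}

# trailing difference / z-score against the 60 windows spanning
# [t - 20:20, t - 0:20]: windows k-61 .. k-2 (1-based); the first 61
# windows lack a full history and are missing.
history_norm <- function(v, n_hist = 60L) {
  K <- length(v)
  diff_out <- rep(NA_real_, K)
  z_out <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    lo <- k - n_hist - 1L
    hi <- k - 2L
    if (lo < 1L) next
    pop <- v[lo:hi]
    m <- mean(pop)
    s <- sd(pop)
    diff_out[k] <- v[k] - m
    z_out[k] <- if (is.na(s) || s == 0) NA_real_ else (v[k] - m) / s
  }
  list(diff = diff_out, z = z_out)
}

#' The 12 per-window EDA metrics
#'
#' From an [decompose_eda()] result, computes per 20-second window: the mean
#' baseline level; its difference and z-score against the population of the
#' 60 windows spanning 20 min 20 s to 20 s before the window start (missing
#' for the first 61 windows, and the z-score missing when that population
#' has zero variance); the least-squares slope of the baseline over the
#' window and over the 120 seconds centered on the window midpoint (missing
#' when edge truncation leaves under half the span); the RMS of the bandpass
#' signal over the window with the same difference/z normalization; and peak
#' counts and average peak heights at the high and low thresholds
#' (average height missing for zero-peak windows).
#'
#' @param decomp an `eda_decomposition`.
#' @param width window width, seconds.
#' @param n_hist number of history windows in the normalization population.
#' @param high_threshold,low_threshold peak height thresholds, microsiemens.
#' @param min_separation minimum peak separation, seconds.
#' @return data frame with the 12 EDA metric columns, one row per window.
#' @export
eda_window_metrics <- function(decomp, width = 20, n_hist = 60L,
                               high_threshold = 0.15, low_threshold = 0.02,
                               min_separation = 1) {
  stopifnot(inherits(decomp, "eda_decomposition"))
  rate <- decomp$baseline$sample_rate
  per <- as.integer(round(rate * width))
  N <- n_samples(decomp$baseline)
  K <- floor(N / per)
  if (K < 1) stop("decomposition shorter than one window", call. = FALSE)
  B <- win_matrix(decomp$baseline$values, per, K)
  P <- win_matrix(decomp$bandpass$values, per, K)

  avg_eda_level <- colMeans(B)
  rms_eda <- sqrt(colMeans(P^2))

  # 20-s slope: closed-form least squares with the fixed within-window grid
  tw <- (seq_len(per) - 1) / rate
  tc <- tw - mean(tw)
  eda_slope_20s <- as.numeric(crossprod(tc, B)) / sum(tc^2)

  # 120-s slope: line fit over [mid-60, mid+60), truncated at the edges;
  # missing when fewer than half of the span's samples are available
  half <- 60
  full_n <- as.integer(round(2 * half * rate))
  t_all <- (seq_len(N) - 1) / rate
  eda_slope_120s <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    mid <- (k - 1) * width + width / 2
    i0 <- max(1L, ceiling((mid - half) * rate) + 1L)
    i1 <- min(N, floor((mid + half) * rate - 1e-9) + 1L)
    if (i1 - i0 + 1L < full_n / 2) next
    tt <- t_all[i0:i1] - mean(t_all[i0:i1])
    eda_slope_120s[k] <- sum(tt * decomp$baseline$values[i0:i1]) / sum(tt^2)
  }

  lev <- history_norm(avg_eda_level, n_hist)
  rms <- history_norm(rms_eda, n_hist)

  n_peaks_high <- integer(K); n_peaks_low <- integer(K)
  avg_peak_height_high <- rep(NA_real_, K)
  avg_peak_height_low <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    seg <- P[, k]
    ph <- detect_peaks(seg, rate, high_threshold, min_separation)
    pl <- detect_peaks(seg, rate, low_threshold, min_separation)
    n_peaks_high[k] <- nrow(ph)
    n_peaks_low[k] <- nrow(pl)
    if (nrow(ph)) avg_peak_height_high[k] <- mean(ph$height)
    if (nrow(pl)) avg_peak_height_low[k] <- mean(pl$height)
  }

  data.frame(
    avg_eda_level = avg_eda_level,
    avg_eda_level_diff = lev$diff,
    avg_eda_level_z = lev$z,
    eda_slope_20s = eda_slope_20s,
    eda_slope_120s = eda_slope_120s,
    rms_eda = rms_eda,
    rms_eda_diff = rms$diff,
    rms_eda_z = rms$z,
    n_peaks_high = n_peaks_high,
    avg_peak_height_high = avg_peak_height_high,
    n_peaks_low = n_peaks_low,
    avg_peak_height_low = avg_peak_height_low
  )
}

#' Peak metrics alone
#'
#' Convenience wrapper returning only the four peak columns of
#' [eda_window_metrics()].
#'
#' @inheritParams eda_window_metrics
#' @return data frame with `n_peaks_high`, `avg_peak_height_high`,
#'   `n_peaks_low`, `avg_peak_height_low`.
#' @export
peak_metrics <- function(decomp, width = 20, high_threshold = 0.15,
                         low_threshold = 0.02, min_separation = 1) {
  m <- eda_window_metrics(decomp, width = width,
                          high_threshold = high_threshold,
                          low_threshold = low_threshold,
                          min_separation = min_separation)
  m[, c("n_peaks_high", "avg_peak_height_high",
        "n_peaks_low", "avg_peak_height_low")]
}

#' Good/bad data flags on 5-second intervals
#'
#' A surrogate signal-quality rule standing in for the device vendor's
#' unpublished algorithm, and deliberately pluggable through its thresholds:
#' an interval is flagged bad (-1) if within it the EDA leaves
#' `eda_range` microsiemens, shows an absolute one-sample jump above
#' `max_jump` microsiemens, or the temperature leaves `temp_range` degrees C;
#' otherwise good (+1). The flag stream has `ceiling(duration / 5)` entries.
#'
#' @param session a [sensor_session()].
#' @param interval rating interval, seconds.
#' @param eda_range,temp_range plausibility ranges.
#' @param max_jump maximum plausible one-sample EDA step, microsiemens.
#' @return integer vector of +1 / -1 flags.
#' @export
quality_flags <- function(session, interval = 5,
                          eda_range = c(0.01, 100), max_jump = 5,
                          temp_range = c(20, 45)) {
  stopifnot(inherits(session, "sensor_session"))
  dur <- session_duration(session)
  n_int <- ceiling(dur / interval)
  eda <- session$eda$values
  temp <- session$temp$values
  rate <- session$eda$sample_rate
  flags <- integer(n_int)
  for (i in seq_len(n_int)) {
    i0 <- as.integer((i - 1) * interval * rate) + 1L
    i1 <- min(length(eda), as.integer(i * interval * rate))
    e <- eda[i0:i1]
    tv <- temp[i0:min(length(temp), i1)]
    bad <- any(e < eda_range[1] | e > eda_range[2]) ||
      (length(e) > 1 && any(abs(diff(e)) > max_jump)) ||
      any(tv < temp_range[1] | tv > temp_range[2])
    flags[i] <- if (bad) -1L else 1L
  }
  flags
}

#' Windowed bad-data value
#'
#' Sum of the four 5-second flags spanned by each 20-second window, giving
#' 4 (all good), 2 (one bad), 0 (two bad), -2 (three bad) or -4 (all bad).
#'
#' @param flags integer vector of +1 / -1 flags from [quality_flags()].
#' @param per flags per window.
#' @return integer vector, one value in `{-4,-2,0,2,4}` per window.
#' @export
bad_data_values <- function(flags, per = 4L) {
  K <- floor(length(flags) / per)
  if (!K) return(integer(0))
  as.integer(colSums(matrix(flags[seq_len(K * per)], nrow = per)))
}

#' Extract the 19-metric window table from a session
#'
#' Runs the full feature stage on one officer-shift: EDA decomposition and
#' its 12 metrics, band-limited activity counts averaged per window, mean
#' skin temperature, bad-data values, time bookkeeping, and the windowed
#' event code (mode of the 1 Hz event-assignment stream; all zero when no
#' event stream is supplied). Windows are non-overlapping, 20 s, contiguous
#' from the session start; a trailing partial window is dropped. Channels
#' whose spans disagree by more than one window raise an error.
#'
#' @param session a [sensor_session()].
#' @param event_values optional 1 Hz event-assignment stream: either the
#'   data frame from [event_assignment_timeline()] or a numeric vector
#'   covering the session.
#' @param width window width, seconds.
#' @param tz_offset timezone offset from UTC in seconds, for the
#'   elapsed-from-midnight metric.
#' @param ... further arguments passed to [eda_window_metrics()] and, when
#'   named `interval`, `eda_range`, `max_jump` or `temp_range`, to
#'   [quality_flags()].
#' @return a `window_table` data frame with exactly the 19 metric columns.
#' @export
extract_metrics <- function(session, event_values = NULL, width = 20,
                            tz_offset = 0, ...) {
  stopifnot(inherits(session, "sensor_session"))
  dur <- session_duration(session)
  spans <- c(dur, stream_duration(session$temp), stream_duration(session$acc),
             stream_duration(session$bvp))
  if (diff(range(spans)) > width)
    stop("channel span mismatch exceeds one window", call. = FALSE)
  K <- floor(dur / width)
  if (K < 1) stop("session shorter than one window", call. = FALSE)

  dots <- list(...)
  qf_names <- intersect(names(dots), c("interval", "eda_range", "max_jump",
                                       "temp_range"))
  ew_args <- dots[setdiff(names(dots), qf_names)]

  tm <- window_time_metrics(session$start_time, K, width, tz_offset)

  decomp <- decompose_eda(session$eda)
  eda_m <- do.call(eda_window_metrics,
                   c(list(decomp = decomp, width = width), ew_args))
  eda_m <- eda_m[seq_len(K), , drop = FALSE]

  counts <- activity_counts(activity_signal(session$acc))
  KC <- min(K, floor(n_samples(counts) / width))
  avg_activity_count <- rep(NA_real_, K)
  avg_activity_count[seq_len(KC)] <-
    colMeans(win_matrix(counts$values, as.integer(width), KC))

  per_temp <- as.integer(round(session$temp$sample_rate * width))
  KT <- min(K, floor(n_samples(session$temp) / per_temp))
  avg_temp <- rep(NA_real_, K)
  avg_temp[seq_len(KT)] <- colMeans(win_matrix(session$temp$values,
                                               per_temp, KT))

  flags <- do.call(quality_flags, c(list(session = session), dots[qf_names]))
  bad <- bad_data_values(flags)
  bad_data_value <- rep(NA_integer_, K)
  bad_data_value[seq_len(min(K, length(bad)))] <-
    bad[seq_len(min(K, length(bad)))]

  if (is.null(event_values)) {
    event_code <- rep(0, K)
  } else {
    event_code <- window_event_code(event_values, width = width)
    if (length(event_code) < K)
      stop("event stream does not span the session", call. = FALSE)
    event_code <- event_code[seq_len(K)]
  }

  out <- cbind(
    tm,
    data.frame(event_code = event_code, bad_data_value = bad_data_value,
               avg_activity_count = avg_activity_count, avg_temp = avg_temp),
    eda_m
  )
  out <- out[, WINDOW_METRICS]
  class(out) <- c("window_table", "data.frame")
  attr(out, "start_time") <- session$start_time
  attr(out, "window_width") <- width
  out
}
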