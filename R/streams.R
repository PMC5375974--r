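#' Construct a raw sensor stream
#'
#' A `raw_stream` is one regularly sampled channel: a shared session start
#' time (UNIX seconds), a fixed sample rate, and the samples themselves.
#' Sample `i` (1-based) is taken at `start_time + (i - 1) / sample_rate`;
#' a stream of duration `D` covers `[start_time, start_time + D)`, so the
#' last sample falls at `D - 1/sample_rate`.
#'
#' @param start_time session start, UNIX seconds.
#' @param sample_rate sampling rate in Hz, `> 0`.
#' @param values numeric vector (single channel) or matrix with one row per
#'   sample (multichannel, e.g. 3 columns for a 3-axis accelerometer).
#' @return an object of class `raw_stream`.
#' @export
raw_stream <- function(start_time, sample_rate, values) {
  if (!is.numeric(start_time) || length(start_time) != 1L || !is.finite(start_time))
    stop("start_time must be a single finite number (UNIX seconds)", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || !is.finite(sample_rate) ||
      sample_rate <= 0)
    stop("sample_rate must be a single positive number", call. = FALSE)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.numeric(values))
    stop("values must be numeric", call. = FALSE)
  if (!all(is.finite(values)))
    stop("values must be finite", call. = FALSE)
  structure(
    list(start_time = as.numeric(start_time),
         sample_rate = as.numeric(sample_rate),
         values = values),
    class = "raw_stream"
  )
}

#' @export
print.raw_stream <- function(x, ...) {
  n <- n_samples(x)
  cat(sprintf("<raw_stream> %d samples x %d channel(s) @ %g Hz, %.1f s from t0=%.3f\n",
              n, n_channels(x), x$sample_rate, n / x$sample_rate, x$start_time))
  invisible(x)
}

n_samples <- function(stream) {
  if (is.matrix(stream$values)) nrow(stream$values) else length(stream$values)
}

n_channels <- function(stream) {
  if (is.matrix(stream$values)) ncol(stream$values) else 1L
}

stream_duration <- function(stream) n_samples(stream) / stream$sample_rate

#' Assemble a sensor session
#'
#' One officer-shift of raw channel streams sharing a single start time:
#' electrodermal activity (4 Hz, microsiemens), skin temperature (4 Hz,
#' degrees C), 3-axis acceleration (32 Hz, g), blood volume pulse (64 Hz,
#' arbitrary units), and irregular interbeat intervals. The IBI table gives,
#' per detected beat, its offset from session start (seconds) and the
#' interval it closes (seconds); offsets must be strictly increasing and
#' durations positive.
#'
#' @param eda,temp,acc,bvp [raw_stream()] objects at 4, 4, 32 and 64 Hz
#'   respectively; `acc` must have 3 channels.
#' @param ibi data frame with numeric columns `offset` and `duration`
#'   (may have zero rows).
#' @return an object of class `sensor_session`.
#' @export
sensor_session <- function(eda, temp, acc, bvp, ibi) {
  for (nm in c("eda", "temp", "acc", "bvp")) {
    s <- get(nm)
    if (!inherits(s, "raw_stream"))
      stop(sprintf("%s must be a raw_stream", nm), call. = FALSE)
  }
  starts <- c(eda$start_time, temp$start_time, acc$start_time, bvp$start_time)
  if (diff(range(starts)) > 1e-6)
    stop("all channel streams must share one session start time", call. = FALSE)
  expect_rate <- c(eda = 4, temp = 4, acc = 32, bvp = 64)
  for (nm in names(expect_rate)) {
    s <- get(nm)
    if (abs(s$sample_rate - expect_rate[[nm]]) > 1e-9)
      stop(sprintf("%s stream must be sampled at %g Hz", nm, expect_rate[[nm]]),
           call. = FALSE)
  }
  if (n_channels(acc) != 3L)
    stop("channel count: acc must have exactly 3 channels", call. = FALSE)
  if (n_channels(eda) != 1L || n_channels(temp) != 1L || n_channels(bvp) != 1L)
    stop("channel count: eda, temp and bvp must be single-channel", call. = FALSE)
  ibi <- as.data.frame(ibi)
  if (!all(c("offset", "duration") %in% names(ibi)))
    stop("ibi must have columns offset and duration", call. = FALSE)
  ibi <- ibi[, c("offset", "duration")]
  if (nrow(ibi)) {
    if (any(!is.finite(ibi$offset)) || any(!is.finite(ibi$duration)))
      stop("ibi entries must be finite", call. = FALSE)
    if (any(diff(ibi$offset) <= 0))
      stop("ibi offsets must be strictly increasing", call. = FALSE)
    if (any(ibi$duration <= 0))
      stop("ibi durations must be positive", call. = FALSE)
  }
  structure(
    list(start_time = eda$start_time, eda = eda, temp = temp, acc = acc,
         bvp = bvp, ibi = ibi),
    class = "sensor_session"
  )
}

#' @export
print.sensor_session <- function(x, ...) {
  cat(sprintf("<sensor_session> start %.3f, duration %.1f s\n",
              x$start_time, session_duration(x)))
  cat(sprintf("  eda  %7d samples @ 4 Hz   temp %7d samples @ 4 Hz\n",
              n_samples(x$eda), n_samples(x$temp)))
  cat(sprintf("  acc  %7d samples @ 32 Hz  bvp  %7d samples @ 64 Hz\n",
              n_samples(x$acc), n_samples(x$bvp)))
  cat(sprintf("  ibi  %7d beats\n", nrow(x$ibi)))
  invisible(x)
}

#' Session duration in seconds
#'
#' Duration implied by the EDA stream (the reference channel for the
#' 20-second window grid).
#'
#' @param session a [sensor_session()].
#' @return duration in seconds.
#' @export
session_duration <- function(session) stream_duration(session$eda)
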