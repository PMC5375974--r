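# Savitzky-Golay smoothing with reflect padding so interior and edge samples
# alike use the central (least-squares polynomial) filter row.
sg_smooth <- function(x, order, n) {
  h <- (n - 1L) / 2L
  if (length(x) <= n)
    stop("stream shorter than the polynomial filter window", call. = FALSE)
  pad <- c(rev(x[2:(h + 1L)]), x, rev(x[(length(x) - h):(length(x) - 1L)]))
  y <- signal::sgolayfilt(pad, p = order, n = n)
  y[(h + 1L):(h + length(x))]
}

#' Decompose an EDA stream into tonic level and phasic fluctuation
#'
#' Splits a 4 Hz skin-conductance stream into two bands with third-order
#' polynomial (Savitzky-Golay) smoothing: the *baseline* (tonic EDA level,
#' roughly the 0-0.04 Hz band) from a 101-point window, and the *bandpass*
#' (phasic fluctuations, roughly 0.04-0.4 Hz) obtained by removing the
#' baseline and smoothing the residual with an 11-point window. The nominal
#' 100- and 10-point windows are realized as the nearest odd lengths, as a
#' centered polynomial filter requires. Edges use reflect padding; the
#' first and last half-window of each band should be treated with caution.
#'
#' @param eda a 4 Hz [raw_stream()] of skin conductance, microsiemens.
#' @param baseline_n,bandpass_n odd filter window lengths in samples.
#' @param order polynomial order of both filters.
#' @return an object of class `eda_decomposition`: list with `baseline` and
#'   `bandpass` [raw_stream()]s the same length as the input.
#' @export
decompose_eda <- function(eda, baseline_n = 101L, bandpass_n = 11L,
                          order = 3L) {
  stopifnot(inherits(eda, "raw_stream"))
  if (n_channels(eda) != 1L)
    stop("channel count: EDA must be single-channel", call. = FALSE)
  x <- eda$values
  baseline <- sg_smooth(x, order, baseline_n)
  bandpass <- sg_smooth(x - baseline, order, bandpass_n)
  structure(
    list(baseline = raw_stream(eda$start_time, eda$sample_rate, baseline),
         bandpass = raw_stream(eda$start_time, eda$sample_rate, bandpass)),
    class = "eda_decomposition"
  )
}

#' @export
print.eda_decomposition <- function(x, ...) {
  cat(sprintf("<eda_decomposition> %d samples @ %g Hz (baseline + bandpass)\n",
              n_samples(x$baseline), x$baseline$sample_rate))
  invisible(x)
}

#' Collapse 3-axis acceleration to a band-limited activity signal
#'
#' Per-sample Euclidean norm `sqrt(x^2 + y^2 + z^2)` of the 32 Hz
#' accelerometer channels, band-passed to 0.1-7 Hz with a fifth-order
#' Butterworth filter applied forward and backward (zero phase; effective
#' order 10). The high-pass corner removes the gravity component, so a
#' motionless wrist yields activity near zero.
#'
#' @param acc a 3-channel 32 Hz [raw_stream()], units of g.
#' @param band two-vector of band edges in Hz, or `NULL` to return the raw
#'   (unfiltered) magnitude signal.
#' @param order Butterworth design order (per pass).
#' @return a single-channel 32 Hz [raw_stream()] activity signal.
#' @export
activity_signal <- function(acc, band = c(0.1, 7), order = 5L) {
  stopifnot(inherits(acc, "raw_stream"))
  if (n_channels(acc) != 3L)
    stop("channel count: acceleration must have 3 channels", call. = FALSE)
  mag <- sqrt(rowSums(acc$values^2))
  if (is.null(band))
    return(raw_stream(acc$start_time, acc$sample_rate, mag))
  bf <- signal::butter(order, band / (acc$sample_rate / 2), type = "pass")
  filtered <- signal::filtfilt(bf, mag)
  raw_stream(acc$start_time, acc$sample_rate, filtered)
}

#' Activity counts over 1-second epochs
#'
#' For each non-overlapping 1-second epoch, the sum of absolute values of
#' the band-limited activity signal's samples (32 per epoch at 32 Hz).
#' A trailing partial epoch is dropped.
#'
#' @param activity a 32 Hz [raw_stream()] from [activity_signal()].
#' @return a 1 Hz [raw_stream()] of counts (arbitrary units).
#' @export
activity_counts <- function(activity) {
  stopifnot(inherits(activity, "raw_stream"))
  rate <- activity$sample_rate
  per <- as.integer(round(rate))
  n_epoch <- floor(n_samples(activity) / per)
  x <- abs(activity$values[seq_len(n_epoch * per)])
  counts <- colSums(matrix(x, nrow = per))
  raw_stream(activity$start_time, 1, counts)
}
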