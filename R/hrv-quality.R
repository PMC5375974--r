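#' Gap statistics and longest valid segment of an interbeat-interval record
#'
#' A beat at offset `o` closing an interval `d` covers `[o - d, o]`. The
#' record has a gap wherever the next beat's covered span does not continue
#' the previous one within `tolerance` — i.e. where
#' `offset[k] - offset[k-1] > duration[k] + tolerance` — and at the session
#' edges when the first beat starts, or the last beat ends, more than
#' `tolerance` from the boundary. Valid segments are the maximal gap-free
#' runs; the report carries the longest segment length and the mean and SD
#' of the gap lengths (SD 0 for a single gap; both missing when there are
#' no gaps).
#'
#' @param ibi data frame with `offset` (seconds from session start, strictly
#'   increasing) and `duration` (seconds, positive) columns.
#' @param session_duration session length, seconds.
#' @param tolerance tiling tolerance, seconds.
#' @return an object of class `ibi_quality`: list with
#'   `longest_valid_segment`, `gap_mean`, `gap_sd`, `n_gaps`, `segments`
#'   (data frame of start/end) and `gaps` (data frame of start/end).
#' @export
ibi_gap_stats <- function(ibi, session_duration, tolerance = 0.25) {
  ibi <- as.data.frame(ibi)
  if (nrow(ibi)) {
    if (any(ibi$duration <= 0))
      stop("ibi durations must be positive", call. = FALSE)
    if (any(diff(ibi$offset) <= 0))
      stop("ibi offsets must be strictly increasing", call. = FALSE)
  }
  gaps <- data.frame(start = numeric(0), end = numeric(0))
  if (!nrow(ibi)) {
    segments <- data.frame(start = numeric(0), end = numeric(0))
    if (session_duration > tolerance)
      gaps <- data.frame(start = 0, end = session_duration)
  } else {
    beat_start <- ibi$offset - ibi$duration
    internal <- which(diff(ibi$offset) > ibi$duration[-1] + tolerance)
    seg_first <- c(1L, internal + 1L)
    seg_last <- c(internal, nrow(ibi))
    segments <- data.frame(start = beat_start[seg_first],
                           end = ibi$offset[seg_last])
    if (length(internal))
      gaps <- data.frame(start = ibi$offset[internal],
                         end = beat_start[internal + 1L])
    if (beat_start[1] > tolerance)
      gaps <- rbind(data.frame(start = 0, end = beat_start[1]), gaps)
    if (session_duration - ibi$offset[nrow(ibi)] > tolerance)
      gaps <- rbind(gaps, data.frame(start = ibi$offset[nrow(ibi)],
                                     end = session_duration))
  }
  gap_len <- gaps$end - gaps$start
  structure(
    list(
      longest_valid_segment = if (nrow(segments))
        max(segments$end - segments$start) else 0,
      gap_mean = if (length(gap_len)) mean(gap_len) else NA_real_,
      gap_sd = if (length(gap_len) > 1) sd(gap_len)
               else if (length(gap_len) == 1) 0 else NA_real_,
      n_gaps = length(gap_len),
      segments = segments,
      gaps = gaps
    ),
    class = "ibi_quality"
  )
}

#' @export
print.ibi_quality <- function(x, ...) {
  cat(sprintf("<ibi_quality> longest valid segment %.1f s; %d gap(s)",
              x$longest_valid_segment, x$n_gaps))
  if (x$n_gaps)
    cat(sprintf(" [mean %.1f s, sd %.1f s]", x$gap_mean, x$gap_sd))
  cat("\n")
  invisible(x)
}

# total length of the union of [start, end] spans intersected with [lo, hi]
covered_length <- function(start, end, lo, hi) {
  s <- pmax(start, lo)
  e <- pmin(end, hi)
  keep <- e > s
  if (!any(keep)) return(0)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  total <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) cur_e <- max(cur_e, e[i])
    else { total <- total + (cur_e - cur_s); cur_s <- s[i]; cur_e <- e[i] }
  }
  total + (cur_e - cur_s)
}

#' Per-window interbeat-interval quality rating
#'
#' Mirrors the EDA bad-data scale: each 20-second window splits into four
#' 5-second intervals, an interval rates good (+1) when beat coverage — the
#' union of spans `[offset - duration, offset]` intersected with the
#' interval — reaches the coverage fraction, else bad (-1), and the window
#' rating is the sum of its four interval flags, a value in
#' `{-4, -2, 0, 2, 4}`.
#'
#' @param ibi data frame with `offset` and `duration` columns.
#' @param session_duration session length, seconds.
#' @param width window width, seconds.
#' @param interval rating interval, seconds.
#' @param coverage minimum covered fraction for a good interval.
#' @return integer vector, one rating per complete window.
#' @export
ibi_window_quality <- function(ibi, session_duration, width = 20,
                               interval = 5, coverage = 0.8) {
  ibi <- as.data.frame(ibi)
  K <- floor(session_duration / width)
  per <- as.integer(width / interval)
  n_int <- K * per
  flags <- integer(n_int)
  start <- if (nrow(ibi)) ibi$offset - ibi$duration else numeric(0)
  for (i in seq_len(n_int)) {
    lo <- (i - 1) * interval
    hi <- lo + interval
    cov <- if (nrow(ibi)) covered_length(start, ibi$offset, lo, hi) else 0
    flags[i] <- if (cov >= coverage * interval - 1e-9) 1L else -1L
  }
  as.integer(colSums(matrix(flags, nrow = per)))
}
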