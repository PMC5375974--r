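EVENT_VALUES <- c(0, 0.5, 1.0, 2.0, 2.5, 3.0)

#' Per-second event-assignment timeline from a CAD log
#'
#' Codes every second of the span by call phase: 0 when unassigned (the
#' neutral "unallocated" code), 0.5 throughout a canceled call's dispatched
#' span, 1.0 from dispatch to first arrival, 2.0 from first arrival until
#' the next lifecycle event among second arrival / transport / cleared
#' (and again from a second arrival to cleared when no transport occurs),
#' 2.5 from second arrival to transport when the second arrival precedes
#' transport, and 3.0 from an arrestee-transport start to the call being
#' cleared. Each coded second also carries the call id. Call spans falling
#' outside the requested span are clipped to it; overlapping calls and
#' lifecycle-order violations are errors.
#'
#' @param cad a `cad_log` data frame.
#' @param span two-vector `c(start, end)`, UNIX seconds; the timeline covers
#'   `[start, end)` at 1 Hz.
#' @return data frame with one row per second: `time`, `value`, `call_id`.
#' @export
event_assignment_timeline <- function(cad, span) {
  cad <- as_cad_log(cad)
  stopifnot(length(span) == 2, span[2] > span[1])
  times <- seq(span[1], span[2] - 1)
  value <- numeric(length(times))
  call_id <- rep(NA_character_, length(times))

  seg_end <- ifelse(cad$canceled, cad$canceled_time, cad$cleared)
  seg_end[is.na(seg_end)] <- cad$dispatched[is.na(seg_end)]
  if (nrow(cad) > 1) {
    o <- order(cad$dispatched)
    if (any(cad$dispatched[o][-1] < seg_end[o][-nrow(cad)]))
      stop("overlapping calls for one officer", call. = FALSE)
  }

  paint <- function(from, to, val, id) {
    if (is.na(from) || is.na(to) || to <= from) return()
    i0 <- max(1L, as.integer(floor(from - span[1])) + 1L)
    i1 <- min(length(times), as.integer(ceiling(to - span[1])))
    if (i1 < i0) return()
    idx <- i0:i1
    idx <- idx[times[idx] >= from & times[idx] < to]
    value[idx] <<- val
    call_id[idx] <<- id
  }

  for (i in seq_len(nrow(cad))) {
    id <- cad$call_id[i]
    if (isTRUE(cad$canceled[i])) {
      paint(cad$dispatched[i], cad$canceled_time[i], 0.5, id)
      next
    }
    a1 <- cad$arrive1[i]; a2 <- cad$arrive2[i]
    tr <- cad$transport[i]; cl <- cad$cleared[i]
    paint(cad$dispatched[i], a1, 1.0, id)
    if (!is.na(a1)) {
      nxt <- suppressWarnings(min(c(a2, tr, cl), na.rm = TRUE))
      if (is.finite(nxt)) paint(a1, nxt, 2.0, id)
    }
    if (!is.na(a2)) {
      if (!is.na(tr)) {
        if (a2 < tr) paint(a2, tr, 2.5, id)
      } else if (!is.na(cl)) {
        paint(a2, cl, 2.0, id)
      }
    }
    if (!is.na(tr) && !is.na(cl)) paint(tr, cl, 3.0, id)
  }
  data.frame(time = times, value = value, call_id = call_id,
             stringsAsFactors = FALSE)
}

#' Windowed event code: mode of the per-second assignments
#'
#' The event code of each 20-second window is the mode of its 20
#' event-assignment values; ties are broken toward the larger value (the
#' deeper call phase). A trailing partial window is dropped.
#'
#' @param values the data frame from [event_assignment_timeline()] or a
#'   plain numeric 1 Hz vector.
#' @param width window width, seconds.
#' @return numeric vector, one event code per window.
#' @export
window_event_code <- function(values, width = 20) {
  if (is.data.frame(values)) values <- values$value
  per <- as.integer(width)
  K <- floor(length(values) / per)
  if (!K) return(numeric(0))
  m <- matrix(values[seq_len(K * per)], nrow = per)
  apply(m, 2, function(v) {
    tab <- table(v)
    cand <- as.numeric(names(tab)[tab == max(tab)])
    max(cand)
  })
}

#' Link AVL pings to window midpoints
#'
#' For each window midpoint, the xy of the nearest ping within the linkage
#' tolerance (default 30 s, the slowest expected ping cadence); windows with
#' no ping that close get missing coordinates.
#'
#' @param midpoints numeric vector of window midpoints, UNIX seconds (or a
#'   `window_table`, whose midpoints are used).
#' @param avl an `avl_track` data frame.
#' @param tolerance maximum midpoint-to-ping distance, seconds.
#' @return data frame with `x` and `y`, one row per window.
#' @export
link_avl <- function(midpoints, avl, tolerance = 30) {
  if (is.data.frame(midpoints) && "time_stamp" %in% names(midpoints)) {
    width <- attr(midpoints, "window_width")
    if (is.null(width)) width <- 20
    midpoints <- midpoints$time_stamp + width / 2
  }
  avl <- as_avl_track(avl)
  n <- length(midpoints)
  out <- data.frame(x = rep(NA_real_, n), y = rep(NA_real_, n))
  if (!nrow(avl)) return(out)
  pos <- findInterval(midpoints, avl$time)
  for (j in seq_len(n)) {
    cand <- unique(pmin(pmax(c(pos[j], pos[j] + 1L), 1L), nrow(avl)))
    d <- abs(avl$time[cand] - midpoints[j])
    b <- cand[which.min(d)]
    if (min(d) <= tolerance) {
      out$x[j] <- avl$x[b]
      out$y[j] <- avl$y[b]
    }
  }
  out
}

#' Fuse a window table with CAD and AVL context
#'
#' Left-joins the operational context onto the window table (row count is
#' never changed): for windows whose event code exceeds zero, the id, type
#' and priority of the call that dominates the window's coded seconds; an
#' `allocated` flag, true when call-phase values above zero hold a majority
#' of the window; and per-window vehicle coordinates from [link_avl()].
#' All sources must belong to one officer-shift; mismatched officer ids
#' across CAD and AVL are an error.
#'
#' @param table a `window_table` from [extract_metrics()].
#' @param cad a `cad_log`.
#' @param avl an `avl_track`.
#' @param tolerance AVL linkage tolerance, seconds.
#' @return a `fused_table`: the window table plus `call_id`, `call_type`,
#'   `priority`, `allocated`, `x`, `y`.
#' @export
fuse <- function(table, cad, avl, tolerance = 30) {
  stopifnot(inherits(table, "window_table"))
  cad <- as_cad_log(cad)
  avl <- as_avl_track(avl)
  if (nrow(cad) && nrow(avl)) {
    off_cad <- unique(cad$officer_id)
    off_avl <- unique(avl$officer_id)
    if (length(off_cad) > 1 || length(off_avl) > 1 ||
        (length(off_cad) && length(off_avl) && off_cad != off_avl))
      stop("officer-id mismatch across CAD and AVL sources", call. = FALSE)
  }
  width <- attr(table, "window_width")
  if (is.null(width)) width <- 20
  K <- nrow(table)
  start <- if (K) table$time_stamp[1] else attr(table, "start_time")
  span <- c(start, start + K * width)

  tl <- event_assignment_timeline(cad, span)
  vmat <- matrix(tl$value[seq_len(K * width)], nrow = width)
  idmat <- matrix(tl$call_id[seq_len(K * width)], nrow = width)

  call_id <- rep(NA_character_, K)
  allocated <- logical(K)
  for (k in seq_len(K)) {
    allocated[k] <- sum(vmat[, k] > 0) > width / 2
    if (table$event_code[k] > 0) {
      ids <- idmat[, k][vmat[, k] > 0]
      if (length(ids)) {
        tab <- table(ids)
        call_id[k] <- names(tab)[which.max(tab)]
      }
    }
  }
  idx <- match(call_id, cad$call_id)
  xy <- link_avl(table$time_stamp + width / 2, avl, tolerance)

  out <- as.data.frame(table)
  out$call_id <- call_id
  out$call_type <- cad$call_type[idx]
  out$priority <- cad$priority[idx]
  out$allocated <- allocated
  out$x <- xy$x
  out$y <- xy$y
  class(out) <- c("fused_table", "window_table", "data.frame")
  attr(out, "start_time") <- attr(table, "start_time")
  attr(out, "window_width") <- width
  out
}
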