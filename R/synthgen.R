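#' Configuration for a synthetic officer shift
#'
#' Collects every tunable of the synthetic-shift generator. Defaults emulate
#' a 12-hour patrol shift recorded by a wrist-worn multichannel device:
#' tonic skin conductance around 2 microsiemens with slow upward drift (sweat
#' accumulation at the electrodes), discrete skin-conductance responses (SCRs)
#' arriving as a Poisson process whose rate is elevated during calls —
#' strongly so during high-stress calls — wrist temperature near 33 C,
#' mostly-stationary acceleration with occasional movement bouts, a heart
#' period that shortens under stress, and vehicle-location pings every 3 s
#' while en route versus every 30 s while stationary.
#'
#' @param seed integer seed; every random draw in the generator flows from it.
#' @param shift_start shift start, UNIX seconds.
#' @param shift_hours shift duration in hours (`> 0`).
#' @param calls list of [call_spec()] records; must lie within the shift and
#'   must not overlap one another.
#' @param tonic_level tonic EDA level at shift start, microsiemens.
#' @param tonic_drift tonic drift, microsiemens per hour.
#' @param noise_sd measurement noise SD on EDA, microsiemens.
#' @param scr_rise,scr_decay SCR kernel time constants, seconds
#'   (`scr_decay > scr_rise > 0`).
#' @param scr_rate_by_stress named vector `c(none=, low=, high=)` of SCR
#'   event rates, events per minute, outside calls / during low-stress calls /
#'   during high-stress calls.
#' @param scr_amp_meanlog,scr_amp_sdlog log-normal parameters of SCR
#'   amplitudes (microsiemens).
#' @param temp_base baseline wrist temperature, degrees C.
#' @param activity_bout_rate movement bouts per hour.
#' @param heart_period,heart_period_high mean interbeat interval in seconds
#'   outside and during high-stress calls.
#' @param ibi_gap_rate sensor-dropout gaps per hour in the beat record.
#' @param ibi_gap_len two-vector, min/max gap length in seconds.
#' @param avl_ping_fast,avl_ping_slow AVL ping intervals, seconds, while
#'   moving / stationary (`avl_ping_fast <= avl_ping_slow`).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         shift_start = 1464771600,
                         shift_hours = 12,
                         calls = list(),
                         tonic_level = 2,
                         tonic_drift = 0.1,
                         noise_sd = 0.01,
                         scr_rise = 0.75,
                         scr_decay = 3,
                         scr_rate_by_stress = c(none = 1, low = 2, high = 5),
                         scr_amp_meanlog = log(0.3),
                         scr_amp_sdlog = 0.4,
                         temp_base = 33,
                         activity_bout_rate = 6,
                         heart_period = 0.8,
                         heart_period_high = 0.65,
                         ibi_gap_rate = 1,
                         ibi_gap_len = c(20, 60),
                         avl_ping_fast = 3,
                         avl_ping_slow = 30) {
  if (shift_hours <= 0) stop("shift_hours must be positive", call. = FALSE)
  if (!(scr_decay > scr_rise && scr_rise > 0))
    stop("need scr_decay > scr_rise > 0", call. = FALSE)
  if (avl_ping_fast > avl_ping_slow)
    stop("need avl_ping_fast <= avl_ping_slow", call. = FALSE)
  if (!all(c("none", "low", "high") %in% names(scr_rate_by_stress)))
    stop("scr_rate_by_stress must name rates none, low, high", call. = FALSE)
  rates <- c(scr_rate_by_stress, activity_bout_rate, ibi_gap_rate)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  cfg <- structure(
    list(seed = as.integer(seed), shift_start = shift_start,
         shift_hours = shift_hours, calls = calls,
         tonic_level = tonic_level, tonic_drift = tonic_drift,
         noise_sd = noise_sd, scr_rise = scr_rise, scr_decay = scr_decay,
         scr_rate_by_stress = scr_rate_by_stress,
         scr_amp_meanlog = scr_amp_meanlog, scr_amp_sdlog = scr_amp_sdlog,
         temp_base = temp_base, activity_bout_rate = activity_bout_rate,
         heart_period = heart_period, heart_period_high = heart_period_high,
         ibi_gap_rate = ibi_gap_rate, ibi_gap_len = ibi_gap_len,
         avl_ping_fast = avl_ping_fast, avl_ping_slow = avl_ping_slow),
    class = "synth_config"
  )
  validate_calls(cfg)
  cfg
}

#' One call-for-service lifecycle record
#'
#' Timestamps follow the CAD lifecycle `received <= dispatched <= arrive1 <=
#' arrive2 <= transport <= cleared`, with the later stages optional.
#' Canceled calls carry no arrive/transport/cleared times; instead
#' `canceled_time` records when the cancellation closed the call (the end of
#' its dispatched span).
#'
#' @param call_id,officer_id identifiers (character or integer).
#' @param call_type free-text call category.
#' @param priority integer dispatch priority (1 = most urgent).
#' @param stress_level `"low"` or `"high"`; drives the synthetic SCR rate.
#' @param received,dispatched UNIX seconds.
#' @param arrive1,arrive2,transport,cleared optional UNIX seconds.
#' @param canceled logical flag.
#' @param canceled_time UNIX seconds; required when `canceled`.
#' @return an object of class `call_spec`.
#' @export
call_spec <- function(call_id, officer_id, call_type, priority,
                      stress_level = c("low", "high"),
                      received, dispatched,
                      arrive1 = NA_real_, arrive2 = NA_real_,
                      transport = NA_real_, cleared = NA_real_,
                      canceled = FALSE, canceled_time = NA_real_) {
  stress_level <- match.arg(stress_level)
  ts <- c(received = received, dispatched = dispatched, arrive1 = arrive1,
          arrive2 = arrive2, transport = transport, cleared = cleared)
  if (canceled) {
    if (any(!is.na(ts[c("arrive1", "arrive2", "transport", "cleared")])))
      stop("canceled calls must have no arrive/transport/cleared times",
           call. = FALSE)
    if (is.na(canceled_time))
      stop("canceled calls need a canceled_time", call. = FALSE)
    if (canceled_time < dispatched)
      stop("canceled_time must not precede dispatched", call. = FALSE)
  } else {
    present <- ts[!is.na(ts)]
    if (any(diff(present) < 0))
      stop(sprintf("call %s: lifecycle timestamps must be nondecreasing",
                   as.character(call_id)), call. = FALSE)
  }
  structure(
    list(call_id = call_id, officer_id = officer_id, call_type = call_type,
         priority = as.integer(priority), stress_level = stress_level,
         received = received, dispatched = dispatched,
         arrive1 = arrive1, arrive2 = arrive2, transport = transport,
         cleared = cleared, canceled = isTRUE(canceled),
         canceled_time = canceled_time),
    class = "call_spec"
  )
}

call_end <- function(call) {
  if (call$canceled) return(call$canceled_time)
  for (f in c("cleared", "transport", "arrive2", "arrive1"))
    if (!is.na(call[[f]])) return(call[[f]])
  call$dispatched
}

validate_calls <- function(cfg) {
  calls <- cfg$calls
  if (!length(calls)) return(invisible(TRUE))
  if (!all(vapply(calls, inherits, logical(1), "call_spec")))
    stop("calls must be a list of call_spec objects", call. = FALSE)
  end <- cfg$shift_start + cfg$shift_hours * 3600
  spans <- t(vapply(calls, function(cl) c(cl$dispatched, call_end(cl)),
                    numeric(2)))
  if (any(spans[, 1] < cfg$shift_start) || any(spans[, 2] > end))
    stop("calls must lie within the shift span", call. = FALSE)
  o <- order(spans[, 1])
  spans <- spans[o, , drop = FALSE]
  if (nrow(spans) > 1 && any(spans[-1, 1] < spans[-nrow(spans), 2]))
    stop("overlapping calls for one officer", call. = FALSE)
  invisible(TRUE)
}

#' Draw a random non-overlapping call schedule for a shift
#'
#' Convenience generator of [call_spec()] lists: call start times are spread
#' over the shift, on-scene phases last 10-40 minutes, a fraction of calls
#' are high-stress (priority 1) and a fraction are canceled before arrival.
#'
#' @param config a [synth_config()]; only its span and seed are used.
#' @param n_calls number of calls to draw.
#' @param officer_id officer identifier stamped on every call.
#' @param p_high probability a call is high-stress.
#' @param p_canceled probability a call is canceled before arrival.
#' @return list of [call_spec()] records, time-ordered.
#' @export
synth_calls <- function(config, n_calls = 6, officer_id = "officer-1",
                        p_high = 1 / 3, p_canceled = 0.1) {
  set.seed(config$seed + 1000003L)
  dur <- config$shift_hours * 3600
  # partition the shift into n slots, one call per slot, to guarantee
  # non-overlap without rejection sampling
  slot <- dur / n_calls
  calls <- vector("list", n_calls)
  for (i in seq_len(n_calls)) {
    slot0 <- config$shift_start + (i - 1) * slot
    slot_end <- slot0 + slot
    # lifecycle scaled to the slot so any shift length yields valid calls
    received <- slot0 + runif(1, 0.02, 0.10) * slot
    dispatched <- received + runif(1, 0.005, 0.02) * slot
    high <- runif(1) < p_high
    canceled <- runif(1) < p_canceled
    if (canceled) {
      calls[[i]] <- call_spec(
        call_id = sprintf("C%03d", i), officer_id = officer_id,
        call_type = "canceled_call", priority = 3L,
        stress_level = "low", received = received, dispatched = dispatched,
        canceled = TRUE,
        canceled_time = dispatched +
          runif(1, 0.05, 0.2) * (slot_end - dispatched))
      next
    }
    arrive1 <- dispatched + runif(1, 0.03, 0.10) * slot
    cleared <- arrive1 + runif(1, 0.2, 0.6) * (slot_end - arrive1 - 30)
    transport <- if (high && runif(1) < 0.5)
      arrive1 + 0.7 * (cleared - arrive1) else NA_real_
    calls[[i]] <- call_spec(
      call_id = sprintf("C%03d", i), officer_id = officer_id,
      call_type = if (high) "domestic_disturbance" else
        sample(c("traffic_stop", "property_check", "stolen_vehicle"), 1),
      priority = if (high) 1L else 3L,
      stress_level = if (high) "high" else "low",
      received = received, dispatched = dispatched, arrive1 = arrive1,
      transport = transport, cleared = cleared)
  }
  calls
}

#' Superpose skin-conductance-response kernels into a phasic EDA stream
#'
#' Each SCR is a bi-exponential kernel
#' `a * (exp(-t/decay) - exp(-t/rise))`, normalized so its peak equals the
#' requested amplitude, placed at its event time; the stream is the sum of
#' all kernels sampled at `rate_hz` over `[0, duration)` and is zero before
#' the first event.
#'
#' @param event_times event onsets, seconds from stream start, within
#'   `[0, duration]`.
#' @param rise,decay kernel time constants, seconds (`decay > rise > 0`).
#' @param amplitudes non-negative peak amplitudes, microsiemens; recycled to
#'   the length of `event_times`.
#' @param rate_hz sampling rate, Hz.
#' @param duration stream duration, seconds.
#' @return numeric vector of `rate_hz * duration` phasic EDA samples.
#' @export
synth_scr_train <- function(event_times, rise, decay, amplitudes,
                            rate_hz = 4, duration) {
  if (!(decay > rise && rise > 0))
    stop("need decay > rise > 0", call. = FALSE)
  if (any(amplitudes < 0))
    stop("amplitudes must be non-negative", call. = FALSE)
  if (length(event_times) &&
      (min(event_times) < 0 || max(event_times) > duration))
    stop("event times must lie within [0, duration]", call. = FALSE)
  n <- round(rate_hz * duration)
  out <- numeric(n)
  if (!length(event_times)) return(out)
  amplitudes <- rep_len(amplitudes, length(event_times))
  # unit-peak normalization: kernel max is at t* = log(decay/rise)/(1/rise-1/decay)
  tpk <- log(decay / rise) * rise * decay / (decay - rise)
  peak <- exp(-tpk / decay) - exp(-tpk / rise)
  t <- (seq_len(n) - 1) / rate_hz
  # kernel support truncated where it has decayed to < 1e-6 of peak
  support <- decay * log(1e6)
  for (k in seq_along(event_times)) {
    i0 <- ceiling(event_times[k] * rate_hz) + 1
    i1 <- min(n, floor((event_times[k] + support) * rate_hz) + 1)
    if (i0 > n || i1 < i0) next
    dt <- t[i0:i1] - event_times[k]
    out[i0:i1] <- out[i0:i1] +
      amplitudes[k] * (exp(-dt / decay) - exp(-dt / rise)) / peak
  }
  out
}

# piecewise-constant SCR rate (events/min) over [0, dur), from the call list
stress_segments <- function(cfg) {
  dur <- cfg$shift_hours * 3600
  bounds <- c(0, dur)
  lev <- character(0)
  starts <- numeric(0)
  for (cl in cfg$calls) {
    s <- cl$dispatched - cfg$shift_start
    e <- call_end(cl) - cfg$shift_start
    bounds <- c(bounds, s, e)
    starts <- c(starts, s)
    lev <- c(lev, cl$stress_level)
  }
  bounds <- sort(unique(bounds))
  seg <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  seg$level <- "none"
  for (i in seq_along(starts)) {
    e <- call_end(cfg$calls[[i]]) - cfg$shift_start
    inside <- seg$start >= starts[i] & seg$end <= e
    seg$level[inside] <- lev[i]
  }
  seg$rate <- cfg$scr_rate_by_stress[seg$level]
  seg
}

#' Generate one synthetic officer-shift of sensor streams
#'
#' Builds a full [sensor_session()] from a [synth_config()]: EDA is a
#' drifting tonic level plus a train of SCR kernels (Poisson arrivals whose
#' rate follows the call schedule's stress levels) plus Gaussian noise,
#' clipped below at 0.001 microsiemens; temperature is a slow oscillation
#' around `temp_base`; acceleration is gravity plus noise with randomly
#' placed movement bouts; BVP is a unit-amplitude waveform tracking the
#' instantaneous heart phase; beats give the IBI record, from which random
#' contiguous spans are deleted to emulate sensor dropout.
#'
#' Ground truth for downstream tests is attached as
#' `attr(session, "truth")`: the injected SCR event log (`scr_events`), the
#' realized IBI gap schedule (`ibi_gaps`), and the movement bout schedule
#' (`activity_bouts`). Output is deterministic given the config (seed
#' included).
#'
#' @param config a [synth_config()].
#' @return a [sensor_session()] with a `truth` attribute.
#' @export
synth_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_calls(config)
  set.seed(config$seed)
  dur <- config$shift_hours * 3600
  n_eda <- round(4 * dur)
  t_eda <- (seq_len(n_eda) - 1) / 4

  # --- SCR events: piecewise-constant-rate Poisson process -------------
  seg <- stress_segments(config)
  ev_time <- numeric(0); ev_level <- character(0)
  for (i in seq_len(nrow(seg))) {
    len <- seg$end[i] - seg$start[i]
    nev <- rpois(1, seg$rate[i] * len / 60)
    if (nev > 0) {
      ev_time <- c(ev_time, sort(runif(nev, seg$start[i], seg$end[i])))
      ev_level <- c(ev_level, rep(seg$level[i], nev))
    }
  }
  o <- order(ev_time)
  ev_time <- ev_time[o]; ev_level <- ev_level[o]
  ev_amp <- rlnorm(length(ev_time), config$scr_amp_meanlog, config$scr_amp_sdlog)
  phasic <- synth_scr_train(ev_time, config$scr_rise, config$scr_decay,
                            ev_amp, 4, dur)
  tonic <- config$tonic_level + config$tonic_drift * t_eda / 3600
  eda_v <- tonic + phasic + rnorm(n_eda, 0, config$noise_sd)
  eda_v <- pmax(eda_v, 0.001)

  # --- temperature: slow drift-free oscillation + small noise ----------
  temp_v <- config$temp_base +
    0.5 * sin(2 * pi * t_eda / (3 * 3600)) + rnorm(n_eda, 0, 0.02)
  temp_v <- pmin(pmax(temp_v, 20), 45)

  # --- acceleration: gravity + noise + movement bouts ------------------
  n_acc <- round(32 * dur)
  acc_v <- cbind(rnorm(n_acc, 0, 0.01), rnorm(n_acc, 0, 0.01),
                 rnorm(n_acc, 1, 0.01))
  n_bout <- rpois(1, config$activity_bout_rate * config$shift_hours)
  bout_start <- sort(runif(n_bout, 0, dur))
  bout_len <- runif(n_bout, 30, 120)
  for (b in seq_len(n_bout)) {
    i0 <- floor(bout_start[b] * 32) + 1
    i1 <- min(n_acc, floor((bout_start[b] + bout_len[b]) * 32))
    if (i1 < i0) next
    m <- i1 - i0 + 1
    # band-limited shaking: a few Hz of oscillation with random phase
    tb <- (seq_len(m) - 1) / 32
    for (ax in 1:3) {
      f <- runif(1, 1, 4)
      acc_v[i0:i1, ax] <- acc_v[i0:i1, ax] +
        0.3 * sin(2 * pi * f * tb + runif(1, 0, 2 * pi)) + rnorm(m, 0, 0.05)
    }
  }

  # --- beats, BVP and IBI with logged dropout gaps ---------------------
  period_at <- function(tt) {
    p <- rep(config$heart_period, length(tt))
    for (cl in config$calls) {
      if (cl$stress_level != "high") next
      s <- cl$dispatched - config$shift_start
      e <- call_end(cl) - config$shift_start
      p[tt >= s & tt < e] <- config$heart_period_high
    }
    p
  }
  n_max <- ceiling(dur / (0.9 * config$heart_period_high))
  jit <- rnorm(n_max, 0, 0.02)
  beats <- numeric(n_max); tcur <- config$heart_period; k <- 0L
  while (tcur < dur && k < n_max) {
    k <- k + 1L
    beats[k] <- tcur
    tcur <- tcur + period_at(tcur) * pmax(1 + jit[k], 0.5)
  }
  beats <- beats[seq_len(k)]
  ibi_all <- data.frame(offset = beats,
                        duration = c(beats[1], diff(beats)))

  n_gap <- rpois(1, config$ibi_gap_rate * config$shift_hours)
  gap_start <- sort(runif(n_gap, 0, dur))
  gap_len <- runif(n_gap, config$ibi_gap_len[1], config$ibi_gap_len[2])
  gap_end <- pmin(gap_start + gap_len, dur)
  keep <- rep(TRUE, nrow(ibi_all))
  for (g in seq_len(n_gap))
    keep <- keep & !(ibi_all$offset >= gap_start[g] & ibi_all$offset <= gap_end[g])
  # surviving beats keep their own beat-to-beat durations; a deleted span
  # then shows up as an offset discontinuity, exactly as device dropout does
  ibi <- ibi_all[keep, , drop = FALSE]
  rownames(ibi) <- NULL

  # BVP: sinusoid of the instantaneous heart phase
  n_bvp <- round(64 * dur)
  t_bvp <- (seq_len(n_bvp) - 1) / 64
  phase <- stats::approx(x = c(0, beats, dur), y = 0:(length(beats) + 1),
                         xout = t_bvp, rule = 2)$y
  bvp_v <- sin(2 * pi * phase)

  session <- sensor_session(
    eda = raw_stream(config$shift_start, 4, eda_v),
    temp = raw_stream(config$shift_start, 4, temp_v),
    acc = raw_stream(config$shift_start, 32, acc_v),
    bvp = raw_stream(config$shift_start, 64, bvp_v),
    ibi = ibi
  )
  attr(session, "truth") <- list(
    scr_events = data.frame(time = ev_time, amplitude = ev_amp,
                            level = ev_level),
    ibi_gaps = if (n_gap) data.frame(start = gap_start, end = gap_end)
               else data.frame(start = numeric(0), end = numeric(0)),
    activity_bouts = if (n_bout) data.frame(start = bout_start,
                                            end = pmin(bout_start + bout_len, dur))
                     else data.frame(start = numeric(0), end = numeric(0))
  )
  session
}

#' Build the CAD event log for a synthetic shift
#'
#' One record per configured call, carrying the officer identifier, call
#' details (type, priority), the lifecycle timestamps, and the canceled flag.
#' Lifecycle order and non-overlap are enforced.
#'
#' @param config a [synth_config()].
#' @return a `cad_log` data frame (see [read_cad_log()] for columns).
#' @export
synth_cad_log <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_calls(config)
  calls <- config$calls
  df <- data.frame(
    officer_id = vapply(calls, function(x) as.character(x$officer_id), ""),
    call_id = vapply(calls, function(x) as.character(x$call_id), ""),
    call_type = vapply(calls, function(x) as.character(x$call_type), ""),
    priority = vapply(calls, function(x) as.integer(x$priority), 1L),
    received = vapply(calls, `[[`, 0, "received"),
    dispatched = vapply(calls, `[[`, 0, "dispatched"),
    arrive1 = vapply(calls, `[[`, 0, "arrive1"),
    arrive2 = vapply(calls, `[[`, 0, "arrive2"),
    transport = vapply(calls, `[[`, 0, "transport"),
    cleared = vapply(calls, `[[`, 0, "cleared"),
    canceled = vapply(calls, `[[`, TRUE, "canceled"),
    canceled_time = vapply(calls, `[[`, 0, "canceled_time"),
    stringsAsFactors = FALSE
  )
  if (!length(calls))
    df <- empty_cad_log()
  as_cad_log(df)
}

#' Build the AVL ping track for a synthetic shift
#'
#' Ping cadence follows the movement schedule implied by the CAD log: the
#' fast interval while en route to a call (dispatch to first arrival), the
#' slow interval otherwise. Coordinates are planar xy in meters from an
#' arbitrary origin; while en route the vehicle moves linearly toward a
#' per-call scene location. Each ping carries time, xy, speed, status,
#' call id (when within a call span) and officer id.
#'
#' @param config a [synth_config()].
#' @param cad a `cad_log` as returned by [synth_cad_log()].
#' @param officer_id officer identifier stamped on pings when the CAD log is
#'   empty.
#' @return an `avl_track` data frame (see [read_avl_track()] for columns).
#' @export
synth_avl_track <- function(config, cad, officer_id = "officer-1") {
  stopifnot(inherits(config, "synth_config"))
  cad <- as_cad_log(cad)
  set.seed(config$seed + 2000029L)
  dur <- config$shift_hours * 3600
  if (nrow(cad)) officer_id <- cad$officer_id[1]

  enroute <- cbind(cad$dispatched, cad$arrive1) - config$shift_start
  enroute <- enroute[!is.na(enroute[, 2]), , drop = FALSE]
  span_start <- cad$dispatched - config$shift_start
  span_end <- ifelse(cad$canceled, cad$canceled_time,
                     ifelse(is.na(cad$cleared), cad$dispatched, cad$cleared)) -
    config$shift_start
  scene <- matrix(rnorm(2 * nrow(cad), 0, 2000), ncol = 2)

  in_which <- function(tt, lo, hi) {
    i <- which(tt >= lo & tt < hi)
    if (length(i)) i[1] else NA_integer_
  }

  t <- 0; pos <- c(0, 0)
  times <- numeric(0); xs <- numeric(0); ys <- numeric(0)
  speeds <- numeric(0); status <- character(0); call_ids <- character(0)
  while (t <= dur) {
    ie <- in_which(t, enroute[, 1], enroute[, 2])
    ic <- in_which(t, span_start, span_end)
    st <- if (!is.na(ie)) "enroute" else if (!is.na(ic)) "onscene" else "stationary"
    dt <- if (st == "enroute") config$avl_ping_fast else config$avl_ping_slow
    sp <- 0
    if (st == "enroute") {
      # move toward the scene at a speed that would arrive on time
      tgt <- scene[which(span_start == enroute[ie, 1])[1], ]
      remain <- enroute[ie, 2] - t
      step <- if (remain > dt) (tgt - pos) * dt / remain else (tgt - pos)
      pos <- pos + step
      sp <- sqrt(sum(step^2)) / dt
    }
    times <- c(times, t); xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
    speeds <- c(speeds, sp); status <- c(status, st)
    call_ids <- c(call_ids, if (!is.na(ic)) cad$call_id[ic] else NA_character_)
    t <- t + dt
  }
  as_avl_track(data.frame(
    time = config$shift_start + times, x = xs, y = ys, speed = speeds,
    status = status, call_id = call_ids, officer_id = officer_id,
    stringsAsFactors = FALSE
  ))
}
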