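# Independent brute-force oracles for the windowed metrics. These are
# deliberately naive (explicit loops, stats::lm where a line is fit) and
# share nothing with the package's vectorized implementations beyond the
# filtered input streams they both consume.

naive_peaks <- function(x, rate_hz, threshold, min_sep) {
  n <- length(x)
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    if (x[i] > x[i - 1] && x[i] >= x[i + 1] && x[i] >= threshold)
      cand <- c(cand, i)
  }
  kept <- integer(0)
  pool <- cand
  while (length(pool)) {
    best <- pool[x[pool] == max(x[pool])][1]  # ties: earliest
    kept <- c(kept, best)
    pool <- pool[abs(pool - best) >= min_sep * rate_hz]
  }
  sort(kept)
}

naive_mode_larger <- function(v) {
  counts <- sapply(unique(v), function(u) sum(v == u))
  max(unique(v)[counts == max(counts)])
}

naive_window_table <- function(session, width = 20, n_hist = 60,
                               high = 0.15, low = 0.02, sep = 1,
                               tz_offset = 0) {
  decomp <- decompose_eda(session$eda)
  base <- decomp$baseline$values
  band <- decomp$bandpass$values
  rate <- 4
  per <- rate * width
  K <- floor(length(base) / per)

  act <- activity_signal(session$acc)$values
  temp <- session$temp$values

  avg <- slope20 <- slope120 <- rms <- numeric(K)
  nph <- npl <- integer(K)
  aph <- apl <- rep(NA_real_, K)
  avg_act <- avg_temp <- numeric(K)
  bad <- integer(K)

  t_all <- (seq_along(base) - 1) / rate
  for (k in seq_len(K)) {
    idx <- ((k - 1) * per + 1):(k * per)
    avg[k] <- mean(base[idx])
    slope20[k] <- coef(stats::lm(base[idx] ~ t_all[idx]))[2]
    mid <- (k - 1) * width + width / 2
    sel <- which(t_all >= mid - 60 & t_all < mid + 60)
    slope120[k] <- if (length(sel) < rate * 120 / 2) NA_real_ else
      coef(stats::lm(base[sel] ~ t_all[sel]))[2]
    rms[k] <- sqrt(mean(band[idx]^2))
    ph <- naive_peaks(band[idx], rate, high, sep)
    pl <- naive_peaks(band[idx], rate, low, sep)
    nph[k] <- length(ph); npl[k] <- length(pl)
    if (length(ph)) aph[k] <- mean(band[idx][ph])
    if (length(pl)) apl[k] <- mean(band[idx][pl])

    # per-second activity counts then mean of the window's 20
    counts <- numeric(width)
    for (s in seq_len(width)) {
      e0 <- ((k - 1) * width + s - 1) * 32 + 1
      counts[s] <- sum(abs(act[e0:(e0 + 31)]))
    }
    avg_act[k] <- mean(counts)
    avg_temp[k] <- mean(temp[idx])

    flags <- integer(4)
    for (q in 1:4) {
      f0 <- ((k - 1) * 4 + q - 1) * 5 * rate + 1
      e <- session$eda$values[f0:(f0 + 5 * rate - 1)]
      tv <- temp[f0:(f0 + 5 * rate - 1)]
      is_bad <- any(e < 0.01 | e > 100) || any(abs(diff(e)) > 5) ||
        any(tv < 20 | tv > 45)
      flags[q] <- if (is_bad) -1L else 1L
    }
    bad[k] <- sum(flags)
  }

  avg_diff <- avg_z <- rms_diff <- rms_z <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    lo <- k - n_hist - 1
    hi <- k - 2
    if (lo < 1) next
    pop_a <- avg[lo:hi]; pop_r <- rms[lo:hi]
    avg_diff[k] <- avg[k] - mean(pop_a)
    if (sd(pop_a) > 0) avg_z[k] <- (avg[k] - mean(pop_a)) / sd(pop_a)
    rms_diff[k] <- rms[k] - mean(pop_r)
    if (sd(pop_r) > 0) rms_z[k] <- (rms[k] - mean(pop_r)) / sd(pop_r)
  }

  ts <- session$start_time + width * (seq_len(K) - 1)
  data.frame(
    time_stamp = ts,
    elapsed_time = width * (seq_len(K) - 1),
    elapsed_from_midnight = (ts + tz_offset) %% 86400,
    event_code = rep(0, K),
    bad_data_value = bad,
    avg_activity_count = avg_act,
    avg_temp = avg_temp,
    avg_eda_level = avg, avg_eda_level_diff = avg_diff,
    avg_eda_level_z = avg_z,
    eda_slope_20s = slope20, eda_slope_120s = slope120,
    rms_eda = rms, rms_eda_diff = rms_diff, rms_eda_z = rms_z,
    n_peaks_high = nph, avg_peak_height_high = aph,
    n_peaks_low = npl, avg_peak_height_low = apl
  )
}

# short session with a handful of calls, reused across tests
make_test_config <- function(seed = 11, hours = 0.5, calls = list(), ...) {
  synth_config(seed = seed, shift_hours = hours, calls = calls, ...)
}

# a decomposition object built directly from known component streams
make_decomp <- function(baseline, bandpass, rate = 4, start = 0) {
  structure(
    list(baseline = raw_stream(start, rate, baseline),
         bandpass = raw_stream(start, rate, bandpass)),
    class = "eda_decomposition"
  )
}

# amplitude of a sinusoid at frequency f in a stream, by discrete Fourier
# projection over an integer number of cycles (independent of the filters)
fft_amplitude <- function(x, rate, f) {
  n_cyc <- floor(length(x) / rate / (1 / f))
  n <- round(n_cyc * rate / f)
  x <- x[seq_len(n)]
  t <- (seq_len(n) - 1) / rate
  2 * sqrt(mean(x * sin(2 * pi * f * t))^2 + mean(x * cos(2 * pi * f * t))^2)
}
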