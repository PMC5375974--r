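make_call <- function(start, len = 600, stress = "high", id = "C001",
                      officer = "officer-1") {
  call_spec(call_id = id, officer_id = officer,
            call_type = if (stress == "high") "domestic_disturbance"
                        else "traffic_stop",
            priority = if (stress == "high") 1L else 3L,
            stress_level = stress,
            received = start, dispatched = start + 30,
            arrive1 = start + 150, cleared = start + 150 + len)
}

test_that("generator is deterministic and streams have the contracted shapes", {
  cfg <- make_test_config(seed = 5, hours = 0.2)
  s1 <- synth_session(cfg)
  s2 <- synth_session(cfg)
  expect_identical(s1, s2)

  dur <- 0.2 * 3600
  expect_equal(n_samples(s1$eda), 4 * dur)
  expect_equal(n_samples(s1$temp), 4 * dur)
  expect_equal(n_samples(s1$acc), 32 * dur)
  expect_equal(n_samples(s1$bvp), 64 * dur)
  expect_equal(n_channels(s1$acc), 3L)

  cfg12 <- synth_config(seed = 5, shift_hours = 12)
  s12 <- synth_session(cfg12)
  expect_equal(n_samples(s12$eda), 172800)
})

test_that("with no signal sources the EDA is flat at the tonic level", {
  cfg <- make_test_config(seed = 3, hours = 0.1, tonic_drift = 0,
                          noise_sd = 0,
                          scr_rate_by_stress = c(none = 0, low = 0, high = 0))
  s <- synth_session(cfg)
  expect_equal(s$eda$values, rep(2, 4 * 360))
})

test_that("EDA stays positive under heavy noise (clipped at 0.001)", {
  cfg <- make_test_config(seed = 9, hours = 0.1, noise_sd = 5)
  s <- synth_session(cfg)
  expect_true(min(s$eda$values) >= 0.001)
})

test_that("SCR arrivals are denser inside a high-stress call than off-call", {
  call <- make_call(1464771600 + 600, len = 900, stress = "high")
  cfg <- make_test_config(seed = 21, hours = 1, calls = list(call))
  s <- synth_session(cfg)
  ev <- attr(s, "truth")$scr_events
  span <- c(call$dispatched, call$cleared) - cfg$shift_start
  in_call <- sum(ev$time >= span[1] & ev$time < span[2])
  # equal-length quiet interval at the end of the shift
  quiet <- c(3600 - diff(span), 3600)
  off_call <- sum(ev$time >= quiet[1] & ev$time < quiet[2])
  expect_gt(in_call, off_call)
})

test_that("injected SCRs are recoverable by downstream peak detection", {
  cfg <- make_test_config(seed = 33, hours = 0.5, noise_sd = 0,
                          scr_rate_by_stress = c(none = 1, low = 2, high = 5))
  s <- synth_session(cfg)
  ev <- attr(s, "truth")$scr_events
  decomp <- decompose_eda(s$eda)
  # detect over the whole phasic stream at the low threshold
  pk <- detect_peaks(decomp$bandpass$values, 4, 0.02, 1)
  hit <- vapply(ev$time, function(tt)
    any(pk$time >= tt & pk$time <= tt + 3), TRUE)
  expect_gte(mean(hit), 0.8)
})

test_that("SCR kernel train is zero without events, unit-peaked, and linear", {
  expect_equal(synth_scr_train(numeric(0), 0.75, 3, numeric(0), 4, 60),
               rep(0, 240))
  one <- synth_scr_train(30, 0.75, 3, 1, 4, 120)
  expect_lt(abs(max(one) - 1), 0.01)
  expect_true(all(one[1:120] == 0))  # zero before the event at 30 s
  a <- synth_scr_train(20, 0.75, 3, 0.5, 4, 120)
  b <- synth_scr_train(30, 0.75, 3, 1.2, 4, 120)
  both <- synth_scr_train(c(20, 30), 0.75, 3, c(0.5, 1.2), 4, 120)
  expect_equal(both, a + b)
})

test_that("generator rejects invalid configurations and inputs", {
  expect_error(synth_config(shift_hours = 0), "positive")
  expect_error(synth_config(scr_rise = 3, scr_decay = 1), "scr_decay")
  expect_error(synth_config(avl_ping_fast = 60, avl_ping_slow = 30),
               "avl_ping_fast")
  expect_error(synth_scr_train(10, 0.75, 3, -1, 4, 60), "non-negative")
  expect_error(synth_scr_train(100, 0.75, 3, 1, 4, 60), "within")
  late <- make_call(1464771600 + 3500, len = 900)
  expect_error(synth_config(shift_hours = 1, calls = list(late)),
               "within the shift")
  a <- make_call(1464771600 + 600, len = 900)
  b <- make_call(1464771600 + 900, len = 900, id = "C002")
  expect_error(synth_config(shift_hours = 2, calls = list(a, b)),
               "overlapping")
})

test_that("CAD log mirrors the configured calls with valid lifecycles", {
  cfg0 <- make_test_config(seed = 2, hours = 1)
  expect_equal(nrow(synth_cad_log(cfg0)), 0L)

  canc <- call_spec(call_id = "C009", officer_id = "officer-1",
                    call_type = "canceled_call", priority = 3L,
                    stress_level = "low",
                    received = 1464771700, dispatched = 1464771760,
                    canceled = TRUE, canceled_time = 1464771900)
  cfg1 <- make_test_config(seed = 2, hours = 1, calls = list(canc))
  log1 <- synth_cad_log(cfg1)
  expect_true(log1$canceled[1])
  expect_false(is.na(log1$received[1]))
  expect_false(is.na(log1$dispatched[1]))
  expect_true(is.na(log1$arrive1[1]))
  expect_true(is.na(log1$cleared[1]))

  cfg <- synth_config(seed = 4, shift_hours = 6)
  calls <- synth_calls(cfg, n_calls = 8, p_canceled = 0)
  cfg <- synth_config(seed = 4, shift_hours = 6, calls = calls)
  log <- synth_cad_log(cfg)
  expect_equal(nrow(log), 8L)
  expect_true(all(log$cleared > log$dispatched))
  expect_true(all(log$dispatched >= log$received))
})

test_that("AVL ping cadence follows the movement schedule", {
  cfg0 <- make_test_config(seed = 6, hours = 1)
  avl0 <- synth_avl_track(cfg0, synth_cad_log(cfg0))
  expect_equal(nrow(avl0), floor(3600 / 30) + 1)
  expect_true(all(diff(avl0$time) == 30))

  cfg <- synth_config(seed = 6, shift_hours = 2)
  calls <- synth_calls(cfg, n_calls = 3, p_canceled = 0)
  cfg <- synth_config(seed = 6, shift_hours = 2, calls = calls)
  cad <- synth_cad_log(cfg)
  avl <- synth_avl_track(cfg, cad)
  expect_true(all(avl$time >= cfg$shift_start))
  expect_true(all(avl$time <= cfg$shift_start + 2 * 3600))
  # consecutive pings that are both en route are never farther apart than
  # consecutive stationary pings
  gaps <- diff(avl$time)
  enroute_pair <- avl$status[-nrow(avl)] == "enroute" &
    avl$status[-1] == "enroute"
  stat_pair <- avl$status[-nrow(avl)] == "stationary" &
    avl$status[-1] == "stationary"
  expect_true(max(gaps[enroute_pair]) <= min(gaps[stat_pair]))
  # speed positive only while moving
  expect_true(all(avl$speed[avl$status != "enroute"] == 0))
})

test_that("logged IBI gap schedule matches what quality assessment recovers", {
  cfg <- make_test_config(seed = 13, hours = 1, ibi_gap_rate = 3)
  s <- synth_session(cfg)
  truth <- attr(s, "truth")$ibi_gaps
  expect_gt(nrow(truth), 0)
  q <- ibi_gap_stats(s$ibi, session_duration(s))
  # every truth gap overlaps a detected gap of comparable length
  for (g in seq_len(nrow(truth))) {
    ovl <- q$gaps$start < truth$end[g] & q$gaps$end > truth$start[g]
    expect_true(any(ovl))
    det <- q$gaps[ovl, ][1, ]
    expect_lt(abs((det$end - det$start) - (truth$end[g] - truth$start[g])), 3)
  }
})
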