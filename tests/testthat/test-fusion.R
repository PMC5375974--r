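base_t <- 1464771600

std_call <- function(dispatch, arrive1 = NULL, arrive2 = NULL,
                     transport = NULL, cleared = NULL, canceled = FALSE,
                     canceled_time = NULL, id = "C001") {
  df <- shiftsense:::empty_cad_log()
  df[1, c("officer_id", "call_id", "call_type")] <-
    c("officer-1", id, "test_call")
  df$priority[1] <- 2L
  df$received[1] <- dispatch - 60
  df$dispatched[1] <- dispatch
  df$arrive1[1] <- if (is.null(arrive1)) NA_real_ else arrive1
  df$arrive2[1] <- if (is.null(arrive2)) NA_real_ else arrive2
  df$transport[1] <- if (is.null(transport)) NA_real_ else transport
  df$cleared[1] <- if (is.null(cleared)) NA_real_ else cleared
  df$canceled[1] <- canceled
  df$canceled_time[1] <- if (is.null(canceled_time)) NA_real_ else canceled_time
  df
}

test_that("an empty CAD log yields an all-zero timeline", {
  tl <- event_assignment_timeline(shiftsense:::empty_cad_log(),
                                  c(base_t, base_t + 600))
  expect_equal(nrow(tl), 600L)
  expect_true(all(tl$value == 0))
  expect_true(all(is.na(tl$call_id)))
})

test_that("call phases paint the printed per-second values", {
  cad <- std_call(base_t + 100, arrive1 = base_t + 220,
                  cleared = base_t + 400)
  tl <- event_assignment_timeline(cad, c(base_t, base_t + 600))
  expect_equal(sum(tl$value == 1.0), 120L)  # dispatch to first arrival
  expect_equal(sum(tl$value == 2.0), 180L)  # on scene until cleared
  expect_equal(sum(tl$value == 0), 300L)
  expect_true(all(tl$value[tl$time >= base_t + 100 &
                           tl$time < base_t + 220] == 1.0))

  canc <- std_call(base_t + 100, canceled = TRUE,
                   canceled_time = base_t + 250)
  tlc <- event_assignment_timeline(canc, c(base_t, base_t + 600))
  expect_true(all(tlc$value[tlc$time >= base_t + 100 &
                            tlc$time < base_t + 250] == 0.5))
  expect_equal(sum(tlc$value == 0.5), 150L)

  full <- std_call(base_t + 60, arrive1 = base_t + 120,
                   arrive2 = base_t + 200, transport = base_t + 300,
                   cleared = base_t + 420)
  tlf <- event_assignment_timeline(full, c(base_t, base_t + 600))
  expect_true(all(tlf$value[tlf$time >= base_t + 300 &
                            tlf$time < base_t + 420] == 3.0))
  expect_true(all(tlf$value[tlf$time >= base_t + 200 &
                            tlf$time < base_t + 300] == 2.5))
  expect_true(all(tlf$value[tlf$time >= base_t + 120 &
                            tlf$time < base_t + 200] == 2.0))

  # second arrival but no transport: on-scene code continues to cleared
  noturn <- std_call(base_t + 60, arrive1 = base_t + 120,
                     arrive2 = base_t + 200, cleared = base_t + 420)
  tln <- event_assignment_timeline(noturn, c(base_t, base_t + 600))
  expect_true(all(tln$value[tln$time >= base_t + 200 &
                            tln$time < base_t + 420] == 2.0))

  expect_true(all(tlf$value %in% c(0, 0.5, 1, 2, 2.5, 3)))
})

test_that("overlapping calls are rejected", {
  a <- std_call(base_t + 100, arrive1 = base_t + 200, cleared = base_t + 500)
  b <- std_call(base_t + 400, arrive1 = base_t + 450, cleared = base_t + 700,
                id = "C002")
  expect_error(event_assignment_timeline(rbind(a, b), c(base_t, base_t + 900)),
               "overlapping")
})

test_that("windowed event code is the mode with ties toward the deeper phase", {
  expect_equal(window_event_code(rep(1.0, 20)), 1.0)
  expect_equal(window_event_code(c(rep(0, 12), rep(1, 8))), 0)
  # oracle check: equal counts, then the tie-break
  v <- c(rep(1, 10), rep(2, 10))
  expect_equal(sum(v == 1), sum(v == 2))
  expect_equal(naive_mode_larger(v), 2.0)
  expect_equal(window_event_code(v), 2.0)
  expect_equal(window_event_code(c(rep(0.5, 7), rep(0, 6), rep(3, 7))), 3.0)
})

test_that("AVL linkage picks the nearest ping within tolerance", {
  avl <- data.frame(time = base_t + c(0, 100, 210), x = c(1, 2, 3),
                    y = c(10, 20, 30), speed = 0, status = "stationary",
                    call_id = NA_character_, officer_id = "officer-1")
  got <- link_avl(base_t + c(100, 155, 300), avl, tolerance = 30)
  expect_equal(got$x, c(2, NA, NA))  # 155 is 45 s from nearest (tol 30)
  got2 <- link_avl(base_t + 155, avl, tolerance = 60)
  expect_equal(got2$x, 2)  # 55 s to ping 2 beats 55... ties go to earlier

  # dense track: every midpoint resolves and matches brute-force search
  dense <- data.frame(time = base_t + seq(0, 1000, by = 10),
                      x = rnorm(101), y = rnorm(101), speed = 0,
                      status = "stationary", call_id = NA_character_,
                      officer_id = "officer-1")
  mids <- base_t + seq(10, 990, by = 20) + 10
  got3 <- link_avl(mids, dense, tolerance = 30)
  for (j in seq_along(mids)) {
    b <- which.min(abs(dense$time - mids[j]))
    expect_equal(got3$x[j], dense$x[b])
  }
  expect_true(all(!is.na(got3$x)))
})

test_that("fusion joins call context without changing the row count", {
  cfg <- synth_config(seed = 23, shift_hours = 1)
  calls <- synth_calls(cfg, n_calls = 2, p_high = 1, p_canceled = 0)
  cfg <- synth_config(seed = 23, shift_hours = 1, calls = calls)
  s <- synth_session(cfg)
  cad <- synth_cad_log(cfg)
  avl <- synth_avl_track(cfg, cad)
  tl <- event_assignment_timeline(cad, c(cfg$shift_start,
                                         cfg$shift_start + 3600))
  wt <- extract_metrics(s, tl)
  fz <- fuse(wt, cad, avl)

  expect_equal(nrow(fz), nrow(wt))
  expect_s3_class(fz, "fused_table")
  expect_true(all(c("call_id", "call_type", "priority", "allocated",
                    "x", "y") %in% names(fz)))

  # windows inside a call carry that call's priority and id
  for (i in seq_len(nrow(cad))) {
    inside <- fz$time_stamp >= cad$dispatched[i] + 20 &
      fz$time_stamp + 20 <= cad$cleared[i] - 20
    expect_true(all(fz$call_id[inside] == cad$call_id[i]))
    expect_true(all(fz$priority[inside] == cad$priority[i]))
    expect_true(all(fz$allocated[inside]))
  }
  # fully off-call windows carry no context
  tl_mat <- matrix(tl$value[seq_len(nrow(fz) * 20)], nrow = 20)
  off <- colSums(tl_mat > 0) == 0
  expect_true(all(is.na(fz$call_id[off])))
  expect_true(all(!fz$allocated[off]))

  # event spans recovered within one window of the generator truth
  for (i in seq_len(nrow(cad))) {
    coded <- which(fz$event_code > 0 & fz$call_id == cad$call_id[i])
    span_windows <- (cad$cleared[i] - cad$dispatched[i]) / 20
    expect_lt(abs(length(coded) - span_windows), 2)
  }
})

test_that("empty context leaves the window table intact with missing columns", {
  s <- synth_session(make_test_config(seed = 24, hours = 1 / 6))
  wt <- extract_metrics(s)
  fz <- fuse(wt, shiftsense:::empty_cad_log(),
             synth_avl_track(make_test_config(seed = 24, hours = 1 / 6),
                             shiftsense:::empty_cad_log())[0, ])
  expect_equal(nrow(fz), nrow(wt))
  expect_true(all(is.na(fz$call_id)))
  expect_true(all(!fz$allocated))
  expect_true(all(is.na(fz$x)))
  expect_equal(fz$avg_eda_level, wt$avg_eda_level)
})

test_that("officer mismatch across CAD and AVL is an error", {
  cfg <- synth_config(seed = 25, shift_hours = 1)
  calls <- synth_calls(cfg, n_calls = 1, p_canceled = 0)
  cfg <- synth_config(seed = 25, shift_hours = 1, calls = calls)
  s <- synth_session(cfg)
  cad <- synth_cad_log(cfg)
  avl <- synth_avl_track(cfg, cad)
  avl$officer_id <- "officer-2"
  wt <- extract_metrics(s)
  expect_error(fuse(wt, cad, avl), "officer-id mismatch")
})
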