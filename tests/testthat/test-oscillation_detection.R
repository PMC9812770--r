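test_that("make_trace averages, standardizes and masks artifacts", {
  X <- rbind(sin(1:1000 / 10), sin(1:1000 / 10))
  rec <- recording(X, rate = 100, area = "M1")
  expect_equal(make_trace(rec, "plain_mean"), X[1, ])
  # different gains contribute equal variance after z-scoring
  rec2 <- recording(rbind(X[1, ], 10 * X[1, ]), rate = 100, area = "M1")
  tz <- make_trace(rec2, "zscore_mean")
  expect_equal(stats::sd(tz), stats::sd((X[1, ] - mean(X[1, ])) / sd(X[1, ])),
               tolerance = 1e-10)
  # a 50 s.d. spike is masked out
  X3 <- matrix(rnorm(2000), 2)
  X3[1, 500] <- 50 * sd(X3[1, ])
  rec3 <- recording(X3, rate = 100, area = "M1")
  tr <- make_trace(rec3, "plain_mean")
  expect_equal(tr[500], X3[2, 500])      # only the clean channel remains
  expect_error(make_trace(recording(X, 100, "M1",
                                    channel_ok = c(FALSE, FALSE)),
                          "plain_mean"), "no good channels")
})

test_that("zero-phase band-pass preserves in-band tones and rejects out-of-band", {
  rate <- 250
  t <- seq(0, 60, by = 1 / rate)[-1]
  so_band <- default_config()$detection$so
  x1 <- sin(2 * pi * 1 * t)
  y1 <- bandpass_zero_phase(x1, rate, so_band$hp, so_band$lp)
  mid <- (10 * rate):(50 * rate)
  expect_lt(abs(max(y1[mid]) - 1), 0.05)          # amplitude within 5%
  # phase ~ 0: peak positions align within 2 samples
  pk_in <- mid[which.max(x1[mid])]
  pk_out <- mid[which.max(y1[(pk_in - 50):(pk_in + 50)])] # local
  expect_lt(abs(which.max(y1[(pk_in - 50):(pk_in + 50)]) - 51), 3)
  x50 <- sin(2 * pi * 50 * t)
  y50 <- bandpass_zero_phase(x50, rate, so_band$hp, so_band$lp)
  expect_lt(20 * log10(max(abs(y50[mid])) / 1), -20)
  yc <- bandpass_zero_phase(rep(5, length(t)), rate, so_band$hp, so_band$lp)
  expect_lt(max(abs(yc[mid])), 0.05)       # DC rejected to < 1% of input
})

test_that("SO detector applies percentile, amplitude and duration rules", {
  rate <- 200
  n <- 100 * rate
  t <- (1:n) / rate
  base <- sin(2 * pi * 1 * t)                  # candidate waves, amplitude 1
  inject <- function(trace, center_s, halfwave_s, amp = 10) {
    n_half <- round(halfwave_s * rate)
    up <- amp * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n_half)))
    w <- c(up, -up)
    i0 <- round(center_s * rate) - n_half
    trace[(i0 + 1):(i0 + length(w))] <- w
    trace
  }
  nrems <- interval_set(0, 100)
  tr_ok <- inject(base, 50, 0.3)               # peak->trough 300 ms
  ev <- detect_so(tr_ok, rate, nrems)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$t_onset - (50 - 0.3 + 0.15)), 0.05)  # down-state peak
  expect_lt(abs(ev$t_peak - (50 + 0.15)), 0.05)          # up-state trough
  expect_equal(ev$t_peak - ev$t_onset, 0.3, tolerance = 0.02)
  tr_long <- inject(base, 50, 0.6)             # 600 ms -> rejected
  expect_equal(nrow(detect_so(tr_long, rate, nrems)), 0L)
  expect_equal(nrow(detect_so(rep(0, n), rate, nrems)), 0L)
})

test_that("envelope detector honors dual thresholds and minimum duration", {
  rate <- 500
  n <- 120 * rate
  set.seed(9)
  cfg <- default_config()$detection$spindle
  noise <- bandpass_zero_phase(rnorm(n), rate, cfg$hp, cfg$lp)
  noise <- noise / sd(noise)
  inject_burst <- function(trace, center_s, dur_s, freq, amp) {
    m <- round(dur_s * rate)
    tt <- seq_len(m) / rate
    w <- amp * sin(pi * seq(0, 1, length.out = m)) * sin(2 * pi * freq * tt)
    i0 <- round(center_s * rate) - round(m / 2)
    trace[(i0 + 1):(i0 + m)] <- trace[(i0 + 1):(i0 + m)] + w
    trace
  }
  nrems <- interval_set(0, 120)
  tr <- inject_burst(noise, 60, 0.8, 12, 6)
  ev <- detect_envelope_events(tr, rate, nrems, "SPINDLE", config = cfg)
  hit <- which(abs(ev$t_peak - 60) < 0.4)
  expect_length(hit, 1L)
  expect_lt(abs(ev$t_onset[hit] - (60 - 0.4)), 0.1)   # boundary error < 100 ms
  expect_lt(abs(ev$t_end[hit] - (60 + 0.4)), 0.1)
  # oracle: naive sample-by-sample threshold scan of the same envelope
  env <- rep(NA_real_, n)
  env[] <- gaussian_smooth(hilbert_envelope(tr), rate, cfg$env_smooth)
  mu <- mean(env); sg <- sd(env)
  oracle <- brute_envelope_events(env, rate, mu + cfg$lower_sd * sg,
                                  mu + cfg$upper_sd * sg, cfg$min_dur)
  expect_equal(nrow(ev), nrow(oracle))
  expect_equal(ev$t_onset, oracle[, 1] / rate, tolerance = 2 / rate)
  # short SWR-like burst below min duration is rejected
  swr_cfg <- default_config()$detection$swr
  noise2 <- bandpass_zero_phase(rnorm(n), rate, c(150, 4), c(240, 4))
  noise2 <- noise2 / sd(noise2)
  tr2 <- inject_burst(noise2, 60, 0.03, 200, 3)
  ev2 <- detect_envelope_events(tr2, rate, nrems, "SWR", config = swr_cfg)
  expect_false(any(abs(ev2$t_peak - 60) < 0.1))
  # same burst stretched past the minimum duration is accepted
  tr2b <- inject_burst(noise2, 60, 0.1, 200, 6)
  ev2b <- detect_envelope_events(tr2b, rate, nrems, "SWR", config = swr_cfg)
  expect_true(any(abs(ev2b$t_peak - 60) < 0.1))
  # burst above lower but never above upper threshold is rejected
  tr3 <- inject_burst(noise, 30, 0.8, 12, 1.8)
  ev3 <- detect_envelope_events(tr3, rate, nrems, "SPINDLE", config = cfg)
  expect_false(any(abs(ev3$t_peak - 30) < 0.4))
})

test_that("detection is invariant to adding a masked-out artifact sample", {
  blk <- small_sleep_block(seed = 33, sleep_s = 420)
  st <- stage_sleep(blk$recordings$M1)
  det1 <- detect_oscillations(blk$recordings, st$intervals)
  rec2 <- blk$recordings
  mid <- ncol(rec2$M1$samples) %/% 2L
  rec2$M1$samples[1, mid] <- 1e5          # gross artifact on one channel
  det2 <- detect_oscillations(rec2, st$intervals)
  expect_equal(det2$so_m1$t_peak, det1$so_m1$t_peak, tolerance = 1e-6)
  expect_equal(det2$spindle_m1$t_peak, det1$spindle_m1$t_peak,
               tolerance = 1e-6)
})

test_that("detectors recover injected events on a synthetic block", {
  blk <- small_sleep_block(seed = 42, sleep_s = 600)
  st <- stage_sleep(blk$recordings$M1)
  det <- detect_oscillations(blk$recordings, st$intervals)
  tru <- blk$truth$events
  expect_gte(match_f1(det$so_m1$t_peak, tru$m1_so_up)$f1, 0.9)
  expect_gte(match_f1(det$swr$t_peak, tru$swr_peak)$f1, 0.9)
  expect_gte(match_f1(det$spindle_m1$t_peak, tru$spindle_peak)$f1, 0.85)
  # structural invariants: inside NREMS, sorted, non-overlapping
  for (tab in det) {
    if (nrow(tab) == 0L) next
    expect_true(all(in_intervals(tab$t_peak, st$intervals)))
    expect_false(is.unsorted(tab$t_onset))
    if (nrow(tab) > 1L)
      expect_true(all(tab$t_onset[-1L] >= tab$t_end[-nrow(tab)] - 1e-9))
  }
})
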