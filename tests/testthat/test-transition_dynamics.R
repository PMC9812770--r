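test_that("tertile splitting is contiguous with remainder to the last", {
  expect_equal(tertile_split(30), rep(1:3, each = 10))
  expect_equal(table(tertile_split(31)), table(rep(1:3, c(10, 10, 11))))
  sess <- lapply(1:13, function(d) rnorm(30, mean = d))
  ts <- tertile_series(sess, mean)
  expect_equal(nrow(ts), 39L)            # 13 days x 3 tertiles
  tiny <- tertile_series(list(c(1, 2)), mean)
  expect_equal(tiny$value, rep(1.5, 3))
  expect_equal(unique(tiny$flag), "replicated")
})

test_that("smoothing preserves constants and normalization hits [0, 1]", {
  const <- smooth_normalize(rep(4, 20))
  expect_equal(const$smoothed, rep(4, 20))
  expect_equal(const$flag, "constant")
  sn <- smooth_normalize(c(rep(0, 15), rep(1, 24)) + rnorm(39, 0, 0.01))
  expect_equal(range(sn$normalized), c(0, 1))
  # monotone ramp keeps its ordering through kernel smoothing
  ramp <- smooth_normalize(seq(0, 1, length.out = 39))
  expect_false(is.unsorted(ramp$normalized))
})

test_that("sigmoid fit recovers noiseless and noisy midpoints", {
  x <- rep(1:13, each = 3) + rep(0:2 / 3, 13)
  y <- 1 / (1 + exp(-2 * (x - 6.5)))
  f <- fit_sigmoid(x, y)
  expect_lt(abs(f$x_mid - 6.5), 0.05)
  expect_equal(f$direction, "rise")
  expect_gt(f$r2, 0.999)
  flat <- fit_sigmoid(x, rep(0.5, length(x)) + rnorm(length(x), 0, 1e-4))
  expect_true(abs(flat$k) < 1e-3 || flat$r2 < 0.1 ||
                identical(flat$flag, "no_transition"))
  # noisy recovery: median error across replicates within half a day
  set.seed(8)
  errs <- replicate(25, {
    yy <- y + rnorm(length(y), 0, 0.1)
    abs(fit_sigmoid(x, yy)$x_mid - 6.5)
  })
  expect_lte(median(errs), 0.5)
  expect_error(fit_sigmoid(1:5, rnorm(5)), "at least 8")
})

test_that("moving-window scan finds constructed transitions", {
  flat_rise <- c(rep(1, 5), 1 + (1:8) * 0.5) + 0
  ts <- transition_scan(flat_rise)
  expect_equal(ts$day, 6L)
  step9 <- c(rep(0, 8), rep(3, 5))
  expect_equal(transition_scan(step9)$day, 9L)
  lin <- (1:13) * 0.7
  expect_equal(transition_scan(lin)$flag, "no_transition")
  expect_error(transition_scan(1:5), "shorter")
})

test_that("piecewise OLS recovers exact slopes and truncates at the plateau", {
  x <- rep(1:13, each = 3) + rep(0:2 / 3, 13)
  y <- ifelse(x < 6, 0.2 * x, 1.2 + 0.8 * (x - 6))
  pw <- piecewise_slopes(x, y, breakpoints = 6)
  expect_equal(pw$slope, c(0.2, 0.8), tolerance = 1e-10)
  # slopes invariant to adding a constant
  pw2 <- piecewise_slopes(x, y + 5, breakpoints = 6)
  expect_equal(pw2$slope, pw$slope, tolerance = 1e-12)
  # rise then plateau: last segment stops at the argmax
  y3 <- ifelse(x < 6, 0, pmin(x - 6, 4))
  pw3 <- piecewise_slopes(x, y3, breakpoints = 6,
                          truncate_last_at_max = TRUE)
  expect_equal(pw3$to[2], x[which.max(y3)])
  expect_equal(pw3$slope[2], 1, tolerance = 1e-10)
  expect_error(piecewise_slopes(1:4, 1:4, breakpoints = 3.5), "fewer than 3")
})

test_that("change point equals exhaustive SSE minimization", {
  x <- c(rep(0, 20), rep(1, 19))
  cp <- change_point(x)
  expect_equal(cp$index, 21L)
  expect_equal(cp$residual, 0)
  expect_equal(cp$pre_mean, 0); expect_equal(cp$post_mean, 1)
  const <- change_point(rep(2, 10))
  expect_equal(const$index, 2L)          # earliest split on ties
  expect_equal(const$flag, "degenerate")
  expect_error(change_point(1:3), "too short")
  # property: equals an independent cumulative-sum oracle on random series
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(4:50, 1)
    v <- rnorm(n) + c(rep(0, n %/% 2), rep(runif(1, 0, 2), n - n %/% 2))
    cs <- cumsum(v); cs2 <- cumsum(v^2)
    sse <- function(a, b) { # SSE of v[a..b] about its mean, via cumsums
      s <- cs[b] - if (a > 1) cs[a - 1] else 0
      s2 <- cs2[b] - if (a > 1) cs2[a - 1] else 0
      s2 - s^2 / (b - a + 1)
    }
    tot <- vapply(2:n, function(i) sse(1, i - 1) + sse(i, n), numeric(1))
    expect_equal(change_point(v)$index, which.min(tot) + 1L)
  }
})

test_that("success-rate change uses a 2-day history with zero padding", {
  rates <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  ch <- success_rate_change(rates)
  expect_equal(ch[1], 0.1)               # history before day 1 is zero
  expect_equal(ch[2], 0.2 - mean(c(0, 0.1)))
  expect_equal(ch[5], 0.5 - mean(c(0.3, 0.4)))
})

test_that("logistic staging splits sessions at the grand-midpoint", {
  expect_equal(stage_model(1:13, rnorm(13), rnorm(13), 6.2, 7.9)$grand_midpoint,
               7.05)
  # well-separated synthetic stages classify accurately
  set.seed(11)
  day <- 1:13
  dso <- ifelse(day <= 7, 8, 2) + rnorm(13, 0, 0.5)
  pm <- ifelse(day <= 7, 30, 70) + rnorm(13, 0, 3)
  sm <- stage_model(day, dso, pm, 6.5, 7.5)
  acc <- mean((sm$prob > 0.5) == (sm$stage == 2L))
  expect_gte(acc, 0.95)
  expect_error(stage_model(1:5, rnorm(5), rnorm(5), 20, 22), "degenerate")
})
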