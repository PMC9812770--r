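test_that("nearest-lag linkage matches brute force and breaks ties earlier", {
  expect_equal(nearest_lags(c(1, 5, 9), c(1, 5, 9))$lags, c(0, 0, 0))
  # exactly midway -> earlier reference -> positive lag
  expect_equal(nearest_lags(5, c(4, 6))$lags, 1)
  set.seed(4)
  tg <- runif(300, 0, 100); rf <- runif(40, 0, 100)
  expect_equal(nearest_lags(tg, rf)$lags, brute_nearest_lags(tg, rf))
  expect_error(nearest_lags(1, numeric(0)), "empty reference")
})

test_that("coupling fractions count closed windows in percent", {
  ls0 <- nearest_lags(c(1, 2, 3), c(1, 2, 3))
  expect_equal(coupling_fraction(ls0, c(-0.5, 0.5))$value, 100)
  ls <- list(lags = c(-1.0, 0.5, 0.9), n_targets = 3L)
  expect_equal(coupling_fraction(ls, c(-0.75, 0.75))$value, 100 / 3,
               tolerance = 1e-10)
  und <- coupling_fraction(list(lags = numeric(0), n_targets = 0L), c(-1, 1))
  expect_true(is.na(und$value))
  expect_equal(und$flag, "undefined")
  # window endpoints are closed
  expect_equal(coupling_fraction(list(lags = 0.75, n_targets = 1L),
                                 c(-0.75, 0.75))$value, 100)
})

test_that("PFC-M1 and SO-spindle coupling use their stated windows", {
  pfc <- seq(10, 100, by = 10)
  expect_equal(pfc_m1_so_coupling(pfc, pfc + 0.1)$value, 100)
  expect_equal(pfc_m1_so_coupling(pfc, pfc + 0.5)$value, 0)
  # spindle nesting window is asymmetric [-0.5, 1.0]
  so <- c(50)
  expect_equal(so_spindle_coupling(so, 50.8)$value, 100)
  expect_equal(so_spindle_coupling(so, 49.2)$value, 0)
})

test_that("delta coupling is a signed antisymmetric difference", {
  a <- list(value = 30, n = 10L); b <- list(value = 22, n = 12L)
  expect_equal(delta_coupling(a, b), 8)
  expect_equal(delta_coupling(b, a), -delta_coupling(a, b))
  expect_equal(delta_coupling(a, a), 0)
  expect_error(delta_coupling(a, list(value = NA_real_)), "undefined")
})

test_that("triple coupling requires both SO and spindle near the SWR", {
  expect_equal(multi_coupling(10, 10, 10)$value, 100)
  expect_equal(multi_coupling(10, 10.5, 30)$value, 0)   # no spindle near
  # independent Poisson trains match the product-of-coverage oracle
  set.seed(5)
  nrems <- interval_set(0, 4000)
  so <- sort(runif(400, 1, 3999)); sp <- sort(runif(400, 1, 3999))
  swr <- sort(runif(2000, 1, 3999))
  got <- multi_coupling(swr, so, sp)$value
  expected <- 100 * window_coverage(so, c(-1, 1), nrems) *
    window_coverage(sp, c(-1, 1), nrems)
  expect_lt(abs(got - expected), 3 * sqrt(expected * (100 - expected) / 2000))
  # quadruple restricts to PFC-coupled SOs
  q0 <- multi_coupling(10, 10, 10, mode = "quadruple", pfc_up = 50)
  expect_equal(q0$value, 0)
  q1 <- multi_coupling(10, 10, 10, mode = "quadruple", pfc_up = 10.1)
  expect_equal(q1$value, 100)
})

test_that("circular permutation preserves counts and matches coverage", {
  nrems <- interval_set(c(0, 150), c(100, 200))
  refs <- c(10, 40, 90, 160)
  set.seed(6)
  swr <- sort(from_concat_time(runif(25, 0, 150), nrems))
  n_seen <- integer(0)
  metric <- function(sh) {
    n_seen <<- c(n_seen, length(sh))
    so_swr_coupling(refs, sh)
  }
  nul <- circular_null(metric, swr, nrems, reps = 400, seed = 2)
  expect_true(all(n_seen == length(swr)))
  cov <- window_coverage(refs, c(-0.75, 0.75), nrems)
  se <- sd(nul$values) / sqrt(nul$reps)
  expect_lt(abs(nul$mean - 100 * cov), 3 * se)
  expect_error(circular_null(metric, numeric(0), nrems), "empty")
})

test_that("single-event analytic null case gives 1.5% in expectation", {
  nrems <- interval_set(0, 100)
  metric <- function(sh) so_swr_coupling(50, sh, c(-0.75, 0.75))
  nul <- circular_null(metric, 30, nrems, reps = 1000, seed = 3)
  se <- sd(nul$values) / sqrt(1000)
  expect_lt(abs(nul$mean - 1.5), 3 * se)
  expect_equal(100 * window_coverage(50, c(-0.75, 0.75), nrems), 1.5)
})

test_that("subsampled coupling behaves at the boundary and on average", {
  pfc <- c(10, 20, 30, 40)
  m1 <- c(10.1, 20.5, 29.9, 55)
  # n_sub = n -> every repetition equals the full metric
  full <- pfc_m1_so_coupling(pfc, m1)$value
  sub <- subsampled_coupling(pfc, m1, n_sub = 4, reps = 20, seed = 1)
  expect_true(all(sub$values == full))
  # fewer references can only lose matches
  sub2 <- subsampled_coupling(pfc, m1, n_sub = 2, reps = 500, seed = 1)
  expect_lte(sub2$mean, full + 1e-9)
  # enumeration oracle over all C(4,2) subsets
  combos <- utils::combn(4, 2)
  exp_mean <- mean(apply(combos, 2, function(ix)
    pfc_m1_so_coupling(pfc[ix], m1)$value))
  expect_lt(abs(sub2$mean - exp_mean), 3 * sd(sub2$values) / sqrt(500))
  flagged <- subsampled_coupling(pfc, m1, n_sub = 10, reps = 5, seed = 1)
  expect_equal(flagged$flag, "too_few_references")
})

test_that("SWR condition labels follow the 1 s horizon rule", {
  nrems <- interval_set(0, 200)
  labs <- label_swr_conditions(c(10, 50, 120), c(10.5, 51.5, 119),
                               nrems, seed = 2)
  expect_equal(labs$so_plus, c(TRUE, FALSE, FALSE))
  expect_length(labs$swr_minus_onsets, 3L)
  # SWR- epochs fit entirely inside NREMS
  expect_true(all(in_intervals(labs$swr_minus_onsets, nrems)))
  expect_true(all(in_intervals(labs$swr_minus_onsets + 1 - 1e-9, nrems)))
  expect_error(label_swr_conditions(1, 2, interval_set(0, 0.5), seed = 1),
               "too short")
})
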