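test_that("the generator is a pure function of (config, seed)", {
  cfg <- sim_config(sleep_s = 300)
  a <- simulate_sleep_block(cfg, day = 4, seed = 7, lfp = TRUE)
  b <- simulate_sleep_block(cfg, day = 4, seed = 7, lfp = TRUE)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$recordings$M1$samples, b$recordings$M1$samples)
  c <- simulate_sleep_block(cfg, day = 4, seed = 8, lfp = FALSE)
  expect_false(identical(a$truth$events$swr_peak, c$truth$events$swr_peak))
})

test_that("generated events respect NREMS bounds and refractory spacing", {
  cfg <- sim_config()
  tru <- simulate_sleep_events(cfg, day = 6, seed = 9)
  for (ev in tru$events) expect_true(all(in_intervals(ev, tru$nrems)))
  expect_true(all(diff(tru$events$m1_so_up) > cfg$refractory_s$so))
  expect_true(all(diff(tru$events$swr_peak) > cfg$refractory_s$swr))
  # recorded coverage is a proper fraction
  expect_true(tru$coverage$so_swr > 0 && tru$coverage$so_swr < 1)
})

test_that("scheduled coupling probabilities are realized in the event trains", {
  cfg <- sim_config()
  # saturation: every SWR nested -> coupling ~ 100%
  cfg1 <- sim_config(coupling = utils::modifyList(
    cfg$coupling, list(so_swr_post = list(U = 1, L = 1, x_mid = 6, k = 1,
                                          lag_sd = 0.2))))
  tru1 <- simulate_sleep_events(cfg1, day = 6, seed = 10)
  cp1 <- so_swr_coupling(tru1$events$m1_so_up, tru1$events$swr_peak)$value
  expect_gte(cp1, 95)
  # zero PFC-M1 coupling -> estimate near chance coverage
  cfg0 <- sim_config(coupling = utils::modifyList(
    cfg$coupling, list(pfc_m1 = list(U = 0, L = 0, x_mid = 6, k = 1,
                                     lag_sd = 0.05))))
  tru0 <- simulate_sleep_events(cfg0, day = 6, seed = 11)
  cp0 <- pfc_m1_so_coupling(tru0$events$pfc_so_up, tru0$events$m1_so_up)$value
  expect_lt(abs(cp0 - 100 * tru0$coverage$pfc_m1), 6)
})

test_that("training spikes follow the latent-driven Poisson model", {
  cfg <- sim_config()
  tr <- simulate_training_block(cfg, day = 8, seed = 12)
  expect_equal(nrow(tr$trials), cfg$trials$n)
  expect_length(tr$spikes$units, cfg$spikes$n_units)
  # total in-window spike count matches the rate integral (chi-square)
  bin <- 0.015
  expected <- 0
  for (z in tr$truth$latents) {
    lam <- pmin(cfg$spikes$baseline_hz * exp(tr$truth$U %*% t(z)) * bin, 20)
    expected <- expected + sum(lam)
  }
  win <- cfg$trials$window
  observed <- sum(vapply(tr$spikes$units, function(u)
    sum(vapply(tr$trials$reach_onset, function(on)
      sum(u$times >= on + win[1] & u$times < on + win[2]), numeric(1))),
    numeric(1)))
  z2 <- (observed - expected)^2 / expected
  expect_lt(z2, qchisq(0.99, 1))
})

test_that("replay injection tags the configured fraction and compresses", {
  cfg <- sim_config()
  tr <- simulate_training_block(cfg, day = 10, seed = 13)
  swr <- sort(runif(300, 1100, 2900))
  rep_out <- inject_replay(cfg, swr, tr, c(1000, 3000), seed = 14)
  expect_length(rep_out$replay_tag, 300L)
  expect_lt(abs(mean(rep_out$replay_tag) - cfg$replay$fraction), 0.1)
  bad <- sim_config(replay = list(fraction = 0.3, compression = 3,
                                  gain = 1))
  expect_error(inject_replay(bad, swr, tr, c(1000, 3000)), "compression")
})

test_that("a full study records schedules consistent with its own truth", {
  study <- simulate_study(sim_config(), n_days = 13, seed = 15,
                          lfp = FALSE, training = FALSE)
  expect_length(study$days, 13L)
  expect_equal(nrow(study$truth_schedule), 13L)
  # scheduled rise/drop midpoints sit where configured
  sched <- study$truth_schedule
  expect_lt(sched$p_pfc_m1[1], sched$p_pfc_m1[13])
  expect_gt(sched$p_so_swr_post[1], sched$p_so_swr_post[13])
  expect_equal(sched$p_so_swr_pre, rep(0.25, 13))
  # per-day realized post-sleep coupling tracks the schedule
  est <- vapply(1:13, function(d) {
    ev <- study$days[[d]]$post$truth$events
    so_swr_coupling(ev$m1_so_up, ev$swr_peak)$value
  }, numeric(1))
  cover <- vapply(1:13, function(d)
    study$days[[d]]$post$truth$coverage$so_swr, numeric(1))
  expect_arg <- sched$p_so_swr_post + (1 - sched$p_so_swr_post) * cover
  expect_lt(max(abs(est / 100 - expect_arg)), 0.12)
})
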