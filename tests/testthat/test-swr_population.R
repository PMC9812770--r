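test_that("event PETH matches a naive histogram and floors partial bins", {
  set.seed(19)
  units <- lapply(1:4, function(i)
    list(unit_id = paste0("u", i), area = "M1",
         times = sort(runif(500, 0, 200))))
  sp <- spike_train_set(units)
  evs <- c(20, 60, 110)
  arr <- event_peth(sp, evs, c(0, 1))
  expect_equal(dim(arr), c(4L, 66L, 3L))      # floor(1000/15) bins
  for (e in seq_along(evs)) for (i in 1:4) {
    naive <- vapply(seq_len(66), function(b) {
      lo <- evs[e] + (b - 1) * 0.015; hi <- evs[e] + b * 0.015
      sum(units[[i]]$times >= lo & units[[i]]$times < hi)
    }, numeric(1))
    expect_equal(arr[i, , e], naive)
  }
  # per-event normalization gives zero-mean rows
  arrn <- event_peth(sp, evs, c(0, 1), normalize = TRUE)
  expect_equal(unname(rowMeans(arrn[, , 1])), rep(0, 4), tolerance = 1e-12)
})

test_that("reach template is an idempotent per-bin mean", {
  set.seed(20)
  trs <- replicate(6, matrix(rnorm(120), 40, 3), simplify = FALSE)
  tmpl <- reach_template(trs)
  manual <- Reduce(`+`, lapply(trs, resample_rows, n_out = 100)) / 6
  expect_equal(tmpl, manual)
  expect_equal(reach_template(list(tmpl)), tmpl)      # idempotent
  same <- reach_template(list(trs[[1]], trs[[1]]))
  expect_equal(same, resample_rows(trs[[1]], 100))
  expect_error(reach_template(list()), "no trials")
})

test_that("reactivation search respects the 405 ms bound and finds replay", {
  cfg <- sim_config()
  tr <- simulate_training_block(cfg, day = 10, seed = 5)
  tens <- bin_zscore(tr$spikes, tr$trials, cfg$trials$window)
  mod <- fit_gpfa(tens, q = 3, max_iter = 60)
  tmpl <- projection_template(mod, tens)
  set.seed(21)
  swr <- sort(runif(180, 1100, 2900))
  rep_out <- inject_replay(cfg, swr, tr, c(1000, 3000), seed = 7)
  tagged <- which(rep_out$replay_tag)
  res <- reactivation_search(rep_out$spikes, swr[tagged], mod, tmpl,
                             tens$mean, tens$sd)
  expect_true(all(res$size_ms + res$lag_ms <= 405, na.rm = TRUE))
  # injected 0.5x compression: template spans 600 ms -> replay ~300 ms
  modal <- as.numeric(names(sort(table(res$size_ms), decreasing = TRUE))[1])
  expect_lte(abs(modal - 300), 15)
  expect_gt(median(res$r, na.rm = TRUE), 0.5)
})

test_that("fixed-window reactivation separates replay from background", {
  cfg <- sim_config()
  tr <- simulate_training_block(cfg, day = 10, seed = 6)
  tens <- bin_zscore(tr$spikes, tr$trials, cfg$trials$window)
  mod <- fit_gpfa(tens, q = 3, max_iter = 60)
  tmpl <- projection_template(mod, tens)
  set.seed(22)
  swr <- sort(runif(150, 1100, 2900))
  rep_out <- inject_replay(cfg, swr, tr, c(1000, 3000), seed = 8)
  r <- reactivation_fixed(rep_out$spikes, swr, mod, tmpl, tens$mean, tens$sd)
  expect_true(all(abs(r) <= 1, na.rm = TRUE))
  expect_gt(mean(r[rep_out$replay_tag], na.rm = TRUE),
            mean(r[!rep_out$replay_tag], na.rm = TRUE))
  # shuffled null sits below the tagged mean
  nul <- reactivation_null(rep_out$spikes, swr, mod, tmpl, tens$mean,
                           tens$sd, reps = 40, seed = 9)
  expect_gt(mean(r[rep_out$replay_tag], na.rm = TRUE),
            quantile(nul$values, 0.975))
})

test_that("CCA recovers shared latents and matches the eigen solution", {
  set.seed(23)
  n <- 1500; px <- 8; py <- 10
  lat <- as.numeric(arima.sim(list(ar = 0.9), n))
  ax <- rnorm(px, 0, 0.6); ay <- rnorm(py, 0, 0.6)
  X <- outer(lat, ax) + matrix(rnorm(n * px), n)
  Y <- outer(lat, ay) + matrix(rnorm(n * py), n)
  m <- fit_cca(X, Y)
  # brute force from the true generative covariance
  Sxx <- diag(px) + var(lat) * outer(ax, ax)
  Syy <- diag(py) + var(lat) * outer(ay, ay)
  Sxy <- var(lat) * outer(ax, ay)
  rho_true <- sqrt(max(Re(eigen(solve(Sxx) %*% Sxy %*% solve(Syy) %*%
                                  t(Sxy))$values)))
  expect_lt(abs(m$cor - rho_true), 0.05)
  # perfect shared latent, no noise -> correlation 1
  m1 <- fit_cca(outer(lat, ax), outer(lat, ay))
  expect_equal(m1$cor, 1, tolerance = 1e-6)
  expect_gt(m1$ridge, 0)                  # rank-1 data needs the ridge path
  # independent areas stay at the permutation-null level
  Xi <- matrix(rnorm(n * px), n); Yi <- matrix(rnorm(n * py), n)
  mi <- fit_cca(Xi, Yi)
  perm <- replicate(40, fit_cca(Xi[sample(n), ], Yi)$cor)
  expect_lt(mi$cor, quantile(perm, 0.99) * 1.2)
  expect_error(fit_cca(X[, 1, drop = FALSE], Y), ">= 2 units")
})

test_that("cross-area R is conditionwise and sign-flip invariant", {
  set.seed(24)
  n <- 400
  lat <- rnorm(n)
  X <- outer(lat, c(1, 0.5)) + matrix(rnorm(n * 2, 0, 0.3), n)
  Y <- outer(lat, c(0.8, -0.4)) + matrix(rnorm(n * 2, 0, 0.3), n)
  m <- fit_cca(X, Y)
  out <- cross_area_r(m, list(a = X, b = X), list(a = Y, b = Y))
  expect_equal(out$delta, 0)
  m2 <- m; m2$wx <- -m$wx; m2$wy <- -m$wy
  out2 <- cross_area_r(m2, list(a = X, b = X), list(a = Y, b = Y))
  expect_equal(out2$r, out$r, tolerance = 1e-12)
  flagged <- cross_area_r(m, list(a = X), list(a = Y),
                          n_events = c(a = 2), min_events = 5)
  expect_true(is.na(flagged$r[["a"]]))
  expect_match(flagged$flag, "too_few_events")
})
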