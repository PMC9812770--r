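test_that("binning and z-scoring satisfy the standardization identities", {
  units <- list(
    list(unit_id = "a", area = "M1", times = sort(runif(400, 0, 100))),
    list(unit_id = "b", area = "M1", times = sort(runif(300, 0, 100))),
    # metronome unit: exactly one spike per bin -> zero variance -> excluded
    list(unit_id = "c", area = "M1", times = seq(0.0075, 100, by = 0.015)))
  sp <- spike_train_set(units)
  trials <- trial_table(1:12, seq(5, 93, by = 8))
  expect_warning(tens <- bin_zscore(sp, trials, c(-0.2, 0.4),
                                    min_rate_hz = 0),
                 "excluded")
  expect_equal(tens$n_bins, 40L)                  # 600 ms / 15 ms
  expect_equal(tens$unit_ids, c("a", "b"))
  conc <- do.call(cbind, tens$counts)
  expect_equal(rowMeans(conc), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(conc, 1, sd), c(1, 1), tolerance = 1e-12)
})

test_that("EM fitting is monotone and recovers the generating subspace", {
  dat <- make_gpfa_data(p = 20, q = 3, T_bins = 30, N = 40,
                        taus = c(0.05, 0.1, 0.15), seed = 12)
  fit <- fit_gpfa(dat$tensor, q = 3, max_iter = 80)
  ll <- fit$loglik
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-1])))
  expect_lt(subspace_angle(dat$C, fit$C), 15)
  # factors ordered by explained shared variance
  expect_false(is.unsorted(rev(colSums(fit$C^2))))
  expect_error(fit_gpfa(dat$tensor, q = 25), "smaller")
})

test_that("q = 0 degenerates to an independent diagonal Gaussian", {
  dat <- make_gpfa_data(p = 6, q = 1, T_bins = 10, N = 12, taus = 0.1,
                        seed = 13)
  fit0 <- fit_gpfa(dat$tensor, q = 0)
  conc <- do.call(cbind, dat$tensor$counts)
  ll_ref <- sum(dnorm(conc, rowMeans(conc),
                      sqrt(apply(conc, 1, var)), log = TRUE))
  expect_equal(fit0$loglik, ll_ref, tolerance = 1e-8)
})

test_that("leave-neuron-out selection recovers the generating dimensionality", {
  dat <- make_gpfa_data(p = 20, q = 3, T_bins = 30, N = 30,
                        taus = c(0.05, 0.1, 0.15), seed = 14)
  sel <- select_dim(dat$tensor, dims = 1:5, max_iter = 30)
  expect_equal(sel$q, 3)
  # single candidate returned as-is
  expect_equal(select_dim(dat$tensor, dims = 4)$q, 4)
  expect_error(select_dim(dat$tensor, dims = integer(0)), "empty")
})

test_that("trajectories report shared variance and ignore unit order", {
  dat <- make_gpfa_data(p = 15, q = 2, T_bins = 20, N = 20,
                        taus = c(0.08, 0.15), seed = 15, noise = c(0.01, 0.05))
  fit <- fit_gpfa(dat$tensor, q = 2, max_iter = 60)
  tr <- extract_trajectories(fit, dat$tensor, n_factors = 2)
  truth_ratio <- sum(dat$C^2) / (sum(dat$C^2) + sum(dat$Rdiag))
  expect_lt(abs(tr$shared_over_total - truth_ratio), 0.05)
  # permuting unit order permutes loadings rows only; trajectories unchanged
  perm <- sample(15)
  tens_p <- dat$tensor
  tens_p$counts <- lapply(dat$tensor$counts, function(m) m[perm, ])
  fit_p <- fit
  fit_p$C <- fit$C[perm, , drop = FALSE]
  fit_p$d <- fit$d[perm]; fit_p$Rdiag <- fit$Rdiag[perm]
  tr_p <- extract_trajectories(fit_p, tens_p, n_factors = 2)
  expect_equal(tr_p$trajectories[[1]], tr$trajectories[[1]],
               tolerance = 1e-8)
})

test_that("Procrustes alignment matches the closed-form solution", {
  set.seed(16)
  ref <- matrix(rnorm(300), 100, 3)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  day <- 0.7 * ref %*% rot + matrix(rep(c(1, -2, 0.5), each = 100), 100)
  out <- align_days(list(list(day)), reference = ref)
  # a rotated/scaled/shifted copy aligns back onto the reference
  expect_equal(out$aligned[[1]][[1]], ref, tolerance = 1e-6,
               ignore_attr = TRUE)
  # random configuration: vegan's transform equals the SVD closed form
  Y <- matrix(rnorm(300), 100, 3)
  out2 <- align_days(list(list(Y)), reference = ref)
  expect_equal(unclass(out2$aligned[[1]][[1]]), brute_procrustes(ref, Y)$aligned,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(align_days(list(list(ref), list(ref))), "fewer than 3")
})

test_that("trajectory correlation behaves as a resampled Pearson r", {
  set.seed(17)
  tr <- matrix(rnorm(120), 40, 3)
  expect_equal(gpfa_correlation(tr, tr), 1)
  expect_equal(gpfa_correlation(tr, -tr), -1)
  # invariant to simultaneous rotation of trajectory and template
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  tmpl <- matrix(rnorm(120), 40, 3)
  expect_equal(gpfa_correlation(tr %*% rot, tmpl %*% rot),
               gpfa_correlation(tr, tmpl), tolerance = 1e-10)
  expect_error(gpfa_correlation(matrix(0, 40, 3), tmpl), "zero-variance")
  # noise attenuation follows the closed form E[R] ~ 1/sqrt(1 + s2/var)
  tmpl2 <- matrix(sin(seq(0, 6 * pi, length.out = 300)), 100, 3)
  v <- var(as.vector(tmpl2))
  sig <- sqrt(v)                                  # noise as large as signal
  rs <- replicate(300, gpfa_correlation(tmpl2 + matrix(rnorm(300, 0, sig),
                                                       100, 3), tmpl2))
  expect_lt(abs(mean(rs) - 1 / sqrt(2)), 0.05)
})

test_that("fidelity is mean over s.d. and scale invariant", {
  r <- c(0.5, 0.5, 0.6)
  expect_equal(fidelity(r), mean(r) / sd(r))
  expect_equal(fidelity(r), 9.2376, tolerance = 1e-4)
  expect_equal(fidelity(3 * r), fidelity(r))
  expect_error(fidelity(c(0.5, 0.6)), "at least 3")
  expect_error(fidelity(rep(0.4, 5)), "zero s.d.")
})

test_that("spike shuffling preserves per-unit counts per event", {
  set.seed(18)
  arr <- array(rpois(10 * 20 * 6, 0.5), c(10, 20, 6))
  sur <- spike_shuffle_surrogate(arr, reps = 3, seed = 1)
  for (s in sur) {
    expect_equal(apply(s, c(1, 3), sum), apply(arr, c(1, 3), sum))
    expect_false(identical(s, arr))
  }
  vals <- spike_shuffle_surrogate(arr, reps = 4, seed = 1, fn = sum)
  expect_equal(unlist(vals), rep(sum(arr), 4))
})
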