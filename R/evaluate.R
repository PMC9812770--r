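# Ground-truth recovery evaluations on the synthetic generator. Each
# function regenerates its inputs from a seed, runs the relevant pipeline
# stages and measures recovery against the recorded truth; they back both
# the package's validation test suite and scripts/acceptance.R.

#' Detector recovery on a full-scale synthetic sleep block
#'
#' Simulates ~30 min of NREMS (about 300 SOs, 150 SWRs and 60 spindles at
#' the default rates), stages and detects, and scores each detector against
#' ground truth (match = peak-time difference under 100 ms).
#'
#' @param seed RNG seed.
#' @param sleep_s sleep-block duration (s).
#' @return named list: per-kind F1, median matched peak-time error (ms),
#'   truth counts, NREMS minutes.
#' @export
eval_detector_recovery <- function(seed = 1, sleep_s = 2600) {
  cfg <- sim_config(sleep_s = sleep_s)
  blk <- simulate_sleep_block(cfg, day = 3, seed = seed, lfp = TRUE)
  st <- stage_sleep(blk$recordings$M1, seed = seed)
  det <- detect_oscillations(blk$recordings, st$intervals)
  tru <- blk$truth$events
  score <- function(est, truth) {
    if (length(est) == 0L || length(truth) == 0L)
      return(list(f1 = 0, err_ms = NA_real_))
    rec_hit <- vapply(truth, function(x) any(abs(est - x) < 0.1), logical(1))
    prec_hit <- vapply(est, function(x) any(abs(truth - x) < 0.1), logical(1))
    prec <- mean(prec_hit); rec <- mean(rec_hit)
    err <- stats::median(vapply(est[prec_hit], function(x)
      min(abs(truth - x)), numeric(1))) * 1000
    list(f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
         err_ms = err)
  }
  so <- score(det$so_m1$t_peak, tru$m1_so_up)
  swr <- score(det$swr$t_peak, tru$swr_peak)
  spi <- score(det$spindle_m1$t_peak, tru$spindle_peak)
  list(so_f1 = so$f1, swr_f1 = swr$f1, spindle_f1 = spi$f1,
       so_peak_err_ms = so$err_ms, swr_peak_err_ms = swr$err_ms,
       spindle_peak_err_ms = spi$err_ms,
       n_so = length(tru$m1_so_up), n_swr = length(tru$swr_peak),
       n_spindle = length(tru$spindle_peak),
       nrems_min = interval_duration(st$intervals) / 60)
}

#' Coupling-estimator calibration
#'
#' For each injected coupling probability, event trains with a known
#' coupled fraction are generated and the estimated coupling compared with
#' the unbiased expectation `p + (1 - p) c`, `c` the realized
#' window-coverage (chance-coincidence) rate.
#'
#' @param seed RNG seed.
#' @param reps replicates per probability.
#' @param n_targets target events per replicate.
#' @param ps injected probabilities.
#' @return list: per-p bias (mean estimate minus mean expectation,
#'   percentage points) and the maximum absolute bias.
#' @export
eval_coupling_calibration <- function(seed = 1, reps = 200, n_targets = 500,
                                      ps = c(0.2, 0.5, 0.8)) {
  nrems <- interval_set(0, 3000)
  set.seed(seed)
  bias <- stats::setNames(numeric(length(ps)), paste0("p", ps))
  for (k in seq_along(ps)) {
    p <- ps[k]
    err <- vapply(seq_len(reps), function(r) {
      refs <- sort(stats::runif(300, 0, 3000))
      coupled <- stats::runif(n_targets) < p
      tg <- ifelse(coupled,
                   sample(refs, n_targets, replace = TRUE) +
                     stats::rnorm(n_targets, 0, 0.05),
                   stats::runif(n_targets, 0, 3000))
      tg <- pmin(pmax(tg, 0), 2999.99)
      est <- pfc_m1_so_coupling(refs, sort(tg))$value
      cov <- window_coverage(refs, c(-0.2, 0.2), nrems)
      est - 100 * (p + (1 - p) * cov)
    }, numeric(1))
    bias[k] <- mean(err)
  }
  list(bias_pts = bias, max_abs_bias_pts = max(abs(bias)))
}

#' Circular-permutation null correctness
#'
#' The shuffle-null mean must equal the analytic window-coverage fraction;
#' checked on a multi-interval configuration (within Monte-Carlo error at
#' 1,000 repetitions) and on the single-event closed-form case (1 SO, 1 SWR,
#' 100 s NREMS, +/-0.75 s window: 1.5%).
#'
#' @param seed RNG seed.
#' @param reps shuffle repetitions.
#' @return list: null means, analytic coverages (percent) and the deviation
#'   in Monte-Carlo standard errors.
#' @export
eval_null_correctness <- function(seed = 1, reps = 1000) {
  nrems <- interval_set(c(0, 150), c(100, 220))
  set.seed(seed)
  refs <- sort(from_concat_time(stats::runif(5, 0, 170), nrems))
  swr <- sort(from_concat_time(stats::runif(25, 0, 170), nrems))
  metric <- function(sh) so_swr_coupling(refs, sh)
  nul <- circular_null(metric, swr, nrems, reps = reps, seed = seed + 1)
  cov <- 100 * window_coverage(refs, c(-0.75, 0.75), nrems)
  se <- stats::sd(nul$values) / sqrt(reps)
  single <- circular_null(function(sh) so_swr_coupling(50, sh, c(-0.75, 0.75)),
                          30, interval_set(0, 100), reps = reps,
                          seed = seed + 2)
  se1 <- stats::sd(single$values) / sqrt(reps)
  list(null_mean_pct = nul$mean, coverage_pct = cov,
       deviation_se = abs(nul$mean - cov) / se,
       single_event_null_mean_pct = single$mean,
       single_event_expected_pct = 1.5,
       single_event_deviation_se = abs(single$mean - 1.5) / se1)
}

# tertile coupling series for one simulated study (internal)
study_coupling_series <- function(study) {
  pm <- NULL; ds <- NULL
  n_days <- length(study$days)
  for (d in seq_len(n_days)) {
    post <- study$days[[d]]$post$truth
    pre <- study$days[[d]]$pre$truth
    idx <- tertile_split(length(post$events$m1_so_up))
    idx_po <- tertile_split(length(post$events$swr_peak))
    idx_pr <- tertile_split(length(pre$events$swr_peak))
    for (k in 1:3) {
      pm <- rbind(pm, data.frame(day = d, tertile = k,
        value = pfc_m1_so_coupling(post$events$pfc_so_up,
                                   post$events$m1_so_up[idx == k])$value))
      po <- so_swr_coupling(post$events$m1_so_up,
                            post$events$swr_peak[idx_po == k])$value
      pr <- so_swr_coupling(pre$events$m1_so_up,
                            pre$events$swr_peak[idx_pr == k])$value
      ds <- rbind(ds, data.frame(day = d, tertile = k, value = po - pr))
    }
  }
  list(pfc_m1 = pm, dso_swr = ds)
}

#' Transition-dynamics recovery
#'
#' Four checks: noiseless sigmoid midpoint recovery; median midpoint error
#' under additive noise; change-point agreement with an exhaustive
#' cumulative-sum search on random series; and end-to-end 13-day studies
#' with a PFC-M1 rise scheduled before a SO-SWR drop, scoring how often the
#' recovered rise midpoint precedes the recovered drop midpoint.
#'
#' @param seed RNG seed.
#' @param noise_reps noisy-sigmoid replicates.
#' @param study_reps end-to-end study replicates.
#' @param cp_reps random change-point series.
#' @return named list of recovery metrics.
#' @export
eval_transition_recovery <- function(seed = 1, noise_reps = 200,
                                     study_reps = 50, cp_reps = 200) {
  x <- rep(1:13, each = 3) + rep(0:2 / 3, 13)
  y0 <- 1 / (1 + exp(-2 * (x - 6.5)))
  err0 <- abs(fit_sigmoid(x, y0)$x_mid - 6.5)
  set.seed(seed)
  errs <- vapply(seq_len(noise_reps), function(r)
    abs(fit_sigmoid(x, y0 + stats::rnorm(length(x), 0, 0.1))$x_mid - 6.5),
    numeric(1))
  # change-point: exhaustive cumulative-sum oracle
  agree <- vapply(seq_len(cp_reps), function(r) {
    n <- sample(4:50, 1)
    v <- stats::rnorm(n) + c(rep(0, n %/% 2),
                             rep(stats::runif(1, 0, 2), n - n %/% 2))
    cs <- cumsum(v); cs2 <- cumsum(v^2)
    sse <- function(a, b) {
      s <- cs[b] - if (a > 1) cs[a - 1] else 0
      s2 <- cs2[b] - if (a > 1) cs2[a - 1] else 0
      s2 - s^2 / (b - a + 1)
    }
    tot <- vapply(2:n, function(i) sse(1, i - 1) + sse(i, n), numeric(1))
    change_point(v)$index == which.min(tot) + 1L
  }, logical(1))
  # end-to-end rise-before-drop recovery
  rises <- numeric(study_reps); drops <- numeric(study_reps)
  for (r in seq_len(study_reps)) {
    study <- simulate_study(sim_config(), seed = seed + 7919L * r,
                            lfp = FALSE, training = FALSE)
    ser <- study_coupling_series(study)
    xs <- ser$pfc_m1$day + (ser$pfc_m1$tertile - 1) / 3
    rises[r] <- fit_sigmoid(xs, smooth_normalize(ser$pfc_m1$value)$normalized,
                            range = c(3, 11))$x_mid
    drops[r] <- fit_sigmoid(xs, smooth_normalize(ser$dso_swr$value)$normalized,
                            range = c(3, 11))$x_mid
  }
  list(noiseless_xmid_error_d = err0,
       noisy_xmid_median_error_d = stats::median(errs),
       change_point_agreement = mean(agree),
       rise_before_drop_frac = mean(rises < drops),
       mean_rise_d = mean(rises), mean_drop_d = mean(drops))
}

#' GPFA recovery from the generative model
#'
#' Fits data simulated directly from the linear-Gaussian GPFA model and
#' measures the largest principal angle between the recovered and the true
#' loading subspaces, EM log-likelihood monotonicity, and how often
#' leave-neuron-out cross-validation selects the generating dimensionality.
#'
#' @param seed RNG seed.
#' @param select_reps dimensionality-selection replicates.
#' @return named list: `subspace_angle_deg`, `monotone_frac`,
#'   `selected_mode`, `select_correct_frac`.
#' @export
eval_gpfa_recovery <- function(seed = 1, select_reps = 20) {
  gen <- function(p, q, T_bins, N, taus, sd0) {
    set.seed(sd0)
    C <- matrix(stats::rnorm(p * q, 0, 0.5), p, q)
    Rd <- stats::runif(p, 0.05, 0.2)
    K <- lapply(taus, function(tau) {
      dt <- outer(seq_len(T_bins), seq_len(T_bins), "-") * 0.015
      0.999 * exp(-dt^2 / (2 * tau^2)) + 0.001 * diag(T_bins)
    })
    Y <- lapply(seq_len(N), function(n) {
      z <- vapply(seq_len(q), function(j)
        as.numeric(t(chol(K[[j]])) %*% stats::rnorm(T_bins)),
        numeric(T_bins))
      t(z %*% t(C)) + matrix(stats::rnorm(p * T_bins, 0, sqrt(Rd)), p, T_bins)
    })
    list(tensor = structure(list(counts = Y, bin_s = 0.015, n_bins = T_bins),
                            class = "trial_tensor"), C = C)
  }
  angle <- function(A, B) {
    s <- svd(crossprod(qr.Q(qr(A)), qr.Q(qr(B))))$d
    acos(min(max(min(s), -1), 1)) * 180 / pi
  }
  dat <- gen(30, 3, 40, 100, c(0.05, 0.1, 0.15), seed)
  fit <- fit_gpfa(dat$tensor, q = 3, max_iter = 100)
  mono <- all(diff(fit$loglik) > -1e-6 * abs(fit$loglik[-1]))
  sel <- integer(select_reps)
  for (r in seq_len(select_reps)) {
    d2 <- gen(20, 3, 30, 30, c(0.05, 0.1, 0.15), seed + 104729L * r)
    sel[r] <- select_dim(d2$tensor, dims = 1:6, max_iter = 30)$q
  }
  tab <- table(sel)
  list(subspace_angle_deg = angle(dat$C, fit$C),
       monotone_frac = as.numeric(mono),
       selected_mode = as.numeric(names(tab)[which.max(tab)]),
       select_correct_frac = mean(sel == 3))
}

#' Trajectory-fidelity monotonicity across a latent-noise ladder
#'
#' Simulates training blocks at increasing latent-noise levels (fixed
#' seeds), runs the GPFA pipeline and measures fidelity (mean/s.d. of
#' trajectory-template correlations across trials) per level.
#'
#' @param seed RNG seed.
#' @param levels latent-noise s.d. ladder (increasing).
#' @param n_trials trials per block.
#' @return list: `fidelity` per level, `monotone_frac` (fraction of
#'   consecutive decreases).
#' @export
eval_fidelity_ladder <- function(seed = 1,
                                 levels = c(0.15, 0.3, 0.6, 1.0, 1.6),
                                 n_trials = 60) {
  fid <- numeric(length(levels))
  for (k in seq_along(levels)) {
    cfg <- sim_config(latent_noise = levels[k],
                      trials = list(n = n_trials, window = c(-0.2, 0.4),
                                    iti_s = c(8, 15)))
    tr <- simulate_training_block(cfg, day = 6, seed = seed)
    tens <- bin_zscore(tr$spikes, tr$trials, cfg$trials$window)
    mod <- fit_gpfa(tens, q = 3, max_iter = 40)
    trj <- extract_trajectories(mod, tens)$trajectories
    tmpl <- reach_template(trj)
    r <- vapply(trj, gpfa_correlation, numeric(1), template = tmpl)
    fid[k] <- fidelity(r)
  }
  list(fidelity = fid, monotone_frac = mean(diff(fid) < 0))
}

#' Reactivation detection power and compression recovery
#'
#' A fixed awake session defines the manifold and reach template; per
#' replicate, post-sleep SWRs receive time-compressed replay in a scheduled
#' fraction, and detection asks whether the mean fixed-window reactivation
#' correlation of real SWRs exceeds the 97.5th percentile of the per-unit
#' spike-shuffle null. The modal best-window size from the compression/lag
#' search is compared with the injected compression.
#'
#' @param seed RNG seed.
#' @param reps replicates.
#' @param n_swr SWRs per replicate.
#' @param null_reps shuffle repetitions per replicate.
#' @return list: `power`, `delta_positive_frac` (SWR+ minus SWR- contrast),
#'   `modal_size_ms`, `expected_size_ms`, `mean_delta_r`.
#' @export
eval_reactivation_power <- function(seed = 1, reps = 50, n_swr = 200,
                                    null_reps = 40) {
  cfg <- sim_config()
  tr <- simulate_training_block(cfg, day = 10, seed = seed)
  tens <- bin_zscore(tr$spikes, tr$trials, cfg$trials$window)
  mod <- fit_gpfa(tens, q = 3, max_iter = 60)
  tmpl <- projection_template(mod, tens)
  span <- c(1000, 3000)
  detected <- logical(reps); dpos <- logical(reps); deltas <- numeric(reps)
  modal <- NA_real_
  for (r in seq_len(reps)) {
    s <- seed + 7907L * r
    set.seed(s)
    swr <- sort(stats::runif(n_swr, span[1] + 50, span[2] - 50))
    rep_out <- inject_replay(cfg, swr, tr, span, seed = s + 1L)
    r_plus <- reactivation_fixed(rep_out$spikes, swr, mod, tmpl,
                                 tens$mean, tens$sd)
    set.seed(s + 2L)
    minus_onsets <- sort(stats::runif(n_swr, span[1] + 50, span[2] - 50))
    r_minus <- reactivation_fixed(rep_out$spikes, minus_onsets, mod, tmpl,
                                  tens$mean, tens$sd)
    nul <- reactivation_null(rep_out$spikes, swr, mod, tmpl, tens$mean,
                             tens$sd, reps = null_reps, seed = s + 3L)
    detected[r] <- mean(r_plus, na.rm = TRUE) >
      stats::quantile(nul$values, 0.975, names = FALSE)
    deltas[r] <- mean(r_plus, na.rm = TRUE) - mean(r_minus, na.rm = TRUE)
    dpos[r] <- deltas[r] > 0
    if (r == 1L) {
      sr <- reactivation_search(rep_out$spikes, swr[rep_out$replay_tag],
                                mod, tmpl, tens$mean, tens$sd)
      tb <- table(sr$size_ms)
      modal <- as.numeric(names(tb)[which.max(tb)])
    }
  }
  tmpl_ms <- (cfg$trials$window[2] - cfg$trials$window[1]) * 1000
  list(power = mean(detected), delta_positive_frac = mean(dpos),
       mean_delta_r = mean(deltas), modal_size_ms = modal,
       expected_size_ms = tmpl_ms * cfg$replay$compression)
}

#' CCA communication-subspace recovery
#'
#' Checks the fitted top canonical correlation against the brute-force
#' value from the true generative covariance, the behaviour on independent
#' areas against a permutation null, and whether a shared latent present
#' only during one condition yields a positive cross-area correlation
#' difference.
#'
#' @param seed RNG seed.
#' @param reps condition-contrast replicates.
#' @return named list of recovery metrics.
#' @export
eval_cca_recovery <- function(seed = 1, reps = 40) {
  set.seed(seed)
  n <- 2000; px <- 10; py <- 12
  lat <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  ax <- stats::rnorm(px, 0, 0.6); ay <- stats::rnorm(py, 0, 0.6)
  X <- outer(lat, ax) + matrix(stats::rnorm(n * px), n)
  Y <- outer(lat, ay) + matrix(stats::rnorm(n * py), n)
  m <- fit_cca(X, Y)
  Sxx <- diag(px) + stats::var(lat) * outer(ax, ax)
  Syy <- diag(py) + stats::var(lat) * outer(ay, ay)
  Sxy <- stats::var(lat) * outer(ax, ay)
  rho_true <- sqrt(max(Re(eigen(solve(Sxx) %*% Sxy %*% solve(Syy) %*%
                                  t(Sxy))$values)))
  Xi <- matrix(stats::rnorm(n * px), n); Yi <- matrix(stats::rnorm(n * py), n)
  indep <- fit_cca(Xi, Yi)$cor
  perm <- vapply(seq_len(40), function(i)
    fit_cca(Xi[sample(n), ], Yi)$cor, numeric(1))
  dpos <- vapply(seq_len(reps), function(r) {
    set.seed(seed + 6101L * r)
    nb <- 800
    lat2 <- as.numeric(stats::arima.sim(list(ar = 0.8), nb))
    Xp <- outer(lat2, ax) + matrix(stats::rnorm(nb * px, 0, 1.2), nb)
    Yp <- outer(lat2, ay) + matrix(stats::rnorm(nb * py, 0, 1.2), nb)
    Xm <- matrix(stats::rnorm(nb * px, 0, 1.2), nb)
    Ym <- matrix(stats::rnorm(nb * py, 0, 1.2), nb)
    mm <- fit_cca(rbind(Xp, Xm), rbind(Yp, Ym))
    out <- cross_area_r(mm, list(so_plus = Xp, so_minus = Xm),
                        list(so_plus = Yp, so_minus = Ym))
    out$delta > 0
  }, logical(1))
  list(cca_cor = m$cor, cca_cor_true = rho_true,
       cca_abs_error = abs(m$cor - rho_true),
       indep_cor = indep, perm_null_q99 = stats::quantile(perm, 0.99,
                                                          names = FALSE),
       delta_cross_area_positive_frac = mean(dpos))
}
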