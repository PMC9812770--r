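# Synthetic multi-day sessions with recorded ground truth.
#
# The generator emulates the study design: per day, a pre-training sleep
# block, a reach-training block and a post-training sleep block. Sleep
# blocks alternate NREMS bouts and wake; NREMS carries slow oscillations
# (biphasic raised-cosine waves), spindles (amplitude-modulated 10-15 Hz
# bursts) and hippocampal SWRs (150-250 Hz bursts) whose rates, amplitudes
# and cross-area coupling probabilities/lags are configurable and follow
# day-indexed sigmoid schedules. Training trials drive Poisson spikes
# through a low-dimensional latent trajectory; a configurable fraction of
# post-sleep SWRs carries a time-compressed replay of the trial template.
# Every scheduled true value is recorded so pipeline estimates can be
# compared with their ground truth.

#' Generator configuration
#'
#' Defaults reflect rat NREMS physiology at desk scale: ~10 SOs, ~5 SWRs
#' and ~2 spindles per NREMS minute, 1018 samples/s LFP, 30-unit
#' populations with 3 shared latents, and 13-day schedules with a PFC-M1
#' coupling rise at day 6 and a post-sleep SO-SWR coupling drop at day 8.
#'
#' @param ... named overrides of any default (nested lists are merged).
#' @return nested named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    rate = 1018,
    n_days = 13,
    sleep_s = 2700,                       # per sleep block
    nrems = list(bout_s = c(60, 120), wake_s = c(20, 60)),
    lfp = list(n_channels = 4, bg_uv = 60, delta_nrems_uv = 130,
               gamma_wake_uv = 45,
               so_amp_uv = c(350, 550), so_halfwave_s = c(0.22, 0.38),
               spindle_amp = 8, spindle_dur_s = c(0.6, 1.0),
               spindle_freq_hz = 12.5,
               swr_amp = 7, swr_dur_s = c(0.06, 0.12), swr_freq_hz = 200),
    rates_per_min = list(so = 10, swr = 5, spindle = 2),
    refractory_s = list(so = 1.5, swr = 0.3, spindle = 2.5),
    coupling = list(
      pfc_m1 = list(U = 0.8, L = 0.3, x_mid = 6, k = 2, lag_sd = 0.05),
      so_swr_post = list(U = 0.6, L = 0.2, x_mid = 8, k = -2, lag_sd = 0.3),
      so_swr_pre = 0.25,
      so_spindle = list(p = 0.5, window = c(-0.5, 1.0))),
    spikes = list(n_units = 30, q = 3, loading_sd = 0.8, baseline_hz = 10,
                  sleep_hz = 5),
    trials = list(n = 40, window = c(-0.2, 0.4), iti_s = c(8, 15)),
    latent_noise = list(U = 1.0, L = 0.25, x_mid = 6, k = -1.5),
    success = list(U = 0.75, L = 0.1, x_mid = 5, k = 1.5),
    replay = list(fraction = 0.3, compression = 0.5, gain = 1.5))
  user <- list(...)
  if (length(user)) cfg <- utils::modifyList(cfg, user)
  structure(cfg, class = c("sim_config", "list"))
}

#' Evaluate a day-indexed sigmoid schedule
#'
#' @param sched list with `U`, `L`, `x_mid`, `k` (or a single number, taken
#'   as constant).
#' @param day day index.
#' @return schedule value at `day`.
#' @export
schedule_value <- function(sched, day) {
  if (is.numeric(sched) && length(sched) == 1L) return(sched)
  sched$L + (sched$U - sched$L) / (1 + exp(-sched$k * (day - sched$x_mid)))
}

# alternating NREMS / wake bouts over [0, total_s)
simulate_nrems_schedule <- function(total_s, bout_s, wake_s) {
  t <- stats::runif(1, wake_s[1], wake_s[2])     # start awake
  s <- c(); e <- c()
  while (t < total_s) {
    dur <- stats::runif(1, bout_s[1], bout_s[2])
    if (t + dur > total_s) dur <- total_s - t
    if (dur >= 30) { s <- c(s, t); e <- c(e, t + dur) }
    t <- t + dur + stats::runif(1, wake_s[1], wake_s[2])
  }
  interval_set(s, e)
}

# homogeneous event train inside NREMS with a refractory gap; the draw rate
# is inflated to first order so the realized rate matches the configured one
# after thinning
draw_event_times <- function(nrems, rate_hz, refractory_s) {
  tot <- interval_duration(nrems)
  eff <- rate_hz / max(1 - rate_hz * refractory_s, 0.5)
  n <- stats::rpois(1, eff * tot)
  if (n == 0L) return(numeric(0))
  tc <- sort(stats::runif(n, 0, tot))
  keep <- c(TRUE, diff(tc) > refractory_s)
  from_concat_time(tc[keep], nrems)
}

# thin a train so no two events are closer than gap (keep earlier)
enforce_gap <- function(t, gap) {
  t <- sort(t)
  if (length(t) < 2L) return(t)
  out <- t[1L]
  for (x in t[-1L]) if (x - out[length(out)] > gap) out <- c(out, x)
  out
}

#' Simulate the event structure of one sleep block
#'
#' PFC SO up-states are a refractory Poisson train in NREMS; each M1 SO is
#' coupled to a PFC SO (lag ~ N(0, lag_sd)) with the scheduled probability,
#' otherwise placed uniformly; SWR peaks sit within the +/-0.75 s nesting
#' window of an M1 SO up-state with the scheduled probability; spindle
#' peaks nest similarly in their asymmetric window. Realized
#' window-coverage fractions (the chance-coincidence rates an estimator
#' must be compared against) are recorded.
#'
#' @param config a `sim_config`.
#' @param day day index (drives the schedules).
#' @param block `"pre_sleep"` or `"post_sleep"`.
#' @param seed RNG seed.
#' @param t0 block start on the session clock (s).
#' @return list: `nrems` (`interval_set`), `events` (named lists of truth
#'   times), `p` (scheduled probabilities), `coverage` (realized
#'   chance-coincidence rates), `coupled` (per-event truth flags).
#' @export
simulate_sleep_events <- function(config, day, block = "post_sleep",
                                  seed = 1, t0 = 0) {
  set.seed(seed)
  nrems <- simulate_nrems_schedule(config$sleep_s, config$nrems$bout_s,
                                   config$nrems$wake_s)
  r <- config$rates_per_min
  p_pfc_m1 <- schedule_value(config$coupling$pfc_m1, day)
  p_so_swr <- if (block == "post_sleep")
    schedule_value(config$coupling$so_swr_post, day)
  else schedule_value(config$coupling$so_swr_pre, day)
  pfc <- draw_event_times(nrems, r$so / 60, config$refractory_s$so)
  # M1 SOs: coupled fraction rides on PFC partners
  n_m1 <- length(pfc)
  coupled_m1 <- stats::runif(n_m1) < p_pfc_m1
  lag <- stats::rnorm(n_m1, 0, config$coupling$pfc_m1$lag_sd)
  m1 <- ifelse(coupled_m1, pfc + lag, NA_real_)
  unc <- draw_event_times(nrems, r$so / 60, config$refractory_s$so)
  fill <- rep(NA_real_, sum(!coupled_m1))
  n_fill <- min(length(fill), length(unc))
  fill[seq_len(n_fill)] <- unc[seq_len(n_fill)]
  m1[!coupled_m1] <- fill
  ok <- !is.na(m1) & in_intervals(m1, nrems)
  m1 <- m1[ok]; coupled_m1 <- coupled_m1[ok]
  o <- order(m1); m1 <- m1[o]; coupled_m1 <- coupled_m1[o]
  gap_ok <- c(TRUE, diff(m1) > config$refractory_s$so)
  m1 <- m1[gap_ok]; coupled_m1 <- coupled_m1[gap_ok]
  # SWRs nested on M1 SOs
  n_swr <- stats::rpois(1, r$swr / 60 * interval_duration(nrems))
  coupled_swr <- stats::runif(n_swr) < p_so_swr & length(m1) > 0
  host <- if (length(m1)) sample(m1, n_swr, replace = TRUE) else rep(NA, n_swr)
  lag_swr <- pmin(pmax(stats::rnorm(n_swr, 0, config$coupling$so_swr_post$lag_sd),
                       -0.74), 0.74)
  swr <- ifelse(coupled_swr, host + lag_swr, NA_real_)
  unc_swr <- draw_event_times(nrems, r$swr / 60, config$refractory_s$swr)
  need <- which(!coupled_swr | !in_intervals(ifelse(is.na(swr), -1, swr), nrems))
  fill <- rep(NA_real_, length(need))
  n_fill <- min(length(fill), length(unc_swr))
  fill[seq_len(n_fill)] <- unc_swr[seq_len(n_fill)]
  swr[need] <- fill
  coupled_swr[need] <- FALSE
  keep <- !is.na(swr)
  swr <- swr[keep]; coupled_swr <- coupled_swr[keep]
  o <- order(swr); swr <- swr[o]; coupled_swr <- coupled_swr[o]
  gap_ok <- c(TRUE, diff(swr) > config$refractory_s$swr)
  swr <- swr[gap_ok]; coupled_swr <- coupled_swr[gap_ok]
  # spindles nested on local SOs
  n_sp <- stats::rpois(1, r$spindle / 60 * interval_duration(nrems))
  p_sp <- config$coupling$so_spindle$p
  coupled_sp <- stats::runif(n_sp) < p_sp & length(m1) > 0
  host_sp <- if (length(m1)) sample(m1, n_sp, replace = TRUE) else rep(NA, n_sp)
  wsp <- config$coupling$so_spindle$window
  sp <- ifelse(coupled_sp, host_sp + stats::runif(n_sp, wsp[1], wsp[2]),
               NA_real_)
  unc_sp <- draw_event_times(nrems, r$spindle / 60, config$refractory_s$spindle)
  need <- which(!coupled_sp | !in_intervals(ifelse(is.na(sp), -1, sp), nrems))
  fill <- rep(NA_real_, length(need))
  n_fill <- min(length(fill), length(unc_sp))
  fill[seq_len(n_fill)] <- unc_sp[seq_len(n_fill)]
  sp[need] <- fill
  coupled_sp[need] <- FALSE
  sp <- sort(sp[!is.na(sp)])
  sp <- enforce_gap(sp, config$refractory_s$spindle)
  shift <- function(x) x + t0
  nrems_s <- interval_set(nrems$start + t0, nrems$end + t0)
  cov_pfc <- window_coverage(shift(pfc), c(-0.2, 0.2), nrems_s)
  cov_so <- if (length(m1)) window_coverage(shift(m1), c(-0.75, 0.75), nrems_s) else 0
  list(nrems = nrems_s,
       events = list(pfc_so_up = shift(pfc), m1_so_up = shift(m1),
                     swr_peak = shift(swr), spindle_peak = shift(sp)),
       p = list(pfc_m1 = p_pfc_m1, so_swr = p_so_swr, so_spindle = p_sp),
       coverage = list(pfc_m1 = cov_pfc, so_swr = cov_so),
       coupled = list(m1 = coupled_m1, swr = coupled_swr, spindle = coupled_sp))
}

# one biphasic SO waveform (down-peak then up-trough), raised cosine
so_waveform <- function(rate, halfwave_s, amp) {
  n_half <- round(halfwave_s * rate)
  up <- amp * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n_half)))
  c(up * 0.9, -up)     # positive hump then deeper negative hump
}

#' Simulate LFP recordings for one sleep block
#'
#' Background is pink noise per channel; NREMS bouts receive an additional
#' slow (delta-band) component and wake segments additional gamma so the
#' staging classifier has contrast; SO, spindle and SWR waveforms are
#' injected coherently across channels at the ground-truth times.
#'
#' @param config a `sim_config`.
#' @param truth output of [simulate_sleep_events()].
#' @param seed RNG seed.
#' @param t0 block start (s).
#' @param areas which areas to synthesize.
#' @return named list of `recording` objects.
#' @export
simulate_sleep_lfp <- function(config, truth, seed = 1, t0 = 0,
                               areas = c("PFC", "M1", "HPC")) {
  set.seed(seed + 1L)
  rate <- config$rate
  n <- round(config$sleep_s * rate)
  lf <- config$lfp
  nrems_local <- interval_set(truth$nrems$start - t0, truth$nrems$end - t0)
  tgrid <- (seq_len(n) - 1L) / rate
  in_n <- in_intervals(tgrid, nrems_local)
  slow_mask <- as.numeric(in_n)
  out <- list()
  for (area in areas) {
    X <- matrix(0, lf$n_channels, n)
    # narrowband components synthesized at decimated rates, then upsampled
    band_noise <- function(sub_rate, hp, lp) {
      ns <- ceiling(n / rate * sub_rate) + 8L
      y <- bandpass_zero_phase(stats::rnorm(ns), sub_rate, hp, lp)
      stats::approx(seq_len(ns) / sub_rate, y, xout = tgrid, rule = 2)$y
    }
    for (ch in seq_len(lf$n_channels)) {
      bg <- pink_noise(n, rate) * lf$bg_uv
      delta <- band_noise(32, c(0.3, 2), c(1.2, 4))
      delta <- delta / stats::sd(delta) * lf$delta_nrems_uv * slow_mask
      gamma <- band_noise(256, c(30, 4), c(60, 4))
      gamma <- gamma / stats::sd(gamma) * lf$gamma_wake_uv * (1 - slow_mask)
      X[ch, ] <- bg + delta + gamma
    }
    ev <- truth$events
    if (area %in% c("PFC", "M1")) {
      ups <- (if (area == "PFC") ev$pfc_so_up else ev$m1_so_up) - t0
      for (u in ups) {
        hw <- stats::runif(1, lf$so_halfwave_s[1], lf$so_halfwave_s[2])
        amp <- stats::runif(1, lf$so_amp_uv[1], lf$so_amp_uv[2])
        w <- so_waveform(rate, hw, amp)
        # trough of the waveform sits at the up-state time
        i_tr <- round(length(w) * 3 / 4)
        i0 <- round(u * rate) - i_tr
        idx <- (i0 + 1L):(i0 + length(w))
        ok <- idx >= 1L & idx <= n
        X[, idx[ok]] <- sweep(X[, idx[ok], drop = FALSE], 2L, w[ok], "+")
      }
      for (s in ev$spindle_peak - t0) {
        dur <- stats::runif(1, lf$spindle_dur_s[1], lf$spindle_dur_s[2])
        m <- round(dur * rate)
        tt <- seq_len(m) / rate
        env <- sin(pi * seq(0, 1, length.out = m))
        w <- lf$spindle_amp * lf$bg_uv / 10 * env *
          sin(2 * pi * lf$spindle_freq_hz * tt)
        i0 <- round(s * rate) - round(m / 2)
        idx <- (i0 + 1L):(i0 + m)
        ok <- idx >= 1L & idx <= n
        X[, idx[ok]] <- sweep(X[, idx[ok], drop = FALSE], 2L, w[ok], "+")
      }
    }
    if (area == "HPC") {
      for (s in ev$swr_peak - t0) {
        dur <- stats::runif(1, lf$swr_dur_s[1], lf$swr_dur_s[2])
        m <- round(dur * rate)
        tt <- seq_len(m) / rate
        env <- sin(pi * seq(0, 1, length.out = m))
        w <- lf$swr_amp * lf$bg_uv / 10 * env *
          sin(2 * pi * lf$swr_freq_hz * tt)
        i0 <- round(s * rate) - round(m / 2)
        idx <- (i0 + 1L):(i0 + m)
        ok <- idx >= 1L & idx <= n
        X[, idx[ok]] <- sweep(X[, idx[ok], drop = FALSE], 2L, w[ok], "+")
      }
    }
    out[[area]] <- recording(X, rate, area, t0 = t0)
  }
  out
}

#' Simulate one sleep block (events + optional LFP)
#'
#' @param config a `sim_config`.
#' @param day day index.
#' @param seed RNG seed.
#' @param block `"pre_sleep"` or `"post_sleep"`.
#' @param t0 block start (s).
#' @param lfp also synthesize LFP recordings.
#' @return list: `truth` (see [simulate_sleep_events()]), `recordings`
#'   (when `lfp = TRUE`).
#' @export
simulate_sleep_block <- function(config, day, seed = 1, block = "post_sleep",
                                 t0 = 0, lfp = TRUE) {
  truth <- simulate_sleep_events(config, day, block, seed, t0)
  rec <- if (lfp) simulate_sleep_lfp(config, truth, seed, t0) else NULL
  list(truth = truth, recordings = rec)
}

# smooth 3-latent template over n_bins (fixed shape)
latent_template <- function(n_bins, q = 3) {
  x <- seq(0, 1, length.out = n_bins)
  cbind(sin(pi * x),
        x * (1 - x) * 4 - 0.5,
        sin(2 * pi * x) * 0.8)[, seq_len(q), drop = FALSE]
}

# smooth per-trial latent noise: Gaussian-smoothed white noise, rescaled so
# the marginal s.d. after smoothing equals the requested one
smooth_noise <- function(n_bins, q, sd, smooth_bins = 4) {
  m <- matrix(stats::rnorm(n_bins * q), n_bins, q)
  sm <- apply(m, 2L, function(col) gaussian_smooth(col, 1, smooth_bins * 2))
  sm <- as.matrix(sm)
  for (j in seq_len(ncol(sm))) {
    s0 <- stats::sd(sm[, j])
    if (s0 > 0) sm[, j] <- sm[, j] / s0 * sd
  }
  sm
}

#' Simulate one reach-training block
#'
#' Each trial's latent trajectory is the smooth 3-latent template plus
#' day-scheduled smooth noise; spikes are an inhomogeneous Poisson process
#' with rate exp-linear in the loading-weighted latents plus baseline.
#'
#' @param config a `sim_config`.
#' @param day day index (drives the latent-noise and success schedules).
#' @param seed RNG seed.
#' @param t0 block start (s).
#' @param area area label for the units.
#' @return list: `spikes` (`spike_train_set`), `trials` (`trial_table`),
#'   `truth` (loadings, per-trial latents, noise level, success
#'   probability).
#' @export
simulate_training_block <- function(config, day, seed = 1, t0 = 0,
                                    area = "M1") {
  set.seed(seed + 2L)
  sp <- config$spikes
  win <- config$trials$window
  bin <- 0.015
  n_bins <- floor((win[2] - win[1]) / bin)
  tmpl <- latent_template(n_bins, sp$q)
  noise_sd <- schedule_value(config$latent_noise, day)
  p_succ <- schedule_value(config$success, day)
  set.seed(seed * 13L + 7L)      # loadings fixed per animal via base seed
  U <- matrix(stats::rnorm(sp$n_units * sp$q, 0, sp$loading_sd),
              sp$n_units, sp$q)
  set.seed(seed + 1000L * day)
  onsets <- t0 + cumsum(stats::runif(config$trials$n, config$trials$iti_s[1],
                                     config$trials$iti_s[2]))
  lat <- vector("list", config$trials$n)
  spikes_per_unit <- vector("list", sp$n_units)
  for (i in seq_len(sp$n_units)) spikes_per_unit[[i]] <- numeric(0)
  for (tr in seq_len(config$trials$n)) {
    z <- tmpl + smooth_noise(n_bins, sp$q, noise_sd)
    lat[[tr]] <- z
    drive <- U %*% t(z)                                  # units x bins
    rate_hz <- sp$baseline_hz * exp(drive)
    lambda <- rate_hz * bin
    counts <- matrix(stats::rpois(length(lambda), pmin(lambda, 20)),
                     nrow(lambda))
    for (i in seq_len(sp$n_units)) {
      nz <- which(counts[i, ] > 0L)
      if (length(nz)) {
        ts <- rep(onsets[tr] + win[1] + (nz - 1L) * bin, counts[i, nz]) +
          stats::runif(sum(counts[i, nz]), 0, bin)
        spikes_per_unit[[i]] <- c(spikes_per_unit[[i]], ts)
      }
    }
  }
  units <- lapply(seq_len(sp$n_units), function(i)
    list(unit_id = sprintf("%s_u%02d", area, i), area = area,
         times = sort(spikes_per_unit[[i]])))
  success <- stats::runif(config$trials$n) < p_succ
  trials <- trial_table(seq_len(config$trials$n), onsets,
                        pellet_touch = onsets + 0.35, success = success,
                        hand = "L")
  list(spikes = spike_train_set(units), trials = trials,
       truth = list(U = U, latents = lat, template = tmpl,
                    noise_sd = noise_sd, p_success = p_succ))
}

#' Simulate background sleep spiking and inject replay
#'
#' Sleep spiking is homogeneous Poisson per unit; for a configured fraction
#' of SWRs, spikes drawn from the template-driven rate — time-compressed by
#' the configured factor — are inserted starting at the SWR onset.
#'
#' @param config a `sim_config`.
#' @param swr_onsets SWR onset times (s).
#' @param training output of [simulate_training_block()] (for loadings and
#'   template).
#' @param sleep_span `c(start, end)` of the sleep block (s).
#' @param seed RNG seed.
#' @return list: `spikes` (`spike_train_set`), `replay_tag` (logical per
#'   SWR).
#' @export
inject_replay <- function(config, swr_onsets, training, sleep_span, seed = 1) {
  set.seed(seed + 3L)
  sp <- config$spikes
  rp <- config$replay
  if (rp$compression <= 0.2 || rp$compression >= 2.0)
    stop("compression must lie in (0.2, 2.0)")
  U <- training$truth$U
  tmpl <- training$truth$template
  bin <- 0.015
  dur <- nrow(tmpl) * bin * rp$compression
  n_bins_r <- max(2L, round(nrow(tmpl) * rp$compression))
  z_r <- resample_rows(tmpl, n_bins_r)
  bin_r <- dur / n_bins_r
  tag <- stats::runif(length(swr_onsets)) < rp$fraction
  per_unit <- vector("list", sp$n_units)
  span_len <- sleep_span[2] - sleep_span[1]
  for (i in seq_len(sp$n_units)) {
    n_bg <- stats::rpois(1, sp$sleep_hz * span_len)
    per_unit[[i]] <- sleep_span[1] + sort(stats::runif(n_bg, 0, span_len))
  }
  for (e in which(tag)) {
    drive <- U %*% t(z_r) * rp$gain
    rate_hz <- sp$baseline_hz * exp(drive)
    lambda <- pmin(rate_hz * bin_r, 20)
    counts <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda))
    for (i in seq_len(sp$n_units)) {
      nz <- which(counts[i, ] > 0L)
      if (length(nz)) {
        ts <- rep(swr_onsets[e] + (nz - 1L) * bin_r, counts[i, nz]) +
          stats::runif(sum(counts[i, nz]), 0, bin_r)
        per_unit[[i]] <- c(per_unit[[i]], ts)
      }
    }
  }
  units <- lapply(seq_len(sp$n_units), function(i)
    list(unit_id = sprintf("M1_u%02d", i), area = "M1",
         times = sort(per_unit[[i]])))
  list(spikes = spike_train_set(units), replay_tag = tag)
}

#' Simulate a full multi-day study
#'
#' Per day: pre-training sleep (baseline SO-SWR coupling), training, and
#' post-training sleep (coupling per the day schedules). By default only
#' the event/spike structure is generated (the LFP level is exercised per
#' block via [simulate_sleep_block()]); set `lfp = TRUE` for full signals.
#'
#' @param config a `sim_config`.
#' @param n_days number of days (defaults to the config).
#' @param seed RNG seed.
#' @param lfp synthesize LFP for every block (slow; default FALSE).
#' @param training include training blocks / spikes (default TRUE).
#' @return list of class `sim_study`: `days` (per day: `pre`, `post`
#'   sleep-block lists, `training`), `truth_schedule` (data.frame of the
#'   scheduled per-day true values), `config`.
#' @export
simulate_study <- function(config = sim_config(), n_days = config$n_days,
                           seed = 1, lfp = FALSE, training = TRUE) {
  days <- vector("list", n_days)
  sched <- NULL
  for (d in seq_len(n_days)) {
    base <- seed + 101L * d
    pre <- simulate_sleep_block(config, d, seed = base, block = "pre_sleep",
                                t0 = 0, lfp = lfp)
    tr <- if (training)
      simulate_training_block(config, d, seed = base,
                              t0 = config$sleep_s + 60)
    post_t0 <- config$sleep_s + 60 +
      (if (training) config$trials$n * mean(config$trials$iti_s) + 120 else 60)
    post <- simulate_sleep_block(config, d, seed = base + 1L,
                                 block = "post_sleep", t0 = post_t0,
                                 lfp = lfp)
    days[[d]] <- list(pre = pre, post = post, training = tr)
    sched <- rbind(sched, data.frame(
      day = d,
      p_pfc_m1 = schedule_value(config$coupling$pfc_m1, d),
      p_so_swr_post = schedule_value(config$coupling$so_swr_post, d),
      p_so_swr_pre = schedule_value(config$coupling$so_swr_pre, d),
      latent_noise = schedule_value(config$latent_noise, d),
      p_success = schedule_value(config$success, d)))
  }
  structure(list(days = days, truth_schedule = sched, config = config),
            class = "sim_study")
}
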