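# SO / spindle / SWR detection on NREMS LFP.
#
# SOs: delta-filtered (0.1-4 Hz) mean LFP; positive-to-negative zero
# crossings define candidate waves whose preceding peak (down-state) and
# following trough (up-state) are tested against percentile thresholds and a
# peak-to-trough duration criterion. Spindles (10-15 Hz) and SWRs
# (150-250 Hz) use a Gaussian-smoothed Hilbert envelope with mu + k*sigma
# double thresholds and a minimum duration.

#' Build the detection trace from a recording
#'
#' Samples deviating more than `artifact_sd` standard deviations from a
#' channel's mean are masked (set `NA`) before averaging; bad channels are
#' skipped. `"zscore_mean"` standardizes each channel first so each
#' contributes unit variance.
#'
#' @param rec a `recording`.
#' @param mode `"plain_mean"` (SO detection) or `"zscore_mean"`
#'   (spindle/SWR detection).
#' @param channels optional integer subset of channels (e.g. the three
#'   designated dorsal-CA1 channels for SWRs).
#' @param artifact_sd artifact threshold in channel standard deviations.
#' @return numeric vector (may contain `NA` at masked samples).
#' @export
make_trace <- function(rec, mode = c("plain_mean", "zscore_mean"),
                       channels = NULL, artifact_sd = 10) {
  mode <- match.arg(mode)
  keep <- which(rec$channel_ok)
  if (!is.null(channels)) keep <- intersect(keep, channels)
  if (length(keep) == 0L) stop("no good channels available")
  X <- rec$samples[keep, , drop = FALSE]
  mu <- rowMeans(X)
  sdev <- apply(X, 1L, stats::sd)
  mask <- abs(X - mu) > artifact_sd * sdev
  X[mask] <- NA_real_
  if (mode == "zscore_mean") {
    mu2 <- rowMeans(X, na.rm = TRUE)
    sd2 <- apply(X, 1L, stats::sd, na.rm = TRUE)
    sd2[sd2 == 0] <- 1
    X <- (X - mu2) / sd2
  }
  colMeans(X, na.rm = TRUE)
}

#' Zero-phase band-pass filtering
#'
#' Two independent Butterworth filters applied forward-backward
#' (`signal::filtfilt`): high-pass first, then low-pass, so the net phase
#' shift is zero. `NA` samples (masked artifacts) are linearly interpolated
#' before filtering so masking a sample cannot shift event times elsewhere.
#'
#' @param x numeric trace.
#' @param rate sampling rate (samples/s).
#' @param hp `c(cutoff_hz, order)` for the high-pass stage.
#' @param lp `c(cutoff_hz, order)` for the low-pass stage.
#' @return filtered numeric vector.
#' @export
bandpass_zero_phase <- function(x, rate, hp, lp) {
  if (rate <= 2 * lp[1]) stop("rate must exceed twice the low-pass cutoff")
  if (anyNA(x)) {
    idx <- which(!is.na(x))
    if (length(idx) < 2L) stop("trace is entirely masked")
    x <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  }
  bh <- signal::butter(hp[2], hp[1] / (rate / 2), type = "high")
  y <- signal::filtfilt(bh, x)
  bl <- signal::butter(lp[2], lp[1] / (rate / 2), type = "low")
  signal::filtfilt(bl, y)
}

#' Detect slow oscillations
#'
#' @param filtered delta-band filtered trace.
#' @param rate sampling rate (samples/s).
#' @param nrems `interval_set` of NREMS bouts (session clock).
#' @param t0 session-clock time of the first sample.
#' @param area area label for the emitted events.
#' @param config the `detection$so` block of [default_config()].
#' @return an `event_table` of kind `"SO"` (`t_onset` = down-state peak,
#'   `t_peak` = up-state trough, `t_end` = next negative-to-positive
#'   crossing).
#' @export
detect_so <- function(filtered, rate, nrems, t0 = 0, area = "M1",
                      config = default_config()$detection$so) {
  n <- length(filtered)
  t <- t0 + (seq_len(n) - 1L) / rate
  if (!any(in_intervals(t, nrems))) stop("no NREMS samples in trace")
  s <- sign(filtered)
  p2n <- which(s[-n] > 0 & s[-1L] <= 0)        # index of last positive sample
  n2p <- which(s[-n] <= 0 & s[-1L] > 0)
  if (length(p2n) == 0L || length(n2p) == 0L)
    return(event_table())
  pos <- findInterval(p2n, n2p)
  ok0 <- pos >= 1L & pos < length(n2p)
  zc <- p2n[ok0]; a_idx <- n2p[pos[ok0]]; b_idx <- n2p[pos[ok0] + 1L]
  if (length(zc) == 0L) return(event_table())
  cand <- matrix(NA_integer_, length(zc), 3L)
  for (w in seq_along(zc)) {
    z <- zc[w]; a <- a_idx[w]; b <- b_idx[w]
    pk <- a + which.max(filtered[(a + 1L):z])
    tr <- z + which.min(filtered[(z + 1L):b])
    # wave must lie wholly within one NREMS bout
    iv <- findInterval(t[pk], nrems$start)
    if (iv < 1L || t[b + 1L] > nrems$end[iv] || t[pk] < nrems$start[iv]) next
    cand[w, ] <- c(pk, tr, b + 1L)
  }
  cand <- cand[!is.na(cand[, 1L]), , drop = FALSE]
  if (nrow(cand) == 0L) return(event_table())
  peaks <- filtered[cand[, 1L]]
  troughs <- filtered[cand[, 2L]]
  peak_thr <- stats::quantile(peaks, config$peak_pct, names = FALSE)
  trough_thr <- stats::quantile(troughs, config$trough_pct, names = FALSE)
  dur <- t[cand[, 2L]] - t[cand[, 1L]]
  ok <- troughs < trough_thr & peaks > peak_thr &
    dur >= config$dur_min & dur <= config$dur_max
  event_table(kind = rep("SO", sum(ok)), area = rep(area, sum(ok)),
              t_onset = t[cand[ok, 1L]], t_peak = t[cand[ok, 2L]],
              t_end = t[cand[ok, 3L]],
              peak_amp = peaks[ok], trough_amp = troughs[ok])
}

#' Detect envelope events (spindles / SWRs)
#'
#' The Hilbert envelope is computed separately within each NREMS bout (no
#' analytic signal across gaps) and smoothed with a Gaussian window; the
#' mean and s.d. of the pooled NREMS envelope define the
#' `mu + upper_sd * sigma` / `mu + lower_sd * sigma` thresholds. An event is
#' a maximal run above the lower threshold that contains at least one sample
#' above the upper threshold and lasts at least `min_dur`.
#'
#' @param filtered band-filtered trace (spindle or ripple band).
#' @param rate sampling rate (samples/s).
#' @param nrems `interval_set` of NREMS bouts.
#' @param kind `"SPINDLE"` or `"SWR"`.
#' @param t0 session-clock time of the first sample.
#' @param area area label for the emitted events.
#' @param config the matching `detection$spindle` / `detection$swr` block.
#' @return an `event_table` (`t_onset`/`t_end` lower-threshold crossings,
#'   `t_peak` envelope maximum).
#' @export
detect_envelope_events <- function(filtered, rate, nrems,
                                   kind = c("SPINDLE", "SWR"), t0 = 0,
                                   area = if (kind == "SWR") "HPC" else "M1",
                                   config = NULL) {
  kind <- match.arg(kind)
  if (is.null(config))
    config <- default_config()$detection[[tolower(kind)]]
  if (nrow(nrems) == 0L) stop("empty NREMS interval set")
  n <- length(filtered)
  t <- t0 + (seq_len(n) - 1L) / rate
  env <- rep(NA_real_, n)
  for (i in seq_len(nrow(nrems))) {
    idx <- which(t >= nrems$start[i] & t < nrems$end[i])
    if (length(idx) < 4L) next
    env[idx] <- gaussian_smooth(hilbert_envelope(filtered[idx]), rate,
                                config$env_smooth)
  }
  pooled <- env[!is.na(env)]
  if (length(pooled) == 0L) stop("empty NREMS")
  mu <- mean(pooled); sigma <- stats::sd(pooled)
  upper <- mu + config$upper_sd * sigma
  lower <- mu + config$lower_sd * sigma
  above <- !is.na(env) & env > lower
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- NULL
  for (j in which(r$values)) {
    a <- starts[j]; b <- ends[j]
    if ((b - a + 1L) / rate < config$min_dur) next
    seg <- env[a:b]
    if (!any(seg > upper)) next
    pk <- a + which.max(seg) - 1L
    out <- rbind(out, c(a, pk, b))
  }
  if (is.null(out)) return(event_table())
  event_table(kind = rep(kind, nrow(out)), area = rep(area, nrow(out)),
              t_onset = t[out[, 1L]], t_peak = t[out[, 2L]], t_end = t[out[, 3L]],
              peak_amp = env[out[, 2L]])
}

#' Run all three detectors on one sleep block
#'
#' @param recordings named list of `recording`s (`PFC`, `M1`, `HPC`).
#' @param nrems NREMS `interval_set` for the block.
#' @param swr_channels integer indices of the designated CA1 channels.
#' @param config the `detection` block of [default_config()].
#' @return named list of `event_table`s: `so_pfc`, `so_m1`, `spindle_pfc`,
#'   `spindle_m1`, `swr`.
#' @export
detect_oscillations <- function(recordings, nrems, swr_channels = 1:3,
                                config = default_config()$detection) {
  out <- list()
  for (area in c("PFC", "M1")) {
    rec <- recordings[[area]]
    tr <- make_trace(rec, "plain_mean", artifact_sd = config$artifact_sd)
    filt <- bandpass_zero_phase(tr, rec$rate, config$so$hp, config$so$lp)
    out[[paste0("so_", tolower(area))]] <-
      detect_so(filt, rec$rate, nrems, rec$t0, area, config$so)
    trz <- make_trace(rec, "zscore_mean", artifact_sd = config$artifact_sd)
    filt_sp <- bandpass_zero_phase(trz, rec$rate, config$spindle$hp, config$spindle$lp)
    out[[paste0("spindle_", tolower(area))]] <-
      detect_envelope_events(filt_sp, rec$rate, nrems, "SPINDLE", rec$t0,
                             area, config$spindle)
  }
  hpc <- recordings$HPC
  trh <- make_trace(hpc, "zscore_mean", channels = swr_channels,
                    artifact_sd = config$artifact_sd)
  filt_swr <- bandpass_zero_phase(trh, hpc$rate, config$swr$hp, config$swr$lp)
  out$swr <- detect_envelope_events(filt_swr, hpc$rate, nrems, "SWR", hpc$t0,
                                    "HPC", config$swr)
  out
}
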