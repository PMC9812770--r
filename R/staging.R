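# NREMS staging from LFP band power. The averaged LFP is cut into
# non-overlapping 6 s epochs; per epoch a Hann-tapered periodogram is averaged
# over the slow-wave (0.1-4 Hz) and gamma (30-60 Hz) bands, a 2-means
# classifier separates NREMS from the rest, and short runs are discarded.

#' Per-epoch band-power features
#'
#' @param trace averaged LFP (numeric vector, microvolts).
#' @param rate sampling rate (samples/s).
#' @param epoch_s epoch length (s); a trailing partial epoch is discarded.
#' @param delta_band,gamma_band band limits (Hz).
#' @return data.frame with one row per complete epoch: `epoch`, `start`,
#'   `delta_power`, `gamma_power` (mean periodogram density over the band).
#' @export
epoch_features <- function(trace, rate, epoch_s = 6,
                           delta_band = c(0.1, 4), gamma_band = c(30, 60)) {
  n_per <- floor(epoch_s * rate)
  n_ep <- floor(length(trace) / n_per)
  if (n_ep < 1L) stop("trace shorter than one epoch")
  freqs <- seq(0, rate / 2, by = rate / n_per)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, n_per - 1) / (n_per - 1)) # Hann
  u <- sum(taper^2)
  nf <- floor(n_per / 2) + 1L
  in_delta <- freqs[seq_len(nf)] >= delta_band[1] & freqs[seq_len(nf)] <= delta_band[2]
  in_gamma <- freqs[seq_len(nf)] >= gamma_band[1] & freqs[seq_len(nf)] <= gamma_band[2]
  out <- data.frame(epoch = seq_len(n_ep),
                    start = (seq_len(n_ep) - 1L) * epoch_s,
                    delta_power = NA_real_, gamma_power = NA_real_)
  for (i in seq_len(n_ep)) {
    seg <- trace[((i - 1L) * n_per + 1L):(i * n_per)]
    seg[!is.finite(seg)] <- mean(seg, na.rm = TRUE)
    seg <- (seg - mean(seg)) * taper
    pxx <- Mod(stats::fft(seg))^2 / (rate * u)      # one-sided PSD, uV^2/Hz
    pxx <- pxx[seq_len(nf)]
    pxx[2:(nf - 1L)] <- 2 * pxx[2:(nf - 1L)]
    out$delta_power[i] <- mean(pxx[in_delta])
    out$gamma_power[i] <- mean(pxx[in_gamma])
  }
  out
}

#' Classify epochs into NREMS vs other
#'
#' 2-means on standardized (delta, gamma) power; the cluster with the higher
#' mean delta power is NREMS, which also makes the labels invariant to the
#' solver's arbitrary cluster indexing.
#'
#' @param features output of [epoch_features()].
#' @param restarts number of k-means restarts (best inertia kept).
#' @param seed RNG seed for the restarts.
#' @return character vector, `"NREMS"` or `"OTHER"`, one per epoch.
#' @export
classify_nrems <- function(features, restarts = 10, seed = 1) {
  X <- cbind(features$delta_power, features$gamma_power)
  if (nrow(X) < 2L) stop("need at least 2 epochs to classify")
  if (all(apply(X, 2L, function(c) max(c) - min(c)) < .Machine$double.eps))
    stop("degenerate clustering: all epoch features identical")
  Xs <- scale(X)
  Xs[, !is.finite(apply(Xs, 2L, stats::sd))] <- 0
  Xs[!is.finite(Xs)] <- 0
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  km <- stats::kmeans(Xs, centers = 2L, nstart = restarts)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  mean_delta <- tapply(features$delta_power, km$cluster, mean)
  nrems_cluster <- as.integer(names(which.max(mean_delta)))
  ifelse(km$cluster == nrems_cluster, "NREMS", "OTHER")
}

#' Merge NREMS epochs and drop short runs
#'
#' Adjacent NREMS epochs are merged into bouts; merged runs shorter than
#' `min_run_s` are excluded (exactly `min_run_s` is retained).
#'
#' @param labels per-epoch labels from [classify_nrems()].
#' @param starts epoch start times (s).
#' @param epoch_s epoch length (s).
#' @param min_run_s minimum retained run length (s).
#' @return an `interval_set` of NREMS bouts.
#' @export
consolidate_nrems <- function(labels, starts, epoch_s = 6, min_run_s = 30) {
  is_n <- labels == "NREMS"
  if (!any(is_n)) return(interval_set())
  r <- rle(is_n)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values & (r$lengths * epoch_s >= min_run_s)
  if (!any(keep)) return(interval_set())
  interval_set(starts[starts_idx[keep]],
               starts[ends_idx[keep]] + epoch_s)
}

#' Stage one sleep block
#'
#' Convenience wrapper: average the good channels of a recording, compute
#' epoch features, classify and consolidate. Interval times are on the
#' session clock (offset by the recording's `t0`).
#'
#' @param rec a `recording` (conventionally M1).
#' @param config the `staging` block of [default_config()].
#' @param seed RNG seed passed to [classify_nrems()].
#' @return list with `intervals` (`interval_set`), `labels`, `features`.
#' @export
stage_sleep <- function(rec, config = default_config()$staging, seed = 1) {
  trace <- colMeans(rec$samples[rec$channel_ok, , drop = FALSE])
  feats <- epoch_features(trace, rec$rate, config$epoch_s,
                          config$delta_band, config$gamma_band)
  labels <- classify_nrems(feats, config$kmeans_restarts, seed)
  iv <- consolidate_nrems(labels, feats$start, config$epoch_s, config$min_run_s)
  if (nrow(iv) > 0L) iv <- interval_set(iv$start + rec$t0, iv$end + rec$t0)
  list(intervals = iv, labels = labels, features = feats)
}
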