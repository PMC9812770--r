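# SWR-locked population analyses: peri-event time histograms, projection of
# sleep activity onto the awake manifold (neural trajectory reactivation),
# compression/lag window search, spike-shuffle nulls, and the PFC-M1
# communication subspace (CCA).

#' Peri-event time histogram tensor
#'
#' @param spikes a `spike_train_set`.
#' @param event_times event reference times (s).
#' @param window `c(lo, hi)` seconds relative to each event; bins beyond the
#'   last full bin are discarded (`floor` rule).
#' @param bin_s bin width (s).
#' @param normalize z-score each unit within each event window.
#' @return 3-d array units x bins x events with `dimnames[[1]]` = unit ids.
#' @export
event_peth <- function(spikes, event_times, window, bin_s = 0.015,
                       normalize = FALSE) {
  n_bins <- floor((window[2] - window[1]) / bin_s)
  if (n_bins < 1L) stop("empty window")
  units <- spikes$units
  arr <- array(0, dim = c(length(units), n_bins, length(event_times)),
               dimnames = list(vapply(units, function(u) u$unit_id,
                                      character(1)), NULL, NULL))
  edges0 <- window[1] + bin_s * (0:n_bins)
  for (e in seq_along(event_times)) {
    for (i in seq_along(units)) {
      rel <- units[[i]]$times - event_times[e]
      rel <- rel[rel >= edges0[1L] & rel < edges0[n_bins + 1L]]
      if (length(rel))
        arr[i, , e] <- tabulate(findInterval(rel, edges0), nbins = n_bins)
    }
  }
  if (normalize) {
    for (e in seq_along(event_times)) {
      m <- arr[, , e, drop = FALSE]
      mu <- apply(m, 1L, mean); sdev <- apply(m, 1L, stats::sd)
      sdev[sdev == 0] <- 1
      arr[, , e] <- (arr[, , e] - mu) / sdev
    }
  }
  arr
}

#' Mean reach template
#'
#' Mean over trials of the top-factor trajectories, after resampling each
#' trial to a common length.
#'
#' @param trajectories list of bins x factors matrices.
#' @param n_points common resampling length.
#' @return bins x factors matrix (the template).
#' @export
reach_template <- function(trajectories, n_points = 100) {
  if (length(trajectories) == 0L) stop("no trials")
  rs <- lapply(trajectories, resample_rows, n_out = n_points)
  Reduce(`+`, rs) / length(rs)
}

#' Reach template in projection coordinates
#'
#' Sleep activity is compared with the awake template in the coordinates of
#' the template-space projection (orthonormalized top loadings), so the
#' template itself must be built the same way: each awake trial's z-scored
#' counts are projected onto the basis and the projections averaged.
#'
#' @param model awake `gpfa_model`.
#' @param tensor awake `trial_tensor` (z-scored counts).
#' @param n_factors number of top factors.
#' @param n_points resampling length.
#' @return bins x factors template matrix.
#' @export
projection_template <- function(model, tensor, n_factors = 3,
                                n_points = 100) {
  basis <- template_space(model, n_factors)
  projs <- lapply(tensor$counts, function(m) t(crossprod(basis, m)))
  reach_template(projs, n_points)
}

# orthonormal basis of the top factors of a model; sleep activity is
# projected with it after z-scoring with the awake parameters
template_space <- function(model, n_factors = 3) {
  nf <- min(n_factors, ncol(model$C))
  qr.Q(qr(model$C[, seq_len(nf), drop = FALSE]))
}

# project a units x bins count matrix into the template space
project_counts <- function(counts, basis, mu, sdev) {
  z <- (counts - mu) / ifelse(sdev == 0, 1, sdev)
  t(crossprod(basis, z))                     # bins x n_factors
}

#' Reactivation window search
#'
#' For every window size in `sizes_ms` and every lag (15 ms steps) with
#' `lag + size <= max_ms`, the sleep spikes are binned, z-scored with the
#' awake parameters, projected onto the awake top-3 template space, linearly
#' resampled to the template length, and correlated with the reach template;
#' the (size, lag) with maximal correlation is returned per event.
#'
#' @param spikes a `spike_train_set` (sleep block).
#' @param swr_onsets SWR onset times (s).
#' @param model awake `gpfa_model`.
#' @param template reach template (bins x 3).
#' @param awake_mean,awake_sd per-unit z-scoring parameters from the awake
#'   `trial_tensor`.
#' @param sizes_ms candidate window sizes (ms).
#' @param lag_step_ms lag grid step (ms).
#' @param max_ms window end bound after SWR onset (ms).
#' @param bin_s bin width (s).
#' @return data.frame per event: `r`, `size_ms`, `lag_ms` (`NA` rows for
#'   events with no spikes in any window).
#' @export
reactivation_search <- function(spikes, swr_onsets, model, template,
                                awake_mean, awake_sd,
                                sizes_ms = seq(75, 405, by = 30),
                                lag_step_ms = 15, max_ms = 405,
                                bin_s = 0.015) {
  basis <- template_space(model)
  grid <- do.call(rbind, lapply(sizes_ms, function(sz) {
    lags <- seq(0, max_ms - sz, by = lag_step_ms)
    data.frame(size_ms = sz, lag_ms = lags)
  }))
  out <- data.frame(r = rep(NA_real_, length(swr_onsets)),
                    size_ms = NA_real_, lag_ms = NA_real_)
  full <- event_peth(spikes, swr_onsets, c(0, max_ms / 1000), bin_s)
  for (e in seq_along(swr_onsets)) {
    best <- c(r = -Inf, size = NA, lag = NA)
    for (g in seq_len(nrow(grid))) {
      b0 <- round(grid$lag_ms[g] / 1000 / bin_s)
      nb <- floor(grid$size_ms[g] / 1000 / bin_s)
      counts <- full[, (b0 + 1L):(b0 + nb), e, drop = FALSE]
      dim(counts) <- dim(counts)[1:2]
      if (sum(counts) == 0) next
      proj <- project_counts(counts, basis, awake_mean, awake_sd)
      if (all(apply(proj, 2L, stats::sd) == 0)) next
      r <- tryCatch(gpfa_correlation(proj, template), error = function(e) NA)
      if (!is.na(r) && r > best["r"])
        best <- c(r = r, size = grid$size_ms[g], lag = grid$lag_ms[g])
    }
    if (is.finite(best[["r"]])) {
      out$r[e] <- best[["r"]]
      out$size_ms[e] <- best[["size"]]
      out$lag_ms[e] <- best[["lag"]]
    }
  }
  out
}

#' Fixed-window reactivation correlation
#'
#' Single `[onset, onset + fixed_ms]` window (default 195 ms, zero lag),
#' projected and correlated as in [reactivation_search()].
#'
#' @inheritParams reactivation_search
#' @param fixed_ms window size (ms).
#' @return numeric vector of reactivation correlations, one per event
#'   (`NA` when an event window is empty).
#' @export
reactivation_fixed <- function(spikes, swr_onsets, model, template,
                               awake_mean, awake_sd, fixed_ms = 195,
                               bin_s = 0.015) {
  basis <- template_space(model)
  arr <- event_peth(spikes, swr_onsets, c(0, fixed_ms / 1000), bin_s)
  W <- interp_matrix(dim(arr)[2L], 100L)
  tvec <- concat_centered(resample_rows(template, 100L))
  vapply(seq_along(swr_onsets), function(e) {
    counts <- arr[, , e, drop = FALSE]
    dim(counts) <- dim(counts)[1:2]
    if (sum(counts) == 0) return(NA_real_)
    proj <- project_counts(counts, basis, awake_mean, awake_sd)
    v <- concat_centered(W %*% proj)
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(v, tvec)
  }, numeric(1))
}

#' Spike-shuffled reactivation null
#'
#' Per-unit circular permutation of the binned counts within the
#' permutation window (default -200 to +400 ms around the SWR onset),
#' repeated; each surrogate is cropped to the fixed analysis window,
#' projected and correlated. The mean per-event correlation over
#' repetitions is the null level.
#'
#' @inheritParams reactivation_fixed
#' @param perm_window permutation window `c(lo, hi)` (s) relative to onset.
#' @param reps number of shuffles.
#' @param seed RNG seed.
#' @return list: `per_rep` (reps x events matrix of correlations),
#'   `null_mean_r` (mean over reps of the per-rep event means), `values`
#'   (per-rep event-mean correlations).
#' @export
reactivation_null <- function(spikes, swr_onsets, model, template,
                              awake_mean, awake_sd, fixed_ms = 195,
                              perm_window = c(-0.2, 0.4), bin_s = 0.015,
                              reps = 1000, seed = 1) {
  basis <- template_space(model)
  arr <- event_peth(spikes, swr_onsets, perm_window, bin_s)
  crop0 <- round(-perm_window[1] / bin_s)
  nb <- floor(fixed_ms / 1000 / bin_s)
  W <- interp_matrix(nb, 100L)
  tvec <- concat_centered(resample_rows(template, 100L))
  score <- function(a) {
    vapply(seq_len(dim(a)[3L]), function(e) {
      counts <- a[, (crop0 + 1L):(crop0 + nb), e, drop = FALSE]
      dim(counts) <- dim(counts)[1:2]
      if (sum(counts) == 0) return(NA_real_)
      proj <- project_counts(counts, basis, awake_mean, awake_sd)
      v <- concat_centered(W %*% proj)
      if (stats::sd(v) == 0) return(NA_real_)
      stats::cor(v, tvec)
    }, numeric(1))
  }
  per_rep <- spike_shuffle_surrogate(arr, reps = reps, seed = seed, fn = score)
  per_rep <- do.call(rbind, per_rep)
  means <- rowMeans(per_rep, na.rm = TRUE)
  list(per_rep = per_rep, null_mean_r = mean(means), values = means)
}

#' Canonical correlation communication subspace
#'
#' Bins x units matrices from the two areas (concatenated across events,
#' mean-subtracted) are related by CCA; only the top canonical variable is
#' retained. When a within-area covariance is rank-deficient, a ridge
#' `eps * mean(diag)` is added (and reported).
#'
#' @param X,Y bins x units matrices (PFC, M1).
#' @param eps ridge fraction used when rank-deficient.
#' @return object of class `cca_model`: `wx`, `wy` (top canonical weight
#'   vectors), `cor` (top canonical correlation), `ridge` (0 or the ridge
#'   used).
#' @export
fit_cca <- function(X, Y, eps = 1e-6) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) < 2L || ncol(Y) < 2L) stop("need >= 2 units per area")
  if (nrow(X) != nrow(Y)) stop("X and Y must have matching rows")
  if (nrow(X) <= ncol(X) + ncol(Y))
    stop("need more bins than total units")
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  ridge <- 0
  res <- tryCatch(stats::cancor(Xc, Yc), error = function(e) NULL)
  qx <- qr(Xc); qy <- qr(Yc)
  if (is.null(res) || qx$rank < ncol(X) || qy$rank < ncol(Y)) {
    # ridge-regularized generalized eigenproblem
    Sxx <- crossprod(Xc) / (nrow(Xc) - 1L)
    Syy <- crossprod(Yc) / (nrow(Yc) - 1L)
    Sxy <- crossprod(Xc, Yc) / (nrow(Xc) - 1L)
    ridge <- eps * mean(c(diag(Sxx), diag(Syy)))
    Sxx <- Sxx + ridge * diag(ncol(X))
    Syy <- Syy + ridge * diag(ncol(Y))
    cx <- chol(Sxx); cy <- chol(Syy)
    Mt <- backsolve(cx, t(backsolve(cy, t(Sxy), transpose = TRUE)),
                    transpose = TRUE)
    sv <- svd(Mt)
    wx <- backsolve(cx, sv$u[, 1L])
    wy <- backsolve(cy, sv$v[, 1L])
    rho <- sv$d[1L]
  } else {
    wx <- res$xcoef[, 1L]
    wy <- res$ycoef[, 1L]
    rho <- res$cor[1L]
  }
  structure(list(wx = wx, wy = wy, cor = rho, ridge = ridge),
            class = "cca_model")
}

#' Per-condition cross-area correlation
#'
#' Projects each area's condition data onto the session's top canonical
#' weights and correlates the two projections over the concatenated
#' condition bins.
#'
#' @param model a `cca_model`.
#' @param x_by_cond,y_by_cond named lists of bins x units matrices per
#'   condition (same names, matching rows within condition).
#' @param min_events minimum events per condition (conditions built from
#'   fewer are flagged).
#' @param n_events optional named vector of event counts per condition.
#' @return list: `r` (named per condition), `delta`
#'   (`r[1] - r[2]` for the first two conditions), `flag`.
#' @export
cross_area_r <- function(model, x_by_cond, y_by_cond, min_events = 5,
                         n_events = NULL) {
  conds <- names(x_by_cond)
  r <- stats::setNames(rep(NA_real_, length(conds)), conds)
  flag <- NULL
  for (cn in conds) {
    if (!is.null(n_events) && n_events[[cn]] < min_events) {
      flag <- c(flag, paste0(cn, ":too_few_events"))
      next
    }
    px <- as.matrix(x_by_cond[[cn]]) %*% model$wx
    py <- as.matrix(y_by_cond[[cn]]) %*% model$wy
    if (stats::sd(px) == 0 || stats::sd(py) == 0) {
      flag <- c(flag, paste0(cn, ":degenerate"))
      next
    }
    r[cn] <- stats::cor(px, py)
  }
  delta <- if (length(conds) >= 2L) r[[1L]] - r[[2L]] else NA_real_
  list(r = r, delta = delta, flag = flag)
}
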