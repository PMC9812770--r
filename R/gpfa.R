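# Gaussian-process factor analysis of trial-binned population activity.
#
# Observation model per 15 ms bin: y_t = C z_t + d + eps, eps ~ N(0, R)
# with diagonal R (private noise); each latent z^(j) follows a zero-mean GP
# over bins with a squared-exponential kernel
# K_j(t, t') = (1 - s) exp(-(t - t')^2 dt^2 / (2 tau_j^2)) + s * delta,
# s a fixed small innovation-noise fraction. Fitting is EM: the E-step is
# exact (joint Gaussian posterior over the whole trial), the M-step updates
# (C, d), R in closed form and each timescale by a bounded 1-D search that
# never accepts a worse value, so the marginal log-likelihood is
# non-decreasing.

#' Bin spikes around reach onsets and z-score
#'
#' Counts per 15 ms bin in `window` relative to each trial's reach onset;
#' each unit is z-transformed using its concatenated-across-trials mean and
#' s.d. Units with zero variance or a mean in-window rate below
#' `min_rate_hz` are excluded (with a warning).
#'
#' @param spikes a `spike_train_set` (one area).
#' @param trials a `trial_table`.
#' @param window `c(lo, hi)` seconds relative to reach onset.
#' @param bin_s bin width (s).
#' @param min_rate_hz exclusion threshold for near-silent units.
#' @return list of class `trial_tensor`: `counts` (list of units x bins
#'   matrices, z-scored), `raw` (integer counts), `unit_ids`, `mean`, `sd`
#'   (per-unit z-scoring parameters), `bin_s`, `window`, `n_bins`.
#' @export
bin_zscore <- function(spikes, trials, window, bin_s = 0.015,
                       min_rate_hz = 0.5) {
  if (nrow(trials) == 0L) stop("no trials")
  n_bins <- floor((window[2] - window[1]) / bin_s)
  if (n_bins < 1L) stop("empty window")
  edges <- window[1] + bin_s * (0:n_bins)
  units <- spikes$units
  raw <- lapply(trials$reach_onset, function(on) {
    m <- matrix(0L, length(units), n_bins)
    for (i in seq_along(units)) {
      rel <- units[[i]]$times - on
      rel <- rel[rel >= edges[1L] & rel < edges[n_bins + 1L]]
      if (length(rel))
        m[i, ] <- tabulate(findInterval(rel, edges), nbins = n_bins)
    }
    m
  })
  conc <- do.call(cbind, raw)
  mu <- rowMeans(conc)
  sdev <- apply(conc, 1L, stats::sd)
  rate <- mu / bin_s
  keep <- sdev > 0 & rate >= min_rate_hz
  if (!all(keep))
    warning(sum(!keep), " unit(s) excluded (silent or below ",
            min_rate_hz, " Hz)")
  if (!any(keep)) stop("no usable units")
  ids <- vapply(units, function(u) u$unit_id, character(1))[keep]
  z <- lapply(raw, function(m) (m[keep, , drop = FALSE] - mu[keep]) / sdev[keep])
  structure(list(counts = z, raw = lapply(raw, function(m) m[keep, , drop = FALSE]),
                 unit_ids = ids, mean = mu[keep], sd = sdev[keep],
                 bin_s = bin_s, window = window, n_bins = n_bins),
            class = "trial_tensor")
}

# squared-exponential kernel over bin indices
se_kernel <- function(T_bins, tau_s, bin_s, gp_noise) {
  dt <- outer(seq_len(T_bins), seq_len(T_bins), "-") * bin_s
  (1 - gp_noise) * exp(-dt^2 / (2 * tau_s^2)) + gp_noise * diag(T_bins)
}

# E-step machinery shared by fit/inference/prediction.
# Returns posterior means (q x T per trial), the posterior covariance of the
# latent-major stacked vector, and per-trial log-likelihood.
gpfa_estep <- function(Y_list, C, d, Rdiag, taus, bin_s, gp_noise) {
  p <- nrow(C); q <- ncol(C); T_bins <- ncol(Y_list[[1L]])
  N <- length(Y_list)
  Kinv_blocks <- vector("list", q)
  logdetK <- 0
  for (j in seq_len(q)) {
    K <- se_kernel(T_bins, taus[j], bin_s, gp_noise)
    ch <- chol(K)
    logdetK <- logdetK + 2 * sum(log(diag(ch)))
    Kinv_blocks[[j]] <- chol2inv(ch)
  }
  Kinv <- matrix(0, q * T_bins, q * T_bins)
  for (j in seq_len(q)) {
    idx <- ((j - 1L) * T_bins + 1L):(j * T_bins)
    Kinv[idx, idx] <- Kinv_blocks[[j]]
  }
  Rinv <- 1 / Rdiag
  CtRC <- crossprod(C, C * Rinv)          # q x q
  Prec <- Kinv + kronecker(CtRC, diag(T_bins))
  chP <- chol(Prec)
  logdetPrec <- 2 * sum(log(diag(chP)))
  Sigma <- chol2inv(chP)                  # posterior covariance (shared)
  B <- t(C * Rinv)                        # q x p
  A <- matrix(0, q * T_bins, N)
  quad_base <- numeric(N)
  for (n in seq_len(N)) {
    Yc <- Y_list[[n]] - d
    An <- B %*% Yc                        # q x T
    A[, n] <- as.vector(t(An))
    quad_base[n] <- sum(Yc^2 * Rinv)
  }
  M <- Sigma %*% A                        # posterior means, stacked
  quad_red <- colSums(A * M)
  ll <- -0.5 * (p * T_bins * log(2 * pi) + T_bins * sum(log(Rdiag)) +
                  logdetK + logdetPrec) * N -
    0.5 * sum(quad_base - quad_red)
  means <- lapply(seq_len(N), function(n)
    matrix(M[, n], nrow = T_bins, ncol = q)) # T x q each
  list(means = means, Sigma = Sigma, ll = ll, Kinv_blocks = Kinv_blocks,
       logdetK = logdetK)
}

#' Fit a GPFA model
#'
#' @param tensor a `trial_tensor` from [bin_zscore()].
#' @param q latent dimensionality (`q < n_units`); `q = 0` degenerates to an
#'   independent diagonal-Gaussian model.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param gp_noise fixed innovation-noise fraction of the GP kernel.
#' @param tau_init initial timescale (s).
#' @param min_trials minimum trial count.
#' @return object of class `gpfa_model`: loadings `C` (ordered by explained
#'   shared variance, descending), mean `d`, private variances `Rdiag`,
#'   timescales `taus` (s), `bin_s`, `loglik` (per-iteration trace), `q`.
#' @export
fit_gpfa <- function(tensor, q, tol = 1e-6, max_iter = 500, gp_noise = 1e-3,
                     tau_init = 0.1, min_trials = 10) {
  Y_list <- tensor$counts
  p <- nrow(Y_list[[1L]]); T_bins <- ncol(Y_list[[1L]]); N <- length(Y_list)
  if (q >= p) stop("q must be smaller than the number of units")
  if (N < min_trials) stop("need at least ", min_trials, " trials")
  conc <- do.call(cbind, Y_list)
  d <- rowMeans(conc)
  if (q == 0L) {
    Rdiag <- apply(conc, 1L, stats::var)
    ll <- sum(stats::dnorm(conc, d, sqrt(Rdiag), log = TRUE))
    return(structure(list(C = matrix(0, p, 0L), d = d, Rdiag = Rdiag,
                          taus = numeric(0), bin_s = tensor$bin_s,
                          loglik = ll, q = 0L, gp_noise = gp_noise),
                     class = "gpfa_model"))
  }
  # PCA initialization
  cc <- conc - d
  sv <- svd(cc, nu = q, nv = 0L)
  C <- sv$u %*% diag(sv$d[seq_len(q)] / sqrt(ncol(cc)), q)
  resid <- pmax(apply(cc, 1L, stats::var) - rowSums(C^2), 1e-3)
  Rdiag <- resid
  taus <- rep(tau_init, q)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    es <- gpfa_estep(Y_list, C, d, Rdiag, taus, tensor$bin_s, gp_noise)
    ll_trace <- c(ll_trace, es$ll)
    if (!is.finite(es$ll)) stop("non-finite likelihood")
    if (iter > 1L && (es$ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- es$ll
    # sufficient statistics
    Vsum <- matrix(0, q, q)                       # sum_t Cov(z_t)
    for (j1 in seq_len(q)) for (j2 in seq_len(q)) {
      i1 <- ((j1 - 1L) * T_bins + 1L):(j1 * T_bins)
      i2 <- ((j2 - 1L) * T_bins + 1L):(j2 * T_bins)
      Vsum[j1, j2] <- sum(diag(es$Sigma[i1, i2, drop = FALSE]))
    }
    Szz <- N * Vsum
    Sz <- matrix(0, q, 1L)
    Syz <- matrix(0, p, q)
    Sy <- rowSums(conc)
    Syy_diag <- rowSums(conc^2)
    for (n in seq_len(N)) {
      Mn <- t(es$means[[n]])                      # q x T
      Szz <- Szz + tcrossprod(Mn)
      Sz <- Sz + rowSums(Mn)
      Syz <- Syz + Y_list[[n]] %*% t(Mn)
    }
    NT <- N * T_bins
    # joint update of [C d]
    G <- rbind(cbind(Szz, Sz), cbind(t(Sz), NT))
    H <- cbind(Syz, Sy)
    Cd <- H %*% solve(G)
    C <- Cd[, seq_len(q), drop = FALSE]
    d <- Cd[, q + 1L]
    Rdiag <- pmax((Syy_diag - rowSums(Cd * H)) / NT, 1e-6)
    # timescale update (latent-wise bounded search; keep the better value)
    for (j in seq_len(q)) {
      i1 <- ((j - 1L) * T_bins + 1L):(j * T_bins)
      Sj <- N * es$Sigma[i1, i1]
      for (n in seq_len(N)) Sj <- Sj + tcrossprod(es$means[[n]][, j])
      obj <- function(tau) {
        K <- se_kernel(T_bins, tau, tensor$bin_s, gp_noise)
        ch <- tryCatch(chol(K), error = function(e) NULL)
        if (is.null(ch)) return(Inf)
        sum(chol2inv(ch) * Sj) + 2 * N * sum(log(diag(ch)))
      }
      cand <- stats::optimize(obj, c(tensor$bin_s / 2, 1))$minimum
      if (obj(cand) < obj(taus[j])) taus[j] <- cand
    }
  }
  # order factors by explained shared variance
  o <- order(colSums(C^2), decreasing = TRUE)
  structure(list(C = C[, o, drop = FALSE], d = d, Rdiag = Rdiag,
                 taus = taus[o], bin_s = tensor$bin_s, loglik = ll_trace,
                 q = q, gp_noise = gp_noise),
            class = "gpfa_model")
}

#' @export
print.gpfa_model <- function(x, ...) {
  cat(sprintf("<gpfa_model: %d units, q=%d, taus=%s s, %d EM iters>\n",
              nrow(x$C), x$q, paste(signif(x$taus, 3), collapse = "/"),
              length(x$loglik)))
  invisible(x)
}

#' Posterior-mean latent trajectories
#'
#' @param model a `gpfa_model`.
#' @param tensor a `trial_tensor` with matching units.
#' @param n_factors number of top factors to retain.
#' @return list of class `trajectory_set`: `trajectories` (list of
#'   bins x n_factors matrices), `shared_frac` (per-factor shared-variance
#'   fractions), `shared_over_total` (`tr(CC') / tr(CC' + R)`).
#' @export
extract_trajectories <- function(model, tensor, n_factors = 3) {
  if (nrow(model$C) != nrow(tensor$counts[[1L]]))
    stop("model/tensor unit mismatch")
  es <- gpfa_estep(tensor$counts, model$C, model$d, model$Rdiag, model$taus,
                   model$bin_s, model$gp_noise)
  nf <- min(n_factors, model$q)
  shared_per <- colSums(model$C^2)
  trajs <- lapply(es$means, function(m) m[, seq_len(nf), drop = FALSE])
  list(trajectories = trajs,
       shared_frac = shared_per / sum(shared_per),
       shared_over_total = sum(shared_per) / (sum(shared_per) + sum(model$Rdiag)))
}

#' Leave-neuron-out latent dimensionality selection
#'
#' For each candidate `q`, models are fitted on training trials
#' (`n_folds`-fold split) and every unit of each held-out trial is
#' predicted from the latents inferred using the remaining units; the `q`
#' minimizing the summed squared prediction error is selected.
#'
#' @param tensor a `trial_tensor`.
#' @param dims candidate dimensionalities.
#' @param max_iter EM cap per candidate fit.
#' @param n_folds trial-level cross-validation folds.
#' @param ... forwarded to [fit_gpfa()].
#' @return list: `q` (selected), `errors` (named per candidate).
#' @export
select_dim <- function(tensor, dims = 1:6, max_iter = 100, n_folds = 2,
                       ...) {
  if (length(dims) == 0L) stop("empty candidate set")
  if (length(dims) == 1L)
    return(list(q = dims, errors = stats::setNames(NA_real_, dims)))
  N <- length(tensor$counts)
  folds <- rep_len(seq_len(n_folds), N)
  errs <- stats::setNames(numeric(length(dims)), dims)
  for (k in seq_along(dims)) {
    qq <- dims[k]
    tot <- 0
    for (f in seq_len(n_folds)) {
      train <- tensor; train$counts <- tensor$counts[folds != f]
      test <- tensor; test$counts <- tensor$counts[folds == f]
      fit <- fit_gpfa(train, qq, max_iter = max_iter, min_trials = 2, ...)
      tot <- tot + lno_error(fit, test)
    }
    errs[k] <- tot
  }
  list(q = dims[which.min(errs)], errors = errs)
}

# leave-one-unit-out squared prediction error, summed over units and trials
lno_error <- function(model, tensor) {
  p <- nrow(model$C)
  total <- 0
  for (i in seq_len(p)) {
    keep <- setdiff(seq_len(p), i)
    Yk <- lapply(tensor$counts, function(m) m[keep, , drop = FALSE])
    es <- gpfa_estep(Yk, model$C[keep, , drop = FALSE], model$d[keep],
                     model$Rdiag[keep], model$taus, model$bin_s,
                     model$gp_noise)
    for (n in seq_along(Yk)) {
      pred <- as.numeric(model$C[i, , drop = FALSE] %*% t(es$means[[n]])) +
        model$d[i]
      total <- total + sum((tensor$counts[[n]][i, ] - pred)^2)
    }
  }
  total
}

#' Procrustes alignment of daily manifolds
#'
#' Each day's mean trajectory (in its own top-factor space) is aligned to a
#' reference — by default the mean manifold of the final three days — with
#' a Procrustes transformation (rotation/reflection, scaling, translation);
#' the same transformation is applied to that day's single-trial
#' trajectories.
#'
#' @param day_trajectories list (one per day) of lists of bins x 3 trial
#'   trajectories.
#' @param reference optional bins x 3 reference; defaults to the grand mean
#'   of the final three days' mean trajectories (resampled to a common
#'   length).
#' @param n_points common resampling length.
#' @return list: `aligned` (same shape as input, trajectories resampled to
#'   `n_points` and transformed), `reference`, `disparity` (per day).
#' @export
align_days <- function(day_trajectories, reference = NULL, n_points = 100) {
  n_days <- length(day_trajectories)
  day_means <- lapply(day_trajectories, function(trials) {
    rs <- lapply(trials, resample_rows, n_out = n_points)
    Reduce(`+`, rs) / length(rs)
  })
  if (is.null(reference)) {
    if (n_days < 3L) stop("reference undefined: fewer than 3 days")
    last3 <- day_means[(n_days - 2L):n_days]
    reference <- Reduce(`+`, last3) / 3
  }
  aligned <- vector("list", n_days)
  disparity <- numeric(n_days)
  for (dd in seq_len(n_days)) {
    pr <- vegan::procrustes(reference, day_means[[dd]], scale = TRUE,
                            symmetric = FALSE)
    disparity[dd] <- pr$ss
    aligned[[dd]] <- lapply(day_trajectories[[dd]], function(tr)
      stats::predict(pr, resample_rows(tr, n_points)))
  }
  list(aligned = aligned, reference = reference, disparity = disparity)
}

#' Trajectory-template correlation (GPFA correlation)
#'
#' Both trajectories are linearly resampled to 100 points per factor, each
#' factor is mean-centered, and the Pearson correlation is taken over the
#' concatenated factors. Per-factor centering makes the statistic exactly
#' invariant to a simultaneous rotation of trajectory and template.
#'
#' @param trajectory,template bins x factors matrices.
#' @param n_points resampling length per factor.
#' @return scalar correlation.
#' @export
gpfa_correlation <- function(trajectory, template, n_points = 100) {
  a <- concat_centered(resample_rows(trajectory, n_points))
  b <- concat_centered(resample_rows(template, n_points))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance trajectory")
  stats::cor(a, b)
}

# concatenate a bins x factors matrix after centering each factor
concat_centered <- function(m) {
  as.vector(scale(m, center = TRUE, scale = FALSE))
}

#' Neural-trajectory fidelity
#'
#' Signal-to-noise ratio of GPFA correlations across trials:
#' `mean(R) / sd(R)` (successful and failed trials pooled).
#'
#' @param r vector of GPFA correlations (one per trial; >= 3).
#' @return scalar fidelity.
#' @export
fidelity <- function(r) {
  if (length(r) < 3L) stop("need at least 3 trials")
  s <- stats::sd(r)
  if (s == 0) stop("fidelity undefined: zero s.d.")
  mean(r) / s
}

#' Per-unit circular spike shuffling of an event tensor
#'
#' Each unit's binned counts are rotated circularly within each event's
#' permutation window by an independent uniform offset, preserving per-unit
#' counts while destroying cross-unit temporal structure.
#'
#' @param tensor 3-d array, units x bins x events (binned over the
#'   permutation window).
#' @param reps number of shuffles.
#' @param seed RNG seed.
#' @param fn optional function(surrogate array) -> value; when given, the
#'   per-rep values are returned instead of the surrogate tensors.
#' @return list of surrogate arrays, or the list of `fn` values.
#' @export
spike_shuffle_surrogate <- function(tensor, reps = 1000, seed = 1, fn = NULL) {
  d <- dim(tensor)
  set.seed(seed)
  one <- function() {
    out <- tensor
    for (e in seq_len(d[3L])) {
      shifts <- sample.int(d[2L], d[1L], replace = TRUE) - 1L
      for (i in seq_len(d[1L])) {
        if (shifts[i] == 0L) next
        v <- tensor[i, , e]
        out[i, , e] <- c(v[(d[2L] - shifts[i] + 1L):d[2L]],
                         v[seq_len(d[2L] - shifts[i])])
      }
    }
    out
  }
  res <- vector("list", reps)
  for (r in seq_len(reps)) {
    s <- one()
    res[[r]] <- if (is.null(fn)) s else fn(s)
  }
  res
}
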