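# Shared oracles and small fixture builders. Oracles are deliberately
# written as naive brute-force computations, independent of the package's
# code paths.

# event-matching F1 at a peak-time tolerance
match_f1 <- function(est, truth, tol = 0.1) {
  if (length(est) == 0L || length(truth) == 0L)
    return(list(precision = 0, recall = 0, f1 = 0))
  rec <- mean(vapply(truth, function(x) any(abs(est - x) < tol), logical(1)))
  prec <- mean(vapply(est, function(x) any(abs(truth - x) < tol), logical(1)))
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec, f1 = f1)
}

# O(n^2) nearest-reference search
brute_nearest_lags <- function(targets, refs) {
  vapply(targets, function(t) {
    d <- abs(t - refs)
    cand <- refs[d == min(d)]
    t - min(cand)   # tie toward the earlier reference
  }, numeric(1))
}

# brute-force periodogram band power via explicit DFT sums (Hann taper)
brute_band_power <- function(seg, rate, band) {
  n <- length(seg)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  x <- (seg - mean(seg)) * taper
  freqs <- (0:(floor(n / 2))) * rate / n
  sel <- which(freqs >= band[1] & freqs <= band[2])
  tt <- seq_len(n) - 1L
  pw <- vapply(sel, function(k) {
    f <- (k - 1L)
    re <- sum(x * cos(2 * pi * f * tt / n))
    im <- sum(x * sin(2 * pi * f * tt / n))
    scale <- if (k == 1L || (n %% 2L == 0L && k == length(freqs))) 1 else 2
    scale * (re^2 + im^2) / (rate * sum(taper^2))
  }, numeric(1))
  mean(pw)
}

# naive O(n) envelope threshold scan (sample-by-sample state machine)
brute_envelope_events <- function(env, rate, lower, upper, min_dur) {
  out <- NULL
  i <- 1L
  n <- length(env)
  while (i <= n) {
    if (!is.na(env[i]) && env[i] > lower) {
      j <- i
      while (j < n && !is.na(env[j + 1L]) && env[j + 1L] > lower) j <- j + 1L
      if ((j - i + 1L) / rate >= min_dur && any(env[i:j] > upper))
        out <- rbind(out, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# MATLAB-style Procrustes (translation + scaling + rotation), closed form
brute_procrustes <- function(X, Y) {
  xc <- colMeans(X); yc <- colMeans(Y)
  X0 <- sweep(X, 2L, xc); Y0 <- sweep(Y, 2L, yc)
  nx <- sqrt(sum(X0^2)); ny <- sqrt(sum(Y0^2))
  X0 <- X0 / nx; Y0 <- Y0 / ny
  s <- svd(crossprod(X0, Y0))
  rot <- s$v %*% t(s$u)
  scale <- sum(s$d) * nx / ny
  trans <- xc - scale * yc %*% rot
  list(rotation = rot, scale = scale, translation = trans,
       aligned = scale * Y %*% rot + matrix(trans, nrow(Y), ncol(Y),
                                            byrow = TRUE))
}

# simulate a linear-Gaussian GPFA dataset directly from the model
make_gpfa_data <- function(p, q, T_bins, N, taus, bin = 0.015, seed = 1,
                           noise = c(0.05, 0.2), loading_sd = 0.5) {
  set.seed(seed)
  C <- matrix(stats::rnorm(p * q, 0, loading_sd), p, q)
  Rd <- stats::runif(p, noise[1], noise[2])
  K <- lapply(taus, function(tau) {
    dt <- outer(seq_len(T_bins), seq_len(T_bins), "-") * bin
    0.999 * exp(-dt^2 / (2 * tau^2)) + 0.001 * diag(T_bins)
  })
  Y <- lapply(seq_len(N), function(n) {
    z <- vapply(seq_len(q), function(j)
      as.numeric(t(chol(K[[j]])) %*% stats::rnorm(T_bins)), numeric(T_bins))
    t(z %*% t(C)) + matrix(stats::rnorm(p * T_bins, 0, sqrt(Rd)), p, T_bins)
  })
  tens <- structure(list(counts = Y, bin_s = bin, n_bins = T_bins,
                         mean = rep(0, p), sd = rep(1, p),
                         unit_ids = paste0("u", seq_len(p))),
                    class = "trial_tensor")
  list(tensor = tens, C = C, Rdiag = Rd)
}

# largest principal angle (degrees) between column spans
subspace_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(max(min(s), -1), 1)) * 180 / pi
}

# small sleep-block fixture (event-level truth + optional LFP)
small_sleep_block <- function(seed = 42, sleep_s = 600, day = 3, lfp = TRUE) {
  simulate_sleep_block(sim_config(sleep_s = sleep_s), day = day, seed = seed,
                       lfp = lfp)
}
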