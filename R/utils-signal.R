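# Small numerical helpers shared by the staging and detection code.

#' Magnitude of the analytic signal
#'
#' FFT construction of the analytic signal (positive frequencies doubled,
#' negative zeroed); the modulus is the instantaneous amplitude envelope.
#'
#' @param x real numeric vector.
#' @return numeric vector, `Mod(analytic(x))`, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  # pad to a highly composite length: R's mixed-radix FFT degrades badly on
  # lengths with large prime factors
  m <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x, rep(0, m - n))
  h <- numeric(m)
  if (m %% 2L == 0L) {
    h[c(1L, m / 2L + 1L)] <- 1
    h[2:(m / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((m + 1L) / 2L)] <- 2
  }
  env <- Mod(stats::fft(stats::fft(xp) * h, inverse = TRUE) / m)
  env[seq_len(n)]
}

#' Gaussian smoothing of a sampled signal
#'
#' Kernel standard deviation is `width_s / 2` (the configured "window" length
#' is read as the full width at two sigma), truncated at three sigma and
#' normalized to sum to one. Edges are handled by renormalizing over the
#' available samples, so constants are preserved.
#'
#' @param x numeric vector.
#' @param rate sampling rate (samples/s).
#' @param width_s window length (s).
#' @return smoothed numeric vector, same length.
#' @export
gaussian_smooth <- function(x, rate, width_s) {
  sigma <- width_s / 2 * rate
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  n <- length(x)
  m <- stats::nextn(n + length(k) - 1L, c(2, 3, 5))
  fk <- stats::fft(c(k, rep(0, m - length(k))))
  conv <- function(v) {
    fv <- stats::fft(c(v, rep(0, m - n)))
    Re(stats::fft(fv * fk, inverse = TRUE) / m)
  }
  num <- conv(x)
  den <- conv(rep(1, n))
  idx <- (half + 1L):(half + n)
  num[idx] / den[idx]
}

#' 1/f ("pink") background noise
#'
#' Gaussian white noise shaped in the frequency domain by 1/sqrt(f), the
#' canonical broadband LFP background.
#'
#' @param n number of samples.
#' @param rate sampling rate (samples/s).
#' @return numeric vector of length `n`, zero mean, unit standard deviation.
#' @export
pink_noise <- function(n, rate = 1018) {
  m <- stats::nextn(n, c(2, 3, 5))
  white <- stats::rnorm(m)
  f <- seq(0, rate / 2, length.out = floor(m / 2) + 1L)
  shape <- 1 / sqrt(pmax(f, f[2L]))
  spec <- stats::fft(white)
  full <- c(shape, rev(shape[2:(m - length(shape) + 1L)]))
  x <- Re(stats::fft(spec * full, inverse = TRUE) / m)
  as.numeric(scale(x[seq_len(n)]))
}

# linear-interpolation matrix mapping n_in samples to n_out samples
interp_matrix <- function(n_in, n_out) {
  if (n_in == 1L) return(matrix(1, n_out, 1L))
  xi <- seq(1, n_in, length.out = n_out)
  lo <- pmin(floor(xi), n_in - 1L)
  w <- xi - lo
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), lo)] <- 1 - w
  W[cbind(seq_len(n_out), lo + 1L)] <- w
  W
}

# linear resampling of a matrix (bins x factors) to n_out rows
resample_rows <- function(m, n_out) {
  m <- as.matrix(m)
  interp_matrix(nrow(m), n_out) %*% m
}
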