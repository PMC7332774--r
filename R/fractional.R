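#' Fractional Gaussian noise with a prescribed Hurst exponent
#'
#' Exact simulation by circulant embedding (Davies–Harte) of the fGn
#' autocovariance.  The series is monofractal: its wavelet-leader first
#' log-cumulant converges to `hurst` and the second to zero.
#'
#' @param n_samples series length (>= 1024).
#' @param hurst Hurst exponent, strictly inside (0, 1).
#' @param seed integer seed; same seed, same series.
#' @param rate nominal sampling rate attached to the result (Hz).
#' @return a [uniform_series()] of length `n_samples`, unit variance.
#' @export
generate_fractional_signal <- function(n_samples, hurst, seed, rate = 1) {
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie strictly inside (0, 1)")
  stopifnot(n_samples >= 1024)
  set.seed(seed)
  uniform_series(rfgn(n_samples, hurst), rate = rate)
}

# Raw fGn draw using the current RNG state.
rfgn <- function(n, H) {
  m <- 2^ceiling(log2(2 * (n - 1)))
  k <- 0:(m / 2)
  gamma <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(gamma, rev(gamma[2:(m / 2)]))
  lambda <- Re(fft(circ))
  lambda[lambda < 0] <- 0 # numerical guard; fGn embedding is nonneg in theory
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  w <- fft(sqrt(lambda) * z, inverse = FALSE) / sqrt(m)
  Re(w)[1:n]
}

#' Multifractal random walk increments
#'
#' Increments `eps * exp(omega)` where `eps` is white Gaussian and `omega` is a
#' Gaussian field with logarithmic covariance
#' `lambda2 * log(L / (|k| + 1))` (zero beyond the correlation length `L`),
#' generated by circulant embedding.  The walk `cumsum(x)` is multifractal
#' with second log-cumulant approximately `-lambda2`.  Used as an independent
#' oracle for the multifractality estimator.
#'
#' @param n_samples length.
#' @param lambda2 intermittency parameter (e.g. 0.05).
#' @param seed integer seed.
#' @param corr_length correlation length `L` in samples (default `n_samples/8`).
#' @return numeric vector of increments, normalized to unit variance.
#' @export
generate_mrw <- function(n_samples, lambda2, seed,
                         corr_length = floor(n_samples / 8)) {
  stopifnot(n_samples >= 1024, lambda2 > 0, corr_length > 2)
  set.seed(seed)
  m <- 2^ceiling(log2(2 * n_samples))
  k <- 0:(m / 2)
  cov <- ifelse(k < corr_length, lambda2 * log(corr_length / (k + 1)), 0)
  circ <- c(cov, rev(cov[2:(m / 2)]))
  lambda <- Re(fft(circ))
  lambda[lambda < 0] <- 0
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  omega <- Re(fft(sqrt(lambda) * z) / sqrt(m))[1:n_samples]
  # centre so that E[exp(2*omega)] = 1 (keeps the variance bounded)
  omega <- omega - lambda2 * log(corr_length)
  x <- rnorm(n_samples) * exp(omega)
  x / sd(x)
}

# Band-limited Gaussian noise at `rate` Hz in (f_lo, f_hi], unit variance,
# returned with its exact quarter-cycle (Hilbert) quadrature so that a second
# process can be coupled at a 90-degree phase offset.
rband_analytic <- function(n, rate, f_lo, f_hi) {
  m <- 2^ceiling(log2(max(n, 64)))
  freqs <- (0:(m - 1)) / m * rate
  keep <- freqs > f_lo & freqs <= f_hi
  spec <- complex(real = rnorm(m), imaginary = rnorm(m))
  spec[!keep] <- 0
  z <- fft(spec, inverse = TRUE)[1:n] # one-sided spectrum -> analytic signal
  re <- Re(z); im <- Im(z)
  s <- sd(re)
  if (s < .Machine$double.eps) s <- 1
  list(re = re / s, im = im / s)
}

rband <- function(n, rate, f_lo, f_hi) rband_analytic(n, rate, f_lo, f_hi)$re
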