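# Analytic Morlet continuous wavelet machinery.
#
# All transforms run through FFTs on a zero-padded grid; multi-column batches
# (channels, surrogates) go through a single mvfft call.  The mother wavelet is
# the analytic Morlet with centre angular frequency omega0 = 6, so scale
# s = omega0 / (2*pi*f) for centre frequency f.  The cone of influence uses the
# e-folding time sqrt(2)*s.

MORLET_OMEGA0 <- 6

# Dyadic frequency grid covering (f_lo, f_hi] at `voices` voices per octave.
dyadic_freqs <- function(f_lo, f_hi, voices = 12) {
  n_oct <- log2(f_hi / f_lo)
  k <- ceiling(n_oct * voices)
  f_hi * 2^(-(k:0) / voices)
}

# Precomputed transform plan for signals of length n at `rate` Hz.  Padding
# covers the widest wavelet/smoothing kernel support (~6 scales) so circular
# wrap-around only touches cone-of-influence samples.
cwt_plan <- function(n, rate, freqs) {
  max_scale <- MORLET_OMEGA0 / (2 * pi * min(freqs))
  npad <- stats::nextn(n + ceiling(6 * max_scale * rate), c(2, 3))
  scales <- MORLET_OMEGA0 / (2 * pi * freqs)           # seconds
  w <- 2 * pi * rate * c(0:(npad / 2), -((npad / 2 - 1):1)) / npad
  J <- length(freqs)
  H <- matrix(0, npad, J)
  pos <- w > 0
  for (j in seq_len(J)) {
    H[pos, j] <- pi^(-1 / 4) * sqrt(2) * exp(-(scales[j] * w[pos] - MORLET_OMEGA0)^2 / 2)
  }
  tt <- (seq_len(n) - 1) / rate
  span <- (n - 1) / rate
  coi_excl <- outer(tt, sqrt(2) * scales, `<`) |
    outer(span - tt, sqrt(2) * scales, `<`)
  # 3-pass box of half width h has sd sqrt(h(h+1)/3); match sigma = scale
  box_h <- vapply(scales, function(s) {
    sigma <- s * rate
    max(1L, as.integer(round(sqrt(sigma^2 / 3 + 0.25) - 0.5)))
  }, 1L)
  list(n = n, npad = npad, rate = rate, freqs = freqs,
       scales = scales, J = J, H = H, coi_excl = coi_excl, box_h = box_h)
}

pad_fft <- function(x, plan) {
  fft(c(x, numeric(plan$npad - length(x))))
}

# CWT of one signal: n x J complex matrix.
morlet_cwt <- function(x, plan) {
  xh <- pad_fft(x, plan)
  W <- mvfft(xh * plan$H, inverse = TRUE) / plan$npad
  W[seq_len(plan$n), , drop = FALSE]
}

# Batched CWT of k signals (columns of X): returns npad x (J*k); column block
# b = (k-1)*J + j holds scale j of signal k.  Rows are kept at npad so that
# smoothing can run on the same grid; truncate after smoothing.
morlet_cwt_block <- function(X, plan) {
  k <- ncol(X)
  Xh <- mvfft(rbind(X, matrix(0, plan$npad - nrow(X), k)))
  Hrep <- plan$H[, rep(seq_len(plan$J), times = k), drop = FALSE]
  Xrep <- Xh[, rep(seq_len(k), each = plan$J), drop = FALSE]
  mvfft(Xrep * Hrep, inverse = TRUE) / plan$npad
}



# Scale-proportional Gaussian time smoothing of a real n x (J*k) field by a
# cascade of three boxcar passes per scale (their convolution approximates
# the Gaussian of standard deviation `scale` closely and runs in O(n) via
# cumulative sums; a 3-pass box of half width h has sd sqrt(h*(h+1))).
time_smooth_real_block <- function(Z, plan) {
  J <- plan$J
  k <- ncol(Z) / J
  n <- min(nrow(Z), plan$n)
  Z <- Z[seq_len(n), , drop = FALSE]
  box3_smooth(Z, rep(plan$box_h, times = k))
}

# Full smoothing of a real field (e.g. squared magnitudes, imaginary parts).
tf_smooth_real <- function(Z, plan) {
  scale_smooth_block(time_smooth_real_block(Z, plan), plan$J)
}

# Boxcar over 3 adjacent voices within each J-block.
scale_smooth_block <- function(Z, J) {
  if (J == 1) return(Z)
  k <- ncol(Z) / J
  out <- Z
  idx <- which(rep(c(FALSE, rep(TRUE, J - 1)), k))
  out[, idx] <- out[, idx] + Z[, idx - 1]
  idx <- which(rep(c(rep(TRUE, J - 1), FALSE), k))
  out[, idx] <- out[, idx] + Z[, idx + 1]
  out <- out / 3
  edge <- which(rep(c(TRUE, rep(FALSE, J - 2), TRUE), k))
  out[, edge] <- out[, edge] * 1.5
  out
}

# Full coherence smoothing S(.) of Eq.-style cross/auto scalograms (complex
# path: real and imaginary parts are smoothed with the identical kernel, so
# ratios of identically smoothed fields are exact).
tf_smooth <- function(Z, plan) {
  S <- time_smooth_real_block(Re(Z), plan) +
    1i * time_smooth_real_block(Im(Z), plan)
  scale_smooth_block(S, plan$J)
}

#' Time-frequency wavelet coherence
#'
#' Complex coherence `C = S(Wx Wy*) / sqrt(S|Wx|^2 S|Wy|^2)` between two
#' equally sampled series, with analytic-Morlet scalograms and smoothing `S`
#' in time (a Gaussian-shaped kernel of standard deviation equal to the
#' scale, realized as a three-pass boxcar cascade) and across scales (boxcar
#' over 3 voices).  Without smoothing the ratio is identically 1; the kernel
#' widths are fixed constants of the method.
#'
#' @param x,y numeric vectors of equal length (>= 512 recommended).
#' @param rate sampling rate, Hz.
#' @param freqs centre-frequency grid; default a dyadic grid at
#'   `voices` voices/octave from `4 / span` Hz to Nyquist.
#' @param voices voices per octave for the default grid.
#' @return list of class `"wavelet_coherence"`: `coherence` (n x J complex),
#'   `freqs`, `rate`, `coi_excl` (logical n x J, TRUE where the cone of
#'   influence invalidates the estimate).
#' @export
wavelet_coherence <- function(x, y, rate = 8, freqs = NULL, voices = 12) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (is.null(freqs)) {
    f_lo <- max(4 / (n / rate), rate / n)
    freqs <- dyadic_freqs(f_lo, rate / 2, voices)
  }
  plan <- cwt_plan(n, rate, freqs)
  Wx <- morlet_cwt_block(cbind(x), plan)
  Wy <- morlet_cwt_block(cbind(y), plan)
  Sxx <- tf_smooth_real(Mod(Wx)^2, plan)
  Syy <- tf_smooth_real(Mod(Wy)^2, plan)
  Sxy <- tf_smooth(Wx * Conj(Wy), plan)[seq_len(n), , drop = FALSE]
  C <- Sxy / sqrt(pmax(Sxx * Syy, .Machine$double.xmin))
  structure(list(coherence = C,
                 freqs = freqs, rate = rate,
                 coi_excl = plan$coi_excl),
            class = "wavelet_coherence")
}

#' Band coupling from a coherence object
#'
#' The coupling statistic at each time sample: the maximum over in-band
#' scales of the absolute imaginary part of the coherence.  Samples inside
#' the cone of influence of any in-band scale are returned as `NA`.
#'
#' @param C a [wavelet_coherence()] result.
#' @param band `c(f_lo, f_hi)`; scales with centre frequency in `(f_lo, f_hi]`.
#' @return numeric vector over time (NA inside the cone).
#' @export
band_coupling <- function(C, band) {
  sel <- C$freqs > band[1] & C$freqs <= band[2]
  if (!any(sel)) stop("no scales inside the requested band")
  im <- abs(Im(C$coherence[, sel, drop = FALSE]))
  im[C$coi_excl[, sel, drop = FALSE]] <- NA
  suppressWarnings(out <- apply(im, 1, max, na.rm = TRUE))
  out[!is.finite(out)] <- NA
  out
}

#' Instantaneous band power via the analytic-Morlet CWT
#'
#' Squared scalogram magnitudes summed over the scales whose centre frequency
#' falls in each band, per time sample.  Cone-of-influence samples (for each
#' band, the cone of its largest in-band scale) are flagged.
#'
#' @param series a [uniform_series()] (>= 64 samples).
#' @param bands named list of `c(f_lo, f_hi)` bands, e.g.
#'   `list(LF = c(0.08, 0.2), HF = c(0.2, 4))`.
#' @param voices voices per octave.
#' @return list of class `"spectral_series"`: `power` (n x n_bands matrix),
#'   `coi_excl` (same shape, logical), `rate`, `t0`.
#' @export
cwt_band_power <- function(series, bands, voices = 12) {
  stopifnot(inherits(series, "uniform_series"))
  x <- series$values
  if (length(x) < 64) stop("series too short for band-power analysis")
  f_lo <- min(vapply(bands, `[`, 0, 1))
  f_hi <- max(vapply(bands, `[`, 0, 2))
  if (f_hi > series$rate / 2 + 1e-9) stop("band exceeds the Nyquist frequency")
  freqs <- dyadic_freqs(f_lo, min(f_hi, series$rate / 2), voices)
  plan <- get_plan(length(x), series$rate, freqs)
  W <- morlet_cwt(x - mean(x), plan)
  P2 <- Mod(W)^2
  power <- matrix(0, length(x), length(bands),
                  dimnames = list(NULL, names(bands)))
  coi <- matrix(FALSE, length(x), length(bands),
                dimnames = list(NULL, names(bands)))
  for (b in seq_along(bands)) {
    sel <- freqs > bands[[b]][1] & freqs <= bands[[b]][2]
    if (!any(sel)) stop("no scales inside band ", names(bands)[b])
    power[, b] <- rowSums(P2[, sel, drop = FALSE])
    coi[, b] <- rowSums(plan$coi_excl[, sel, drop = FALSE]) > 0
  }
  structure(list(power = power, coi_excl = coi,
                 rate = series$rate, t0 = series$t0),
            class = "spectral_series")
}
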