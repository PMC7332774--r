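# Wavelet-leader multifractal log-cumulants.
#
# Daubechies-3 discrete wavelet pyramid, leaders as the supremum of absolute
# coefficients over the 3-neighbourhood at all finer scales, log-cumulants
# C1(j) (mean of log-leaders) and C2(j) (their variance) regressed on j*ln 2
# with weights n_j.  Signals are demeaned and integrated (cumulative sum)
# before analysis, so that series with increments of Hurst exponent H in
# (0, 1) — fractional Gaussian noise, multifractal-random-walk increments,
# band-passed EEG — land in the positive-regularity range the leader
# formalism requires; the first log-cumulant of fGn then estimates H itself.

DB3_H <- c(0.3326705529509569, 0.8068915093133388, 0.4598775021193313,
           -0.1350110200102546, -0.0854412738822415, 0.0352262918821007)
DB3_G <- rev(DB3_H) * c(1, -1, 1, -1, 1, -1)

conv_valid <- function(x, f) {
  # y[k] = sum_m f[m] * x[k + m - 1],  k = 1 .. n - length(f) + 1
  L <- length(f)
  as.numeric(stats::filter(x, rev(f), method = "convolution",
                           sides = 1))[L:length(x)]
}

# Pyramid of detail-coefficient magnitudes, L1-normalized (x 2^(-j/2)).
dwt_leader_pyramid <- function(x, min_coeffs = 8L) {
  a <- x
  j <- 0L
  out <- list()
  while (TRUE) {
    j <- j + 1L
    if (length(a) < length(DB3_H) + 2L) break
    d <- conv_valid(a, DB3_G)
    a <- conv_valid(a, DB3_H)
    keep <- seq(1, length(d), by = 2)
    a <- a[seq(1, length(a), by = 2)]
    dj <- abs(d[keep]) * 2^(-j / 2)
    if (length(dj) < min_coeffs) break
    out[[j]] <- dj
  }
  out
}

# Leaders: running sup over dyadic children across scales, then the
# 3-neighbourhood max at each scale; border leaders dropped.
wavelet_leaders <- function(pyr) {
  sup <- NULL
  leaders <- vector("list", length(pyr))
  for (j in seq_along(pyr)) {
    d <- pyr[[j]]
    nj <- length(d)
    if (is.null(sup)) {
      sup <- d
    } else {
      child <- matrix(-Inf, 2, nj)
      avail <- length(sup)
      i1 <- pmin(2 * seq_len(nj) - 1, avail)
      i2 <- pmin(2 * seq_len(nj), avail)
      child[1, ] <- sup[i1]
      child[2, ] <- sup[i2]
      sup <- pmax(d, child[1, ], child[2, ])
    }
    if (nj >= 3) {
      L <- pmax(sup[1:(nj - 2)], sup[2:(nj - 1)], sup[3:nj])
      leaders[[j]] <- L[L > 0]
    } else {
      leaders[[j]] <- numeric(0)
    }
  }
  leaders
}

#' Wavelet-leader log-cumulants c1 and c2
#'
#' Estimates the first two log-cumulants of the multifractal spectrum: `c1`,
#' the dominant Hurst/self-similarity exponent, and `c2`, the (typically
#' non-positive) multifractality width.  `c1`/`c2` are the slopes of the mean
#' and variance of log-leaders against `j * ln 2`, fitted over octaves
#' `j1 = 3` to `j2 = floor(log2(n)) - 3` with weights equal to the number of
#' leaders per scale.  Estimates are invariant to amplitude scaling.
#'
#' @param x numeric vector (>= 1024 samples) or a [uniform_series()].
#' @param rate sampling rate, Hz (metadata only).
#' @return list of class `"log_cumulants"`: `c1`, `c2`, `scale_range`,
#'   `n_leaders`; `c1`/`c2` are `NA` when fewer than 3 usable scales exist.
#' @export
log_cumulants <- function(x, rate = 1) {
  if (inherits(x, "uniform_series")) { rate <- x$rate; x <- x$values }
  na_out <- structure(list(c1 = NA_real_, c2 = NA_real_,
                           scale_range = c(NA, NA), n_leaders = integer(0)),
                      class = "log_cumulants")
  if (length(x) < 1024 || any(!is.finite(x)) || sd(x) == 0) return(na_out)
  xi <- cumsum(x - mean(x))
  pyr <- dwt_leader_pyramid(xi)
  if (!length(pyr)) return(na_out)
  lead <- wavelet_leaders(pyr)
  j2 <- min(length(lead), floor(log2(length(x))) - 3)
  j1 <- 3L
  js <- seq(j1, j2)
  js <- js[vapply(lead[js], length, 0L) >= 4]
  if (length(js) < 3) return(na_out)
  C1 <- vapply(js, function(j) mean(log(lead[[j]])), 0)
  C2 <- vapply(js, function(j) {
    lg <- log(lead[[j]]); mean(lg^2) - mean(lg)^2
  }, 0)
  nj <- vapply(js, function(j) length(lead[[j]]), 0L)
  xj <- js * log(2)
  structure(list(c1 = wls_slope(xj, C1, nj),
                 c2 = wls_slope(xj, C2, nj),
                 scale_range = c(js[1], js[length(js)]),
                 n_leaders = nj),
            class = "log_cumulants")
}

wls_slope <- function(x, y, w) {
  xm <- sum(w * x) / sum(w); ym <- sum(w * y) / sum(w)
  sum(w * (x - xm) * (y - ym)) / sum(w * (x - xm)^2)
}

#' @export
print.log_cumulants <- function(x, ...) {
  cat(sprintf("<log_cumulants> c1=%.4g c2=%.4g over octaves %s-%s\n",
              x$c1, x$c2, x$scale_range[1], x$scale_range[2]))
  invisible(x)
}

#' EEG delta-band instantaneous power
#'
#' Power in the delta band (0.5-4] Hz per time sample, via the
#' analytic-Morlet CWT (squared magnitudes summed over in-band scales).
#'
#' @param x one EEG channel, numeric vector (band-pass filtered).
#' @param rate sampling rate, Hz (>= 64).
#' @param voices voices per octave.
#' @return list of class `"delta_power_series"`: `power` (length of `x`),
#'   `coi_excl` logical, `rate`.
#' @export
delta_power <- function(x, rate = 256, voices = 12) {
  if (rate < 64) stop("delta-band analysis needs rate >= 64 Hz")
  if (length(x) < 4 * rate) stop("signal too short for delta-band analysis")
  sp <- cwt_band_power(uniform_series(x, rate), bands = list(delta = c(0.5, 4)),
                       voices = voices)
  structure(list(power = as.numeric(sp$power[, "delta"]),
                 coi_excl = as.logical(sp$coi_excl[, "delta"]),
                 rate = rate),
            class = "delta_power_series")
}

#' Epoch mean and SD of an EEG channel or power series
#'
#' @param x numeric vector starting at time `t_start`.
#' @param rate sampling rate, Hz.
#' @param epoch `c(t0, t1)`, half-open.
#' @param t_start time of the first sample.
#' @return `c(mu, sd)` (NA for empty epochs).
#' @export
eeg_epoch_stats <- function(x, rate, epoch, t_start = 0) {
  temporal_stats(slice_values(x, rate, t_start, epoch[1], epoch[2]))
}

# Block-mean decimation by an integer factor.
decimate_mean <- function(x, factor) {
  n <- floor(length(x) / factor)
  if (n < 1) return(numeric(0))
  colMeans(matrix(x[seq_len(n * factor)], nrow = factor))
}

#' Multifractal EEG features of one event
#'
#' For each channel and for the pre and post epochs (the during epoch is too
#' short for fractal estimation): `c1` and `c2` of the band-passed channel and
#' of its delta-power envelope (decimated to `envelope_rate` Hz).
#' Too-short epochs yield missing values.
#'
#' @param eeg_filt 8 x n band-passed EEG matrix.
#' @param rate EEG rate, Hz.
#' @param epochs an `"epoch_set"` from [segment_epochs()].
#' @param delta list of per-channel [delta_power()] results (same time base;
#'   may be at a decimated rate), or `NULL` to compute from `eeg_filt`.
#' @param envelope_rate rate of the decimated power envelope (default 8 Hz).
#' @return named numeric vector: `eeg_<ch>__c1_raw__<epoch>` etc.
#' @export
eeg_fractal_features <- function(eeg_filt, rate, epochs, delta = NULL,
                                 envelope_rate = 8) {
  out <- numeric(0)
  for (ch in seq_len(nrow(eeg_filt))) {
    chname <- rownames(eeg_filt)[ch]
    dp <- if (is.null(delta)) delta_power(eeg_filt[ch, ], rate)
          else delta[[ch]]
    fac <- max(1L, round(dp$rate / envelope_rate))
    for (ep in c("pre", "post")) {
      sl <- epochs[[ep]]
      raw <- slice_values(eeg_filt[ch, ], rate, 0, sl[1], sl[2])
      env <- decimate_mean(slice_values(dp$power, dp$rate, 0, sl[1], sl[2]), fac)
      lc_raw <- log_cumulants(raw, rate)
      lc_env <- log_cumulants(env, envelope_rate)
      v <- c(lc_raw$c1, lc_raw$c2, lc_env$c1, lc_env$c2)
      names(v) <- sprintf("eeg_%s__%s__%s", chname,
                          c("c1_raw", "c2_raw", "c1_delta", "c2_delta"), ep)
      out <- c(out, v)
    }
  }
  out
}
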