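#' Mean and sample SD of a series
#'
#' @param x numeric vector.
#' @return `c(mu, sd)`; both `NA` for fewer than 2 finite samples.
#' @export
temporal_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(c(mu = NA_real_, sd = NA_real_))
  c(mu = mean(x), sd = sd(x))
}

#' Resample a tachogram or SpO2 series onto a uniform grid
#'
#' Linear interpolation of RR-as-a-function-of-time (value = RR interval at
#' its beat time) or of a 1-Hz SpO2 series onto a uniform grid, default 8 Hz.
#' Values at original grid points are preserved exactly.
#'
#' @param x a [tachogram()] or a [uniform_series()].
#' @param rate target rate, Hz (default 8).
#' @param t0,t1 optional time span; defaults to the input span.
#' @return a [uniform_series()].
#' @export
resample_uniform <- function(x, rate = 8, t0 = NULL, t1 = NULL) {
  if (inherits(x, "tachogram")) {
    tx <- x$beat_times; vx <- x$rr
  } else if (inherits(x, "uniform_series")) {
    tx <- series_times(x); vx <- x$values
  } else if (is.numeric(x)) {
    tx <- seq_along(x) - 1; vx <- x
  } else stop("cannot resample this input")
  if (length(vx) < 2) stop("need at least 2 samples to resample")
  if (is.null(t0)) t0 <- tx[1]
  if (is.null(t1)) t1 <- tx[length(tx)]
  grid <- seq(t0, t1, by = 1 / rate)
  vals <- approx(tx, vx, xout = grid, rule = 2)$y
  uniform_series(vals, rate = rate, t0 = t0)
}

#' Epoch statistics of spectral band-power series
#'
#' Mean and SD of HF, LF, HFnu = HF/(LF+HF) and LFHF = LF/HF over the in-epoch
#' samples that lie outside the cone of influence.
#'
#' @param spectral a `spectral_series` from [cwt_band_power()] with bands
#'   `LF` and `HF`.
#' @param epoch `c(t0, t1)`, half-open.
#' @return named vector of 8 values (`NA` when no valid samples).
#' @export
spectral_epoch_features <- function(spectral, epoch) {
  tt <- spectral$t0 + (seq_len(nrow(spectral$power)) - 1) / spectral$rate
  inwin <- tt >= epoch[1] & tt < epoch[2]
  ok <- inwin & !spectral$coi_excl[, "LF"] & !spectral$coi_excl[, "HF"]
  out <- rep(NA_real_, 8)
  names(out) <- c("mu_hf", "sd_hf", "mu_lf", "sd_lf",
                  "mu_hfnu", "sd_hfnu", "mu_lfhf", "sd_lfhf")
  if (sum(ok) < 2) return(out)
  hf <- spectral$power[ok, "HF"]; lf <- spectral$power[ok, "LF"]
  tot <- lf + hf
  hfnu <- ifelse(tot > 0, hf / tot, NA)
  lfhf <- ifelse(hf > 0, lf / hf, NA)
  c(temporal_stats(hf), temporal_stats(lf),
    temporal_stats(hfnu), temporal_stats(lfhf)) -> v
  out[] <- v
  out
}

#' First zero crossing of the autocorrelation function
#'
#' Smallest positive integer lag at which the sample autocorrelation is
#' non-positive.  When no crossing occurs within n/2 lags, n/2 is returned
#' with a `flagged` attribute.
#'
#' @param x numeric vector (>= 16 samples, non-constant).
#' @return integer lag in samples.
#' @export
acf_first_zero <- function(x) {
  stopifnot(length(x) >= 16)
  if (sd(x) == 0) stop("constant series has no autocorrelation zero")
  n <- length(x)
  max_lag <- floor(n / 2)
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf[-1]
  hit <- which(a <= 0)
  if (!length(hit)) return(structure(max_lag, flagged = TRUE))
  as.integer(hit[1])
}

#' Poincare-plot descriptors
#'
#' Embeds the series as `X = [x(t), x(t + tau)]` with `tau` the first zero of
#' the autocorrelation, and summarizes the cloud by the singular values of the
#' column-centred matrix scaled by `1/sqrt(n-1)` (SD2 = major axis, SD1 =
#' minor axis) plus the uncentred column means (centroids Cx, Cy).
#'
#' @param x numeric vector (>= 16 samples).
#' @param tau optional lag override, samples.
#' @return list of class `"poincare"`: `tau`, `SD1`, `SD2`, `Cx`, `Cy`.
#' @export
poincare_features <- function(x, tau = NULL) {
  if (length(x) < 16 || any(!is.finite(x))) {
    return(structure(list(tau = NA, SD1 = NA_real_, SD2 = NA_real_,
                          Cx = NA_real_, Cy = NA_real_), class = "poincare"))
  }
  if (sd(x) == 0) {
    return(structure(list(tau = 1L, SD1 = 0, SD2 = 0, Cx = x[1], Cy = x[1]),
                     class = "poincare"))
  }
  if (is.null(tau)) tau <- as.integer(acf_first_zero(x))
  tau <- max(1L, min(tau, length(x) - 8L))
  n <- length(x) - tau
  X <- cbind(x[1:n], x[(tau + 1):(tau + n)])
  Cx <- mean(X[, 1]); Cy <- mean(X[, 2])
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d / sqrt(n - 1)
  structure(list(tau = tau, SD1 = min(sv), SD2 = max(sv), Cx = Cx, Cy = Cy),
            class = "poincare")
}

#' @export
print.poincare <- function(x, ...) {
  cat(sprintf("<poincare> tau=%s SD1=%.4g SD2=%.4g Cx=%.4g Cy=%.4g\n",
              x$tau, x$SD1, x$SD2, x$Cx, x$Cy))
  invisible(x)
}

#' Phase-rectified signal averaging
#'
#' Anchors are samples where the mean of the following `T` seconds is lower
#' (direction "down") or higher ("up") than the mean of the preceding `T`
#' seconds.  Fragments of 120 s centred on each anchor (fragments crossing the
#' series edge are dropped) are aligned and averaged; the profile is
#' summarized by the ordinary-least-squares slope of the whole curve
#' (`slope_ov`) and of the `[anchor, anchor + T]` stretch (`slope_ap`).
#'
#' @param series a [uniform_series()] covering at least 360 s.
#' @param T_s anchor window parameter, seconds.
#' @param direction `"down"` or `"up"`.
#' @return object of class `"prsa_profile"`: `curve` (length
#'   `120 * rate + 1`), `n_anchors`, `slope_ov`, `slope_ap`, `T_s`,
#'   `direction`, `rate`; a flagged all-NA profile when there are no anchors.
#' @export
prsa <- function(series, T_s, direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(inherits(series, "uniform_series"))
  x <- series$values
  rate <- series$rate
  if (length(x) / rate < 360) stop("PRSA needs at least 360 s of signal")
  Tn <- max(1L, as.integer(round(T_s * rate)))
  half <- as.integer(round(60 * rate))
  n <- length(x)
  cs <- c(0, cumsum(x))
  # mean over [i, i+Tn) and [i-Tn, i)
  idx <- seq_len(n)
  fwd <- rep(NA_real_, n); bwd <- rep(NA_real_, n)
  ok_f <- idx + Tn - 1 <= n
  fwd[ok_f] <- (cs[idx[ok_f] + Tn] - cs[idx[ok_f]]) / Tn
  ok_b <- idx - Tn >= 1
  bwd[ok_b] <- (cs[idx[ok_b]] - cs[idx[ok_b] - Tn]) / Tn
  cmp <- if (direction == "down") fwd < bwd else fwd > bwd
  anchors <- which(!is.na(cmp) & cmp & idx - half >= 1 & idx + half <= n)
  L <- 2L * half + 1L
  if (!length(anchors)) {
    return(structure(list(curve = rep(NA_real_, L), n_anchors = 0L,
                          slope_ov = NA_real_, slope_ap = NA_real_,
                          T_s = T_s, direction = direction, rate = rate,
                          flagged = TRUE),
                     class = "prsa_profile"))
  }
  frag_idx <- outer(-half:half, anchors, `+`)
  curve <- rowMeans(matrix(x[frag_idx], nrow = L))
  tt <- (-half:half) / rate
  slope_ov <- ols_slope(tt, curve)
  ap <- which(tt >= 0 & tt <= T_s)
  slope_ap <- if (length(ap) >= 2) ols_slope(tt[ap], curve[ap]) else NA_real_
  structure(list(curve = curve, n_anchors = length(anchors),
                 slope_ov = slope_ov, slope_ap = slope_ap,
                 T_s = T_s, direction = direction, rate = rate,
                 flagged = FALSE),
            class = "prsa_profile")
}

ols_slope <- function(t, y) {
  t <- t - mean(t)
  sum(t * (y - mean(y))) / sum(t^2)
}

#' @export
print.prsa_profile <- function(x, ...) {
  cat(sprintf("<prsa_profile> T=%g s (%s), %d anchors, slope_ov=%.4g, slope_ap=%.4g\n",
              x$T_s, x$direction, x$n_anchors, x$slope_ov, x$slope_ap))
  invisible(x)
}

#' @export
plot.prsa_profile <- function(x, ...) {
  tt <- (seq_along(x$curve) - 1) / x$rate - 60
  plot(tt, x$curve, type = "l", xlab = "time around anchor (s)",
       ylab = "averaged signal",
       main = sprintf("PRSA profile, T = %g s (%s)", x$T_s, x$direction), ...)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' PRSA slope feature set
#'
#' `(slope_ov, slope_ap)` for each anchor parameter in `T_list`, computed once
#' on the whole event window.
#'
#' @inheritParams prsa
#' @param T_list vector of anchor parameters, seconds.
#' @return named numeric vector of `2 * length(T_list)` values.
#' @export
prsa_feature_set <- function(series, T_list = c(1, 5, 10, 20, 50, 100),
                             direction = "down") {
  out <- numeric(0)
  for (T_s in T_list) {
    p <- prsa(series, T_s, direction)
    v <- c(p$slope_ov, p$slope_ap)
    names(v) <- sprintf(c("slope_ov_T%g", "slope_ap_T%g"), T_s)
    out <- c(out, v)
  }
  out
}
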