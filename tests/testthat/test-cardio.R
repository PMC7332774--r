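test_that("temporal stats equal the textbook formulas", {
  expect_equal(temporal_stats(c(1, 1, 1)), c(mu = 1, sd = 0))
  expect_equal(temporal_stats(c(0, 2)), c(mu = 1, sd = sqrt(2)))
  set.seed(2)
  x <- rnorm(257)
  st <- temporal_stats(x)
  expect_equal(st[["mu"]], sum(x) / length(x), tolerance = 1e-12)
  expect_equal(st[["sd"]], sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
               tolerance = 1e-12)
  expect_true(all(is.na(temporal_stats(c(1)))))
})

test_that("uniform resampling preserves nodes and recovers modulation", {
  rr <- rep(0.5, 100)
  tc <- tachogram(cumsum(rr), rr)
  u <- resample_uniform(tc, 8)
  expect_true(all(abs(u$values - 0.5) < 1e-12))
  # 1-Hz input points are preserved exactly on the 8-Hz grid
  set.seed(3); v <- cumsum(rnorm(60))
  u2 <- resample_uniform(v, 8)
  expect_equal(u2$values[seq(1, length(u2$values), by = 8)], v,
               tolerance = 1e-12)
  # sinusoidal RR modulation: dominant FFT bin at the modulation frequency
  tt <- seq(0, 400, by = 0.5)
  rr2 <- 0.5 + 0.05 * sin(2 * pi * 0.1 * tt[-1])
  tc2 <- tachogram(cumsum(rr2), rr2)
  u3 <- resample_uniform(tc2, 8)
  v3 <- u3$values - mean(u3$values)
  sp <- Mod(fft(v3))[2:(length(v3) %/% 2)]
  f <- (seq_along(sp)) * 8 / length(v3)
  expect_equal(f[which.max(sp)], 0.1, tolerance = 0.01)
})

test_that("band powers respond to in-band sinusoids and scale quadratically", {
  rate <- 8
  t <- (0:3071) / rate
  mk <- function(f) uniform_series(sin(2 * pi * f * t), rate)
  bands <- list(LF = c(0.08, 0.2), HF = c(0.2, 4))
  sp_lf <- cwt_band_power(mk(0.1), bands)
  ok <- !sp_lf$coi_excl[, "LF"] & !sp_lf$coi_excl[, "HF"]
  expect_gt(mean(sp_lf$power[ok, "LF"]), 10 * mean(sp_lf$power[ok, "HF"]))
  sp_hf <- cwt_band_power(mk(1), bands)
  ok <- !sp_hf$coi_excl[, "LF"] & !sp_hf$coi_excl[, "HF"]
  expect_gt(mean(sp_hf$power[ok, "HF"]), 10 * mean(sp_hf$power[ok, "LF"]))
  sp2 <- cwt_band_power(uniform_series(2 * sin(2 * pi * 1 * t), rate), bands)
  expect_equal(sp2$power[ok, "HF"], 4 * sp_hf$power[ok, "HF"], tolerance = 0.01)
  expect_error(cwt_band_power(mk(1), list(X = c(3, 10))), "Nyquist")
})

test_that("spectral epoch features equal a slice-then-stat oracle", {
  set.seed(8)
  x <- uniform_series(rnorm(2048), 8)
  sp <- cwt_band_power(x, list(LF = c(0.08, 0.2), HF = c(0.2, 4)))
  ep <- c(60, 180)
  v <- spectral_epoch_features(sp, ep)
  tt <- (seq_len(2048) - 1) / 8
  sel <- tt >= 60 & tt < 180 & !sp$coi_excl[, "LF"] & !sp$coi_excl[, "HF"]
  hf <- sp$power[sel, "HF"]; lf <- sp$power[sel, "LF"]
  expect_equal(v[["mu_hf"]], mean(hf), tolerance = 1e-12)
  expect_equal(v[["sd_lf"]], sd(lf), tolerance = 1e-12)
  expect_equal(v[["mu_hfnu"]], mean(hf / (hf + lf)), tolerance = 1e-12)
  expect_equal(v[["mu_lfhf"]], mean(lf / hf), tolerance = 1e-12)
  expect_true(all(v[c("mu_hfnu", "sd_hfnu")] >= 0))
  expect_true(v[["mu_hfnu"]] <= 1)
  # epoch with no valid samples -> missing
  expect_true(all(is.na(spectral_epoch_features(sp, c(0, 0.5)))))
})

test_that("ACF first zero matches known cases", {
  set.seed(21)
  lags <- replicate(40, acf_first_zero(rnorm(512)))
  # iid data: each lag is non-positive with probability 1/2, so the first
  # zero falls within the first three lags ~87% of the time
  expect_gt(mean(lags <= 3), 0.7)
  expect_lt(median(lags), 3)
  P <- 64
  x <- sin(2 * pi * (0:2047) / P)
  expect_equal(acf_first_zero(x), P / 4, tolerance = 1)
  expect_error(acf_first_zero(rep(1, 64)), "constant")
})

test_that("Poincare descriptors: constants, isotropy and energy identity", {
  p0 <- poincare_features(rep(3.5, 64))
  expect_equal(c(p0$SD1, p0$SD2), c(0, 0))
  expect_equal(c(p0$Cx, p0$Cy), c(3.5, 3.5))
  set.seed(5)
  g <- rnorm(4096)
  pg <- poincare_features(g)
  expect_equal(pg$SD1 / pg$SD2, 1, tolerance = 0.1)
  expect_equal(pg$SD1, 1, tolerance = 0.1)
  for (seed in 1:20) {
    set.seed(seed)
    x <- cumsum(rnorm(300)) + rnorm(300)
    p <- poincare_features(x)
    tau <- p$tau; n <- length(x) - tau
    X <- cbind(x[1:n], x[(tau + 1):(tau + n)])
    expect_gte(p$SD2, p$SD1)
    expect_equal(p$SD1^2 + p$SD2^2, var(X[, 1]) + var(X[, 2]),
                 tolerance = 1e-9)
  }
})

test_that("PRSA recovers ramp slopes and is symmetric under negation", {
  rate <- 8
  n <- 400 * rate
  a <- 0.03
  ramp_down <- uniform_series(-a * (0:(n - 1)) / rate, rate)
  p <- prsa(ramp_down, 10, "down")
  expect_gt(p$n_anchors, 0)
  expect_equal(p$slope_ov, -a, tolerance = 1e-6)
  expect_equal(p$slope_ap, -a, tolerance = 1e-6)
  # increasing ramp has no "down" anchors
  ramp_up <- uniform_series(a * (0:(n - 1)) / rate, rate)
  expect_equal(prsa(ramp_up, 10, "down")$n_anchors, 0)
  # down-profile of -x is the negated up-profile of x
  set.seed(12)
  x <- uniform_series(cumsum(rnorm(n)), rate)
  neg <- uniform_series(-x$values, rate)
  pd <- prsa(neg, 5, "down"); pu <- prsa(x, 5, "up")
  expect_equal(pd$curve, -pu$curve, tolerance = 1e-9)
  expect_equal(pd$slope_ov, -pu$slope_ov, tolerance = 1e-9)
  # white noise: overall slope consistent with zero
  slopes <- sapply(1:20, function(s) {
    set.seed(900 + s)
    prsa(uniform_series(rnorm(2^14), rate), 5, "down")$slope_ov
  })
  expect_lt(abs(mean(slopes)) , 3 * sd(slopes) / sqrt(length(slopes)))
  # feature-set arity and linearity in amplitude
  fs1 <- prsa_feature_set(x, c(1, 5, 10, 20, 50, 100), "down")
  expect_length(fs1, 12)
  x2 <- uniform_series(2 * x$values, rate)
  fs2 <- prsa_feature_set(x2, c(1, 5, 10, 20, 50, 100), "down")
  expect_equal(fs2, 2 * fs1, tolerance = 1e-9)
})
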