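test_that("mean RR equals the brute-force mean", {
  expect_equal(mean_rr(tachogram(cumsum(rep(0.5, 3)), rep(0.5, 3))), 0.5)
  expect_equal(mean_rr(tachogram(cumsum(c(0.4, 0.6)), c(0.4, 0.6))), 0.5)
  set.seed(4)
  rr <- 0.4 + 0.1 * runif(500)
  expect_equal(mean_rr(tachogram(cumsum(rr), rr)), sum(rr) / length(rr),
               tolerance = 1e-12)
})

test_that("bradycardia detector agrees with the brute-force run scan", {
  for (seed in 1:40) {
    tc <- random_tachogram(seed)
    got <- detect_bradycardias(tc)
    want <- oracle_brady_runs(tc$rr)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
      expect_equal(got$i_start, want[, 1], info = paste("seed", seed))
      expect_equal(got$i_end, want[, 2], info = paste("seed", seed))
    }
  }
})

test_that("sub-minimum-duration excursions are rejected", {
  rr <- rep(0.5, 800); rr[400:402] <- 0.9 # 2.7 s < 4 s
  expect_equal(nrow(detect_bradycardias(tachogram(cumsum(rr), rr))), 0)
  rr[400:405] <- 0.9 # 5.4 s
  b <- detect_bradycardias(tachogram(cumsum(rr), rr))
  expect_equal(nrow(b), 1)
  expect_gt(b$max_rr_s, 1.5 * mean(rr))
  expect_true(b$t_onset < b$t_peak & b$t_peak < b$t_offset)
  expect_gte(b$duration_s, 4)
})

test_that("desaturation detector finds injected dips at all thresholds", {
  expect_equal(nrow(detect_desaturations(rep(96, 600), 3)), 0)
  spo2 <- inject_desaturation(rep(96, 900), 450, 12, 40)
  for (thr in c(3, 5, 10)) {
    d <- detect_desaturations(spo2, thr)
    expect_equal(nrow(d), 1)
    expect_equal(d$depth_pct, 12, tolerance = 0.5)
  }
})

test_that("raising the threshold never increases hypoxic event counts", {
  for (seed in 1:25) {
    pair <- quick_cardio_pair(seed + 4000, duration = 900, n_events = 2,
                              depth_pct = runif(1, 4, 14))
    b <- detect_bradycardias(pair$tach)
    counts <- sapply(c(3, 5, 10), function(thr) {
      nrow(pair_events(b, detect_desaturations(pair$spo2, thr)))
    })
    expect_true(all(diff(counts) <= 0), info = paste("seed", seed))
  }
})

test_that("pairing matches interval intersection with nearest-nadir ties", {
  brady <- data.frame(t_onset = 600, t_peak = 605, t_offset = 612,
                      max_rr_s = 0.9, duration_s = 12, i_start = 1, i_end = 5)
  desat <- data.frame(t_onset = 600, t_nadir = 610, t_offset = 640,
                      baseline_pct = 96, nadir_pct = 86, depth_pct = 10)
  expect_equal(nrow(pair_events(brady, desat)), 1)
  far <- transform(desat, t_onset = 800, t_nadir = 810, t_offset = 840)
  expect_equal(nrow(pair_events(brady, far)), 0)
  # two bradycardias flank one desaturation: only the nearer pairs
  b2 <- rbind(brady, transform(brady, t_onset = 660, t_peak = 665, t_offset = 672))
  d1 <- transform(desat, t_onset = 630, t_nadir = 655, t_offset = 680)
  p <- pair_events(b2, d1)
  expect_equal(nrow(p), 1)
  expect_equal(p$t_peak, 665)
})

test_that("epochs partition the window without overlap", {
  cfg <- pipeline_config()
  ev <- data.frame(t_onset = 600, t_peak = 606, t_offset = 615,
                   desat_t_onset = 598, desat_t_offset = 640)
  ep <- segment_epochs(ev, record_span = 1200, config = cfg)
  expect_equal(ep$window, c(426, 786))
  expect_equal(ep$pre[2], ep$during[1])
  expect_equal(ep$during[2], ep$post[1])
  expect_equal(diff(ep$pre) + diff(ep$during) + diff(ep$post), 360)
  expect_false(ep$truncated)
  # event near the record start: truncated and flagged
  ev2 <- transform(ev, t_onset = 55, t_peak = 60, t_offset = 70,
                   desat_t_onset = 50, desat_t_offset = 90)
  ep2 <- segment_epochs(ev2, record_span = 1200, config = cfg)
  expect_true(ep2$truncated)
  expect_equal(ep2$window[1], 0)
  # random events: epochs stay ordered and inside the window
  set.seed(11)
  for (k in 1:200) {
    tp <- runif(1, 0, 1200); on <- tp - runif(1, 1, 30); off <- tp + runif(1, 1, 60)
    evk <- data.frame(t_onset = on, t_peak = tp, t_offset = off,
                      desat_t_onset = on - 5, desat_t_offset = off + 10)
    epk <- segment_epochs(evk, 1200, cfg)
    expect_true(epk$pre[1] <= epk$pre[2] && epk$pre[2] <= epk$during[2] &&
                  epk$during[2] <= epk$post[2])
    expect_gte(epk$window[1], 0); expect_lte(epk$window[2], 1200)
  }
})

test_that("EEG band-pass attenuates out-of-band and keeps in-band sinusoids", {
  rate <- 256
  t <- (0:(30 * rate - 1)) / rate
  lo <- sin(2 * pi * 0.1 * t)
  mid <- sin(2 * pi * 10 * t)
  f_lo <- preprocess_eeg(lo, rate)
  f_mid <- preprocess_eeg(mid, rate)
  core <- (5 * rate):(25 * rate)
  amp <- function(x) sqrt(mean(x[core]^2)) * sqrt(2)
  expect_lt(amp(f_lo) / amp(lo), 10^(-20 / 20)) # > 20 dB down
  expect_equal(amp(f_mid), 1, tolerance = 0.05)
  # near-idempotence in the passband
  f2 <- preprocess_eeg(f_mid, rate)
  expect_equal(amp(f2), amp(f_mid), tolerance = 0.05)
  expect_error(preprocess_eeg(mid, 30), "40")
})
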