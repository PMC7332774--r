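test_that("fractional generator is seeded and H=0.5 is white", {
  s1 <- generate_fractional_signal(2048, 0.5, seed = 9)
  s2 <- generate_fractional_signal(2048, 0.5, seed = 9)
  s3 <- generate_fractional_signal(2048, 0.5, seed = 10)
  expect_identical(s1$values, s2$values)
  expect_false(identical(s1$values, s3$values))
  a <- stats::acf(s1$values, lag.max = 5, plot = FALSE)$acf[-1]
  expect_lt(max(abs(a)), 0.08)
  expect_error(generate_fractional_signal(2048, 1.2, seed = 1), "hurst")
})

test_that("bradycardia injection matches its analytic construction", {
  rr <- rep(0.42, 3000)
  tc <- tachogram(cumsum(rr), rr)
  tc2 <- inject_bradycardia(tc, 300, 2.0, 8)
  win <- tc2$beat_times > 280 & tc2$beat_times < 320
  expect_equal(max(tc2$rr[win]), 0.84, tolerance = 0.017)
  # total duration grows by the profile's added RR mass:
  # integral of (d-1)*raised_cosine over support 2*dur = (d-1)*dur
  added <- sum(tc2$rr) - sum(tc$rr)
  expect_equal(added, (2.0 - 1) * 8, tolerance = 0.1)
  # depth 1.2 never crosses the 1.5x detection factor
  tc3 <- inject_bradycardia(tc, 600, 1.2, 8)
  expect_lt(max(tc3$rr), 1.5 * mean(tc3$rr))
  expect_equal(nrow(detect_bradycardias(tc3)), 0)
  expect_error(inject_bradycardia(tc2, 303, 2, 8), "overlap")
})

test_that("desaturation injection matches construction and identity at 0", {
  spo2 <- rep(96, 900)
  s2 <- inject_desaturation(spo2, 450, 12, 30)
  expect_equal(min(s2), 84, tolerance = 0.5)
  expect_identical(inject_desaturation(spo2, 450, 0, 30), spo2)
  d <- detect_desaturations(s2, 10)
  expect_equal(nrow(d), 1)
  # shallow dip is invisible at a 10% threshold
  s3 <- inject_desaturation(spo2, 450, 4, 30)
  expect_equal(nrow(detect_desaturations(s3, 10)), 0)
  expect_error(inject_desaturation(s2, 455, 5, 20), "overlap")
})

test_that("cohort layout: stressed half, deterministic, seed-sensitive", {
  cs <- cohort_spec(n_subjects = 4, groups = "5days", record_duration_s = 420,
                    events_mean = 1, rng_seed = 5)
  co1 <- generate_cohort(cs)
  expect_length(co1, 4)
  expect_equal(sum(vapply(co1, `[[`, TRUE, "stress_label")), 2)
  co2 <- generate_cohort(cs)
  expect_equal(co1[[1]]$eeg[1, 1:50], co2[[1]]$eeg[1, 1:50])
  co3 <- generate_cohort(cs, seed = 6)
  expect_false(identical(co1[[1]]$eeg[1, 1:50], co3[[1]]$eeg[1, 1:50]))
})

test_that("null effect spec makes the stressed flag inert", {
  cs <- cohort_spec(n_subjects = 2, groups = "34weeks", record_duration_s = 420,
                    events_mean = 1, rng_seed = 7)
  r0 <- generate_subject(cs, null_effects(), FALSE, "34weeks", seed = 77)
  r1 <- generate_subject(cs, null_effects(), TRUE, "34weeks", seed = 77)
  expect_identical(r0$eeg, r1$eeg)
  expect_identical(r0$tachogram$rr, r1$tachogram$rr)
  expect_identical(r0$spo2, r1$spo2)
  expect_false(r0$stress_label); expect_true(r1$stress_label)
})

test_that("stress shifts deepen detected desaturations by the injected amount", {
  depths <- function(stressed) {
    unlist(lapply(1:12, function(k) {
      rec <- quick_record(800 + k, stressed = stressed, duration = 720,
                         events_mean = 2)
      detect_desaturations(rec$spo2, 3)$depth_pct
    }))
  }
  d0 <- depths(FALSE); d1 <- depths(TRUE)
  expect_gt(length(d0), 5); expect_gt(length(d1), 5)
  expect_equal(mean(d1) - mean(d0), 4, tolerance = 1.6)
})

test_that("injected well-separated bradycardias are all detected", {
  pair <- quick_cardio_pair(606, duration = 1200, n_events = 3)
  b <- detect_bradycardias(pair$tach)
  expect_equal(nrow(b), 3)
  expect_equal(sort(b$t_peak), pair$peaks, tolerance = 2)
})
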