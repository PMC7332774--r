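#' Stress effect sizes for the synthetic cohort
#'
#' Controls how records of stressed subjects differ from controls, mirroring
#' the contrasts the analysis is meant to recover: deeper desaturations,
#' higher EEG regularity (first log-cumulant), stronger EEG–heart coupling in
#' the group's coherence band and, in the PSG group, more high-frequency HRV
#' power.  With all shifts zero the stressed flag has no effect on the
#' generative process (null cohort).
#'
#' @param desat_depth_shift_pct extra desaturation depth under stress,
#'   percentage points (default +4).
#' @param eeg_hurst_shift increase of the EEG background Hurst exponent under
#'   stress (default +0.15).
#' @param coupling_shift increase of the EEG-RR band-coherence mixing weight
#'   under stress (default +0.2).
#' @param hf_power_shift relative increase of the HF RR modulation amplitude
#'   under stress, PSG group only (default +0.5).
#' @return object of class `"effect_spec"`.
#' @export
effect_spec <- function(desat_depth_shift_pct = 4,
                        eeg_hurst_shift = 0.15,
                        coupling_shift = 0.2,
                        hf_power_shift = 0.5) {
  stopifnot(is.finite(desat_depth_shift_pct), is.finite(eeg_hurst_shift),
            is.finite(coupling_shift), is.finite(hf_power_shift))
  structure(list(desat_depth_shift_pct = desat_depth_shift_pct,
                 eeg_hurst_shift = eeg_hurst_shift,
                 coupling_shift = coupling_shift,
                 hf_power_shift = hf_power_shift),
            class = "effect_spec")
}

#' Null effects: all shifts zero
#' @return an [effect_spec()] with every shift set to 0.
#' @export
null_effects <- function() effect_spec(0, 0, 0, 0)

#' Synthetic cohort layout
#'
#' @param n_subjects subjects per monitoring group (>= 2; half are labelled
#'   stressed, rounding down for odd n).
#' @param groups monitoring groups to generate.
#' @param record_duration_s record length, seconds (default 3600).
#' @param events_mean mean of the per-subject Poisson event-count draw
#'   (default 8, truncated below at 1 and above at what the record can hold
#'   with events at least one full analysis window apart).
#' @param baseline_rr_s baseline RR interval, seconds (default 0.42).
#' @param baseline_spo2_pct baseline oxygen saturation, percent (default 96).
#' @param rng_seed master seed; per-subject seeds are derived from it.
#' @return object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 10, groups = MONITORING_GROUPS,
                        record_duration_s = 3600, events_mean = 8,
                        baseline_rr_s = 0.42, baseline_spo2_pct = 96,
                        rng_seed = 1L) {
  stopifnot(n_subjects >= 2, record_duration_s >= 360, events_mean > 0,
            baseline_rr_s > 0.2, baseline_rr_s < 1,
            baseline_spo2_pct > 50, baseline_spo2_pct <= 100,
            all(groups %in% MONITORING_GROUPS))
  structure(list(n_subjects = as.integer(n_subjects), groups = groups,
                 record_duration_s = record_duration_s,
                 events_mean = events_mean,
                 baseline_rr_s = baseline_rr_s,
                 baseline_spo2_pct = baseline_spo2_pct,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

# Internal generator constants (documented in the methods vignette).
SYNTH <- list(
  eeg_hurst_base = 0.6,      # background EEG regularity, controls
  eeg_bg_uv = 15,            # fractional background amplitude, microvolts
  eeg_delta_uv = 30,         # delta oscillation amplitude, microvolts
  env_depth = 0.45,          # delta amplitude-envelope modulation depth
  env_shared_w = 0.8,        # weight of the shared (coupled) envelope process
  coupling_base = 0.35,      # baseline RR-side mixing weight of the shared proc.
  rr_couple_amp = 0.012,     # relative RR modulation in the coupling band
  rr_lf_amp = 0.008,         # relative LF RR modulation (when distinct from above)
  rr_hf_amp = 0.008,         # relative HF (breathing band) RR modulation
  spo2_ar_sigma = 0.3,       # oximeter noise sd, percent
  spo2_ar_rho = 0.9,         # oximeter noise AR(1) coefficient
  desat_depth_mean = 8,      # baseline desaturation depth, percent
  desat_depth_sd = 2.5,
  desat_depth_min = 3.5,
  desat_dur_range = c(15, 45),   # seconds
  brady_depth_range = c(1.7, 2.5),
  brady_dur_range = c(6, 12),    # seconds (full width at half elongation)
  event_edge_pad = 30            # seconds beyond the analysis half window
)

raised_cosine <- function(t, t_peak, duration_s) {
  u <- (t - t_peak) / duration_s
  out <- numeric(length(t))
  inside <- abs(u) <= 0.5
  out[inside] <- 0.5 * (1 + cos(2 * pi * u[inside]))
  out
}

#' Inject a bradycardia into a tachogram
#'
#' Multiplies the RR intervals inside the event window by a raised-cosine
#' profile peaking at `depth_factor` and re-times all subsequent beats so that
#' beat-time differences stay consistent with the intervals.  `duration_s` is
#' the full width at half the peak elongation (the profile support is twice
#' that), so a `depth_factor = 2` event stays above a 1.5x detection factor
#' for about `duration_s` seconds.  The record's total duration grows by the
#' RR mass the profile adds.
#'
#' @param tach a [tachogram()].
#' @param t_peak event peak time, seconds.
#' @param depth_factor peak RR elongation factor (> 1).
#' @param duration_s event duration (full width at half elongation), seconds.
#' @return the modified tachogram; injected event windows are tracked so that
#'   overlapping injections raise an error.
#' @export
inject_bradycardia <- function(tach, t_peak, depth_factor, duration_s) {
  stopifnot(inherits(tach, "tachogram"), depth_factor > 1, duration_s > 0)
  t0 <- tach$beat_times[1] - tach$rr[1]
  t_end <- tach$beat_times[length(tach$beat_times)]
  if (t_peak - duration_s < t0 || t_peak + duration_s > t_end) {
    stop("bradycardia must lie inside the record")
  }
  prev <- attr(tach, "injected_events")
  win <- c(t_peak - duration_s, t_peak + duration_s)
  for (w in prev) {
    if (win[1] < w[2] && w[1] < win[2]) stop("bradycardia overlaps an existing event")
  }
  mid <- tach$beat_times - tach$rr / 2
  factor <- 1 + (depth_factor - 1) * raised_cosine(mid, t_peak, 2 * duration_s)
  rr_new <- tach$rr * factor
  out <- tachogram(t0 + cumsum(rr_new), rr_new)
  attr(out, "injected_events") <- c(prev, list(win))
  out
}

#' Inject a desaturation into an SpO2 series
#'
#' Subtracts a smooth raised-cosine dip of depth `depth_pct` centred at
#' `t_nadir`; values are clipped at 0.  `depth_pct = 0` is the identity.
#'
#' @param spo2 numeric vector at 1 Hz (sample i is time i-1 s).
#' @param t_nadir nadir time, seconds.
#' @param depth_pct dip depth below the local baseline, percentage points.
#' @param duration_s dip duration, seconds.
#' @return the modified series; overlapping injections raise an error.
#' @export
inject_desaturation <- function(spo2, t_nadir, depth_pct, duration_s) {
  stopifnot(depth_pct >= 0, duration_s > 0)
  tt <- seq_along(spo2) - 1
  if (depth_pct == 0) return(spo2)
  if (t_nadir - duration_s / 2 < 0 || t_nadir + duration_s / 2 > max(tt)) {
    stop("desaturation must lie inside the record")
  }
  prev <- attr(spo2, "injected_events")
  win <- c(t_nadir - duration_s / 2, t_nadir + duration_s / 2)
  for (w in prev) {
    if (win[1] < w[2] && w[1] < win[2]) stop("desaturation overlaps an existing event")
  }
  out <- pmax(spo2 - depth_pct * raised_cosine(tt, t_nadir, duration_s), 0)
  attr(out, "injected_events") <- c(prev, list(win))
  out
}

# Evenly spread event peaks with jitter, spacing >= 2*half_window.
place_events <- function(n_ev, duration_s, half_window) {
  pad <- half_window + SYNTH$event_edge_pad
  usable <- duration_s - 2 * pad
  if (usable < 0) stop("record too short to hold any event window")
  max_ev <- floor(usable / (2 * half_window)) + 1
  n_ev <- min(n_ev, max_ev)
  if (n_ev < 1) stop("record too short to hold any event window")
  if (n_ev == 1) {
    jit <- runif(1, -min(30, usable / 2), min(30, usable / 2))
    return(pad + usable / 2 + jit)
  }
  step <- usable / (n_ev - 1)
  jit_max <- max(0, min(30, (step - 2 * half_window) / 2))
  pad + (0:(n_ev - 1)) * step + runif(n_ev, -jit_max, jit_max)
}

#' Generate one synthetic subject
#'
#' Builds a [polygraphic_record()] with the statistical structure the analysis
#' assumes: EEG = fractional background plus a delta-band oscillation whose
#' amplitude envelope shares a band-limited process (at a 90-degree phase
#' offset) with an RR modulation in the group's coherence band; a tachogram
#' with LF/HF modulations and injected raised-cosine bradycardias; SpO2 with
#' slow AR(1) oximeter noise and desaturations co-timed with the bradycardias.
#' Stress shifts (see [effect_spec()]) are applied on top; the random-draw
#' sequence is identical for stressed and control subjects, so a null effect
#' spec yields statistically indistinguishable arms.
#'
#' @param cspec a [cohort_spec()].
#' @param espec an [effect_spec()].
#' @param stressed logical label.
#' @param group monitoring group.
#' @param seed integer seed.
#' @param subject_id id string.
#' @param config a [pipeline_config()] (window geometry and band map).
#' @return a [polygraphic_record()].
#' @export
generate_subject <- function(cspec, espec, stressed, group, seed,
                             subject_id = sprintf("S%04d", seed %% 10000L),
                             config = pipeline_config()) {
  stopifnot(inherits(cspec, "cohort_spec"), inherits(espec, "effect_spec"),
            group %in% MONITORING_GROUPS)
  set.seed(seed)
  dur <- cspec$record_duration_s
  half <- config$window_half_s
  rate8 <- config$resample_rate_hz
  band <- config$band_map[[group]]
  stressed <- isTRUE(stressed)

  # --- event plan -----------------------------------------------------------
  n_ev <- max(1L, rpois(1, cspec$events_mean))
  t_peaks <- place_events(n_ev, dur, half)
  n_ev <- length(t_peaks)
  brady_depth <- runif(n_ev, SYNTH$brady_depth_range[1], SYNTH$brady_depth_range[2])
  brady_dur <- runif(n_ev, SYNTH$brady_dur_range[1], SYNTH$brady_dur_range[2])
  desat_depth <- pmax(SYNTH$desat_depth_min,
                      rnorm(n_ev, SYNTH$desat_depth_mean, SYNTH$desat_depth_sd)) +
    (if (stressed) espec$desat_depth_shift_pct else 0)
  desat_dur <- runif(n_ev, SYNTH$desat_dur_range[1], SYNTH$desat_dur_range[2])
  desat_jit <- runif(n_ev, -3, 3)

  # --- shared coupling process ---------------------------------------------
  n8 <- ceiling(dur * rate8) + 1
  z <- rband_analytic(n8, rate8, band[1], band[2])
  c_mix <- min(0.95, SYNTH$coupling_base +
                 (if (stressed) espec$coupling_shift else 0))

  # --- tachogram ------------------------------------------------------------
  v_ind <- rband(n8, rate8, band[1], band[2])
  mod_couple <- c_mix * z$im + sqrt(1 - c_mix^2) * v_ind
  hf_amp <- SYNTH$rr_hf_amp *
    (1 + (if (stressed && group == "PSG") espec$hf_power_shift else 0))
  mod_hf <- rband(n8, rate8, 0.2, min(4, rate8 / 2))
  rr_mod <- SYNTH$rr_couple_amp * mod_couple + hf_amp * mod_hf
  if (band[2] <= 0.08) { # coupling band is VLF: add an independent LF term
    rr_mod <- rr_mod + SYNTH$rr_lf_amp * rband(n8, rate8, 0.08, 0.2)
  }
  rr_of_t <- function(t) {
    i <- pmin(n8, pmax(1L, as.integer(round(t * rate8)) + 1L))
    f <- 1
    for (k in seq_len(n_ev)) {
      f <- f * (1 + (brady_depth[k] - 1) * raised_cosine(t, t_peaks[k], 2 * brady_dur[k]))
    }
    cspec$baseline_rr_s * (1 + rr_mod[i]) * f
  }
  n_beats_max <- ceiling(dur / (cspec$baseline_rr_s * 0.9)) + 16
  beats <- numeric(n_beats_max); rrs <- numeric(n_beats_max)
  t <- 0; k <- 0L
  while (t < dur) {
    step <- rr_of_t(t)
    t <- t + step; k <- k + 1L
    beats[k] <- t; rrs[k] <- step
  }
  tach <- tachogram(beats[1:k], rrs[1:k])

  # --- SpO2 -----------------------------------------------------------------
  n1 <- floor(dur)
  ar <- as.numeric(stats::filter(
    rnorm(n1, 0, SYNTH$spo2_ar_sigma * sqrt(1 - SYNTH$spo2_ar_rho^2)),
    SYNTH$spo2_ar_rho, method = "recursive"))
  spo2 <- cspec$baseline_spo2_pct + ar
  tt1 <- seq_len(n1) - 1
  for (kk in seq_len(n_ev)) {
    spo2 <- spo2 - desat_depth[kk] *
      raised_cosine(tt1, t_peaks[kk] + desat_jit[kk], desat_dur[kk])
  }
  spo2 <- pmin(pmax(spo2, 0), 100)

  # --- EEG ------------------------------------------------------------------
  hurst <- min(0.95, SYNTH$eeg_hurst_base +
                 (if (stressed) espec$eeg_hurst_shift else 0))
  n_eeg <- ceiling(dur * 256)
  up <- ceiling(256 / rate8)
  env_shared <- rep(z$re, each = up)[1:n_eeg]
  eeg <- matrix(0, nrow = 8, ncol = n_eeg,
                dimnames = list(CANONICAL_CHANNELS, NULL))
  for (ch in 1:8) {
    bg <- rfgn(n_eeg, hurst)
    carrier <- rband(n_eeg, 256, 0.5, 4)
    env_own <- rep(rband(n8, rate8, band[1], band[2]), each = up)[1:n_eeg]
    env <- pmax(0.05, 1 + SYNTH$env_depth *
                  (SYNTH$env_shared_w * env_shared +
                     sqrt(1 - SYNTH$env_shared_w^2) * env_own))
    eeg[ch, ] <- SYNTH$eeg_bg_uv * bg + SYNTH$eeg_delta_uv * carrier * env
  }

  pma <- switch(group,
                `5days`   = rnorm(1, 32, 1.5),
                `34weeks` = rnorm(1, 34, 0.5),
                PSG       = rnorm(1, 38.5, 1))
  pma <- min(45, max(24, pma))

  polygraphic_record(
    subject_id = subject_id, eeg = eeg, eeg_rate = 256,
    tachogram = tach, spo2 = spo2,
    pma_weeks = pma, group = group, stress_label = stressed
  )
}

#' Generate a synthetic cohort
#'
#' Per monitoring group, generates `n_subjects` records of which the first
#' half (rounding down) are stressed; per-subject seeds are derived
#' deterministically from the master seed so cohorts are reproducible and
#' disjoint seeds give disjoint cohorts.
#'
#' @inheritParams generate_subject
#' @param seed master seed (defaults to `cspec$rng_seed`).
#' @return list of [polygraphic_record()]s.
#' @export
generate_cohort <- function(cspec, espec = effect_spec(), seed = cspec$rng_seed,
                            config = pipeline_config()) {
  stopifnot(inherits(cspec, "cohort_spec"))
  if (cspec$n_subjects < 2) stop("need at least 2 subjects per group")
  records <- list()
  for (gi in seq_along(cspec$groups)) {
    g <- cspec$groups[gi]
    n_str <- cspec$n_subjects %/% 2
    for (si in seq_len(cspec$n_subjects)) {
      sid <- sprintf("%s-S%02d", g, si)
      rec <- generate_subject(
        cspec, espec, stressed = si <= n_str, group = g,
        seed = derive_seed(seed, gi, si), subject_id = sid, config = config
      )
      records[[sid]] <- rec
    }
  }
  log_stage("simulate", groups = length(cspec$groups),
            subjects = length(records))
  records
}
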