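#' Pipeline configuration
#'
#' Collects every tunable of the event detector, the feature extractors, the
#' coupling-graph stage and the classifier in one validated list.  Defaults
#' follow the study protocol the pipeline implements: bradycardia = RR
#' elongation above `brady_factor` times the whole-record mean RR sustained for
#' at least `brady_min_dur_s` seconds; desaturations deeper than
#' `desat_threshold_pct` percent below a 60-s running-median baseline; analysis
#' windows of `2 * window_half_s` seconds centred on the bradycardia peak.
#'
#' @param desat_threshold_pct desaturation depth threshold, percent; the study
#'   protocol uses 3, 5 and 10.
#' @param brady_factor RR elongation factor relative to the whole-record mean
#'   RR (default 1.5).
#' @param brady_min_dur_s minimal summed RR duration of a supra-threshold run
#'   for it to count as a bradycardia (seconds, default 4).
#' @param window_half_s half width of the event analysis window (seconds,
#'   default 180, i.e. 3 min before and after the bradycardia peak).
#' @param prsa_T_list PRSA anchor-window parameters T, seconds.
#' @param band_map named list mapping monitoring group to the coherence band:
#'   `VLF = (0.033, 0.08]` Hz for the `5days` group, `LF = (0.08, 0.2]` Hz for
#'   `34weeks` and `PSG`.
#' @param n_surrogates number of AAFT surrogates per coupling test (default 19,
#'   giving a one-sided significance level of 1/20).
#' @param rng_seed master seed governing every stochastic stage.
#' @param ensemble_size ensemble sizes tried by the 10-fold cross-validation
#'   inside each training fold.
#' @param subspace_fraction each base learner sees at most
#'   `floor(n_train * subspace_fraction)` features (default 1/10).
#' @param correlation_cap maximal absolute pairwise Pearson correlation among
#'   retained features (default 0.9).
#' @param resample_rate_hz common uniform rate (Hz) for RR, SpO2 and EEG
#'   delta-power node series (default 8).
#' @param chart_rate_hz rate at which topological index charts are evaluated
#'   (default 1 Hz; the coherence smoothing width exceeds several seconds, so a
#'   finer chart grid carries no extra information).
#' @param voices_per_octave scale resolution of the analytic-Morlet grids
#'   used for band powers (default 12).
#' @param coherence_voices scale resolution of the coherence grid (default 6;
#'   with the 3-voice boxcar this smooths over half an octave, a standard
#'   resolution/variance balance for coherence estimation).
#' @param stationarity_factor,stationarity_beats the "return to stationarity"
#'   rule closing a bradycardia: first beat after the peak whose RR falls to
#'   `stationarity_factor` times the mean RR, sustained for
#'   `stationarity_beats` beats.
#' @param pair_before_s,pair_after_s pairing tolerance: a desaturation is
#'   paired with a bradycardia when their intervals intersect
#'   `[t_onset - pair_before_s, t_offset + pair_after_s]`.
#' @param n_sup_objective `"H+E"` (as printed in the redundancy objective) or
#'   `"H-E"`.
#' @param eeg_node `"delta_power"` (default) or `"delta_band"`: the EEG node
#'   series entering the coupling graph.
#' @param feature_groups which feature families to assemble: any of
#'   `"cardio"`, `"eeg"`, `"network"`.
#'
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(desat_threshold_pct = 3,
                            brady_factor = 1.5,
                            brady_min_dur_s = 4,
                            window_half_s = 180,
                            prsa_T_list = c(1, 5, 10, 20, 50, 100),
                            band_map = list(
                              `5days`   = c(0.033, 0.08),
                              `34weeks` = c(0.08, 0.2),
                              PSG       = c(0.08, 0.2)
                            ),
                            n_surrogates = 19,
                            rng_seed = 1L,
                            ensemble_size = c(15L, 30L, 60L),
                            subspace_fraction = 0.1,
                            correlation_cap = 0.9,
                            resample_rate_hz = 8,
                            chart_rate_hz = 1,
                            voices_per_octave = 12,
                            coherence_voices = 6,
                            stationarity_factor = 1.1,
                            stationarity_beats = 5L,
                            pair_before_s = 30,
                            pair_after_s = 60,
                            n_sup_objective = c("H+E", "H-E"),
                            eeg_node = c("delta_power", "delta_band"),
                            feature_groups = c("cardio", "eeg", "network")) {
  n_sup_objective <- match.arg(n_sup_objective)
  eeg_node <- match.arg(eeg_node)
  feature_groups <- match.arg(feature_groups, several.ok = TRUE)
  stopifnot(
    desat_threshold_pct > 0, brady_factor > 1, brady_min_dur_s > 0,
    window_half_s > 0, all(prsa_T_list > 0), n_surrogates >= 1,
    subspace_fraction > 0, subspace_fraction <= 1,
    correlation_cap > 0, correlation_cap <= 1,
    resample_rate_hz > 0, chart_rate_hz > 0, voices_per_octave >= 3,
    coherence_voices >= 3
  )
  for (b in band_map) {
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1] ||
        b[2] > resample_rate_hz / 2) {
      stop("each band in 'band_map' must be (lo, hi] with 0 < lo < hi <= rate/2")
    }
  }
  cfg <- list(
    desat_threshold_pct = desat_threshold_pct,
    brady_factor = brady_factor,
    brady_min_dur_s = brady_min_dur_s,
    window_half_s = window_half_s,
    prsa_T_list = prsa_T_list,
    band_map = band_map,
    n_surrogates = as.integer(n_surrogates),
    rng_seed = as.integer(rng_seed),
    ensemble_size = as.integer(ensemble_size),
    subspace_fraction = subspace_fraction,
    correlation_cap = correlation_cap,
    resample_rate_hz = resample_rate_hz,
    chart_rate_hz = chart_rate_hz,
    voices_per_octave = voices_per_octave,
    coherence_voices = coherence_voices,
    stationarity_factor = stationarity_factor,
    stationarity_beats = as.integer(stationarity_beats),
    pair_before_s = pair_before_s,
    pair_after_s = pair_after_s,
    n_sup_objective = n_sup_objective,
    eeg_node = eeg_node,
    feature_groups = feature_groups
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  bradycardia: RR > %.2f x mean RR for >= %g s\n",
              x$brady_factor, x$brady_min_dur_s))
  cat(sprintf("  desaturation threshold: %g %%\n", x$desat_threshold_pct))
  cat(sprintf("  window: +/- %g s around bradycardia peak\n", x$window_half_s))
  cat(sprintf("  surrogates per coupling test: %d\n", x$n_surrogates))
  cat(sprintf("  feature groups: %s\n", paste(x$feature_groups, collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$rng_seed))
  invisible(x)
}

# Deterministic per-stream sub-seed derivation: Weyl-type integer mixing kept
# inside the 32-bit range so set.seed() accepts it on any platform.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 2654435761) %% 2147483647
  }
  as.integer(h)
}

# One structured log line per pipeline stage.
log_stage <- function(stage, ...) {
  kv <- list(...)
  msg <- paste(sprintf("%s=%s", names(kv), vapply(kv, format, "")),
               collapse = " ")
  message(sprintf("[neostress] %s %s", stage, msg))
}
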