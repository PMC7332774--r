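#' @importFrom stats approx median sd var cor fft mvfft rnorm runif rpois
#'   quantile setNames lm coef predict qnorm complete.cases
#' @importFrom utils head tail read.csv write.csv
NULL

CANONICAL_CHANNELS <- c("Fp1", "Fp2", "C3", "C4", "T3", "T4", "O1", "O2")
MONITORING_GROUPS <- c("5days", "34weeks", "PSG")

#' RR tachogram
#'
#' A beat-interval series: strictly increasing beat times (seconds from record
#' start) with one RR interval per beat; `rr[i]` is the interval ending at
#' `beat_times[i]`, so consecutive beat-time differences equal the intervals.
#'
#' @param beat_times strictly increasing beat times (s).
#' @param rr RR intervals (s), same length, all positive.
#' @return object of class `"tachogram"` with fields `beat_times`, `rr` and
#'   the cached whole-record mean `mean_rr`.
#' @export
tachogram <- function(beat_times, rr) {
  stopifnot(length(beat_times) == length(rr), length(rr) >= 1)
  if (any(rr <= 0)) stop("RR intervals must be positive")
  if (any(diff(beat_times) <= 0)) stop("beat times must be strictly increasing")
  drift <- abs(diff(beat_times) - rr[-1])
  if (length(drift) && max(drift) > 1e-3) {
    stop("beat-time differences disagree with RR intervals by more than 1 ms")
  }
  structure(list(beat_times = as.numeric(beat_times),
                 rr = as.numeric(rr),
                 mean_rr = mean(rr)),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> %d beats over %.1f s, mean RR %.3f s\n",
              length(x$rr), diff(range(x$beat_times)), x$mean_rr))
  invisible(x)
}

#' Uniformly sampled series
#'
#' @param values numeric vector, finite.
#' @param rate sampling rate, Hz.
#' @param t0 time of the first sample, seconds.
#' @return object of class `"uniform_series"`.
#' @export
uniform_series <- function(values, rate, t0 = 0) {
  stopifnot(rate > 0)
  if (any(!is.finite(values))) stop("uniform series values must be finite")
  structure(list(values = as.numeric(values), rate = rate, t0 = t0),
            class = "uniform_series")
}

series_times <- function(s) s$t0 + (seq_along(s$values) - 1) / s$rate

# Half-open [t0, t1) slice of a uniform series; returns values.
slice_values <- function(values, rate, t_start, t0, t1) {
  i0 <- ceiling((t0 - t_start) * rate - 1e-9) + 1
  i1 <- ceiling((t1 - t_start) * rate - 1e-9)
  i0 <- max(i0, 1L); i1 <- min(i1, length(values))
  if (i1 < i0) return(numeric(0))
  values[i0:i1]
}

#' One subject's polygraphic record
#'
#' Bundles the three signal modalities of a monitoring session — 8 monopolar
#' EEG channels (microvolts, referenced to Cz), the RR tachogram and
#' 1-Hz pulse-oximetry SpO2 — with subject metadata: post-menstrual age,
#' monitoring group and the binary stress label (any non-zero pain score the
#' day before the recording).
#'
#' @param subject_id character id.
#' @param eeg 8 x n matrix, microvolts; rows ordered as `channel_names`.
#' @param channel_names 8 channel labels; must be a permutation of
#'   Fp1, Fp2, C3, C4, T3, T4, O1, O2 (rows are reordered canonically).
#' @param eeg_rate EEG sampling rate, Hz (default 256).
#' @param tachogram a [tachogram()].
#' @param spo2 SpO2 percent at 1 Hz (numeric vector or `uniform_series`).
#' @param pma_weeks post-menstrual age, weeks (24–45).
#' @param group monitoring group: `"5days"`, `"34weeks"` or `"PSG"`.
#' @param stress_label logical; `TRUE` when the pain score the previous day
#'   was non-zero.
#' @return object of class `"polygraphic_record"`.
#' @export
polygraphic_record <- function(subject_id, eeg, channel_names = CANONICAL_CHANNELS,
                               eeg_rate = 256, tachogram, spo2,
                               pma_weeks, group, stress_label) {
  stopifnot(is.matrix(eeg))
  if (nrow(eeg) != 8) {
    missing <- setdiff(CANONICAL_CHANNELS, channel_names)
    stop(sprintf("EEG must have 8 channels; missing: %s",
                 paste(missing, collapse = ", ")))
  }
  if (!setequal(channel_names, CANONICAL_CHANNELS)) {
    stop(sprintf("unexpected EEG channel labels; missing: %s",
                 paste(setdiff(CANONICAL_CHANNELS, channel_names),
                       collapse = ", ")))
  }
  eeg <- eeg[match(CANONICAL_CHANNELS, channel_names), , drop = FALSE]
  rownames(eeg) <- CANONICAL_CHANNELS
  if (!inherits(tachogram, "tachogram")) stop("'tachogram' must be a tachogram object")
  if (inherits(spo2, "uniform_series")) {
    if (abs(spo2$rate - 1) > 1e-9) stop("SpO2 must be sampled at 1 Hz")
    spo2 <- spo2$values
  }
  if (any(spo2 < 0 | spo2 > 100)) stop("SpO2 values must lie in [0, 100]")
  if (!group %in% MONITORING_GROUPS) {
    stop("group must be one of ", paste(MONITORING_GROUPS, collapse = ", "))
  }
  if (pma_weeks < 24 || pma_weeks > 45) stop("pma_weeks must lie in [24, 45]")
  span <- min(ncol(eeg) / eeg_rate, length(spo2),
              max(tachogram$beat_times))
  if (span < 360) stop("all signals must cover a common span of at least 6 min")
  structure(list(subject_id = as.character(subject_id),
                 eeg = eeg, channel_names = CANONICAL_CHANNELS,
                 eeg_rate = eeg_rate,
                 tachogram = tachogram, spo2 = as.numeric(spo2),
                 pma_weeks = pma_weeks, group = group,
                 stress_label = isTRUE(stress_label)),
            class = "polygraphic_record")
}

#' @export
print.polygraphic_record <- function(x, ...) {
  cat(sprintf("<polygraphic_record> subject %s (group %s, PMA %.1f wk, %s)\n",
              x$subject_id, x$group, x$pma_weeks,
              if (x$stress_label) "stressed" else "non-stressed"))
  cat(sprintf("  EEG: 8 x %d @ %g Hz | tachogram: %d beats | SpO2: %d s @ 1 Hz\n",
              ncol(x$eeg), x$eeg_rate, length(x$tachogram$rr), length(x$spo2)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CSV/JSON bundle IO.  A record bundle is a directory with
#   eeg.csv       time_s,Fp1,Fp2,C3,C4,T3,T4,O1,O2   (microvolts)
#   tachogram.csv beat_time_s,rr_s
#   spo2.csv      time_s,spo2_pct                    (1 Hz)
#   meta.json     {subject_id, pma_weeks, group, lps_prev_day}

fmt_num <- function(x) formatC(x, format = "g", digits = 15)

#' Write a record to a CSV/JSON bundle
#'
#' Writes `eeg.csv`, `tachogram.csv`, `spo2.csv` and `meta.json` into `path`.
#' Output is deterministic: two writes of the same record are byte-identical.
#'
#' @param record a [polygraphic_record()].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "polygraphic_record"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  n <- ncol(record$eeg)
  tt <- (seq_len(n) - 1) / record$eeg_rate
  eeg_df <- data.frame(time_s = fmt_num(tt))
  for (ch in record$channel_names) {
    eeg_df[[ch]] <- fmt_num(record$eeg[ch, ])
  }
  write.csv(eeg_df, file.path(path, "eeg.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(beat_time_s = fmt_num(record$tachogram$beat_times),
                       rr_s = fmt_num(record$tachogram$rr)),
            file.path(path, "tachogram.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(time_s = fmt_num(seq_along(record$spo2) - 1),
                       spo2_pct = fmt_num(record$spo2)),
            file.path(path, "spo2.csv"), row.names = FALSE, quote = FALSE)
  meta <- list(subject_id = record$subject_id,
               pma_weeks = record$pma_weeks,
               group = record$group,
               lps_prev_day = as.integer(record$stress_label))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "meta.json"))
  invisible(path)
}

#' Read a record from a CSV/JSON bundle
#'
#' Reads the bundle written by [write_record()]; channels are reordered to the
#' canonical montage and all validation of [polygraphic_record()] applies.
#' Only CSV bundles are supported.
#'
#' @param path bundle directory.
#' @param eeg_rate EEG sampling rate of the bundle, Hz.
#' @return a [polygraphic_record()].
#' @export
read_record <- function(path, eeg_rate = 256) {
  need <- c("eeg.csv", "tachogram.csv", "spo2.csv", "meta.json")
  miss <- need[!file.exists(file.path(path, need))]
  if (length(miss)) stop("bundle is missing: ", paste(miss, collapse = ", "))
  eeg_df <- read.csv(file.path(path, "eeg.csv"), check.names = FALSE)
  chans <- setdiff(names(eeg_df), "time_s")
  if (length(chans) >= 2) {
    dt <- diff(eeg_df$time_s[1:2])
    if (abs(dt - 1 / eeg_rate) > 1e-6) {
      stop(sprintf("EEG sampling rate mismatch: file step %.6g s, expected %.6g s",
                   dt, 1 / eeg_rate))
    }
  }
  eeg <- t(as.matrix(eeg_df[chans]))
  tach_df <- read.csv(file.path(path, "tachogram.csv"))
  if (any(diff(tach_df$beat_time_s) <= 0)) {
    stop("non-monotone beat times in tachogram.csv")
  }
  spo2_df <- read.csv(file.path(path, "spo2.csv"))
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  polygraphic_record(
    subject_id = meta$subject_id,
    eeg = eeg, channel_names = chans, eeg_rate = eeg_rate,
    tachogram = tachogram(tach_df$beat_time_s, tach_df$rr_s),
    spo2 = spo2_df$spo2_pct,
    pma_weeks = meta$pma_weeks, group = meta$group,
    stress_label = meta$lps_prev_day > 0
  )
}
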