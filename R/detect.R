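#' Mean RR of a tachogram
#'
#' Arithmetic mean of all RR intervals of the entire tachogram, including any
#' event beats (no artifact rejection beyond range clipping at construction).
#'
#' @param tach a [tachogram()].
#' @return mean RR, seconds.
#' @export
mean_rr <- function(tach) {
  stopifnot(inherits(tach, "tachogram"))
  if (length(tach$rr) < 2) stop("tachogram must contain at least 2 beats")
  mean(tach$rr)
}

# Interval i spans [beat_times[i] - rr[i], beat_times[i]].
rr_onsets <- function(tach) tach$beat_times - tach$rr

#' Detect bradycardias
#'
#' A bradycardia is a maximal run of beats whose RR interval exceeds
#' `brady_factor` times the whole-record mean RR, with summed RR duration of
#' at least `brady_min_dur_s` seconds.  Runs separated by fewer than 5
#' sub-threshold beats are merged.  The peak is the (earliest) maximal RR
#' interval; the offset is the "return to stationarity": the first beat after
#' the peak whose RR falls to `stationarity_factor` times the mean RR,
#' sustained for `stationarity_beats` beats.
#'
#' @param tach a [tachogram()].
#' @param config a [pipeline_config()].
#' @return data.frame with one row per event: `t_onset`, `t_peak`, `t_offset`,
#'   `max_rr_s`, `duration_s`, plus the beat index range `i_start`, `i_end`
#'   of the supra-threshold run.
#' @export
detect_bradycardias <- function(tach, config = pipeline_config()) {
  rrm <- mean_rr(tach)
  thr <- config$brady_factor * rrm
  above <- tach$rr > thr
  if (!any(above)) return(empty_brady_df())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < 5 sub-threshold beats
  if (nrow(runs) > 1) {
    keep_start <- runs$start[1]; merged <- list()
    cur <- runs[1, ]
    for (k in 2:nrow(runs)) {
      if (runs$start[k] - cur$end - 1 < 5) {
        cur$end <- runs$end[k]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- runs[k, ]
      }
    }
    merged[[length(merged) + 1]] <- cur
    runs <- do.call(rbind, merged)
  }
  onsets <- rr_onsets(tach)
  out <- lapply(seq_len(nrow(runs)), function(k) {
    i0 <- runs$start[k]; i1 <- runs$end[k]
    idx <- i0:i1
    if (sum(tach$rr[idx]) < config$brady_min_dur_s) return(NULL)
    imax <- idx[which.max(tach$rr[idx])]
    t_off <- stationarity_time(tach, imax, rrm, config)
    data.frame(t_onset = onsets[i0],
               t_peak = tach$beat_times[imax],
               t_offset = t_off,
               max_rr_s = tach$rr[imax],
               duration_s = t_off - onsets[i0],
               i_start = i0, i_end = i1)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_brady_df())
  # a stationarity tail never extends into the next event: cap the offset at
  # the following run's onset so events stay ordered and non-overlapping
  if (nrow(out) > 1) {
    for (k in 2:nrow(out)) {
      if (out$t_offset[k - 1] > out$t_onset[k]) {
        out$t_offset[k - 1] <- out$t_onset[k]
        out$duration_s[k - 1] <- out$t_offset[k - 1] - out$t_onset[k - 1]
      }
    }
  }
  rownames(out) <- NULL
  out
}

empty_brady_df <- function() {
  data.frame(t_onset = numeric(0), t_peak = numeric(0), t_offset = numeric(0),
             max_rr_s = numeric(0), duration_s = numeric(0),
             i_start = integer(0), i_end = integer(0))
}

# First beat after the peak with RR <= factor * mean sustained for >= n beats;
# returns the onset time of that beat's interval (fallback: last beat).
stationarity_time <- function(tach, i_peak, rrm, config) {
  thr <- config$stationarity_factor * rrm
  n <- length(tach$rr)
  need <- config$stationarity_beats
  j <- i_peak + 1L
  while (j <= n) {
    if (tach$rr[j] <= thr) {
      jj <- j
      while (jj <= n && tach$rr[jj] <= thr) jj <- jj + 1L
      if (jj - j >= need || jj > n) return(rr_onsets(tach)[j])
      j <- jj
    }
    j <- j + 1L
  }
  tach$beat_times[n]
}

#' Detect SpO2 desaturations
#'
#' The local baseline is the running median of the preceding 60 s.  An event
#' is a maximal contiguous region with SpO2 below `baseline_at_onset -
#' threshold`, extended outwards to where the signal re-crosses
#' `baseline_at_onset - threshold/2`; its depth is baseline-at-onset minus
#' the nadir.
#'
#' @param spo2 numeric vector, percent, 1 Hz (sample i is time i-1 s).
#' @param threshold_pct depth threshold, percent.
#' @param config a [pipeline_config()].
#' @return data.frame with `t_onset`, `t_nadir`, `t_offset`, `baseline_pct`,
#'   `nadir_pct`, `depth_pct`.
#' @export
detect_desaturations <- function(spo2, threshold_pct = NULL,
                                 config = pipeline_config()) {
  if (is.null(threshold_pct)) threshold_pct <- config$desat_threshold_pct
  n <- length(spo2)
  stopifnot(n >= 360)
  base <- trailing_median(spo2, 60L)
  below <- spo2 < base - threshold_pct
  if (!any(below)) return(empty_desat_df())
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  cores <- data.frame(start = starts[r$values], end = ends[r$values])
  out <- list(); last_end <- -Inf
  for (k in seq_len(nrow(cores))) {
    i0 <- cores$start[k]
    if (i0 <= last_end) next
    b0 <- base[i0]
    half <- b0 - threshold_pct / 2
    a <- i0
    while (a > 1 && spo2[a - 1] < half) a <- a - 1
    b <- cores$end[k]
    while (b < n && spo2[b + 1] < half) b <- b + 1
    nadir_i <- (a:b)[which.min(spo2[a:b])]
    out[[length(out) + 1]] <- data.frame(
      t_onset = a - 1, t_nadir = nadir_i - 1, t_offset = b - 1,
      baseline_pct = b0, nadir_pct = spo2[nadir_i],
      depth_pct = b0 - spo2[nadir_i])
    last_end <- b
  }
  if (!length(out)) return(empty_desat_df())
  do.call(rbind, out)
}

empty_desat_df <- function() {
  data.frame(t_onset = numeric(0), t_nadir = numeric(0), t_offset = numeric(0),
             baseline_pct = numeric(0), nadir_pct = numeric(0),
             depth_pct = numeric(0))
}

# Running median of the preceding `w` samples (expanding prefix early on).
trailing_median <- function(x, w) {
  n <- length(x)
  lagged <- c(NA, x[-n])
  out <- zoo::rollapplyr(lagged, width = w, FUN = median, na.rm = TRUE,
                         partial = TRUE, fill = NA)
  out[1] <- x[1]
  out
}

#' Pair bradycardias with desaturations into hypoxic events
#'
#' A desaturation is a candidate partner of a bradycardia when its interval
#' intersects `[t_onset - pair_before_s, t_offset + pair_after_s]`.  Candidate
#' pairs are assigned greedily by increasing nadir-to-peak distance, each
#' desaturation used at most once; unpaired bradycardias are dropped.
#'
#' @param bradys data.frame from [detect_bradycardias()].
#' @param desats data.frame from [detect_desaturations()].
#' @param config a [pipeline_config()].
#' @return data.frame with the bradycardia columns plus `desat_*` columns.
#' @export
pair_events <- function(bradys, desats, config = pipeline_config()) {
  if (nrow(bradys) == 0 || nrow(desats) == 0) return(empty_pair_df())
  cand <- list()
  for (b in seq_len(nrow(bradys))) {
    lo <- bradys$t_onset[b] - config$pair_before_s
    hi <- bradys$t_offset[b] + config$pair_after_s
    for (d in seq_len(nrow(desats))) {
      if (desats$t_onset[d] <= hi && desats$t_offset[d] >= lo) {
        cand[[length(cand) + 1]] <- c(b = b, d = d,
                                      dist = abs(desats$t_nadir[d] - bradys$t_peak[b]))
      }
    }
  }
  if (!length(cand)) return(empty_pair_df())
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, "dist"]), , drop = FALSE]
  used_b <- logical(nrow(bradys)); used_d <- logical(nrow(desats))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    b <- cand[k, "b"]; d <- cand[k, "d"]
    if (used_b[b] || used_d[d]) next
    used_b[b] <- TRUE; used_d[d] <- TRUE
    rows[[length(rows) + 1]] <- cbind(
      bradys[b, , drop = FALSE],
      setNames(desats[d, , drop = FALSE],
               paste0("desat_", names(desats))))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$t_peak), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_pair_df <- function() {
  cbind(empty_brady_df(),
        setNames(empty_desat_df(), paste0("desat_", names(empty_desat_df()))))
}

#' Epoch boundaries of a hypoxic event
#'
#' The analysis window is `[t_peak - window_half_s, t_peak + window_half_s]`,
#' truncated (and flagged) at record edges.  Epochs partition it half-open:
#' pre = window start to the bradycardia onset, during = onset to offset,
#' post = offset to window end.  SpO2-specific pre/post use the
#' desaturation's own onset/offset.
#'
#' @param event one row of [pair_events()] output.
#' @param record_span total record span, seconds (scalar), or a
#'   [polygraphic_record()].
#' @param config a [pipeline_config()].
#' @return list of class `"epoch_set"` with `window`, `pre`, `during`, `post`,
#'   `spo2_pre`, `spo2_during`, `spo2_post` (each `c(t0, t1)`), and
#'   `truncated` flag.
#' @export
segment_epochs <- function(event, record_span, config = pipeline_config()) {
  if (inherits(record_span, "polygraphic_record")) {
    record_span <- min(ncol(record_span$eeg) / record_span$eeg_rate,
                       length(record_span$spo2),
                       max(record_span$tachogram$beat_times))
  }
  w0 <- event$t_peak - config$window_half_s
  w1 <- event$t_peak + config$window_half_s
  truncated <- w0 < 0 || w1 > record_span
  w0 <- max(w0, 0); w1 <- min(w1, record_span)
  clip <- function(a, b) c(max(w0, min(a, w1)), max(w0, min(b, w1)))
  out <- list(
    window = c(w0, w1),
    pre = clip(w0, event$t_onset),
    during = clip(event$t_onset, event$t_offset),
    post = clip(event$t_offset, w1),
    spo2_pre = clip(w0, event$desat_t_onset),
    spo2_during = clip(event$desat_t_onset, event$desat_t_offset),
    spo2_post = clip(event$desat_t_offset, w1),
    truncated = truncated
  )
  class(out) <- "epoch_set"
  out
}

#' Band-pass filter EEG for analysis
#'
#' Zero-phase 1-20 Hz band-pass (4th-order Butterworth applied
#' forward-backward); length preserved.
#'
#' @param eeg channels x samples matrix (or a vector).
#' @param rate sampling rate, Hz (> 40).
#' @return filtered matrix/vector of the same shape.
#' @export
preprocess_eeg <- function(eeg, rate = 256) {
  if (rate <= 40) stop("EEG sampling rate must exceed 40 Hz")
  bf <- signal::butter(4, c(1, 20) / (rate / 2), type = "pass")
  filt1 <- function(x) as.numeric(signal::filtfilt(bf, x))
  if (is.matrix(eeg)) {
    out <- t(apply(eeg, 1, filt1))
    dimnames(out) <- dimnames(eeg)
    out
  } else {
    filt1(eeg)
  }
}

#' Detect and pair hypoxic events of one record
#'
#' Convenience wrapper: bradycardias, desaturations at the configured
#' threshold, pairing, and epoch segmentation.
#'
#' @param record a [polygraphic_record()].
#' @param config a [pipeline_config()].
#' @return data.frame of paired events with an `event_id` column; the epoch
#'   sets are attached as attribute `"epochs"` (a list).
#' @export
detect_events <- function(record, config = pipeline_config()) {
  bradys <- detect_bradycardias(record$tachogram, config)
  desats <- detect_desaturations(record$spo2, config$desat_threshold_pct, config)
  paired <- pair_events(bradys, desats, config)
  if (nrow(paired)) {
    paired$event_id <- sprintf("%s-E%02d", record$subject_id, seq_len(nrow(paired)))
    attr(paired, "epochs") <- lapply(seq_len(nrow(paired)), function(k) {
      segment_epochs(paired[k, ], record, config)
    })
  }
  paired
}
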