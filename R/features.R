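# Per-event feature extraction: cardiovascular, EEG and network families.

#' Feature registry
#'
#' Enumerates every feature the extractors can emit, with family tags
#' (`cardio`, `eeg`, `network`), epoch tags and log-transform flags (power
#' features are natural-log transformed at assembly).  Counts per family are
#' a property of this pipeline's accounting: means/SDs per epoch, PRSA slopes
#' and Poincare descriptors once per event window, fractal log-cumulants on
#' the pre/post epochs, topology indices per partition/epoch.
#'
#' @param config a [pipeline_config()].
#' @return data.frame: `name`, `family`, `epoch`, `log_transform`.
#' @export
feature_registry <- function(config = pipeline_config()) {
  rows <- list()
  add <- function(name, family, epoch, logt = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, family = family, epoch = epoch, log_transform = logt)
  }
  eps <- c("pre", "during", "post")
  for (ep in eps) {
    add(sprintf("rr__mu__%s", ep), "cardio", ep)
    add(sprintf("rr__sd__%s", ep), "cardio", ep)
    for (nm in c("mu_hf", "sd_hf", "mu_lf", "sd_lf"))
      add(sprintf("rr__%s__%s", nm, ep), "cardio", ep, logt = TRUE)
    for (nm in c("mu_hfnu", "sd_hfnu"))
      add(sprintf("rr__%s__%s", nm, ep), "cardio", ep)
    for (nm in c("mu_lfhf", "sd_lfhf"))
      add(sprintf("rr__%s__%s", nm, ep), "cardio", ep, logt = TRUE)
    add(sprintf("spo2__mu__%s", ep), "cardio", ep)
    add(sprintf("spo2__sd__%s", ep), "cardio", ep)
  }
  for (T_s in config$prsa_T_list) {
    for (sig in c("rr", "spo2")) {
      add(sprintf("%s__slope_ov_T%g__whole", sig, T_s), "cardio", "whole")
      add(sprintf("%s__slope_ap_T%g__whole", sig, T_s), "cardio", "whole")
    }
  }
  for (sig in c("rr", "spo2")) {
    for (nm in c("sd1", "sd2", "cx", "cy"))
      add(sprintf("%s__%s__whole", sig, nm), "cardio", "whole")
  }
  for (ch in CANONICAL_CHANNELS) {
    for (ep in eps) {
      add(sprintf("eeg_%s__mu__%s", ch, ep), "eeg", ep)
      add(sprintf("eeg_%s__sd__%s", ch, ep), "eeg", ep)
      add(sprintf("eeg_%s__mu_pdelta__%s", ch, ep), "eeg", ep, logt = TRUE)
      add(sprintf("eeg_%s__sd_pdelta__%s", ch, ep), "eeg", ep, logt = TRUE)
    }
    for (ep in c("pre", "post")) {
      for (nm in c("c1_raw", "c2_raw", "c1_delta", "c2_delta"))
        add(sprintf("eeg_%s__%s__%s", ch, nm, ep), "eeg", ep)
    }
  }
  for (p in names(GRAPH_PARTITIONS)) {
    for (ix in c("path_length", "efficiency", "clustering", "eccentricity", "n_sup")) {
      for (st in c("mu", "sd")) {
        for (ep in eps) {
          add(sprintf("net_%s__%s__%s__%s", p, ix, st, ep), "network", ep)
        }
      }
    }
  }
  do.call(rbind, rows)
}

# Beat-domain RR values inside a half-open epoch (by interval midpoint).
rr_in_epoch <- function(tach, epoch) {
  mid <- tach$beat_times - tach$rr / 2
  tach$rr[mid >= epoch[1] & mid < epoch[2]]
}

# SpO2 values (1 Hz) inside a half-open epoch.
spo2_in_epoch <- function(spo2, epoch) {
  slice_values(spo2, 1, 0, epoch[1], epoch[2])
}

# Cardiovascular + oximetry features of one event window.  The SpO2
# epoch-stat block is threshold-dependent (desaturation-anchored epochs) and
# is separated out so callers can cache the rest across thresholds.
cardio_window_features <- function(record, event, epochs, config) {
  out <- numeric(0)
  win <- epochs$window
  for (ep in c("pre", "during", "post")) {
    st <- temporal_stats(rr_in_epoch(record$tachogram, epochs[[ep]]))
    names(st) <- sprintf("rr__%s__%s", c("mu", "sd"), ep)
    out <- c(out, st)
  }
  rr_u <- resample_uniform(record$tachogram, config$resample_rate_hz,
                           t0 = win[1], t1 = win[2])
  sp <- cwt_band_power(rr_u, bands = list(LF = c(0.08, 0.2),
                                          HF = c(0.2, config$resample_rate_hz / 2)),
                       voices = config$voices_per_octave)
  for (ep in c("pre", "during", "post")) {
    v <- spectral_epoch_features(sp, epochs[[ep]])
    names(v) <- sprintf("rr__%s__%s", names(v), ep)
    out <- c(out, v)
  }
  pv <- prsa_feature_set(rr_u, config$prsa_T_list, direction = "up")
  names(pv) <- sprintf("rr__%s__whole", names(pv))
  out <- c(out, pv)
  spo2_u <- resample_uniform(record$spo2, config$resample_rate_hz,
                             t0 = win[1], t1 = win[2])
  pv <- prsa_feature_set(spo2_u, config$prsa_T_list, direction = "down")
  names(pv) <- sprintf("spo2__%s__whole", names(pv))
  out <- c(out, pv)
  pc <- poincare_features(rr_in_epoch(record$tachogram, win))
  v <- c(pc$SD1, pc$SD2, pc$Cx, pc$Cy)
  names(v) <- sprintf("rr__%s__whole", c("sd1", "sd2", "cx", "cy"))
  out <- c(out, v)
  pc <- poincare_features(spo2_in_epoch(record$spo2, win))
  v <- c(pc$SD1, pc$SD2, pc$Cx, pc$Cy)
  names(v) <- sprintf("spo2__%s__whole", c("sd1", "sd2", "cx", "cy"))
  c(out, v)
}

spo2_epoch_features <- function(record, epochs) {
  out <- numeric(0)
  for (ep in c("pre", "during", "post")) {
    st <- temporal_stats(spo2_in_epoch(record$spo2, epochs[[paste0("spo2_", ep)]]))
    names(st) <- sprintf("spo2__%s__%s", c("mu", "sd"), ep)
    out <- c(out, st)
  }
  out
}

# EEG features of one window: epoch stats of the filtered channels and their
# delta power, plus pre/post multifractal log-cumulants.  Returns the features
# and the per-channel delta-power series (reused as coupling-graph nodes).
# The delta-band CWT runs on 4x-decimated EEG (64 Hz): the band tops out at
# 4 Hz, so decimation is transparent in-band and cuts the transform cost.
eeg_window_features <- function(eeg_filt_win, rate, win, epochs, config) {
  out <- numeric(0)
  delta <- vector("list", 8)
  ds <- 4L
  rate_d <- rate / ds
  for (ch in 1:8) {
    xd <- decimate_mean(eeg_filt_win[ch, ], ds)
    dp <- delta_power(xd, rate_d, voices = config$voices_per_octave)
    delta[[ch]] <- dp
    chname <- rownames(eeg_filt_win)[ch]
    for (ep in c("pre", "during", "post")) {
      sl <- epochs[[ep]]
      st <- eeg_epoch_stats(eeg_filt_win[ch, ], rate, sl, t_start = win[1])
      names(st) <- sprintf("eeg_%s__%s__%s", chname, c("mu", "sd"), ep)
      pw <- dp$power
      pw[dp$coi_excl] <- NA
      stp <- eeg_epoch_stats(pw, rate_d, sl, t_start = win[1])
      names(stp) <- sprintf("eeg_%s__%s__%s", chname, c("mu_pdelta", "sd_pdelta"), ep)
      out <- c(out, st, stp)
    }
  }
  ep0 <- lapply(epochs, function(e) if (is.numeric(e)) e - win[1] else e)
  class(ep0) <- "epoch_set"
  fr <- eeg_fractal_features(eeg_filt_win, rate, ep0, delta = delta,
                             envelope_rate = config$resample_rate_hz)
  list(features = c(out, fr), delta = delta)
}

# Extract every feature family of one event.  `eeg_filt` is the band-passed
# full-record EEG; the window slice is cut here.
extract_event_features <- function(record, eeg_filt, event, epochs, config,
                                   event_seed) {
  win <- epochs$window
  feats <- numeric(0)
  if ("cardio" %in% config$feature_groups) {
    feats <- c(feats, cardio_window_features(record, event, epochs, config),
               spo2_epoch_features(record, epochs))
  }
  need_eeg <- "eeg" %in% config$feature_groups
  need_net <- "network" %in% config$feature_groups
  if (need_eeg || need_net) {
    rate <- record$eeg_rate
    i0 <- max(1L, floor(win[1] * rate) + 1L)
    i1 <- min(ncol(eeg_filt), floor(win[2] * rate))
    eeg_win <- eeg_filt[, i0:i1, drop = FALSE]
    ef <- eeg_window_features(eeg_win, rate, win, epochs, config)
    if (need_eeg) feats <- c(feats, ef$features)
    if (need_net) {
      rate8 <- config$resample_rate_hz
      n8 <- floor((win[2] - win[1]) * rate8)
      nodes <- matrix(0, n8, 10)
      for (ch in 1:8) {
        if (config$eeg_node == "delta_power") {
          env <- ef$delta[[ch]]$power
          fac <- round(ef$delta[[ch]]$rate / rate8)
        } else {
          env <- eeg_win[ch, ]
          fac <- round(rate / rate8)
        }
        nodes[, ch] <- decimate_mean(env, fac)[seq_len(n8)]
      }
      rr_u <- resample_uniform(record$tachogram, rate8, t0 = win[1], t1 = win[2])
      nodes[, 9] <- rr_u$values[seq_len(n8)]
      sp_u <- resample_uniform(record$spo2, rate8, t0 = win[1], t1 = win[2])
      nodes[, 10] <- sp_u$values[seq_len(n8)]
      band <- config$band_map[[record$group]]
      g <- build_coupling_graph(nodes, band, config, seed = event_seed,
                                t0 = win[1])
      feats <- c(feats, topology_features(g, epochs, config))
    }
  }
  feats
}

#' Assemble the per-event feature table
#'
#' Detects and pairs hypoxic events in each record at one or more
#' desaturation thresholds and extracts every configured feature family.
#' Features anchored on the bradycardia window (HRV, EEG, network) are
#' computed once per bradycardia and shared across thresholds; only the
#' desaturation-anchored SpO2 epoch statistics are threshold-specific.
#' Power features are natural-log transformed (`log(x + tiny)`).
#'
#' @param records list of [polygraphic_record()]s (or zero-argument functions
#'   returning one — records are then materialized one at a time).
#' @param config a [pipeline_config()].
#' @param thresholds desaturation thresholds (percent) to assemble tables for.
#' @return named list (one element per threshold) of data.frames with columns
#'   `subject_id`, `group`, `event_id`, `label`, `pma_weeks` and the feature
#'   columns; zero-row tables (with a `flag` attribute) when nothing was
#'   detected.
#' @export
assemble_features <- function(records, config = pipeline_config(),
                              thresholds = config$desat_threshold_pct) {
  reg <- feature_registry(config)
  reg <- reg[reg$family %in% config$feature_groups, ]
  tables <- setNames(vector("list", length(thresholds)),
                     as.character(thresholds))
  for (thr in as.character(thresholds)) tables[[thr]] <- list()
  for (rec in records) {
    if (is.function(rec)) rec <- rec()
    eeg_filt <- if (any(c("eeg", "network") %in% config$feature_groups)) {
      preprocess_eeg(rec$eeg, rec$eeg_rate)
    } else NULL
    bradys <- detect_bradycardias(rec$tachogram, config)
    cache <- new.env(parent = emptyenv())
    subj_hash <- sum(utf8ToInt(rec$subject_id))
    for (thr in thresholds) {
      desats <- detect_desaturations(rec$spo2, thr, config)
      paired <- pair_events(bradys, desats, config)
      if (!nrow(paired)) next
      for (k in seq_len(nrow(paired))) {
        ev <- paired[k, ]
        epochs <- segment_epochs(ev, rec, config)
        key <- sprintf("b%.0f", ev$t_peak * 1000)
        if (is.null(cache[[key]])) {
          cache[[key]] <- extract_event_features(
            rec, eeg_filt, ev, epochs, config,
            event_seed = derive_seed(config$rng_seed, subj_hash, round(ev$t_peak)))
        }
        feats <- cache[[key]]
        if ("cardio" %in% config$feature_groups) {
          sf <- spo2_epoch_features(rec, epochs)
          feats[names(sf)] <- sf
        }
        row <- c(list(subject_id = rec$subject_id, group = rec$group,
                      event_id = sprintf("%s-T%g-E%02d", rec$subject_id, thr, k),
                      label = rec$stress_label, pma_weeks = rec$pma_weeks),
                 as.list(feats[reg$name]))
        names(row) <- c("subject_id", "group", "event_id", "label",
                        "pma_weeks", reg$name)
        tables[[as.character(thr)]][[length(tables[[as.character(thr)]]) + 1]] <- row
      }
    }
    log_stage("extract", subject = rec$subject_id,
              bradycardias = nrow(bradys))
  }
  eps <- .Machine$double.xmin
  for (thr in names(tables)) {
    rows <- tables[[thr]]
    if (!length(rows)) {
      tb <- data.frame(subject_id = character(0), group = character(0),
                       event_id = character(0), label = logical(0),
                       pma_weeks = numeric(0))
      for (nm in reg$name) tb[[nm]] <- numeric(0)
      attr(tb, "flag") <- "no events"
      tables[[thr]] <- tb
      next
    }
    tb <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
    for (nm in reg$name[reg$log_transform]) {
      tb[[nm]] <- log(pmax(tb[[nm]], 0) + eps)
    }
    rownames(tb) <- NULL
    tables[[thr]] <- tb
  }
  tables
}
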