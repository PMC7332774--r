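#' Run the full stress-classification pipeline
#'
#' Chains the stages: (optionally) generate or load a cohort, detect and pair
#' bradycardia/desaturation events at each threshold, extract the configured
#' feature families and evaluate the subspace-LDA classifier with
#' leave-one-patient-out cross-validation per monitoring group and threshold.
#' Fully reproducible from the configuration and its seed.
#'
#' @param cohort one of: a list of [polygraphic_record()]s, a directory whose
#'   sub-directories are record bundles (see [write_record()]), or a
#'   [cohort_spec()] (records are then generated subject-by-subject with
#'   `espec`).
#' @param config a [pipeline_config()].
#' @param thresholds desaturation thresholds to evaluate (percent).
#' @param espec an [effect_spec()] used when `cohort` is a [cohort_spec()].
#' @param keep_features keep the per-event feature tables in the report.
#' @param out_dir optional directory: feature tables and the report summary
#'   are written there as CSV/JSON.
#' @return object of class `"stress_report"`: `summary` data.frame (group,
#'   threshold, auc, kappa, n_events, n_subjects, flag), `scores`,
#'   `features` (per-threshold tables, if kept), `config`, `seed`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         thresholds = c(3, 5, 10), espec = effect_spec(),
                         keep_features = TRUE, out_dir = NULL) {
  records <- resolve_cohort(cohort, espec, config)
  tables <- assemble_features(records, config, thresholds = thresholds)
  n_rows <- sum(vapply(tables, nrow, 0L))
  log_stage("extracted", thresholds = length(tables), event_rows = n_rows)
  groups <- unique(unlist(lapply(tables, function(tb) unique(tb$group))))
  rows <- list(); scores <- list()
  if (!length(groups)) {
    for (thr in names(tables)) {
      rows[[length(rows) + 1]] <- data.frame(
        group = NA_character_, threshold = as.numeric(thr), auc = NA_real_,
        kappa = NA_real_, n_events = 0L, n_subjects = 0L, flag = "no events")
    }
  }
  for (thr in names(tables)) {
    tb <- tables[[thr]]
    for (g in groups) {
      sub <- tb[tb$group == g, , drop = FALSE]
      if (!nrow(sub)) {
        rows[[length(rows) + 1]] <- data.frame(
          group = g, threshold = as.numeric(thr), auc = NA_real_,
          kappa = NA_real_, n_events = 0L, n_subjects = 0L,
          flag = "no events")
        next
      }
      res <- lopo_evaluate(sub, config,
                           seed = derive_seed(config$rng_seed, 23L,
                                              match(g, MONITORING_GROUPS),
                                              round(as.numeric(thr))))
      rows[[length(rows) + 1]] <- data.frame(
        group = g, threshold = as.numeric(thr), auc = res$auc,
        kappa = res$kappa, n_events = res$n_events,
        n_subjects = res$n_subjects, flag = res$flag %||% "")
      if (!is.null(res$scores)) {
        res$scores$group <- g
        res$scores$threshold <- as.numeric(thr)
        scores[[length(scores) + 1]] <- res$scores
      }
    }
  }
  report <- structure(list(
    summary = do.call(rbind, rows),
    scores = if (length(scores)) do.call(rbind, scores) else NULL,
    features = if (keep_features) tables else NULL,
    config = config, seed = config$rng_seed
  ), class = "stress_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (thr in names(tables)) {
      write.csv(tables[[thr]],
                file.path(out_dir, sprintf("features_thr%s.csv", thr)),
                row.names = FALSE)
    }
    writeLines(jsonlite::toJSON(report$summary, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA, na = "null"),
               file.path(out_dir, "report.json"))
  }
  report
}

resolve_cohort <- function(cohort, espec, config) {
  if (inherits(cohort, "cohort_spec")) {
    specs <- list()
    for (gi in seq_along(cohort$groups)) {
      g <- cohort$groups[gi]
      n_str <- cohort$n_subjects %/% 2
      for (si in seq_len(cohort$n_subjects)) {
        specs[[length(specs) + 1]] <- list(
          g = g, gi = gi, si = si, stressed = si <= n_str,
          sid = sprintf("%s-S%02d", g, si))
      }
    }
    # thunks: records are generated one at a time and discarded after use
    return(lapply(specs, function(sp) {
      force(sp)
      function() generate_subject(cohort, espec, stressed = sp$stressed,
                                  group = sp$g,
                                  seed = derive_seed(cohort$rng_seed, sp$gi, sp$si),
                                  subject_id = sp$sid, config = config)
    }))
  }
  if (is.character(cohort) && length(cohort) == 1 && dir.exists(cohort)) {
    dirs <- list.dirs(cohort, recursive = FALSE)
    return(lapply(dirs, function(d) { force(d); function() read_record(d) }))
  }
  if (is.list(cohort) && length(cohort) &&
      all(vapply(cohort, inherits, TRUE, "polygraphic_record"))) {
    return(cohort)
  }
  stop("'cohort' must be records, a bundle directory or a cohort_spec")
}

#' @export
print.stress_report <- function(x, ...) {
  cat("<stress_report> leave-one-patient-out stress classification\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
summary.stress_report <- function(object, ...) {
  s <- object$summary
  cat(sprintf("stress_report: %d group x threshold cells, seed %d\n",
              nrow(s), object$seed))
  ok <- is.finite(s$auc)
  if (any(ok)) {
    cat(sprintf("  AUC range  [%.3f, %.3f]\n", min(s$auc[ok]), max(s$auc[ok])))
    cat(sprintf("  kappa range [%.3f, %.3f]\n",
                min(s$kappa[ok]), max(s$kappa[ok])))
  }
  invisible(s)
}

#' @export
plot.stress_report <- function(x, ...) {
  s <- x$summary[is.finite(x$summary$auc), ]
  if (!nrow(s)) { warning("nothing to plot"); return(invisible(x)) }
  graphics::barplot(s$auc, names.arg = sprintf("%s\n>%g%%", s$group, s$threshold),
                    ylim = c(0, 1), ylab = "pooled LOPO AUC", ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
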