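# Event-level stress classification: feature preprocessing, the subspace-LDA
# ensemble and leave-one-patient-out evaluation.

#' Fisher-type F-score of a feature
#'
#' `F = [(mean+ - mean)^2 + (mean- - mean)^2] / (var+ + var-)` with class
#' means/variances (the Chen–Lin discrimination score).  Missing values are
#' excluded.
#'
#' @param x numeric feature values.
#' @param labels logical (or two-level) class labels.
#' @return scalar F (0, flagged, when the denominator vanishes).
#' @export
f_score <- function(x, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(x) & !is.na(labels)
  x <- x[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) stop("both classes must be present")
  xp <- x[labels]; xn <- x[!labels]
  if (length(xp) < 2 || length(xn) < 2) return(structure(0, flagged = TRUE))
  num <- (mean(xp) - mean(x))^2 + (mean(xn) - mean(x))^2
  den <- var(xp) + var(xn)
  if (den <= 0) return(structure(0, flagged = TRUE))
  num / den
}

#' Age-correct features against post-menstrual age
#'
#' Per feature, the Pearson correlation with PMA is assessed on the training
#' rows; when significant (p < 0.05) the feature is replaced — in training
#' and test rows alike — by the residuals of a univariate linear fit on PMA
#' whose coefficients come from the training rows only.
#'
#' @param X numeric feature matrix (rows = events).
#' @param pma PMA per row, weeks.
#' @param train_mask logical rows used for estimation.
#' @param p_cut significance cut-off (default 0.05).
#' @return matrix of the same shape; attribute `"corrected"` lists the
#'   corrected columns.
#' @export
age_correct <- function(X, pma, train_mask, p_cut = 0.05) {
  stopifnot(nrow(X) == length(pma), nrow(X) == length(train_mask))
  if (sum(train_mask) < 3) return(X)
  corrected <- character(0)
  for (j in seq_len(ncol(X))) {
    xt <- X[train_mask, j]; pt <- pma[train_mask]
    ok <- is.finite(xt) & is.finite(pt)
    if (sum(ok) < 3 || sd(xt[ok]) == 0 || sd(pt[ok]) == 0) next
    ct <- suppressWarnings(stats::cor.test(xt[ok], pt[ok]))
    if (is.na(ct$p.value) || ct$p.value >= p_cut) next
    fit <- lm(y ~ p, data = data.frame(y = xt[ok], p = pt[ok]))
    b <- coef(fit)
    X[, j] <- X[, j] - (b[1] + b[2] * pma)
    corrected <- c(corrected, colnames(X)[j] %||% as.character(j))
  }
  attr(X, "corrected") <- corrected
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Greedy correlation filter over F-score-ranked features
#'
#' Walks the features in descending F-score order and drops any feature whose
#' absolute Pearson correlation with an already retained feature exceeds the
#' cap.
#'
#' @param X feature matrix.
#' @param scores F-score per column.
#' @param cap correlation cap (default 0.9).
#' @param max_keep optional cap on the number retained.
#' @return integer indices of retained columns, in descending score order.
#' @export
correlation_filter <- function(X, scores, cap = 0.9, max_keep = Inf) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  for (j in ord) {
    if (length(keep) >= max_keep) break
    xj <- X[, j]
    if (sum(is.finite(xj)) < 3 || sd(xj, na.rm = TRUE) == 0) next
    ok <- TRUE
    for (k in keep) {
      r <- suppressWarnings(cor(xj, X[, k], use = "pairwise.complete.obs"))
      if (is.finite(r) && abs(r) > cap) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, j)
  }
  keep
}

# --- internal LDA base learner ---------------------------------------------
# Pooled-covariance Gaussian discriminant; shrinkage gamma toward the scaled
# identity when the pooled covariance is numerically degenerate.
lda_fit <- function(X, y, gamma = 0.1) {
  y <- as.logical(y)
  if (!any(y) || all(y)) { # degenerate resample: uninformative learner
    return(list(w = matrix(0, ncol(X), 1), b = 0, shrunk = TRUE))
  }
  m1 <- colMeans(X[y, , drop = FALSE])
  m0 <- colMeans(X[!y, , drop = FALSE])
  n1 <- sum(y); n0 <- sum(!y)
  S <- (crossprod(sweep(X[y, , drop = FALSE], 2, m1)) +
          crossprod(sweep(X[!y, , drop = FALSE], 2, m0))) / (n1 + n0 - 2)
  shrunk <- FALSE
  if (!is.finite(rcond_sym(S)) || rcond_sym(S) < 1e-10) {
    S <- (1 - gamma) * S + gamma * mean(diag(S)) * diag(ncol(X))
    shrunk <- TRUE
    if (rcond_sym(S) < 1e-12) S <- S + 1e-8 * diag(ncol(X))
  }
  Sinv <- tryCatch(solve(S), error = function(e) {
    solve(S + 1e-6 * mean(diag(S)) * diag(ncol(X)))
  })
  w <- Sinv %*% (m1 - m0)
  # equal class priors: the training class mix varies across LOPO folds in a
  # way that is anti-correlated with the held-out label, so a log(n1/n0)
  # prior term would bias pooled null scores away from chance
  b <- -0.5 * sum((m1 + m0) * w)
  list(w = w, b = b, shrunk = shrunk)
}

rcond_sym <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA)
  if (any(!is.finite(ev))) return(NA_real_)
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

lda_score <- function(fit, X) {
  z <- as.numeric(X %*% fit$w) + fit$b
  1 / (1 + exp(-z))
}

#' Fit a subspace-LDA ensemble
#'
#' An ensemble of linear-discriminant learners, each trained on a stratified
#' bootstrap resample of the training events and a uniformly random feature
#' subset of size `min(floor(n_train * subspace_fraction), n_features)`.
#' The ensemble score is the mean learner posterior.  The ensemble size is
#' selected by 10-fold cross-validation over `config$ensemble_size` inside
#' the training data; missing values are imputed with training-column
#' medians.
#'
#' @param X training feature matrix (column names required).
#' @param y logical labels.
#' @param config a [pipeline_config()].
#' @param seed integer seed.
#' @param select_L run the internal CV selection (default TRUE; FALSE uses
#'   the largest configured size, for the nested CV itself).
#' @return object of class `"subspace_lda"`.
#' @export
subspace_lda <- function(X, y, config = pipeline_config(), seed = 1L,
                         select_L = TRUE) {
  y <- as.logical(y)
  if (!any(y) || all(y)) stop("training data must contain both classes")
  med <- apply(X, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- med[j]
  }
  keep <- which(apply(X, 2, sd) > 0)
  if (!length(keep)) stop("no informative features")
  X <- X[, keep, drop = FALSE]
  dim_sub <- max(1L, min(floor(nrow(X) * config$subspace_fraction), ncol(X)))
  L_grid <- config$ensemble_size
  L <- max(L_grid)
  cv_auc <- NULL
  if (select_L && length(L_grid) > 1 && nrow(X) >= 20 &&
      sum(y) >= 5 && sum(!y) >= 5) {
    cv_auc <- cv_select_L(X, y, L_grid, dim_sub, config, seed)
    # prefer the largest (most stable) ensemble within tolerance of the best
    # CV AUC: bagging variance decreases monotonically in the ensemble size,
    # so near-ties should not select a small ensemble on CV noise
    ok_L <- cv_auc >= max(cv_auc) - 0.02
    L <- max(L_grid[ok_L])
  }
  set.seed(derive_seed(seed, 7L))
  learners <- fit_ensemble(X, y, L, dim_sub)
  structure(list(learners = learners, L = L, dim_sub = dim_sub,
                 features = colnames(X), medians = med, keep = keep,
                 cv_auc = cv_auc, n_train = nrow(X)),
            class = "subspace_lda")
}

fit_ensemble <- function(X, y, L, dim_sub) {
  idx1 <- which(y); idx0 <- which(!y)
  m <- max(length(idx1), length(idx0)) # balanced stratified bootstrap
  resample <- function(idx) idx[sample.int(length(idx), m, replace = TRUE)]
  lapply(seq_len(L), function(l) {
    boot <- c(resample(idx1), resample(idx0))
    fs <- sort(sample.int(ncol(X), dim_sub))
    fit <- lda_fit(X[boot, fs, drop = FALSE], y[boot])
    fit$fs <- fs
    fit
  })
}

cv_select_L <- function(X, y, L_grid, dim_sub, config, seed) {
  set.seed(derive_seed(seed, 11L))
  nf <- 10L
  fold <- integer(nrow(X))
  fold[y] <- sample(rep_len(seq_len(nf), sum(y)))
  fold[!y] <- sample(rep_len(seq_len(nf), sum(!y)))
  scores <- matrix(NA_real_, nrow(X), length(L_grid))
  for (f in seq_len(nf)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    set.seed(derive_seed(seed, 13L, f))
    learners <- fit_ensemble(X[tr, , drop = FALSE], y[tr], max(L_grid), dim_sub)
    s_all <- vapply(learners, function(fit) {
      lda_score(fit, X[!tr, fit$fs, drop = FALSE])
    }, numeric(sum(!tr)))
    s_all <- matrix(s_all, nrow = sum(!tr))
    for (gi in seq_along(L_grid)) {
      scores[!tr, gi] <- rowMeans(s_all[, seq_len(L_grid[gi]), drop = FALSE])
    }
  }
  apply(scores, 2, function(s) {
    ok <- is.finite(s)
    if (length(unique(y[ok])) < 2) return(0.5)
    auc_rank(s[ok], y[ok])
  })
}

#' @export
predict.subspace_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- object$medians[object$features[j]]
  }
  s <- vapply(object$learners, function(fit) {
    lda_score(fit, X[, fit$fs, drop = FALSE])
  }, numeric(nrow(X)))
  rowMeans(matrix(s, nrow = nrow(X)))
}

#' @export
print.subspace_lda <- function(x, ...) {
  cat(sprintf("<subspace_lda> %d learners, %d-dim subspaces over %d features (n=%d)\n",
              x$L, x$dim_sub, length(x$features), x$n_train))
  invisible(x)
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve via the Mann–Whitney rank statistic (midranks on
#' ties).
#'
#' @param scores numeric scores.
#' @param labels logical labels (TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement from the 2x2 confusion table; defined as 0
#' (flagged) when the expected agreement is 1.
#'
#' @param pred,truth logical vectors of equal length.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  n <- length(pred)
  po <- mean(pred == truth)
  pe <- mean(pred) * mean(truth) + mean(!pred) * mean(!truth)
  if (abs(1 - pe) < 1e-12) return(structure(0, flagged = TRUE))
  (po - pe) / (1 - pe)
}

#' Leave-one-patient-out evaluation
#'
#' Iterates subjects: all events of one subject form the test fold; the
#' training fold is preprocessed from scratch (median imputation, age
#' correction, F-score ranking with the greedy correlation filter keeping at
#' most `3 * floor(n_train/10)` features) and a [subspace_lda()] ensemble is
#' fitted; the held-out events are scored.  All test scores are pooled into a
#' single AUC (rank statistic) and Cohen's kappa at a posterior threshold of
#' 0.5.
#'
#' @param table a feature table from [assemble_features()] (one group).
#' @param config a [pipeline_config()].
#' @param seed integer seed.
#' @return list of class `"lopo_result"`: `auc`, `kappa`, `n_events`,
#'   `n_subjects`, `scores` (pooled data.frame), `fold_features` (per fold,
#'   the training F-scores of the retained features, named, in descending
#'   order), `flag`.
#' @export
lopo_evaluate <- function(table, config = pipeline_config(),
                          seed = config$rng_seed) {
  meta_cols <- c("subject_id", "group", "event_id", "label", "pma_weeks")
  feat_cols <- setdiff(names(table), meta_cols)
  subj <- unique(table$subject_id)
  subj_lab <- vapply(subj, function(s) table$label[table$subject_id == s][1], NA)
  flag <- NULL
  if (nrow(table) == 0) {
    return(structure(list(auc = NA_real_, kappa = NA_real_, n_events = 0L,
                          n_subjects = 0L, scores = NULL, flag = "no events"),
                     class = "lopo_result"))
  }
  if (length(unique(subj_lab)) < 2 || sum(subj_lab) < 2 || sum(!subj_lab) < 2) {
    return(structure(list(auc = NA_real_, kappa = NA_real_,
                          n_events = nrow(table), n_subjects = length(subj),
                          scores = NULL, flag = "needs >= 2 subjects per class"),
                     class = "lopo_result"))
  }
  X_all <- as.matrix(table[, feat_cols, drop = FALSE])
  pooled <- list()
  fold_features <- list()
  for (s in subj) {
    test <- table$subject_id == s
    train <- !test
    y_tr <- table$label[train]
    if (length(unique(y_tr)) < 2) next
    Xc <- age_correct(X_all, table$pma_weeks, train_mask = train)
    X_tr <- Xc[train, , drop = FALSE]
    scores_f <- vapply(seq_len(ncol(X_tr)), function(j) {
      xj <- X_tr[, j]
      if (sum(is.finite(xj)) < 4 || sd(xj, na.rm = TRUE) == 0) return(0)
      tryCatch(as.numeric(f_score(xj, y_tr)), error = function(e) 0)
    }, 0)
    max_keep <- max(2L, 3L * floor(nrow(X_tr) * config$subspace_fraction))
    keep <- correlation_filter(X_tr, scores_f, cap = config$correlation_cap,
                               max_keep = max_keep)
    fold_features[[s]] <- setNames(scores_f[keep], colnames(X_tr)[keep])
    if (length(keep) < 2) next
    model <- subspace_lda(X_tr[, keep, drop = FALSE], y_tr, config,
                          seed = derive_seed(seed, 17L, which(subj == s)))
    sc <- predict(model, as.data.frame(Xc[test, keep, drop = FALSE],
                                       check.names = FALSE))
    pooled[[s]] <- data.frame(subject_id = s,
                              event_id = table$event_id[test],
                              label = table$label[test], score = sc)
  }
  if (!length(pooled)) {
    return(structure(list(auc = NA_real_, kappa = NA_real_,
                          n_events = nrow(table), n_subjects = length(subj),
                          scores = NULL, flag = "no scorable folds"),
                     class = "lopo_result"))
  }
  pooled <- do.call(rbind, pooled)
  rownames(pooled) <- NULL
  auc <- auc_rank(pooled$score, pooled$label)
  kap <- cohens_kappa(pooled$score > 0.5, pooled$label)
  log_stage("classify", folds = length(unique(pooled$subject_id)),
            events = nrow(pooled), auc = sprintf("%.3f", auc))
  structure(list(auc = auc, kappa = as.numeric(kap),
                 n_events = nrow(pooled),
                 n_subjects = length(unique(pooled$subject_id)),
                 scores = pooled, fold_features = fold_features, flag = flag),
            class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat(sprintf("<lopo_result> %s (n_events=%d)\n", x$flag, x$n_events))
  } else {
    cat(sprintf("<lopo_result> AUC=%.3f kappa=%.3f over %d events from %d subjects\n",
                x$auc, x$kappa, x$n_events, x$n_subjects))
  }
  invisible(x)
}
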