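test_that("F-score matches the class-separation formula", {
  set.seed(19)
  x <- rnorm(200); y <- rep(c(TRUE, FALSE), each = 100)
  got <- as.numeric(f_score(x, y))
  xp <- x[y]; xn <- x[!y]
  want <- ((mean(xp) - mean(x))^2 + (mean(xn) - mean(x))^2) /
    (var(xp) + var(xn))
  expect_equal(got, want, tolerance = 1e-12)
  expect_lt(as.numeric(f_score(rnorm(400), rep(c(TRUE, FALSE), 200))), 0.05)
  # monotone in class separation
  fs <- sapply(c(0.5, 1, 2), function(mu) {
    set.seed(20)
    as.numeric(f_score(c(rnorm(200, mu), rnorm(200, -mu)),
                       rep(c(TRUE, FALSE), each = 200)))
  })
  expect_true(all(diff(fs) > 0))
  expect_error(f_score(x, rep(TRUE, 200)), "classes")
})

test_that("correlation filter keeps the higher-scoring of correlated pairs", {
  set.seed(22)
  a <- rnorm(100)
  X <- cbind(f1 = a, f2 = a + 0.05 * rnorm(100), f3 = rnorm(100), f4 = a)
  keep <- correlation_filter(X, scores = c(2, 3, 1, 3.5), cap = 0.9)
  expect_true(4 %in% keep)          # duplicate of f1 with top score: kept
  expect_false(any(c(1, 2) %in% keep)) # r > 0.9 with f4: dropped
  expect_true(3 %in% keep)
  # orthogonal features all retained
  O <- matrix(rnorm(300), 100, 3)
  expect_length(correlation_filter(O, scores = 3:1, cap = 0.9), 3)
})

test_that("age correction regresses out PMA on training rows only", {
  set.seed(23)
  pma <- runif(60, 28, 40)
  X <- cbind(dep = 2 * pma + rnorm(60, 0, 0.01), indep = rnorm(60))
  train <- rep(TRUE, 60); train[1:10] <- FALSE
  Xc <- age_correct(X, pma, train)
  expect_lt(abs(cor(Xc[train, "dep"], pma[train])), 0.1)
  expect_lt(max(abs(Xc[train, "dep"])), 0.2)
  expect_equal(Xc[, "indep"], X[, "indep"]) # uncorrelated: untouched
  # coefficients come from the training rows: a held-out block at extreme
  # PMA is corrected with the train fit (small residuals under extrapolation
  # of the true linear relation)
  set.seed(29)
  pma2 <- c(runif(50, 28, 36), rep(44, 10))
  X2 <- cbind(f = 3 * pma2 + rnorm(60, 0, 0.01))
  tr2 <- c(rep(TRUE, 50), rep(FALSE, 10))
  X2c <- age_correct(X2, pma2, tr2)
  expect_lt(max(abs(X2c[!tr2, 1])), 0.1)
})

test_that("internal LDA learner agrees with MASS::lda directions", {
  skip_if_not_installed("MASS")
  set.seed(24)
  X <- rbind(matrix(rnorm(200, 1), 100, 2), matrix(rnorm(200, -1), 100, 2))
  y <- rep(c(TRUE, FALSE), each = 100)
  fit <- neostress:::lda_fit(X, y)
  m <- MASS::lda(X, grouping = y)
  w_mass <- as.numeric(m$scaling)
  cosang <- abs(sum(fit$w * w_mass) /
                  sqrt(sum(fit$w^2) * sum(w_mass^2)))
  expect_gt(cosang, 0.999)
  sc <- neostress:::lda_score(fit, X)
  expect_gt(auc_rank(sc, y), 0.95)
  # degenerate covariance falls back to shrinkage instead of failing
  Xd <- cbind(X[, 1], X[, 1])
  fitd <- neostress:::lda_fit(Xd, y)
  expect_true(fitd$shrunk)
  expect_true(all(is.finite(fitd$w)))
})

test_that("AUC by ranks equals trapezoidal ROC integration", {
  trap_auc <- function(s, y) {
    th <- sort(unique(c(-Inf, s, Inf)), decreasing = TRUE)
    tpr <- sapply(th, function(t) mean(s[y] >= t))
    fpr <- sapply(th, function(t) mean(s[!y] >= t))
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  for (seed in 1:10) {
    set.seed(seed)
    s <- rnorm(80); y <- runif(80) > 0.4
    if (length(unique(y)) < 2) next
    expect_equal(auc_rank(s, y), trap_auc(s, y), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(31)
  s <- rnorm(100); y <- runif(100) > 0.5
  expect_equal(auc_rank(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-9)
})

test_that("Cohen's kappa matches hand-computed confusion tables", {
  expect_equal(cohens_kappa(c(TRUE, FALSE), c(TRUE, FALSE)), 1)
  expect_equal(cohens_kappa(c(TRUE, FALSE), c(FALSE, TRUE)), -1)
  pred <- c(rep(TRUE, 40), rep(FALSE, 40), rep(TRUE, 10), rep(FALSE, 10))
  truth <- c(rep(TRUE, 40), rep(FALSE, 40), rep(FALSE, 10), rep(TRUE, 10))
  expect_equal(cohens_kappa(pred, truth), 0.6, tolerance = 1e-12)
  k0 <- cohens_kappa(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(as.numeric(k0), 0)
  expect_true(attr(k0, "flagged"))
})

test_that("subspace LDA separates separable data and is seed-deterministic", {
  set.seed(25)
  n <- 60
  X <- cbind(sig = c(rnorm(n, 2), rnorm(n, -2)),
             matrix(rnorm(2 * n * 5), 2 * n, 5))
  colnames(X) <- paste0("f", 1:6)
  y <- rep(c(TRUE, FALSE), each = n)
  m1 <- subspace_lda(X, y, seed = 5)
  expect_gte(auc_rank(predict(m1, as.data.frame(X)), y), 0.99)
  m2 <- subspace_lda(X, y, seed = 5)
  expect_identical(predict(m1, as.data.frame(X)), predict(m2, as.data.frame(X)))
  # permuted labels: near-chance CV
  set.seed(26)
  yp <- sample(y)
  mp <- subspace_lda(X, yp, seed = 6)
  expect_lt(auc_rank(predict(mp, as.data.frame(X)), y), 0.75)
})

test_that("LOPO pools every scorable subject and honours the protocol", {
  set.seed(27)
  n_subj <- 8; ev_per <- 6
  subj <- rep(sprintf("S%02d", 1:n_subj), each = ev_per)
  lab <- rep(c(TRUE, FALSE), each = n_subj / 2 * ev_per)
  X <- matrix(rnorm(n_subj * ev_per * 6), ncol = 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  X[, 1] <- X[, 1] + ifelse(lab, 1.8, -1.8)
  tb <- data.frame(subject_id = subj, group = "34weeks",
                   event_id = paste0(subj, "-", seq_along(subj)),
                   label = lab, pma_weeks = rep(runif(n_subj, 30, 38),
                                                each = ev_per),
                   X, check.names = FALSE)
  res <- suppressMessages(lopo_evaluate(tb, pipeline_config(), seed = 3))
  expect_gte(res$auc, 0.95)
  expect_gte(res$kappa, 0.7)
  expect_setequal(unique(res$scores$subject_id), unique(subj))
  # no subject is scored by a model trained on its own events:
  # a one-subject-only marker feature cannot help its own fold
  expect_equal(res$n_events, nrow(tb))
  # single-class truth is flagged, not an error
  tb1 <- tb; tb1$label <- TRUE
  r1 <- lopo_evaluate(tb1, pipeline_config(), seed = 3)
  expect_true(is.na(r1$auc))
  expect_match(r1$flag, "subjects per class")
})

test_that("preprocessing is fitted inside folds: a test-only canary cannot leak", {
  # The canary tracks the labels of one subject's events only (S01) and is
  # pure noise elsewhere.  In S01's own fold the training data exclude S01,
  # so the canary's training F-score is tiny and it cannot top the ranking;
  # in the other folds S01 is in training and the canary ranks first.
  set.seed(28)
  n_subj <- 8; ev_per <- 6
  subj <- rep(sprintf("S%02d", 1:n_subj), each = ev_per)
  lab <- rep(rep(c(TRUE, FALSE), 4), each = ev_per)
  X <- matrix(rnorm(n_subj * ev_per * 4), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  canary <- rnorm(length(subj))
  s1_rows <- subj == "S01" # S01 is a stressed subject: canary spikes there
  canary[s1_rows] <- 100 + rnorm(ev_per)
  tb <- data.frame(subject_id = subj, group = "34weeks",
                   event_id = as.character(seq_along(subj)), label = lab,
                   pma_weeks = 34, X, canary = canary, check.names = FALSE)
  res <- suppressMessages(lopo_evaluate(tb, pipeline_config(), seed = 4))
  used <- res$fold_features[["S01"]][["canary"]]
  expect_equal(used,
               as.numeric(f_score(canary[subj != "S01"], lab[subj != "S01"])),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(used, as.numeric(f_score(canary, lab)),
                                tolerance = 1e-6)))
})
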