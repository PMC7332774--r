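# Independent brute-force oracles and small fixture builders.

# Brute-force bradycardia scan: recompute the whole-record mean, enumerate
# maximal supra-threshold runs (merging gaps < 5 beats), keep runs with
# summed RR >= min duration.  Returns run index ranges.
oracle_brady_runs <- function(rr, factor = 1.5, min_dur = 4) {
  thr <- factor * mean(rr)
  above <- rr > thr
  runs <- list()
  i <- 1
  n <- length(rr)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  # merge gaps < 5 beats
  if (length(runs) > 1) {
    merged <- list(runs[[1]])
    for (k in 2:length(runs)) {
      last <- merged[[length(merged)]]
      if (runs[[k]][1] - last[2] - 1 < 5) {
        merged[[length(merged)]][2] <- runs[[k]][2]
      } else merged[[length(merged) + 1]] <- runs[[k]]
    }
    runs <- merged
  }
  keep <- Filter(function(r) sum(rr[r[1]:r[2]]) >= min_dur, runs)
  do.call(rbind, keep)
}

# Random tachograms with occasional excursions, for detector equivalence.
random_tachogram <- function(seed, n = 1200) {
  set.seed(seed)
  rr <- 0.4 + 0.08 * abs(rnorm(n))
  n_exc <- sample(0:3, 1)
  for (k in seq_len(n_exc)) {
    i0 <- sample(50:(n - 60), 1)
    len <- sample(3:18, 1)
    rr[i0:(i0 + len - 1)] <- rr[i0:(i0 + len - 1)] * runif(1, 1.4, 2.6)
  }
  tachogram(cumsum(rr), rr)
}

# Floyd-Warshall shortest paths written independently (scalar triple loop).
oracle_fw <- function(A) {
  M <- nrow(A)
  D <- matrix(Inf, M, M)
  for (i in 1:M) for (j in 1:M) if (i != j && A[i, j] > 0) D[i, j] <- 1 / A[i, j]
  diag(D) <- 0
  for (k in 1:M) for (i in 1:M) for (j in 1:M) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_graph_indices <- function(A) {
  D <- oracle_fw(A)
  M <- nrow(A)
  off <- !diag(TRUE, M)
  fin <- off & is.finite(D)
  pl <- if (any(fin)) mean(D[fin]) else NA_real_
  eff <- mean(ifelse(is.finite(D), 1 / D, 0)[off])
  wmax <- max(A)
  cl <- 0
  if (wmax > 0) {
    wn <- A / wmax
    ci <- numeric(M)
    for (i in 1:M) {
      nb <- which(A[i, ] > 0)
      if (length(nb) < 2) next
      s <- 0
      for (j in nb) for (h in nb) {
        if (j != h) s <- s + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
      }
      ci[i] <- s / (length(nb) * (length(nb) - 1))
    }
    cl <- mean(ci)
  }
  ecc <- numeric(0)
  for (i in 1:M) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d)) ecc <- c(ecc, max(d))
  }
  ec <- if (length(ecc)) mean(ecc) else NA_real_
  c(path_length = pl, efficiency = eff, clustering = cl, eccentricity = ec)
}

oracle_n_sup <- function(A, objective = "H+E") {
  w0 <- sort(A[upper.tri(A)][A[upper.tri(A)] > 0], decreasing = TRUE)
  e <- length(w0)
  if (!e) return(0L)
  vals <- sapply(0:(e - 1), function(n) {
    kept <- w0[seq_len(e - n)]
    removed <- if (n > 0) w0[(e - n + 1):e] else numeric(0)
    wh <- kept / sum(kept)
    H <- -sum(wh * log(wh))
    E <- sum(removed^2) + sum((wh - kept)^2)
    if (objective == "H+E") H + E else H - E
  })
  as.integer(which.max(vals) - 1L)
}

random_symmetric_graph <- function(seed, M = 10, density = 0.5) {
  set.seed(seed)
  A <- matrix(0, M, M)
  up <- which(upper.tri(A))
  on <- sample(up, max(1, round(density * length(up))))
  A[on] <- runif(length(on), 0.05, 1)
  A + t(A)
}

# Small synthetic record (fast): short duration, few events.
quick_record <- function(seed, stressed = FALSE, group = "34weeks",
                         duration = 900, events_mean = 2,
                         espec = effect_spec()) {
  cs <- cohort_spec(n_subjects = 2, groups = group, record_duration_s = duration,
                    events_mean = events_mean, rng_seed = seed)
  generate_subject(cs, espec, stressed = stressed, group = group, seed = seed)
}

# Tachogram + SpO2 only (no EEG cost) for detector-level simulations.
quick_cardio_pair <- function(seed, duration = 900, n_events = 2,
                              depth_pct = 8, brady_depth = 2.0) {
  set.seed(seed)
  n_beats <- ceiling(duration / 0.4)
  rr <- 0.42 * (1 + 0.015 * sin(2 * pi * 0.1 * cumsum(rep(0.42, n_beats))) +
                  0.008 * rnorm(n_beats))
  tach <- tachogram(cumsum(rr), rr)
  spo2 <- 96 + as.numeric(stats::filter(rnorm(duration, 0, 0.13), 0.9,
                                        method = "recursive"))
  peaks <- seq(200, duration - 200, length.out = max(n_events, 1))[seq_len(n_events)]
  for (p in peaks) {
    tach <- inject_bradycardia(tach, p, brady_depth, 8)
    spo2 <- inject_desaturation(spo2, p, depth_pct, 30)
  }
  list(tach = tach, spo2 = pmin(pmax(spo2, 0), 100), peaks = peaks)
}
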