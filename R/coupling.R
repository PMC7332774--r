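# Surrogate-validated imaginary-coherence coupling and the 10-node graph.

#' Amplitude-adjusted Fourier transform surrogate
#'
#' Returns a series with exactly the same amplitude multiset as `x` (sorted
#' values are identical) and approximately the same power spectrum, with
#' randomized phase structure: rank-remap to a Gaussian, phase-randomize,
#' rank-remap the original amplitudes back.
#'
#' @param x numeric vector (>= 64 samples, non-constant).
#' @param seed optional integer seed.
#' @return numeric vector of the same length.
#' @export
aaft_surrogate <- function(x, seed = NULL) {
  n <- length(x)
  if (n < 64) stop("AAFT needs at least 64 samples")
  if (sd(x) == 0) stop("cannot build a surrogate of a constant series")
  if (!is.null(seed)) set.seed(seed)
  g <- sort(rnorm(n))[rank(x, ties.method = "first")]
  gf <- fft(g)
  ref <- fft(rnorm(n)) # real input -> conjugate-symmetric random phases
  gf2 <- complex(modulus = Mod(gf), argument = Arg(ref))
  gf2[1] <- gf[1]
  gs <- Re(fft(gf2, inverse = TRUE) / n)
  sort(x)[rank(gs, ties.method = "first")]
}

# Frequency grid for a coupling band: dyadic voices covering (lo, hi], with
# the sub-band edge voice retained as smoothing margin.
band_freq_grid <- function(band, voices) dyadic_freqs(band[1], band[2], voices)

# Coupling statistic machinery on a precomputed plan.  A block holds the
# real/imaginary parts of the CWT of k signals (npad x J*k, block-major per
# signal) and the smoothed autospectra A; smoothing of the imaginary
# cross-scalogram runs in real arithmetic (smoothing is real-linear, and only
# the imaginary coherence enters the coupling statistic).
coupling_block <- function(X, plan) {
  W <- morlet_cwt_block(X, plan)
  ReW <- Re(W); ImW <- Im(W)
  A <- tf_smooth_real(ReW^2 + ImW^2, plan)
  list(ReW = ReW, ImW = ImW, A = A)
}

# Per-time in-band coupling (max over in-band scales of |Im C|) for every
# signal in block `bx` against the single-signal block `by`; returns an
# n x k matrix with NA inside the cone of influence.
block_coupling_t <- function(bx, by, plan, sel) {
  J <- plan$J
  k <- ncol(bx$ReW) / J
  repJ <- rep(seq_len(J), times = k)
  # Im(Wx * Conj(Wy)) = Im(Wx) Re(Wy) - Re(Wx) Im(Wy)
  cross_im <- bx$ImW * by$ReW[, repJ, drop = FALSE] -
    bx$ReW * by$ImW[, repJ, drop = FALSE]
  S <- tf_smooth_real(cross_im, plan)
  denom <- sqrt(pmax(bx$A * by$A[, repJ, drop = FALSE], .Machine$double.xmin))
  imC <- abs(S) / denom
  n <- plan$n
  out <- matrix(-Inf, n, k)
  for (j in which(sel)) {
    cols <- j + (seq_len(k) - 1L) * J
    out <- pmax(out, imC[, cols, drop = FALSE])
  }
  excl <- rowSums(plan$coi_excl[, sel, drop = FALSE]) > 0
  out[excl, ] <- NA
  out
}

#' Surrogate-validated band coupling between two series
#'
#' The observed statistic is the time-mean (outside the cone of influence) of
#' the in-band coupling — the maximum over in-band scales of the absolute
#' imaginary coherence.  It is declared significant when it exceeds the same
#' statistic of every one of `n_surr` AAFT surrogates of `x` (`y` left
#' intact), a one-sided test at level `1/(n_surr + 1)`.
#'
#' @param x,y numeric vectors, equal length, sampled at `rate` Hz.
#' @param band `c(f_lo, f_hi)` Hz.
#' @param n_surr number of surrogates (default 19, level 0.05).
#' @param seed integer seed for the surrogate draws.
#' @param rate sampling rate, Hz.
#' @param voices voices per octave of the coherence scale grid (default 6,
#'   matching [build_coupling_graph()]).
#' @return list: `weight` (observed coupling if significant, else 0),
#'   `significant`, `observed`, `surrogate_max`.
#' @export
validate_coupling <- function(x, y, band, n_surr = 19, seed = 1L,
                              rate = 8, voices = 6) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  freqs <- band_freq_grid(band, voices)
  plan <- get_plan(length(x), rate, freqs)
  sel <- freqs > band[1] & freqs <= band[2]
  bx <- coupling_block(cbind(x - mean(x)), plan)
  by <- coupling_block(cbind(y - mean(y)), plan)
  obs_t <- block_coupling_t(bx, by, plan, sel)
  obs <- mean(obs_t, na.rm = TRUE)
  set.seed(seed)
  xs <- vapply(seq_len(n_surr), function(k) aaft_surrogate(x), numeric(length(x)))
  bs <- coupling_block(sweep(xs, 2, colMeans(xs)), plan)
  surr_t <- block_coupling_t(bs, by, plan, sel)
  surr <- colMeans(surr_t, na.rm = TRUE)
  sig <- obs > max(surr)
  list(weight = if (sig) obs else 0, significant = sig,
       observed = obs, surrogate_max = max(surr))
}

# Plan cache: event windows share their length, so transforms reuse kernels.
.plan_cache <- new.env(parent = emptyenv())

get_plan <- function(n, rate, freqs) {
  key <- paste0("p", n, "_", rate, "_", length(freqs), "_",
                signif(freqs[1], 8), "_", signif(freqs[length(freqs)], 8))
  p <- .plan_cache[[key]]
  if (is.null(p)) {
    p <- cwt_plan(n, rate, freqs)
    # keep the cache small: drop stale entries beyond 8 plans
    if (length(ls(.plan_cache)) >= 8) rm(list = ls(.plan_cache)[1], envir = .plan_cache)
    .plan_cache[[key]] <- p
  }
  p
}

#' Build the 10-node coupling graph of one hypoxic event
#'
#' Nodes are the 8 EEG delta-power envelopes (or delta-band signals), the RR
#' series and SpO2, all resampled to a common rate over the event window.
#' Every pair is tested with [validate_coupling()]-style AAFT surrogates;
#' non-significant pairs are masked to zero.  The per-time adjacency uses the
#' in-band coupling of the significant pairs, evaluated on the chart grid.
#'
#' @param nodes n x 10 matrix of node series at `rate` Hz (columns ordered
#'   EEG channels 1..8, RR, SpO2), time starting at `t0` seconds.
#' @param band coupling band `c(f_lo, f_hi)` Hz.
#' @param config a [pipeline_config()].
#' @param seed integer seed for the surrogate draws.
#' @param t0 window start time, seconds.
#' @param node_names optional node labels.
#' @return object of class `"coupling_graph"`: `weights` (10 x 10 symmetric,
#'   zero diagonal, significant time-mean couplings), `significance_mask`,
#'   `chart_times`, `chart_adj` (n_chart x 45 pair couplings on the chart
#'   grid), `pairs` (2 x 45 index matrix), `nodes`, `band`.
#' @export
build_coupling_graph <- function(nodes, band, config = pipeline_config(),
                                 seed = config$rng_seed, t0 = 0,
                                 node_names = c(CANONICAL_CHANNELS, "HRV", "SpO2")) {
  stopifnot(is.matrix(nodes), ncol(nodes) == 10)
  if (any(!is.finite(nodes))) stop("node series must be finite")
  n <- nrow(nodes)
  rate <- config$resample_rate_hz
  freqs <- band_freq_grid(band, config$coherence_voices)
  plan <- get_plan(n, rate, freqs)
  sel <- freqs > band[1] & freqs <= band[2]
  M <- 10L
  Xc <- sweep(nodes, 2, colMeans(nodes))
  obs_blocks <- lapply(seq_len(M), function(i) coupling_block(Xc[, i, drop = FALSE], plan))

  pairs <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)
  pairs <- t(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]) # 2 x 45
  n_pairs <- ncol(pairs)

  chart_step <- max(1L, as.integer(round(rate / config$chart_rate_hz)))
  chart_idx <- seq(1L, n, by = chart_step)

  obs_stat <- numeric(n_pairs)
  chart_adj <- matrix(NA_real_, length(chart_idx), n_pairs)
  surr_max <- numeric(n_pairs)

  # observed couplings
  pair_col <- function(i, j) which(pairs[1, ] == i & pairs[2, ] == j)
  for (i in seq_len(M - 1)) {
    js <- (i + 1):M
    ct <- block_coupling_t(
      list(ReW = do.call(cbind, lapply(js, function(j) obs_blocks[[j]]$ReW)),
           ImW = do.call(cbind, lapply(js, function(j) obs_blocks[[j]]$ImW)),
           A = do.call(cbind, lapply(js, function(j) obs_blocks[[j]]$A))),
      obs_blocks[[i]], plan, sel)
    for (k in seq_along(js)) {
      col <- pair_col(i, js[k])
      obs_stat[col] <- mean(ct[, k], na.rm = TRUE)
      chart_adj[, col] <- pmin(pmax(ct[chart_idx, k], 0), 1)
    }
  }

  # surrogate maxima: surrogates of the lower-index node of each pair,
  # shared across its partners
  for (i in seq_len(M - 1)) {
    set.seed(derive_seed(seed, 101L, i))
    xs <- vapply(seq_len(config$n_surrogates),
                 function(k) aaft_surrogate(Xc[, i]), numeric(n))
    bs <- coupling_block(sweep(xs, 2, colMeans(xs)), plan)
    for (j in (i + 1):M) {
      st <- block_coupling_t(bs, obs_blocks[[j]], plan, sel)
      surr_max[pair_col(i, j)] <- max(colMeans(st, na.rm = TRUE))
    }
  }

  significant <- obs_stat > surr_max
  weights <- matrix(0, M, M, dimnames = list(node_names, node_names))
  for (k in seq_len(n_pairs)) {
    if (significant[k]) {
      w <- min(max(obs_stat[k], 0), 1)
      weights[pairs[1, k], pairs[2, k]] <- w
      weights[pairs[2, k], pairs[1, k]] <- w
    }
  }
  chart_adj[, !significant] <- 0
  valid <- rowSums(is.na(chart_adj)) == 0
  structure(list(weights = weights, significance_mask = significant,
                 observed = obs_stat, surrogate_max = surr_max,
                 chart_times = t0 + (chart_idx - 1) / rate,
                 chart_valid = valid,
                 chart_adj = chart_adj, pairs = pairs,
                 nodes = node_names, band = band),
            class = "coupling_graph")
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat(sprintf("<coupling_graph> 10 nodes, %d/%d significant pairs, band (%g, %g] Hz\n",
              sum(x$significance_mask), length(x$significance_mask),
              x$band[1], x$band[2]))
  invisible(x)
}

#' @export
plot.coupling_graph <- function(x, ...) {
  graphics::image(seq_len(10), seq_len(10), x$weights,
                  xlab = "", ylab = "", axes = FALSE,
                  main = "validated coupling weights", ...)
  graphics::axis(1, at = seq_len(10), labels = x$nodes, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(10), labels = x$nodes, las = 2, cex.axis = 0.7)
  invisible(x)
}

# Dense adjacency of one chart sample.
chart_adjacency <- function(g, k) {
  M <- length(g$nodes)
  A <- matrix(0, M, M)
  w <- g$chart_adj[k, ]
  A[t(g$pairs)] <- w
  A[t(g$pairs[2:1, , drop = FALSE])] <- w
  A
}
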