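# Weighted-graph topology indices and the redundancy (superfluous-connection)
# optimum.

#' Topological indices of one weighted adjacency matrix
#'
#' Distances are inverse weights (`d_ij = 1/A_ij` for positive weights,
#' infinite otherwise); shortest paths by Floyd–Warshall.  Path length is the
#' mean finite shortest distance over ordered node pairs; efficiency the mean
#' of inverse distances over all ordered pairs (zero for disconnected ones);
#' clustering the node average of the Onnela weighted coefficient (geometric
#' mean triangle intensity on weights normalized by the maximum, zero for
#' nodes of degree < 2); eccentricity the node average of each connected
#' node's maximum finite distance.
#'
#' @param A symmetric non-negative matrix with zero diagonal.
#' @return named vector: `path_length`, `efficiency`, `clustering`,
#'   `eccentricity` (`NA` where undefined, e.g. an edgeless graph).
#' @export
graph_indices <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be square")
  if (any(A < 0)) stop("A must be non-negative")
  if (max(abs(A - t(A))) > 1e-12) stop("A must be symmetric")
  M <- nrow(A)
  D <- ifelse(A > 0, 1 / A, Inf)
  diag(D) <- 0
  for (k in seq_len(M)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  off <- row(D) != col(D)
  fin <- off & is.finite(D)
  path_length <- if (any(fin)) mean(D[fin]) else NA_real_
  inv <- ifelse(is.finite(D), 1 / D, 0)
  efficiency <- mean(inv[off])
  wmax <- max(A)
  if (wmax > 0) {
    w3 <- (A / wmax)^(1 / 3)
    num <- diag(w3 %*% w3 %*% w3)
    deg <- rowSums(A > 0)
    ci <- ifelse(deg >= 2, num / (deg * (deg - 1)), 0)
    clustering <- mean(ci)
  } else {
    clustering <- 0
  }
  Doff <- D; diag(Doff) <- NA
  ecc_i <- apply(Doff, 1, function(r) {
    r <- r[is.finite(r) & !is.na(r)]
    if (length(r)) max(r) else NA_real_
  })
  eccentricity <- if (all(is.na(ecc_i))) NA_real_ else mean(ecc_i, na.rm = TRUE)
  c(path_length = path_length, efficiency = efficiency,
    clustering = clustering, eccentricity = eccentricity)
}

#' Number of superfluous connections
#'
#' Orders the positive upper-triangle weights descending and, for each number
#' `n` of smallest weights removed (0 to e-1), evaluates the redundancy
#' objective: the entropy `H = -sum(w log w)` of the remaining weights
#' renormalized to a distribution, plus the squared error `E` between the new
#' and the original weight set (removed weights contribute their squared
#' original value).  Returns the `n` maximizing `H + E` (or `H - E` when the
#' configuration says so), the smallest on ties.
#'
#' @param A symmetric non-negative adjacency matrix.
#' @param objective `"H+E"` (default, as the redundancy objective is printed)
#'   or `"H-E"`.
#' @return integer `n_sup` (0 for an edgeless graph, flagged).
#' @export
n_superfluous <- function(A, objective = c("H+E", "H-E")) {
  objective <- match.arg(objective)
  w0 <- A[upper.tri(A)]
  w0 <- sort(w0[w0 > 0], decreasing = TRUE)
  e <- length(w0)
  if (e == 0) return(structure(0L, flagged = TRUE))
  sign_e <- if (objective == "H+E") 1 else -1
  best_val <- -Inf; best_n <- 0L
  for (n in 0:(e - 1)) {
    kept <- w0[seq_len(e - n)]
    removed <- if (n > 0) w0[(e - n + 1):e] else numeric(0)
    wh <- kept / sum(kept)
    H <- -sum(wh * log(wh))
    E <- sum(removed^2) + sum((wh - kept)^2)
    val <- H + sign_e * E
    if (val > best_val + 1e-12) { best_val <- val; best_n <- n }
  }
  as.integer(best_n)
}

GRAPH_PARTITIONS <- list(
  eeg_eeg  = function(i, j) i <= 8 & j <= 8,
  eeg_spo2 = function(i, j) (i <= 8 & j == 10) | (j <= 8 & i == 10),
  eeg_rr   = function(i, j) (i <= 8 & j == 9) | (j <= 8 & i == 9),
  all      = function(i, j) rep(TRUE, length(i))
)

#' Per-epoch topology feature chart of a coupling graph
#'
#' Evaluates path length, efficiency, clustering, eccentricity and the number
#' of superfluous connections on every (valid) chart sample of the
#' partition-restricted adjacency, then aggregates mean and SD within the
#' pre/during/post epochs.
#'
#' @param graph a [build_coupling_graph()] result.
#' @param epochs an `"epoch_set"` from [segment_epochs()].
#' @param config a [pipeline_config()].
#' @return named numeric vector
#'   `net_<partition>__<index>__<mu|sd>__<epoch>` (120 values).
#' @export
topology_features <- function(graph, epochs, config = pipeline_config()) {
  idx_names <- c("path_length", "efficiency", "clustering", "eccentricity", "n_sup")
  tt <- graph$chart_times
  valid <- graph$chart_valid
  part_masks <- lapply(GRAPH_PARTITIONS, function(f) {
    f(graph$pairs[1, ], graph$pairs[2, ])
  })
  charts <- lapply(part_masks, function(m) {
    matrix(NA_real_, length(tt), 5, dimnames = list(NULL, idx_names))
  })
  M <- length(graph$nodes)
  for (k in which(valid)) {
    w <- graph$chart_adj[k, ]
    for (p in seq_along(part_masks)) {
      wp <- w * part_masks[[p]]
      A <- matrix(0, M, M)
      A[t(graph$pairs)] <- wp
      A <- A + t(A)
      charts[[p]][k, 1:4] <- graph_indices(A)
      charts[[p]][k, 5] <- n_superfluous(A, config$n_sup_objective)
    }
  }
  out <- numeric(0)
  for (p in seq_along(charts)) {
    pname <- names(GRAPH_PARTITIONS)[p]
    for (ep in c("pre", "during", "post")) {
      sl <- epochs[[ep]]
      inep <- valid & tt >= sl[1] & tt < sl[2]
      for (ix in idx_names) {
        v <- charts[[p]][inep, ix]
        v <- v[is.finite(v)]
        st <- if (length(v) >= 2) c(mean(v), sd(v))
              else if (length(v) == 1) c(v, 0)
              else c(NA_real_, NA_real_)
        names(st) <- sprintf("net_%s__%s__%s__%s", pname, ix, c("mu", "sd"), ep)
        out <- c(out, st)
      }
    }
  }
  out
}
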