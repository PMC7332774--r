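test_that("coherence limits: self-coherence and quarter-period lag", {
  set.seed(14)
  x <- rnorm(1024)
  C <- wavelet_coherence(x, x, rate = 8)
  expect_lt(max(abs(Mod(C$coherence) - 1)), 1e-6)
  expect_lt(max(abs(Im(C$coherence))), 1e-6)
  expect_error(wavelet_coherence(x, x[-1]), "equal length")
  t <- (0:4095) / 8
  Cl <- wavelet_coherence(sin(2 * pi * 0.05 * t),
                          sin(2 * pi * 0.05 * t - pi / 2), rate = 8,
                          freqs = neostress:::dyadic_freqs(0.033, 0.08, 6))
  bc <- band_coupling(Cl, c(0.033, 0.08))
  expect_gte(max(bc, na.rm = TRUE), 0.9)
  expect_gte(mean(bc, na.rm = TRUE), 0.9)
})

test_that("band coupling equals the brute-force max over in-band scales", {
  set.seed(15)
  C <- wavelet_coherence(rnorm(1024), rnorm(1024), rate = 8)
  band <- c(0.1, 0.5)
  got <- band_coupling(C, band)
  sel <- C$freqs > band[1] & C$freqs <= band[2]
  im <- abs(Im(C$coherence[, sel, drop = FALSE]))
  im[C$coi_excl[, sel, drop = FALSE]] <- NA
  want <- apply(im, 1, function(r) if (all(is.na(r))) NA else max(r, na.rm = TRUE))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(band_coupling(C, c(10, 20)), "band")
})

test_that("AAFT surrogates keep the amplitude multiset and spectrum shape", {
  set.seed(16)
  x <- as.numeric(stats::filter(rnorm(1024), 0.95, method = "recursive"))
  s1 <- aaft_surrogate(x, seed = 1)
  expect_identical(sort(s1), sort(x))
  expect_false(identical(s1, aaft_surrogate(x, seed = 2)))
  spec <- function(v) Mod(fft(v - mean(v)))[2:256]
  expect_gt(cor(spec(x), spec(s1)), 0.9)
  expect_error(aaft_surrogate(rep(1, 128)), "constant")
})

test_that("validated coupling separates coupled pairs from identical ones", {
  # identical series: imaginary coherence is zero, never significant
  set.seed(18)
  x <- rnorm(1024)
  v <- validate_coupling(x, x, c(0.08, 0.2), seed = 3)
  expect_false(v$significant)
  expect_equal(v$weight, 0)
  # strongly phase-lagged coupled pair: significant in >= 95% of trials
  hits <- sapply(1:20, function(k) {
    set.seed(700 + k)
    z <- neostress:::rband_analytic(1024, 8, 0.08, 0.2)
    a <- z$re + 0.2 * rnorm(1024)
    b <- z$im + 0.2 * rnorm(1024)
    validate_coupling(a, b, c(0.08, 0.2), seed = 800 + k)$significant
  })
  expect_gte(mean(hits), 0.95)
})

test_that("graph indices match igraph and a scalar Floyd-Warshall oracle", {
  skip_if_not_installed("igraph")
  A1 <- matrix(1, 4, 4); diag(A1) <- 0
  expect_equal(graph_indices(A1),
               c(path_length = 1, efficiency = 1, clustering = 1,
                 eccentricity = 1))
  # 3-node chain: d(A,C) = 1 + 2 = 3, mean over ordered pairs = 2
  A2 <- matrix(0, 3, 3); A2[1, 2] <- A2[2, 1] <- 1; A2[2, 3] <- A2[3, 2] <- 0.5
  gi <- graph_indices(A2)
  expect_equal(gi[["path_length"]], mean(c(1, 2, 3)))
  for (seed in 1:30) {
    A <- random_symmetric_graph(seed, M = 10, density = runif(1, 0.1, 0.9))
    got <- graph_indices(A)
    want <- oracle_graph_indices(A)
    expect_equal(got, want, tolerance = 1e-9, info = paste("seed", seed))
    g <- igraph::graph_from_adjacency_matrix(
      ifelse(A > 0, 1 / A, 0), mode = "undirected", weighted = TRUE)
    D <- igraph::distances(g)
    off <- !diag(TRUE, 10)
    expect_equal(got[["path_length"]],
                 mean(D[off & is.finite(D)]), tolerance = 1e-9)
    expect_equal(got[["efficiency"]],
                 mean(ifelse(is.finite(D), 1 / D, 0)[off]), tolerance = 1e-9)
  }
  expect_error(graph_indices(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("n_superfluous equals exhaustive objective evaluation", {
  A1 <- matrix(0, 3, 3); A1[1, 2] <- A1[2, 1] <- 0.7
  expect_equal(as.integer(n_superfluous(A1)), 0L)
  for (seed in 1:40) {
    A <- random_symmetric_graph(seed + 50, M = 8, density = runif(1, 0.2, 0.9))
    expect_equal(as.integer(n_superfluous(A)), oracle_n_sup(A))
    expect_equal(as.integer(n_superfluous(A, "H-E")), oracle_n_sup(A, "H-E"))
  }
  # duplicated weights: smallest argmax wins
  for (seed in 1:10) {
    set.seed(seed)
    w <- sample(c(0.2, 0.2, 0.5, 0.5, 0.9), 5, replace = TRUE)
    A <- matrix(0, 4, 4)
    A[upper.tri(A)][1:5] <- w
    A <- A + t(A)
    expect_equal(as.integer(n_superfluous(A)), oracle_n_sup(A))
  }
  # permutation invariance
  A <- random_symmetric_graph(99, M = 10)
  base <- as.integer(n_superfluous(A))
  for (k in 1:20) {
    p <- sample(10)
    expect_equal(as.integer(n_superfluous(A[p, p])), base)
  }
})

test_that("coupling graph isolates an injected single-pair coupling", {
  cfg <- pipeline_config()
  hits <- sapply(1:6, function(k) {
    set.seed(40 + k)
    n <- 1440
    z <- neostress:::rband_analytic(n, 8, 0.08, 0.2)
    nodes <- matrix(rnorm(n * 10), n, 10)
    nodes[, 1] <- z$re + 0.15 * rnorm(n)   # EEG1
    nodes[, 9] <- z$im + 0.15 * rnorm(n)   # HRV, quarter-period lagged
    g <- build_coupling_graph(nodes, c(0.08, 0.2), cfg, seed = 60 + k)
    pair_idx <- which(g$pairs[1, ] == 1 & g$pairs[2, ] == 9)
    g$significance_mask[pair_idx]
  })
  expect_gte(mean(hits), 0.9)
  # structural invariants of the chart adjacency
  set.seed(47)
  nodes <- matrix(rnorm(1440 * 10), 1440, 10)
  g <- build_coupling_graph(nodes, c(0.08, 0.2), cfg, seed = 70)
  expect_equal(g$weights, t(g$weights))
  expect_true(all(diag(g$weights) == 0))
  expect_true(all(g$weights >= 0 & g$weights <= 1))
  A <- neostress:::chart_adjacency(g, which(g$chart_valid)[1])
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
})

test_that("topology features: partitions, constancy and the slice oracle", {
  cfg <- pipeline_config()
  set.seed(48)
  nodes <- matrix(rnorm(1440 * 10), 1440, 10)
  z <- neostress:::rband_analytic(1440, 8, 0.08, 0.2)
  nodes[, 1] <- z$re + 0.1 * rnorm(1440)
  nodes[, 9] <- z$im + 0.1 * rnorm(1440)
  g <- build_coupling_graph(nodes, c(0.08, 0.2), cfg, seed = 90)
  ep <- structure(list(window = c(0, 180), pre = c(0, 80), during = c(80, 100),
                       post = c(100, 180)), class = "epoch_set")
  tf <- topology_features(g, ep, cfg)
  expect_length(tf, 4 * 5 * 2 * 3)
  # the EEG-EEG partition of a graph whose only edge is EEG1-HRV is empty
  only19 <- g
  only19$significance_mask[] <- FALSE
  only19$chart_adj[] <- 0
  pair_idx <- which(g$pairs[1, ] == 1 & g$pairs[2, ] == 9)
  only19$chart_adj[, pair_idx] <- 0.5
  tf2 <- topology_features(only19, ep, cfg)
  eeg_eeg <- tf2[grepl("^net_eeg_eeg__(path_length|efficiency|clustering)", names(tf2))]
  expect_true(all(is.na(eeg_eeg) | eeg_eeg == 0))
  # time-constant adjacency: all SDs are 0
  sds <- tf2[grepl("__sd__", names(tf2))]
  expect_true(all(is.na(sds) | sds == 0))
  # full partition equals recomputing indices on the dense adjacency
  k <- which(g$chart_valid)[5]
  A <- neostress:::chart_adjacency(g, k)
  expect_equal(unname(graph_indices(A)), unname(oracle_graph_indices(A)),
               tolerance = 1e-9)
})
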