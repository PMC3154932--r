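test_that("series_acf is the biased estimator with acf[0] = 1", {
  set.seed(1)
  x <- rnorm(500)
  a <- series_acf(x, 20)
  expect_equal(a[1], 1)
  # direct-oracle check of the biased estimator at a few lags
  xc <- x - mean(x)
  for (tau in c(1, 5, 20)) {
    oracle <- sum(xc[1:(500 - tau)] * xc[(tau + 1):500]) / sum(xc^2)
    expect_equal(a[tau + 1], oracle, tolerance = 1e-12)
  }
  s <- toy_series(4000, p = 0, k = 1 / 8, seed = 2)
  expect_gt(series_acf(s, 10)[9], 0.95)          # lag 8 of the period-8 series
  # white-noise null band at 3/sqrt(L)
  w <- series_acf(rnorm(1e4), 50)[-1]
  expect_gte(mean(abs(w) < 3 / sqrt(1e4)), 0.95)
  expect_error(series_acf(rep(1, 50), 5), "constant")
  expect_error(series_acf(1:50, 50), "maxlag")
})

test_that("periodogram satisfies Parseval and resolves sinusoids", {
  set.seed(3)
  for (L in c(256, 1001)) {
    x <- rnorm(L)
    p <- periodogram(x)
    expect_lt(abs(sum(p$power) - mean((x - mean(x))^2)), 1e-10)
  }
  L <- 512
  x <- sin(2 * pi * 32 * seq_len(L) / L)
  p <- periodogram(x)
  expect_equal(p$freq[which.max(p$power)], 32 / L)
  expect_gt(max(p$power) / median(p$power), 100)
  # toy endpoints: sharp line at frequency k for p = 0, flat for p = 1
  sp0 <- periodogram(toy_series(4096, 0, k = 1 / 8, seed = 4))
  expect_equal(sp0$freq[which.max(sp0$power)], 1 / 8)
  sp1 <- periodogram(toy_series(4096, 1, k = 1 / 8, seed = 5))
  expect_lt(max(sp1$power) / median(sp1$power), 20)
})

test_that("spectral_slope recovers power-law exponents", {
  f <- seq(0.001, 0.5, length.out = 200)
  expect_equal(spectral_slope(data.frame(freq = f, power = f^-2), c(0, 0.5)),
               -2, tolerance = 0.01)
  set.seed(6)
  expect_lt(abs(spectral_slope(periodogram(rnorm(1e5)), c(0.001, 0.5))), 0.2)
  expect_error(spectral_slope(data.frame(freq = f[1:5], power = f[1:5]),
                              c(0, 1)), "fewer than 10")
})

test_that("strengths sum weights in each direction", {
  net <- forward_map(toy_series(5000, 0.3, 0.1, seed = 7), 10)
  st <- strengths(net)
  expect_equal(st$out_strength, rep(1, 10))
  expect_equal(sum(st$in_strength), sum(st$out_strength))
  ring <- fixture_network("ring", 6)
  expect_equal(strengths(ring)$in_strength, rep(1, 6))
})

test_that("shortest paths under inverted weights match independent oracles", {
  # ring of unit weights: lengths 1..Q-1, each occurring Q times
  ring <- fixture_network("ring", 7)
  sp <- shortest_path_distribution(ring)
  expect_identical(sp$n_unreachable, 0L)
  expect_equal(sort(unique(sp$lengths)), 1:6)
  expect_true(all(table(sp$lengths) == 7))
  # two-node chain with w = 0.5
  W2 <- matrix(c(0, 0.5, 0, 0), 2, byrow = TRUE)
  expect_equal(shortest_path_distribution(W2)$lengths, 2)
  expect_identical(shortest_path_distribution(W2)$n_unreachable, 1L)
  # random instances vs igraph and vs exhaustive path enumeration
  for (seed in 1:3) {
    W <- random_markov_matrix(8, seed = seed)
    W[W < 0.1] <- 0                                # some sparsity
    mine <- shortest_path_distribution(W)
    inv <- ifelse(W > 0, 1 / W, 0)
    g <- igraph::graph_from_adjacency_matrix(inv, mode = "directed",
                                             weighted = TRUE)
    d <- igraph::distances(g, mode = "out")
    expect_equal(sort(mine$lengths),
                 sort(d[row(d) != col(d) & is.finite(d)]))
    brute <- brute_force_shortest_paths(W)
    expect_equal(sort(mine$lengths),
                 sort(brute[row(brute) != col(brute) & is.finite(brute)]))
  }
})

test_that("modularity matches closed forms, bounds and igraph", {
  W <- random_markov_matrix(9, seed = 4)
  expect_equal(network_modularity(W, rep(1L, 9)), 0)
  blocks <- fixture_network("modular", 12, m = 2, p_in = 0.9, p_out = 0,
                            seed = 5, connected = FALSE)
  expect_equal(network_modularity(blocks, rep(1:2, each = 6)), 0.5)
  set.seed(8)
  for (i in 1:10) {
    mem <- sample.int(3, 9, replace = TRUE)
    q <- network_modularity(W, mem)
    expect_true(q >= -1 && q <= 1)
    # igraph as the independent oracle on the symmetrized graph
    A <- (W + t(W)) / 2
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE, diag = TRUE)
    expect_equal(q, igraph::modularity(g, mem, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
  expect_error(network_modularity(W, rep(1L, 4)), "every node")
})

test_that("community detection recovers planted blocks", {
  blocks <- fixture_network("modular", 12, m = 2, p_in = 0.9, p_out = 0,
                            seed = 6, connected = FALSE)
  mem <- detect_communities(blocks)
  expect_identical(length(unique(mem)), 2L)
  expect_identical(length(unique(mem[1:6])), 1L)
  expect_identical(length(unique(mem[7:12])), 1L)
  # weakly coupled planted partition: >= 90% pairwise (Rand) agreement
  truth <- rep(1:2, each = 10)
  rand_index <- function(a, b) {
    pairs <- combn(length(a), 2)
    same_a <- a[pairs[1, ]] == a[pairs[2, ]]
    same_b <- b[pairs[1, ]] == b[pairs[2, ]]
    mean(same_a == same_b)
  }
  agreements <- sapply(1:10, function(s) {
    net <- fixture_network("modular", 20, m = 2, p_in = 0.8, p_out = 0.01,
                           seed = 100 + s)
    rand_index(detect_communities(net), truth)
  })
  expect_gte(mean(agreements >= 0.9), 0.9)
})

test_that("the shuffle null separates structured from exchangeable series", {
  # an i.i.d. series is its own null: observed within 3 null sd of the mean
  x <- toy_series(5000, p = 1, k = 0.1, seed = 9)
  ns <- modularity_shuffle_null(x, Q = 20, R = 10, seed = 10)
  null_sd <- ns$null_se * sqrt(ns$n_replicates)
  expect_lt(abs(ns$observed - ns$null_mean), 3 * null_sd)
  expect_gte(ns$null_se, 0)
})

test_that("compare_generations reports zero for identical inputs and separates regimes", {
  s <- toy_series(2000, 0.1, 0.05, seed = 11)
  st <- series_stats(s, maxlag = 50)
  d <- compare_generations(st, st)
  expect_true(all(unlist(d) == 0))
  ns <- network_stats(forward_map(s, 10))
  dn <- compare_generations(ns, ns)
  expect_true(all(unlist(dn) == 0))
  # arc-weight distributions of the two toy endpoints are far apart
  n0 <- network_stats(forward_map(toy_series(1e4, 0, 1 / 20, seed = 12), 20))
  n1 <- network_stats(forward_map(toy_series(1e4, 1, 1 / 20, seed = 13), 20))
  expect_gt(compare_generations(n0, n1)$arc_weight_ks, 0.5)
  st2 <- series_stats(s[1:1000], maxlag = 40)
  expect_error(compare_generations(st, st2), "lag grids")
  expect_error(compare_generations(st, ns), "both")
})

test_that("periodogram peakedness decreases monotonically with toy noise", {
  ratios <- sapply(c(0, 0.1, 0.3, 1), function(p) {
    mean(sapply(1:10, function(s) {
      sp <- periodogram(toy_series(4096, p, k = 1 / 8, seed = 1000 * p + s))
      max(sp$power) / median(sp$power)
    }))
  })
  expect_true(all(diff(ratios) < 0))
})
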