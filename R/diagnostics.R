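# Statistics quantifying round-trip fidelity: time-series measures (ACF,
# periodogram, spectral slope, value distribution) and network measures
# (strengths, arc weights, inverse-weight shortest paths, modularity with a
# value-shuffle null), plus first- vs second-generation comparators.

#' Autocorrelation function (biased estimator)
#'
#' Mean-removed autocovariance at lags `0..maxlag` divided by the lag-0
#' autocovariance (the standard biased estimator, dividing every lag by `L`).
#'
#' @param series numeric vector.
#' @param maxlag largest lag, `maxlag < length(series)`.
#' @return Numeric vector of length `maxlag + 1` (lags `0..maxlag`);
#'   element 1 is always 1.
#' @export
series_acf <- function(series, maxlag) {
  check_finite_numeric(series, "series")
  L <- length(series)
  if (maxlag >= L) stop("maxlag must be smaller than the series length")
  if (var(series) == 0) stop("constant series has no autocorrelation")
  as.numeric(acf(series, lag.max = maxlag, plot = FALSE, demean = TRUE,
                 type = "correlation")$acf)
}

#' Periodogram of a time series
#'
#' Squared modulus of the discrete Fourier transform of the mean-removed
#' series over the positive Fourier frequencies `k/L`, `k = 1..floor(L/2)`,
#' normalized (one-sided) so that the total power equals the biased sample
#' variance exactly (Parseval).
#'
#' @param series numeric vector of length `L >= 4`.
#' @return A data.frame with columns `freq` (cycles per step) and `power`.
#' @export
periodogram <- function(series) {
  check_finite_numeric(series, "series")
  L <- length(series)
  if (L < 4L) stop("need at least 4 points")
  x <- series - mean(series)
  X <- fft(x)
  half <- L %/% 2L
  k <- seq_len(half)
  p <- Mod(X[k + 1L])^2 / L^2
  doubled <- k < L / 2                   # conjugate pairs; Nyquist (even L) not
  p[doubled] <- 2 * p[doubled]
  data.frame(freq = k / L, power = p)
}

#' Spectral slope over a frequency band
#'
#' Least-squares slope of `log(power)` against `log(frequency)` over the
#' frequencies in `(band[1], band[2]]`.  Non-positive powers are dropped; at
#' least 10 frequencies must remain.
#'
#' @param spectrum a data.frame as returned by [periodogram()].
#' @param band numeric length-2 vector `(lo, hi)` of frequencies.
#' @return The scalar slope.
#' @export
spectral_slope <- function(spectrum, band) {
  sel <- spectrum$freq > band[1] & spectrum$freq <= band[2] & spectrum$power > 0
  if (sum(sel) < 10L) stop("fewer than 10 usable frequencies in band")
  fit <- lm(log(power) ~ log(freq), data = spectrum[sel, ])
  unname(coef(fit)[2L])
}

#' Node in- and out-strengths
#'
#' `in_strength(i) = sum_j W[j, i]`, `out_strength(i) = sum_j W[i, j]`.  For a
#' Markov network every non-dangling out-strength is 1.
#'
#' @param W a [markov_network] or square matrix.
#' @return A list with numeric vectors `in_strength` and `out_strength`.
#' @export
strengths <- function(W) {
  W <- as_weight_matrix(W)
  list(in_strength = colSums(W), out_strength = rowSums(W))
}

#' Shortest-path-length distribution under inverted weights
#'
#' Arc length is the inverse weight `1/W[i, j]` (so strong transitions are
#' short); path length is the minimum sum of inverted weights over directed
#' paths.  Computed for all ordered node pairs by Floyd-Warshall; unreachable
#' pairs are excluded from the multiset and counted separately.
#'
#' @param W a [markov_network] or square non-negative matrix.
#' @return A list with `lengths` (finite path lengths over ordered pairs
#'   `i != j`) and `n_unreachable` (number of unreachable ordered pairs).
#' @export
shortest_path_distribution <- function(W) {
  W <- as_weight_matrix(W)
  if (any(W < 0)) stop("weights must be non-negative")
  N <- nrow(W)
  D <- matrix(Inf, N, N)
  nz <- W > 0
  D[nz] <- 1 / W[nz]
  diag(D) <- 0
  for (k in seq_len(N))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  off <- D[row(D) != col(D)]
  list(lengths = off[is.finite(off)], n_unreachable = sum(!is.finite(off)))
}

#' Newman-Girvan modularity of a partition
#'
#' The directed weight matrix is symmetrized (`(W + t(W)) / 2`) and normalized
#' by its total weight; modularity is `sum_m (e_mm - a_m^2)` where `e_mm` is
#' the fraction of weight inside community `m` and `a_m` the fraction of
#' weight attached to it.
#'
#' @param W a [markov_network] or square non-negative matrix.
#' @param membership integer community label per node (all nodes covered).
#' @return Scalar modularity in `[-1, 1]`.
#' @export
network_modularity <- function(W, membership) {
  W <- as_weight_matrix(W)
  N <- nrow(W)
  membership <- as.integer(membership)
  if (length(membership) != N || anyNA(membership))
    stop("membership must label every node")
  A <- (W + t(W)) / 2
  total <- sum(A)
  if (total <= 0) stop("network has no weight")
  k <- rowSums(A)
  q <- 0
  for (com in unique(membership)) {
    idx <- membership == com
    if (!any(idx)) stop("empty community")
    e <- sum(A[idx, idx, drop = FALSE]) / total
    a <- sum(k[idx]) / total
    q <- q + e - a^2
  }
  q
}

#' Detect communities by greedy modularity maximization
#'
#' Greedy agglomerative modularity optimization (fast-greedy) on the
#' symmetrized weight matrix with self-loops removed.  Deterministic; the
#' `seed` argument is accepted for interface uniformity.
#'
#' @param W a [markov_network] or square non-negative matrix.
#' @param seed integer seed (the algorithm is deterministic; kept for API
#'   symmetry with the stochastic operations).
#' @return Integer membership vector (community label per node).
#' @export
detect_communities <- function(W, seed = NULL) {
  W <- as_weight_matrix(W)
  A <- (W + t(W)) / 2
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  with_seed(seed, {
    cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
    as.integer(igraph::membership(cl))
  })
}

#' Modularity of a quantile graph against a value-shuffle null
#'
#' Forward-maps the series, detects communities and computes the observed
#' modularity; then repeats on `R` random permutations of the values (which
#' keep the value distribution but destroy temporal order) to obtain the null
#' mean and standard error.
#'
#' @param series numeric time series.
#' @param Q number of quantiles of the forward map.
#' @param R number of shuffle replicates (>= 2).
#' @param seed master integer seed.
#' @inheritParams normalize_rows
#' @return A list with `observed`, `null_mean`, `null_se`, `n_replicates` and
#'   `null_values`.
#' @export
modularity_shuffle_null <- function(series, Q, R = 10L, seed = NULL,
                                    dangling_policy = "error") {
  R <- as.integer(R)
  if (R < 2L) stop("need at least 2 shuffle replicates")
  net <- forward_map(series, Q, dangling_policy)
  observed <- network_modularity(net, detect_communities(net))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, R))
  null_values <- vapply(seeds, function(s) {
    sh <- shuffle_series(series, seed = s)
    n <- forward_map(sh, Q, dangling_policy)
    network_modularity(n, detect_communities(n))
  }, numeric(1))
  list(observed = observed,
       null_mean = mean(null_values),
       null_se = sd(null_values) / sqrt(R),
       n_replicates = R,
       null_values = null_values)
}

#' Summary statistics of a time series
#'
#' The per-generation bundle compared by [compare_generations()]:
#' autocorrelation function, periodogram, value histogram (density, fixed
#' breaks) and the raw sorted values (for Kolmogorov-Smirnov distances).
#'
#' @param series numeric vector.
#' @param maxlag largest ACF lag (default 100, capped at `L - 1`).
#' @param breaks histogram break points; `NULL` for 20 equal bins over the
#'   value range.  Pass common breaks when comparing two series.
#' @return An object of class `series_stats`.
#' @export
series_stats <- function(series, maxlag = 100L, breaks = NULL) {
  L <- length(series)
  maxlag <- min(as.integer(maxlag), L - 1L)
  if (is.null(breaks))
    breaks <- seq(min(series), max(series), length.out = 21L)
  h <- graphics::hist(series, breaks = breaks, plot = FALSE)
  structure(list(acf = series_acf(series, maxlag),
                 spectrum = periodogram(series),
                 histogram = list(breaks = h$breaks, density = h$density),
                 values = sort(series)),
            class = "series_stats")
}

#' Summary statistics of a network
#'
#' In/out-strengths, the multiset of nonzero arc weights, finite
#' inverse-weight shortest-path lengths, and the modularity of the detected
#' community partition.
#'
#' @param W a [markov_network] or square non-negative matrix.
#' @return An object of class `network_stats`.
#' @export
network_stats <- function(W) {
  W <- as_weight_matrix(W)
  st <- strengths(W)
  sp <- shortest_path_distribution(W)
  mem <- detect_communities(W)
  structure(list(in_strength = st$in_strength,
                 out_strength = st$out_strength,
                 arc_weights = W[W > 0],
                 path_lengths = sp$lengths,
                 n_unreachable = sp$n_unreachable,
                 membership = mem,
                 modularity = network_modularity(W, mem)),
            class = "network_stats")
}

# two-sample Kolmogorov-Smirnov statistic (max ECDF gap)
ks_distance <- function(a, b) {
  g <- sort(unique(c(a, b)))
  Fa <- findInterval(g, sort(a)) / length(a)
  Fb <- findInterval(g, sort(b)) / length(b)
  max(abs(Fa - Fb))
}

# L1 distance between bin proportions of two samples over common breaks
hist_l1 <- function(a, b, nbins = 20L) {
  rng <- range(c(a, b))
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  pa <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins) / length(a)
  pb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins) / length(b)
  sum(abs(pa - pb))
}

# Mean |log10 relative power| difference over logarithmic frequency bins.
# Power is normalized by total power and floored at 1e-6 (a 60 dB dynamic
# range): components more than 60 dB below the total are treated as absent,
# so numerically-zero spectral floors of exactly periodic signals do not
# register as differences.
log_spectrum_l1 <- function(s1, s2, nbins = 30L, floor_rel = 1e-6) {
  if (nrow(s1) != nrow(s2) || max(abs(s1$freq - s2$freq)) > 1e-12)
    stop("spectra are on different frequency grids")
  lf <- log10(s1$freq)
  bins <- cut(lf, breaks = seq(min(lf), max(lf), length.out = nbins + 1L),
              include.lowest = TRUE)
  rel1 <- pmax(s1$power / sum(s1$power), floor_rel)
  rel2 <- pmax(s2$power / sum(s2$power), floor_rel)
  m1 <- tapply(log10(rel1), bins, mean)
  m2 <- tapply(log10(rel2), bins, mean)
  ok <- !is.na(m1) & !is.na(m2)
  mean(abs(m1[ok] - m2[ok]))
}

#' Compare first- and second-generation statistics
#'
#' For two [series_stats()] bundles: maximum absolute ACF difference (same lag
#' grid required), L1 distance of log-binned log-spectra (same frequency grid
#' required), and the Kolmogorov-Smirnov distance of the value distributions.
#' For two [network_stats()] bundles: KS distance of arc weights and L1
#' histogram distances of in-strengths, arc weights and shortest-path lengths.
#' Identical inputs give all-zero distances.
#'
#' @param stats1,stats2 two objects of the same class, `series_stats` or
#'   `network_stats`.
#' @return A named list of scalar distances.
#' @export
compare_generations <- function(stats1, stats2) {
  if (inherits(stats1, "series_stats") && inherits(stats2, "series_stats")) {
    if (length(stats1$acf) != length(stats2$acf))
      stop("ACF lag grids differ")
    list(acf_max_abs = max(abs(stats1$acf - stats2$acf)),
         spectrum_l1 = log_spectrum_l1(stats1$spectrum, stats2$spectrum),
         value_ks = ks_distance(stats1$values, stats2$values))
  } else if (inherits(stats1, "network_stats") &&
             inherits(stats2, "network_stats")) {
    list(in_strength_l1 = hist_l1(stats1$in_strength, stats2$in_strength),
         arc_weight_l1 = hist_l1(stats1$arc_weights, stats2$arc_weights),
         arc_weight_ks = ks_distance(stats1$arc_weights, stats2$arc_weights),
         path_length_l1 = hist_l1(stats1$path_lengths, stats2$path_lengths))
  } else stop("stats1 and stats2 must both be series_stats or network_stats")
}

#' Round-trip experiment over the toy ensemble
#'
#' For each noise probability `p`: generate `realizations` first-generation
#' series, forward-map them at `Q` quantiles, apply the inverse map with the
#' known quantile correspondence to obtain second-generation series of the
#' same length, forward-map those into second-generation networks, and record
#' every [compare_generations()] distance between paired generations, plus the
#' same distances between independent first-generation pairs (the resampling
#' null bands).
#'
#' @param p_values noise probabilities of the toy ensemble.
#' @param realizations independent realizations per `p`.
#' @param length series length `L`.
#' @param Q number of quantiles.
#' @param k toy increment (default `1/Q` so the `p = 0` graph is a ring).
#' @param seed master integer seed.
#' @param maxlag ACF lag range for the series comparison.
#' @return A data.frame with columns `p`, `kind` (`"roundtrip"` pairs
#'   generation 1 with generation 2; `"null"` pairs two independent first
#'   generations), `domain` (`series`/`network`), `metric`, `value`.
#' @export
roundtrip_experiment <- function(p_values = c(0, 0.05, 1), realizations = 10L,
                                 length = 10000L, Q = 50L, k = 1 / Q,
                                 seed = NULL, maxlag = 100L) {
  seeds <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max, 4L * realizations * base::length(p_values)),
    ncol = 4L))
  rows <- list()
  add <- function(p, kind, domain, d) {
    rows[[base::length(rows) + 1L]] <<- data.frame(
      p = p, kind = kind, domain = domain,
      metric = names(d), value = unlist(d, use.names = FALSE))
  }
  ridx <- 0L
  for (p in p_values) {
    gen1 <- vector("list", realizations)
    gen2 <- vector("list", realizations)
    for (r in seq_len(realizations)) {
      ridx <- ridx + 1L
      s1 <- toy_series(length, p = p, k = k, seed = seeds[ridx, 1L])
      g1 <- forward_map(s1, Q)
      inv <- inverse_map(g1, length, seed = seeds[ridx, 2L],
                         partition = g1$partition)
      s2 <- inv$series
      g2 <- forward_map(s2, Q)
      # extra independent first generations for the null bands
      s1b <- toy_series(length, p = p, k = k, seed = seeds[ridx, 3L])
      gen1[[r]] <- list(series = s1, net = g1,
                        series_b = s1b, net_b = forward_map(s1b, Q))
      gen2[[r]] <- list(series = s2, net = g2)
    }
    breaks <- seq(0, 1, length.out = 21L)
    for (r in seq_len(realizations)) {
      ss1 <- series_stats(gen1[[r]]$series, maxlag, breaks)
      ss2 <- series_stats(gen2[[r]]$series, maxlag, breaks)
      ssb <- series_stats(gen1[[r]]$series_b, maxlag, breaks)
      add(p, "roundtrip", "series", compare_generations(ss1, ss2))
      add(p, "null", "series", compare_generations(ss1, ssb))
      ns1 <- network_stats(gen1[[r]]$net)
      ns2 <- network_stats(gen2[[r]]$net)
      nsb <- network_stats(gen1[[r]]$net_b)
      add(p, "roundtrip", "network", compare_generations(ns1, ns2))
      add(p, "null", "network", compare_generations(ns1, nsb))
    }
  }
  do.call(rbind, rows)
}
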