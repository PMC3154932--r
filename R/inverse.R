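# Inverse map: adjacency normalization, simulated-annealing seriation of the
# transition matrix, random-walk path generation and within-quantile emission.

#' Normalize a non-negative adjacency matrix to Markov (row-stochastic) form
#'
#' `W[i, j] = A[i, j] / sum_k A[i, k]`.  For a symmetric 0/1 adjacency this is
#' division by the node degree.  Already row-stochastic input is returned
#' unchanged (up to floating point).  Zero rows are handled per
#' `dangling_policy` as in [normalize_rows()].
#'
#' @param A square non-negative numeric matrix (or a [markov_network], which
#'   is passed through after re-normalization).
#' @inheritParams normalize_rows
#' @return A [markov_network].
#' @export
normalize_adjacency <- function(A, dangling_policy = c("error", "selfloop", "uniform")) {
  dangling_policy <- match.arg(dangling_policy)
  part <- if (inherits(A, "markov_network")) A$partition
  A <- as_weight_matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  check_finite_numeric(c(A), "adjacency entries")
  if (any(A < 0)) stop("adjacency entries must be non-negative")
  if (all(A == 0)) stop("all-zero adjacency matrix")
  N <- nrow(A)
  rs <- rowSums(A)
  W <- matrix(0, N, N)
  ok <- rs > 0
  W[ok, ] <- A[ok, , drop = FALSE] / rs[ok]
  net <- if (any(!ok)) {
    cnt <- W; cnt[!ok, ] <- 0
    # reuse the dangling handling of normalize_rows on the already-normalized rows
    dangling <- which(!ok)
    if (dangling_policy == "error")
      stop(sprintf("dangling node(s) with no outgoing arcs: %s",
                   paste(dangling, collapse = ", ")))
    if (dangling_policy == "selfloop") W[cbind(dangling, dangling)] <- 1
    else W[dangling, ] <- 1 / N
    qn_log("warn", sprintf("repaired %d dangling node(s) with policy '%s'",
                           length(dangling), dangling_policy))
    markov_network(W)
  } else markov_network(W)
  net$partition <- part
  net
}

#' Distance-to-diagonal seriation cost of a node ordering
#'
#' For an ordering `order` (position -> node), every matrix element is
#' weighted by its distance to the diagonal:
#' `C(order) = (1/N) * sum_{u,v} W[order[u], order[v]] * |u - v|`.
#' Orderings that concentrate large weights near the diagonal have low cost;
#' the cost is invariant under reversal of the ordering.
#'
#' @param W a [markov_network] or square non-negative matrix.
#' @param order integer permutation of `1..N` mapping position to node.
#' @return The scalar cost.
#' @export
ordering_cost <- function(W, order) {
  W <- as_weight_matrix(W)
  N <- nrow(W)
  order <- as.integer(order)
  if (length(order) != N || anyNA(order) || !setequal(order, seq_len(N)))
    stop("order must be a permutation of 1..N matching dim(W)")
  pos <- integer(N)
  pos[order] <- seq_len(N)
  sum(W * abs(outer(pos, pos, "-"))) / N
}

# Sparse cost evaluator used inside the annealer: cost as a function of the
# position vector pos (node -> position), over the nonzero entries only.
make_cost_fun <- function(W) {
  nz <- which(W != 0, arr.ind = TRUE)
  off <- nz[nz[, 1] != nz[, 2], , drop = FALSE]   # diagonal contributes 0
  ii <- off[, 1]; jj <- off[, 2]; ww <- W[off]
  N <- nrow(W)
  function(pos) sum(ww * abs(pos[ii] - pos[jj])) / N
}

#' Propose a segment move for the seriation annealer
#'
#' Picks a segment of contiguous positions (cyclically) and a new position for
#' its first node, both uniformly at random; the remaining nodes keep their
#' relative order and the segment is reinserted.  The segment width is
#' `1 + floor(|g|)` with `g` drawn from a zero-mean Gaussian whose variance is
#' `width_scale * theta_rel * N`, clipped to `[1, N - 1]`: at low relative
#' temperature only single-node moves are proposed.
#'
#' Uses the current RNG stream (seed it with `set.seed()` for reproducibility).
#'
#' @param order integer permutation of `1..N` (position -> node).
#' @param theta_rel relative temperature in `(0, 1]`.
#' @param width_scale proportionality constant of the Gaussian width (default 1).
#' @return A permutation of the same length (possibly identical to `order`).
#' @export
propose_segment_move <- function(order, theta_rel, width_scale = 1) {
  N <- length(order)
  if (N < 2L) return(order)
  g <- rnorm(1, mean = 0, sd = sqrt(width_scale * theta_rel * N))
  w <- min(max(1L, 1L + as.integer(floor(abs(g)))), N - 1L)
  s <- sample.int(N, 1L)
  seg_pos <- (s - 1L + seq_len(w) - 1L) %% N + 1L
  seg <- order[seg_pos]
  rest <- order[-seg_pos]
  p <- sample.int(N, 1L)
  ins <- (p - 1L) %% (length(rest) + 1L)         # 0-based slot among the rest
  append(rest, seg, after = ins)
}

#' Annealing schedule for the seriation search
#'
#' @param initial_temperature positive start temperature; `NULL` (default)
#'   auto-calibrates so that roughly half of the uphill probe moves would be
#'   accepted over 200 probe proposals.
#' @param cooling_factor geometric cooling factor in (0, 1); default 0.995.
#' @param moves_per_level proposals attempted per temperature level;
#'   `NULL` defaults to `N^2`.
#' @param min_temperature_ratio stop once the temperature falls below this
#'   fraction of the initial temperature (default 1e-6).  The search also
#'   stops after a full level with zero accepted (order-changing) moves.
#' @param segment_width_scale Gaussian width constant of
#'   [propose_segment_move()].
#' @param seed integer seed of the annealing RNG stream.
#' @return An object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(initial_temperature = NULL,
                               cooling_factor = 0.995,
                               moves_per_level = NULL,
                               min_temperature_ratio = 1e-6,
                               segment_width_scale = 1,
                               seed = NULL) {
  if (!is.null(initial_temperature) && initial_temperature <= 0)
    stop("initial_temperature must be positive")
  if (cooling_factor <= 0 || cooling_factor >= 1)
    stop("cooling_factor must lie in (0, 1)")
  if (!is.null(moves_per_level) && moves_per_level < 1)
    stop("moves_per_level must be positive")
  if (min_temperature_ratio <= 0) stop("min_temperature_ratio must be positive")
  if (segment_width_scale <= 0) stop("segment_width_scale must be positive")
  structure(list(initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 moves_per_level = moves_per_level,
                 min_temperature_ratio = min_temperature_ratio,
                 segment_width_scale = segment_width_scale,
                 seed = seed),
            class = "annealing_schedule")
}

#' Seriate a weight matrix by simulated annealing
#'
#' Minimizes the distance-to-diagonal cost [ordering_cost()] over node
#' orderings with segment moves ([propose_segment_move()]) and Metropolis
#' acceptance: downhill moves always accepted, uphill moves with probability
#' `exp(-dC / Theta)` under geometric cooling.  Returns the best ordering ever
#' visited; deterministic given `schedule$seed`.
#'
#' @param W a [markov_network] or square non-negative matrix, `N >= 2`.
#' @param schedule an [annealing_schedule()].
#' @param init optional initial ordering (default identity).
#' @return A list with `order` (best permutation, position -> node), `cost`
#'   (its cost), `initial_cost`, and `levels` (temperature levels run).
#' @export
anneal_ordering <- function(W, schedule = annealing_schedule(), init = NULL) {
  W <- as_weight_matrix(W)
  N <- nrow(W)
  if (N < 2L) stop("need at least two nodes")
  if (!inherits(schedule, "annealing_schedule"))
    stop("schedule must be an annealing_schedule")
  cost_of <- make_cost_fun(W)
  cur <- if (is.null(init)) seq_len(N) else as.integer(init)
  if (!setequal(cur, seq_len(N))) stop("init must be a permutation of 1..N")
  pos <- integer(N); pos[cur] <- seq_len(N)
  cur_cost <- cost_of(pos)
  best <- cur; best_cost <- cur_cost; initial_cost <- cur_cost
  moves <- schedule$moves_per_level
  if (is.null(moves)) moves <- N * N
  wscale <- schedule$segment_width_scale

  run <- function() {
    # calibrate initial temperature: ~50% acceptance of uphill probe moves
    theta0 <- schedule$initial_temperature
    if (is.null(theta0)) {
      up <- numeric(0)
      for (i in seq_len(200L)) {
        cand <- propose_segment_move(cur, 1, wscale)
        cpos <- integer(N); cpos[cand] <- seq_len(N)
        d <- cost_of(cpos) - cur_cost
        if (d > 0) up <- c(up, d)
      }
      theta0 <- if (length(up)) mean(up) / log(2) else 1
    }
    theta <- theta0
    levels <- 0L
    repeat {
      accepted <- 0L
      for (m in seq_len(moves)) {
        cand <- propose_segment_move(cur, theta / theta0, wscale)
        if (identical(cand, cur)) next
        cpos <- integer(N); cpos[cand] <- seq_len(N)
        cand_cost <- cost_of(cpos)
        d <- cand_cost - cur_cost
        if (d <= 0 || runif(1) < exp(-d / theta)) {
          cur <<- cand; cur_cost <<- cand_cost
          accepted <- accepted + 1L
          if (cand_cost < best_cost) { best <<- cand; best_cost <<- cand_cost }
        }
      }
      levels <- levels + 1L
      qn_log("debug", sprintf(
        "level %d: theta=%.3g cur=%.6g best=%.6g acc=%.2f",
        levels, theta, cur_cost, best_cost, accepted / moves))
      theta <- theta * schedule$cooling_factor
      if (theta < schedule$min_temperature_ratio * theta0 || accepted == 0L)
        break
    }
    levels
  }
  levels <- with_seed(schedule$seed, run())
  list(order = best, cost = best_cost, initial_cost = initial_cost,
       levels = levels)
}

#' Random walk on a Markov network
#'
#' Starting from `start` (uniform over nodes when `NULL`), successive nodes
#' are drawn from the current node's row of transition probabilities, for a
#' path of exactly `length` nodes.
#'
#' @param W a [markov_network] or row-stochastic matrix.
#' @param length number of nodes in the path (L >= 1).
#' @param seed integer seed (optional).
#' @param start starting node in `1..N`, or `NULL` for uniform choice.
#' @return Integer vector of node indices of length `length`.
#' @export
random_walk <- function(W, length, seed = NULL, start = NULL) {
  W <- as_weight_matrix(W)
  N <- nrow(W)
  L <- as.integer(length)
  if (L < 1L) stop("length must be at least 1")
  rs <- rowSums(W)
  live <- abs(rs - 1) < 1e-8
  if (!all(live | rs == 0))
    stop("W must be row-stochastic (rows summing to 1, or empty)")
  cum <- t(apply(W, 1L, cumsum))
  with_seed(seed, {
    path <- integer(L)
    cur <- if (is.null(start)) sample.int(N, 1L) else as.integer(start)
    if (cur < 1L || cur > N) stop("start node out of range")
    path[1L] <- cur
    if (L > 1L) {
      u <- runif(L - 1L)
      for (t in 2:L) {
        if (!live[cur])
          stop(sprintf("random walk reached dangling node %d", cur))
        cur <- findInterval(u[t - 1L], cum[cur, ], left.open = TRUE) + 1L
        if (cur > N) cur <- N                 # guard against rounding at 1.0
        path[t] <- cur
      }
    }
    path
  })
}

#' Emit a time series from a node path
#'
#' Each visited node `q` emits a value drawn uniformly from its quantile
#' interval `[b_q, b_{q+1})`.  When `partition` is `NULL` the uniform
#' partition of `[0, 1)` into `Q` equal bins is used.  A zero-width bin emits
#' its boundary value.
#'
#' @param path integer node sequence (values in `1..Q`).
#' @param partition a [quantile_partition], or `NULL` for the uniform default.
#' @param Q number of quantiles; required when `partition` is `NULL`
#'   (defaults to `max(path)`).
#' @param seed integer seed (optional).
#' @return Numeric vector of emitted values, one per path node.
#' @export
emit_series <- function(path, partition = NULL, Q = NULL, seed = NULL) {
  path <- as.integer(path)
  if (is.null(partition)) {
    if (is.null(Q)) Q <- max(path)
    partition <- uniform_partition(Q)
  }
  if (any(path < 1L) || any(path > partition$Q))
    stop("path contains nodes outside the partition")
  lo <- partition$boundaries[path]
  hi <- partition$boundaries[path + 1L]
  with_seed(seed, lo + runif(length(path)) * (hi - lo))
}

#' Inverse map: network to time series
#'
#' Normalizes the adjacency matrix to Markov form, associates nodes with
#' quantiles, runs a random walk and emits values uniformly within each
#' visited node's quantile interval.  When a `partition` is supplied (a known
#' node-to-quantile correspondence, e.g. from a previous [forward_map()]),
#' node `q` is identified with quantile `q` and the seriation step is skipped;
#' otherwise the ordering is recovered by [anneal_ordering()] so that the
#' emitted series is as smooth as possible (`reorder = FALSE` keeps the input
#' order).
#'
#' The master `seed` is split into independent sub-streams for annealing,
#' start-node choice, the walk and the emission, so each stage is
#' independently reproducible.
#'
#' @param network a [markov_network] or square non-negative adjacency matrix.
#' @param length length of the emitted series.
#' @param seed master integer seed.
#' @param partition optional [quantile_partition] giving the node-to-quantile
#'   correspondence and emission bins.
#' @param reorder run the annealing seriation (default: only when no
#'   `partition` is supplied).
#' @param schedule an [annealing_schedule()] for the seriation step.
#' @param start starting node, or `NULL` for a uniform random start.
#' @inheritParams normalize_rows
#' @return A list with `series` (numeric), `path` (node indices), `order`
#'   (position -> node permutation used for the quantile association) and
#'   `network` (the normalized [markov_network]).
#' @export
inverse_map <- function(network, length, seed = NULL, partition = NULL,
                        reorder = is.null(partition),
                        schedule = annealing_schedule(),
                        start = NULL,
                        dangling_policy = c("error", "selfloop", "uniform")) {
  dangling_policy <- match.arg(dangling_policy)
  net <- normalize_adjacency(network, dangling_policy)
  N <- net$Q
  if (is.null(partition) && !is.null(net$partition)) partition <- net$partition
  seeds <- split_seed(seed, c("anneal", "start", "walk", "emit"))
  order <- seq_len(N)
  if (reorder) {
    sch <- schedule
    if (is.null(sch$seed)) sch$seed <- seeds$anneal
    order <- anneal_ordering(net, sch)$order
  }
  start_node <- if (is.null(start)) {
    with_seed(seeds$start, sample.int(N, 1L))
  } else as.integer(start)
  path <- random_walk(net, length, seed = seeds$walk, start = start_node)
  pos <- integer(N); pos[order] <- seq_len(N)   # node -> quantile position
  quantile_path <- pos[path]
  series <- emit_series(quantile_path, partition = partition, Q = N,
                        seed = seeds$emit)
  list(series = series, path = path, order = order, network = net)
}
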