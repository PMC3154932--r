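# Forward map: time series -> quantile symbols -> transition counts ->
# row-stochastic weighted directed network.

#' Quantile partition constructor
#'
#' Holds the number of bins `Q`, the `Q + 1` non-decreasing bin boundaries and
#' the per-bin occupancy.  Produced by [assign_quantiles()] and carried along
#' by [forward_map()] so that an inverse map can emit values on the original
#' scale.
#'
#' @param Q integer number of quantile bins (>= 2).
#' @param boundaries numeric vector of length `Q + 1`, non-decreasing.
#' @param occupancy integer vector of length `Q`; number of points per bin.
#' @return An object of class `quantile_partition`.
#' @export
quantile_partition <- function(Q, boundaries, occupancy = rep(NA_integer_, Q)) {
  Q <- as.integer(Q)
  if (Q < 2L) stop("Q must be at least 2")
  if (length(boundaries) != Q + 1L)
    stop("boundaries must have length Q + 1")
  check_finite_numeric(boundaries, "boundaries")
  if (any(diff(boundaries) < 0)) stop("boundaries must be non-decreasing")
  structure(list(Q = Q, boundaries = as.numeric(boundaries),
                 occupancy = as.integer(occupancy)),
            class = "quantile_partition")
}

#' Uniform partition of [0, 1) into Q equal bins
#'
#' The default partition used by [emit_series()] when no empirical partition
#' is available.
#'
#' @inheritParams quantile_partition
#' @return A `quantile_partition`.
#' @export
uniform_partition <- function(Q) {
  quantile_partition(Q, seq(0, 1, length.out = Q + 1L))
}

#' @export
print.quantile_partition <- function(x, ...) {
  cat(sprintf("quantile_partition: Q = %d, range [%g, %g]\n",
              x$Q, x$boundaries[1], x$boundaries[x$Q + 1L]))
  invisible(x)
}

#' Assign each point of a time series to a quantile bin
#'
#' Rank-based assignment with stable tie-breaking by time index: the points
#' are sorted by value (ties keep time order) and split into `Q` consecutive
#' blocks; when the length `L` is not divisible by `Q` the first `L %% Q`
#' (lowest-valued) bins receive one extra point.  Every bin therefore holds
#' `floor(L/Q)` or `ceiling(L/Q)` points, and the assignment is invariant
#' under any strictly increasing transform of the values.
#'
#' @param series numeric vector, the time series (all values finite).
#' @param Q integer number of quantile bins, `2 <= Q <= length(series)`.
#' @return A list with components
#'   \describe{
#'     \item{symbols}{integer vector in `1..Q`, same length and order as
#'       `series`; symbol 1 is the lowest-valued bin.}
#'     \item{partition}{a [quantile_partition]; boundary `q` is the smallest
#'       value in block `q` (the last boundary is the overall maximum).}
#'   }
#' @examples
#' assign_quantiles(c(0.1, 0.9, 0.2, 0.8), Q = 2)$symbols  # 1 2 1 2
#' @export
assign_quantiles <- function(series, Q) {
  check_finite_numeric(series, "series")
  Q <- as.integer(Q)
  L <- length(series)
  if (Q < 2L) stop("Q must be at least 2")
  if (L < Q) stop("more quantiles than points")
  ord <- order(series)                      # radix sort: stable in time index
  base <- L %/% Q
  sizes <- base + (seq_len(Q) <= (L %% Q))
  symbols <- integer(L)
  symbols[ord] <- rep.int(seq_len(Q), sizes)
  sorted <- series[ord]
  starts <- cumsum(c(1L, sizes[-Q]))
  boundaries <- c(sorted[starts], sorted[L])
  list(symbols = symbols,
       partition = quantile_partition(Q, boundaries, sizes))
}

#' Assign points to the bins of an existing quantile partition
#'
#' Boundary-based assignment against previously computed bins: a value `x`
#' gets symbol `q` when `b_q <= x < b_{q+1}` (values outside the partition's
#' range are clamped to the first or last bin).  This is how a second
#' generation reuses the first generation's quantiles when the
#' node-to-quantile correspondence is known.
#'
#' @param series numeric vector.
#' @param partition a [quantile_partition].
#' @return Integer symbols in `1..Q`.
#' @export
assign_bins <- function(series, partition) {
  check_finite_numeric(series, "series")
  if (!inherits(partition, "quantile_partition"))
    stop("partition must be a quantile_partition")
  b <- partition$boundaries
  sym <- findInterval(series, b[-c(1L, length(b))]) + 1L
  pmin(pmax(sym, 1L), partition$Q)
}

#' Count first-order symbol transitions
#'
#' `counts[i, j]` is the number of consecutive pairs `(t, t + 1)` with symbol
#' `i` followed by symbol `j`.  Only the `L - 1` consecutive pairs are
#' counted; there is no wrap-around from the last point to the first.
#'
#' @param symbols integer vector in `1..Q`.
#' @param Q integer number of symbols.
#' @return A `Q x Q` integer matrix with total sum `length(symbols) - 1`.
#' @export
count_transitions <- function(symbols, Q) {
  Q <- as.integer(Q)
  L <- length(symbols)
  if (L < 2L) stop("need at least two symbols")
  s <- as.integer(symbols)
  if (anyNA(s) || any(s < 1L) || any(s > Q))
    stop(sprintf("symbols out of range 1..%d", Q))
  idx <- (s[-L] - 1L) * Q + s[-1L]
  matrix(tabulate(idx, nbins = Q * Q), nrow = Q, ncol = Q, byrow = TRUE)
}

#' Markov network constructor
#'
#' A weighted directed network on `Q` nodes whose weight matrix `W` is
#' row-stochastic (each non-dangling row sums to 1): `W[i, j]` is the
#' probability of moving from node `i` to node `j`.  Optionally carries the
#' [quantile_partition] of the series it was estimated from.
#'
#' @param W square numeric matrix of transition probabilities.
#' @param partition optional [quantile_partition].
#' @return An object of class `markov_network` with fields `W`, `Q`
#'   (number of nodes) and `partition`.
#' @export
markov_network <- function(W, partition = NULL) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("W must be a square matrix")
  check_finite_numeric(c(W), "weights")
  if (any(W < 0) || any(W > 1 + 1e-12)) stop("weights must lie in [0, 1]")
  if (!is.null(partition) && !inherits(partition, "quantile_partition"))
    stop("partition must be a quantile_partition")
  structure(list(W = unname(W), Q = nrow(W), partition = partition),
            class = "markov_network")
}

#' @export
print.markov_network <- function(x, ...) {
  cat(sprintf("markov_network: %d nodes, %d arcs, %s partition\n",
              x$Q, sum(x$W > 0), if (is.null(x$partition)) "no" else "with"))
  invisible(x)
}

# Accept either a markov_network or a bare row-stochastic matrix.
as_weight_matrix <- function(network) {
  if (inherits(network, "markov_network")) network$W
  else if (is.matrix(network)) network
  else stop("expected a markov_network or a square matrix")
}

#' Row-normalize transition counts into a Markov network
#'
#' Each row with a positive sum is divided by its sum.  A zero row (a
#' "dangling" node, only possible for the bin holding just the final time
#' point) is handled according to `dangling_policy`:
#' `"error"` aborts naming the node, `"selfloop"` inserts a unit self-loop,
#' `"uniform"` spreads probability `1/Q` over all nodes.
#'
#' @param counts non-negative matrix of transition counts.
#' @param dangling_policy one of `"error"`, `"selfloop"`, `"uniform"`.
#' @return A [markov_network].
#' @export
normalize_rows <- function(counts,
                           dangling_policy = c("error", "selfloop", "uniform")) {
  dangling_policy <- match.arg(dangling_policy)
  if (!is.matrix(counts) || nrow(counts) != ncol(counts))
    stop("counts must be a square matrix")
  check_finite_numeric(c(counts), "counts")
  if (any(counts < 0)) stop("counts must be non-negative")
  Q <- nrow(counts)
  rs <- rowSums(counts)
  W <- matrix(0, Q, Q)
  ok <- rs > 0
  W[ok, ] <- counts[ok, , drop = FALSE] / rs[ok]
  if (any(!ok)) {
    dangling <- which(!ok)
    if (dangling_policy == "error")
      stop(sprintf("dangling node(s) with no outgoing transitions: %s",
                   paste(dangling, collapse = ", ")))
    if (dangling_policy == "selfloop")
      W[cbind(dangling, dangling)] <- 1
    else
      W[dangling, ] <- 1 / Q
    qn_log("warn", sprintf("repaired %d dangling node(s) with policy '%s'",
                           length(dangling), dangling_policy))
  }
  markov_network(W)
}

#' Forward map: time series to weighted directed network
#'
#' Composition of [assign_quantiles()], [count_transitions()] and
#' [normalize_rows()].  The returned network carries the quantile partition of
#' the input series so a subsequent inverse map can reuse the original bins.
#'
#' When `partition` is supplied the series is assigned to those existing bins
#' with [assign_bins()] (the known-correspondence round trip) instead of
#' computing fresh rank-based quantiles.
#'
#' @inheritParams assign_quantiles
#' @inheritParams normalize_rows
#' @param partition optional [quantile_partition] whose bins are reused.
#' @return A [markov_network] with a `partition`.
#' @examples
#' s <- toy_series(1000, p = 0, k = 1/8, seed = 1)
#' g <- forward_map(s, Q = 8)
#' rowSums(g$W)  # all exactly 1: a ring of unit-weight arcs
#' @export
forward_map <- function(series, Q,
                        dangling_policy = c("error", "selfloop", "uniform"),
                        partition = NULL) {
  dangling_policy <- match.arg(dangling_policy)
  if (is.null(partition)) {
    aq <- assign_quantiles(series, Q)
    symbols <- aq$symbols
    partition <- aq$partition
  } else {
    if (!missing(Q) && !is.null(Q) && as.integer(Q) != partition$Q)
      stop("Q disagrees with the supplied partition")
    Q <- partition$Q
    symbols <- assign_bins(series, partition)
  }
  counts <- count_transitions(symbols, Q)
  net <- normalize_rows(counts, dangling_policy)
  net$partition <- partition
  net
}
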