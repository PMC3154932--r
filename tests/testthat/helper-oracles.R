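# Independent oracles used across tests.  These deliberately use different
# algorithms / libraries than the implementation they check.

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# exhaustive seriation minimum by brute force
brute_force_min_cost <- function(W) {
  W <- if (inherits(W, "markov_network")) W$W else W
  perms <- all_permutations(nrow(W))
  min(apply(perms, 1L, function(p) ordering_cost(W, p)))
}

# all-pairs shortest paths under inverted weights by recursive enumeration of
# simple paths (exponential; N <= 8 only)
brute_force_shortest_paths <- function(W) {
  W <- if (inherits(W, "markov_network")) W$W else W
  N <- nrow(W)
  best <- matrix(Inf, N, N)
  recurse <- function(node, target, visited, len) {
    if (len >= best[visited[1L], target]) return(invisible(NULL))
    if (node == target) {
      best[visited[1L], target] <<- len
      return(invisible(NULL))
    }
    for (nxt in which(W[node, ] > 0)) {
      if (!(nxt %in% visited) || nxt == target)
        recurse(nxt, target, c(visited, nxt), len + 1 / W[node, nxt])
    }
    invisible(NULL)
  }
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i != j) recurse(i, j, i, 0)
  }
  best
}

# a random strictly row-stochastic matrix without self-loops
random_markov_matrix <- function(N, seed) {
  set.seed(seed)
  W <- matrix(runif(N * N), N, N)
  diag(W) <- 0
  W / rowSums(W)
}

# symmetric banded matrix whose natural order is the unique seriation optimum
band_matrix <- function(N, widths = 2L) {
  W <- matrix(0, N, N)
  for (d in seq_len(widths)) {
    idx <- cbind(seq_len(N - d), seq_len(N - d) + d)
    W[idx] <- 1 / d
    W[idx[, 2:1, drop = FALSE]] <- 1 / d
  }
  W / rowSums(W)
}
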