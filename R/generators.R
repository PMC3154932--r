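# Input families used to validate the round trip: the tunable
# periodic-to-random toy ensemble, Lorenz and Roessler trajectories, synthetic
# ring/modular/star networks, and the value-shuffle used for modularity nulls.

#' Toy ensemble: time series ranging from periodic to random
#'
#' `x_1 = eta_1`; for `t > 1`, with probability `1 - p` the series advances
#' deterministically, `x_t = (x_{t-1} + k) mod 1`, and with probability `p`
#' the point is replaced by noise, `x_t = eta_t`, with `eta` i.i.d. uniform on
#' `[0, 1)`.  `p = 0` gives an exactly periodic sawtooth of period `1/k`
#' (whose quantile graph at `Q = 1/k` is a ring); `p = 1` gives i.i.d. uniform
#' noise (whose quantile graph approaches the complete graph with weights
#' `1/Q`).
#'
#' @param length number of points `L >= 1`.
#' @param p probability in `[0, 1]` that a step is replaced by noise.
#' @param k deterministic increment per step (cycles per step), in `(0, 1)`.
#' @param seed integer seed (optional).
#' @return Numeric vector of length `length`, values in `[0, 1)`.
#' @export
toy_series <- function(length, p, k = 0.125, seed = NULL) {
  L <- as.integer(length)
  if (L < 1L) stop("length must be at least 1")
  if (!is.numeric(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (!is.numeric(k) || k <= 0 || k >= 1) stop("k must lie in (0, 1)")
  with_seed(seed, {
    noisy <- c(TRUE, if (L > 1L) runif(L - 1L) < p)
    eta <- runif(L)
    t <- seq_len(L)
    last <- cummax(t * noisy)        # index of the most recent noise draw
    (eta[last] + (t - last) * k) %% 1
  })
}

# shared fixed-step RK4 integrator; deriv(state) -> state derivative
rk4_integrate <- function(deriv, state, dt, n_steps, discard, coord = 1L) {
  total <- n_steps + discard
  out <- numeric(n_steps)
  for (i in seq_len(total)) {
    k1 <- deriv(state)
    k2 <- deriv(state + dt / 2 * k1)
    k3 <- deriv(state + dt / 2 * k2)
    k4 <- deriv(state + dt * k3)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(state))) stop("trajectory diverged (non-finite state)")
    if (i > discard) out[i - discard] <- state[coord]
  }
  out
}

#' Lorenz trajectory (first coordinate)
#'
#' Integrates `dx = sigma (y - x)`, `dy = x (rho - z) - y`, `dz = x y - beta z`
#' with fixed-step 4th-order Runge-Kutta and returns the `x` coordinate, which
#' at the canonical chaotic parameters oscillates between the positive and the
#' negative region as the trajectory switches between the attractor's two
#' lobes.
#'
#' @param length number of samples returned (one per integration step).
#' @param sigma,rho,beta Lorenz parameters; canonical chaotic defaults
#'   `10, 28, 8/3`.
#' @param dt integration step (default 0.05: about 14 samples per characteristic
#'   Lorenz oscillation and 120 per Roessler cycle, coarse enough that the
#'   Lorenz quantile graph is bulky while the Roessler one stays chain-like).
#' @param initial_state numeric 3-vector `(x, y, z)`.
#' @param discard burn-in steps dropped before sampling (default 1000).
#' @return Numeric vector of length `length`.
#' @export
lorenz_series <- function(length, sigma = 10, rho = 28, beta = 8 / 3,
                          dt = 0.05, initial_state = c(0, 1, 1.05),
                          discard = 1000L) {
  L <- as.integer(length)
  if (L < 2L) stop("length must be at least 2")
  if (dt <= 0) stop("dt must be positive")
  deriv <- function(s)
    c(sigma * (s[2] - s[1]),
      s[1] * (rho - s[3]) - s[2],
      s[1] * s[2] - beta * s[3])
  rk4_integrate(deriv, as.numeric(initial_state), dt, L, as.integer(discard))
}

#' Roessler trajectory (first coordinate)
#'
#' Integrates `dx = -y - z`, `dy = x + a y`, `dz = b + z (x - c)` with
#' fixed-step RK4 and returns the `x` coordinate: a quasiperiodic oscillation
#' whose successive peaks and troughs have different amplitudes.
#'
#' @param length number of samples returned.
#' @param a,b,c Roessler parameters; canonical chaotic defaults
#'   `0.2, 0.2, 5.7`.
#' @inheritParams lorenz_series
#' @return Numeric vector of length `length`.
#' @export
rossler_series <- function(length, a = 0.2, b = 0.2, c = 5.7,
                           dt = 0.05, initial_state = c(1, 1, 0),
                           discard = 1000L) {
  L <- as.integer(length)
  if (L < 2L) stop("length must be at least 2")
  if (dt <= 0) stop("dt must be positive")
  deriv <- function(s)
    c(-s[2] - s[3],
      s[1] + a * s[2],
      b + s[3] * (s[1] - c))
  rk4_integrate(deriv, as.numeric(initial_state), dt, L, as.integer(discard))
}

#' Synthetic network fixtures
#'
#' Three network classes spanning the topologies relevant to the inverse map:
#' \describe{
#'   \item{ring}{the directed cycle `1 -> 2 -> ... -> N -> 1` (the quantile
#'     graph of a noiseless periodic series).}
#'   \item{modular}{`m` equal blocks; inside each block a directed cycle plus
#'     random arcs with probability `p_in`, between blocks random arcs with
#'     probability `p_out < p_in`.  High modularity; a random walker dwells
#'     inside a block, so the inverse-map series is persistent.}
#'   \item{star_hubs}{`h` hubs, each bidirectionally connected to a disjoint
#'     set of leaves, with all hub-hub arcs present.  Low modularity; a walker
#'     bounces through hubs across branches, so the series is noisy.}
#' }
#' Strong connectivity is required; generation is retried (up to 100 times)
#' when random arcs leave the network not strongly connected.
#'
#' @param kind one of `"ring"`, `"modular"`, `"star_hubs"`.
#' @param N number of nodes (>= 2).
#' @param m number of blocks (modular; default 4).
#' @param p_in,p_out intra/inter-block arc probabilities (modular).
#' @param h number of hubs (star_hubs; default 3).
#' @param seed integer seed (optional).
#' @param connected require strong connectivity (default TRUE); set FALSE to
#'   allow deliberately disconnected fixtures such as `modular` with
#'   `p_out = 0`.
#' @return A row-normalized [markov_network].
#' @export
fixture_network <- function(kind = c("ring", "modular", "star_hubs"), N,
                            m = 4L, p_in = 0.5, p_out = 0.02, h = 3L,
                            seed = NULL, connected = TRUE) {
  kind <- match.arg(kind)
  N <- as.integer(N)
  if (N < 2L) stop("N must be at least 2")
  build <- function() {
    A <- matrix(0, N, N)
    if (kind == "ring") {
      A[cbind(seq_len(N), c(2:N, 1L))] <- 1
    } else if (kind == "modular") {
      if (p_out >= p_in) stop("p_out must be smaller than p_in")
      block <- sort(rep_len(seq_len(m), N))
      for (b in seq_len(m)) {
        idx <- which(block == b)
        if (length(idx) > 1L)
          A[cbind(idx, c(idx[-1L], idx[1L]))] <- 1   # block cycle: connectivity
      }
      same <- outer(block, block, "==")
      rnd <- matrix(runif(N * N), N, N)
      A[same & rnd < p_in] <- 1
      A[!same & rnd < p_out] <- 1
      diag(A) <- 0
    } else {
      if (h < 1L || h >= N) stop("need 1 <= h < N hubs")
      hubs <- seq_len(h)
      leaf_owner <- rep_len(hubs, N - h)
      leaves <- (h + 1L):N
      A[cbind(leaves, leaf_owner)] <- 1
      A[cbind(leaf_owner, leaves)] <- 1
      A[hubs, hubs] <- 1
      diag(A) <- 0
    }
    A
  }
  A <- with_seed(seed, {
    ok <- NULL
    for (try in seq_len(100L)) {
      cand <- build()
      g <- igraph::graph_from_adjacency_matrix(cand > 0, mode = "directed")
      if (!connected || igraph::is_connected(g, mode = "strong")) {
        ok <- cand
        break
      }
      qn_log("info", sprintf("fixture not strongly connected, retry %d", try))
    }
    if (is.null(ok))
      stop("failed to generate a strongly connected fixture in 100 tries")
    ok
  })
  normalize_adjacency(A)
}

#' Shuffle the values of a time series
#'
#' A uniform random permutation of the values: the value distribution is
#' preserved while all temporal order is destroyed.  Used as the null model
#' for the modularity of quantile graphs.
#'
#' @param series numeric vector.
#' @param seed integer seed (optional).
#' @return Numeric vector, a permutation of `series`.
#' @export
shuffle_series <- function(series, seed = NULL) {
  if (length(series) < 2L) stop("need at least two points to shuffle")
  with_seed(seed, sample(series))
}
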