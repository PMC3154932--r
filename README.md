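# quantnet

Quantile-graph maps between time series and networks — a forward map Φ from a
univariate series to a weighted directed network, and an approximate inverse
Φ⁻¹ from a network back to a series.

## What problem this solves, and for whom

Time-series analysis and network science each have deep toolkits, but maps
from one domain to the other usually lose the connection back: a network
built from a series cannot be turned into a series again, so network metrics
cannot be interpreted in dynamical terms (and vice versa).  `quantnet`
implements a dual representation for researchers in nonlinear dynamics,
physiology and systems biology who want to

* characterize dynamical regimes of a series (periodic, chaotic, random,
  heart-rate-like) through the topology of its **quantile graph**, and
* characterize network topology (modular vs hub-dominated) through the
  dynamics of random-walk **surrogate series**.

## The map

**Forward (Φ).** Split the series `x_1..x_L` into `Q` rank-based quantile
bins; bin `q` becomes node `q`.  Count the `L − 1` consecutive transitions
between bins and row-normalize:

    W[i, j] = #{t : x_t ∈ bin i, x_{t+1} ∈ bin j} / #{t : x_t ∈ bin i}

`W` is a row-stochastic Markov matrix — every node's out-strength is exactly
one — and Φ is invariant under any strictly increasing transform of the
values.  `Q` is the only parameter.

**Inverse (Φ⁻¹).** Row-normalize an arbitrary non-negative adjacency matrix,
associate nodes with quantiles — either a known correspondence, or by
seriation: simulated annealing on the distance-to-diagonal cost

    C(π) = (1/N) Σ_{u,v} W[π(u), π(v)] · |u − v|

with segment moves and Metropolis acceptance `exp(−ΔC/Θ)` — then run a random
walk of length `L` and emit each visited node's value uniformly inside its
quantile interval.

Generators for the validation world (a periodic-to-random toy ensemble,
Lorenz and Rössler trajectories, ring/modular/star network fixtures), and the
diagnostics used to compare generations (ACF, periodogram, spectral slope,
strengths, inverse-weight shortest paths, Newman modularity against a
value-shuffle null) are included.  See the methods vignette
(`vignettes/quantile-graph-duality.Rmd`) for assumptions, parameter
rationale, and what the round-trip tests do and do not establish.

## Worked example

```r
library(quantnet)

# a mostly periodic series: sawtooth with 5% noise resets
s <- toy_series(10000, p = 0.05, k = 1/50, seed = 1)
g <- forward_map(s, Q = 50)
g
#> markov_network: 50 nodes, 545 arcs, with partition
range(rowSums(g$W))            # Markov contract: out-strengths unitary
#> [1] 1 1

# round trip with the known node-quantile correspondence
inv <- inverse_map(g, length = 10000, seed = 2, partition = g$partition)
g2  <- forward_map(inv$series, partition = g$partition)
max(abs(g$W - g2$W))           # transition matrix recovered to sampling noise
#> [1] 0.0452657

# chaotic attractor topology: Lorenz quantile graph vs value-shuffle null
x <- lorenz_series(10000)
null <- modularity_shuffle_null(x, Q = 50, R = 10, seed = 3)
sprintf("Lorenz modularity: %.3f vs shuffle null %.3f +/- %.4f",
        null$observed, null$null_mean, null$null_se)
#> "Lorenz modularity: 0.569 vs shuffle null 0.038 +/- 0.0008"
```

The 545 arcs reflect one strong `q → q+1` ring (the sawtooth) plus a cloud of
weak noise arcs; the modularity of the Lorenz graph sits hundreds of standard
errors above its temporal-shuffle null because the attractor's two lobes map
into two dominant modules, while shuffling destroys all temporal structure.

A command-line interface covers the same pipeline
(`generate`, `map`, `invert`, `stats`, `roundtrip`):

```sh
Rscript inst/cli/quantnet generate toy --p 0 --k 0.125 --length 64 --seed 1 --output toy.txt
Rscript inst/cli/quantnet map --input toy.txt --quantiles 8 --output ring.tsv
```

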