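# infocap

Information-theoretic analysis of dose-response data with continuous,
possibly high-dimensional readouts — typically single-cell signaling
responses. Given a table with one row per cell, a discrete stimulus label
in the first column and one or more numeric response columns (e.g.
successive time points of a trajectory), `infocap` estimates:

* **Mutual information** MI(X, Y) between stimulus X and response Y, in
  bits — 2^MI is roughly the number of stimulus levels the system resolves
  under a given input distribution P(X);
* **Channel capacity** C\* = max over P(X) of MI(X, Y) — the same quantity
  under the most favorable input distribution, together with that
  distribution P\*(X);
* **Pairwise probabilities of correct discrimination (PCD)** — for each
  pair of stimulus levels at equal priors, the fraction of cells a Bayes
  rule assigns to the correct level, from 0.5 (indistinguishable) to 1
  (perfectly resolved).

## The method

Instead of estimating the (possibly high-dimensional) output densities
P(y | X = x_i), the package estimates the *discrete* conditional input
distribution P(x_i | Y = y) with multinomial logistic regression,

log( P(x_i | Y = y) / P(x_m | Y = y) ) = α_i + β_iᵀ y,  i = 1, …, m − 1,

and replaces the expectation over P(Y | X = x_i) by the average over that
level's cells:

MI(X, Y) ≈ Σ_i P(x_i) (1/n_i) Σ_l log₂( P̂(x_i | y_l^i) / P(x_i) ).

Capacity is obtained by alternate maximization of the lower bound
J(P, Q) = Σ_i P(x_i) E[ log₂( Q(x_i | Y) / P(x_i) ) | X = x_i ]: the
optimal P for fixed Q is a softmax of the per-level expected log-posteriors
D_i(Q), and the optimal Q for fixed P is the model posterior re-calibrated
to P — which for a logistic model is an exact, closed-form shift of the
intercepts only. The regression is therefore fitted **once**; the iteration
is a sequence of cheap vector updates. PCD for a pair is the average of
max{P̂(x_i | y), P̂(x_j | y)} over held-out cells of both levels, averaged
over repeated stratified train/test splits to control classifier
optimism.

Synthetic channels with exactly known densities (log-normal dose-response,
shifted Gaussians, disjoint and identical supports) and density-based
oracles (quadrature MI, discretized Blahut–Arimoto capacity, the analytic
Gaussian discrimination probability Φ(d/2σ)) are included for validation.

## Worked example

```r
library(infocap)

# a log-normal channel: Y | x ~ exp(N(mu(x), 1)), mu(x) = 10 x / (1 + x),
# eleven doses from 0 to 100, 1000 cells per dose
spec <- scenario1_spec()
cells <- simulate_channel(spec, n_per_level = 1000, seed = 5)

# the posterior log-ratio of a log-normal channel is linear in log(y)
cells <- transform_response(cells, log)

estimate_mi(cells)$mi_bits        # 1.586518  (quadrature oracle: 1.594362)
cap <- estimate_capacity(cells)
cap$capacity_bits                 # 1.730089  (discretized-BA oracle: 1.737385)
round(cap$optimal_input, 3)       # most mass on the extreme, resolvable doses

pair <- estimate_pcd_pair(cells, "0", "100", repeats = 50, seed = 1)
pair$mean                         # ~1: the extreme doses are fully resolved
```

The capacity of ~1.73 bits says this channel resolves about
2^1.73 ≈ 3.3 of its eleven doses; the PCD matrix
(`estimate_pcd_matrix()`) shows *which* dose pairs are resolvable.

A command-line wrapper with the same functionality
(`mi`, `capacity`, `pcd`, `simulate` subcommands) is installed at
`system.file("cli", "infocap.R", package = "infocap")`.

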