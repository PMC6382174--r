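---
title: "Geometric integrated information and the spectral search for the minimum information bipartition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric integrated information and the spectral search for the minimum information bipartition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phig)
```

## The model

`phig` measures how much information a multivariate signal integrates
*across* a two-way split of its channels. The underlying model is the lagged
linear regression of a weakly stationary Gaussian system,

$$X_t = A\,X_{t-\tau} + E,$$

with the regression matrix given by the normal equation
$A = \Sigma_{X_t X_{t-\tau}} \Sigma_{X_{t-\tau} X_{t-\tau}}^{-1}$ and the
residual covariance by the conditional covariance of the present given the
past, $\Sigma_E = \Sigma_{X_t X_t} - A\,\Sigma_{X_t X_{t-\tau}}^\top$. We
use the general conditional-covariance form; the commonly quoted shortcut
that substitutes the lagged covariance for $\Sigma_{X_t X_t}$ is valid only
under exact stationarity, and with finite samples the two estimates differ.

A **disconnected model** of the same system forces the two sub-communities
of a bipartition to evolve independently: its regression matrix $A'$ is
zero outside the partition's diagonal blocks. Geometric integrated
information is the minimized Kullback–Leibler divergence between the full
and disconnected models. With the disconnected residual covariance profiled
out as $\Sigma_{E'} = \Sigma_E + (A-A')\,\Sigma_{X_{t-\tau}X_{t-\tau}}(A-A')^\top$,
this reduces to

$$\Phi^G = \tfrac{1}{2}\log_2 \frac{|\Sigma_{E'}|}{|\Sigma_E|}
\quad\text{bits},$$

minimized over the within-block entries of $A'$. $\Phi^G$ is non-negative
and bounded by the temporal mutual information
$\tfrac12 \log_2(|\Sigma_{X_tX_t}|/|\Sigma_E|)$; both properties are
asserted numerically in the test suite.

The **minimum information bipartition** (MIB) is the split minimizing the
*normalized* quantity $\Phi^G/K$, where $K$ is the smaller of the two
sub-communities' Gaussian entropies. Normalization penalizes one-vs-all
splits, whose tiny marginal entropy would otherwise make almost any cut
look weak. A partition whose $K$ falls below $10^{-6}$ bits is flagged
invalid rather than divided by; Gaussian differential entropies can be
negative, so the safeguard also catches near-deterministic channels.

## Finding the disconnected model

There is no closed form for the optimal $A'$. The objective
$F(A') = \tfrac12\log_2|\Sigma_E + (A-A')S(A-A')^\top| - \tfrac12\log_2|\Sigma_E|$
(with $S$ the past covariance) is smooth with the analytic gradient
$-\tfrac{1}{\ln 2}\,\Sigma_{E'}^{-1}(A-A')S$ restricted to the free block
entries. Two solvers share the work:

* **Block fixed point** (compiled, used when the feasible set has at most
  450 entries): with $W = \Sigma_{E'}^{-1}$ frozen, the stationarity
  condition $[W(A-A')S]_{\text{within-block}} = 0$ is *linear* in the free
  entries of $A'$; the dense linear solve is iterated with Aitken
  extrapolation and step-halving. It converges in a few tens of iterations
  to gradient norms around $10^{-6}$ and per-iteration objective changes
  below $10^{-12}$ bits.
* **L-BFGS-B** with the analytic gradient for larger systems, and as the
  restart when the fixed point stalls early. When L-BFGS-B exhausts its
  iteration cap with the gradient still above tolerance, a few fixed-point
  iterations from its endpoint act as Newton-quality polish and typically
  drive the gradient norm below tolerance outright.

Both declare convergence at gradient norm $\le$ `tol` (default $10^{-8}$)
or per-iteration decrease below $\sim 10^{-12}$ bits, the optimization is
initialized at the block-diagonal part of $A$ (so the reported value can
never exceed that feasible starting objective), and floating-point
negatives above $-10^{-6}$ are clipped to zero while anything more negative
raises an error. The solvers are cross-checked in the tests against a dense
$10^{-3}$-step grid search on two-channel systems, multi-start Nelder–Mead
on three-channel systems, and each other on eight-channel systems.

When the spectral search scores candidates on systems beyond the
fixed-point size cutoff, it first ranks all candidates with a
loose-tolerance pass and then re-optimizes only the winner at full
tolerance; the returned minimizer is therefore always fully converged,
while the per-candidate table carries screening-precision values.

## The spectral candidate grid

Scoring all $2^{n-1}-1$ bipartitions is infeasible beyond small $n$. The
package's fast search clusters the Pearson correlation matrix of the data:
each correlation $r$ is mapped to a non-negative weight through the power
adjacency $w = ((r+1)/2)^\beta$ for ten $\beta$ values log-spaced on
$[1, 10]$; the raw correlation matrix with negatives floored at zero joins
them as an eleventh source matrix. Every source is thresholded at the 199
percentile cutoffs $\{0, 0.005, \dots, 0.99\}$ and each thresholded graph
is bipartitioned spectrally, giving $11 \times 199 = 2189$ candidates
before deduplication. Normalized $\Phi^G$ is evaluated once per unique
valid candidate and the minimizer is returned.

The spectral step takes the eigenvectors of the two smallest eigenvalues
of the symmetric-normalized Laplacian $I - D^{-1/2} W D^{-1/2}$ (the
normalized-cut relaxation) and discretizes them with k-means (several
deterministic farthest-point initializations derived from the seed) plus
the sign and median splits of the Fiedler vector, keeping the rounding
with the lowest normalized cut. A full sweep over every threshold split of
the Fiedler vector would minimize Ncut more exactly per graph, but it
makes the 2,189 clusterings collapse onto a handful of near-identical
partitions; the k-means-family discretization keeps the candidate set
diverse across thresholds, which is what the downstream MIB search
actually benefits from (measured directly: brute-force-equality on VAR
systems is higher with the diverse discretization, at the cost of exact
per-graph Ncut optimality on unstructured dense graphs, where it still
stays within 1.5x of the exhaustive minimum). Isolated nodes (which
thresholding creates freely) receive zero-degree rows and simply fall out
of the eigenstructure. The whole pipeline is deterministic given the
correlation matrix and a seed.

Two properties tie the fast search to the exhaustive one: the spectral
minimum can never fall below the brute-force minimum (it scores a subset),
and on systems where both run the tests require equality in the large
majority of seeds.

## Synthetic networks

Three generators produce the structural graphs used in validation:

* **Brain-like (Hebbian) connectomes.** Nodes are assigned uniformly to
  $\lceil \ln n \rceil$ modules (natural log; 3 modules at 14 nodes, 5 at
  100). Edges are cast within modules with probability $4.5/s$ for module
  size $s \ge 4$ (else $4/s$) and across modules with probability
  $3.3/(\bar s M)$ (else $3.75/(\bar s M)$), where $\bar s$ is the mean
  size of the two modules involved — the rule is stated per-module, so a
  cross-module pair needs a convention. A rich-get-richer step then
  redistributes degrees: the 38th-percentile degree anchors the low end of
  a piecewise profile that ramps to $Z = (n + \ln n)/7$, a three-parameter
  logistic is least-squares fit to that profile, and each node's degree is
  adjusted toward the curve in seeded random order. Taken as absolute
  degree targets the printed profile collapses the graph (most nodes map
  to a single connection, and the result is never connected at realistic
  sizes), so the fitted curve is used as the *shape* of the new degree
  sequence and rescaled to conserve total edge mass:
  $t_i = \mathrm{round}(S(c_i)\,\bar c / \overline{S(c)})$. This keeps the
  poor-get-poorer / rich-get-richer intent, yields connected modular graphs
  with long right-tailed degree distributions (positive sample skewness in
  at least 18 of 20 seeds is a test contract), and is the package's own
  resolution of an ambiguous recipe. Connectivity is enforced by
  regeneration, up to 100 attempts.
* **Cut networks.** A brain-like graph whose modules are assigned whole to
  two halves (greedy balancing, seeded tie-breaks), with every crossing
  edge deleted and both halves required to stay internally connected. The
  cut is returned as the ground-truth bipartition; structurally it carries
  zero crossing weight, so with enough data the MIB converges onto it.
* **Watts–Strogatz graphs** via the standard edge-rewiring construction
  (igraph), regenerated until connected; the rewiring probability $p$
  interpolates from ring lattices to random graphs, raising global
  efficiency and lowering modularity.

## Dynamics

**Coupled stochastic Rössler oscillators.** Each node follows the
three-variable Rössler system with $a = b = 0.2$, $c = 9$, frequencies
drawn from $\mathcal N(10, 0.1)$, diffusive coupling
$-\sigma \sum_h g_{ih} x_h$ through the Laplacian coefficients on the
$x$-equation, and noise $d\,\eta$ with $d = 750$ on the $y$-equation.
Integration is plain Euler at $dt = 0.001$ with the noise entering as
$d\,\eta\,dt$ (per-step standard deviation 0.75); an Euler–Maruyama
$\sqrt{dt}$ scaling is available behind a flag, but at these parameter
values it destabilizes the $z$-equation and diverges, so the plain scaling
is the default. The first 5,000 steps are discarded as transient. The $y$
component is recorded every `record_every` steps (default 100, i.e. one
sample per 0.1 time units): consecutive raw Euler steps are dominated by
the single-step noise increment, and spacing the samples out both
decorrelates them and extends the physical time span the recording covers,
which is what the correlation matrix and the lagged model actually need.
The experiment drivers therefore work at a recorded-sample lag of
$\tau = 1$. Coupling strengths default to the midpoint of the
master-stability interval $(0.186/\lambda_2,\; 4.614/\lambda_{\max})$ of
the graph Laplacian — the classic synchronizability bounds for
$x$-coupled Rössler networks — with a warning when the interval is empty.
For cut graphs the bound uses the smallest *positive* Laplacian eigenvalue,
since the cut Laplacian has a double zero.

**VAR dynamics.** A stable first-order autoregression
$A = 0.2\,I + c\,W/\mathrm{rowdeg}$, rescaled to spectral radius 0.9 when
needed, driven by unit Gaussian innovations. It serves both as a second
dynamical family for the validation experiments and as the analytically
tractable oracle (its stationary covariance solves a discrete Lyapunov
equation, used throughout the tests).

## Validation experiments and problem sizes

* `run_small_validation()` — brain-like oscillator networks small enough
  for exhaustive search; records the normalized-$\Phi$ gap between the
  spectral and brute-force minima and their Rand index. Default desk
  scale: 10 networks of 12 and 14 nodes, 25,000 samples, recording
  interval 400 steps (the near-tie structure among the best bipartitions
  of small synchronized oscillator networks only resolves with long
  recordings).
* `run_cut_validation()` — structurally cut networks where the MIB is
  known; compares normalized $\Phi$ across the spectral partition and the
  cut. Default: 10 networks of 50 nodes, 100,000 samples.
* `run_structure_sweep()` — Watts–Strogatz networks across 19 rewiring
  probabilities at fixed coupling 0.25; correlates non-normalized $\Phi^G$
  across the spectral MIB with binary global efficiency and with Newman
  modularity (Spearman, average ranks for ties). Default: 5 networks per
  probability, 100 nodes, mean degree 6, 25,000 samples at recording
  interval 25, and a coarsened candidate grid (3 power transforms plus the
  raw matrix, percentile step 0.1) whose correlations are indistinguishable
  from denser grids at a fraction of the cost.

Reports are bit-reproducible from (config, master seed): child seeds are
derived deterministically, and every aggregate recomputes exactly from the
per-network records it summarizes (a test contract).

## What the generators do and do not emulate

The synthetic connectomes reproduce coarse statistics of real structural
networks — modularity with rich cross-module connectivity and a
right-skewed degree distribution — but none of the geometry, distance
dependence, or weighted heterogeneity of real tractography; oscillator
recordings emulate the near-Gaussian, globally synchronized character of
resting ECoG, not its spectral content or non-stationarity. Passing the
validation experiments shows the search machinery recovers the
informational structure of *these* systems; it licenses no claim about any
particular empirical recording, and analyses of real neural data (the
natural application) remain the user's responsibility, including lag
selection — `select_time_lag()` scans a lag grid and flags the case where
integration is negligible at every lag.

## Numerical choices and degenerate inputs

* Covariances are symmetrized and use the $1/(n_{\text{pairs}}-1)$
  normalization; each channel is demeaned over its own aligned window.
* A past covariance with condition number above $10^{12}$ raises a
  conditioning error; no silent ridge regularization.
* Percentile cutoffs use the default (type-7) sample quantile; weights
  strictly below the cutoff are zeroed, so the 0th percentile leaves the
  graph untouched, and consecutive equal cutoffs reuse the previous
  clustering.
* Ties in MIB searches break toward smaller raw $\Phi^G$, then first
  occurrence (enumeration order for the exhaustive search, provenance
  order for the candidate grid).
* Bipartition counts are exact in doubles up to $n = 53$; Bell numbers via
  the Bell triangle up to $n = 22$.
* All-zero graphs, empty-sided k-means solutions, disconnected graphs
  where connectivity is required, and deterministic channels all raise
  classed errors (`phig_degenerate_data`, `phig_domain_error`, ...) rather
  than propagating NaNs; in the candidate grid, degenerate thresholded
  graphs are counted as skipped.

## Known limitations

* The Gaussian lag model is the estimator's world: strongly non-Gaussian
  or non-stationary signals are outside its guarantees.
* Exact MIB recovery in small synchronized oscillator networks is
  intrinsically fragile: the best few bipartitions often differ by less
  than $10^{-4}$ normalized bits, below finite-sample resolution, so the
  fast search sometimes returns a partition whose normalized $\Phi$ ties
  the exhaustive minimum to three or four decimals without being the same
  split. The cut-network experiment, where the minimum is structurally
  forced, does not show this fragility.
* The brute-force reference is capped at 18 channels; beyond that only
  the spectral search runs, and its result is an upper bound on the true
  normalized minimum.
* Multi-way (k > 2) partitions and non-Gaussian estimators are out of
  scope.

## A worked call

```{r example, eval = FALSE}
g   <- brain_like_network(12, seed = 1)
msf <- master_stability_coupling(g)
ts  <- simulate_rossler(g, rossler_params(sigma = msf$sigma_mid,
                                          n_points = 25000,
                                          record_every = 400), seed = 2)
model <- fit_transition_model(ts, tau = 1)
brute    <- brute_force_mib(model)
spectral <- spectral_mib(ts, tau = 1, seed = 1, model = model)
glance(spectral)
rand_index(brute$best$partition, spectral$best$partition)
```
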