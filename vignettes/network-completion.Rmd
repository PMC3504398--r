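---
title: "Network completion by dynamic programming and least squares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network completion by dynamic programming and least squares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dplsq)
```

## The model

A directed network $G(V, E)$ over $n$ genes fixes, for each gene $v_i$,
its regulator set $e^-(v_i)$ (no self-loops). The expression value
$x_i$ evolves by

$$\frac{dx_i}{dt} = a_0^i + \sum_{j=1}^{h} a_j^i\, x_{i_j}
  + \sum_{j<k} a_{j,k}^i\, x_{i_j} x_{i_k} + b_i\,\omega,$$

where $x_{i_1},\dots,x_{i_h}$ are the regulators of $v_i$. The linear
terms carry direct activation ($a_j^i > 0$) or inhibition
($a_j^i < 0$); the pairwise products model cooperative regulation and
are treated as weaker than the direct terms. $b_i\,\omega$ is process
noise, $\omega$ uniform on $[-1,1]$ redrawn per gene per step.
Simulation and fitting both use the Euler-style discretization

$$x_i(t+1) = x_i(t) + \Delta t\Big(a_0^i + \sum_j a_j^i x_{i_j}(t)
  + \sum_{j<k} a_{j,k}^i x_{i_j}(t)x_{i_k}(t) + b_i\omega\Big),$$

with the noise inside the $\Delta t$-scaled parenthesis, so its
effective per-step magnitude is $\Delta t\, b_i$. No continuous-time
integrator is used anywhere: the discrete map *is* the model.

Observations add uniform measurement error: $y_i(t) = x_i(t) + o\,
\epsilon$, $\epsilon$ uniform on $[-1,1]$, independent per gene and
time point. The observation error level $o$ is a single scalar shared
by all genes — the benchmark protocol varies one error level at a time
— though nothing in the fitting machinery depends on that choice.

## Least-squares fitting

The update is linear in the coefficients, so for a fixed candidate
regulator set the best coefficients minimize the convex quadratic

$$S^i = \sum_{\text{series}}\ \sum_{t}\ \big|\,y_i(t+1) -
  [\,y_i(t) + \Delta t\, \hat f_i(y(t))\,]\,\big|^2 ,$$

summed over every consecutive pair of time points within each series
(pairs never span series boundaries). Internally the regression is
solved on the difference-quotient scale, with response
$(y_i(t{+}1)-y_i(t))/\Delta t$; the reported SSE is rescaled by
$\Delta t^2$ so that it is exactly $S^i$ above. The two scales differ
only by that constant factor, so every argmin — and hence every
completed network — is identical under either convention.

Numerical choices:

* The hot path solves the normal equations on precomputed Gram
  matrices: the full design (intercept, all $n$ linear columns, all
  $\binom{n}{2}$ product columns) is assembled once per data set, and
  any candidate set's system is a submatrix lookup. This is what makes
  scanning thousands of candidate sets per gene cheap.
* Rank-deficient systems (constant trajectories, duplicated
  regressors) fall back to the Moore–Penrose pseudo-inverse, i.e. the
  minimum-norm least-squares solution, with a warning. Degenerate data
  are legal inputs, not errors.
* Overparameterized fits (more coefficients than transitions) are
  permitted with a warning — the caller controls data volume, and short
  single-series data genuinely overfit; the benchmark protocol uses 20
  short series for exactly that reason.

## The dynamic program

Let $\sigma_{h_j,k_j,j}$ be the minimum SSE at gene $v_j$ after
deleting $h_j$ of its incoming edges and adding $k_j$ new ones
(disjoint sets, additions drawn from $V - v_j - e^-(v_j)$, never a
self-loop), found by exhaustive enumeration of the
$\binom{\deg^-}{h_j}\binom{n-1-\deg^-}{k_j}$ combinations. Per-node
caps $H$ and $K$ (default 3 each) bound the enumeration; cells with
$h_j > H$, $k_j > K$, a resulting in-degree $\ge n$, or no valid
combination hold an `Inf` sentinel — a true `Inf`, so sums through
infeasible cells stay infinite rather than merely large.

Because the per-gene SSEs are independent given the edit counts, the
total over the first $i$ genes satisfies

$$D[h,k,j+1] = \min_{h'+h''=h,\; k'+k''=k}
  \big\{ D[h',k',j] + \sigma_{h'',k'',j+1} \big\},$$

and $D[h,k,n]$ is the global optimum; the inner scan only visits
$h'' \le H$, $k'' \le K$, so each cell costs $(H{+}1)(K{+}1)$ lookups.
The value is invariant to the node ordering. Addition-only and
deletion-only completion are the same program with the complementary
budget pinned to zero, and inference is addition-only completion from
the edgeless network.

The recursion alone gives the optimal *value*; the completed network is
the deliverable, so each DP cell also stores its argmin split
$(h'', k'')$ and each $\sigma$ cell its argmin edit sets, and a
traceback from $(h, k, n)$ reconstructs one optimal assignment. Ties
(within $10^{-12}$ absolute) are broken toward the smallest $h''$, then
$k''$, and toward the lexicographically first edit sets, making every
result reproducible bit for bit. Infeasible budgets return an explicit
infeasible result object rather than an error.

On clean, noise-free data ties deserve a note: adding any regulator to
a gene whose true regulators are already present leaves its SSE at
zero, so zero-noise *addition* placements are only pinned down because
an unfixed gene elsewhere keeps a strictly positive SSE. With any
observation noise the nested-model property (more regressors never
increase SSE) makes every extra edge reduce SSE slightly; the DP places
edges where the reduction is largest, which is what makes the noisy
benchmark informative.

## The synthetic benchmark

`trial_config()` encodes the simulation protocol used throughout:

| parameter | default | meaning |
|---|---|---|
| `lin_range` | $[-1, 1]$ | intercept and linear coefficients, uniform |
| `pair_range` | $[-0.5, 0.5]$ | pairwise coefficients, uniform (weaker than linear) |
| `b` | 0.2 | process-noise amplitude |
| `o` | — | observation error level (half-width of uniform error) |
| `n_series` | 20 | independent initial conditions, uniform $[-1,1]$ |
| `n_timepoints` | 10 | observed rows per series (9 transitions) |
| `dt` | 0.2 | time step; small enough to avoid divergence, large enough for visible change |

Twenty series of ten points give 200 observed rows and 180 transition
equations per trial — enough to determine the 7 coefficients of an
in-degree-3 gene comfortably, while a single long series of the same
total length would overfit. A completion trial perturbs the true
network by `h_del` random spurious additions and `k_add` random
deletions (rejecting duplicates, uniform over valid edit sets), hands
the perturbed network to the completion run, and scores the result by
edit accuracy — the fraction of the $h+k$ performed edits that are
correct — and by the success flag (exact restoration). An inference
trial starts from the edgeless network instead.

The shipped benchmark topology (`benchmark_network("wnt5a")`) is a
10-gene network in which every gene has exactly 3 regulators (30
edges), using the gene names of the WNT5A melanoma study. Its edge set
is a deterministic synthetic surrogate (each gene regulated by the
genes 1, 2 and 4 positions after it in a fixed circular order): the
benchmark statistics exercised here depend on the size and in-degree
structure, not on which particular edges are present. Replicated
networks (`replicate_network()`) scale the benchmark up as disjoint
copies with coefficients resampled per copy, so cross-copy edges are
never correct and the inference task grows genuinely harder with $n$.

All trial randomness flows from one seed, with each trial in a grid
deterministically reseeded from the root seed and its indices, so any
single cell is reproducible in isolation.

What the generator does *not* emulate: real expression data have
non-uniform sampling, gene-specific noise scales, unobserved
regulators, and dynamics that need not follow this bilinear form.
Passing benchmark results therefore demonstrate correctness of the
estimator and optimizer under the model's own assumptions — the
generator draws from exactly the model family being fitted — not
performance on microarray data. The TSV loader's linear-interpolation
flag (`read_timeseries(..., interpolate_missing = TRUE)`) supports
real data with scattered missing values, but no claim about real-data
accuracy is made or tested here.

## Design choices

* **Budgets are exact, not upper bounds.** Exactly $h$ deletions and
  $k$ additions are performed; minimality in the Occam's-razor sense is
  explored by running the program over a range of budgets rather than
  automated away.
* **Per-node caps and budgets interact.** The per-node enumeration is
  clamped to $\min(H, h)$ and $\min(K, k)$: a node can never usefully
  exceed the global budget, and caps above the budget change nothing.
* **Evaluation counts directed edges.** An edge recovered with the
  wrong orientation counts as wrong, for completion and inference
  alike.
* **Accuracy formula.** Edit accuracy is
  $(h + k - |E_{orig}| + |E_{orig} \cap E_{cmpl}|)/(h+k)$, clamped to
  $[0,1]$: since the budgets force $|E_{cmpl}| = |E_{orig}|$, each
  missing original edge corresponds to one wrong edit, so the score is
  1 exactly when all edits are correct and 0 when none is.
* **Random baseline.** For context when reading inference results,
  `random_baseline(n_select, n_possible, n_true)` gives the expected
  number of correct edges under uniform selection without replacement,
  $n_{true}/n_{possible} \times n_{select}$ — e.g. 6.94 of 25 for a
  25-edge network over 90 candidate edges.

## Problem sizes and limitations

The per-gene enumeration grows as $n^{H+K}$, so the method is practical
for bounded in-degree and small caps ($K \le 3$) on networks up to on
the order of 100 genes; there is deliberately no greedy fallback for
larger caps. The test suite validates the dynamic program against
global brute-force enumeration on 5-gene instances and runs the
benchmark grids at reduced trial counts (16–100 trials per cell, 10
trials for the 30-gene inference benchmark), and
`scripts/acceptance.R` reproduces the headline benchmark numbers at
100/30/10 trials in a few minutes on one CPU. Statistical tolerances in
the suite are set from the sampling noise those counts imply.

Known limitations: plain least squares with no regularization
(a penalty would change the objective the DP optimizes and is left out
on purpose); a single shared observation error level in the benchmark
protocol; no automatic budget selection; no undirected-match scoring
mode.
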