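---
title: "Modelling and removing ambient RNA contamination in single-cell counts"
author: "scAmbient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and removing ambient RNA contamination in single-cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scAmbient)
library(Matrix)
```

## The problem

In droplet-based single-cell RNA-seq, free-floating mRNA from lysed or
stressed cells — ambient RNA — is captured and barcoded together with each
cell's own transcripts. The observed UMI count vector of a cell is
therefore a mixture: most counts come from the cell's native
transcriptome, but a fraction reflects the ambient pool, which is itself
a blend of every population present in the suspension. Marker genes of
one cell type then appear, at low level, in all others, which distorts
differential expression, marker detection and cluster interpretation.

scAmbient estimates the contamination fraction of every cell and splits
the observed gene-by-cell matrix into a native and a contamination
matrix, given (only) the raw counts and a per-cell population label.

## The model

Let $X$ be the $G \times M$ count matrix and $z_j \in \{1,\dots,K\}$
the population of cell $j$ with $N_j$ total UMIs. Each population $k$
has a native expression profile $\phi_k$, a multinomial distribution
over genes. Transcript $t$ of cell $j$ carries a latent indicator
$y_{jt}$: with probability $\theta_j$ it is native and drawn from
$\phi_{z_j}$; otherwise it is contamination and drawn from

$$\eta_k \;=\; \sum_{k' \neq k} w_{k'}\, \phi_{k'},$$

a weighted combination of all *other* populations' profiles, with
$w_{k'}$ the share of population $k'$ in the expected native
transcripts outside $k$. This encodes the physical origin of the
ambient pool: populations that produce more native mRNA contribute more
contamination, and a gene highly expressed in *other* populations gets
high probability under $\eta_k$. The per-cell native proportion
$\theta_j$ has a shared prior $\mathrm{Beta}(a_1, a_2)$, which pools
information on the contamination level across the dataset.

Note that the model never uses normalised expression — all estimates are
computed from raw counts, avoiding any dependence on a normalisation
method.

## Variational inference

The posterior over $(\theta, Y)$ is approximated by a factorised
family: a Beta $(\gamma_{j1}, \gamma_{j2})$ per cell and a Bernoulli
responsibility per transcript. Because every update depends on a
transcript only through its gene, responsibilities collapse to one
value $\pi_{jg}$ per (cell, gene) pair with a nonzero count, weighted
by the count — this equivalence is verified against a literal
per-transcript implementation in the test suite. Coordinate ascent on
the evidence lower bound (ELBO) alternates:

* **responsibilities**:
  $\pi_{jg1} \propto \phi_{z_j g} \exp(\Psi(\gamma_{j1}) -
  \Psi(\gamma_{j1}+\gamma_{j2}))$, and analogously for the
  contamination side with $\eta$ and $\gamma_{j2}$ ($\Psi$ is the
  digamma function);
* **Beta posteriors**:
  $\gamma_{ji} = a_i + \sum_g x_{jg}\,\pi_{jgi}$, so
  $\gamma_{j1}+\gamma_{j2} = a_1 + a_2 + N_j$ always;
* **native profiles**:
  $\phi_{kg} \propto \sum_{j: z_j = k} x_{jg}\, \pi_{jg1}$;
* **contamination profiles**: $\eta_{kg}$ proportional to the total
  expected native count of gene $g$ over all cells *outside* $k$. This
  is algebraically identical to first computing the weights $w_{k'}$
  (each outside population's share of expected native transcripts) and
  then combining the outside populations' expected-native profiles;
  both routes are compared to $10^{-12}$ in the tests.
* **prior hyperparameters** (optional): a damped Newton step on the
  marginal objective of $(a_1, a_2)$, using the digamma gradient and
  the trigamma Hessian
  $H_{ii} = M(\Psi'(a_1+a_2) - \Psi'(a_i))$,
  $H_{ij} = M\,\Psi'(a_1+a_2)$. Steps are halved (at most 20 times)
  until both components are positive and the objective has not
  decreased; a numerically singular Hessian skips the update with a
  warning. Both derivatives are validated against central finite
  differences.

The per-cell contamination estimate is the variational posterior mean
$\gamma_{j2} / (\gamma_{j1} + \gamma_{j2})$, and the decomposition is
$\text{native}_{jg} = x_{jg}\pi_{jg1}$,
$\text{contamination}_{jg} = x_{jg}(1 - \pi_{jg1})$, which reproduces
the observed matrix entrywise by construction.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `a1`, `a2` | 10, 10 | Beta prior on the native proportion; symmetric and mild, so the data dominate after a few hundred UMIs |
| `estimate_prior` | `TRUE` | learn $(a_1,a_2)$ by empirical Bayes; set `FALSE` to keep the stated prior and obtain a provably monotone ELBO trace |
| `pi_init` | 0.9 | initial native responsibility, i.e. an assumed 10% contamination; any value in (0,1) converges to the same fixed point in practice |
| `tol` | 1e-3 | stop when no cell's contamination fraction moved more than this between sweeps — the quantity users consume, cheap to monitor |
| `max_iter` | 500 | sweep cap; typical datasets converge in 20–60 sweeps |
| `epsilon` | 1e-20 | smoothing floor added to profile numerators before row normalisation; prevents $\log 0$ with negligible distortion |
| `min_counts`, `min_cells` | 3, 3 | gene inclusion rule: at least 3 counts across at least 3 cells |
| `integer_output` | `FALSE` | per-cell largest-remainder rounding of the native matrix; documented as lossy |

Labels must describe at least two populations: with $K = 1$ the
contamination distribution — built from the *other* populations — does
not exist, and the fit refuses to start. Zero-count cells are dropped
with a warning. A population whose expected native mass vanishes gets a
uniform profile and a warning rather than a failure.

## Numerical choices

* **Initialisation.** $\phi_k$ starts at the smoothed, normalised raw
  count sums of population $k$; $\eta_k$ and the weights are computed
  from the same masses via the contamination update; $\gamma_j =
  (a_1 + 0.9\,N_j,\; a_2 + 0.1\,N_j)$. The fit contains no random
  draws, so results are bit-reproducible given inputs and
  configuration; the only seeds live in the simulator and the fallback
  clustering.
* **Update order.** Within a sweep: responsibilities, Beta posteriors,
  native profiles, contamination profiles (recomputed from the fresh
  $\phi$, not lagged a sweep), then the optional Newton step. The ELBO
  is recorded after the profile updates of each sweep.
* **ELBO monotonicity.** The responsibility, $\gamma$ and $\phi$
  updates are exact coordinate maximisations, but $\eta$ is *defined*
  as the pooled outside-population profile rather than chosen to
  maximise the bound, so monotonicity of the recorded trace is an
  empirical property, not a theorem. In practice the trace is
  non-decreasing throughout the convergent phase; forcing hundreds of
  extra sweeps past convergence (`tol = 0`) on very small datasets can
  produce sub-1e-3 wobbles from this $\eta$ redefinition. At the test
  suite's reference scale (200 cells, 50 forced sweeps, fixed prior)
  the trace is monotone to 1e-6.
* **Rounding.** The real-valued decomposition is exact; the optional
  integer mode floors each native entry and promotes the largest
  fractional remainders within each cell until the cell's native total
  matches the rounded real-valued total, never exceeding the observed
  count, so conservation survives rounding.

## The simulator

`simulate_ambient_counts()` mirrors the generative model: population
profiles drawn from a symmetric Dirichlet, per-cell native proportion
from $\mathrm{Beta}(a_1, a_2)$ (or fixed), `round(theta * N)` native
UMIs from the cell's own profile (round-half-even, unbiased) and the
remainder from a weighted combination of the other populations'
profiles. Its defaults are the package's reference conditions: 3
populations, 500 genes, 600 cells, 1000 UMIs per cell,
$\theta \sim \mathrm{Beta}(8, 2)$ — a mean contamination of 20%, the
level used throughout the recovery tests. The default profile
concentration of 0.1 produces the heavy-tailed, largely
population-specific expression profiles typical of sorted cell types;
the contamination weights default to each population's expected native
UMI mass (matching the model's definition of the ambient pool), with a
`"uniform"` mode for stress testing, since the physical pool
composition is not observable.

What the simulator does *not* emulate: doublets, empty droplets,
sequencing error, UMI collisions, overdispersed per-cell depth, batch
effects, or continuous/overlapping cell states. Passing the recovery
tests therefore shows the inference recovers the model's own truth at
realistic scale — it does not certify accuracy on tissues whose
populations share substantial expression, where the method is
deliberately conservative and keeps shared counts as native.

## The fallback clustering

When no labels are supplied, `estimate_clusters()` library-size
normalises to 10,000 counts per cell, applies `log1p`, projects onto
the top 10 principal components and runs k-means with a fixed seed
(re-initialising up to 10 times if a cluster comes back empty). This is
a deliberately minimal stand-in so the tool is usable end-to-end; it is
not a published clustering method, the number of clusters must be
supplied by the user, and for serious work the labels from your actual
clustering pipeline are preferable. Broader population labels are often
better than fine subclusters: contamination profiles are built from
*other* populations, so splitting one lineage into many subclusters
removes that lineage's shared genes from its own contamination
estimate.

## Problem sizes in the test suite

The suite exercises exact-equivalence oracles on tiny instances (up to
3 cells, 5 genes, 10 UMIs per cell, where per-transcript enumeration is
cheap), invariants on hundreds of randomized small instances, and
parameter recovery at the reference scale of 600 cells by 500 genes at
1000 UMIs per cell — a size chosen to be large enough for stable
population profiles while keeping the full suite fast on a laptop.

## Known limitations

* Cluster labels are required (or delegated to the fallback); label
  quality bounds estimate quality.
* Populations with strongly shared expression lead to conservative
  contamination estimates — shared counts are attributed to native
  expression by design, so true biology is not removed.
* One matrix and one label vector per run; multi-batch or multi-channel
  designs are the caller's loop, and channel-specific ambient pools are
  not modelled.
* Cells that are in truth doublets show up as highly contaminated
  rather than being detected as doublets; use a dedicated doublet
  caller for that purpose.
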