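---
title: "Propagation on coding-non-coding gene-disease networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagation on coding-non-coding gene-disease networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Curated associations between diseases and their causal genes — both
protein-coding genes and long non-coding RNAs (lncRNAs) — form a bipartite
network: genes on one side, diseases on the other, an edge wherever a
mutation or dysfunction of the gene is implicated in the disease. Known
lncRNA-disease associations are sparse, so the practical question is
prioritization: given what is curated, which unobserved gene-disease pairs
are most plausible? lncProp implements a network answer: genes that share
diseases are related, and a gene related to many genes of a disease is a
candidate for that disease.

# Model

## Resource-allocation weighting

Let $a_{il} \in \{0,1\}$ be the bipartite adjacency between gene $x_i$ and
disease $y_l$, with degrees $k(x_i)$ and $k(y_l)$. The gene projection is
weighted by the two-step resource-allocation process: each gene splits one
unit of resource equally over its diseases, then each disease splits what
it received equally over its genes. Collapsing both steps,

$$w_{ij} = \frac{1}{k(x_j)} \sum_l \frac{a_{il}\,a_{jl}}{k(y_l)},$$

the fraction of gene $j$'s resource that lands on gene $i$. Properties the
package tests and relies on:

* columns of connected genes sum to exactly 1 (resource conservation);
* $w_{ij} > 0$ iff $i = j$ (connected) or $i, j$ share a disease;
* the detailed-balance relation $w_{ij} k(x_j) = w_{ji} k(x_i)$;
* a degree-0 gene receives an all-zero row and column rather than an
  error, so gene indexing is stable when edges are held out upstream.

`two_step_spread()` keeps the two-step process as executable definition;
`resource_allocation_weights()` must agree with it entrywise to 1e-12,
which is the package's primary correctness oracle for the weighting.

The self-return weight $w_{jj}$ is produced by the process itself (a
gene's resource partly returns to it) and is **kept** during propagation;
`zero_diagonal = TRUE` removes it for sensitivity analysis.

## Propagation

For a query disease $d$, the initial information $Y$ is 1 on genes
associated with $d$ and 0 elsewhere. Scores follow the semi-supervised
propagation iteration

$$F_t = \alpha W F_{t-1} + (1-\alpha) Y, \qquad F_0 = Y,$$

whose limit solves $(I - \alpha W) F = (1-\alpha) Y$. The closed form is
implemented separately (`propagate_closed_form()`, a direct linear solve)
and used as the independent oracle for the iterative path: the spectral
radius of $\alpha W$ is below 1 for $\alpha < 1$ because the columns of
$W$ sum to at most 1, so the system is never singular.

Genes *not* associated with $d$ are ranked by descending score. Ties are
broken by ascending gene id in locale-independent (radix) order: ranks
define prediction sets, so they must be deterministic across platforms.
The prediction set is the top $\lceil 0.01\,n \rceil$ candidates (never
empty when candidates exist) or a user-chosen top-$k$ (default 10).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.618 | weight of propagated vs. initial information |
| `tol` | 1e-5 | stopping threshold on the deviation statistic |
| `stat` | `"mad"` | mean absolute deviation between consecutive score vectors |
| `max_iter` | 1000 | safeguard; convergence is geometric and reached in tens of iterations |
| `fraction` | 0.01 | top-fraction prediction rule |
| `delta_max` | 100 | largest rank threshold of the ROC sweep |

The stopping statistic deserves a note. With the **mean absolute**
deviation at `tol`, the stopped iterate is within roughly
$\alpha/(1-\alpha) \cdot \texttt{tol}$ of the closed-form limit (about
$1.6\times$`tol` at the default $\alpha$), so iterative and closed-form
scores agree to a small multiple of `tol`. A **mean squared** deviation
threshold of the same numerical value stops while per-gene deviations are
still near $\sqrt{\texttt{tol}}$, leaving scores order-of-$10^{-3}$ from
the limit at `tol` = 1e-5. Because ranks — not raw scores — drive every
downstream result, both statistics give the same predictions in practice;
the absolute form is the default so that the score vector itself is
well-converged, and `stat = "msd"` is available.

A propagation invariant worth stating precisely: scores are non-negative,
and when no gene is isolated the iteration conserves total mass,
$\mathbf{1}^\top F = \mathbf{1}^\top Y$. Individual scores of hub genes
*can* exceed 1 even for 0/1 initial information — $W$ is column-stochastic
but its rows need not sum to 1 — which is why the tests assert
non-negativity and mass conservation rather than a unit upper bound per
gene.

# Evaluation

## LOOCV and the rank-threshold ROC

Each retained association $(g,d)$ is hidden in turn. The weight matrix is
**rebuilt on the reduced network** for every fold — removal changes both
endpoint degrees, and the held-out edge must not leak into $W$ — then the
propagation runs for $d$ and the rank of $g$ among $d$'s candidates is
recorded. Degree-one nodes are removed first (single pass over the input
degrees): a held-out edge at a degree-one endpoint isolates the node,
which can then receive no information. Single-pass pruning is the literal
reading of removing "the nodes whose degree was one"; `iterate = TRUE`
prunes to a fixpoint for comparison.

For rank thresholds $\delta = 1..100$, TPR($\delta$) is the fraction of
held-out associations recovered within the top $\delta$ and FPR($\delta$)
the fraction of unassociated pairs ranked within the top $\delta$. The AUC
is the trapezoid over the (FPR, TPR) sweep with endpoints $(0,0)$ and
$(1,1)$ appended, because the $\delta$-sweep need not reach FPR $=1$.
Negative (unassociated-pair) ranks are computed **once from the full
filtered network**: the FPR definition does not tie negatives to folds,
and per-fold recomputation multiplies cost by the edge count for the same
asymptotics. `per_fold_negatives = TRUE` switches to the per-fold variant.

## Randomization and robustness

The null model throughout is the degree-preserving double edge swap:
pick edges $(g_1,d_1)$, $(g_2,d_2)$, rewire to $(g_1,d_2)$, $(g_2,d_1)$,
reject the swap if it would duplicate an edge; 10$\times$|edges| attempts
by default. Every gene and disease degree is preserved exactly.

The MSS-style robustness test fixes the top-1% prediction set on the full
network, then repeatedly (a) drops 10% of edges uniformly and (b)
shuffles the network degree-preservingly, re-running the prediction on
each, and counts per fixed prediction how often it recurs ($R$ under
resampling, $R_r$ under randomization). "Re-predicted" means the pair
lands in the replicate's own top-1% set, with the threshold recomputed on
the reduced candidate pool. The comparison statistic is a z-test of the
mean recurrence rate against the per-replicate random recurrence
distribution, with sample (n−1) standard deviation.

Projection topology (degree histograms with a descriptive log-log slope,
Watts-Strogatz local clustering, giant components) is compared against
degree-sequence-preserving rewires of the projection. The network average
clustering coefficient counts degree-<2 vertices as 0 by default
(`include_low_degree = FALSE` excludes them; published averages rarely
say which convention they use, so both are exposed). No power-law
exponent is fitted by maximum likelihood: the log-log slope is
descriptive only.

# The synthetic generator

Real curated lncRNA-disease tables are not redistributable here, so every
fixture is generated. The generator plants exactly the structure the
method exploits:

* **Disease classes.** Diseases are partitioned into ~20 phenotype
  classes; each gene has a home class. A gene's edges fall in its home
  class with odds multiplied by `within_class_bias`.
* **Heavy-tailed degrees.** Genes and diseases are drawn with weight
  $(\text{degree}+1)^p$, $p = 1/(\texttt{degree\_exponent}-1)$; the
  default exponent 2 gives linear preferential attachment and
  hub-dominated tails on the gene side (median gene degree 1).
* **Hidden truths.** Extra pairs drawn by the same biased rule but never
  emitted form a planted recovery target.

Defaults were fixed once, by a small design calibration run before any
acceptance test was written: `within_class_bias = 100` concentrates about
84% of a gene's edges in its home class — consistent with the
observation that most disease-associated lncRNAs act within a single
disease class — and yields clearly recoverable planted signal (LOOCV AUC
around 0.75 on the small preset) while degree-preserving shuffles stay
near 0.5. With `within_class_bias = 1` the generator is a pure
preferential-attachment null and shows no same-class enrichment, which
the tests use as a negative control.

Two presets: `"small"` (60 diseases, 70 lncRNAs + 180 coding genes, 500
edges) runs the full pipeline in seconds and is the scale used by the
test suite and the acceptance script; `"paper_scale"` (214 diseases, 295
lncRNAs + 801 coding genes, 1558 edges) matches the size of a realistic
curated integration and is used for structural checks only.

What the generator does **not** emulate: curation noise and literature
ascertainment bias (hub diseases are over-studied, not just
over-connected); correlated gene classes (a real gene can act in several
classes); disease-disease similarity beyond class identity; and any
specific gene or disease identity. Passing tests therefore demonstrate
that the pipeline recovers planted co-association structure, not that it
attains any particular accuracy on curated human data.

# Numerical and design notes

* Dense $W$ below 2000 genes, sparse above; identical contract.
* `max_iter = 1000` is a safeguard only; the contraction factor is
  $\alpha$ per iteration.
* Shuffle, generator, robustness and ensemble functions take explicit
  `seed` arguments and are bit-reproducible given (input, seed).
* Degenerate inputs: a disease with no genes propagates to all-zero
  scores with a warning; a network that filters to nothing makes
  `loocv()` fail loudly; a projection ensemble with zero swaps raises a
  zero-variance error rather than reporting z = Inf.
* Problem sizes in the shipped tests: LOOCV ensembles use the small
  preset (about 440 folds after degree filtering, roughly a second per
  replicate); the robustness check uses 100 resamples; the shuffle
  calibration in the acceptance script uses 50 replicates. These sizes
  were chosen to make the stochastic assertions stable at desk scale.

# Limitations

Replacing a biological gene-similarity matrix with the weighted
projection of the very network being evaluated means information flows
only through observed co-association; genes with a single known disease
are uninformative once that edge is hidden, which is exactly why LOOCV
prunes degree-one nodes. AUC values on synthetic fixtures calibrate the
machinery, not biological performance. The package deliberately omits
literature mining, identifier mapping to curated databases, and module
detection.
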