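---
title: "Classifying small-sample transcriptomes by spectral conjugate gradient NMF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying small-sample transcriptomes by spectral conjugate gradient NMF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgnmf)
```

## The problem

Expression profiling of a hybrid fish panel — or any comparable design —
produces a matrix with tens of thousands of gene rows and only a handful of
sample columns. With 8 samples and ~20000 features, k-means and PCA are
unreliable: there are far too few observations per feature to estimate the
quantities those methods rest on. Nonnegative matrix factorization (NMF)
handles this regime naturally because it models the *columns*: each sample
is approximated as a nonnegative combination of a small number of
nonnegative gene-expression signatures.

Given a nonnegative matrix $A \in \mathbb{R}^{n \times m}$ (genes × samples)
and a class count $r$, the package solves

$$\min_{W, H \ge 0} \; F(W, H) = \tfrac12 \lVert A - WH \rVert_F^2,$$

with $W \in \mathbb{R}^{n \times r}$ the **basis matrix** (column $k$ is the
expression signature, or metagene, of class $k$) and
$H \in \mathbb{R}^{r \times m}$ the **coordinate matrix** (column $j$ locates
sample $j$ in the span of $W$'s columns). In the ideal case where each
column of $H$ has a single nonzero, $r$ is exactly a partition of the
samples into $r$ classes; real data only approximates this, which is why a
soft membership matrix (below) accompanies every fit.

## Preprocessing

`normalize_rows()` rescales each gene row to $[0, 1]$ by its own min and
max. This puts all genes on a common scale before the factorization so
that a handful of high-count genes cannot dominate the Frobenius objective.
A constant row has no min–max range and no class signal; it is mapped to
all zeros (and counted) rather than dividing by zero. The row minima and
maxima are kept on the object so reports can refer back to raw values.

## The solver

### Alternating subproblems

`nmf_factorize()` alternates two convex least-squares subproblems: minimize
over $W$ with $H$ fixed, then over $H$ with $W$ fixed. Each subproblem is
solved *unconstrained* by the spectral conjugate gradient method below,
warm-started from the previous factor, and the result is then projected
onto the nonnegative orthant entrywise ($x \mapsto \max(x, 0)$). The outer
loop stops when the projected-gradient KKT residual falls to a fixed
fraction $\varepsilon$ of its value at the random start,
$\mathrm{KKT}(W, H) \le \varepsilon\,\mathrm{KKT}(W^0, H^0)$, or when
`max_outer_iter` sweeps have run. The *relative* form matters: the iterates
can stagnate in a curved valley where an absolute threshold would never
fire, while the ratio still records how far the run got from its start.

The KKT residual used is the standard first-order measure for
bound-constrained problems: for each factor entry the residual equals the
partial derivative where the entry is positive, and $\min(0, \partial F)$
where the entry sits at zero; the scalar is the Frobenius norm over both
factors. It is zero exactly at a KKT point, and the stopping *ratio* is
invariant to any constant rescaling of this definition.

### The spectral conjugate gradient inner solver

Each subproblem is a quadratic in the free factor. `solve_subproblem()`
iterates

* direction: $D_0 = -G$; for $k \ge 1$,
  $D_k = -\theta_k G_k + \beta_k D_{k-1}$, where $\theta_k$ (a spectral
  scaling of the gradient) and $\beta_k$ (a conjugacy coefficient) are
  computed from the iterate difference $s_{k-1}$, the gradient difference
  $y_{k-1}$, and the component $\bar y_{k-1}$ of $y_{k-1}$ orthogonal to
  the current gradient. Two branches are used, switching on whether
  $\langle D_{k-1}, \bar y_{k-1}\rangle$ exceeds
  $\eta \lVert G_{k-1}\rVert^2$;
* line search: the largest step $\alpha = \rho^l$ satisfying the
  Armijo-type inequality
  $F(X + \alpha D) \le F(X) + \delta_1 \alpha \langle G, D\rangle
  - \delta_2 \alpha^2 \lVert D \rVert^2$, whose extra curvature-penalty
  term guarantees a *strict* decrease of at least
  $\delta_2 \alpha^2 \lVert D\rVert^2$ per accepted step;
* stop when $\lVert G \rVert \le \varepsilon$ (Frobenius norm).

Because the subproblem is an exact quadratic, the objective along any
direction is a quadratic in $\alpha$ whose coefficients come from cached
Gram products — the line search costs a few scalars per trial step, and
the gradient updates incrementally as $G \leftarrow G + \alpha D B B^\top$.
The inner loop is implemented twice: a compiled loop (the default) and a
pure-R reference assembled from the exported building blocks
(`initial_direction()`, `curvature_quantities()`, `spectral_params()`,
`search_direction()`, `backtracking_step()`); the test suite drives both
and checks they produce the same iterates.

### Safeguards

Three situations the printed recursion does not itself exclude are handled
explicitly, and each is counted in the fit's `restarts`:

* **Non-descent directions.** In floating point (or with degenerate
  curvature) $D_k$ can fail $\langle G, D_k \rangle < 0$; it is replaced by
  $-G$, preserving the line-search precondition.
* **Vanishing denominators.** Any branch denominator smaller than
  `1e-300` in magnitude triggers the same steepest-descent restart rather
  than a division.
* **Extreme-norm directions.** Rarely the conjugate recursion emits a
  direction with enormous norm (we have observed
  $\lVert D\rVert^2 \sim 10^9$ near rank-deficient Gram matrices). The
  curvature-penalty term then rejects *every* step $\rho^l$ down to
  $l = 60$. Rather than aborting the whole factorization, the solver
  retries the iteration once from $-G$ — for a convex quadratic a
  steepest-descent step satisfying the inequality always exists — and only
  a failure of that retry is raised as an error.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `delta1` | 0.4 | sufficient-decrease coefficient of the line search |
| `delta2` | 0.001 | curvature-penalty coefficient (forces strict descent) |
| `eta` | 0.001 | branch threshold for the $\theta,\beta$ formulas |
| `rho` | 0.65 | backtracking contraction; steps are $\rho^l$ |
| `epsilon` | 1e-7 | inner gradient tolerance and outer relative-KKT tolerance |
| `max_inner_iter` | 1000 | iteration cap per subproblem |
| `max_backtracks` | 60 | line-search cap ($\rho^{60} \approx 6\cdot10^{-12}$) |
| `max_outer_iter` | 200 | outer sweep cap |

The first five are the established working values for this method; the
same constant $\varepsilon$ serves both tolerances (separate knobs exist
with equal defaults). The caps are ours: the method's sources state none,
and uncapped loops are not acceptable in production code. Classification
results on well-separated data are insensitive to `rho` anywhere in
$[0.05, 0.75]$ — the test suite checks partition invariance over
$\rho \in \{0.05, 0.35, 0.65, 0.75\}$ and across ten random
initializations.

### What descent is — and is not — guaranteed

Within one subproblem the objective trace decreases strictly at every
accepted step. Across *outer* sweeps, however, this scheme solves each
subproblem without sign constraints and projects afterwards, and the
projection can undo part of the subproblem's progress: on unstructured
random matrices we observe occasional sweeps where $F$ *rises* before
resuming its descent. This is a property of the solve-then-project
alternation itself, not of our implementation — descent overall
(final $\le$ initial) holds in every run we generate, and on structured
expression-like data the trace is monotone in all but rare transient
spikes. The relative-KKT stop does not depend on monotonicity. Related,
on unstructured data the alternation can settle in a basin slightly worse
than 500 multiplicative-update iterations from the same start (we observe
final objectives up to ~10% above the multiplicative-update baseline on a
few percent of random $50 \times 8$ instances at $r = 6$, while structured
data always reaches parity); the acceptance script reports the measured
parity ratio rather than hiding it.

## Classification

### Membership matrix

`membership_matrix()` converts a fit into soft memberships. For sample $j$,
each gene $g$ with positive reconstructed expression contributes the share
$W_{g i} h_{i j} / \sum_k W_{g k} h_{k j}$ that class $i$ explains of it;
$R_{i j}$ averages these shares over the contributing genes ($n'_j$ of
them, reported per sample). Columns of $R$ sum to 1 by construction.
Genes whose denominator is zero for a sample are excluded from that
sample's average — including them under any convention would break the
column-sum identity. A sample with *no* contributing gene has undefined
membership and is reported by name.

### Hard assignment and the H-versus-R question

`assign_classes()` assigns each sample the argmax of its score column,
ties to the lowest class index, and records a per-sample clarity measure
`ratio_gap` (largest over second-largest entry; infinite when the
second-largest is 0). Scores can be the membership matrix $R$ or the raw
coordinate matrix $H$. The two agree when the rows of $W$ share an order
of magnitude, but the factorization is only determined up to a positive
diagonal rescaling $W D^{-1}, D H$, and a fit can place wildly different
scales on different rows of $H$ — in which case the raw-$H$ argmax follows
the scaling, not the structure. $R$ is invariant to that rescaling in its
gene shares, so membership-based assignment is what the package's own
accuracy measurements use; both sources remain available because their
disagreement is itself diagnostic of unbalanced basis magnitudes.

### Choosing the number of classes

`select_rank()` fits every candidate rank (several seeded starts each) and
selects the elbow of the objective: the largest $r$ whose best objective
improves on $r - 1$ by at least the fraction `min_gain` (default 0.5,
i.e. a new class must at least halve the unexplained signal). Gains are
not credited once the objective is below $10^{-8}$ of
$\tfrac12\lVert A\rVert_F^2$, so an already-exact fit is not "improved"
further. We deliberately do *not* select by counting clearly-classified
samples: when the rank is too small, the fit merges two classes into one
shared basis column and the merged samples still look perfectly clear, so
clarity counting systematically favors under-fitting (we verified this
both on generated data and by computing ratio gaps on published coordinate
tables of this method). Clarity diagnostics (`n_clear` at threshold `tau`,
default 5, and median gaps) are still reported per rank, along with a
`no_structure` flag when no rank clears the gain threshold — the user can
always override from the diagnostics table.

### Downstream analyses

`sample_correlation()` computes the Pearson (optionally Spearman)
correlation between sample columns. Its role is quality control: a
replicate that correlates less with its own siblings than with other
samples carries detection error and explains its own misclassification.
`top_genes()` ranks genes per class by basis weight after scaling each
column to unit maximum (ranking is then invariant to the scale ambiguity);
`shared_genes()` intersects the per-class lists. The "highly expressed"
cutoff is a list length, `k` (default 200): intersection counts are
threshold-dependent, so the knob is exposed rather than hidden.

## The synthetic generator

`planted_matrix()` builds $A = \max(0, W^* H^* + \text{noise})$ with known
structure: disjoint blocks of `signal_genes_per_class` high-weight genes
per class (weights uniform in 0.8–1.2 over a uniform background below
0.05), near-one-hot coordinate columns (dominant weight 1, off-class 0.02,
so the dominant class holds $\ge 80\%$ of column mass up to $r = 13$), and
zero-truncated Gaussian noise. The default 500 genes × 8 samples × 6
classes is a down-scaled version of the motivating design (8 fish, 6
classes, ~20000 genes); tests that need a rank sweep use 400 × 12 so every
candidate rank stays below the sample count, and the full-scale timing
check uses $20093 \times 8$. Noise is Gaussian rather than count-like on
purpose: the pipeline consumes min–max-normalized values in $[0, 1]$, and
a count model would add realism the code paths never see. Consequently,
passing tests demonstrate correct recovery of planted low-rank structure
under additive noise — they do not certify behavior under RNA-seq
dispersion, library-size, or mapping-bias effects, which the generator
deliberately does not model.

`replicate_groups()` emulates repeated sampling periods: each base sample
is re-emitted per period with coordinates
$\text{rc} \cdot H^*_{:,j} + (1-\text{rc}) \cdot u$, $u$ uniform, so
sibling correlation rises monotonically with the fidelity parameter
`replicate_corr`; designated outlier samples instead receive an
independent random near-one-hot column, mimicking a sample with large
detection error. At `replicate_corr = 1` and zero noise, replicates are
identical.

## Numerical choices, degeneracies, tie-breaks

* Constant gene rows normalize to zeros, not NaN; their count is kept.
* Exact ties in `assign_classes()` go to the lowest class index; ties in
  gene ranking go to the lower gene index (file order), making outputs
  reproducible.
* Classes that die during alternation (all-zero basis column or
  coordinate row) are re-seeded with uniform noise at scale $10^{-4}$ and
  counted — a dead class would otherwise make membership denominators
  degenerate.
* A zero KKT residual at the random start (probability zero in theory, a
  degenerate input in practice) is an error instructing a reseed.
* Class labels are arbitrary under the permutation ambiguity of NMF, so
  every comparison across runs uses *partitions* of the sample set
  (`same_partition()`), never label values.
* All randomness flows through explicit integer seeds; the caller's RNG
  state is saved and restored around every draw.

## Problem sizes used by the shipped checks

The test suite and the acceptance script generate everything they consume:
gradient checks on matrices up to $6 \times 4$; line-search contracts on
1000 random descent steps; recovery and robustness runs on
$500 \times 8$ / $300 \times 8$ six-class panels over ten seeds; rank
scans on $400 \times 12$ panels for planted $r = 2,\dots,6$; baseline
parity on twenty $50 \times 8$ instances; and one full-scale
$20093 \times 8$ factorization as a timing smoke test. These sizes were
chosen so the full suite completes in minutes on a single CPU while still
exercising every code path at the study's true aspect ratio.

## Known limitations

* The factorization is non-convex and non-unique; different seeds can give
  different $W, H$ even when the induced partition is stable. Numeric
  entries of $W$ and $H$ are therefore not comparable across runs, only
  partitions and memberships are.
* The solve-then-project alternation has no global descent guarantee
  across sweeps (see above) and can, on unstructured data, converge to a
  basin slightly worse than multiplicative updates.
* Membership averaging weights every contributing gene equally; a few
  genes with near-zero reconstructed expression contribute shares as
  noisy as any other gene's.
* The elbow rule assumes candidate ranks are consecutive; gains are not
  meaningful across holes in the scan.
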