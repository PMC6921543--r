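---
title: "Inferring Boolean networks from temporal cytokine panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring Boolean networks from temporal cytokine panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytobool)
```

## The problem and the model

Macrophages polarize into distinct activation phenotypes (classically
activated M1 under LPS; alternatively activated M2a under IL-4 and M2c
under IL-10), and the cytokines they secrete are both the drivers and the
read-out of that process. `cytobool` models a panel of secreted cytokines
as a *synchronous Boolean network*: each protein is up- (1) or
down-regulated (0), and every protein's next state is a logic function of
its regulators' current states. The package turns a sparse temporal
protein panel — here 27 cytokines at 7 time points (0, 0.5, 1, 3, 6, 12,
24 h) with 4 replicates per stimulus — into such a network in six stages,
each exposed as ordinary functions and driven by the numbered scripts
under `analysis/`:

1. **Profile enrichment.** Each profile is fitted with a penalized
   smoothing spline minimizing
   $p\sum_i a_i (x_i - s(t_i))^2 + (1-p)\int s''(t)^2\,dt$
   over natural cubic splines, and resampled on a 50-point grid.
2. **Binarization.** A per-protein activation threshold $\delta_i$ comes
   from one-dimensional K-means under the absolute-deviation objective
   $J = \sum_j \sum_{i \in C_j} |x_i - C_j|$, cascaded from 8 clusters
   down to 2.
3. **Structure inference.** A per-child linear program selects sparse
   regulator sets: minimize
   $\sum_j |w_{j}|\,\bar x_j + \frac{1}{\gamma} w^0 + \frac{1}{\lambda}\sum_l \zeta_l$
   subject to $w^0 + \sum_j w_j x_{j,m} \ge \delta_i$ on samples where the
   child is active and $w^0 + \sum_j w_j x_{j,m} \le \zeta_l$,
   $\zeta_l \ge 0$, where it is inactive. Positive weights are promotion
   links, negative ones inhibition.
4. **Pruning.** A link survives only if its contribution
   $|w_j|\,\bar x_j$ reaches 70% of the largest contribution into the
   same child.
5. **Logic determination.** Each child's truth table is filled from the
   binarized transitions (state at step $k$ to child bit at $k+1$) and
   minimized to a two-level sum-of-products (Quine–McCluskey with free
   don't-cares — the algorithmic equivalent of reading a Karnaugh map),
   then checked against the LP's signs and the transition agreement,
   escalating to pooled per-replicate fitting when either check fails.
6. **Dynamics and reduction.** The network's synchronous dynamics are
   written as $X(k+1) = M \ltimes X(k)$ with $\ltimes$ the semi-tensor
   product and $M$ a $2^N \times 2^N$ logical matrix; attractors and
   basins are enumerated, and the network is reduced to its feedback core
   by stripping output nodes and collapsing pass-through chains.

Three published activation networks (M1, M2a, M2c), with their LP
weights, core node lists, and binarized core trajectories, ship as
fixtures (`macrophage_fixture()`); the packaged state tables reproduce
their printed transitions step for step.

### Modeling assumptions

* Regulation is fixed over the 24-h window: one rule set explains every
  transition.
* Significant regulatory events are slower than the 13.5-min simulation
  interval, so the synchronous update approximates the real kinetics.
* Each protein is well described by two expression regimes separated by a
  single threshold.

## The delta-state convention

A joint state of $n$ nodes is the canonical unit vector
$e^{2^n}_k$ with $k = 1 + $ the integer value of the *complemented* bit
string, first-listed node most significant: all-ones maps to index 1,
all-zeros to $2^n$. This is the indexing induced by the semi-tensor
product of per-node vectors when 1 maps to $(1,0)^T$. `state_to_index()`
and `index_to_state()` implement the bijection, and the packaged state
tables verify it against every printed core state.

`transition_matrix()` builds $M$ two independent ways — algebraically
(per-node structure matrices lifted with Khatri–Rao products of
variable-extraction operators) and by brute-force evaluation of every
state — and the test suite requires them to agree on random networks.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `p` (smoothing) | GCV-selected | — | `p = 1` interpolates, `p = 0` is the least-squares line; with no stated value, generalized cross-validation is the standard automatic rule. Error weights `a_i` default to 1. |
| grid | 40 × 13.5 min + 10 over (9, 24] h | hours | most regulation happens in the first 9 h; 13.5 min is the implied simulation interval. The alternative convention (40 points spanning [0, 9] inclusive, spacing 540/39 min) is available as `resample_grid("inclusive")`. |
| `k_start` | 8 | clusters | the cascade's starting resolution; fine enough to isolate small peaks before merging. |
| `gamma` | 100 | — | bias penalty $1/\gamma$: a large `gamma` makes the bias much cheaper than link weights, pushing explanatory burden onto regulators. |
| `lambda` | 1 (or CV) | expression² | slack penalty $1/\lambda$; cross-validation searches a log grid capped at $L\sigma^2$ (L = inactive-sample count). |
| `prune_fraction` | 0.7 | — | contribution threshold; chosen to minimize links while keeping total weight. |
| `alpha` | 0.01 | — | KS screen significance for keeping a protein versus control. |
| `agreement_threshold` | 0.85 | — | transition-agreement level below which logic fitting escalates to per-replicate data. |

## The synthetic-data generator

Real panels of this design are rarely public, so the generator renders a
*known* Boolean network into continuous panels with the same design
(7 time points, 4 replicates, control + stimulated groups), making every
downstream stage testable against ground truth.

Each node carries a high-state and a low-state *shape kernel* from three
archetypes: promotion $c\,t/(1+t)$, inhibition $c/(1+t) + \mathrm{bias}$,
and a Gaussian bell. The network is simulated on the 13.5-min grid; a
protein's continuous level at time $t$ is its current state's kernel
evaluated at the time since that protein last switched (the kernel clock
resets at each switch, because the archetype shapes describe single
transitions). Replicates differ only by multiplicative lognormal noise
with a detection floor; the control group renders the all-low state.

**Separation condition.** The default kernel pair places the high state
on a plateau at 10 units with a 20% initial overshoot and the low state
below 1 unit. The within-state drift must stay well below the
between-state gap: the binarization threshold is derived from the
globally optimal two-clustering, and if a state is visited only briefly
while the other state drifts more than the gap, the optimal split lands
inside a state band rather than between states. With the default 20%
drift against a 9-unit gap, zero-noise round trips (render, fit with
`p = 1`, resample, binarize) recover the ground-truth trajectory at every
grid point for every node that visits both states. A node that never
leaves one state carries no threshold information — such profiles are
exactly what the sensitivity band and the KS screen are there to catch.

**What the generator does not emulate:** receptor signaling, mRNA
dynamics, cross-regulation of measurement noise, or detection saturation.
Passing the synthetic suites therefore demonstrates the *pipeline's*
correctness under its own assumptions, not biological validity of any
inferred network.

## Identifiability: what the LP can and cannot recover

The structure LP relates *concurrent* samples — the child's activity and
its candidate parents' levels at the same grid point. Three consequences,
verified analytically and empirically during development, shape how the
package is validated:

* The LP constrains the predictor only relative to the threshold
  $\delta_i$ (at least $\delta_i$ on active samples, at most a slack on
  inactive ones). It is a threshold-cover program, not a regression, so
  it does not reproduce expression *values* even on noise-free data.
* For an AND-regulated child, either parent alone covers every active
  sample, and the total inactive slack is invariant to splitting weight
  between the parents — the second parent is not identifiable from the
  LP alone.
* An OR-regulated child's activity is a superset of each parent's, so
  the reversed edge (child covering parent) is always the cheaper cover.

Directed-edge recovery through the LP is therefore intrinsically partial;
its contract is tested as what it is (optimality against an independent
generic solver, sparsity and sign recovery on designed covers, pruning
arithmetic). For end-to-end validation the pipeline offers
`candidates = "all"` (panels of at most 6 proteins): every other protein
enters the child's truth table and the minimization itself discards
non-essential parents. With all $2^n$ initial states rendered as groups
(`pool_groups = TRUE`), truth tables are complete and the inferred
network is exactly logically equivalent to the generator — the
configuration used by the exact-recovery study in `analysis/05` and the
acceptance tests. The default `candidates = "lp"` path keeps the LP's
role of narrowing candidates, which is what makes motifs of more than 5
regulators tractable on 50 samples.

## Numerical and procedural choices

* **Threshold reading.** "Average of the mean distance from each
  cluster" admits two readings; the default takes the midpoint of the two
  final cluster centroids (a single horizontal threshold line), with the
  within-cluster-dispersion reading behind
  `threshold_rule = "dispersion"`.
* **L1 centroids.** The clustering objective uses absolute deviations,
  so centroids are medians; `centroid = "mean"` switches to the L2
  variant.
* **Global final split.** The 8-to-2 merge cascade is deterministic
  (quantile initialization, closest-centroid merging, Lloyd refits), and
  because optimal 1-D clusters are contiguous in sorted order, the final
  two-cluster stage is refined by exhaustive split search; the returned
  2-clustering is the global optimum of its objective.
* **Ties at the threshold** binarize to 0 (strictly-above rule); a zero
  threshold is replaced by the detection floor $10^{-6}$.
* **Inactive-sample constraint.** The slack bounds the predictor *above*
  on inactive samples; this is the reading under which the slack term
  actually penalizes false activation of down-regulated children.
* **Absolute weights** enter the LP by the standard positive/negative
  variable split; parent columns are rescaled to unit maximum before the
  simplex solve (the raw tableau is badly conditioned when expression
  scales differ) and weights are rescaled back.
* **Truth-table conflicts** resolve by majority vote with conflict
  counts retained; an exact tie leaves the row don't-care, since equal
  evidence leaves it unconstrained.
* **Minimization ties** between equally small covers break by
  lexicographic implicant order, for reproducibility.
* **Degenerate inputs.** Constant series collapse clusters and fall back
  to the floor threshold; an all-don't-care table minimizes to constant
  0; an empty network yields zero metrics with density 0 by convention.
* **KS screen caveat.** The screen compares *fitted, resampled* curves,
  whose points are autocorrelated; the nominal p-value is approximate
  (empirically the null rejection rate at $\alpha = 0.01$ is
  conservative, about 0.3–0.8%). The screen is implemented as specified
  for comparability.

## Core reduction and the one-step delay

Output (childless) nodes never feed back, so stripping them is exactly
dynamics-preserving and reconstruction is mechanical: each removed node's
rule is evaluated along the core trajectory one step behind, in reverse
removal order. Chain collapse substitutes a pass-through node's rule into
its child with negation parity composed — but drops a one-step delay: in
the full network the child reads the transduction node's *previous*
value. Fixed points are unaffected (at a fixed point the delayed and
current values coincide), and the published core trajectories follow the
delay-free rules, so the collapsed core is the right object for attractor
analysis and evolution maps. Exact trajectory round trips, by contrast,
are performed on the output-stripped network
(`reduce_core()$stripped_network`), where `reconstruct_trajectory()`
reproduces the full network bit for bit; the test suite checks both
facts. Nodes whose single parent equals their single child (mutual
feedback pairs) are never collapsed.

The published M1 and M2a core memberships cannot be derived from their
rule tables by any purely topological rule (their printed figures carry
edges absent from the tables); those cores ship as explicit node lists,
and only the M2c reduction (24 nodes, to 6 after stripping, to 5 after
collapsing the single transduction node) is asserted as a computation.

## Problem sizes used by the test and acceptance suites

Exhaustive checks run at the sizes where exhaustion is cheap: state-space
bijections to $n = 8$, STP-versus-enumeration on random 3–6-node
networks, logic minimization against exhaustive evaluation up to 5
parents, LP cross-checks on instances of up to 6 candidates and 20
samples, recovery studies on 4–5-node panels with up to 16 stimulus
groups, and Monte-Carlo calibrations at 1000 replicates. The full suite
completes in well under a minute on one CPU.

## Known limitations

* Dynamics faster than the sampling design (state flips between
  consecutive measurements) cannot be recovered from 7-point profiles;
  the sensitivity band flags the affected binarizations rather than
  hiding them.
* Constantly-high profiles are mis-thresholded by any two-cluster rule;
  the logic stage's self-regulation escalation is the designed mitigation.
* LP-based direction assignment is associative, not causal; see the
  identifiability section.
* Only synchronous, deterministic Boolean semantics are implemented — no
  asynchronous updates, no probabilistic networks, no multi-level
  discretization.
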