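---
title: "Group-level metabolic brain networks: models, choices, and limits"
author: "metconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level metabolic brain networks: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metconn)
```

## The model

A single static FDG-PET scan per animal yields one regional uptake
vector per subject, so connectivity cannot be estimated within a
subject. The group-level construction treats *subjects as repeated
observations of one network*: for a group with subjects
$s = 1 \dots n$ and atlas regions $i = 1 \dots 96$, metabolic
connectivity is the inter-subject Pearson correlation

$$ R_{ij} \;=\; \mathrm{cor}\big( (x_{1i},\dots,x_{ni}),\, (x_{1j},\dots,x_{nj}) \big), $$

where $x_{si}$ is subject $s$'s globally normalized SUV in region $i$
(each subject's regional values divided by that subject's whole-brain
mean; at the region level the "whole brain" is the union of the 96
atlas regions). The construction has two consequences that shape
everything downstream:

* there is **one network per group**, not per subject, so group
  comparisons cannot use subject-level variance — all inference is by
  **group-label permutation**;
* with $n \approx 23$ subjects, each $R_{ij}$ is a noisy estimate
  (s.e. $\approx (1-r^2)/\sqrt{n-3}$), which sets a hard power ceiling
  discussed at the end.

Because correlation matrices are not comparable across densities, each
group's $R$ is binarized over a **sparsity sweep**
$S = 0.05, 0.06, \dots, 0.50$: at each $S$ the
$k = \mathrm{round}(S \cdot 4560)$ strongest correlations become the
edges of an undirected, unweighted graph ($4560 = \binom{96}{2}$).
Metrics are computed per layer and summarized by the trapezoidal area
under the metric-versus-sparsity curve (AUC), the scalar on which
groups are compared.

## Graph metrics

On each binary layer the package computes the standard
connectomics battery: characteristic path length $L_p$ (mean
shortest-path length), clustering coefficient $C_p$ (mean over nodes of
the realized fraction of edges among neighbours), global efficiency
$E_{glob}$ (mean inverse distance), local efficiency $E_{loc}$ (mean
over nodes of the efficiency of the neighbour-induced subgraph), and
per node the degree $D$, Brandes betweenness centrality $BC$
(unnormalized, each unordered endpoint pair counted once) and nodal
efficiency $E_{nod}$. Small-worldness is
$\sigma = \gamma / \lambda$ with $\gamma = C_p / \langle C_p^{rand}
\rangle$ and $\lambda = L_p / \langle L_p^{rand} \rangle$, the
ensemble being degree-preserving Maslov–Sneppen rewirings (double-edge
swaps rejecting self-loops and multi-edges, 10 swap attempts per edge;
ensemble size 5000 by default, configurable). $\sigma > 1$ indicates
small-world organization.

Conventions for thresholded, possibly fragmented graphs, fixed so that
independent oracles can reproduce every number:

* **Disconnected pairs.** $L_p$ averages over *finite* distances only;
  efficiency-type metrics use $1/\infty = 0$. This keeps $L_p$ defined
  at low sparsity without inventing a finite penalty distance. A graph
  with no connected pair yields `NA`, which AUC integration drops
  pairwise with a warning.
* **Low-degree nodes.** Nodes with fewer than two neighbours contribute
  0 (not `NA`, not excluded) to $C_p$ and $E_{loc}$ means.
* **Edge ranking.** Thresholding ranks edges by *signed* correlation
  (most positive first), treating connectivity as positive coupling;
  ranking by magnitude is available (`rank_by = "absolute"`). Ties at
  the cut are broken by larger $|r|$, then region order, with a
  warning — deterministic across platforms, as is the
  half-away-from-zero rounding of $S \cdot 4560$.

## Permutation inference

All tests share one scheme: shuffle the group labels (sizes
preserved), rebuild *both* group networks and everything derived from
them, recompute the statistic, and repeat $P$ times (default 5000).
Two-tailed p-values use the add-one estimator
$p = (1 + \#\{|d^{null}| \ge |d^{obs}|\})/(1 + P)$, which never
returns 0 and has floor $1/(P+1)$. Permutation index sets are drawn
from the smaller group and complemented, so relabelling the groups
negates every observed difference and leaves every p-value exactly
unchanged.

* **Edges**: statistic $r^A_{ij} - r^B_{ij}$, reported at
  $p < 0.001$ uncorrected, split by sign.
* **Global metrics**: statistic
  $\mathrm{AUC}^A - \mathrm{AUC}^B$ at $p < 0.05$. For
  $\gamma/\lambda/\sigma$ the rewired ensemble is recomputed inside
  every permutation at a reduced, configurable size (default 100 in
  loops vs 5000 for observed curves) — the normalization must share
  the permutation's sampling noise or the null is too narrow.
* **Nodal metrics**: per region and metric, the AUC difference;
  Benjamini–Hochberg FDR at $q = 0.05$ applied separately within each
  96-region family ($D$, $BC$, $E_{nod}$) — the conservative default;
  joint correction across families is a trivial config change.

## Robustness simulation

Damage is simulated by deleting nodes one at a time: *random failure*
(40 independent uniform orders, trajectories averaged) or *targeted
attack* (nodes in descending betweenness). Design choices where the
procedure is genuinely underdetermined:

* The targeted order ranks nodes by the **AUC of BC over the sparsity
  grid** (consistent with how nodal metrics are compared elsewhere) and
  is **static** — computed once on the intact network, not recomputed
  after each removal.
* After each removal the surviving weighted matrix is re-thresholded at
  the **minimum density with full connectivity** (edges added in ranked
  order until the union-find closes), so path-based metrics remain
  finite at every step.
* The largest connected component is tracked on the **intact binary
  network** (binarized once at its own minimum connected density) with
  the removed nodes deleted. On the re-thresholded graph the LCC would
  equal the survivor count by construction; fragmentation is only
  observable on the fixed graph.
* Per-step group comparisons rerun the full attack inside each
  permutation; the targeted order is recomputed from each permuted
  group's own BC ranking, while random orders are reused across
  permutations (variance reduction). A projected-cost guard refuses
  runs that would exceed a configurable evaluation budget, pointing at
  `n_perm`, `n_reps` and step subsampling.

## The synthetic cohort generator

The generator exists so that every stage is testable without scans. It
draws subjects i.i.d. from a group-specific multivariate normal whose
correlation matrix realizes (i) a community block structure (default:
four communities of 24 regions, within-community $r = 0.5$, between
$0.1$) and (ii) planted per-edge group differences. Defaults emulate
the study design: 96 regions, 23 + 24 subjects, SUV scale 1 ± 0.15
after global normalization.

* **Marginals.** Gaussian, shifted and scaled. Pearson correlation —
  the only downstream consumer — is location/scale invariant, so a
  log-normal or otherwise skewed marginal would change nothing the
  pipeline sees; physics-level realism (scanner noise, partial-volume
  effects, spatial smoothing) is explicitly *not* emulated.
* **PSD repair.** Planted entries can make the requested matrix
  indefinite. It is repaired to the nearest correlation matrix by
  Higham's alternating projections; the realized max deviation is
  reported, and a planted entry moved by more than 0.1 aborts with the
  offending pairs named. Not every request is realizable: a node
  cannot correlate at 0.8 with many mutually weakly-correlated
  partners (feasibility roughly $c^2 \le b + (1-b)/m$ for $m$ partners
  of pairwise correlation $b$) — strong hubs exist only as modules.
* **Reproducibility.** Every stochastic stage derives a child seed from
  one master seed via a labelled 32-bit FNV-1a hash
  (`child_seed(seed, label, index)`); operations refuse to run without
  a seed. Two runs of the full pipeline from one configuration are
  byte-identical, and the report manifest records the seed and a
  content hash of the configuration.

What passing tests on synthetic data do show: the machinery — metric
kernels against brute-force oracles, exact thresholding, calibrated
type-I error of all permutation tests, deterministic end-to-end
reports. What they cannot show: robustness to violations the generator
does not produce — non-exchangeable subjects (batch effects, scanner
drift), outlier animals, or spatially correlated noise leaking into
inter-subject correlations.

## Problem sizes used by the test suite

Simulation-heavy checks run at reduced sizes chosen as this package's
own test design: type-I calibration of the global-AUC test uses 200
null cohorts at n = 23/24 with 200 permutations on a 5-point sparsity
grid (0.1–0.5 step 0.1; the type-I property does not depend on grid
resolution); robustness calibration uses 100 null cohorts, 100
permutations, 2 random repetitions and two subsampled steps; power
checks use 1999 permutations (the smallest count whose add-one p can
fall below 0.001). The acceptance script runs the full 46-point grid
for observed quantities and reduced permutation counts (499–1999) for
the tests, finishing in minutes on one CPU.

## Known limitations

* **Statistical power at n ≈ 23/24 is intrinsically low.** For a
  correlation difference of 0.8 vs 0.0, a Fisher-z calculation gives
  $z \approx \mathrm{atanh}(0.8)/\sqrt{1/20 + 1/21} \approx 3.5$,
  so even an oracle two-sided test at $\alpha = 0.001$ has power
  $\approx 0.59$ — and the permutation test, whose add-one p at
  $P = 1999$ requires the observed difference to exceed essentially
  every null draw, achieves materially less. The test suite measures
  these recovery rates directly and documents the ceiling rather than
  hiding it. Nodal FDR recovery of a planted hub is harder still:
  Benjamini–Hochberg over 96 regions needs a raw p near $5 \times
  10^{-4}$ for a lone signal, while the permutation null of degree-AUC
  differences at these group sizes is as wide as the largest observed
  difference a PSD-realizable hub perturbation can produce. Detected
  differences at this design size are trustworthy; absence of
  detections is weak evidence of absence.
* **The sweep couples regions through a fixed edge budget.** Raising
  one module's correlations necessarily evicts other edges at a given
  sparsity, so degree differences are relative, not absolute — a
  strengthened module can *lower* other regions' degrees.
* The image path assumes volumes already registered to the atlas;
  no spatial preprocessing is performed.
* Weighted-network variants, partial correlations, covariate
  adjustment and cluster-based edge statistics are out of scope.
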