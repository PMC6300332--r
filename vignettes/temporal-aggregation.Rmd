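---
title: "Temporal aggregation and scan-based surveillance of dynamic networks"
author: "dynetscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal aggregation and scan-based surveillance of dynamic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynetscan)
```

## The problem

Communication data on a fixed set of individuals arrive as counts between
pairs of nodes, aggregated over some reporting interval. Prospective network
surveillance asks whether the communication pattern has recently changed —
for instance, whether one community has started talking to itself much more
than its established baseline. Two practical decisions precede any
monitoring method: the *temporal aggregation level* (how many basic time
units are summed into one monitored snapshot) and whether counts are kept or
collapsed to *binary* contact indicators. Both change how much of the
anomalous signal survives into the monitored statistic. This package
provides a simulation laboratory for quantifying those effects with a
concrete model/method pair: a degree-corrected stochastic block model
(DCSBM) generator with injectable sustained rate shifts, and the
moving-window scan monitor of Priebe and colleagues.

## The network model

The node set is partitioned into $R$ known communities, $|V_r|$ nodes in
community $r$. Each node carries a communication propensity $\theta_i > 0$
and each pair of communities a propensity $P_{r,r'} > 0$. Conditional on
these, the entry of the time-$t$ adjacency matrix for the unordered pair
$\{i, j\}$ is an independent draw

$$C_t(i,j) \sim \mathrm{Poisson}(\lambda_{ij}), \qquad
  \lambda_{ij} = \theta_i \theta_j P_{r(i), r(j)},$$

with a zero diagonal (no self-loops) and $C_t(j,i) = C_t(i,j)$ (undirected).
The model is identified by the constraint
$\sum_{i \in V_r} \theta_i = |V_r|$, enforced exactly by
`drawDegreePropensities()` after drawing raw propensities i.i.d. from a
Type-I Pareto distribution (density $s\,m^s/x^{s+1}$, $x \ge m$). The
defaults $m = 1$, $s = 3$ give mean $1.5$ and the right-skewed degree
heterogeneity seen in empirical contact networks; shapes $\le 1$
(infinite mean) are permitted with a warning for exploration. Homophily is
modeled by `blockPropensity()`: constant diagonal $P^0_{r,r}$ and
off-diagonal $P^0_{r,r}/\rho$ with ratio $\rho = 2$ by default, so
within-community contact is twice as likely as between-community contact.

An anomaly is a *sustained* multiplicative shift of one community's
within-propensity: after the shift time $\tau$,
$P_{1,1} = (1+s)\,P^0_{1,1}$ for the rest of the run ($s$ is the relative
shift magnitude; `shiftSpec(fraction, time)`). The convention, fixed
throughout the package, is that $\tau$ is the **last baseline index**: the
first anomalous matrix is $C_{\tau+1}$. Degree propensities are drawn once
per run and held fixed; successive matrices are independent given the
parameters.

## Aggregation and binarization

`aggregateSequence()` sums non-overlapping blocks of $W$ consecutive unit
matrices, so $T$ unit matrices become $T/W$ snapshots covering intervals
$((m-1)W,\ mW]$; the total count is conserved and each output matrix keeps
its covering interval so that signals can be reported in original time
units. A run length not divisible by $W$ is a hard error — silent
truncation would corrupt the shift-time bookkeeping that the whole study
depends on. `binarizeSequence()` maps a cell to $1$ exactly when its count
reaches the threshold (default $1$: *any* communication). When both
operations are requested the package always computes
$B^{(W)} = \mathrm{binarize}(C^{(W)})$ — aggregate first, then binarize —
and refuses to aggregate an already-binary sequence, because the two orders
genuinely differ (two sub-threshold intervals can sum to a supra-threshold
block).

## The scan monitor

For each snapshot the monitor computes three per-node locality statistics
(`neighborhoodStats()`):

* $O^0_{t,i}$ — the degree of node $i$: the sum of row $i$, i.e. the number
  of communications to or from $i$ (for binary data, the neighbor count);
* $O^k_{t,i}$, $k = 1, 2$ — the size of the $k$-th neighborhood: the sum of
  entries over unordered pairs whose endpoints both lie within
  support-graph distance $k$ of $i$. Membership is decided on the support
  graph (a cell with count $\ge 1$ is an edge) and includes $i$ itself, so
  $O^0 \le O^1 \le O^2$ always holds and the binary case is the classical
  induced-edge-count statistic.

Each statistic is standardized against its own recent past
(`windowedStandardize()`): at index $t$ the mean and sample standard
deviation (divisor $w - 1$) of the **previous** $w = 20$ values are used,

$$O^{k*}_{t,i} = \frac{O^k_{t,i} - \bar O^k_{t,i}}
  {\max\{\widehat{\mathrm{sd}}(O^k_{t,i}),\ 1\}},$$

with the unit floor keeping near-constant windows from exploding the
statistic. The across-node maxima $M^k_t = \max_i O^{k*}_{t,i}$ are then
standardized a second time over their own 20-point moving window, and a
signal is raised at $t$ when
$\max(M^{0*}_t, M^{1*}_t, M^{2*}_t) \ge 4$. Because two windows must stack
before the second standardization is defined, a sequence must contain at
least $2w + 1 = 41$ snapshots, and the first signal-eligible index is 41 —
this is why the study's runs contain $T = 860$ unit matrices: even at
$W = 20$ the aggregated sequence still has $43 \ge 41$ snapshots.

Numerical choices: the rolling moments are computed from cumulative sums
with a non-negativity guard on the variance; windows with insufficient
history yield `NA`, never zero-filled values; ties at the threshold signal
(the rule is $\ge$); only the upper triangle of each matrix is ever drawn,
mirrored afterwards, so symmetry is exact. The per-node statistics are
computed in compiled code (RcppArmadillo) as quadratic forms of
neighborhood membership matrices; the test suite checks the kernel against
two independent oracles (a set-expansion BFS in plain R, and
igraph shortest-path distances) and the whole two-stage pipeline against a
literal loop transcription of the formulas.

## The Monte-Carlo harness

A `ScenarioConfig` bundles one experimental condition; its defaults are the
study's headline settings ($|V| = 20$ in two communities of 10, $T = 860$,
window 20, threshold 4, homophily 2:1, Pareto(1, 3), binarization
threshold 1). The harness measures:

* **Detection rate** (`detectionRate()`): the proportion of shifted runs
  with a signal at an aggregated point whose original end time lies in
  $(\tau, T]$. Replications are allocated equally (round-robin) over the
  configured shift times — by default all offsets of one aggregation
  period, $\tau \in \{T-20, \dots, T-20+W-1\}$, and the single time
  $T - 20$ for $W = 1$ — so late offsets, which leave fewer anomalous unit
  matrices inside the final period and fewer signaling opportunities, are
  represented fairly. Runs end at $T$; they are deliberately *not* extended
  to $\tau + 20$, which is exactly what drives the late-offset performance
  drop that `shiftOffsetProfile()` quantifies.
* **False alarm rate** (`falseAlarmRate()`): the identical pipeline with no
  shift applied; a false alarm is any signal after the designated
  (hypothetical) shift time. With `shiftFraction = 0`, `detectionRate()`
  and `falseAlarmRate()` are the same computation — the no-shift limit is
  exact, and the test suite asserts it.
* **Conditional signal delay** (`conditionalDelayDistribution()`): among
  detected runs, `delay = signalTime - (tau + 1)` in original time units,
  so a signal at the first post-shift period has delay 0, and a $W = 20$
  signal at $t = 860$ after $\tau = 840$ has delay 19.

Signals that occur *before* the shift time in a detection run are recorded
separately (`preShiftSignal`) and never counted as detections, keeping the
detection and false-alarm bookkeeping disjoint.

Every replication draws its own L'Ecuyer-CMRG substream derived from the
master seed and the run index (`runStream()`), so any single run can be
reproduced in isolation and results do not depend on execution order or on
how a sweep is parallelized. Grid sweeps (`sweepScenarios()`) give each
cell a deterministic seed derived from its master seed and position, and
record per-cell failures instead of aborting.

## Shared draws across aggregation levels

Within one run, all aggregation levels are definitionally coupled: the
aggregated sequence is the block sum of the same unit draws, never a fresh
simulation at block-level rates, so level comparisons are not inflated by
generation noise. Across the *headline* per-level experiments the offset
sets $\{T-20, \dots, T-20+W-1\}$ differ by level, so those estimates use
independent replications. For direct level-to-level contrasts at a common
shift time, `compareAggregationLevels()` scans the same unit sequences at
every level (shared draws by default, with `sharedDraws = FALSE` as the
independent alternative).

## Problem sizes and what the defaults mean

| Parameter | Default | Meaning |
|---|---|---|
| `nNodes`, `communitySizes` | 20; (10, 10) | network order and block sizes |
| `baselineDiag` $P^0_{r,r}$ | 1 | within-community propensity; 0.2 is a sparse network, 5 a dense one |
| `homophilyRatio` | 2 | within:between contact ratio |
| `paretoScale`, `paretoShape` | 1, 3 | degree-heterogeneity law (mean 1.5) |
| `runLength` $T$ | 860 | unit snapshots per run (43 at $W = 20$) |
| `shiftFraction` $s$ | 0.5 | relative within-community rate increase |
| `aggregationLevel` $W$ | 1 | units summed per monitored snapshot |
| `binarizeThreshold` | 1 | count needed for a binary contact |
| `windowWidth` | 20 | scan moving-window width (snapshots) |
| `signalThreshold` | 4 | signal when $\max_k M^{k*} \ge 4$ |
| `replications` | 200 | Monte-Carlo runs per condition |

The package's own experiments (test suite and the acceptance script) use
200 replications per condition and 500 for the single-offset late-shift
profile; at these sizes a rate near 50% carries a Monte-Carlo standard
error of about 3.5 percentage points, which the harness always reports
alongside the estimate.

## What the generator does and does not emulate

The generator reproduces the study conditions exactly: Poisson counts from
a DCSBM with per-community-normalized Pareto propensities, homophilous
block structure, sustained single-community shifts at configurable offsets,
and aggregation by summation. It does **not** emulate several features of
real communication data: temporal dependence between successive snapshots
(matrices are independent given the parameters), seasonality (assumed
already removed by the basic aggregation level), directed edges,
self-loops, transient anomalies, anomalies spanning several communities, or
unknown community structure. Conclusions drawn from green tests therefore
speak to the model/method pair under these idealized conditions, not to
arbitrary real networks.

## Known limitations and practical cautions

* **Threshold calibration at sparse, unaggregated data.** At unit width on
  sparse networks the locality statistics are small discrete counts; their
  windows often have standard deviation below the unit floor, so raw
  jumps pass through standardization, and occasional large neighborhood
  jumps give the maxima a heavy upper tail. The default threshold of 4
  then admits a non-negligible false-signal rate. The false alarm rate is
  a *property of the configuration*, not a constant of the method:
  `falseAlarmRate()` should be run for the intended configuration and the
  threshold adjusted before operational use.
* **Single opportunity at high aggregation.** At $W = 20$ with a 20-period
  detection allowance there is exactly one signal-eligible aggregated
  point after the shift; a shift late in the period leaves mostly baseline
  data inside it, and detection collapses — the package reproduces this
  cliff, and `shiftOffsetProfile()` makes it visible.
* **Self-standardizing monitor.** The scan has no in-control model; after
  roughly one window of anomalous data the shifted behavior becomes the
  new baseline, so sustained shifts must be caught within about 20
  monitored points or not at all.
* The harness treats the signal threshold as an input; it does not
  optimize it to hit a target false alarm rate.
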