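# dynetscan

Simulation and monitoring toolkit for studying how the **temporal
aggregation level** of dynamic-network communication data — and its
conversion from counts to binary contact indicators — affects prospective
anomaly detection. The package is aimed at researchers in network
surveillance and statistical process monitoring who want a controlled,
reproducible laboratory for a model/method pair rather than a one-off
simulation script.

## What it does

**Generator.** Sequences of symmetric, zero-diagonal count adjacency
matrices are simulated from a degree-corrected stochastic block model
(DCSBM): conditional on known communities, the count for pair {i, j} is
Poisson with mean λ_ij = θ_i θ_j P_{r(i), r(j)}, where the node
propensities θ are Pareto(1, 3) draws rescaled so that each community's θ
sum equals its size, and P has a homophilous 2:1 within:between structure.
An anomaly is a sustained multiplicative shift of community 1's
within-propensity, P₁₁ → (1 + s) P₁₁⁰, starting right after a configurable
shift time τ.

**Monitor.** Priebe's moving-window scan method: per-node degree and first
two neighborhood sizes O⁰ ≤ O¹ ≤ O², standardized against the previous 20
snapshots (sample sd floored at 1), maximized over nodes, standardized a
second time, with a signal when max(M⁰*, M¹*, M²*) ≥ 4. Monitoring can run
on raw unit-width counts, on sums of W consecutive matrices
(W ∈ {1, 2, 5, 10, 20} in the headline experiments), and on binarized
versions (cell = 1 iff count ≥ threshold, applied after aggregation).

**Harness.** A Monte-Carlo layer estimates false alarm rates, detection
rates (signal within the 20 post-shift periods), conditional signal delays
and shift-offset profiles over grids of scenarios, with per-replication
L'Ecuyer-CMRG substreams so every run is reproducible from (seed, run
index) alone.

## Worked example

```r
library(dynetscan)

cs <- communityStructure(c(10, 10))
set.seed(7)
th  <- drawDegreePropensities(cs)               # Pareto(1, 3), normalized per community
P0  <- blockPropensity(1, 2, 2)                 # within 1, between 0.5
x   <- generateSequence(cs, th, P0, shift = shiftSpec(1.5, 840), runLength = 860)
x
#> NetworkSequence: 860 snapshots of a 20-node network (count data)
#>   step width 1, covering original time (0, 860]

sc <- scanSequence(aggregateSequence(x, 5))     # window 20, threshold 4
sc
#> ScanResult: 172 monitored points (window 20, threshold 4)
#>   signalable from index 41; 1 signal(s) at original time(s) 845
```

The +150% shift entered at τ = 840 (so matrix 841 is the first anomalous
one) and the scan flagged the very first aggregated point ending after the
shift, t = 845 — a conditional delay of 4 original time periods.

Comparing aggregation levels for a moderate (+50%) shift:

```r
cfgs <- lapply(c(1L, 5L), function(W)
  scenarioConfig(baselineDiag = 1, shiftFraction = 0.5,
                 aggregationLevel = W, replications = 100L, seed = 42L))
sweepScenarios(cfgs)[, c("aggregationLevel", "detection_rate", "se", "delay_median")]
#>   aggregationLevel detection_rate         se delay_median
#> 1                1           0.17 0.03756328            0
#> 2                5           0.50 0.05000000            5
```

Summing five unit matrices per snapshot triples the detection rate here —
aggregation amplifies a sustained shift — at the price of a longer median
signal delay, since a signal can only occur at the end of an aggregation
period. Pushing W higher eventually reverses the gain: with detection
limited to 20 post-shift periods, W = 20 leaves a single signaling
opportunity.

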