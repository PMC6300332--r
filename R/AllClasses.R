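#' @import methods
#' @importFrom S4Vectors new2
#' @importFrom stats rpois runif sd median quantile
#' @importFrom utils read.table write.table packageVersion head tail
#' @importFrom parallel nextRNGStream
#' @importFrom Rcpp sourceCpp
#' @useDynLib dynetscan, .registration = TRUE
NULL

#' CommunityStructure: known block membership of a network
#'
#' Partition of the node set into `R` disjoint communities. Community 1 is,
#' by convention, the community into which an anomalous communication-rate
#' shift may be injected.
#'
#' @slot sizes integer vector, number of nodes in each community.
#' @slot membership integer vector of length `sum(sizes)` mapping each node
#'   (1-based) to its community index in `1..R`.
#'
#' @seealso [communityStructure()]
#' @export
setClass("CommunityStructure",
  representation(sizes = "integer", membership = "integer"))

setValidity("CommunityStructure", function(object) {
  if (length(object@sizes) < 1L) return("need at least one community")
  if (any(object@sizes < 1L)) return("community sizes must be positive")
  if (length(object@membership) != sum(object@sizes))
    return("membership length must equal sum of community sizes")
  tab <- tabulate(object@membership, nbins = length(object@sizes))
  if (!identical(tab, as.integer(object@sizes)))
    return("membership counts do not match community sizes")
  TRUE
})

#' DegreePropensity: node-level communication propensities
#'
#' The degree-correction parameters of the DCSBM. Raw draws `rawTheta` come
#' from a Type-I Pareto distribution; `theta` rescales them within each
#' community so that the community sums equal the community sizes, the
#' identifiability constraint of the model.
#'
#' @slot theta numeric, normalized propensities (one per node).
#' @slot rawTheta numeric, the unscaled Pareto draws.
#' @slot paretoScale numeric(1), Pareto scale parameter m.
#' @slot paretoShape numeric(1), Pareto shape parameter.
#' @slot structure the [CommunityStructure-class] the normalization used.
#'
#' @seealso [drawDegreePropensities()]
#' @export
setClass("DegreePropensity",
  representation(theta = "numeric", rawTheta = "numeric",
                 paretoScale = "numeric", paretoShape = "numeric",
                 structure = "CommunityStructure"))

setValidity("DegreePropensity", function(object) {
  n <- length(object@structure@membership)
  if (length(object@theta) != n || length(object@rawTheta) != n)
    return("theta and rawTheta must have one entry per node")
  if (any(object@theta <= 0)) return("all theta must be positive")
  sums <- as.vector(tapply(object@theta, object@structure@membership, sum))
  if (any(abs(sums - object@structure@sizes) > 1e-8 * object@structure@sizes))
    return("per-community theta sums must equal community sizes")
  TRUE
})

#' BlockPropensity: community-level communication propensities
#'
#' The symmetric `R x R` matrix `P` whose entry (r, r') is the propensity of
#' communication between communities r and r'. The standard constructor
#' builds a homophilous matrix: constant diagonal, off-diagonal equal to the
#' diagonal divided by the within:between ratio.
#'
#' @slot P numeric matrix, symmetric with positive entries.
#' @slot baselineDiag numeric(1), the diagonal value used by the standard
#'   constructor (`NA` for matrices built directly).
#' @slot homophilyRatio numeric(1), within:between ratio (`NA` if not built
#'   by the standard constructor).
#'
#' @seealso [blockPropensity()], [applyShift()]
#' @export
setClass("BlockPropensity",
  representation(P = "matrix", baselineDiag = "numeric",
                 homophilyRatio = "numeric"))

setValidity("BlockPropensity", function(object) {
  P <- object@P
  if (nrow(P) != ncol(P)) return("P must be square")
  if (!isSymmetric(unname(P))) return("P must be symmetric")
  if (any(P <= 0)) return("all entries of P must be positive")
  TRUE
})

#' ShiftSpec: a sustained within-community rate shift
#'
#' Describes a sustained multiplicative increase of the within-community
#' propensity of one target community. `time` is the last baseline time
#' index: matrices at times `<= time` follow the baseline rates and matrices
#' at times `>= time + 1` the shifted rates, and the shift never reverts.
#'
#' @slot fraction numeric(1), relative shift magnitude s >= 0; the shifted
#'   within propensity is `(1 + s)` times the baseline one.
#' @slot time integer(1), last baseline time index (tau).
#' @slot targetCommunity integer(1), community receiving the shift.
#'
#' @seealso [shiftSpec()], [applyShift()], [generateSequence()]
#' @export
setClass("ShiftSpec",
  representation(fraction = "numeric", time = "integer",
                 targetCommunity = "integer"))

setValidity("ShiftSpec", function(object) {
  if (length(object@fraction) != 1L || is.na(object@fraction) ||
      object@fraction < 0)
    return("shift fraction must be a single non-negative number")
  if (length(object@time) != 1L || is.na(object@time) || object@time < 0L)
    return("shift time must be a single non-negative integer")
  if (length(object@targetCommunity) != 1L || object@targetCommunity < 1L)
    return("target community must be a positive integer")
  TRUE
})

#' NetworkSequence: a temporal stack of adjacency matrices
#'
#' Ordered sequence of symmetric, zero-diagonal adjacency matrices with
#' non-negative integer entries, stored as a `|V| x |V| x T` array. The t-th
#' matrix summarizes communications over the original-time interval
#' `(startTime + (t-1) * stepWidth, startTime + t * stepWidth]`.
#'
#' @slot counts numeric array `|V| x |V| x T`.
#' @slot stepWidth integer(1), original time units covered by one matrix
#'   (the aggregation level W).
#' @slot startTime numeric(1), original time at which the sequence starts
#'   (the first matrix covers `(startTime, startTime + stepWidth]`).
#' @slot dataType `"count"` or `"binary"`.
#'
#' @seealso [generateSequence()], [aggregateSequence()], [binarizeSequence()],
#'   [scanSequence()]
#' @export
setClass("NetworkSequence",
  representation(counts = "array", stepWidth = "integer",
                 startTime = "numeric", dataType = "character"),
  prototype(counts = array(0, c(0, 0, 0)), stepWidth = 1L,
            startTime = 0, dataType = "count"))

setValidity("NetworkSequence", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3L) return("counts must be a 3-d array (V x V x T)")
  if (d[1L] != d[2L]) return("adjacency matrices must be square")
  if (!(object@dataType %in% c("count", "binary")))
    return("dataType must be 'count' or 'binary'")
  if (length(object@stepWidth) != 1L || object@stepWidth < 1L)
    return("stepWidth must be a positive integer")
  x <- object@counts
  if (d[3L] > 0L && d[1L] > 0L) {
    if (any(x < 0)) return("entries must be non-negative")
    if (any(x != round(x))) return("entries must be integers")
    if (object@dataType == "binary" && any(x > 1))
      return("binary sequences may contain only 0/1")
    if (any(x != aperm(x, c(2L, 1L, 3L))))
      return("every matrix must be symmetric")
    dg <- matrix(x, d[1L] * d[2L], d[3L])[seq(1L, d[1L]^2, by = d[1L] + 1L), ,
                                          drop = FALSE]
    if (any(dg != 0)) return("diagonals must be zero (no self-loops)")
  }
  TRUE
})

#' ScanResult: output of the moving-window scan monitor
#'
#' Holds the per-node locality statistics, their windowed standardizations,
#' the across-node maxima, the second-stage standardized maxima, and the
#' threshold signal flags produced by [scanSequence()]. Rows index monitored
#' (aggregated) time; entries at indices with insufficient window history
#' are `NA`.
#'
#' @slot nodeStats list of three `T x |V|` matrices (orders k = 0, 1, 2).
#' @slot standardizedNodeStats list of three `T x |V|` matrices (O*).
#' @slot maxStats `T x 3` matrix of across-node maxima (M).
#' @slot standardizedMaxStats `T x 3` matrix (M*).
#' @slot signalFlags logical of length T; `TRUE` where
#'   `max_k M*_t^k >= signalThreshold`.
#' @slot windowWidth integer(1), moving-window width.
#' @slot signalThreshold numeric(1).
#' @slot stepWidth integer(1), original time units per monitored index.
#' @slot startTime numeric(1), carried from the scanned sequence.
#'
#' @seealso [scanSequence()], [signalTimes()]
#' @export
setClass("ScanResult",
  representation(nodeStats = "list", standardizedNodeStats = "list",
                 maxStats = "matrix", standardizedMaxStats = "matrix",
                 signalFlags = "logical", windowWidth = "integer",
                 signalThreshold = "numeric", stepWidth = "integer",
                 startTime = "numeric"))

setValidity("ScanResult", function(object) {
  T <- length(object@signalFlags)
  if (nrow(object@maxStats) != T || nrow(object@standardizedMaxStats) != T)
    return("max statistic matrices must have one row per time index")
  if (ncol(object@maxStats) != 3L || ncol(object@standardizedMaxStats) != 3L)
    return("max statistics must have one column per order k = 0, 1, 2")
  if (object@windowWidth < 2L) return("window width must be at least 2")
  TRUE
})

#' ScenarioConfig: one experimental condition of the simulation study
#'
#' Bundles every knob of a simulation condition: network order and block
#' structure, baseline sparsity and homophily, Pareto degree heterogeneity,
#' run length, shift magnitude and candidate shift times, aggregation level,
#' data type, scan parameters, replication count, and the master seed.
#' Defaults are the study's headline settings (T = 860, window 20, signal
#' threshold 4, homophily 2:1, Pareto(1, 3), binarization threshold 1).
#'
#' @slot nNodes integer(1), network order |V|.
#' @slot communitySizes integer, sizes of the communities (sums to nNodes).
#' @slot baselineDiag numeric(1), baseline within-community propensity.
#' @slot homophilyRatio numeric(1), within:between propensity ratio.
#' @slot paretoScale,paretoShape numeric(1), degree-propensity Pareto
#'   parameters.
#' @slot runLength integer(1), number of unit-width matrices T.
#' @slot shiftFraction numeric(1), relative shift magnitude s.
#' @slot shiftTimes integer, candidate last-baseline times over which
#'   replications are allocated equally.
#' @slot aggregationLevel integer(1), W.
#' @slot dataType `"count"` or `"binary"`.
#' @slot binarizeThreshold integer(1), count-to-binary threshold.
#' @slot windowWidth integer(1), scan moving-window width.
#' @slot signalThreshold numeric(1), scan signaling threshold.
#' @slot replications integer(1), Monte-Carlo replications.
#' @slot seed integer(1), master seed.
#'
#' @seealso [scenarioConfig()], [detectionRate()], [falseAlarmRate()]
#' @export
setClass("ScenarioConfig",
  representation(nNodes = "integer", communitySizes = "integer",
                 baselineDiag = "numeric", homophilyRatio = "numeric",
                 paretoScale = "numeric", paretoShape = "numeric",
                 runLength = "integer", shiftFraction = "numeric",
                 shiftTimes = "integer", aggregationLevel = "integer",
                 dataType = "character", binarizeThreshold = "integer",
                 windowWidth = "integer", signalThreshold = "numeric",
                 replications = "integer", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  if (sum(object@communitySizes) != object@nNodes)
    return("community sizes must sum to nNodes")
  if (object@baselineDiag <= 0) return("baselineDiag must be positive")
  if (object@homophilyRatio <= 0) return("homophilyRatio must be positive")
  if (object@shiftFraction < 0) return("shiftFraction must be non-negative")
  T <- object@runLength
  W <- object@aggregationLevel
  if (T %% W != 0L)
    return(sprintf("run length %d is not divisible by aggregation level %d",
                   T, W))
  if (length(object@shiftTimes) &&
      (any(object@shiftTimes < T - 20L) || any(object@shiftTimes > T - 1L)))
    return("shift times must lie in {T-20, ..., T-1}")
  if (!(object@dataType %in% c("count", "binary")))
    return("dataType must be 'count' or 'binary'")
  if (object@binarizeThreshold < 1L)
    return("binarizeThreshold must be at least 1")
  if (object@windowWidth < 2L) return("windowWidth must be at least 2")
  if (object@replications < 1L) return("replications must be at least 1")
  TRUE
})
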