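# Degree-corrected stochastic block model generator.

#' Define a community structure
#'
#' @param sizes positive integer vector of community sizes; nodes are
#'   numbered consecutively, community 1 first. Community 1 is the
#'   convention target of an anomalous shift.
#' @return a [CommunityStructure-class].
#' @examples
#' communityStructure(c(10, 10))
#' @export
communityStructure <- function(sizes) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || anyNA(sizes) || any(sizes < 1L))
    stop("community sizes must be positive integers", call. = FALSE)
  new("CommunityStructure", sizes = sizes,
      membership = rep(seq_along(sizes), sizes))
}

#' Draw node degree propensities from a Pareto distribution
#'
#' Draws one unscaled propensity per node i.i.d. from a Type-I Pareto
#' distribution with density `shape * scale^shape / x^(shape + 1)` for
#' `x >= scale`, then rescales within each community r so that the
#' propensities sum to the community size |V_r| — the identifiability
#' constraint of the DCSBM. The defaults, Pareto(scale = 1, shape = 3),
#' give the right-skewed degree heterogeneity typical of empirical social
#' networks.
#'
#' @param structure a [CommunityStructure-class].
#' @param paretoScale positive scale parameter m.
#' @param paretoShape positive shape parameter; values `<= 1` (infinite
#'   mean) are allowed with a warning.
#' @return a [DegreePropensity-class].
#' @examples
#' set.seed(1)
#' th <- drawDegreePropensities(communityStructure(c(10, 10)))
#' tapply(theta(th), membership(communityStructure(c(10, 10))), sum)
#' @export
drawDegreePropensities <- function(structure, paretoScale = 1,
                                   paretoShape = 3) {
  stopifnot(is(structure, "CommunityStructure"))
  if (!is.numeric(paretoScale) || length(paretoScale) != 1L ||
      is.na(paretoScale) || paretoScale <= 0)
    stop("paretoScale must be a single positive number", call. = FALSE)
  if (!is.numeric(paretoShape) || length(paretoShape) != 1L ||
      is.na(paretoShape) || paretoShape <= 0)
    stop("paretoShape must be a single positive number", call. = FALSE)
  if (paretoShape <= 1)
    warning("Pareto shape <= 1 has infinite mean; draws are still generated",
            call. = FALSE)
  n <- nNodes(structure)
  raw <- rparetoI(n, paretoScale, paretoShape)
  theta <- .normalizeTheta(raw, structure)
  new("DegreePropensity", theta = theta, rawTheta = raw,
      paretoScale = paretoScale, paretoShape = paretoShape,
      structure = structure)
}

#' Type-I Pareto random draws
#'
#' Inverse-CDF sampling from the Pareto distribution with survival function
#' `(scale / x)^shape` for `x >= scale`.
#'
#' @param n number of draws.
#' @param scale,shape positive Pareto parameters.
#' @return numeric vector of draws, all `>= scale`.
#' @export
rparetoI <- function(n, scale = 1, shape = 3) {
  if (scale <= 0 || shape <= 0)
    stop("Pareto scale and shape must be positive", call. = FALSE)
  scale * runif(n)^(-1 / shape)
}

.normalizeTheta <- function(raw, structure) {
  memb <- structure@membership
  sums <- as.vector(tapply(raw, memb, sum))
  raw * (structure@sizes[memb] / sums[memb])
}

#' Build a homophilous block propensity matrix
#'
#' Constructs the `R x R` community propensity matrix with a constant
#' diagonal `baselineDiag` and off-diagonal entries
#' `baselineDiag / homophilyRatio`; the default ratio of 2 makes
#' within-community communication twice as likely as between-community
#' communication.
#'
#' @param baselineDiag positive within-community propensity.
#' @param homophilyRatio positive within:between ratio.
#' @param nCommunities number of communities R.
#' @return a [BlockPropensity-class].
#' @examples
#' propensityMatrix(blockPropensity(0.2, 2, 2))
#' @export
blockPropensity <- function(baselineDiag, homophilyRatio = 2,
                            nCommunities = 2L) {
  if (!is.numeric(baselineDiag) || length(baselineDiag) != 1L ||
      is.na(baselineDiag) || baselineDiag <= 0)
    stop("baselineDiag must be a single positive number", call. = FALSE)
  if (!is.numeric(homophilyRatio) || length(homophilyRatio) != 1L ||
      is.na(homophilyRatio) || homophilyRatio <= 0)
    stop("homophilyRatio must be a single positive number", call. = FALSE)
  nCommunities <- as.integer(nCommunities)
  if (is.na(nCommunities) || nCommunities < 1L)
    stop("nCommunities must be a positive integer", call. = FALSE)
  P <- matrix(baselineDiag / homophilyRatio, nCommunities, nCommunities)
  diag(P) <- baselineDiag
  new("BlockPropensity", P = P, baselineDiag = baselineDiag,
      homophilyRatio = homophilyRatio)
}

#' Wrap an arbitrary symmetric propensity matrix
#'
#' @param P symmetric matrix of positive propensities.
#' @return a [BlockPropensity-class] with unset constructor metadata.
#' @export
asBlockPropensity <- function(P) {
  new("BlockPropensity", P = as.matrix(P), baselineDiag = NA_real_,
      homophilyRatio = NA_real_)
}

#' Specify a sustained within-community rate shift
#'
#' @param fraction relative shift magnitude s >= 0; the within propensity of
#'   the target community becomes `(1 + s)` times its baseline value.
#' @param time last baseline time index tau; the first anomalous matrix is
#'   the one at time `tau + 1`.
#' @param targetCommunity community receiving the shift (default 1).
#' @return a [ShiftSpec-class].
#' @examples
#' shiftSpec(0.5, 840)
#' @export
shiftSpec <- function(fraction, time, targetCommunity = 1L) {
  new("ShiftSpec", fraction = as.numeric(fraction), time = as.integer(time),
      targetCommunity = as.integer(targetCommunity))
}

#' Apply a within-community shift to a block propensity matrix
#'
#' Returns a copy of `blocks` in which only the (target, target) entry is
#' multiplied by `1 + fraction`; all other entries are unchanged.
#'
#' @param blocks a [BlockPropensity-class].
#' @param shift a [ShiftSpec-class].
#' @return a new [BlockPropensity-class].
#' @examples
#' shifted <- applyShift(blockPropensity(1, 2, 2), shiftSpec(0.5, 840))
#' propensityMatrix(shifted)[1, 1]  # 1.5
#' @export
applyShift <- function(blocks, shift) {
  stopifnot(is(blocks, "BlockPropensity"), is(shift, "ShiftSpec"))
  r <- shift@targetCommunity
  if (r > nrow(blocks@P))
    stop("target community outside the block matrix", call. = FALSE)
  P <- blocks@P
  P[r, r] <- P[r, r] * (1 + shift@fraction)
  new("BlockPropensity", P = P, baselineDiag = NA_real_,
      homophilyRatio = NA_real_)
}

#' Compute the Poisson rate matrix of a DCSBM
#'
#' The expected number of communications between nodes i and j per unit
#' time is `theta_i * theta_j * P[r(i), r(j)]`; the diagonal is zero (no
#' self-loops) and the matrix is symmetric.
#'
#' @param theta a [DegreePropensity-class].
#' @param blocks a [BlockPropensity-class] with one row per community.
#' @param structure a [CommunityStructure-class]; defaults to the one
#'   carried by `theta`.
#' @return a symmetric `|V| x |V|` rate matrix with zero diagonal.
#' @export
computeRates <- function(theta, blocks, structure = theta@structure) {
  stopifnot(is(theta, "DegreePropensity"), is(blocks, "BlockPropensity"),
            is(structure, "CommunityStructure"))
  memb <- structure@membership
  if (length(theta@theta) != length(memb))
    stop("theta and community structure disagree on the number of nodes",
         call. = FALSE)
  if (nrow(blocks@P) < max(memb))
    stop("block matrix has fewer communities than the structure",
         call. = FALSE)
  lam <- outer(theta@theta, theta@theta) * blocks@P[memb, memb]
  diag(lam) <- 0
  lam
}

#' Generate a temporal sequence of DCSBM count networks
#'
#' Draws `runLength` unit-width symmetric count matrices whose upper-triangle
#' cells are independent Poisson variates with the DCSBM rates. With a
#' [ShiftSpec-class], matrices at times `<= shift@@time` use the baseline
#' block matrix and matrices at times `>= shift@@time + 1` the shifted one;
#' the shift is sustained. The degree propensities are fixed for the whole
#' sequence.
#'
#' @param structure a [CommunityStructure-class].
#' @param theta a [DegreePropensity-class].
#' @param blocks the baseline [BlockPropensity-class].
#' @param shift a [ShiftSpec-class], or `NULL` for a fully baseline run.
#' @param runLength number of unit-width matrices T.
#' @return a [NetworkSequence-class] (count data, step width 1).
#' @examples
#' set.seed(1)
#' cs <- communityStructure(c(10, 10))
#' th <- drawDegreePropensities(cs)
#' x <- generateSequence(cs, th, blockPropensity(1, 2, 2),
#'                       shift = shiftSpec(0.5, 40), runLength = 60)
#' x
#' @export
generateSequence <- function(structure, theta, blocks, shift = NULL,
                             runLength) {
  stopifnot(is(structure, "CommunityStructure"))
  runLength <- as.integer(runLength)
  if (is.na(runLength) || runLength < 1L)
    stop("runLength must be a positive integer", call. = FALSE)
  lam0 <- computeRates(theta, blocks, structure)
  lam1 <- NULL
  tau <- runLength
  if (!is.null(shift)) {
    stopifnot(is(shift, "ShiftSpec"))
    if (shift@time > runLength)
      stop("shift time must lie in 0..runLength", call. = FALSE)
    tau <- shift@time
    lam1 <- computeRates(theta, applyShift(blocks, shift), structure)
  }
  generateFromRates(lam0, runLength, shiftedRates = lam1, shiftTime = tau)
}

#' Generate a count sequence from explicit rate matrices
#'
#' Low-level generator used by [generateSequence()]: only the upper
#' triangle is drawn (then mirrored, guaranteeing exact symmetry), the
#' diagonal stays zero, and zero rates are permitted (useful for degenerate
#' test inputs).
#'
#' @param rates symmetric `|V| x |V|` matrix of non-negative baseline rates.
#' @param runLength number of matrices T.
#' @param shiftedRates optional rate matrix used from `shiftTime + 1` on.
#' @param shiftTime last time index generated from `rates`.
#' @return a [NetworkSequence-class] (count data, step width 1).
#' @export
generateFromRates <- function(rates, runLength, shiftedRates = NULL,
                              shiftTime = runLength) {
  rates <- as.matrix(rates)
  V <- nrow(rates)
  runLength <- as.integer(runLength)
  shiftTime <- as.integer(shiftTime)
  if (shiftTime < 0L || shiftTime > runLength)
    stop("shiftTime must lie in 0..runLength", call. = FALSE)
  if (is.null(shiftedRates)) shiftTime <- runLength
  up <- which(upper.tri(rates))
  nPair <- length(up)
  draws <- matrix(0, nPair, runLength)
  if (shiftTime > 0L)
    draws[, seq_len(shiftTime)] <-
      rpois(nPair * shiftTime, rep(rates[up], shiftTime))
  if (shiftTime < runLength) {
    post <- runLength - shiftTime
    draws[, shiftTime + seq_len(post)] <-
      rpois(nPair * post, rep(as.matrix(shiftedRates)[up], post))
  }
  arr <- array(0, c(V, V, runLength))
  idx <- rep(up, runLength) +
    rep((seq_len(runLength) - 1L) * V * V, each = nPair)
  arr[idx] <- draws
  arr <- arr + aperm(arr, c(2L, 1L, 3L))
  .newNetworkSequence(arr, stepWidth = 1L, startTime = 0,
                      dataType = "count")
}

# Internal constructor skipping validity (hot path; inputs are constructed
# to satisfy the invariants).
.newNetworkSequence <- function(counts, stepWidth, startTime, dataType) {
  new2("NetworkSequence", counts = counts,
       stepWidth = as.integer(stepWidth), startTime = as.numeric(startTime),
       dataType = dataType, check = FALSE)
}

#' Construct a network sequence from an array or list of matrices
#'
#' @param counts a `|V| x |V| x T` array or a list of T square matrices.
#' @param stepWidth time units covered by each matrix.
#' @param startTime original time at which the sequence starts.
#' @param dataType `"count"` or `"binary"`.
#' @return a validated [NetworkSequence-class].
#' @export
networkSequence <- function(counts, stepWidth = 1L, startTime = 0,
                            dataType = c("count", "binary")) {
  dataType <- match.arg(dataType)
  if (is.list(counts)) {
    V <- nrow(counts[[1L]])
    counts <- array(unlist(counts), c(V, V, length(counts)))
  }
  new("NetworkSequence", counts = counts, stepWidth = as.integer(stepWidth),
      startTime = as.numeric(startTime), dataType = dataType)
}
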