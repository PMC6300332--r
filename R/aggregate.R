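# Temporal aggregation and count-to-binary conversion.

#' Aggregate a count sequence into non-overlapping W-blocks
#'
#' Sums each block of `level` consecutive matrices into one matrix, so a
#' sequence of T unit-width matrices becomes `T / level` matrices of step
#' width `level`. Aggregation conserves the total count and preserves
#' symmetry and the zero diagonal. The sequence length must be divisible by
#' `level`: silent truncation would corrupt the shift-time bookkeeping.
#'
#' @param x a count [NetworkSequence-class].
#' @param level positive integer aggregation level W.
#' @return a [NetworkSequence-class] of step width `stepWidth(x) * level`.
#' @examples
#' x <- networkSequence(array(rep(c(0, 1, 1, 0), 4), c(2, 2, 4)))
#' nSnapshots(aggregateSequence(x, 2))  # 2
#' @export
aggregateSequence <- function(x, level) {
  stopifnot(is(x, "NetworkSequence"))
  if (x@dataType != "count")
    stop("aggregation applies to count sequences; binarize after aggregating",
         call. = FALSE)
  level <- as.integer(level)
  if (is.na(level) || level < 1L)
    stop("aggregation level must be a positive integer", call. = FALSE)
  T <- nSnapshots(x)
  if (T %% level != 0L)
    stop(sprintf(
      "sequence length %d is not divisible by aggregation level %d", T,
      level), call. = FALSE)
  if (level == 1L) return(x)
  V <- nNodes(x)
  nOut <- T %/% level
  blocks <- array(aperm(array(x@counts, c(V * V, level, nOut)),
                        c(2L, 1L, 3L)),
                  c(level, V * V * nOut))
  agg <- array(colSums(blocks), c(V, V, nOut))
  .newNetworkSequence(agg, stepWidth = x@stepWidth * level,
                      startTime = x@startTime, dataType = "count")
}

#' Convert counts to binary indicators
#'
#' Entry-wise conversion: an aggregated cell becomes 1 when its count is at
#' least `threshold`, else 0. The study's convention is threshold 1 —
#' whether communication occurred at all — applied after aggregation
#' (`B^(W) = binarize(C^(W))`).
#'
#' @param x a count [NetworkSequence-class].
#' @param threshold positive integer count threshold.
#' @return a binary [NetworkSequence-class] with the same step width.
#' @examples
#' x <- networkSequence(array(c(0, 3, 3, 0), c(2, 2, 1)))
#' snapshot(binarizeSequence(x), 1)
#' @export
binarizeSequence <- function(x, threshold = 1L) {
  stopifnot(is(x, "NetworkSequence"))
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 1L)
    stop("binarization threshold must be a positive integer", call. = FALSE)
  bin <- (x@counts >= threshold) * 1
  .newNetworkSequence(bin, stepWidth = x@stepWidth, startTime = x@startTime,
                      dataType = "binary")
}

#' Density of a binary network
#'
#' Proportion of the potential connections that are actual connections:
#' the number of unordered connected pairs divided by `|V| (|V| - 1) / 2`.
#'
#' @param mat a symmetric binary adjacency matrix with zero diagonal.
#' @return a number in `[0, 1]`.
#' @examples
#' networkDensity(matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3))  # 3-node path
#' @export
networkDensity <- function(mat) {
  mat <- as.matrix(mat)
  if (!isSymmetric(unname(mat)) || any(diag(mat) != 0))
    stop("density needs a symmetric zero-diagonal matrix", call. = FALSE)
  if (!all(mat %in% c(0, 1)))
    stop("density is defined for binary matrices", call. = FALSE)
  n <- nrow(mat)
  if (n < 2L) return(0)
  sum(mat[upper.tri(mat)]) / (n * (n - 1) / 2)
}
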