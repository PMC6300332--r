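# Priebe's moving-window scan method.

#' Per-node degree and neighborhood-size statistics
#'
#' For a single symmetric zero-diagonal adjacency matrix, computes for each
#' node i the locality statistics of orders k = 0, 1, 2:
#' \itemize{
#'   \item `O0`: the (weighted) degree — sum of row i; for binary data the
#'     number of neighbors.
#'   \item `Ok`, k >= 1: the size of the k-th neighborhood — the sum of
#'     entries over unordered pairs whose endpoints both lie within
#'     support-graph distance k of i (a cell belongs to the support graph
#'     when its count is at least 1, and a node belongs to its own
#'     neighborhood). For binary data this is the induced edge count.
#' }
#' The nesting `O0 <= O1 <= O2` always holds.
#'
#' @param mat symmetric zero-diagonal adjacency matrix (count or binary).
#' @param order which orders to return, a subset of `0:2`.
#' @return a `|V| x length(order)` matrix (column names `"O0"`, ...); a
#'   vector when a single order is requested.
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' neighborhoodStats(tri)            # every node: 2, 3, 3
#' @export
neighborhoodStats <- function(mat, order = 0:2) {
  mat <- as.matrix(mat) * 1
  if (nrow(mat) != ncol(mat) || !isSymmetric(unname(mat)))
    stop("adjacency matrix must be square and symmetric", call. = FALSE)
  if (any(diag(mat) != 0))
    stop("adjacency matrix must have a zero diagonal", call. = FALSE)
  if (any(mat < 0))
    stop("adjacency entries must be non-negative", call. = FALSE)
  if (!all(order %in% 0:2))
    stop("order must be a subset of 0:2", call. = FALSE)
  st <- scan_node_stats_cpp(array(mat, c(dim(mat), 1L)))
  out <- cbind(O0 = st$O0[1L, ], O1 = st$O1[1L, ], O2 = st$O2[1L, ])
  out[, paste0("O", order), drop = length(order) == 1L]
}

#' Two-sided moving-window standardization
#'
#' Standardizes each series value against the `width` values immediately
#' preceding it: output at index t is
#' `(x_t - mean(x_[t-width .. t-1])) / max(sd(x_[t-width .. t-1]), 1)`,
#' with the sample standard deviation (divisor `width - 1`). The unit floor
#' on the denominator keeps near-constant windows from exploding the
#' statistic. Indices without `width` prior observations are `NA`.
#'
#' @param x numeric vector, or matrix with time along rows (each column
#'   standardized independently).
#' @param width positive integer window width (at least 2).
#' @return object of the same shape as `x` with the first `width` entries
#'   (rows) `NA`.
#' @examples
#' windowedStandardize(c(rep(0, 20), 7), width = 20)[21]  # 7: sd floor
#' @export
windowedStandardize <- function(x, width = 20L) {
  width <- as.integer(width)
  if (is.na(width) || width < 2L)
    stop("window width must be an integer >= 2", call. = FALSE)
  isVec <- is.null(dim(x))
  m <- if (isVec) matrix(x, ncol = 1L) else as.matrix(x)
  T <- nrow(m)
  out <- matrix(NA_real_, T, ncol(m), dimnames = dimnames(m))
  if (T > width) {
    cs <- rbind(0, apply(m, 2L, cumsum))
    cs2 <- rbind(0, apply(m * m, 2L, cumsum))
    idx <- (width + 1L):T
    winSum <- cs[idx, , drop = FALSE] - cs[idx - width, , drop = FALSE]
    winSS <- cs2[idx, , drop = FALSE] - cs2[idx - width, , drop = FALSE]
    mu <- winSum / width
    v <- (winSS - width * mu * mu) / (width - 1L)
    v[v < 0] <- 0                       # cumsum round-off guard
    out[idx, ] <- (m[idx, , drop = FALSE] - mu) / pmax(sqrt(v), 1)
  }
  if (isVec) out[, 1L] else out
}

# Core of the scan on a raw counts array; shared by scanSequence and the
# Monte-Carlo harness (which skips S4 construction of intermediates).
.scanCore <- function(counts, windowWidth, signalThreshold) {
  T <- dim(counts)[3L]
  w <- windowWidth
  if (T < 2L * w + 1L)
    stop(sprintf(paste0(
      "scan needs at least %d matrices (two stacked windows of %d plus ",
      "the monitored point); got %d"), 2L * w + 1L, w, T), call. = FALSE)
  O <- scan_node_stats_cpp(counts)
  Ostar <- lapply(O, windowedStandardize, width = w)
  M <- vapply(Ostar, function(m) {
    m[is.na(m)] <- -Inf
    res <- do.call(pmax, as.data.frame(m))
    res[!is.finite(res)] <- NA_real_
    res
  }, numeric(T))
  colnames(M) <- c("M0", "M1", "M2")
  avail <- (w + 1L):T
  Mstar <- matrix(NA_real_, T, 3L,
                  dimnames = list(NULL, c("M0", "M1", "M2")))
  Mstar[avail, ] <- windowedStandardize(M[avail, , drop = FALSE], width = w)
  top <- pmax(Mstar[, 1L], Mstar[, 2L], Mstar[, 3L])
  flags <- !is.na(top) & top >= signalThreshold
  list(O = O, Ostar = Ostar, M = M, Mstar = Mstar, flags = flags)
}

#' Monitor a network sequence with the moving-window scan method
#'
#' Runs the two-stage scan: per-node statistics `O^k` (k = 0, 1, 2) at each
#' time, windowed standardization per node and order into `O*`, across-node
#' maxima `M^k`, a second windowed standardization into `M*^k`, and the
#' signal rule `max(M*^0, M*^1, M*^2) >= signalThreshold`. Two stacked
#' windows are needed before the first signalable index, so a sequence must
#' contain at least `2 * windowWidth + 1` matrices (41 at the default
#' width 20) and signals can occur from index `2 * windowWidth + 1` on.
#'
#' @param x a [NetworkSequence-class] (count or binary, any step width).
#' @param windowWidth moving-window width (default 20).
#' @param signalThreshold signaling threshold (default 4; a signal is
#'   raised when the maximum standardized statistic is `>=` the threshold).
#' @return a [ScanResult-class]; see [signalTimes()] for flagged points in
#'   original time units.
#' @examples
#' x <- networkSequence(array(0, c(3, 3, 45)))
#' scanSequence(x)   # constant sequence: no signals
#' @export
scanSequence <- function(x, windowWidth = 20L, signalThreshold = 4) {
  stopifnot(is(x, "NetworkSequence"))
  windowWidth <- as.integer(windowWidth)
  if (is.na(windowWidth) || windowWidth < 2L)
    stop("window width must be an integer >= 2", call. = FALSE)
  core <- .scanCore(x@counts, windowWidth, signalThreshold)
  new2("ScanResult",
       nodeStats = core$O, standardizedNodeStats = core$Ostar,
       maxStats = core$M, standardizedMaxStats = core$Mstar,
       signalFlags = core$flags, windowWidth = windowWidth,
       signalThreshold = as.numeric(signalThreshold),
       stepWidth = x@stepWidth, startTime = x@startTime, check = FALSE)
}
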