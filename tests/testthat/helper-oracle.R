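# Independent brute-force oracle for the per-node locality statistics.
#
# Deliberately different mechanism from the package kernel (set-expansion
# BFS over explicit neighbor lists instead of matrix algebra): for node i,
# N_k(i) is grown by repeated union of support-graph neighbor sets starting
# from {i}; O^0 is the row sum and O^k the sum of entries over pairs inside
# N_k(i).
oracleNeighborhoodStats <- function(A) {
  V <- nrow(A)
  support <- lapply(seq_len(V), function(i) which(A[i, ] >= 1))
  out <- matrix(0, V, 3, dimnames = list(NULL, c("O0", "O1", "O2")))
  for (i in seq_len(V)) {
    out[i, 1L] <- sum(A[i, ])
    nb <- i
    for (k in 1:2) {
      nb <- sort(unique(c(nb, unlist(support[nb]))))
      out[i, k + 1L] <- sum(A[nb, nb, drop = FALSE]) / 2
    }
  }
  out
}

# Second, library-based oracle (igraph shortest-path distances on the
# support graph); used as a cross-check on random weighted graphs.
igraphNeighborhoodStats <- function(A) {
  g <- igraph::graph_from_adjacency_matrix((A >= 1) * 1, mode = "undirected")
  D <- igraph::distances(g)
  V <- nrow(A)
  out <- matrix(0, V, 3, dimnames = list(NULL, c("O0", "O1", "O2")))
  out[, 1L] <- rowSums(A)
  for (k in 1:2) for (i in seq_len(V)) {
    nb <- which(D[i, ] <= k)
    out[i, k + 1L] <- sum(A[nb, nb, drop = FALSE]) / 2
  }
  out
}

# Random symmetric zero-diagonal count matrix.
randomCountMatrix <- function(V, maxCount = 5) {
  A <- matrix(0, V, V)
  ut <- upper.tri(A)
  A[ut] <- sample(0:maxCount, sum(ut), replace = TRUE,
                  prob = c(0.5, rep(0.5 / maxCount, maxCount)))
  A + t(A)
}

# All binary graphs on n nodes as a V x V x 2^(n(n-1)/2) array.
allBinaryGraphs <- function(n) {
  nPair <- n * (n - 1L) / 2L
  nG <- 2L^nPair
  ut <- which(upper.tri(matrix(0, n, n)))
  arr <- array(0, c(n, n, nG))
  bits <- vapply(seq_len(nG) - 1L,
                 function(g) as.integer(intToBits(g))[seq_len(nPair)],
                 integer(nPair))
  idx <- rep(ut, nG) + rep((seq_len(nG) - 1L) * n * n, each = nPair)
  arr[idx] <- as.numeric(bits)
  arr + aperm(arr, c(2L, 1L, 3L))
}
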