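# Reproducible per-run random streams.
#
# A master seed initializes an L'Ecuyer-CMRG state; replication j uses the
# j-th substream obtained with parallel::nextRNGStream. Outcomes therefore
# depend only on (master seed, run index), not on execution order or degree
# of parallelism.

.baseStreamState <- function(masterSeed) {
  old <- .collectRNGState()
  on.exit(.restoreRNGState(old))
  set.seed(as.integer(masterSeed %% 2147483647L), kind = "L'Ecuyer-CMRG")
  get(".Random.seed", envir = globalenv())
}

#' Derive the random stream of one replication
#'
#' Returns the `.Random.seed` state vector of the `runIndex`-th independent
#' L'Ecuyer-CMRG substream derived from `masterSeed`. Used by the
#' Monte-Carlo harness so that every replication is reproducible from
#' `(masterSeed, runIndex)` alone.
#'
#' @param masterSeed integer master seed.
#' @param runIndex positive integer replication index.
#' @return an RNG state vector suitable for assignment to `.Random.seed`.
#' @examples
#' s1 <- runStream(1, 5)
#' s2 <- runStream(1, 5)
#' identical(s1, s2)
#' @export
runStream <- function(masterSeed, runIndex) {
  runIndex <- as.integer(runIndex)
  if (is.na(runIndex) || runIndex < 1L)
    stop("runIndex must be a positive integer", call. = FALSE)
  s <- .baseStreamState(masterSeed)
  for (k in seq_len(runIndex)) s <- parallel::nextRNGStream(s)
  s
}

# Iterator over successive substreams; the harness advances one stream per
# replication instead of re-deriving from scratch (same states as runStream).
.streamIterator <- function(masterSeed) {
  s <- .baseStreamState(masterSeed)
  function() {
    s <<- parallel::nextRNGStream(s)
    s
  }
}

.collectRNGState <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreRNGState <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate expr under a given RNG state, restoring the caller's state after.
.withRNGState <- function(state, expr) {
  old <- .collectRNGState()
  on.exit(.restoreRNGState(old))
  assign(".Random.seed", state, envir = globalenv())
  expr
}

# Deterministic per-cell seed for sweeps over scenario grids.
.cellSeed <- function(masterSeed, cellIndex) {
  as.integer((as.numeric(masterSeed) + 7919 * as.numeric(cellIndex)) %%
               2147483647)
}
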