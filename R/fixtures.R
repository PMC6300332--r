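# Deterministic fixtures used by the test suite and documentation.

#' Built-in deterministic fixtures
#'
#' Small inputs with hand-computed expected statistics, used in tests and
#' examples. Available fixtures:
#' \describe{
#'   \item{`"triangle"`}{3-node binary triangle; every node has
#'     `O0 = 2, O1 = 3, O2 = 3`.}
#'   \item{`"path3"`}{binary path 1–2–3; node 1 has `O0 = 1, O1 = 1,
#'     O2 = 2`, node 2 has `O0 = O1 = O2 = 2`.}
#'   \item{`"weighted-path3"`}{counts C(1,2) = 5, C(2,3) = 2; node 2 has
#'     `O0 = O1 = 7`, node 1 has `O0 = O1 = 5, O2 = 7`.}
#'   \item{`"constant-sequence"`}{60 identical matrices; all second-stage
#'     standardized maxima are 0 and no signals occur.}
#'   \item{`"shifted-run"`}{seeded 20-node DCSBM run with `tau = 845`,
#'     `T = 860`: at `W = 20` the final aggregation block mixes 5 baseline
#'     with 15 anomalous unit matrices.}
#' }
#'
#' @param name fixture name.
#' @return a list with the fixture object (`matrix` or `sequence`) plus its
#'   `expected` reference values.
#' @examples
#' makeFixture("triangle")$expected
#' @export
makeFixture <- function(name) {
  catalogue <- c("triangle", "path3", "weighted-path3",
                 "constant-sequence", "shifted-run")
  if (!is.character(name) || length(name) != 1L || !(name %in% catalogue))
    stop("unknown fixture; available: ",
         paste(catalogue, collapse = ", "), call. = FALSE)
  switch(name,
    "triangle" = {
      m <- matrix(1, 3, 3) - diag(3)
      list(matrix = m,
           expected = list(O0 = c(2, 2, 2), O1 = c(3, 3, 3),
                           O2 = c(3, 3, 3)))
    },
    "path3" = {
      m <- matrix(0, 3, 3)
      m[1, 2] <- m[2, 1] <- m[2, 3] <- m[3, 2] <- 1
      list(matrix = m,
           expected = list(O0 = c(1, 2, 1), O1 = c(1, 2, 1),
                           O2 = c(2, 2, 2)))
    },
    "weighted-path3" = {
      m <- matrix(0, 3, 3)
      m[1, 2] <- m[2, 1] <- 5
      m[2, 3] <- m[3, 2] <- 2
      list(matrix = m,
           expected = list(O0 = c(5, 7, 2), O1 = c(5, 7, 2),
                           O2 = c(7, 7, 7)))
    },
    "constant-sequence" = {
      m <- matrix(0, 4, 4)
      m[1, 2] <- m[2, 1] <- 3
      m[3, 4] <- m[4, 3] <- 1
      seq <- networkSequence(array(m, c(4, 4, 60)))
      list(sequence = seq,
           expected = list(maxStandardized = 0, signals = integer()))
    },
    "shifted-run" = {
      cs <- communityStructure(c(10L, 10L))
      seq <- .withRNGState(runStream(424242L, 1L), {
        th <- drawDegreePropensities(cs)
        generateSequence(cs, th, blockPropensity(1, 2, 2),
                         shift = shiftSpec(1.5, 845L), runLength = 860L)
      })
      list(sequence = seq, structure = cs,
           expected = list(shiftTime = 845L,
                           finalBlockBaseline = 5L,
                           finalBlockAnomalous = 15L))
    })
}
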