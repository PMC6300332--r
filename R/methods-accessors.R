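# Accessor and show methods.

#' @rdname accessors
setMethod("nNodes", "CommunityStructure",
          function(x) length(x@membership))
#' @rdname accessors
setMethod("nNodes", "NetworkSequence", function(x) dim(x@counts)[1L])
#' @rdname accessors
setMethod("nNodes", "ScenarioConfig", function(x) x@nNodes)

#' @rdname accessors
setMethod("nSnapshots", "NetworkSequence", function(x) dim(x@counts)[3L])
#' @rdname accessors
setMethod("nSnapshots", "ScanResult", function(x) length(x@signalFlags))

#' @rdname accessors
setMethod("stepWidth", "NetworkSequence", function(x) x@stepWidth)
#' @rdname accessors
setMethod("stepWidth", "ScanResult", function(x) x@stepWidth)

#' @rdname accessors
setMethod("dataType", "NetworkSequence", function(x) x@dataType)

#' @rdname accessors
setMethod("startTime", "NetworkSequence", function(x) x@startTime)
#' @rdname accessors
setMethod("startTime", "ScanResult", function(x) x@startTime)

#' @rdname accessors
setMethod("endTimes", "NetworkSequence",
          function(x) x@startTime + seq_len(nSnapshots(x)) * x@stepWidth)
#' @rdname accessors
setMethod("endTimes", "ScanResult",
          function(x) x@startTime + seq_len(nSnapshots(x)) * x@stepWidth)

#' @rdname accessors
setMethod("communitySizes", "CommunityStructure", function(x) x@sizes)
#' @rdname accessors
setMethod("membership", "CommunityStructure", function(x) x@membership)

#' @rdname accessors
setMethod("theta", "DegreePropensity", function(x) x@theta)

#' @rdname accessors
setMethod("propensityMatrix", "BlockPropensity", function(x) x@P)

#' @rdname accessors
setMethod("signalFlags", "ScanResult", function(x) x@signalFlags)

#' @rdname accessors
setMethod("signalTimes", "ScanResult",
          function(x) endTimes(x)[which(x@signalFlags)])

#' @rdname accessors
setMethod("maxStats", "ScanResult", function(x) x@maxStats)

#' @rdname accessors
setMethod("standardizedMaxStats", "ScanResult",
          function(x) x@standardizedMaxStats)

#' @rdname snapshot
setMethod("snapshot", "NetworkSequence", function(x, t) {
  t <- as.integer(t)
  if (t < 1L || t > nSnapshots(x))
    stop("snapshot index out of range", call. = FALSE)
  x@counts[, , t]
})

setMethod("show", "CommunityStructure", function(object) {
  cat("CommunityStructure:", length(object@sizes), "communities,",
      sum(object@sizes), "nodes ( sizes:",
      paste(object@sizes, collapse = ", "), ")\n")
})

setMethod("show", "BlockPropensity", function(object) {
  cat("BlockPropensity (", nrow(object@P), "x", ncol(object@P), "):\n")
  print(object@P)
})

setMethod("show", "NetworkSequence", function(object) {
  cat(sprintf("NetworkSequence: %d snapshots of a %d-node network (%s data)\n",
              nSnapshots(object), nNodes(object), object@dataType))
  cat(sprintf("  step width %d, covering original time (%g, %g]\n",
              object@stepWidth, object@startTime,
              object@startTime + nSnapshots(object) * object@stepWidth))
})

setMethod("show", "ScanResult", function(object) {
  n <- sum(object@signalFlags)
  cat(sprintf("ScanResult: %d monitored points (window %d, threshold %g)\n",
              nSnapshots(object), object@windowWidth,
              object@signalThreshold))
  first <- 2L * object@windowWidth + 1L
  cat(sprintf("  signalable from index %d; %d signal(s)", first, n))
  if (n > 0L)
    cat(" at original time(s)",
        paste(signalTimes(object), collapse = ", "))
  cat("\n")
})

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig:\n")
  cat(sprintf("  |V| = %d (communities: %s), P_rr0 = %g, ratio %g:1\n",
              object@nNodes, paste(object@communitySizes, collapse = ", "),
              object@baselineDiag, object@homophilyRatio))
  cat(sprintf("  T = %d, W = %d, %s data (binarize >= %d), shift s = %g\n",
              object@runLength, object@aggregationLevel, object@dataType,
              object@binarizeThreshold, object@shiftFraction))
  cat(sprintf("  shift times: %s\n",
              if (length(object@shiftTimes))
                paste(range(object@shiftTimes), collapse = "..")
              else "none"))
  cat(sprintf("  scan window %d, threshold %g; %d replications, seed %d\n",
              object@windowWidth, object@signalThreshold,
              object@replications, object@seed))
})
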