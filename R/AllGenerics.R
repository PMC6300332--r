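#' @title Accessors for dynetscan classes
#' @description Small accessor generics: number of nodes, number of
#'   snapshots, time-step width, data type, start time, interval end times,
#'   signal flags and signal times, propensities and membership.
#' @param x a dynetscan object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("nSnapshots", function(x) standardGeneric("nSnapshots"))

#' @rdname accessors
#' @export
setGeneric("stepWidth", function(x) standardGeneric("stepWidth"))

#' @rdname accessors
#' @export
setGeneric("dataType", function(x) standardGeneric("dataType"))

#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' @rdname accessors
#' @export
setGeneric("endTimes", function(x) standardGeneric("endTimes"))

#' @rdname accessors
#' @export
setGeneric("communitySizes", function(x) standardGeneric("communitySizes"))

#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))

#' @rdname accessors
#' @export
setGeneric("propensityMatrix", function(x) standardGeneric("propensityMatrix"))

#' @rdname accessors
#' @export
setGeneric("signalFlags", function(x) standardGeneric("signalFlags"))

#' @rdname accessors
#' @export
setGeneric("signalTimes", function(x) standardGeneric("signalTimes"))

#' @rdname accessors
#' @export
setGeneric("maxStats", function(x) standardGeneric("maxStats"))

#' @rdname accessors
#' @export
setGeneric("standardizedMaxStats",
           function(x) standardGeneric("standardizedMaxStats"))

#' Extract one adjacency matrix from a sequence
#'
#' @param x a [NetworkSequence-class].
#' @param t snapshot index (1-based).
#' @return the t-th `|V| x |V|` adjacency matrix.
#' @export
setGeneric("snapshot", function(x, t) standardGeneric("snapshot"))
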