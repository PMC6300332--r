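# Temporal edge-list and result-table input/output.

#' Read a temporal edge list into a network sequence
#'
#' Expects a delimited text file with header `t i j count` (tab- or
#' comma-separated): 1-based time index, node pair with `i < j`, positive
#' integer count. Omitted cells are zero; time indices missing inside the
#' covered range become zero matrices. Comment lines starting with `#` may
#' carry sequence metadata written by [writeEdgeList()] (`nodes`, `times`,
#' `stepWidth`, `startTime`, `dataType`) and are honoured on read.
#'
#' @param path file path.
#' @param nNodes number of nodes; default: metadata comment, else the
#'   largest node index observed.
#' @param nTimes number of snapshots; default: metadata comment, else the
#'   largest time index observed.
#' @param stepWidth,startTime,dataType sequence metadata overrides.
#' @return a [NetworkSequence-class].
#' @seealso [writeEdgeList()]
#' @export
readEdgeList <- function(path, nNodes = NULL, nTimes = NULL,
                         stepWidth = NULL, startTime = NULL,
                         dataType = NULL) {
  lines <- readLines(path)
  meta <- .parseEdgeListMeta(lines)
  body <- grep("^[[:space:]]*(#|$)", lines, invert = TRUE)
  if (!length(body)) stop("edge list has no header line", call. = FALSE)
  sep <- if (grepl(",", lines[body[1L]])) "," else ""
  df <- read.table(text = lines[body], header = TRUE, sep = sep,
                   strip.white = TRUE)
  if (ncol(df) != 4L)
    stop("edge list must have four columns: t, i, j, count", call. = FALSE)
  names(df) <- c("t", "i", "j", "count")
  lineNo <- body[-1L]
  .edgeListCheck <- function(bad, msg) {
    if (any(bad))
      stop(sprintf("%s (line %d)", msg, lineNo[which(bad)[1L]]),
           call. = FALSE)
  }
  for (col in names(df))
    .edgeListCheck(is.na(df[[col]]) | df[[col]] != round(df[[col]]),
                   sprintf("non-integer value in column '%s'", col))
  .edgeListCheck(df$t < 1L, "time index must be >= 1")
  .edgeListCheck(df$i < 1L | df$j < 1L, "node indices are 1-based")
  .edgeListCheck(df$i == df$j, "self-pairs are not allowed")
  .edgeListCheck(df$i > df$j, "node pairs must satisfy i < j")
  .edgeListCheck(df$count < 1L, "omit zero cells instead of storing them")
  .edgeListCheck(duplicated(df[c("t", "i", "j")]), "duplicate (t, i, j) key")
  V <- as.integer(nNodes %||% meta$nodes %||% max(df$j, 0L))
  T <- as.integer(nTimes %||% meta$times %||% max(df$t, 0L))
  if (nrow(df) && max(df$j) > V)
    stop("node index exceeds declared number of nodes", call. = FALSE)
  if (nrow(df) && max(df$t) > T)
    stop("time index exceeds declared number of snapshots", call. = FALSE)
  arr <- array(0, c(V, V, T))
  if (nrow(df)) {
    arr[cbind(df$i, df$j, df$t)] <- df$count
    arr <- arr + aperm(arr, c(2L, 1L, 3L))
  }
  networkSequence(arr,
                  stepWidth = stepWidth %||% meta$stepWidth %||% 1L,
                  startTime = startTime %||% meta$startTime %||% 0,
                  dataType = dataType %||% meta$dataType %||% "count")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parseEdgeListMeta <- function(lines) {
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#[[:space:]]*([A-Za-z]+):[[:space:]]*(.+)$",
                                ln))[[1L]]
    if (length(m) == 3L) {
      key <- m[2L]
      meta[[key]] <- if (key == "dataType") m[3L] else as.numeric(m[3L])
    }
  }
  meta
}

#' Write a network sequence as a temporal edge list
#'
#' Stores the upper triangle only (symmetry is reconstructed on read),
#' omits zero cells, and sorts records by (t, i, j) so output is canonical.
#' Metadata comment lines make the round trip lossless.
#'
#' @param x a [NetworkSequence-class].
#' @param path output file path.
#' @param sep field separator, tab by default.
#' @return `invisible(path)`.
#' @seealso [readEdgeList()]
#' @export
writeEdgeList <- function(x, path, sep = "\t") {
  stopifnot(is(x, "NetworkSequence"))
  V <- nNodes(x)
  T <- nSnapshots(x)
  up <- which(upper.tri(matrix(0, V, V)), arr.ind = TRUE)
  recs <- do.call(rbind, lapply(seq_len(T), function(t) {
    vals <- x@counts[, , t][upper.tri(matrix(0, V, V))]
    keep <- vals != 0
    if (!any(keep)) return(NULL)
    data.frame(t = t, i = up[keep, 1L], j = up[keep, 2L],
               count = vals[keep])
  }))
  if (is.null(recs))
    recs <- data.frame(t = integer(), i = integer(), j = integer(),
                       count = numeric())
  recs <- recs[order(recs$t, recs$i, recs$j), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# nodes: %d", V),
               sprintf("# times: %d", T),
               sprintf("# stepWidth: %d", x@stepWidth),
               sprintf("# startTime: %g", x@startTime),
               sprintf("# dataType: %s", x@dataType)), con)
  write.table(recs, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an experiment table to CSV
#'
#' Deterministic column order; `#` comment header lines carry the package
#' version, master seed(s) and timestamp. The data section of two sweeps
#' with identical seeds is byte-identical (the timestamp lives in the
#' comments, which [readResults()] skips).
#'
#' @param table experiment table from [sweepScenarios()] (any data frame).
#' @param path output file path.
#' @param seed optional master seed to record in the header.
#' @return `invisible(path)`.
#' @export
writeResults <- function(table, path, seed = NULL) {
  stopifnot(is.data.frame(table))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dynetscan %s", as.character(packageVersion("dynetscan"))),
               sprintf("# seed: %s",
                       if (is.null(seed)) "NA" else format(seed)),
               sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             con)
  write.table(table[, sort(names(table)), drop = FALSE], con, sep = ",",
              quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' Read an experiment table written by [writeResults()]
#'
#' @param path file path.
#' @return a `data.frame`.
#' @export
readResults <- function(path) {
  read.table(path, header = TRUE, sep = ",", comment.char = "#",
             stringsAsFactors = FALSE)
}
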