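# Monte-Carlo experiment harness: detection rates, false alarm rates,
# conditional signal delays, shift-offset profiles, scenario sweeps.

#' Construct a scenario configuration
#'
#' Builds a [ScenarioConfig-class] with the study's headline defaults:
#' a 20-node network in two communities of 10, homophily 2:1,
#' Pareto(1, 3) degree propensities, 860 unit-width matrices, scan window
#' 20 with signal threshold 4, and binarization threshold 1. `shiftTimes`
#' defaults to all offsets of one aggregation period at the end of the run:
#' `{T-20, ..., T-20+W-1}` for `W > 1` and the single time `T-20` for
#' `W = 1`.
#'
#' @param nNodes network order |V|.
#' @param communitySizes community sizes (default: two equal halves).
#' @param baselineDiag baseline within-community propensity `P_rr0`.
#' @param homophilyRatio within:between propensity ratio.
#' @param paretoScale,paretoShape degree-propensity Pareto parameters.
#' @param runLength number of unit-width matrices T.
#' @param shiftFraction relative shift magnitude s (0 for no-shift runs).
#' @param shiftTimes candidate last-baseline times; `NULL` for the default
#'   offset set described above.
#' @param aggregationLevel aggregation level W.
#' @param dataType `"count"` or `"binary"`.
#' @param binarizeThreshold count-to-binary threshold.
#' @param windowWidth scan moving-window width.
#' @param signalThreshold scan signaling threshold.
#' @param replications Monte-Carlo replications.
#' @param seed master seed.
#' @return a validated [ScenarioConfig-class].
#' @examples
#' scenarioConfig(baselineDiag = 0.2, shiftFraction = 0.5,
#'                aggregationLevel = 5L)
#' @export
scenarioConfig <- function(nNodes = 20L,
                           communitySizes = NULL,
                           baselineDiag = 1,
                           homophilyRatio = 2,
                           paretoScale = 1,
                           paretoShape = 3,
                           runLength = 860L,
                           shiftFraction = 0.5,
                           shiftTimes = NULL,
                           aggregationLevel = 1L,
                           dataType = c("count", "binary"),
                           binarizeThreshold = 1L,
                           windowWidth = 20L,
                           signalThreshold = 4,
                           replications = 200L,
                           seed = 1L) {
  dataType <- match.arg(dataType)
  nNodes <- as.integer(nNodes)
  if (is.null(communitySizes))
    communitySizes <- c(nNodes %/% 2L, nNodes - nNodes %/% 2L)
  runLength <- as.integer(runLength)
  aggregationLevel <- as.integer(aggregationLevel)
  if (is.null(shiftTimes)) {
    base <- runLength - 20L
    shiftTimes <- if (aggregationLevel == 1L) base
                  else base + seq_len(aggregationLevel) - 1L
  }
  new("ScenarioConfig", nNodes = nNodes,
      communitySizes = as.integer(communitySizes),
      baselineDiag = as.numeric(baselineDiag),
      homophilyRatio = as.numeric(homophilyRatio),
      paretoScale = as.numeric(paretoScale),
      paretoShape = as.numeric(paretoShape),
      runLength = runLength, shiftFraction = as.numeric(shiftFraction),
      shiftTimes = as.integer(shiftTimes),
      aggregationLevel = aggregationLevel, dataType = dataType,
      binarizeThreshold = as.integer(binarizeThreshold),
      windowWidth = as.integer(windowWidth),
      signalThreshold = as.numeric(signalThreshold),
      replications = as.integer(replications), seed = as.integer(seed))
}

# One full pipeline pass under the current RNG state. Draws theta, generates
# the unit-width sequence (with or without the shift), aggregates,
# optionally binarizes, scans, and books the outcome relative to tau.
.runOnce <- function(config, tau, withShift = TRUE) {
  cs <- communityStructure(config@communitySizes)
  th <- drawDegreePropensities(cs, config@paretoScale, config@paretoShape)
  blocks <- blockPropensity(config@baselineDiag, config@homophilyRatio,
                            length(config@communitySizes))
  shift <- if (withShift && config@shiftFraction > 0)
    shiftSpec(config@shiftFraction, tau) else NULL
  x <- generateSequence(cs, th, blocks, shift = shift,
                        runLength = config@runLength)
  .bookOutcome(x, config, tau)
}

# Aggregate / binarize / scan an already generated unit sequence and book
# detection, pre-shift signals, and delay relative to tau.
.bookOutcome <- function(x, config, tau, aggregationLevel = NULL) {
  W <- if (is.null(aggregationLevel)) config@aggregationLevel
       else as.integer(aggregationLevel)
  agg <- aggregateSequence(x, W)
  if (config@dataType == "binary")
    agg <- binarizeSequence(agg, config@binarizeThreshold)
  core <- .scanCore(agg@counts, config@windowWidth, config@signalThreshold)
  ends <- agg@startTime + seq_len(dim(agg@counts)[3L]) * agg@stepWidth
  post <- core$flags & ends > tau
  detected <- any(post)
  signalTime <- if (detected) min(ends[post]) else NA_real_
  list(detected = detected,
       signalTime = signalTime,
       delay = if (detected) signalTime - (tau + 1) else NA_real_,
       preShiftSignal = any(core$flags & ends <= tau))
}

#' Run one simulation replication
#'
#' Executes the full pipeline of a single run — draw degree propensities,
#' generate `runLength` unit matrices with the sustained shift at
#' `shiftTime`, aggregate at the configured level, binarize if requested,
#' scan — and books the outcome. Detection means a signal at an aggregated
#' point whose original end time lies in `(shiftTime, T]`; signals at or
#' before `shiftTime` are recorded as `preShiftSignal` and do not count as
#' detection. The replication's random stream is derived from
#' `(seed(config), runIndex)` via [runStream()].
#'
#' @param config a [ScenarioConfig-class].
#' @param shiftTime last baseline time tau; `NULL` allocates run
#'   `runIndex` its offset from `config@@shiftTimes` round-robin. `NA` or a
#'   `shiftFraction` of 0 gives a fully baseline (no-shift) run, with
#'   bookkeeping relative to the designated tau.
#' @param runIndex replication index (determines the random stream).
#' @return a one-row `data.frame` with columns `runIndex`, `shiftTime`,
#'   `detected`, `signalTime`, `delay`, `preShiftSignal`.
#' @examples
#' cfg <- scenarioConfig(baselineDiag = 1, shiftFraction = 1.5,
#'                       aggregationLevel = 20L)
#' runSingle(cfg, runIndex = 1)
#' @export
runSingle <- function(config, shiftTime = NULL, runIndex = 1L) {
  stopifnot(is(config, "ScenarioConfig"))
  offsets <- config@shiftTimes
  if (is.null(shiftTime))
    shiftTime <- offsets[(as.integer(runIndex) - 1L) %% length(offsets) + 1L]
  withShift <- !is.na(shiftTime)
  tau <- if (withShift) as.integer(shiftTime) else
    as.integer(offsets[(as.integer(runIndex) - 1L) %% length(offsets) + 1L])
  out <- .withRNGState(runStream(config@seed, runIndex),
                       .runOnce(config, tau, withShift = withShift))
  data.frame(runIndex = as.integer(runIndex), shiftTime = tau,
             detected = out$detected, signalTime = out$signalTime,
             delay = out$delay, preShiftSignal = out$preShiftSignal)
}

# Shared replication loop. withShift = FALSE gives the false-alarm pipeline.
.replicate <- function(config, withShift) {
  n <- config@replications
  offsets <- config@shiftTimes
  nextStream <- .streamIterator(config@seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tau <- offsets[(i - 1L) %% length(offsets) + 1L]
    s <- nextStream()
    out <- .withRNGState(s, .runOnce(config, tau, withShift = withShift))
    rows[[i]] <- c(i, tau, out$detected, out$signalTime, out$delay,
                   out$preShiftSignal)
  }
  m <- do.call(rbind, rows)
  data.frame(runIndex = as.integer(m[, 1L]), shiftTime = as.integer(m[, 2L]),
             detected = as.logical(m[, 3L]), signalTime = m[, 4L],
             delay = m[, 5L], preShiftSignal = as.logical(m[, 6L]))
}

.rateEstimate <- function(hits, n) {
  p <- mean(hits)
  list(rate = p, se = sqrt(p * (1 - p) / n), replications = n)
}

#' Estimate the detection rate of a scenario
#'
#' Runs `replications(config)` independent simulations with the sustained
#' shift, allocating runs equally (round-robin) over the configured shift
#' times, and estimates the proportion of runs in which the scan signals at
#' an aggregated point with original end time in `(tau, T]`. The binomial
#' Monte-Carlo standard error `sqrt(p (1 - p) / n)` is reported alongside.
#'
#' @param config a [ScenarioConfig-class].
#' @return a list with `rate`, `se`, `replications`, and the per-run
#'   `outcomes` data frame.
#' @export
detectionRate <- function(config) {
  stopifnot(is(config, "ScenarioConfig"))
  outcomes <- .replicate(config, withShift = TRUE)
  est <- .rateEstimate(outcomes$detected, nrow(outcomes))
  c(est, list(outcomes = outcomes))
}

#' Estimate the false alarm rate of a scenario
#'
#' Identical pipeline to [detectionRate()] but with no shift applied: the
#' block propensities stay at baseline for the whole run. A false alarm is
#' any signal at an aggregated point with original end time after the
#' designated (here hypothetical) shift time.
#'
#' @param config a [ScenarioConfig-class]; its `shiftFraction` is ignored.
#' @return a list with `rate`, `se`, `replications` and `outcomes`.
#' @export
falseAlarmRate <- function(config) {
  stopifnot(is(config, "ScenarioConfig"))
  outcomes <- .replicate(config, withShift = FALSE)
  est <- .rateEstimate(outcomes$detected, nrow(outcomes))
  c(est, list(outcomes = outcomes))
}

#' Conditional signal delay distribution
#'
#' Among detected runs, the conditional signal delay is the number of
#' original time periods from the first anomalous period to the signal:
#' `delay = signalTime - (tau + 1)`, so a signal at the first post-shift
#' period has delay 0.
#'
#' @param config a [ScenarioConfig-class].
#' @return a list with the vector of `delays`, their `mean` and `median`,
#'   a `histogram` table, the `detectionRate` estimate and `outcomes`.
#' @export
conditionalDelayDistribution <- function(config) {
  est <- detectionRate(config)
  delays <- est$outcomes$delay[est$outcomes$detected]
  list(delays = delays,
       mean = if (length(delays)) mean(delays) else NA_real_,
       median = if (length(delays)) median(delays) else NA_real_,
       histogram = table(factor(delays, levels = 0:20)),
       detectionRate = est$rate, se = est$se,
       replications = est$replications, outcomes = est$outcomes)
}

#' Detection rate as a function of the shift offset
#'
#' Estimates the detection rate separately for each candidate shift time,
#' using `replications(config)` runs per offset. Late offsets leave fewer
#' anomalous matrices inside the final aggregation period (and fewer
#' signaling opportunities), which degrades detection; the profile also
#' shows the recovery when the following aggregation period is entirely
#' anomalous.
#'
#' @param config a [ScenarioConfig-class].
#' @param offsets integer vector of last-baseline times tau to profile
#'   (default `{T-20, ..., T-1}`).
#' @return a `data.frame` with columns `shiftTime`, `positionInPeriod`
#'   (1-based position of the first anomalous matrix within its aggregation
#'   period), `rate`, `se`, `replications`.
#' @export
shiftOffsetProfile <- function(config,
                               offsets = seq(config@runLength - 20L,
                                             config@runLength - 1L)) {
  stopifnot(is(config, "ScenarioConfig"))
  W <- config@aggregationLevel
  rows <- lapply(seq_along(offsets), function(k) {
    tau <- as.integer(offsets[k])
    cellCfg <- config
    cellCfg@shiftTimes <- tau
    cellCfg@seed <- .cellSeed(config@seed, k)
    est <- detectionRate(cellCfg)
    data.frame(shiftTime = tau, positionInPeriod = (tau %% W) + 1L,
               rate = est$rate, se = est$se,
               replications = est$replications)
  })
  do.call(rbind, rows)
}

#' Compare aggregation levels on shared simulated sequences
#'
#' For each replication one unit-width sequence is generated (shared degree
#' propensities and counts) and scanned at every aggregation level, so
#' level-to-level differences are not inflated by simulation variation.
#' Because a single sequence has a single shift time, a common `shiftTime`
#' is used for all levels (default `T - 20`: the last aggregation period is
#' entirely anomalous at every level).
#'
#' @param config a [ScenarioConfig-class]; its `aggregationLevel` is
#'   ignored.
#' @param levels aggregation levels to compare (each must divide T).
#' @param shiftTime common last-baseline time.
#' @param sharedDraws if `FALSE`, each level gets fresh sequences (fresh
#'   random streams per level).
#' @return a `data.frame` with one row per level: `aggregationLevel`,
#'   `rate`, `se`, `replications`.
#' @export
compareAggregationLevels <- function(config, levels = c(1L, 2L, 5L, 10L, 20L),
                                     shiftTime = config@runLength - 20L,
                                     sharedDraws = TRUE) {
  stopifnot(is(config, "ScenarioConfig"))
  levels <- as.integer(levels)
  tau <- as.integer(shiftTime)
  n <- config@replications
  if (sharedDraws) {
    hits <- matrix(FALSE, n, length(levels))
    nextStream <- .streamIterator(config@seed)
    for (i in seq_len(n)) {
      s <- nextStream()
      hits[i, ] <- .withRNGState(s, {
        cs <- communityStructure(config@communitySizes)
        th <- drawDegreePropensities(cs, config@paretoScale,
                                     config@paretoShape)
        blocks <- blockPropensity(config@baselineDiag,
                                  config@homophilyRatio,
                                  length(config@communitySizes))
        shift <- if (config@shiftFraction > 0)
          shiftSpec(config@shiftFraction, tau) else NULL
        x <- generateSequence(cs, th, blocks, shift = shift,
                              runLength = config@runLength)
        vapply(levels, function(W)
          .bookOutcome(x, config, tau, aggregationLevel = W)$detected,
          logical(1L))
      })
    }
    rows <- lapply(seq_along(levels), function(k)
      data.frame(aggregationLevel = levels[k],
                 rate = mean(hits[, k]),
                 se = sqrt(mean(hits[, k]) * (1 - mean(hits[, k])) / n),
                 replications = n))
  } else {
    rows <- lapply(seq_along(levels), function(k) {
      cellCfg <- config
      cellCfg@aggregationLevel <- levels[k]
      cellCfg@shiftTimes <- tau
      cellCfg@seed <- .cellSeed(config@seed, k)
      est <- detectionRate(cellCfg)
      data.frame(aggregationLevel = levels[k], rate = est$rate,
                 se = est$se, replications = est$replications)
    })
  }
  do.call(rbind, rows)
}

#' Evaluate a grid of scenarios
#'
#' Runs [detectionRate()] (and, when `includeFAR`, [falseAlarmRate()]) for
#' every configuration in a list and collects a tidy table with one row per
#' condition. Each cell gets a deterministic seed derived from its master
#' seed and position, so results do not depend on evaluation order; cell
#' failures are recorded in the `error` column rather than aborting the
#' sweep.
#'
#' @param configs list of [ScenarioConfig-class] objects.
#' @param includeFAR also estimate the no-shift false alarm rate per cell.
#' @return an experiment table (`data.frame`): scenario parameters plus
#'   `detection_rate`, `se`, `replications`, optional `far`/`far_se`,
#'   delay summaries, and `error`.
#' @export
sweepScenarios <- function(configs, includeFAR = FALSE) {
  stopifnot(length(configs) >= 1L)
  rows <- lapply(seq_along(configs), function(k) {
    cfg <- configs[[k]]
    stopifnot(is(cfg, "ScenarioConfig"))
    cellCfg <- cfg
    cellCfg@seed <- .cellSeed(cfg@seed, k)
    base <- data.frame(
      nNodes = cfg@nNodes,
      communities = paste(cfg@communitySizes, collapse = "+"),
      baselineDiag = cfg@baselineDiag, homophilyRatio = cfg@homophilyRatio,
      runLength = cfg@runLength, shiftFraction = cfg@shiftFraction,
      aggregationLevel = cfg@aggregationLevel, dataType = cfg@dataType,
      binarizeThreshold = cfg@binarizeThreshold,
      windowWidth = cfg@windowWidth, signalThreshold = cfg@signalThreshold,
      seed = cfg@seed)
    res <- tryCatch({
      est <- detectionRate(cellCfg)
      delays <- est$outcomes$delay[est$outcomes$detected]
      out <- cbind(base, data.frame(
        detection_rate = est$rate, se = est$se,
        replications = est$replications,
        delay_mean = if (length(delays)) mean(delays) else NA_real_,
        delay_median = if (length(delays)) median(delays) else NA_real_,
        error = NA_character_))
      if (includeFAR) {
        farEst <- falseAlarmRate(cellCfg)
        out$far <- farEst$rate
        out$far_se <- farEst$se
      }
      out
    }, error = function(e) {
      out <- cbind(base, data.frame(
        detection_rate = NA_real_, se = NA_real_, replications = NA_integer_,
        delay_mean = NA_real_, delay_median = NA_real_,
        error = conditionMessage(e)))
      if (includeFAR) {
        out$far <- NA_real_
        out$far_se <- NA_real_
      }
      out
    })
    res
  })
  do.call(rbind, rows)
}
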