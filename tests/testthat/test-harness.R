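# Monte-Carlo harness: bookkeeping, allocation, reproducibility, orderings.

shortConfig <- function(...) {
  scenarioConfig(nNodes = 10L, communitySizes = c(5L, 5L), runLength = 100L,
                 ...)
}

test_that("scenario configuration validates the study invariants", {
  cfg <- scenarioConfig(baselineDiag = 0.2, shiftFraction = 0.5,
                        aggregationLevel = 5L)
  expect_equal(cfg@shiftTimes, 840:844)
  cfg1 <- scenarioConfig(aggregationLevel = 1L)
  expect_equal(cfg1@shiftTimes, 840L)
  cfg20 <- scenarioConfig(aggregationLevel = 20L)
  expect_equal(cfg20@shiftTimes, 840:859)
  expect_error(scenarioConfig(runLength = 100L, aggregationLevel = 7L),
               "divisible")
  expect_error(scenarioConfig(shiftTimes = 100L), "shift times")
  expect_error(scenarioConfig(communitySizes = c(5L, 5L)), "sum")
})

test_that("delay and detection conventions on crafted sequences", {
  cfg20 <- scenarioConfig(nNodes = 4L, communitySizes = c(2L, 2L),
                          aggregationLevel = 20L)
  # signal forced at t = 860 only: delay = 860 - (840 + 1) = 19
  arr <- array(0, c(4, 4, 860))
  spike <- matrix(40, 4, 4); diag(spike) <- 0
  arr[, , 841:860] <- spike
  x <- networkSequence(arr)
  out <- dynetscan:::.bookOutcome(x, cfg20, tau = 840L)
  expect_true(out$detected)
  expect_equal(out$signalTime, 860)
  expect_equal(out$delay, 19)
  expect_false(out$preShiftSignal)
  # W = 1: signal at the first post-shift period has delay 0
  cfg1 <- scenarioConfig(nNodes = 4L, communitySizes = c(2L, 2L),
                         aggregationLevel = 1L)
  out1 <- dynetscan:::.bookOutcome(x, cfg1, tau = 840L)
  expect_true(out1$detected)
  expect_equal(out1$signalTime, 841)
  expect_equal(out1$delay, 0)
  # a spike entirely before tau is a pre-shift signal, not a detection
  arr2 <- array(0, c(4, 4, 860))
  arr2[, , 821:840] <- spike
  out2 <- dynetscan:::.bookOutcome(networkSequence(arr2), cfg20, tau = 840L)
  expect_false(out2$detected)
  expect_true(out2$preShiftSignal)
  expect_true(is.na(out2$delay))
})

test_that("post-shift signal opportunities per aggregation level", {
  # ends in (tau, 860] among monitored points (index >= 41)
  opportunities <- function(W, tau) {
    ends <- seq_len(860 / W) * W
    monitored <- ends[seq_len(860 / W) >= 41]
    sum(monitored > tau & monitored <= 860)
  }
  expect_equal(opportunities(1, 840), 20)
  expect_equal(opportunities(2, 840), 10)
  expect_equal(opportunities(5, 840), 4)
  expect_equal(opportunities(10, 840), 2)
  for (tau in c(840, 845, 859)) expect_equal(opportunities(20, tau), 1)
})

test_that("replications are allocated equally over shift offsets", {
  cfg <- scenarioConfig(nNodes = 10L, communitySizes = c(5L, 5L),
                        runLength = 220L, aggregationLevel = 5L,
                        replications = 23L, shiftFraction = 0)
  est <- detectionRate(cfg)
  tab <- table(est$outcomes$shiftTime)
  expect_equal(sort(names(tab)), as.character(200:204))
  expect_lte(diff(range(tab)), 1)
})

test_that("runs are reproducible from (seed, run index) alone", {
  cfg <- shortConfig(baselineDiag = 1, shiftFraction = 2,
                     aggregationLevel = 2L, seed = 99L)
  a <- runSingle(cfg, runIndex = 7L)
  b <- runSingle(cfg, runIndex = 7L)
  expect_identical(a, b)
  # the harness loop uses the same streams as the one-off entry point
  est <- detectionRate(cfg)
  row7 <- est$outcomes[7, ]
  rownames(row7) <- NULL
  expect_identical(row7, a)
  # and does not disturb the caller's RNG
  set.seed(1); before <- .Random.seed
  invisible(runSingle(cfg, runIndex = 2L))
  expect_identical(.Random.seed, before)
  # derived streams differ across run indices
  expect_false(identical(runStream(99L, 1L), runStream(99L, 2L)))
  expect_identical(runStream(99L, 3L), runStream(99L, 3L))
})

test_that("zero shift fraction makes detection the false alarm rate", {
  cfg <- shortConfig(baselineDiag = 1, shiftFraction = 0,
                     aggregationLevel = 1L, replications = 30L, seed = 3L)
  det <- detectionRate(cfg)
  far <- falseAlarmRate(cfg)
  expect_identical(det$outcomes, far$outcomes)
  expect_equal(det$rate, far$rate)
})

test_that("detection rate is monotone in the shift magnitude", {
  rates <- sapply(c(0.25, 5), function(s) {
    cfg <- scenarioConfig(nNodes = 10L, communitySizes = c(5L, 5L),
                          runLength = 220L, baselineDiag = 1,
                          shiftFraction = s, shiftTimes = 200L,
                          aggregationLevel = 5L, replications = 40L,
                          seed = 8L)
    detectionRate(cfg)$rate
  })
  se <- sqrt(0.25 / 40)
  expect_gte(rates[2], rates[1] - 2 * se)
  expect_gt(rates[2], 0.8)   # a 6x rate jump is essentially always caught
})

test_that("moderate aggregation beats no aggregation (W = 5 vs W = 1)", {
  rates <- sapply(c(1L, 5L), function(W) {
    cfg <- scenarioConfig(baselineDiag = 1, shiftFraction = 0.5,
                          aggregationLevel = W, replications = 100L,
                          seed = 61L)
    detectionRate(cfg)$rate
  })
  se <- sqrt(0.25 / 100)
  expect_gt(rates[2], rates[1] + 2 * se)
})

test_that("detection degrades for late shifts within a W = 20 period", {
  cfg <- scenarioConfig(baselineDiag = 1, shiftFraction = 1.5,
                        aggregationLevel = 20L, replications = 30L,
                        seed = 12L)
  prof <- shiftOffsetProfile(cfg, offsets = c(840L, 851L, 859L))
  expect_equal(prof$positionInPeriod, c(1L, 12L, 20L))
  # early and mid offsets detected essentially always; the last offset
  # leaves one anomalous matrix in the block and detection collapses
  expect_gt(prof$rate[1], 0.9)
  expect_gte(prof$rate[2], prof$rate[3])
  expect_lt(prof$rate[3], prof$rate[1])
})

test_that("conditional delays are collected only over detected runs", {
  cfg <- scenarioConfig(nNodes = 10L, communitySizes = c(5L, 5L),
                        runLength = 200L, baselineDiag = 1,
                        shiftFraction = 4, shiftTimes = 180L,
                        aggregationLevel = 1L, replications = 25L, seed = 14L)
  cd <- conditionalDelayDistribution(cfg)
  expect_equal(length(cd$delays), sum(cd$outcomes$detected))
  expect_true(all(cd$delays >= 0))
  # an abrupt 5x shift at W = 1 is caught essentially immediately
  expect_lte(cd$median, 1)
  expect_equal(sum(cd$histogram), length(cd$delays))
})

test_that("scenario sweeps are order-independent and record cell errors", {
  cfgA <- shortConfig(baselineDiag = 1, shiftFraction = 1,
                      aggregationLevel = 2L, replications = 10L, seed = 5L)
  cfgB <- shortConfig(baselineDiag = 0.5, shiftFraction = 2,
                      aggregationLevel = 1L, replications = 10L, seed = 5L)
  tab1 <- sweepScenarios(list(cfgA, cfgB))
  tab2 <- sweepScenarios(list(cfgA, cfgB))
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 2L)
  expect_true(all(is.na(tab1$error)))
  expect_true(all(tab1$detection_rate >= 0 & tab1$detection_rate <= 1))
  # single-cell grid
  expect_equal(nrow(sweepScenarios(list(cfgA))), 1L)
  # a cell whose aggregated length cannot host two windows fails in place
  cfgBad <- shortConfig(aggregationLevel = 10L)  # 10 points < 41
  tab3 <- sweepScenarios(list(cfgA, cfgBad))
  expect_true(is.na(tab3$detection_rate[2]))
  expect_match(tab3$error[2], "41")
  expect_false(is.na(tab3$detection_rate[1]))
})

test_that("shared-draw level comparison is reproducible and sane", {
  cfg <- scenarioConfig(baselineDiag = 1, shiftFraction = 3,
                        replications = 15L, seed = 20L)
  cmp1 <- compareAggregationLevels(cfg, levels = c(1L, 4L, 20L))
  cmp2 <- compareAggregationLevels(cfg, levels = c(1L, 4L, 20L))
  expect_identical(cmp1, cmp2)
  expect_equal(cmp1$aggregationLevel, c(1L, 4L, 20L))
  # a 4x sustained shift with a fully anomalous final block is always seen
  expect_true(all(cmp1$rate >= 0.8))
})
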