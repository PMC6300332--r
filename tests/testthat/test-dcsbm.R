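# DCSBM generator: degree propensities, block matrix, rates, sequences.

test_that("community structure validates sizes and membership", {
  cs <- communityStructure(c(10, 10))
  expect_equal(nNodes(cs), 20L)
  expect_equal(communitySizes(cs), c(10L, 10L))
  expect_equal(membership(cs), rep(1:2, each = 10))
  expect_error(communityStructure(c(10, 0)), "positive")
  expect_error(communityStructure(integer()), "positive")
})

test_that("Pareto draws follow the Type-I closed form", {
  set.seed(1)
  n <- 1e5
  x <- rparetoI(n, scale = 1, shape = 3)
  expect_true(all(x >= 1))
  # closed-form mean shape*m/(shape-1) = 1.5, sd of the mean as tolerance
  mcse <- sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - 1.5), 3 * mcse)
  # survival function at a few points: P(X > q) = q^(-shape)
  for (q in c(1.5, 2, 4))
    expect_lt(abs(mean(x > q) - q^-3), 4 * sqrt(q^-3 / n) + 1e-3)
  expect_error(rparetoI(1, scale = -1), "positive")
})

test_that("degree propensities are normalized per community", {
  cs <- communityStructure(c(10, 10))
  set.seed(42)
  for (r in 1:20) {
    th <- drawDegreePropensities(cs)
    sums <- tapply(theta(th), membership(cs), sum)
    expect_equal(as.vector(sums), c(10, 10), tolerance = 1e-9)
    expect_true(all(theta(th) > 0))
  }
  # unequal communities
  cs3 <- communityStructure(c(3, 7, 5))
  th3 <- drawDegreePropensities(cs3)
  expect_equal(as.vector(tapply(theta(th3), membership(cs3), sum)),
               c(3, 7, 5), tolerance = 1e-9)
})

test_that("equal raw draws normalize to uniform theta", {
  cs <- communityStructure(c(10, 10))
  # force constant raw draws through the normalizer
  raw <- rep(2.7, 20)
  th <- dynetscan:::.normalizeTheta(raw, cs)
  expect_equal(th, rep(1, 20))
})

test_that("propensity parameter validation and infinite-mean warning", {
  cs <- communityStructure(c(4, 4))
  expect_error(drawDegreePropensities(cs, paretoScale = 0), "positive")
  expect_error(drawDegreePropensities(cs, paretoShape = -2), "positive")
  expect_warning(drawDegreePropensities(cs, paretoShape = 0.9),
                 "infinite")
})

test_that("block propensity matrix has the homophily structure", {
  expect_equal(propensityMatrix(blockPropensity(0.2, 2, 2)),
               matrix(c(0.2, 0.1, 0.1, 0.2), 2))
  expect_equal(propensityMatrix(blockPropensity(1, 1, 3)),
               matrix(1, 3, 3))
  P4 <- propensityMatrix(blockPropensity(0.5, 2, 4))
  expect_equal(diag(P4), rep(0.5, 4))
  expect_equal(P4[upper.tri(P4)], rep(0.25, 6))
  expect_error(blockPropensity(-1, 2, 2), "positive")
  expect_error(blockPropensity(1, 0, 2), "positive")
})

test_that("applyShift scales only the target diagonal entry", {
  b <- blockPropensity(1, 2, 3)
  sh <- applyShift(b, shiftSpec(0.5, 840))
  expect_equal(propensityMatrix(sh)[1, 1], 1.5)
  expect_equal(propensityMatrix(sh)[-1, ], propensityMatrix(b)[-1, ])
  expect_equal(propensityMatrix(sh)[1, -1], propensityMatrix(b)[1, -1])
  # zero shift is the identity
  expect_equal(propensityMatrix(applyShift(b, shiftSpec(0, 840))),
               propensityMatrix(b))
  # fixed anomalous propensity implies s = P'/P0 - 1
  s <- 1.0 / 0.02 - 1
  sh2 <- applyShift(blockPropensity(0.02, 2, 2), shiftSpec(s, 840))
  expect_equal(propensityMatrix(sh2)[1, 1], 1.0)
  expect_error(applyShift(b, shiftSpec(1, 840, targetCommunity = 9)),
               "community")
})

test_that("rate matrix follows theta_i theta_j P and has zero diagonal", {
  cs <- communityStructure(c(10, 10))
  th <- new("DegreePropensity", theta = rep(1, 20), rawTheta = rep(1, 20),
            paretoScale = 1, paretoShape = 3, structure = cs)
  lam <- computeRates(th, blockPropensity(1, 2, 2))
  expect_equal(diag(lam), rep(0, 20))
  expect_true(isSymmetric(lam))
  expect_equal(lam[1, 2], 1)    # same community
  expect_equal(lam[1, 11], 0.5) # across communities
  # closed-form total: 2 * C(10,2) within-pairs at 1 plus 100 between at 0.5
  expect_equal(sum(lam[upper.tri(lam)]), 90 + 100 * 0.5)
  # heterogeneous theta enters multiplicatively
  set.seed(3)
  th2 <- drawDegreePropensities(cs)
  lam2 <- computeRates(th2, blockPropensity(1, 2, 2))
  expect_equal(lam2[1, 2], theta(th2)[1] * theta(th2)[2])
  expect_equal(diag(lam2), rep(0, 20))
  # dimension mismatch errors
  expect_error(computeRates(th, blockPropensity(1, 2, 2),
                            communityStructure(c(5, 5))), "nodes")
  csR3 <- communityStructure(c(7, 7, 6))
  thR3 <- drawDegreePropensities(csR3)
  expect_error(computeRates(thR3, blockPropensity(1, 2, 2)), "communities")
})

test_that("all theta equal reduces the model to the ordinary SBM", {
  cs <- communityStructure(c(5, 5))
  th <- new("DegreePropensity", theta = rep(1, 10), rawTheta = rep(1, 10),
            paretoScale = 1, paretoShape = 3, structure = cs)
  lam <- computeRates(th, blockPropensity(0.7, 2, 2))
  within <- lam[1:5, 1:5][upper.tri(matrix(0, 5, 5))]
  between <- as.vector(lam[1:5, 6:10])
  expect_true(all(within == 0.7))
  expect_true(all(between == 0.35))
})

test_that("generated sequences are symmetric integer zero-diagonal counts", {
  cs <- communityStructure(c(5, 5))
  set.seed(7)
  th <- drawDegreePropensities(cs)
  x <- generateSequence(cs, th, blockPropensity(2, 2, 2),
                        shift = shiftSpec(1, 30), runLength = 50)
  expect_s4_class(x, "NetworkSequence")
  expect_equal(nSnapshots(x), 50L)
  expect_equal(dataType(x), "count")
  a <- x@counts
  expect_true(all(a >= 0))
  expect_true(all(a == round(a)))
  expect_identical(a, aperm(a, c(2, 1, 3)))
  for (t in c(1, 25, 50)) expect_equal(diag(snapshot(x, t)), rep(0, 10))
  # object passes its own validity
  expect_true(validObject(networkSequence(a)))
})

test_that("zero rates give identically zero matrices", {
  x <- generateFromRates(matrix(0, 4, 4), 10)
  expect_true(all(x@counts == 0))
})

test_that("shift timing: matrices through tau are baseline, after anomalous", {
  # deterministic check via degenerate rates: baseline 0, shifted huge
  lam0 <- matrix(0, 4, 4)
  lam1 <- matrix(50, 4, 4); diag(lam1) <- 0
  set.seed(11)
  x <- generateFromRates(lam0, 860, shiftedRates = lam1, shiftTime = 845)
  tots <- apply(x@counts, 3, sum)
  expect_true(all(tots[1:845] == 0))
  expect_true(all(tots[846:860] > 0))
  # the final W=20 block mixes 5 baseline with 15 anomalous matrices
  lastBlock <- 841:860
  expect_equal(sum(tots[lastBlock] == 0), 5)
  expect_equal(sum(tots[lastBlock] > 0), 15)
  expect_error(generateFromRates(lam0, 10, shiftedRates = lam1,
                                 shiftTime = 11), "0..runLength")
})

test_that("shift locality: rates outside the target community unchanged", {
  cs <- communityStructure(c(10, 10))
  set.seed(5)
  th <- drawDegreePropensities(cs)
  b <- blockPropensity(1, 2, 2)
  lam0 <- computeRates(th, b)
  lam1 <- computeRates(th, applyShift(b, shiftSpec(1.5, 840)))
  inC1 <- membership(cs) == 1L
  expect_equal(lam1[!inC1, ], lam0[!inC1, ])
  expect_equal(lam1[, !inC1], lam0[, !inC1])
  expect_equal(lam1[inC1, inC1], lam0[inC1, inC1] * 2.5)
})

test_that("generated counts follow the Poisson law cell by cell", {
  cs <- communityStructure(c(10, 10))
  th <- new("DegreePropensity", theta = rep(1, 20), rawTheta = rep(1, 20),
            paretoScale = 1, paretoShape = 3, structure = cs)
  lam <- computeRates(th, blockPropensity(1, 2, 2))
  set.seed(13)
  x <- generateFromRates(lam, 2000)
  # total count across the upper triangle: mean ~ total rate 140
  ut <- upper.tri(lam)
  tots <- apply(x@counts, 3, function(m) sum(m[ut]))
  expect_lt(abs(mean(tots) - 140), 3 * sd(tots) / sqrt(2000))
  # per-cell mean and variance agree with lambda (4 MC SE)
  for (cell in list(c(1, 2), c(1, 11), c(15, 20))) {
    v <- x@counts[cell[1], cell[2], ]
    l <- lam[cell[1], cell[2]]
    expect_lt(abs(mean(v) - l), 4 * sqrt(l / 2000) + 1e-12)
    expect_lt(abs(var(v) - l), 4 * l * sqrt(2 / 1999) + 1e-12)
  }
})
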