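test_that("the noiseless stochastic step equals the deterministic step", {
  net <- buildCoreGRN()
  set.seed(5)
  for (code in sample(0:511, 10)) {
    bits <- decodeState(code, net)
    expect_identical(stochasticStep(net, bits, xi = 0), synchronousStep(net, bits))
  }
  expect_error(stochasticStep(net, decodeState(0, net), xi = 1.5), "xi")
})

test_that("xi = 1 forces disobedience on the one-node identity net", {
  one <- selfActivator()
  set.seed(1)
  expect_identical(unname(stochasticStep(one, c(A = 1L), xi = 1)), 0L)
  expect_identical(unname(stochasticStep(one, c(A = 0L), xi = 1)), 1L)
})

test_that("per-node flip frequency matches the nominal error probability", {
  net <- buildCoreGRN()
  epi <- phenotypeProfiles()["epithelial", ]
  det <- synchronousStep(net, epi)
  xi <- 0.05
  n_draws <- 20000
  set.seed(99)
  flips <- matrix(0L, n_draws, length(det))
  for (d in seq_len(n_draws))
    flips[d, ] <- as.integer(stochasticStep(net, epi, xi) != det)
  freq <- colMeans(flips)
  se <- sqrt(xi * (1 - xi) / n_draws)
  expect_true(all(abs(freq - xi) < 3 * se + 1e-12))
})

test_that("the exact one-step operator has its closed forms", {
  one <- selfActivator()
  P <- exactOneStepOperator(one, 0.05)
  expect_equal(unname(P), rbind(c(0.95, 0.05), c(0.05, 0.95)))

  # xi = 0 reduces to the permutation matrix of the deterministic map
  net <- toggleNet()
  P0 <- exactOneStepOperator(net, 0)
  succ <- successorTable(net)
  for (s in seq_along(succ))
    expect_identical(unname(P0[s, as.character(succ[s])]), 1)
  expect_true(all(rowSums(P0) == 1))
})

test_that("transition-matrix estimation is exact at xi = 0 and matches closed forms", {
  net <- buildCoreGRN()
  tm0 <- estimateTransitionMatrix(net, xi = 0, reps = 10, seed = 1)
  expect_equal(unname(transitionProbabilities(tm0)), diag(3))

  one <- selfActivator()
  tm <- estimateTransitionMatrix(one, xi = 0.1, reps = 20000, seed = 2)
  p <- transitionProbabilities(tm)
  se <- sqrt(0.1 * 0.9 / 20000)
  expect_true(all(abs(p - rbind(c(0.9, 0.1), c(0.1, 0.9))) < 4 * se))
})

test_that("Monte-Carlo transition estimates converge to the basin-aggregated operator", {
  net <- buildCoreGRN()
  bp <- basinPartition(net)
  bp@attractors <- labelAttractors(bp@attractors)
  xi <- 0.05
  reps <- 4000
  tm <- estimateTransitionMatrix(net, xi, reps = reps, basins = bp, seed = 31)
  ex <- aggregateByBasins(exactOneStepOperator(net, xi), bp)
  pe <- transitionProbabilities(ex)
  pm <- transitionProbabilities(tm)
  nPooled <- reps * basinCounts(bp)       # draws pooled per row
  for (i in 1:3) {
    se <- sqrt(pe[i, ] * (1 - pe[i, ]) / nPooled[i])
    expect_true(all(abs(pm[i, ] - pe[i, ]) <= 3 * se + 1e-12),
                label = sprintf("row %d within 3 binomial SEs", i))
  }
  expect_equal(unname(rowSums(pm)), rep(1, 3), tolerance = 1e-12)
})

test_that("distribution iteration follows the Markov recursion", {
  expect_equal(iterateDistribution(diag(2), c(0.3, 0.7), 5)[6, ], c(0.3, 0.7))
  swap <- rbind(c(0, 1), c(1, 0))
  tr <- iterateDistribution(swap, c(1, 0), 3)
  expect_equal(tr[, 1], c(1, 0, 1, 0))
  expect_error(iterateDistribution(diag(2), c(0.5, 0.6), 2), "sum")
  expect_error(iterateDistribution(rbind(c(0.5, 0.4), c(0, 1)), c(1, 0), 2),
               "stochastic")
})

test_that("temporal attainment handles identity and planted-flow chains", {
  ta <- temporalAttainment(diag(3), c(0, 0, 1), 10)
  expect_identical(ta$sequence, 3L)

  ch <- randomChain(3, flowStrength = 0.95, seed = 8)
  ta2 <- temporalAttainment(ch$pi, c(1, 0, 0), 60)
  expect_identical(ta2$sequence, c(1L, 2L, 3L))
  expect_identical(ta2$peakOrder, c(1L, 2L, 3L))
})

test_that("two-state MFPT matches the geometric closed form", {
  p <- 0.2
  pi <- rbind(c(1 - p, p), c(0.3, 0.7))
  m <- mfptAnalytic(pi)
  expect_equal(m[1, 2], 1 / p)
  sim <- mfptSimulate(pi, nPaths = 20000, maxSteps = 10000, seed = 4)
  se <- sqrt((1 - p) / p^2 / 20000)       # sd of geometric / sqrt(n)
  expect_lt(abs(sim$mfpt[1, 2] - 1 / p), 3 * se)
})

test_that("simulated MFPT agrees with the fundamental-matrix solve on random chains", {
  for (seed in 1:4) {
    ch <- randomChain(3, flowStrength = 0.3, seed = 20 + seed)
    ana <- mfptAnalytic(ch$pi)
    sim <- mfptSimulate(ch$pi, nPaths = 4000, maxSteps = 50000, seed = seed)
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      # conservative scale for the path-mean standard error
      se <- ana[i, j] / sqrt(4000)
      expect_lt(abs(sim$mfpt[i, j] - ana[i, j]), 5 * se + 1e-9)
    }
  }
})

test_that("unreachable targets are censored, not an exception", {
  pi <- rbind(c(1, 0), c(0.5, 0.5))       # state 2 unreachable from state 1
  sim <- mfptSimulate(pi, nPaths = 200, maxSteps = 50, seed = 3)
  expect_identical(sim$mfpt[1, 2], Inf)
  expect_identical(sim$censored[1, 2], 200L)
  ls <- netRatesAndOrdering(sim)
  expect_s4_class(ls, "LandscapeSummary")
})

test_that("net rates are antisymmetric and orderings behave at the extremes", {
  ch <- randomChain(3, flowStrength = 0.9, seed = 12)
  ls <- netRatesAndOrdering(mfptAnalytic(ch$pi))
  expect_equal(ls@d, -t(ls@d))
  expect_identical(ls@ordering, c(1L, 2L, 3L))    # planted path recovered

  # symmetric chain: all net rates vanish, no strict ordering exists
  sym <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8))
  ls2 <- netRatesAndOrdering(mfptAnalytic(sym))
  expect_equal(max(abs(ls2@d)), 0)
  expect_length(ls2@ordering, 0L)
})

test_that("state-level MFPT variant runs and respects basin structure", {
  net <- buildCoreGRN()
  bp <- basinPartition(net)
  bp@attractors <- labelAttractors(bp@attractors)
  sim <- mfptSimulate(NULL, nPaths = 200, maxSteps = 2000, seed = 9,
                      stateLevel = list(net = net, xi = 0.1, basins = bp))
  expect_true(all(is.finite(sim$mfpt[upper.tri(sim$mfpt) | lower.tri(sim$mfpt)])))
  expect_true(all(diag(sim$mfpt) == 0))
})
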