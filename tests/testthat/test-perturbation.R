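test_that("simulateMutant agrees bit-for-bit with clamp + basinPartition", {
  net <- buildCoreGRN()
  rep <- simulateMutant(net, "Snai2", "gain")
  direct <- basinPartition(clampNode(net, "Snai2", 1))
  expect_identical(rep@basins@assignment, direct@assignment)
  expect_identical(rep@basins@states, direct@states)
  expect_identical(canonicalCycles(rep@attractors), canonicalCycles(direct@attractors))
  expect_error(simulateMutant(net, "nosuch", "loss"), "unknown node")
})

test_that("mutant basins partition the clamped subspace exactly", {
  net <- buildCoreGRN()
  for (nm in c("ESE2", "p16")) for (mode in c("loss", "gain")) {
    rep <- simulateMutant(net, nm, mode)
    expect_identical(sum(basinCounts(rep@basins)), 256L)
    expect_equal(sum(basinPercentages(rep@basins)), 100, tolerance = 1e-4)
  }
})

test_that("the six-mutant panel reproduces the reference attractor repertoire", {
  panel <- mutantPanel()
  counts <- vapply(panel, function(r) nAttractors(r@attractors), 0L)
  expect_identical(unname(counts), c(1L, 3L, 2L, 1L, 2L, 2L))

  labOf <- function(r) attractorLabels(r@attractors)
  # ESE-2 loss: single mesenchymal attractor with Snai2 on
  expect_identical(labOf(panel$ESE2_loss), "mesenchymal")
  a <- decodeState(attractorCycles(panel$ESE2_loss@attractors)[[1]],
                   buildCoreGRN())
  expect_identical(a[["Snai2"]], 1L)
  # Snai2 loss: normal and senescent epithelial phenotypes
  expect_setequal(labOf(panel$Snai2_loss), c("epithelial", "senescent"))
  # Snai2 gain: single mesenchymal attractor
  expect_identical(labOf(panel$Snai2_gain), "mesenchymal")
  # p16 loss: epithelial and mesenchymal
  expect_setequal(labOf(panel$p16_loss), c("epithelial", "mesenchymal"))
  # p16 gain: a senescent attractor plus a mesenchymal-like state lacking p53
  labs6 <- labOf(panel$p16_gain)
  expect_true("senescent" %in% labs6 || any(grepl("senescent", labs6)))
  other <- which(!grepl("senescent", labs6))
  bits <- decodeState(attractorCycles(panel$p16_gain@attractors)[[other]],
                      buildCoreGRN())
  expect_identical(bits[["Snai2"]], 1L)   # mesenchymal marker on
  expect_identical(bits[["p53"]], 0L)     # incompletely senescent: no p53
  # ESE-2 gain: three attractors, one a hybrid with epithelial and
  # mesenchymal markers co-active
  labs2 <- labOf(panel$ESE2_gain)
  expect_true("epithelial" %in% labs2)
  expect_true("senescent" %in% labs2)
  hybrid <- which(!labs2 %in% c("epithelial", "senescent"))
  expect_length(hybrid, 1L)
  hb <- decodeState(attractorCycles(panel$ESE2_gain@attractors)[[hybrid]],
                    buildCoreGRN())
  expect_identical(hb[["ESE2"]], 1L)      # epithelial marker
  expect_identical(hb[["Snai2"]], 1L)     # mesenchymal marker
})

test_that("panel CSV export writes one file per mutant plus a summary", {
  dir <- withr::local_tempdir()
  summary <- writeMutantPanel(mutantPanel(), dir)
  expect_identical(nrow(summary), 6L)
  expect_true(all(file.exists(file.path(dir, paste0(summary$mutant, ".csv")))))
  expect_true(file.exists(file.path(dir, "panel_summary.csv")))
})

test_that("flipping a fixed point's own table row destroys that attractor", {
  net <- buildCoreGRN()
  wt <- findAttractors(net)
  fp <- attractorCycles(wt)[[1]][1]
  bits <- decodeState(fp, net)
  # flip the output row of the first node's rule addressed by this state
  nd <- networkNodes(net)[1]
  tt <- networkRules(net)[[nd]]
  idx <- 0L
  for (r in tt@regulators) idx <- idx * 2L + bits[[r]]
  outs <- tt@outputs
  outs[idx + 1L] <- 1L - outs[idx + 1L]
  rules <- networkRules(net)
  rules[[nd]] <- TruthTable(tt@regulators, outs)
  pert <- BooleanNetwork(rules, networkNodes(net))
  expect_false(fp %in% unlist(attractorCycles(findAttractors(pert))))
})

test_that("logic robustness reports persistence fractions", {
  net <- buildCoreGRN()
  rob <- logicRobustness(net, nPerturbations = 60, seed = 17)
  expect_identical(rob$mode, "sampled")
  expect_identical(rob$nPerturbations, 60L)
  expect_true(rob$fraction >= 0 && rob$fraction <= 1)
  expect_length(rob$perAttractor, 3L)
  expect_true(all(rob$perAttractor >= rob$fraction - 1e-12))
  # reproducibility under a fixed seed
  rob2 <- logicRobustness(net, nPerturbations = 60, seed = 17)
  expect_identical(rob$fraction, rob2$fraction)
})

test_that("a network is fully robust to zero-effect perturbation sets", {
  # control: a perturbed network in which the flipped bit is flipped back
  # is the wild type, so persistence over it is exactly 1
  net <- buildCoreGRN()
  wt <- findAttractors(net)
  succ <- successorTable(net)
  fps <- unlist(attractorCycles(wt))
  expect_true(all(succ[as.character(fps)] == fps))
})
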