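test_that("mediator collapse composes signs correctly", {
  g <- SignedDigraph(data.frame(from = c("A", "B"), to = c("B", "C"),
                                sign = c(1, -1)))
  r <- reduceDigraph(g, keep = c("A", "C"))
  expect_identical(r@nodes, c("A", "C"))
  expect_identical(nrow(r@edges), 1L)
  expect_identical(r@edges$sign, -1)

  g2 <- SignedDigraph(data.frame(from = c("A", "B"), to = c("B", "C"),
                                 sign = c(-1, -1)))
  r2 <- reduceDigraph(g2, keep = c("A", "C"))
  expect_identical(r2@edges$sign, 1)      # minus times minus
})

test_that("source nodes outside keep are deleted with their out-edges", {
  g <- SignedDigraph(data.frame(from = c("S", "A", "B"),
                                to = c("A", "B", "A"),
                                sign = c(1, 1, -1)))
  r <- reduceDigraph(g, keep = c("A", "B"))
  expect_setequal(r@nodes, c("A", "B"))
  expect_identical(nrow(r@edges), 2L)
})

test_that("digraph reduction is idempotent and order independent", {
  for (seed in 1:6) {
    g <- randomSignedDigraph(12, 20, seed = seed)
    keep <- g@nodes[1:4]
    r1 <- reduceDigraph(g, keep)
    r2 <- reduceDigraph(r1, keep)        # idempotence
    expect_identical(sort(r1@nodes), sort(r2@nodes))
    key <- function(x) sort(paste(x@edges$from, x@edges$to, x@edges$sign))
    expect_identical(key(r1), key(r2))
    # removal-order independence: reduce a node-permuted copy
    perm <- sample(g@nodes)
    gp <- SignedDigraph(g@edges, perm)
    rp <- reduceDigraph(gp, keep)
    expect_identical(sort(r1@nodes), sort(rp@nodes))
    expect_identical(key(r1), key(rp))
  }
})

test_that("opposite-sign parallel edges are retained and flagged", {
  # A -> B -> C (+,+) and A -> D -> C (+,-) compose to parallel A->C edges
  g <- SignedDigraph(data.frame(from = c("A", "B", "A", "D"),
                                to = c("B", "C", "D", "C"),
                                sign = c(1, 1, 1, -1)))
  r <- reduceDigraph(g, keep = c("A", "C"))
  ac <- r@edges[r@edges$from == "A" & r@edges$to == "C", ]
  expect_identical(nrow(ac), 2L)
  expect_setequal(ac$sign, c(1, -1))
  expect_true(all(ac$flagged))
})

test_that("boolean chain reduction preserves fixed points under projection", {
  # A = A, B = A, C = B reduces (keep A, C) to A = A, C = A
  net <- BooleanNetwork(list(
    A = TruthTable("A", c(0L, 1L)),
    B = TruthTable("A", c(0L, 1L)),
    C = TruthTable("B", c(0L, 1L))))
  red <- reduceBoolean(net, keep = c("A", "C"))
  expect_setequal(networkNodes(red), c("A", "C"))
  fps <- sort(unlist(attractorCycles(findAttractors(red))))
  expect_identical(fps, c(0L, 3L))        # (0,0) and (1,1)

  # mediator with negation: B = !A, C = B gives C = !A
  net2 <- BooleanNetwork(list(
    A = TruthTable("A", c(0L, 1L)),
    B = TruthTable("A", c(1L, 0L)),
    C = TruthTable("B", c(0L, 1L))))
  red2 <- reduceBoolean(net2, keep = c("A", "C"))
  ctt <- networkRules(red2)[["C"]]
  expect_identical(ctt@regulators, "A")
  expect_identical(ctt@outputs, c(1L, 0L))
})

test_that("constant sources are substituted into their targets", {
  net <- BooleanNetwork(list(
    S = TruthTable(character(), 1L),
    A = expressionToTruthTable("S & B"),
    B = TruthTable("B", c(0L, 1L))))
  red <- reduceBoolean(net, keep = c("A", "B"))
  expect_setequal(networkNodes(red), c("A", "B"))
  att <- networkRules(red)[["A"]]
  expect_identical(sort(att@regulators), "B")   # S & B with S = 1 is B
  expect_identical(att@outputs, c(0L, 1L))
})

test_that("fixed points are preserved on random mediator-bearing fixtures", {
  checked <- 0
  for (seed in 1:40) {
    fx <- randomBooleanNetwork(7, maxInDegree = 2, seed = 400 + seed)
    net <- fx$network
    keep <- networkNodes(net)[1:3]
    red <- reduceBoolean(net, keep)
    if (length(networkNodes(red)) == length(networkNodes(net))) next
    checked <- checked + 1
    cycles <- attractorCycles(findAttractors(net))
    fullFps <- as.integer(unlist(cycles[lengths(cycles) == 1L]))
    redCyc <- attractorCycles(findAttractors(red))
    redFps <- as.integer(sort(unlist(redCyc[lengths(redCyc) == 1L])))
    # project the original fixed points onto the kept nodes
    nOld <- length(networkNodes(net))
    kept <- match(networkNodes(red), networkNodes(net))
    project <- function(code) {
      bits <- bitwAnd(bitwShiftR(code, (nOld - 1):0), 1L)
      s <- 0L
      for (b in bits[kept]) s <- s * 2L + b
      s
    }
    projected <- as.integer(sort(unique(vapply(fullFps, project, integer(1)))))
    expect_identical(redFps, projected,
                     label = sprintf("seed %d projection", 400 + seed))
    expect_identical(length(projected), length(fullFps),
                     label = sprintf("seed %d bijection", 400 + seed))
  }
  expect_gte(checked, 10)
})
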