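# Independent brute-force oracles, implemented state by state with explicit
# loops and independent cycle extraction, so the vectorized engine is
# checked against a structurally different computation.

# successor of one state (0/1 vector) by direct rule lookup, row by row
oracleStep <- function(net, bits) {
  nodes <- networkNodes(net)
  rules <- networkRules(net)
  clamps <- networkClamps(net)
  out <- integer(length(nodes))
  names(out) <- nodes
  for (nd in nodes) {
    if (nd %in% names(clamps)) { out[nd] <- clamps[[nd]]; next }
    tt <- rules[[nd]]
    idx <- 0L
    for (r in tt@regulators) idx <- idx * 2L + bits[[r]]
    out[nd] <- tt@outputs[idx + 1L]
  }
  out
}

oracleCodeOf <- function(bits) {
  s <- 0
  for (b in bits) s <- s * 2 + b
  as.integer(s)
}

oracleBitsOf <- function(code, n) {
  bits <- integer(n)
  for (i in n:1) { bits[i] <- code %% 2L; code <- code %/% 2L }
  bits
}

# full successor map over the clamp-consistent subspace
oracleSuccessorMap <- function(net) {
  nodes <- networkNodes(net)
  n <- length(nodes)
  clamps <- networkClamps(net)
  codes <- integer(0)
  succ <- integer(0)
  for (code in 0:(2^n - 1)) {
    bits <- oracleBitsOf(code, n)
    names(bits) <- nodes
    okay <- TRUE
    for (nd in names(clamps)) if (bits[[nd]] != clamps[[nd]]) okay <- FALSE
    if (!okay) next
    codes <- c(codes, code)
    succ <- c(succ, oracleCodeOf(oracleStep(net, bits)))
  }
  names(succ) <- codes
  succ
}

# cycles of the successor map, found by walking each state with a visited
# list; returns a sorted list of canonicalized cycles (start at min code)
oracleCycles <- function(succ) {
  codes <- as.integer(names(succ))
  lookup <- function(code) succ[[as.character(code)]]
  cycles <- list()
  seen_cycle_states <- integer(0)
  for (start in codes) {
    path <- integer(0)
    cur <- start
    while (!(cur %in% path)) {
      path <- c(path, cur)
      cur <- lookup(cur)
    }
    cyc <- path[which(path == cur):length(path)]
    if (cyc[1] %in% seen_cycle_states) next
    s <- which.min(cyc)
    cyc <- c(cyc[s:length(cyc)], if (s > 1) cyc[1:(s - 1)])
    if (!cyc[1] %in% seen_cycle_states) {
      cycles[[length(cycles) + 1L]] <- cyc
      seen_cycle_states <- c(seen_cycle_states, cyc)
    }
  }
  cycles[order(vapply(cycles, min, integer(1)))]
}

# basin assignment (attractor index per explored state) from the oracle map
oracleBasinAssignment <- function(succ, cycles) {
  codes <- as.integer(names(succ))
  cyc_index <- integer(0)
  for (i in seq_along(cycles))
    cyc_index[as.character(cycles[[i]])] <- i
  assign <- integer(length(codes))
  for (k in seq_along(codes)) {
    cur <- codes[k]
    while (is.na(cyc_index[as.character(cur)]))
      cur <- succ[[as.character(cur)]]
    assign[k] <- cyc_index[as.character(cur)]
  }
  assign
}

# canonical comparable form of an AttractorSet
canonicalCycles <- function(attrs) {
  cyc <- attractorCycles(attrs)
  cyc[order(vapply(cyc, min, integer(1)))]
}

# small named constructors used across tests
toggleNet <- function() {
  BooleanNetwork(list(
    A = expressionToTruthTable("!B"),
    B = expressionToTruthTable("!A")), c("A", "B"))
}

selfActivator <- function() {
  BooleanNetwork(list(A = TruthTable("A", c(0L, 1L))), "A")
}
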