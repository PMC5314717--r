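#' Create a truth table
#'
#' @param regulators character vector of regulator names (may be empty for a
#'   constant node).
#' @param outputs vector coercible to 0/1 integers of length
#'   \code{2^length(regulators)}, indexed by the regulator configuration read
#'   as an unsigned integer with the first regulator as the most significant
#'   bit.
#' @return a \code{\link{TruthTable}}.
#' @examples
#' TruthTable(c("a", "b"), c(0, 0, 0, 1))  # a AND b
#' @export
TruthTable <- function(regulators = character(), outputs) {
  new("TruthTable", regulators = as.character(regulators),
      outputs = as.integer(outputs))
}

#' Create a Boolean network
#'
#' @param rules named list of \code{\link{TruthTable}} objects; names define
#'   node identity and, through \code{nodes}, bit order.
#' @param nodes optional character vector fixing the node order (defaults to
#'   \code{names(rules)}).
#' @param clamps optional named vector of 0/1 values holding nodes fixed.
#' @return a \code{\link{BooleanNetwork}}.
#' @export
BooleanNetwork <- function(rules, nodes = names(rules), clamps = integer()) {
  cl <- as.integer(clamps)
  names(cl) <- names(clamps)
  new("BooleanNetwork", nodes = as.character(nodes), rules = rules, clamps = cl)
}

#' @describeIn BooleanNetwork node names in canonical (bit) order
#' @param x,object a \code{BooleanNetwork}
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @export
setMethod("networkNodes", "BooleanNetwork", function(x) x@nodes)

#' @describeIn BooleanNetwork list of per-node truth tables
#' @export
setGeneric("networkRules", function(x) standardGeneric("networkRules"))

#' @export
setMethod("networkRules", "BooleanNetwork", function(x) x@rules)

#' @describeIn BooleanNetwork named vector of clamped nodes
#' @export
setGeneric("networkClamps", function(x) standardGeneric("networkClamps"))

#' @export
setMethod("networkClamps", "BooleanNetwork", function(x) x@clamps)

setMethod("show", "BooleanNetwork", function(object) {
  cat(sprintf("BooleanNetwork with %d nodes\n", length(object@nodes)))
  cat("  nodes:", paste(object@nodes, collapse = ", "), "\n")
  if (length(object@clamps))
    cat("  clamps:", paste(sprintf("%s=%d", names(object@clamps), object@clamps),
                           collapse = ", "), "\n")
  for (nd in object@nodes) {
    tt <- object@rules[[nd]]
    cat(sprintf("  %s <- %s\n", nd, truthTableToExpression(tt)))
  }
  invisible(NULL)
})

## ---- state coding -------------------------------------------------------
## Node 1 is the most significant bit; the bijection between the integer
## code in [0, 2^n) and the 0/1 vector is fixed for all serialized output.

#' Encode a 0/1 state vector as an integer code
#'
#' Node 1 of the network is the most significant bit, so for node order
#' (A, B, C) the state A=1, B=0, C=1 has code 5.
#'
#' @param bits 0/1 vector aligned to the node order (a named vector is
#'   re-ordered by name).
#' @param net the \code{\link{BooleanNetwork}} fixing node order.
#' @return integer state code in \code{[0, 2^n)}.
#' @export
encodeState <- function(bits, net) {
  nd <- net@nodes
  if (!is.null(names(bits))) {
    if (!setequal(names(bits), nd)) stop("state names do not match network nodes")
    bits <- bits[nd]
  }
  if (length(bits) != length(nd)) stop("state length does not match network size")
  as.integer(sum(as.integer(bits) * 2^(length(nd) - seq_along(nd))))
}

#' Decode an integer state code into a named 0/1 vector
#'
#' @param code integer state code.
#' @param net the \code{\link{BooleanNetwork}} fixing node order.
#' @return named integer vector of 0/1 values.
#' @export
decodeState <- function(code, net) {
  n <- length(net@nodes)
  bits <- as.integer(bitwAnd(bitwShiftR(as.integer(code), (n - 1):0), 1L))
  names(bits) <- net@nodes
  bits
}

## internal: matrix of all explored states (rows) x nodes (cols).
## With clamps, only clamp-consistent codes are generated.
stateMatrix <- function(net) {
  n <- length(net@nodes)
  if (n > 24) stop("exhaustive enumeration is guarded at n <= 24 nodes")
  codes <- exploredCodes(net)
  bits <- matrix(0L, length(codes), n, dimnames = list(NULL, net@nodes))
  for (i in seq_len(n))
    bits[, i] <- bitwAnd(bitwShiftR(codes, n - i), 1L)
  list(codes = codes, bits = bits)
}

## internal: codes of the explored (clamp-consistent) subspace, increasing
exploredCodes <- function(net) {
  n <- length(net@nodes)
  codes <- 0:(2^n - 1)
  if (length(net@clamps)) {
    for (nd in names(net@clamps)) {
      i <- match(nd, net@nodes)
      keep <- bitwAnd(bitwShiftR(codes, n - i), 1L) == net@clamps[[nd]]
      codes <- codes[keep]
    }
  }
  as.integer(codes)
}

## internal: evaluate one node's truth table over a state bit matrix
evalRuleOnBits <- function(tt, bits) {
  k <- length(tt@regulators)
  if (k == 0L) return(rep(tt@outputs, nrow(bits)))
  idx <- integer(nrow(bits))
  for (r in tt@regulators) idx <- idx * 2L + bits[, r]
  tt@outputs[idx + 1L]
}

#' Full synchronous successor table
#'
#' Computes, for every clamp-consistent state code, the code of its
#' synchronous successor (clamped nodes keep their clamp value). This is the
#' engine primitive behind attractor enumeration and basin partitioning.
#'
#' @param net a \code{\link{BooleanNetwork}} with at most 24 nodes.
#' @return named integer vector: names are the explored state codes, values
#'   the successor codes.
#' @export
successorTable <- function(net) {
  sm <- stateMatrix(net)
  n <- length(net@nodes)
  succ <- integer(length(sm$codes))
  for (i in seq_len(n)) {
    nd <- net@nodes[i]
    out <- if (nd %in% names(net@clamps))
      rep(net@clamps[[nd]], length(sm$codes))
    else
      evalRuleOnBits(net@rules[[nd]], sm$bits)
    succ <- succ + out * 2L^(n - i)
  }
  names(succ) <- sm$codes
  succ
}

#' One synchronous update step
#'
#' Applies every node's truth table to the regulator values in \code{state}
#' simultaneously; clamped nodes keep their clamp value. The input state must
#' respect the clamps.
#'
#' @param net a \code{\link{BooleanNetwork}}.
#' @param state 0/1 vector aligned to (or named by) the node order, or a
#'   single integer state code.
#' @return the successor state in the same form as the input (vector in,
#'   vector out; code in, code out).
#' @export
synchronousStep <- function(net, state) {
  as_code <- length(state) == 1L && is.numeric(state) && length(net@nodes) > 1L
  bits <- if (as_code) decodeState(state, net) else {
    if (length(state) != length(net@nodes))
      stop("state length does not match network size")
    b <- as.integer(state)
    names(b) <- if (is.null(names(state))) net@nodes else names(state)
    b[net@nodes]
  }
  for (nd in names(net@clamps))
    if (bits[[nd]] != net@clamps[[nd]])
      stop(sprintf("input state violates clamp on %s", nd))
  mat <- matrix(bits, 1, dimnames = list(NULL, net@nodes))
  out <- vapply(net@nodes, function(nd) {
    if (nd %in% names(net@clamps)) net@clamps[[nd]]
    else evalRuleOnBits(net@rules[[nd]], mat)
  }, integer(1))
  if (as_code) encodeState(out, net) else out
}

#' Exhaustive attractor enumeration
#'
#' Iterates every clamp-consistent state to its terminal cycle and returns
#' all distinct cycles. Under synchronous determinism every state reaches
#' exactly one cycle; fixed points are cycles of length one.
#'
#' @param net a \code{\link{BooleanNetwork}} with at most 24 nodes.
#' @return an \code{\link{AttractorSet}}; attractors are ordered by their
#'   smallest state code.
#' @export
findAttractors <- function(net) {
  attractorsFromSuccessor(successorTable(net), net@nodes)
}

## internal: shared by findAttractors and basinPartition
attractorsFromSuccessor <- function(succ, nodes) {
  codes <- as.integer(names(succ))
  pos <- match(succ, codes)                  # successor as index into codes
  ## pointer doubling: after k squarings pos = succ^(2^k); 2^k >= |space|
  k <- ceiling(log2(max(length(codes), 2)))
  term <- pos
  for (i in seq_len(k)) term <- term[term]
  ## terminal representatives lie on cycles; extract each cycle once
  reps <- unique(term)
  cycles <- list()
  seen <- integer(0)
  for (r in reps) {
    if (codes[r] %in% seen) next
    cyc <- r
    cur <- pos[r]
    while (cur != r) { cyc <- c(cyc, cur); cur <- pos[cur] }
    ## canonical rotation: start at smallest code
    s <- which.min(codes[cyc])
    cyc <- c(cyc[s:length(cyc)], if (s > 1) cyc[1:(s - 1)])
    cycles[[length(cycles) + 1L]] <- codes[cyc]
    seen <- c(seen, codes[cyc])
  }
  o <- order(vapply(cycles, min, integer(1)))
  cycles <- cycles[o]
  new("AttractorSet", cycles = cycles,
      labels = rep(NA_character_, length(cycles)),
      distances = rep(NA_integer_, length(cycles)), nodes = nodes)
}

#' @describeIn findAttractors number of attractors
#' @param x an \code{AttractorSet}
#' @export
setGeneric("nAttractors", function(x) standardGeneric("nAttractors"))

#' @export
setMethod("nAttractors", "AttractorSet", function(x) length(x@cycles))

#' @describeIn findAttractors list of attractor cycles (integer state codes)
#' @export
setGeneric("attractorCycles", function(x) standardGeneric("attractorCycles"))

#' @export
setMethod("attractorCycles", "AttractorSet", function(x) x@cycles)

#' @describeIn findAttractors labels (phenotype names) per attractor
#' @export
setGeneric("attractorLabels", function(x) standardGeneric("attractorLabels"))

#' @export
setMethod("attractorLabels", "AttractorSet", function(x) x@labels)

#' @describeIn findAttractors TRUE for every attractor that is a fixed point
#' @export
setGeneric("isFixedPoint", function(x) standardGeneric("isFixedPoint"))

#' @export
setMethod("isFixedPoint", "AttractorSet",
          function(x) lengths(x@cycles) == 1L)

setMethod("show", "AttractorSet", function(object) {
  cat(sprintf("AttractorSet: %d attractor(s) over nodes %s\n",
              length(object@cycles), paste(object@nodes, collapse = ",")))
  n <- length(object@nodes)
  for (i in seq_along(object@cycles)) {
    cyc <- object@cycles[[i]]
    bits <- paste(vapply(cyc, function(cd)
      paste(bitwAnd(bitwShiftR(cd, (n - 1):0), 1L), collapse = ""), ""),
      collapse = " -> ")
    lab <- if (is.na(object@labels[i])) "" else sprintf(" [%s]", object@labels[i])
    cat(sprintf("  A%d (len %d)%s: %s\n", i, length(cyc), lab, bits))
  }
  invisible(NULL)
})

#' Basin-of-attraction partition
#'
#' Assigns every clamp-consistent state to the attractor its deterministic
#' trajectory reaches (full forward iteration via the memoized successor
#' table; no sampling) and reports basin sizes as counts and as percentages
#' of the explored space, the latter rounded to two decimals in printed
#' output only.
#'
#' @param net a \code{\link{BooleanNetwork}} with at most 24 nodes.
#' @return a \code{\link{BasinPartition}}.
#' @export
basinPartition <- function(net) {
  succ <- successorTable(net)
  attrs <- attractorsFromSuccessor(succ, net@nodes)
  codes <- as.integer(names(succ))
  pos <- match(succ, codes)
  k <- ceiling(log2(max(length(codes), 2)))
  term <- pos
  for (i in seq_len(k)) term <- term[term]
  cyc_of <- integer(length(codes))          # attractor index per cycle state
  for (i in seq_along(attrs@cycles))
    cyc_of[match(attrs@cycles[[i]], codes)] <- i
  assignment <- cyc_of[term]
  counts <- tabulate(assignment, nbins = length(attrs@cycles))
  new("BasinPartition", attractors = attrs, assignment = assignment,
      states = codes, counts = as.integer(counts),
      percentages = 100 * counts / length(codes))
}

#' @describeIn basinPartition per-attractor basin state counts
#' @param x a \code{BasinPartition}
#' @export
setGeneric("basinCounts", function(x) standardGeneric("basinCounts"))

#' @export
setMethod("basinCounts", "BasinPartition", function(x) x@counts)

#' @describeIn basinPartition per-attractor basin percentages of the explored space
#' @export
setGeneric("basinPercentages", function(x) standardGeneric("basinPercentages"))

#' @export
setMethod("basinPercentages", "BasinPartition", function(x) x@percentages)

setMethod("show", "BasinPartition", function(object) {
  cat(sprintf("BasinPartition over %d states\n", length(object@states)))
  for (i in seq_along(object@counts)) {
    lab <- object@attractors@labels[i]
    cat(sprintf("  A%d%s: %d states (%.2f%%)\n", i,
                if (is.na(lab)) "" else sprintf(" [%s]", lab),
                object@counts[i], object@percentages[i]))
  }
  invisible(NULL)
})

#' Clamp a node to a fixed value
#'
#' Returns a network whose update holds \code{node} at \code{value}
#' regardless of its regulators; subsequent attractor and basin exploration
#' is restricted to the clamp-consistent subspace (\code{2^(n-1)} initial
#' configurations per clamped node).
#'
#' @param net a \code{\link{BooleanNetwork}}.
#' @param node node name.
#' @param value 0 or 1.
#' @return a new \code{\link{BooleanNetwork}} with the clamp added.
#' @export
clampNode <- function(net, node, value) {
  if (!node %in% net@nodes) stop(sprintf("unknown node: %s", node))
  value <- as.integer(value)
  if (!value %in% c(0L, 1L)) stop("clamp value must be 0 or 1")
  cl <- net@clamps
  cl[node] <- value
  BooleanNetwork(net@rules, net@nodes, cl)
}
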