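## Synthetic-data generation: random Boolean networks, random signed
## digraphs and random attractor-level chains with a planted dominant path,
## so that every pipeline stage is testable without external data.
##
## Fixture RNG is isolated from analysis RNG: generators seed a local RNG
## and restore the caller's state, so fixture identity never depends on
## analysis sampling.

#' Generate a random Boolean network
#'
#' Regulators are sampled without replacement per node; rules are drawn
#' from one of two families. \code{"random-table"} fills the truth table
#' with i.i.d. fair coin flips. \code{"sign-consistent-monotone"} assigns
#' each regulator an activating sign with probability
#' \code{activationFraction} and draws a random signed threshold function
#' (positive weights on signed literals), which is monotone increasing in
#' every activator and decreasing in every inhibitor.
#'
#' @param nNodes number of nodes (guarded at 16 for exhaustive-test use).
#' @param maxInDegree maximum regulators per node (actual in-degree is
#'   sampled uniformly from 0..maxInDegree).
#' @param activationFraction probability that a sampled edge activates.
#' @param family \code{"random-table"} or \code{"sign-consistent-monotone"}.
#' @param seed integer seed; the same spec and seed always give the
#'   identical network.
#' @return list with \code{network} (a \code{\link{BooleanNetwork}}),
#'   \code{signs} (data.frame from/to/sign for the monotone family, else
#'   \code{NULL}) and \code{spec} (the generating parameters).
#' @export
randomBooleanNetwork <- function(nNodes, maxInDegree = 3,
                                 activationFraction = 0.5,
                                 family = c("random-table",
                                            "sign-consistent-monotone"),
                                 seed = 1) {
  family <- match.arg(family)
  if (nNodes > 16) stop("fixture networks are guarded at 16 nodes")
  if (maxInDegree > nNodes) stop("in-degree cannot exceed node count")
  .withSeed(seed, {
    nodes <- sprintf("n%02d", seq_len(nNodes))
    rules <- list()
    signRows <- list()
    for (nd in nodes) {
      k <- sample.int(maxInDegree + 1L, 1) - 1L
      regs <- if (k) sample(nodes, k) else character()
      if (family == "random-table") {
        outs <- as.integer(stats::runif(2^k) < 0.5)
      } else {
        sg <- ifelse(stats::runif(k) < activationFraction, 1, -1)
        w <- stats::runif(max(k, 1))
        if (k == 0) {
          outs <- as.integer(stats::runif(1) < 0.5)
        } else {
          theta <- stats::runif(1, 0, sum(w))
          outs <- integer(2^k)
          for (row in 0:(2^k - 1)) {
            bits <- bitwAnd(bitwShiftR(row, (k - 1):0), 1L)
            lits <- ifelse(sg > 0, bits, 1L - bits)
            outs[row + 1] <- as.integer(sum(w * lits) >= theta)
          }
          for (i in seq_len(k))
            signRows[[length(signRows) + 1L]] <-
              data.frame(from = regs[i], to = nd, sign = sg[i])
        }
      }
      rules[[nd]] <- TruthTable(regs, outs)
    }
    list(network = BooleanNetwork(rules, nodes),
         signs = if (length(signRows)) do.call(rbind, signRows) else NULL,
         spec = list(nNodes = nNodes, maxInDegree = maxInDegree,
                     activationFraction = activationFraction,
                     family = family, seed = seed))
  })
}

#' Generate a random signed digraph
#'
#' @param nNodes number of nodes.
#' @param nEdges number of edges (sampled uniformly over ordered pairs,
#'   self-loops excluded).
#' @param activationFraction probability of a positive sign.
#' @param seed integer seed.
#' @return a \code{\link{SignedDigraph}}.
#' @export
randomSignedDigraph <- function(nNodes, nEdges, activationFraction = 0.5,
                                seed = 1) {
  .withSeed(seed, {
    nodes <- sprintf("n%02d", seq_len(nNodes))
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pick <- pairs[sample.int(nrow(pairs), min(nEdges, nrow(pairs))), ]
    pick$sign <- ifelse(stats::runif(nrow(pick)) < activationFraction, 1, -1)
    pick$flagged <- FALSE
    rownames(pick) <- NULL
    SignedDigraph(pick, nodes)
  })
}

#' Generate a random attractor chain with a planted dominant path
#'
#' Builds a row-stochastic matrix as a mixture of uniform noise and the
#' deterministic shift along the planted path 1 -> 2 -> ... -> n (the last
#' state holds): \code{flowStrength} is the mixture weight of the shift, so
#' super-diagonal entries dominate as it approaches 1. The planted path is
#' recorded for ordering-recovery tests.
#'
#' @param nAttractors number of attractor states (>= 2).
#' @param flowStrength mixture weight in (0, 1).
#' @param seed integer seed for the noise component.
#' @return list with \code{pi} (row-stochastic matrix) and \code{path}
#'   (the planted ordering 1..n).
#' @export
randomChain <- function(nAttractors, flowStrength, seed = 1) {
  if (nAttractors < 2) stop("need at least two attractors")
  if (flowStrength <= 0 || flowStrength >= 1)
    stop("flowStrength must be in (0, 1)")
  .withSeed(seed, {
    k <- nAttractors
    noise <- matrix(stats::runif(k * k), k)
    noise <- noise / rowSums(noise)
    shift <- matrix(0, k, k)
    for (i in seq_len(k - 1)) shift[i, i + 1] <- 1
    shift[k, k] <- 1
    pi <- (1 - flowStrength) * noise + flowStrength * shift
    list(pi = pi, path = seq_len(k))
  })
}

#' Write a fixture manifest as JSON
#'
#' Records the generating spec and seed next to serialized fixtures.
#'
#' @param spec list of generator parameters (e.g. the \code{spec} element of
#'   \code{\link{randomBooleanNetwork}}).
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeFixtureManifest <- function(spec, path) {
  jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
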