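#' @import methods
NULL

#' Truth table of a single network node
#'
#' A \code{TruthTable} stores the Boolean update function of one node as an
#' explicit output vector over all combinations of its regulators. Row
#' \code{i} (1-based) of \code{outputs} is the output for the regulator
#' configuration whose bits, read with the \emph{first} regulator as the most
#' significant bit, encode the unsigned integer \code{i - 1}. A node with no
#' regulators is a constant and has a single output.
#'
#' @slot regulators character vector of regulator node names (possibly empty).
#' @slot outputs integer vector of 0/1 values, length \code{2^length(regulators)}.
#' @export
setClass("TruthTable",
  representation(regulators = "character", outputs = "integer"))

setValidity("TruthTable", function(object) {
  k <- length(object@regulators)
  if (length(object@outputs) != 2L^k)
    return(sprintf("outputs must have length 2^%d = %d", k, 2L^k))
  if (!all(object@outputs %in% c(0L, 1L)))
    return("outputs must be 0 or 1")
  if (anyDuplicated(object@regulators))
    return("duplicated regulator names")
  TRUE
})

#' Synchronous Boolean network
#'
#' A \code{BooleanNetwork} is an ordered set of named nodes, one
#' \code{\link{TruthTable}} per node, and an optional set of clamps that hold
#' selected nodes at a fixed value (used for constitutive conditions and for
#' loss/gain-of-function mutants). The node order is the canonical bit order
#' for integer state codes: node 1 is the most significant bit.
#'
#' @slot nodes character vector of unique node names; the canonical order.
#' @slot rules named list of \code{TruthTable} objects, one per node.
#' @slot clamps named integer vector (values 0/1) of clamped nodes; may be empty.
#' @export
setClass("BooleanNetwork",
  representation(nodes = "character", rules = "list", clamps = "integer"))

setValidity("BooleanNetwork", function(object) {
  if (anyDuplicated(object@nodes)) return("node names must be unique")
  if (!identical(sort(names(object@rules)), sort(object@nodes)))
    return("rules must be a named list with exactly one entry per node")
  for (nd in object@nodes) {
    tt <- object@rules[[nd]]
    if (!is(tt, "TruthTable")) return(sprintf("rule for %s is not a TruthTable", nd))
    bad <- setdiff(tt@regulators, object@nodes)
    if (length(bad))
      return(sprintf("rule for %s names unknown regulator(s): %s",
                     nd, paste(bad, collapse = ", ")))
  }
  if (length(object@clamps)) {
    if (is.null(names(object@clamps)) || !all(names(object@clamps) %in% object@nodes))
      return("clamps must be named after existing nodes")
    if (!all(object@clamps %in% c(0L, 1L))) return("clamp values must be 0 or 1")
    if (anyDuplicated(names(object@clamps))) return("duplicated clamp entries")
  }
  TRUE
})

#' Set of attractors of a Boolean network
#'
#' Attractors are state cycles of the synchronous dynamics; a fixed point is
#' a cycle of length one. States are stored as integer codes in
#' \code{[0, 2^n)} under the network's canonical bit order.
#'
#' @slot cycles list of integer vectors; each vector lists the state codes of
#'   one cycle in the order they are visited, starting from the smallest code.
#' @slot labels character vector of one label per attractor (\code{NA} when
#'   unlabelled).
#' @slot distances integer vector; Hamming distance between each attractor
#'   and the profile it was labelled with (\code{NA} when unlabelled).
#' @slot nodes character vector, the node order the codes refer to.
#' @export
setClass("AttractorSet",
  representation(cycles = "list", labels = "character",
                 distances = "integer", nodes = "character"))

setValidity("AttractorSet", function(object) {
  k <- length(object@cycles)
  if (length(object@labels) != k) return("one label per attractor required")
  if (length(object@distances) != k) return("one distance per attractor required")
  all_states <- unlist(object@cycles)
  if (anyDuplicated(all_states)) return("attractor cycles must be disjoint")
  TRUE
})

#' Partition of the state space into basins of attraction
#'
#' Every explored state is assigned to the attractor its deterministic
#' trajectory reaches; synchronous determinism makes the assignment total.
#'
#' @slot attractors an \code{\link{AttractorSet}}.
#' @slot assignment integer vector: for each explored state (in increasing
#'   code order), the index of its attractor.
#' @slot states integer vector of explored state codes (increasing).
#' @slot counts integer vector of per-attractor state counts.
#' @slot percentages numeric vector of per-attractor percentages of the
#'   explored space.
#' @export
setClass("BasinPartition",
  representation(attractors = "AttractorSet", assignment = "integer",
                 states = "integer", counts = "integer", percentages = "numeric"))

setValidity("BasinPartition", function(object) {
  if (length(object@assignment) != length(object@states))
    return("one assignment per explored state required")
  if (sum(object@counts) != length(object@states))
    return("basin counts must sum to the explored state count")
  if (abs(sum(object@percentages) - 100) > 0.01)
    return("basin percentages must sum to 100 within 0.01")
  TRUE
})

#' Attractor-level transition probability matrix
#'
#' Row-stochastic matrix \eqn{\Pi} with entries \eqn{\pi_{ij} =
#' P(A_{t+1} = j \mid A_t = i)}: the probability that one noisy update maps a
#' state of basin \eqn{i} into basin \eqn{j}, pooled over the states of basin
#' \eqn{i} with equal weight.
#'
#' @slot pi numeric square matrix, rows summing to 1.
#' @slot attractors the \code{\link{AttractorSet}} the row/column order is bound to.
#' @slot xi numeric, the per-node error probability used in the estimation.
#' @slot reps integer, number of simulated one-step transitions per state
#'   (0 for the exact operator).
#' @export
setClass("TransitionMatrix",
  representation(pi = "matrix", attractors = "AttractorSet",
                 xi = "numeric", reps = "integer"))

setValidity("TransitionMatrix", function(object) {
  p <- object@pi
  if (nrow(p) != ncol(p)) return("pi must be square")
  if (any(p < 0)) return("pi entries must be non-negative")
  if (any(abs(rowSums(p) - 1) > 1e-9)) return("pi rows must sum to 1 within 1e-9")
  if (nrow(p) != length(object@attractors@cycles))
    return("pi dimension must match the number of attractors")
  TRUE
})

#' Epigenetic-landscape summary
#'
#' Holds the mean first-passage time (MFPT) matrix between attractor pairs,
#' the antisymmetric net transition rate matrix
#' \eqn{d_{ij} = 1/\mathrm{MFPT}_{ij} - 1/\mathrm{MFPT}_{ji}},
#' and the consistent global ordering: the attractor permutation along which
#' every consecutive net rate is strictly positive (length zero when no
#' permutation qualifies).
#'
#' @slot mfpt numeric matrix of mean first-passage steps (\code{Inf} for
#'   censored pairs); diagonal 0.
#' @slot d numeric antisymmetric matrix of net transition rates.
#' @slot ordering integer vector, a permutation of the attractor indices, or
#'   length zero when no consistent ordering exists.
#' @slot censored integer matrix, number of censored sample paths per pair
#'   (all zero for analytic MFPTs).
#' @export
setClass("LandscapeSummary",
  representation(mfpt = "matrix", d = "matrix", ordering = "integer",
                 censored = "matrix"))

setValidity("LandscapeSummary", function(object) {
  if (any(dim(object@mfpt) != dim(object@d))) return("mfpt and d dimensions differ")
  if (max(abs(object@d + t(object@d)), na.rm = TRUE) > 1e-12)
    return("d must be antisymmetric")
  off <- object@mfpt[row(object@mfpt) != col(object@mfpt)]
  if (any(off <= 0)) return("off-diagonal MFPTs must be positive")
  TRUE
})

#' Signed directed graph
#'
#' Plain signed digraph used by the network-reduction step that collapses
#' linear pathways (simple mediators) and removes source nodes.
#'
#' @slot nodes character vector of node names.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{sign} (\code{+1}/\code{-1}) and logical \code{flagged} marking
#'   opposite-sign parallel edges that arose during composition.
#' @export
setClass("SignedDigraph",
  representation(nodes = "character", edges = "data.frame"))

setValidity("SignedDigraph", function(object) {
  e <- object@edges
  need <- c("from", "to", "sign", "flagged")
  if (!all(need %in% names(e))) return("edges must have from, to, sign, flagged")
  if (nrow(e)) {
    if (!all(e$from %in% object@nodes) || !all(e$to %in% object@nodes))
      return("edge endpoints must be graph nodes")
    if (!all(e$sign %in% c(-1, 1))) return("edge signs must be +1 or -1")
  }
  TRUE
})

#' Report of one in-silico mutant simulation
#'
#' @slot node name of the clamped node.
#' @slot mode \code{"loss"} (clamp to 0) or \code{"gain"} (clamp to 1).
#' @slot attractors labelled \code{\link{AttractorSet}} of the clamped network.
#' @slot basins \code{\link{BasinPartition}} over the clamped subspace.
#' @export
setClass("MutantReport",
  representation(node = "character", mode = "character",
                 attractors = "AttractorSet", basins = "BasinPartition"))

setValidity("MutantReport", function(object) {
  if (!object@mode %in% c("loss", "gain")) return("mode must be 'loss' or 'gain'")
  TRUE
})
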