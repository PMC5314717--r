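## In-silico mutants (loss/gain of function by clamping) and robustness of
## the attractor repertoire to permanent alterations of the regulatory
## logic (single truth-table bit flips).

#' Simulate a loss- or gain-of-function mutant
#'
#' Clamps the node constitutively to 0 (loss) or 1 (gain), enumerates the
#' \code{2^(n-1)} clamp-consistent configurations, and returns the labelled
#' attractors together with the basin partition of the clamped subspace.
#' Identical, bit for bit, to \code{basinPartition(clampNode(net, ...))}.
#'
#' @param net a \code{\link{BooleanNetwork}}.
#' @param node node to perturb.
#' @param mode \code{"loss"} (clamp to 0) or \code{"gain"} (clamp to 1).
#' @param profiles phenotype profiles used for labelling (default
#'   \code{\link{phenotypeProfiles}} when the network has the core nodes,
#'   otherwise no labelling).
#' @return a \code{\link{MutantReport}}.
#' @export
simulateMutant <- function(net, node, mode = c("loss", "gain"),
                           profiles = NULL) {
  mode <- match.arg(mode)
  clamped <- clampNode(net, node, if (mode == "loss") 0L else 1L)
  basins <- basinPartition(clamped)
  attrs <- basins@attractors
  if (is.null(profiles) && setequal(net@nodes, colnames(phenotypeProfiles())))
    profiles <- phenotypeProfiles()
  if (!is.null(profiles)) {
    attrs <- labelAttractors(attrs, profiles)
    basins <- initialize(basins, attractors = attrs)
  }
  new("MutantReport", node = node, mode = mode,
      attractors = attrs, basins = basins)
}

setMethod("show", "MutantReport", function(object) {
  cat(sprintf("MutantReport: %s %s-of-function (%d attractors)\n",
              object@node, object@mode, length(object@attractors@cycles)))
  show(object@basins)
  invisible(NULL)
})

#' Run the canonical six-mutant panel
#'
#' Simulates loss and gain of function for ESE-2, Snai2 and p16 (in the
#' order ESE2 loss, ESE2 gain, Snai2 loss, Snai2 gain, p16 loss, p16 gain).
#' For the shipped core network the attractor counts are 1, 3, 2, 1, 2, 2:
#' ESE-2 loss collapses to the mesenchymal stem-like state, ESE-2 gain adds
#' a hybrid attractor with epithelial and mesenchymal markers co-active,
#' Snai2 loss retains the normal and senescent epithelial states, Snai2
#' gain collapses to the mesenchymal state, p16 loss retains the epithelial
#' and mesenchymal states, and p16 gain yields a senescent-epithelial state
#' and a mesenchymal-like state lacking p53.
#'
#' @param net a \code{\link{BooleanNetwork}} (default: the shipped core).
#' @param nodes nodes to perturb (default ESE2, Snai2, p16).
#' @return named list of \code{\link{MutantReport}} objects, names like
#'   \code{"ESE2_loss"}.
#' @export
mutantPanel <- function(net = buildCoreGRN(), nodes = c("ESE2", "Snai2", "p16")) {
  out <- list()
  for (nd in nodes) for (mode in c("loss", "gain")) {
    out[[paste(nd, mode, sep = "_")]] <- simulateMutant(net, nd, mode)
  }
  out
}

#' Write the mutant panel as CSV files
#'
#' One basin CSV per mutant plus a summary table of attractor counts.
#'
#' @param panel list from \code{\link{mutantPanel}}.
#' @param dir output directory (created if needed).
#' @return the summary data.frame, invisibly.
#' @export
writeMutantPanel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(panel))
    writeBasinTable(panel[[nm]]@basins, file.path(dir, paste0(nm, ".csv")))
  summary <- data.frame(
    mutant = names(panel),
    n_attractors = vapply(panel, function(r) length(r@attractors@cycles), 0L),
    labels = vapply(panel, function(r)
      paste(r@attractors@labels, collapse = ";"), ""))
  utils::write.csv(summary, file.path(dir, "panel_summary.csv"),
                   row.names = FALSE)
  invisible(summary)
}

#' Robustness of the attractor repertoire to logic alterations
#'
#' Each perturbation permanently flips one truth-table output bit of the
#' network and the attractors are recomputed; the function reports the
#' fraction of perturbed networks in which every wild-type fixed point is
#' still a fixed point, together with per-attractor persistence. With
#' \code{nPerturbations = NULL} all single-bit flips are enumerated
#' exhaustively; otherwise that many flips are sampled uniformly with
#' replacement.
#'
#' @param net a \code{\link{BooleanNetwork}}.
#' @param nPerturbations number of sampled flips, or \code{NULL} for the
#'   exhaustive enumeration over every table bit.
#' @param seed optional integer seed for sampled mode.
#' @return list with \code{fraction} (all wild-type attractors preserved),
#'   \code{perAttractor} (named persistence fractions),
#'   \code{nPerturbations}, and \code{mode}.
#' @export
logicRobustness <- function(net, nPerturbations = NULL, seed = NULL) {
  wt <- findAttractors(net)
  fixed <- wt@cycles[lengths(wt@cycles) == 1L]
  wtCodes <- vapply(fixed, `[`, integer(1), 1)
  bitIndex <- do.call(rbind, lapply(net@nodes, function(nd) {
    k <- length(net@rules[[nd]]@regulators)
    data.frame(node = nd, row = seq_len(2^k))
  }))
  picks <- if (is.null(nPerturbations)) seq_len(nrow(bitIndex))
    else .withSeed(seed, sample.int(nrow(bitIndex), nPerturbations,
                                    replace = TRUE))
  persist <- matrix(FALSE, length(picks), length(wtCodes))
  colnames(persist) <- vapply(seq_along(wtCodes), function(i) {
    if (is.na(wt@labels[i])) paste0("A", i) else wt@labels[i]
  }, "")
  for (p in seq_along(picks)) {
    b <- bitIndex[picks[p], ]
    rules <- net@rules
    tt <- rules[[b$node]]
    outs <- tt@outputs
    outs[b$row] <- 1L - outs[b$row]
    rules[[b$node]] <- TruthTable(tt@regulators, outs)
    pert <- BooleanNetwork(rules, net@nodes, net@clamps)
    succ <- successorTable(pert)
    persist[p, ] <- succ[as.character(wtCodes)] == wtCodes
  }
  list(fraction = mean(apply(persist, 1, all)),
       perAttractor = colMeans(persist),
       nPerturbations = length(picks),
       mode = if (is.null(nPerturbations)) "exhaustive" else "sampled")
}
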