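## Network reduction: iterative removal of source nodes and simple mediator
## nodes (in-degree 1, out-degree 1) from signed digraphs, and the
## corresponding function-composition reduction of Boolean networks, which
## preserves fixed points.

#' Create a signed digraph
#'
#' @param edges data.frame with columns \code{from}, \code{to}, \code{sign}
#'   (\code{+1}/\code{-1}; \code{"+"}/\code{"-"} also accepted).
#' @param nodes optional node set (defaults to all edge endpoints).
#' @return a \code{\link{SignedDigraph}}.
#' @export
SignedDigraph <- function(edges, nodes = NULL) {
  if (is.character(edges$sign))
    edges$sign <- ifelse(edges$sign %in% c("+", "+1"), 1, -1)
  edges$sign <- as.numeric(edges$sign)
  if (is.null(edges$flagged)) edges$flagged <- FALSE
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  new("SignedDigraph", nodes = as.character(nodes),
      edges = edges[, c("from", "to", "sign", "flagged")])
}

setMethod("show", "SignedDigraph", function(object) {
  cat(sprintf("SignedDigraph: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  if (nrow(object@edges)) {
    s <- ifelse(object@edges$sign > 0, "+", "-")
    fl <- ifelse(object@edges$flagged, " [flagged]", "")
    cat(paste0("  ", object@edges$from, " -", s, "-> ",
               object@edges$to, fl, collapse = "\n"), "\n")
  }
  invisible(NULL)
})

## internal: mark opposite-sign parallel edges (kept, not cancelled)
flagParallel <- function(edges) {
  if (!nrow(edges)) return(edges)
  key <- paste(edges$from, edges$to)
  for (k in unique(key)) {
    i <- which(key == k)
    if (length(unique(edges$sign[i])) > 1) edges$flagged[i] <- TRUE
  }
  edges
}

#' Reduce a signed digraph
#'
#' Repeatedly (a) deletes any source node (no incoming edges) not in
#' \code{keep} together with its outgoing edges, and (b) replaces any simple
#' mediator node \code{m} not in \code{keep} — in-degree one and out-degree
#' one, not a self-loop — with the composed edge whose sign is the product
#' of the two collapsed signs. Iterates to a fixed configuration; nodes in
#' \code{keep} are never removed. Opposite-sign parallel edges arising from
#' composition are retained and flagged rather than cancelled. The result is
#' independent of removal order.
#'
#' @param g a \code{\link{SignedDigraph}}.
#' @param keep character vector of protected node names.
#' @return the reduced \code{\link{SignedDigraph}}.
#' @export
reduceDigraph <- function(g, keep = character()) {
  stopifnot(all(keep %in% g@nodes) || length(g@nodes) == 0)
  nodes <- g@nodes
  edges <- g@edges
  repeat {
    changed <- FALSE
    indeg <- table(factor(edges$to, levels = nodes))
    outdeg <- table(factor(edges$from, levels = nodes))
    ## sources first (structural deletion)
    src <- nodes[indeg == 0 & !nodes %in% keep]
    if (length(src)) {
      edges <- edges[!edges$from %in% src, , drop = FALSE]
      nodes <- setdiff(nodes, src)
      changed <- TRUE
    } else {
      med <- nodes[indeg == 1 & outdeg == 1 & !nodes %in% keep]
      med <- Filter(function(m) {
        ein <- edges[edges$to == m, , drop = FALSE]
        eout <- edges[edges$from == m, , drop = FALSE]
        ein$from != m && eout$to != m       # exclude self-loops
      }, med)
      if (length(med)) {
        m <- med[[1]]
        ein <- edges[edges$to == m, , drop = FALSE]
        eout <- edges[edges$from == m, , drop = FALSE]
        comp <- data.frame(from = ein$from, to = eout$to,
                           sign = ein$sign * eout$sign, flagged = FALSE)
        edges <- edges[edges$to != m & edges$from != m, , drop = FALSE]
        ## drop exact duplicates of an existing edge, keep opposite signs
        dup <- any(edges$from == comp$from & edges$to == comp$to &
                   edges$sign == comp$sign)
        if (!dup) edges <- rbind(edges, comp)
        nodes <- setdiff(nodes, m)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  edges <- flagParallel(edges)
  rownames(edges) <- NULL
  new("SignedDigraph", nodes = nodes, edges = edges)
}

## internal: number of distinct other nodes whose rules use `node`
dependentsOf <- function(net, node) {
  deps <- vapply(net@nodes, function(nd)
    nd != node && node %in% net@rules[[nd]]@regulators, logical(1))
  net@nodes[deps]
}

## internal: substitute mediator m (single regulator a) into target's table
composeMediator <- function(targetTT, m, mTT) {
  a <- mTT@regulators       # length 1
  regs <- targetTT@regulators
  newRegs <- unique(c(setdiff(regs, m), a))
  k <- length(newRegs)
  outs <- integer(2^k)
  for (row in 0:(2^k - 1)) {
    v <- as.integer(bitwAnd(bitwShiftR(row, (k - 1):0), 1L))
    names(v) <- newRegs
    mval <- mTT@outputs[v[[a]] + 1L]
    full <- c(v, stats::setNames(mval, m))
    idx <- 0L
    for (r in regs) idx <- idx * 2L + full[[r]]
    outs[row + 1L] <- targetTT@outputs[idx + 1L]
  }
  TruthTable(newRegs, outs)
}

## internal: substitute a constant value for node s in a truth table
substituteConstant <- function(tt, s, value) {
  if (!s %in% tt@regulators) return(tt)
  regs <- setdiff(tt@regulators, s)
  k <- length(regs)
  outs <- integer(2^k)
  for (row in 0:(2^k - 1)) {
    v <- as.integer(bitwAnd(bitwShiftR(row, (k - 1):0), 1L))
    names(v) <- regs
    full <- c(v, stats::setNames(as.integer(value), s))
    idx <- 0L
    for (r in tt@regulators) idx <- idx * 2L + full[[r]]
    outs[row + 1L] <- tt@outputs[idx + 1L]
  }
  TruthTable(regs, outs)
}

#' Reduce a Boolean network by mediator and source removal
#'
#' Removes, outside \code{keep}: (a) constant source nodes (empty regulator
#' list), whose value is substituted into their targets' tables, and (b)
#' simple mediators — exactly one regulator (not themselves), feeding
#' exactly one other node — whose update function is composed into the
#' target's table. Iterates until no removable node remains. Fixed points
#' of the reduced network are exactly the projections of the fixed points of
#' the original network (cyclic attractors carry no such guarantee under
#' synchronous update).
#'
#' @param net a \code{\link{BooleanNetwork}} without clamps.
#' @param keep character vector of protected node names.
#' @return the reduced \code{\link{BooleanNetwork}}.
#' @export
reduceBoolean <- function(net, keep = character()) {
  if (length(net@clamps)) stop("reduce an unclamped network")
  stopifnot(all(keep %in% net@nodes))
  repeat {
    changed <- FALSE
    for (nd in setdiff(net@nodes, keep)) {
      tt <- net@rules[[nd]]
      deps <- dependentsOf(net, nd)
      if (length(tt@regulators) == 0L) {
        ## constant source: substitute its value everywhere
        rules <- net@rules
        for (d in deps)
          rules[[d]] <- substituteConstant(rules[[d]], nd, tt@outputs[1])
        rules[[nd]] <- NULL
        net <- BooleanNetwork(rules, setdiff(net@nodes, nd))
        changed <- TRUE
        break
      }
      if (length(tt@regulators) == 1L && tt@regulators != nd &&
          length(deps) == 1L && !nd %in% net@rules[[nd]]@regulators) {
        rules <- net@rules
        rules[[deps]] <- composeMediator(rules[[deps]], nd, tt)
        rules[[nd]] <- NULL
        net <- BooleanNetwork(rules, setdiff(net@nodes, nd))
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  net
}

#' Read a signed digraph from a SIF file
#'
#' Lines of the form \code{source <TAB> +/- <TAB> target}.
#'
#' @param path input file.
#' @return a \code{\link{SignedDigraph}}.
#' @export
readSIF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, "", 1),
    to = vapply(parts, `[`, "", 3),
    sign = ifelse(vapply(parts, `[`, "", 2) %in% c("+", "+1"), 1, -1),
    flagged = FALSE)
  SignedDigraph(edges)
}

#' Write a signed digraph to a SIF file
#'
#' @param g a \code{\link{SignedDigraph}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSIF <- function(g, path) {
  s <- ifelse(g@edges$sign > 0, "+", "-")
  writeLines(paste(g@edges$from, s, g@edges$to, sep = "\t"), path)
  invisible(path)
}
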