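## Epigenetic-landscape layer: stochasticity-in-nodes (SIN) noise model,
## attractor-level Markov chain, temporal attainment, mean first-passage
## times and the consistent global attractor ordering.
##
## SIN model: at every time step each node first takes the value dictated
## by its Boolean function and then disobeys it independently with
## probability xi, i.e. P[x_i(t+1) = F_i(x(t))] = 1 - xi and
## P[x_i(t+1) = 1 - F_i(x(t))] = xi. Clamped nodes never flip.

## internal: run code with a temporary RNG seed, restoring caller state
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' One stochastic (SIN) update step
#'
#' Computes the deterministic synchronous successor, then flips every
#' non-clamped node independently with probability \code{xi}.
#'
#' @param net a \code{\link{BooleanNetwork}}.
#' @param state 0/1 state vector or integer code (as
#'   \code{\link{synchronousStep}}).
#' @param xi per-node error probability in \code{[0, 1]}; \code{xi = 0}
#'   reproduces the deterministic step exactly.
#' @return the noisy successor state, same form as the input. Uses the
#'   session RNG; seed upstream for reproducibility.
#' @export
stochasticStep <- function(net, state, xi) {
  if (!is.numeric(xi) || xi < 0 || xi > 1) stop("xi must be in [0, 1]")
  as_code <- length(state) == 1L && is.numeric(state) && length(net@nodes) > 1L
  det <- synchronousStep(net, if (as_code) decodeState(state, net) else state)
  free <- !net@nodes %in% names(net@clamps)
  flips <- stats::runif(length(net@nodes)) < xi
  out <- as.integer(xor(det == 1L, flips & free))
  names(out) <- net@nodes
  if (as_code) encodeState(out, net) else out
}

#' Exact one-step SIN operator on the full state space
#'
#' Returns the transition matrix over all clamp-consistent states with
#' \eqn{P(s \to s') = \xi^h (1-\xi)^{n_f - h}}, where \eqn{h} is the Hamming
#' distance between \eqn{s'} and the deterministic successor of \eqn{s} over
#' the \eqn{n_f} free (non-clamped) nodes. Serves as the analytic oracle for
#' the Monte-Carlo estimator of the attractor-level matrix.
#'
#' @param net a \code{\link{BooleanNetwork}} with at most 12 nodes.
#' @param xi per-node error probability.
#' @return row-stochastic numeric matrix with state codes as dimnames.
#' @export
exactOneStepOperator <- function(net, xi) {
  n <- length(net@nodes)
  if (n > 12) stop("exact operator is guarded at n <= 12 nodes")
  if (xi < 0 || xi > 1) stop("xi must be in [0, 1]")
  succ <- successorTable(net)
  codes <- as.integer(names(succ))
  nf <- n - length(net@clamps)
  ## Hamming distances between deterministic successors and all states
  h <- outer(succ, codes, function(a, b) {
    x <- bitwXor(as.integer(a), as.integer(b))
    v <- integer(length(x))
    for (i in seq_len(n)) v <- v + bitwAnd(bitwShiftR(x, i - 1L), 1L)
    v
  })
  P <- xi^h * (1 - xi)^(nf - h)
  dimnames(P) <- list(codes, codes)
  P
}

#' Aggregate a full-state operator into an attractor-level matrix
#'
#' Pools the rows of a full-state-space transition operator over the states
#' of each basin (equal weight per state) and sums columns within basins,
#' yielding the exact attractor-level transition matrix the Monte-Carlo
#' estimator converges to.
#'
#' @param P full-state operator from \code{\link{exactOneStepOperator}}.
#' @param basins a \code{\link{BasinPartition}} on the same state space.
#' @return a \code{\link{TransitionMatrix}} (reps = 0 marks it exact).
#' @export
aggregateByBasins <- function(P, basins) {
  k <- length(basins@counts)
  pi <- matrix(0, k, k)
  for (i in seq_len(k)) {
    rows <- which(basins@assignment == i)
    rowsum <- colSums(P[rows, , drop = FALSE])
    for (j in seq_len(k))
      pi[i, j] <- sum(rowsum[basins@assignment == j])
    pi[i, ] <- pi[i, ] / length(rows)
  }
  dimnames(pi) <- list(basins@attractors@labels, basins@attractors@labels)
  new("TransitionMatrix", pi = pi, attractors = basins@attractors,
      xi = NA_real_, reps = 0L)
}

#' Estimate the attractor-level transition matrix by simulation
#'
#' For every clamp-consistent state, simulates \code{reps} one-step SIN
#' transitions from the raw state (no deterministic relaxation in between)
#' and estimates \eqn{\pi_{ij}} as the frequency with which states of basin
#' \eqn{i} land in basin \eqn{j}, with counts pooled over all states of
#' basin \eqn{i} (equal weight per state); rows are then normalized.
#'
#' @param net a \code{\link{BooleanNetwork}}.
#' @param xi per-node error probability.
#' @param reps simulated one-step transitions per state (default 10000).
#' @param basins precomputed \code{\link{BasinPartition}} (recomputed if
#'   missing).
#' @param seed optional integer seed (applied locally; caller RNG restored).
#' @return a \code{\link{TransitionMatrix}}.
#' @export
estimateTransitionMatrix <- function(net, xi, reps = 10000,
                                     basins = basinPartition(net),
                                     seed = NULL) {
  stopifnot(reps >= 1)
  .withSeed(seed, {
    n <- length(net@nodes)
    succ <- successorTable(net)
    codes <- as.integer(names(succ))
    idxOf <- integer(2^n)                  # full code -> position in codes
    idxOf[codes + 1L] <- seq_along(codes)
    free <- which(!net@nodes %in% names(net@clamps))
    weights <- 2L^(n - free)               # bit value of each free node
    k <- length(basins@counts)
    tally <- matrix(0, k, k)
    for (s in seq_along(codes)) {
      det <- succ[s]
      flips <- matrix(stats::runif(reps * length(free)) < xi, reps)
      mask <- as.integer(flips %*% weights)
      landed <- basins@assignment[idxOf[bitwXor(det, mask) + 1L]]
      i <- basins@assignment[s]
      tl <- tabulate(landed, nbins = k)
      tally[i, ] <- tally[i, ] + tl
    }
    pi <- tally / rowSums(tally)
    dimnames(pi) <- list(basins@attractors@labels, basins@attractors@labels)
    new("TransitionMatrix", pi = pi, attractors = basins@attractors,
        xi = xi, reps = as.integer(reps))
  })
}

#' @describeIn estimateTransitionMatrix the raw row-stochastic matrix
#' @param x a \code{TransitionMatrix}
#' @export
setGeneric("transitionProbabilities", function(x)
  standardGeneric("transitionProbabilities"))

#' @export
setMethod("transitionProbabilities", "TransitionMatrix", function(x) x@pi)

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix (%d attractors, xi = %s, reps = %d)\n",
              nrow(object@pi), format(object@xi), object@reps))
  print(round(object@pi, 5))
  invisible(NULL)
})

## internal: accept a TransitionMatrix or plain matrix
.asPi <- function(pi) {
  if (is(pi, "TransitionMatrix")) pi <- pi@pi
  if (any(abs(rowSums(pi) - 1) > 1e-8)) stop("pi must be row-stochastic")
  pi
}

#' Iterate the attractor-occupation distribution
#'
#' Applies the Markov recursion \eqn{P_A(t+1) = \Pi^\top P_A(t)}: with
#' \eqn{\Pi} row-stochastic (\eqn{\pi_{ij}} the probability of moving from
#' attractor \eqn{i} to \eqn{j}), the distribution evolves by
#' \eqn{p_j(t+1) = \sum_i p_i(t)\,\pi_{ij}} — i.e. the row vector acts on
#' the right of \eqn{\Pi}.
#'
#' @param pi a \code{\link{TransitionMatrix}} or row-stochastic matrix.
#' @param p0 initial probability vector over attractors (sums to 1).
#' @param steps number of iterations.
#' @return numeric matrix with \code{steps + 1} rows (t = 0..steps), one
#'   column per attractor.
#' @export
iterateDistribution <- function(pi, p0, steps) {
  pim <- .asPi(pi)
  if (abs(sum(p0) - 1) > 1e-8) stop("p0 must sum to 1")
  traj <- matrix(NA_real_, steps + 1, nrow(pim))
  colnames(traj) <- rownames(pim)
  p <- as.numeric(p0)
  traj[1, ] <- p
  for (t in seq_len(steps)) {
    p <- as.numeric(crossprod(pim, p))
    traj[t + 1, ] <- p
  }
  traj
}

#' Temporal sequence of attractor attainment
#'
#' Iterates the distribution and summarizes the attainment pattern in two
#' ways. \code{sequence} records the order in which distinct attractors
#' first become the globally most probable one (argmax trace, ties broken
#' toward the incumbent). \code{peakOrder} records the attractors sorted by
#' the time at which each one's occupation probability peaks (ties broken
#' by descending peak height): the succession of probability waves the
#' attainment curves display. For the shipped core network the peak order
#' is epithelial, then senescent, then mesenchymal stem-like at every
#' tested noise level, whereas the transient senescent wave never holds the
#' global argmax (its basin is the smallest); the peak order is therefore
#' the faithful summary of the attainment succession.
#'
#' @inheritParams iterateDistribution
#' @return list with elements \code{sequence} (argmax-trace order),
#'   \code{peakOrder} (attractors by peak time), \code{argmax} (per-step
#'   most probable attractor), \code{maxProb} (per-attractor maximum of
#'   \eqn{p_A(t)}), \code{peakTime} (per-attractor step of that maximum,
#'   0-based), and \code{curves} (the full trajectory matrix).
#' @export
temporalAttainment <- function(pi, p0, steps) {
  traj <- iterateDistribution(pi, p0, steps)
  k <- ncol(traj)
  argmax <- integer(nrow(traj))
  cur <- which.max(traj[1, ])
  for (t in seq_len(nrow(traj))) {
    best <- max(traj[t, ])
    if (traj[t, cur] < best - 1e-12) cur <- which.max(traj[t, ])
    argmax[t] <- cur
  }
  sequence <- argmax[!duplicated(argmax)]
  maxProb <- apply(traj, 2, max)
  peakTime <- apply(traj, 2, which.max) - 1L
  peakOrder <- order(peakTime, -maxProb)
  list(sequence = sequence, peakOrder = peakOrder, argmax = argmax,
       maxProb = maxProb, peakTime = peakTime, curves = traj)
}

#' Simulated mean first-passage times between attractors
#'
#' For every ordered pair (i, j), simulates \code{nPaths} sample paths of
#' the attractor-level Markov chain started entirely at attractor \eqn{i}
#' (all probability mass localized there) and averages the first step at
#' which attractor \eqn{j} is visited. Paths that have not reached \eqn{j}
#' after \code{maxSteps} steps are censored: the entry is \code{Inf} when
#' all paths are censored, otherwise the mean over completed paths, with
#' censoring counts reported. Sample paths are exchangeable, so the chain
#' population is propagated as per-state counts with multinomial steps —
#' statistically identical to simulating each path separately.
#'
#' @param pi a \code{\link{TransitionMatrix}} or row-stochastic matrix.
#' @param nPaths sample paths per ordered pair (default 10000).
#' @param maxSteps censoring horizon (default 1e5).
#' @param seed optional integer seed (applied locally).
#' @param stateLevel optional list \code{list(net =, xi =, basins =)}; when
#'   supplied, paths are instead simulated on the full state space with SIN
#'   steps from the attractor state, and a visit to \eqn{j} is the first
#'   entry into its basin (sensitivity variant).
#' @return list with \code{mfpt} (matrix, diagonal 0) and \code{censored}
#'   (integer matrix of censored path counts).
#' @export
mfptSimulate <- function(pi, nPaths = 10000, maxSteps = 1e5, seed = NULL,
                         stateLevel = NULL) {
  if (!is.null(stateLevel))
    return(.mfptStateLevel(stateLevel$net, stateLevel$xi, stateLevel$basins,
                           nPaths, maxSteps, seed))
  pim <- .asPi(pi)
  k <- nrow(pim)
  .withSeed(seed, {
    M <- matrix(0, k, k, dimnames = dimnames(pim))
    cen <- matrix(0L, k, k, dimnames = dimnames(pim))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      alive <- integer(k); alive[i] <- nPaths
      sumT <- 0; done <- 0L
      for (t in seq_len(maxSteps)) {
        nxt <- integer(k)
        for (s in which(alive > 0L))
          nxt <- nxt + as.integer(stats::rmultinom(1, alive[s], pim[s, ]))
        hit <- nxt[j]
        sumT <- sumT + as.numeric(hit) * t
        done <- done + hit
        nxt[j] <- 0L
        alive <- nxt
        if (!sum(alive)) break
      }
      cen[i, j] <- as.integer(sum(alive))
      M[i, j] <- if (done == 0L) Inf else sumT / done
    }
    list(mfpt = M, censored = cen)
  })
}

## internal: full-state-space MFPT variant
.mfptStateLevel <- function(net, xi, basins, nPaths, maxSteps, seed) {
  attrs <- basins@attractors
  if (any(lengths(attrs@cycles) != 1L)) stop("state-level MFPT needs fixed points")
  k <- length(attrs@cycles)
  codes <- basins@states
  n <- length(net@nodes)
  succ <- successorTable(net)
  idxOf <- integer(2L^n); idxOf[codes + 1L] <- seq_along(codes)
  free <- which(!net@nodes %in% names(net@clamps))
  weights <- 2L^(n - free)
  .withSeed(seed, {
    M <- matrix(0, k, k); cen <- matrix(0L, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      cur <- rep(idxOf[attrs@cycles[[i]][1] + 1L], nPaths)
      t_hit <- rep(NA_integer_, nPaths)
      aliveIdx <- seq_len(nPaths)
      for (t in seq_len(maxSteps)) {
        det <- succ[cur]
        mask <- as.integer((matrix(stats::runif(length(cur) * length(free)),
                                   length(cur)) < xi) %*% weights)
        cur <- idxOf[bitwXor(det, mask) + 1L]
        hit <- basins@assignment[cur] == j
        if (any(hit)) {
          t_hit[aliveIdx[hit]] <- t
          aliveIdx <- aliveIdx[!hit]
          cur <- cur[!hit]
        }
        if (!length(cur)) break
      }
      cen[i, j] <- length(aliveIdx)
      M[i, j] <- if (all(is.na(t_hit))) Inf else mean(t_hit, na.rm = TRUE)
    }
    list(mfpt = M, censored = cen)
  })
}

#' Analytic mean first-passage times (fundamental-matrix solve)
#'
#' For each target attractor \eqn{j}, solves \eqn{(I - Q)\,m = \mathbf{1}}
#' with \eqn{Q} the transition matrix restricted to the non-target states;
#' \eqn{m_i} is the exact expected first-passage time from \eqn{i} to
#' \eqn{j}. The independent oracle for \code{\link{mfptSimulate}}.
#'
#' @param pi a \code{\link{TransitionMatrix}} or row-stochastic matrix.
#' @return numeric MFPT matrix (diagonal 0; \code{Inf} where the solve is
#'   singular, i.e. the target is unreachable).
#' @export
mfptAnalytic <- function(pi) {
  pim <- .asPi(pi)
  k <- nrow(pim)
  M <- matrix(0, k, k, dimnames = dimnames(pim))
  for (j in seq_len(k)) {
    others <- setdiff(seq_len(k), j)
    Q <- pim[others, others, drop = FALSE]
    m <- tryCatch(solve(diag(length(others)) - Q, rep(1, length(others))),
                  error = function(e) rep(Inf, length(others)))
    M[others, j] <- m
  }
  M
}

#' Net transition rates and the consistent global ordering
#'
#' Computes the antisymmetric net-rate matrix
#' \eqn{d_{ij} = 1/\mathrm{MFPT}_{ij} - 1/\mathrm{MFPT}_{ji}} and searches
#' all attractor permutations (exhaustive; 6 for three attractors) for one
#' in which every consecutive net rate is strictly positive. When present
#' this permutation defines the preferred probability flow across the
#' landscape; when absent the ordering slot has length zero.
#'
#' @param mfpt MFPT matrix, or the list returned by
#'   \code{\link{mfptSimulate}}.
#' @return a \code{\link{LandscapeSummary}}.
#' @export
netRatesAndOrdering <- function(mfpt) {
  cen <- NULL
  if (is.list(mfpt) && !is.null(mfpt$mfpt)) {
    cen <- mfpt$censored; mfpt <- mfpt$mfpt
  }
  k <- nrow(mfpt)
  if (is.null(cen)) cen <- matrix(0L, k, k)
  d <- 1 / mfpt - t(1 / mfpt)
  diag(d) <- 0
  perms <- .permutations(k)
  ordering <- integer(0)
  for (p in perms) {
    ok <- all(vapply(seq_len(k - 1), function(t) {
      v <- d[p[t], p[t + 1]]
      is.finite(v) && v > 0
    }, logical(1)))
    if (ok) { ordering <- as.integer(p); break }
  }
  new("LandscapeSummary", mfpt = mfpt, d = d, ordering = ordering,
      censored = cen)
}

## internal: all permutations of 1..k in lexicographic order
.permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in .permutations(k - 1)) {
      v <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, v[rest])
    }
  }
  out
}

setMethod("show", "LandscapeSummary", function(object) {
  cat("LandscapeSummary\n  MFPT:\n")
  print(round(object@mfpt, 2))
  cat("  net rates d:\n")
  print(signif(object@d, 4))
  if (length(object@ordering))
    cat("  consistent global ordering:",
        paste(object@ordering, collapse = " -> "), "\n")
  else cat("  no consistent global ordering\n")
  invisible(NULL)
})

#' Write a labelled landscape matrix as CSV
#'
#' @param mat matrix (transition probabilities, MFPT or net rates).
#' @param path output CSV file.
#' @param labels optional row/column labels.
#' @return \code{path}, invisibly.
#' @export
writeLandscapeMatrix <- function(mat, path, labels = rownames(mat)) {
  df <- as.data.frame(mat)
  if (!is.null(labels)) { rownames(df) <- labels; colnames(df) <- labels }
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}

#' Write attainment curves as CSV
#'
#' @param curves trajectory matrix from \code{\link{temporalAttainment}}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeAttainmentCurves <- function(curves, path) {
  df <- data.frame(t = seq_len(nrow(curves)) - 1L, curves, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a landscape run configuration as JSON
#'
#' Records the error probability, replicate counts and RNG seed of a
#' landscape analysis so results can be reproduced.
#'
#' @param path output JSON file.
#' @param xi error probability.
#' @param reps one-step transitions per state.
#' @param nPaths MFPT sample paths.
#' @param maxSteps MFPT censoring horizon.
#' @param seed RNG seed used.
#' @return \code{path}, invisibly.
#' @export
writeLandscapeConfig <- function(path, xi, reps, nPaths, maxSteps, seed) {
  jsonlite::write_json(list(xi = xi, reps = reps, nPaths = nPaths,
                            maxSteps = maxSteps, seed = seed),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
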