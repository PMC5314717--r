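## Rule-file input/output.
##
## The plain-text rule format is one line per node,
##   target, boolean-expression
## with operators & | !, parentheses, and the constants 0/1 (the format used
## by the common Boolean-network tools). Expressions are compiled to
## explicit truth tables on read; the writer emits canonical
## sum-of-minterms expressions. A TSV loader accepts explicit truth tables
## (regulator columns plus an output column) and is fully lossless,
## including non-functional regulators.

## internal: validate and parse one boolean expression string; returns
## list(expr = parsed R expression, vars = variables in order of appearance)
parseBooleanExpression <- function(txt) {
  tokens <- gregexpr("[A-Za-z_][A-Za-z0-9_.-]*|[()!&|]|0|1|\\s+", txt)[[1]]
  lens <- attr(tokens, "match.length")
  covered <- sum(lens)
  if (covered != nchar(txt))
    stop(sprintf("cannot tokenize rule expression: '%s'", txt))
  pieces <- substring(txt, tokens, tokens + lens - 1)
  pieces <- pieces[!grepl("^\\s+$", pieces)]
  vars <- unique(pieces[grepl("^[A-Za-z_]", pieces)])
  ## names containing '-' are valid node names but not valid R symbols;
  ## map them to safe aliases before parsing
  safe <- make.names(vars)
  txt2 <- txt
  for (i in order(nchar(vars), decreasing = TRUE))
    txt2 <- gsub(paste0("(?<![A-Za-z0-9_.-])", gsub("([.*+?^${}()|\\[\\]\\\\-])",
                 "\\\\\\1", vars[i]), "(?![A-Za-z0-9_.-])"),
                 safe[i], txt2, perl = TRUE)
  expr <- tryCatch(parse(text = txt2)[[1]],
                   error = function(e) stop(sprintf("bad rule expression: '%s'", txt)))
  ok <- function(e) {
    if (is.symbol(e)) return(as.character(e) %in% safe)
    if (is.numeric(e)) return(e %in% c(0, 1))
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (!op %in% c("&", "|", "!", "(", "&&", "||")) return(FALSE)
      return(all(vapply(as.list(e)[-1], ok, logical(1))))
    }
    FALSE
  }
  if (!ok(expr)) stop(sprintf("disallowed construct in rule expression: '%s'", txt))
  list(expr = expr, vars = vars, safe = safe)
}

#' Compile a Boolean expression into a truth table
#'
#' Regulators are the variables of the expression in order of first
#' appearance; the expression is evaluated over all \code{2^k} regulator
#' configurations.
#'
#' @param txt expression string using node names, \code{&}, \code{|},
#'   \code{!}, parentheses and the constants \code{0}/\code{1}.
#' @return a \code{\link{TruthTable}}.
#' @export
expressionToTruthTable <- function(txt) {
  p <- parseBooleanExpression(txt)
  k <- length(p$vars)
  outs <- integer(2^k)
  for (row in 0:(2^k - 1)) {
    env <- new.env(parent = baseenv())
    for (i in seq_len(k))
      assign(p$safe[i], as.logical(bitwAnd(bitwShiftR(row, k - i), 1L)), envir = env)
    v <- eval(p$expr, env)
    outs[row + 1] <- as.integer(as.logical(v))
  }
  TruthTable(p$vars, outs)
}

#' Canonical expression of a truth table
#'
#' Emits a sum-of-minterms expression (every regulator appears in each
#' minterm, in declared order). Constant tables are written as \code{0} or
#' \code{1}, which drops declared-but-constant regulators; use the TSV
#' format for structurally lossless serialization.
#'
#' @param tt a \code{\link{TruthTable}}.
#' @return character expression string.
#' @export
truthTableToExpression <- function(tt) {
  k <- length(tt@regulators)
  if (k == 0L || all(tt@outputs == tt@outputs[1]))
    return(as.character(tt@outputs[1]))
  ones <- which(tt@outputs == 1L) - 1L
  terms <- vapply(ones, function(row) {
    lits <- vapply(seq_len(k), function(i) {
      on <- bitwAnd(bitwShiftR(row, k - i), 1L) == 1L
      if (on) tt@regulators[i] else paste0("!", tt@regulators[i])
    }, "")
    paste0("(", paste(lits, collapse = " & "), ")")
  }, "")
  paste(terms, collapse = " | ")
}

#' Read a Boolean network from a rule file
#'
#' @param path file with lines \code{target, expression}; an optional
#'   \code{targets, factors} header is skipped; \code{#} comments allowed.
#' @return a \code{\link{BooleanNetwork}}.
#' @export
readBNet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^targets\\s*,\\s*factors$", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  rules <- list()
  nodes <- character()
  for (ln in lines) {
    cut <- regexpr(",", ln, fixed = TRUE)
    if (cut < 0) stop(sprintf("malformed rule line (no comma): '%s'", ln))
    target <- trimws(substr(ln, 1, cut - 1))
    expr <- trimws(substr(ln, cut + 1, nchar(ln)))
    if (target %in% nodes) stop(sprintf("duplicated rule for node %s", target))
    rules[[target]] <- expressionToTruthTable(expr)
    nodes <- c(nodes, target)
  }
  BooleanNetwork(rules, nodes)
}

#' Write a Boolean network to a rule file
#'
#' @param net a \code{\link{BooleanNetwork}} (clamps are not serialized).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBNet <- function(net, path) {
  lines <- c("targets, factors",
             vapply(net@nodes, function(nd)
               sprintf("%s, %s", nd, truthTableToExpression(net@rules[[nd]])), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a network from explicit truth tables in TSV form
#'
#' One block per node separated by blank lines. Each block starts with a
#' header line \code{node <TAB> regulator1 <TAB> ... <TAB> output} followed
#' by \code{2^k} rows of 0/1 values (regulator columns then the output).
#' Fully lossless, including non-functional regulators.
#'
#' @param path input file.
#' @return a \code{\link{BooleanNetwork}}.
#' @export
readTruthTableTSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  rules <- list(); nodes <- character()
  for (b in blocks) {
    b <- b[nzchar(trimws(b))]
    if (!length(b)) next
    hdr <- strsplit(b[1], "\t", fixed = TRUE)[[1]]
    target <- hdr[1]
    regs <- hdr[-c(1, length(hdr))]
    rows <- do.call(rbind, lapply(b[-1], function(x)
      as.integer(strsplit(x, "\t", fixed = TRUE)[[1]])))
    k <- length(regs)
    if (nrow(rows) != 2^k) stop(sprintf("truth table for %s has %d rows, expected %d",
                                        target, nrow(rows), 2^k))
    outs <- integer(2^k)
    for (r in seq_len(nrow(rows))) {
      idx <- 0L
      for (i in seq_len(k)) idx <- idx * 2L + rows[r, i]
      outs[idx + 1L] <- rows[r, k + 1L]
    }
    rules[[target]] <- TruthTable(regs, outs)
    nodes <- c(nodes, target)
  }
  BooleanNetwork(rules, nodes)
}

#' Write a network as explicit truth tables in TSV form
#'
#' @param net a \code{\link{BooleanNetwork}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTruthTableTSV <- function(net, path) {
  out <- character()
  for (nd in net@nodes) {
    tt <- net@rules[[nd]]
    k <- length(tt@regulators)
    out <- c(out, paste(c(nd, tt@regulators, "output"), collapse = "\t"))
    for (row in 0:(2^k - 1)) {
      bits <- if (k) bitwAnd(bitwShiftR(row, (k - 1):0), 1L) else integer()
      out <- c(out, paste(c(bits, tt@outputs[row + 1]), collapse = "\t"))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write an attractor table as CSV
#'
#' Columns: attractor id, label, cycle length, then one 0/1 column per node
#' (for cycles, one row per cycle state).
#'
#' @param attrs an \code{\link{AttractorSet}}.
#' @param path output CSV file.
#' @return the written data.frame, invisibly.
#' @export
writeAttractorTable <- function(attrs, path) {
  n <- length(attrs@nodes)
  rows <- list()
  for (i in seq_along(attrs@cycles)) {
    for (cd in attrs@cycles[[i]]) {
      bits <- as.list(bitwAnd(bitwShiftR(cd, (n - 1):0), 1L))
      names(bits) <- attrs@nodes
      rows[[length(rows) + 1L]] <- c(list(attractor = i,
        label = attrs@labels[i], cycle_length = length(attrs@cycles[[i]])), bits)
    }
  }
  df <- do.call(rbind.data.frame, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a basin-size table as CSV
#'
#' Columns: attractor id, label, count, percent (two decimals).
#'
#' @param basins a \code{\link{BasinPartition}}.
#' @param path output CSV file.
#' @return the written data.frame, invisibly.
#' @export
writeBasinTable <- function(basins, path) {
  df <- data.frame(attractor = seq_along(basins@counts),
                   label = basins@attractors@labels,
                   count = basins@counts,
                   percent = round(basins@percentages, 2))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
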