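## A SPARQL SELECT subset sufficient for registry queries: basic graph
## patterns, nested OPTIONAL groups and FILTER expressions (comparisons and
## regex), evaluated over an RDFGraph by successive joins.

parseSparql <- function(text) {
  text <- paste(text, collapse = "\n")
  prefixes <- OT_NS
  for (m in regmatches(text, gregexpr(
    "PREFIX\\s+([A-Za-z][A-Za-z0-9_-]*)?:\\s*<([^>]*)>", text,
    ignore.case = TRUE))[[1]]) {
    p <- regmatches(m, regexec(
      "PREFIX\\s+([A-Za-z][A-Za-z0-9_-]*)?:\\s*<([^>]*)>", m,
      ignore.case = TRUE))[[1]]
    pfx <- if (is.na(p[2]) || !nzchar(p[2])) "" else p[2]
    prefixes <- c(stats::setNames(p[3], pfx),
                  prefixes[names(prefixes) != pfx])
  }
  sel <- regmatches(text, regexec("SELECT\\s+(DISTINCT\\s+)?(.*?)\\s*WHERE",
                                  text, ignore.case = TRUE))[[1]]
  if (!length(sel)) stop(otCondition(400, "SPARQL parse error: no SELECT...WHERE"))
  vars <- if (grepl("\\*", sel[3])) character()
          else regmatches(sel[3], gregexpr("\\?[A-Za-z][A-Za-z0-9_]*", sel[3]))[[1]]
  braceStart <- regexpr("\\{", text)
  if (braceStart < 0) stop(otCondition(400, "SPARQL parse error: no group"))
  chars <- strsplit(text, "")[[1]]
  group <- .parseGroup(chars, braceStart, prefixes)
  list(vars = sub("^\\?", "", vars), group = group$node,
       distinct = !is.na(sel[2]) && nzchar(sel[2]))
}

## parse a { ... } group starting at chars[i] == "{"
.parseGroup <- function(chars, i, prefixes) {
  stopifnot(chars[i] == "{")
  i <- i + 1L
  items <- list()
  buf <- character()
  ## split on "." statement terminators, but never inside <...> or "..."
  splitStatements <- function(txt) {
    cs <- strsplit(txt, "")[[1]]
    out <- character(); cur <- character(); inU <- FALSE; inQ <- FALSE
    for (ch in cs) {
      if (ch == "<" && !inQ) inU <- TRUE
      if (ch == ">" && !inQ) inU <- FALSE
      if (ch == "\"") inQ <- !inQ
      if (ch == "." && !inU && !inQ) {
        out <- c(out, paste(cur, collapse = "")); cur <- character()
      } else cur <- c(cur, ch)
    }
    c(out, paste(cur, collapse = ""))
  }
  flushPatterns <- function() {
    txt <- trimws(paste(buf, collapse = ""))
    buf <<- character()
    if (!nzchar(txt)) return()
    for (stmt in splitStatements(txt)) {
      stmt <- trimws(stmt)
      if (!nzchar(stmt)) next
      items[[length(items) + 1L]] <<-
        list(kind = "pattern", pattern = .parseTriplePattern(stmt, prefixes))
    }
  }
  n <- length(chars)
  while (i <= n) {
    rest <- paste(chars[i:min(n, i + 9L)], collapse = "")
    if (chars[i] == "}") {
      flushPatterns()
      return(list(node = list(kind = "group", items = items), next_i = i + 1L))
    }
    if (grepl("^OPTIONAL", rest, ignore.case = TRUE)) {
      flushPatterns()
      j <- i + 8L
      while (j <= n && chars[j] != "{") j <- j + 1L
      sub <- .parseGroup(chars, j, prefixes)
      items[[length(items) + 1L]] <- list(kind = "optional", group = sub$node)
      i <- sub$next_i
      next
    }
    if (grepl("^FILTER", rest, ignore.case = TRUE)) {
      flushPatterns()
      j <- i + 6L
      while (j <= n && chars[j] != "(") j <- j + 1L
      depth <- 0L; k <- j
      repeat {
        if (chars[k] == "(") depth <- depth + 1L
        if (chars[k] == ")") depth <- depth - 1L
        if (depth == 0L) break
        k <- k + 1L
        if (k > n) stop(otCondition(400, "SPARQL parse error: unbalanced FILTER"))
      }
      expr <- paste(chars[(j + 1L):(k - 1L)], collapse = "")
      items[[length(items) + 1L]] <-
        list(kind = "filter", expr = .parseFilter(expr, prefixes))
      i <- k + 1L
      next
    }
    if (chars[i] == "\"") {  # copy string literal verbatim into the buffer
      buf <- c(buf, chars[i]); i <- i + 1L
      while (i <= n && chars[i] != "\"") { buf <- c(buf, chars[i]); i <- i + 1L }
      buf <- c(buf, chars[i]); i <- i + 1L
      next
    }
    buf <- c(buf, chars[i])
    i <- i + 1L
  }
  stop(otCondition(400, "SPARQL parse error: unterminated group"))
}

.sparqlTerm <- function(tok, prefixes) {
  if (startsWith(tok, "?")) return(list(kind = "var", name = substring(tok, 2)))
  if (startsWith(tok, "<")) return(list(kind = "value", value = gsub("[<>]", "", tok)))
  if (tok == "a") return(list(kind = "value", value = otURI("rdf:type")))
  if (startsWith(tok, "\""))
    return(list(kind = "value",
                value = sub("\"(.*)\".*", "\\1", tok)))
  m <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9_-]*)?:(.*)$", tok))[[1]]
  if (length(m)) {
    pfx <- if (is.na(m[2])) "" else m[2]
    if (pfx %in% names(prefixes))
      return(list(kind = "value",
                  value = paste0(prefixes[[match(pfx, names(prefixes))]], m[3])))
  }
  stop(otCondition(400, paste("SPARQL parse error: cannot read term", tok)))
}

.parseTriplePattern <- function(stmt, prefixes) {
  toks <- regmatches(stmt, gregexpr(
    "\\?[A-Za-z][A-Za-z0-9_]*|<[^>]*>|\"[^\"]*\"(\\^\\^\\S+)?|[^ \t\n]+",
    stmt))[[1]]
  toks <- toks[nzchar(trimws(toks))]
  if (length(toks) != 3L)
    stop(otCondition(400, paste("SPARQL parse error: bad triple pattern:", stmt)))
  lapply(toks, .sparqlTerm, prefixes = prefixes)
}

.parseFilter <- function(expr, prefixes) {
  expr <- trimws(expr)
  m <- regmatches(expr, regexec(
    "^[Rr][Ee][Gg][Ee][Xx]\\s*\\(\\s*\\?([A-Za-z0-9_]+)\\s*,\\s*\"([^\"]*)\"",
    expr))[[1]]
  if (length(m)) return(list(op = "regex", var = m[2], value = m[3]))
  m <- regmatches(expr, regexec(
    "^\\?([A-Za-z0-9_]+)\\s*(=|!=)\\s*(\\S+)$", expr))[[1]]
  if (length(m)) {
    term <- .sparqlTerm(m[4], prefixes)
    return(list(op = m[3], var = m[2], value = term$value))
  }
  stop(otCondition(400, paste("SPARQL parse error: unsupported FILTER:", expr)))
}

## ---- evaluation ----

.unitSolution <- function() data.frame(row.names = 1)[, FALSE, drop = FALSE]

.matchPattern <- function(tr, pattern) {
  keep <- rep(TRUE, nrow(tr))
  fields <- c("subject", "predicate", "object")
  for (k in 1:3) {
    t0 <- pattern[[k]]
    if (t0$kind == "value") keep <- keep & tr[[fields[k]]] == t0$value
  }
  rows <- tr[keep, , drop = FALSE]
  out <- list()
  for (k in 1:3) {
    t0 <- pattern[[k]]
    if (t0$kind == "var" && is.null(out[[t0$name]]))
      out[[t0$name]] <- rows[[fields[k]]]
  }
  ## a repeated variable in one pattern must bind consistently
  for (k in 1:3) for (j in seq_len(3)) {
    if (j <= k) next
    tk <- pattern[[k]]; tj <- pattern[[j]]
    if (tk$kind == "var" && tj$kind == "var" && tk$name == tj$name) {
      ok <- rows[[fields[k]]] == rows[[fields[j]]]
      out <- lapply(out, function(col) col[ok])
      rows <- rows[ok, , drop = FALSE]
    }
  }
  if (!length(out)) {
    ## all-ground pattern: zero or one unit solution
    return(if (nrow(rows)) .unitSolution() else
             .unitSolution()[FALSE, , drop = FALSE])
  }
  as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
}

.joinSolutions <- function(a, b) {
  if (is.null(a)) return(b)
  common <- intersect(names(a), names(b))
  if (!ncol(a)) return(if (nrow(a)) b else b[FALSE, , drop = FALSE])
  if (!ncol(b)) return(if (nrow(b)) a else a[FALSE, , drop = FALSE])
  if (!length(common)) {
    if (!nrow(a) || !nrow(b))
      return(cbind(a[FALSE, , drop = FALSE], b[FALSE, , drop = FALSE]))
    ia <- rep(seq_len(nrow(a)), each = nrow(b))
    ib <- rep(seq_len(nrow(b)), times = nrow(a))
    return(cbind(a[ia, , drop = FALSE], b[ib, , drop = FALSE]))
  }
  merged <- merge(a, b, by = common, stringsAsFactors = FALSE)
  merged
}

.leftJoinSolutions <- function(a, b) {
  if (!nrow(a)) return(a)
  common <- intersect(names(a), names(b))
  extraCols <- setdiff(names(b), names(a))
  if (!length(common)) {
    if (!nrow(b)) {
      for (cn in extraCols) a[[cn]] <- NA_character_
      return(a)
    }
    return(.joinSolutions(a, b))
  }
  merged <- merge(a, b, by = common, all.x = TRUE, stringsAsFactors = FALSE)
  merged
}

.evalGroup <- function(tr, group, sols = NULL) {
  for (item in group$items) {
    if (item$kind == "pattern") {
      sols <- .joinSolutions(sols, .matchPattern(tr, item$pattern))
    } else if (item$kind == "optional") {
      sub <- .evalGroup(tr, item$group, NULL)
      sols <- if (is.null(sols)) sub else .leftJoinSolutions(sols, sub)
    } else if (item$kind == "filter") {
      if (is.null(sols) || !nrow(sols)) next
      f <- item$expr
      col <- if (f$var %in% names(sols)) sols[[f$var]]
             else rep(NA_character_, nrow(sols))
      keep <- switch(f$op,
        "=" = !is.na(col) & col == f$value,
        "!=" = !is.na(col) & col != f$value,
        regex = !is.na(col) & grepl(f$value, col))
      sols <- sols[keep, , drop = FALSE]
    }
  }
  if (is.null(sols)) .unitSolution() else sols
}

#' Evaluate a SPARQL SELECT query over an RDF graph
#'
#' Supports basic graph patterns, nested OPTIONAL groups, FILTER
#' (equality, inequality, regex) and DISTINCT.
#'
#' @param graph an \linkS4class{RDFGraph}.
#' @param query SPARQL SELECT text.
#' @return data.frame of solutions, one column per selected variable
#'   (NA for unbound optional variables).
#' @export
sparqlSelect <- function(graph, query) {
  parsed <- parseSparql(query)
  sols <- .evalGroup(statements(graph), parsed$group, NULL)
  vars <- if (length(parsed$vars)) parsed$vars else names(sols)
  for (v in setdiff(vars, names(sols))) sols[[v]] <- NA_character_
  out <- sols[, vars, drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Serialize SPARQL solutions as application/sparql-results+xml
#'
#' @param solutions data.frame from \code{\link{sparqlSelect}}.
#' @return XML text in the standard SPARQL results format.
#' @export
sparqlResultsXML <- function(solutions) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  head <- paste0("  <head>\n", paste0(
    "    <variable name=\"", names(solutions), "\"/>\n", collapse = ""),
    "  </head>")
  rows <- vapply(seq_len(nrow(solutions)), function(i) {
    bindings <- vapply(names(solutions), function(v) {
      val <- solutions[i, v]
      if (is.na(val)) return("")
      inner <- if (grepl("^_:", val))
        paste0("<bnode>", esc(substring(val, 3)), "</bnode>")
      else if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", val))
        paste0("<uri>", esc(val), "</uri>")
      else paste0("<literal>", esc(val), "</literal>")
      paste0("      <binding name=\"", v, "\">", inner, "</binding>\n")
    }, "")
    paste0("    <result>\n", paste(bindings, collapse = ""), "    </result>")
  }, "")
  paste0("<?xml version=\"1.0\"?>\n",
         "<sparql xmlns=\"http://www.w3.org/2005/sparql-results#\">\n",
         head, "\n  <results>\n",
         paste(rows, collapse = "\n"),
         if (nrow(solutions)) "\n" else "",
         "  </results>\n</sparql>\n")
}
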