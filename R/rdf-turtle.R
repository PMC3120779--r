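## Turtle / N3 reading and writing.
##
## The writer emits plain Turtle (valid N3 as well): @prefix header, subject
## grouping with ";" / "," and labelled blank nodes. The reader is a
## recursive-descent parser over a hand-rolled tokenizer; it accepts the N3
## "=" shorthand, normalizing it to owl:sameAs while parsing, and both
## anonymous ("[...]") and labelled ("_:x") blank nodes.

.pnameLocalRe <- "^[A-Za-z_][A-Za-z0-9_-]*$"

.abbreviate <- function(uri) {
  for (p in names(OT_NS)) {
    ns <- OT_NS[[p]]
    if (startsWith(uri, ns)) {
      local <- substring(uri, nchar(ns) + 1L)
      if (grepl(.pnameLocalRe, local)) return(paste0(p, ":", local))
    }
  }
  NULL
}

.escapeLit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

.ttlTerm <- function(value, type, dtype, used) {
  if (type == "bnode" || (type == "uri" && isBnode(value))) return(value)
  if (type == "uri") {
    ab <- .abbreviate(value)
    if (!is.null(ab)) {
      used[[sub(":.*", "", ab)]] <- TRUE
      return(ab)
    }
    return(paste0("<", value, ">"))
  }
  lit <- paste0("\"", .escapeLit(value), "\"")
  if (!is.na(dtype)) {
    ab <- .abbreviate(dtype)
    if (!is.null(ab)) {
      used[[sub(":.*", "", ab)]] <- TRUE
      lit <- paste0(lit, "^^", ab)
    } else lit <- paste0(lit, "^^<", dtype, ">")
  }
  lit
}

writeTurtle <- function(graph) {
  tr <- statements(graph)
  used <- new.env(parent = emptyenv())
  body <- character()
  rdfType <- otURI("rdf:type")
  for (s in unique(tr$subject)) {
    rows <- tr[tr$subject == s, , drop = FALSE]
    ## rdf:type first, mirroring the conventional "a <Class>" opening
    rows <- rows[order(rows$predicate != rdfType, rows$predicate), , drop = FALSE]
    subj <- if (isBnode(s)) s else {
      ab <- .abbreviate(s)
      if (!is.null(ab)) { used[[sub(":.*", "", ab)]] <- TRUE; ab }
      else paste0("<", s, ">")
    }
    plines <- vapply(unique(rows$predicate), function(p) {
      prows <- rows[rows$predicate == p, , drop = FALSE]
      objs <- vapply(seq_len(nrow(prows)), function(i)
        .ttlTerm(prows$object[i], prows$type[i], prows$dtype[i], used), "")
      pn <- if (p == rdfType) "a" else {
        ab <- .abbreviate(p)
        if (!is.null(ab)) { used[[sub(":.*", "", ab)]] <- TRUE; ab }
        else paste0("<", p, ">")
      }
      paste0("    ", pn, " ", paste(objs, collapse = ", "))
    }, "")
    body <- c(body, paste0(subj, "\n", paste(plines, collapse = " ;\n"), " ."))
  }
  pfx <- sort(intersect(names(OT_NS), ls(used)))
  header <- vapply(pfx, function(p)
    paste0("@prefix ", p, ": <", OT_NS[[p]], "> ."), "")
  paste(c(header, "", body, ""), collapse = "\n")
}

## ---- tokenizer ----

.ttlTokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list(); line <- 1L; i <- 1L
  push <- function(kind, value) toks[[length(toks) + 1L]] <<-
    list(kind = kind, value = value, line = line)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && chars[i] != "\n") i <- i + 1L; next }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop("unterminated URI at line ", line)
      push("uri", paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L; next
    }
    if (ch == "\"") {
      j <- i + 1L; out <- character()
      while (j <= n && chars[j] != "\"") {
        if (chars[j] == "\\" && j < n) {
          esc <- chars[j + 1L]
          out <- c(out, switch(esc, n = "\n", r = "\r", t = "\t",
                               "\"" = "\"", "\\" = "\\", esc))
          j <- j + 2L
        } else {
          if (chars[j] == "\n") line <- line + 1L
          out <- c(out, chars[j]); j <- j + 1L
        }
      }
      if (j > n) stop("unterminated string literal at line ", line)
      push("string", paste(out, collapse = ""))
      i <- j + 1L; next
    }
    if (ch %in% c(".", ";", ",", "[", "]", "=")) {
      ## "." inside a qname/number is handled below; here it terminates
      push(ch, ch); i <- i + 1L; next
    }
    if (ch == "^" && i < n && chars[i + 1L] == "^") {
      push("^^", "^^"); i <- i + 2L; next
    }
    if (ch == "@") {
      j <- i + 1L
      while (j <= n && grepl("[A-Za-z-]", chars[j])) j <- j + 1L
      push("at", paste(chars[i:(j - 1L)], collapse = ""))
      i <- j; next
    }
    ## bare word: qname, bnode label, keyword or number
    j <- i
    while (j <= n && grepl("[A-Za-z0-9_:.+-]", chars[j])) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    ## a trailing "." is the statement terminator, not part of the name
    while (nchar(word) > 1L && endsWith(word, ".") &&
           !grepl("^[+-]?[0-9]*\\.[0-9]+$", word)) {
      word <- substring(word, 1L, nchar(word) - 1L); j <- j - 1L
    }
    if (word == "") stop("unexpected character '", ch, "' at line ", line)
    push("word", word)
    i <- j; next
  }
  toks
}

## ---- parser ----

parseTurtle <- function(text) {
  toks <- .ttlTokenize(text)
  env <- new.env(parent = emptyenv())
  env$prefixes <- c(OT_NS)  # built-ins available even when not declared
  env$rows <- list()
  env$bn <- 0L
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(kind) {
    t <- peek()
    if (is.null(t) || t$kind != kind)
      stop("expected '", kind, "' at line ",
           if (is.null(t)) "end of input" else t$line)
    advance()
  }
  newBnode <- function() { env$bn <- env$bn + 1L; paste0("_:g", env$bn) }
  emit <- function(s, p, o, type, dtype = NA_character_)
    env$rows[[length(env$rows) + 1L]] <- triple(s, p, o, type, dtype)

  resolveWord <- function(w, line) {
    if (w == "a") return(list(value = otURI("rdf:type"), type = "uri"))
    if (startsWith(w, "_:")) return(list(value = w, type = "bnode"))
    if (grepl("^[+-]?[0-9]+$", w))
      return(list(value = w, type = "literal",
                  dtype = otURI("xsd:integer")))
    if (grepl("^[+-]?[0-9]*\\.[0-9]+$", w))
      return(list(value = w, type = "literal",
                  dtype = otURI("xsd:decimal")))
    m <- regmatches(w, regexec("^([A-Za-z][A-Za-z0-9_.-]*)?:(.*)$", w))[[1]]
    if (!length(m)) stop("cannot interpret '", w, "' at line ", line)
    pfx <- m[2]
    if (!pfx %in% names(env$prefixes) && !(pfx == "" && "" %in% names(env$prefixes)))
      stop("undeclared prefix '", pfx, ":' at line ", line)
    list(value = paste0(env$prefixes[[match(pfx, names(env$prefixes))]], m[3]),
         type = "uri")
  }

  parseObject <- function() {
    t <- peek()
    if (is.null(t)) stop("unexpected end of input")
    if (t$kind == "uri") { advance(); return(list(value = t$value, type = "uri")) }
    if (t$kind == "string") {
      advance()
      dtype <- NA_character_
      if (!is.null(peek()) && peek()$kind == "^^") {
        advance()
        dt <- peek()
        dtype <- if (dt$kind == "uri") advance()$value
                 else resolveWord(advance()$value, dt$line)$value
      } else if (!is.null(peek()) && peek()$kind == "at") {
        advance()  # language tag noted and dropped
      }
      return(list(value = t$value, type = "literal", dtype = dtype))
    }
    if (t$kind == "[") {
      advance()
      b <- newBnode()
      if (!is.null(peek()) && peek()$kind != "]") parsePredicates(b)
      expect("]")
      return(list(value = b, type = "bnode"))
    }
    if (t$kind == "word") {
      advance()
      return(resolveWord(t$value, t$line))
    }
    stop("unexpected token '", t$value, "' at line ", t$line)
  }

  parsePredicates <- function(subject) {
    repeat {
      t <- peek()
      if (is.null(t)) stop("unexpected end of input in predicate list")
      p <- if (t$kind == "uri") advance()$value
           else if (t$kind == "=") { advance(); otURI("owl:sameAs") }
           else if (t$kind == "word") resolveWord(advance()$value, t$line)$value
           else stop("expected predicate at line ", t$line)
      repeat {
        o <- parseObject()
        emit(subject, p, o$value, o$type,
             if (is.null(o$dtype)) NA_character_ else o$dtype)
        if (!is.null(peek()) && peek()$kind == ",") advance() else break
      }
      if (!is.null(peek()) && peek()$kind == ";") {
        advance()
        ## tolerate "; ." trailing separators
        if (!is.null(peek()) && peek()$kind %in% c(".", "]")) break
      } else break
    }
  }

  while (!is.null(peek())) {
    t <- peek()
    if (t$kind == "at" && tolower(t$value) == "@prefix") {
      advance()
      pt <- expect("word")
      pfx <- sub(":$", "", pt$value)
      ut <- expect("uri")
      env$prefixes <- c(stats::setNames(ut$value, pfx),
                        env$prefixes[names(env$prefixes) != pfx])
      expect(".")
      next
    }
    if (t$kind == "word" && toupper(t$value) %in% c("PREFIX", "BASE")) {
      advance()
      pt <- expect("word"); ut <- expect("uri")
      pfx <- sub(":$", "", pt$value)
      env$prefixes <- c(stats::setNames(ut$value, pfx),
                        env$prefixes[names(env$prefixes) != pfx])
      next
    }
    subj <- if (t$kind == "uri") { advance(); t$value }
            else if (t$kind == "[") {
              advance(); b <- newBnode()
              if (!is.null(peek()) && peek()$kind != "]") parsePredicates(b)
              expect("]"); b
            }
            else if (t$kind == "word") {
              w <- advance()
              r <- resolveWord(w$value, w$line)
              r$value
            }
            else stop("expected subject at line ", t$line)
    if (!is.null(peek()) && peek()$kind != ".") parsePredicates(subj)
    expect(".")
  }
  rdfGraph(do.call(rbind, c(list(emptyTriples()), env$rows)))
}
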