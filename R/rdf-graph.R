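#' @import methods
NULL

## Vocabulary namespaces used throughout the OpenTox resource model.
OT_NS <- c(
  ot   = "http://www.opentox.org/api/1.1#",
  ota  = "http://www.opentox.org/algorithmTypes.owl#",
  otee = "http://www.opentox.org/echaEndpoints.owl#",
  bo   = "http://www.blueobelisk.org/ontologies/chemoinformatics-algorithms/#",
  dc   = "http://purl.org/dc/elements/1.1/",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  xsd  = "http://www.w3.org/2001/XMLSchema#"
)

#' Expand a prefixed vocabulary term to a full URI
#'
#' @param qname a term such as \code{"ot:Dataset"} using one of the built-in
#'   prefixes (ot, ota, otee, bo, dc, rdf, rdfs, owl, xsd).
#' @return the full URI as a character scalar.
#' @examples
#' otURI("ot:Feature")
#' @export
otURI <- function(qname) {
  parts <- strsplit(qname, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% names(OT_NS))
    stop("not a known prefixed name: ", qname)
  paste0(OT_NS[[parts[1]]], parts[2])
}

XSD_DOUBLE <- "http://www.w3.org/2001/XMLSchema#double"
XSD_STRING <- "http://www.w3.org/2001/XMLSchema#string"

#' RDFGraph: a set of RDF statements
#'
#' A lightweight triple container: each statement is a row with a subject
#' (URI or blank node label of the form \code{_:b1}), a predicate URI, an
#' object, the object kind (\code{"uri"}, \code{"bnode"} or
#' \code{"literal"}) and, for literals, an optional datatype URI.
#'
#' @slot triples data.frame with columns subject, predicate, object, type,
#'   dtype (character; dtype is \code{NA} for plain literals and non-literals).
#' @export
setClass("RDFGraph", representation(triples = "data.frame"))

emptyTriples <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), type = character(), dtype = character(),
             stringsAsFactors = FALSE)
}

#' Construct an RDF graph
#'
#' @param triples optional data.frame of statements (columns subject,
#'   predicate, object, type, dtype).
#' @return an \linkS4class{RDFGraph}.
#' @export
rdfGraph <- function(triples = emptyTriples()) {
  stopifnot(all(c("subject", "predicate", "object", "type") %in% names(triples)))
  if (is.null(triples$dtype)) triples$dtype <- NA_character_
  triples <- triples[, c("subject", "predicate", "object", "type", "dtype")]
  rownames(triples) <- NULL
  new("RDFGraph", triples = triples)
}

#' Build one statement row
#'
#' @param s,p,o subject, predicate URI, object.
#' @param type object kind: "uri", "bnode" or "literal".
#' @param dtype literal datatype URI or NA.
#' @return one-row data.frame suitable for \code{\link{rdfGraph}}.
#' @export
triple <- function(s, p, o, type = "uri", dtype = NA_character_) {
  data.frame(subject = s, predicate = p, object = as.character(o),
             type = type, dtype = dtype, stringsAsFactors = FALSE)
}

#' @describeIn rdfGraph number of statements
#' @param x an RDFGraph
#' @export
setMethod("length", "RDFGraph", function(x) nrow(x@triples))

#' Statements of a graph
#' @param x an RDFGraph
#' @return the underlying data.frame of statements.
#' @export
statements <- function(x) x@triples

setMethod("show", "RDFGraph", function(object) {
  cat("RDFGraph with", nrow(object@triples), "statements\n")
  if (nrow(object@triples)) {
    n <- min(6L, nrow(object@triples))
    print(utils::head(object@triples[, 1:3], n), row.names = FALSE)
    if (nrow(object@triples) > n) cat("...\n")
  }
})

#' Merge graphs
#'
#' @param ... RDFGraph objects (or statement data.frames).
#' @param deduplicate drop exact duplicate statements.
#' @return the union RDFGraph.
#' @export
graphUnion <- function(..., deduplicate = TRUE) {
  parts <- lapply(list(...), function(g)
    if (is(g, "RDFGraph")) g@triples else g)
  df <- do.call(rbind, c(list(emptyTriples()), parts))
  if (deduplicate) df <- unique(df)
  rdfGraph(df)
}

isBnode <- function(x) startsWith(x, "_:")

graphBnodes <- function(g) {
  tr <- statements(g)
  unique(c(tr$subject[isBnode(tr$subject)],
           tr$object[tr$type == "bnode"]))
}

## key for a triple with bnodes replaced by supplied labels
.tripleKeys <- function(tr, map = NULL) {
  s <- tr$subject
  o <- tr$object
  if (!is.null(map)) {
    bi <- isBnode(s)
    s[bi] <- map[s[bi]]
    bo <- tr$type == "bnode"
    o[bo] <- map[o[bo]]
  }
  paste(s, tr$predicate, o, tr$type, ifelse(is.na(tr$dtype), "", tr$dtype),
        sep = "\r")
}

## Iterative colour refinement of blank nodes: each bnode gets a signature
## built from the (predicate, ground-or-colour) context, repeated until stable.
.refineColours <- function(tr, bnodes) {
  col <- stats::setNames(rep("b", length(bnodes)), bnodes)
  if (!length(bnodes)) return(col)
  repeat {
    sig <- lapply(bnodes, function(b) {
      out <- tr[tr$subject == b, ]
      oo  <- ifelse(out$type == "bnode" & out$object %in% bnodes,
                    col[out$object], out$object)
      inc <- tr[tr$type == "bnode" & tr$object == b, ]
      si  <- ifelse(isBnode(inc$subject), col[inc$subject], inc$subject)
      paste(c(sort(paste("O", out$predicate, oo)),
              sort(paste("I", inc$predicate, si))), collapse = "|")
    })
    ## rank in the sorted signature list is canonical across graphs
    lev <- sort(unique(unlist(sig)))
    newcol <- stats::setNames(vapply(sig, function(s)
      paste0("c", match(s, lev)), ""), bnodes)
    ## combine with previous colour so refinement is monotone
    newcol <- stats::setNames(paste(col, newcol, sep = "."), bnodes)
    if (length(unique(newcol)) == length(unique(col))) return(newcol)
    col <- newcol
  }
}

#' Test whether two graphs are equal up to blank-node relabeling
#'
#' Ground statements are compared as sets; blank nodes are matched by
#' iterative signature refinement, with exhaustive backtracking over any
#' signature ties, so the answer is exact.
#'
#' @param a,b RDFGraph objects.
#' @return TRUE iff the graphs are isomorphic.
#' @export
isomorphicGraphs <- function(a, b) {
  ta <- unique(statements(a)); tb <- unique(statements(b))
  if (nrow(ta) != nrow(tb)) return(FALSE)
  ## fast path: identical under the identity blank-node mapping
  if (identical(sort(.tripleKeys(ta)), sort(.tripleKeys(tb)))) return(TRUE)
  grounded <- function(tr) tr[!isBnode(tr$subject) & tr$type != "bnode", ]
  if (!setequal(.tripleKeys(grounded(ta)), .tripleKeys(grounded(tb))))
    return(FALSE)
  ba <- graphBnodes(a); bb <- graphBnodes(b)
  if (length(ba) != length(bb)) return(FALSE)
  if (!length(ba)) return(TRUE)
  ca <- .refineColours(ta, ba); cb <- .refineColours(tb, bb)
  if (!identical(sort(unname(ca)), sort(unname(cb)))) return(FALSE)
  keyB <- sort(.tripleKeys(tb, map = stats::setNames(bb, bb)))
  ## backtracking over colour classes (classes are almost always singletons)
  classes <- split(ba, ca[ba])
  cand <- lapply(names(classes), function(cl) bb[cb[bb] == cl])
  assign_next <- function(i, map) {
    if (i > length(classes)) {
      full <- unlist(map)
      return(identical(sort(.tripleKeys(ta, map = full)), keyB))
    }
    want <- classes[[i]]
    for (perm in .permutations(cand[[i]])) {
      map[[i]] <- stats::setNames(perm, want)
      if (assign_next(i + 1L, map)) return(TRUE)
    }
    FALSE
  }
  assign_next(1L, vector("list", length(classes)))
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
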