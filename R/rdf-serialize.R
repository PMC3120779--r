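#' Serialize an RDF graph
#'
#' @param graph an \linkS4class{RDFGraph}.
#' @param dialect one of \code{"rdfxml"}, \code{"n3"}, \code{"turtle"}.
#'   RDF/XML is the mandatory interchange representation; the Turtle and N3
#'   output are identical (the writer never uses N3-only shorthand such as
#'   \code{=}).
#' @return serialization as a single character string; re-parsing it yields
#'   a graph isomorphic to \code{graph}.
#' @seealso \code{\link{parseGraph}}, \code{\link{isomorphicGraphs}}
#' @export
serializeGraph <- function(graph, dialect = c("rdfxml", "n3", "turtle")) {
  if (length(dialect) != 1L || !dialect %in% c("rdfxml", "n3", "turtle"))
    stop("unsupported RDF dialect: ", paste(dialect, collapse = "/"))
  switch(dialect,
         rdfxml = writeRDFXML(graph),
         n3 = writeTurtle(graph),
         turtle = writeTurtle(graph))
}

#' Parse an RDF serialization
#'
#' The N3/Turtle reader normalizes the N3 \code{=} shorthand to
#' \code{owl:sameAs} while parsing and accepts blank-node subjects.
#'
#' @param text serialized RDF as a character string.
#' @param dialect one of \code{"rdfxml"}, \code{"n3"}, \code{"turtle"}.
#' @return an \linkS4class{RDFGraph}; syntax errors are reported with the
#'   offending line number.
#' @export
parseGraph <- function(text, dialect = c("rdfxml", "n3", "turtle")) {
  if (length(dialect) != 1L || !dialect %in% c("rdfxml", "n3", "turtle"))
    stop("unsupported RDF dialect: ", paste(dialect, collapse = "/"))
  text <- paste(text, collapse = "\n")
  switch(dialect,
         rdfxml = parseRDFXML(text),
         n3 = parseTurtle(text),
         turtle = parseTurtle(text))
}
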