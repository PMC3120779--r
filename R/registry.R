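## The ontology registry: an aggregating triple store with per-URI
## provenance tagging, RESTful register/deregister and a SPARQL endpoint.
## It is a separate service from the resource store and only ever reads the
## resources it aggregates.

#' Aggregating triple registry
#'
#' Holds one named graph per registered resource URI; queries run over the
#' union. The fetcher dereferences a URI to an RDF graph — by default it is
#' wired to a local \linkS4class{OTStore} dispatcher, mimicking a remote
#' GET with an RDF Accept header.
#'
#' @slot env environment with fields \code{graphs} (named list of
#'   RDFGraph) and \code{fetcher} (function(uri) -> RDFGraph).
#' @export
setClass("OTRegistry", representation(env = "environment"))

#' Create a registry
#'
#' @param fetcher function(uri) returning the RDF graph of the resource;
#'   it must raise an error for unreachable or non-RDF resources.
#' @return an \linkS4class{OTRegistry}.
#' @export
otRegistry <- function(fetcher = NULL) {
  e <- new.env(parent = emptyenv())
  e$graphs <- list()
  e$fetcher <- fetcher
  new("OTRegistry", env = e)
}

#' Fetcher dereferencing URIs against a local store
#' @param store an OTStore.
#' @return function(uri) -> RDFGraph.
#' @export
storeFetcher <- function(store) {
  function(uriString) {
    res <- dispatch(store, "GET", uriString,
                    headers = list(Accept = "application/rdf+xml"))
    if (res$status != 200)
      stop("GET <", uriString, "> failed with status ", res$status)
    if (!identical(res$headers[["Content-Type"]], "application/rdf+xml"))
      stop("<", uriString, "> did not return RDF")
    parseGraph(res$body, "rdfxml")
  }
}

setMethod("show", "OTRegistry", function(object) {
  cat("OTRegistry:", length(object@env$graphs), "registered resource(s),",
      length(registryGraph(object)), "triples\n")
})

#' Union graph of all registered resources
#' @param registry an OTRegistry.
#' @return an \linkS4class{RDFGraph}.
#' @export
registryGraph <- function(registry)
  do.call(graphUnion, c(list(rdfGraph()), unname(registry@env$graphs)))

#' Register a resource: fetch its RDF and merge it into the store
#'
#' Re-registering a URI replaces its previous contribution, so triple
#' counts are unchanged by repeats; a failed fetch leaves the store
#' untouched.
#'
#' @param registry an OTRegistry.
#' @param uriString resource URI (must dereference to RDF).
#' @return invisibly, the number of triples contributed.
#' @export
registerResource <- function(registry, uriString) {
  fetcher <- registry@env$fetcher
  if (is.null(fetcher)) stop("registry has no fetcher configured")
  g <- tryCatch(fetcher(uriString), error = function(e)
    stop(otCondition(400, paste0("registration failed for <", uriString,
                                 ">: ", conditionMessage(e)))))
  registry@env$graphs[[uriString]] <- g
  invisible(length(g))
}

#' Deregister a URI: drop its contribution and every mention of it
#'
#' Removes the triples contributed by the URI and, from other
#' contributions, all triples whose subject or object equals the URI.
#' Idempotent: deregistering an unknown URI succeeds and changes nothing.
#'
#' @param registry an OTRegistry.
#' @param uriString resource URI.
#' @return invisibly, the number of triples removed.
#' @export
deregisterResource <- function(registry, uriString) {
  e <- registry@env
  before <- length(registryGraph(registry))
  e$graphs[[uriString]] <- NULL
  for (src in names(e$graphs)) {
    tr <- statements(e$graphs[[src]])
    keep <- tr$subject != uriString &
      !(tr$type != "literal" & tr$object == uriString)
    if (!all(keep)) e$graphs[[src]] <- rdfGraph(tr[keep, , drop = FALSE])
  }
  invisible(before - length(registryGraph(registry)))
}

#' Run a SPARQL SELECT query over the registry
#'
#' @param registry an OTRegistry.
#' @param query SPARQL SELECT text.
#' @return data.frame of solutions (see \code{\link{sparqlSelect}}).
#' @export
registryQuery <- function(registry, query)
  sparqlSelect(registryGraph(registry), query)

## REST surface of the ontology service:
##   GET  /ontology?query=...           (results as sparql-results+xml)
##   POST /ontology  query=... | uri=...
##   DELETE /ontology?uri=...
registryDispatch <- function(registry, method, params = list(), form = list()) {
  if (method == "GET" || (method == "POST" && !is.null(form$query))) {
    query <- params$query %||% form$query
    if (is.null(query))
      return(otResponse(400, "missing query parameter"))
    sols <- tryCatch(registryQuery(registry, query),
                     otHTTPError = function(e) e)
    if (inherits(sols, "otHTTPError"))
      return(otResponse(sols$status, conditionMessage(sols)))
    return(otResponse(200, sparqlResultsXML(sols),
                      "application/sparql-results+xml"))
  }
  if (method == "POST") {
    if (is.null(form$uri))
      return(otResponse(400, "missing uri parameter"))
    res <- tryCatch(registerResource(registry, form$uri),
                    otHTTPError = function(e) e)
    if (inherits(res, "otHTTPError"))
      return(otResponse(res$status, conditionMessage(res)))
    return(otResponse(200, form$uri))
  }
  if (method == "DELETE") {
    if (is.null(params$uri))
      return(otResponse(400, "missing uri parameter"))
    deregisterResource(registry, params$uri)
    return(otResponse(200, "OK"))
  }
  otResponse(405, "method not allowed; supported: GET, POST, DELETE")
}
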