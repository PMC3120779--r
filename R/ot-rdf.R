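## RDF mapping of the domain types: otTriples() serializes a resource into
## its graph (data entries and feature values as blank nodes, owl:sameAs
## always spelled out, never the N3 "=" shorthand); otFromGraph() is its
## inverse up to graph isomorphism and tolerates third-party statements.

#' Convert a domain resource to an RDF graph
#'
#' @param x an OTFeature, OTDataset, OTModel, OTAlgorithm or OTTask.
#' @param ... method-specific arguments.
#' @return an \linkS4class{RDFGraph} typing the focus node with its ot: class.
#' @export
setGeneric("otTriples", function(x, ...) standardGeneric("otTriples"))

.focusNode <- function(uriString, fallback) {
  if (length(uriString) == 1L && nzchar(uriString)) uriString else fallback
}

.lit <- function(s, p, v, dtype = NA_character_) triple(s, p, v, "literal", dtype)

#' @rdname otTriples
#' @export
setMethod("otTriples", "OTFeature", function(x, ...) {
  validObject(x)
  s <- .focusNode(x@uri, "_:feature")
  rows <- list(triple(s, otURI("rdf:type"), otURI("ot:Feature")))
  if (x@numeric)
    rows <- c(rows, list(triple(s, otURI("rdf:type"), otURI("ot:NumericFeature"))))
  rows <- c(rows, list(.lit(s, otURI("dc:title"), x@title)))
  if (length(x@units))
    rows <- c(rows, list(.lit(s, otURI("ot:units"), x@units)))
  if (length(x@source))
    rows <- c(rows, list(triple(s, otURI("ot:hasSource"), x@source)))
  for (sa in x@sameAs)
    rows <- c(rows, list(triple(s, otURI("owl:sameAs"), sa)))
  df <- do.call(rbind, rows)
  if (nrow(x@extra)) df <- unique(rbind(df, x@extra))
  rdfGraph(df)
})

#' @rdname otTriples
#' @param bnodePrefix label prefix for generated blank nodes.
#' @export
setMethod("otTriples", "OTDataset", function(x, bnodePrefix = "d", ...) {
  s <- .focusNode(x@uri, paste0("_:", bnodePrefix, "s"))
  rows <- list(triple(s, otURI("rdf:type"), otURI("ot:Dataset")))
  if (length(x@title)) rows <- c(rows, list(.lit(s, otURI("dc:title"), x@title)))
  if (length(x@seeAlso))
    rows <- c(rows, list(.lit(s, otURI("rdfs:seeAlso"), x@seeAlso)))
  if (length(x@sourceFile))
    rows <- c(rows, list(.lit(s, otURI("dc:source"), x@sourceFile)))
  k <- 0L
  for (i in seq_along(x@entries)) {
    e <- x@entries[[i]]
    eb <- paste0("_:", bnodePrefix, "e", i)
    rows <- c(rows, list(
      triple(s, otURI("ot:dataEntry"), eb, "bnode"),
      triple(eb, otURI("rdf:type"), otURI("ot:DataEntry")),
      triple(eb, otURI("ot:compound"), e@compound)))
    for (v in e@values) {
      k <- k + 1L
      vb <- paste0("_:", bnodePrefix, "v", k)
      numeric <- is.numeric(v@value)
      rows <- c(rows, list(
        triple(eb, otURI("ot:values"), vb, "bnode"),
        triple(vb, otURI("rdf:type"), otURI("ot:FeatureValue")),
        triple(vb, otURI("ot:feature"), v@feature),
        .lit(vb, otURI("ot:value"), formatValue(v@value),
             if (numeric) XSD_DOUBLE else XSD_STRING)))
    }
  }
  rdfGraph(do.call(rbind, rows))
})

## numeric feature values print like "2.74", never in scientific notation
formatValue <- function(v) {
  if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE, digits = 15)
  else as.character(v)
}

#' @rdname otTriples
#' @export
setMethod("otTriples", "OTAlgorithm", function(x, ...) {
  validObject(x)
  s <- .focusNode(x@uri, "_:algorithm")
  rows <- list(triple(s, otURI("rdf:type"), otURI("ot:Algorithm")))
  for (tp in x@types) rows <- c(rows, list(triple(s, otURI("rdf:type"), tp)))
  rows <- c(rows, list(.lit(s, otURI("dc:title"), x@title)))
  if (length(x@instanceOf))
    rows <- c(rows, list(triple(s, otURI("bo:instanceOf"), x@instanceOf)))
  for (i in seq_len(nrow(x@parameters))) {
    pb <- paste0("_:param", i)
    rows <- c(rows, list(
      triple(s, otURI("ot:parameters"), pb, "bnode"),
      triple(pb, otURI("rdf:type"), otURI("ot:Parameter")),
      .lit(pb, otURI("dc:title"), x@parameters$name[i]),
      .lit(pb, otURI("ot:paramValue"), x@parameters$default[i]),
      .lit(pb, otURI("ot:paramScope"),
           if (x@parameters$required[i]) "mandatory" else "optional")))
  }
  rdfGraph(do.call(rbind, rows))
})

#' @rdname otTriples
#' @export
setMethod("otTriples", "OTModel", function(x, ...) {
  validObject(x)
  s <- .focusNode(x@uri, "_:model")
  rows <- list(triple(s, otURI("rdf:type"), otURI("ot:Model")),
               .lit(s, otURI("dc:title"), x@title),
               triple(s, otURI("ot:algorithm"), x@algorithm))
  if (length(x@trainingDataset))
    rows <- c(rows, list(triple(s, otURI("ot:trainingDataset"), x@trainingDataset)))
  for (f in x@independent)
    rows <- c(rows, list(triple(s, otURI("ot:independentVariables"), f)))
  for (f in x@dependent)
    rows <- c(rows, list(triple(s, otURI("ot:dependentVariables"), f)))
  for (f in x@predicted)
    rows <- c(rows, list(triple(s, otURI("ot:predictedVariables"), f)))
  rdfGraph(do.call(rbind, rows))
})

#' @rdname otTriples
#' @param baseUri service base URI used to mint the task's resource URI.
#' @export
setMethod("otTriples", "OTTask", function(x, baseUri = "", ...) {
  validObject(x)
  s <- if (nzchar(baseUri)) paste0(baseUri, "/task/", x@id) else paste0("_:task")
  rows <- list(triple(s, otURI("rdf:type"), otURI("ot:Task")),
               .lit(s, otURI("ot:hasStatus"), x@status))
  if (length(x@resultUri))
    rows <- c(rows, list(triple(s, otURI("ot:resultURI"), x@resultUri)))
  if (length(x@errorMessage))
    rows <- c(rows, list(.lit(s, otURI("ot:errorReport"), x@errorMessage)))
  rows <- c(rows, list(.lit(s, otURI("dc:date"), formatValue(x@created))))
  rdfGraph(do.call(rbind, rows))
})

## ---- parsing back ----

.objOf <- function(tr, s, p) tr$object[tr$subject == s & tr$predicate == p]

.numericDtypes <- paste0(OT_NS[["xsd"]],
                         c("double", "float", "decimal", "integer", "int", "long"))

#' Reconstruct a domain resource from an RDF graph
#'
#' Inverse of \code{\link{otTriples}} up to graph isomorphism. Extra
#' third-party statements about a feature are retained in its
#' \code{extra} slot; unknown statements elsewhere are ignored.
#'
#' @param graph an \linkS4class{RDFGraph}.
#' @param focus focus node (URI or blank-node label); when NULL the unique
#'   node typed with the expected class is used.
#' @param expected one of "Dataset", "Feature", "Model", "Algorithm", "Task".
#' @return the reconstructed resource object.
#' @export
otFromGraph <- function(graph, focus = NULL,
                        expected = c("Dataset", "Feature", "Model",
                                     "Algorithm", "Task")) {
  expected <- match.arg(expected)
  tr <- statements(graph)
  cls <- otURI(paste0("ot:", expected))
  typed <- tr$subject[tr$predicate == otURI("rdf:type") & tr$object == cls]
  if (is.null(focus)) {
    if (!length(typed)) stop("graph contains no ot:", expected, " node")
    focus <- typed[1]
  } else if (!focus %in% typed) {
    stop("<", focus, "> is not an ot:", expected)
  }
  one <- function(p) {
    v <- .objOf(tr, focus, otURI(p))
    if (length(v)) v[1] else character()
  }
  switch(expected,
    Feature = {
      known <- c(otURI("rdf:type"), otURI("dc:title"), otURI("ot:units"),
                 otURI("ot:hasSource"), otURI("owl:sameAs"))
      mine <- tr[tr$subject == focus, , drop = FALSE]
      extra <- mine[!mine$predicate %in% known, , drop = FALSE]
      otFeature(uri = if (isBnode(focus)) "" else focus,
                title = one("dc:title"),
                units = one("ot:units"),
                source = one("ot:hasSource"),
                sameAs = .objOf(tr, focus, otURI("owl:sameAs")),
                numeric = otURI("ot:NumericFeature") %in%
                  .objOf(tr, focus, otURI("rdf:type")),
                extra = extra)
    },
    Dataset = {
      featureNodes <- tr$subject[tr$predicate == otURI("rdf:type") &
                                   tr$object == otURI("ot:Feature")]
      entryNodes <- .objOf(tr, focus, otURI("ot:dataEntry"))
      entryList <- lapply(entryNodes, function(eb) {
        valueNodes <- .objOf(tr, eb, otURI("ot:values"))
        vals <- lapply(valueNodes, function(vb) {
          f <- .objOf(tr, vb, otURI("ot:feature"))
          if (!length(f)) stop("feature value without ot:feature reference")
          if (!f[1] %in% featureNodes)
            stop("unresolved feature reference: <", f[1], ">")
          vrow <- tr[tr$subject == vb & tr$predicate == otURI("ot:value"), ]
          raw <- vrow$object[1]
          v <- if (!is.na(vrow$dtype[1]) && vrow$dtype[1] %in% .numericDtypes)
            as.numeric(raw) else raw
          otFeatureValue(f[1], v)
        })
        otDataEntry(compound = .objOf(tr, eb, otURI("ot:compound"))[1],
                    values = vals)
      })
      otDataset(uri = if (isBnode(focus)) "" else focus,
                title = one("dc:title"),
                seeAlso = one("rdfs:seeAlso"),
                sourceFile = one("dc:source"),
                entries = entryList)
    },
    Model = otModel(
      uri = if (isBnode(focus)) "" else focus,
      title = one("dc:title"),
      algorithm = one("ot:algorithm"),
      trainingDataset = one("ot:trainingDataset"),
      independent = .objOf(tr, focus, otURI("ot:independentVariables")),
      dependent = .objOf(tr, focus, otURI("ot:dependentVariables")),
      predicted = .objOf(tr, focus, otURI("ot:predictedVariables"))),
    Algorithm = {
      types <- setdiff(.objOf(tr, focus, otURI("rdf:type")), cls)
      paramNodes <- .objOf(tr, focus, otURI("ot:parameters"))
      params <- do.call(rbind, c(list(.emptyParams()), lapply(paramNodes,
        function(pb) data.frame(
          name = .objOf(tr, pb, otURI("dc:title"))[1],
          default = .objOf(tr, pb, otURI("ot:paramValue"))[1],
          required = identical(.objOf(tr, pb, otURI("ot:paramScope"))[1],
                               "mandatory"),
          stringsAsFactors = FALSE))))
      otAlgorithm(uri = if (isBnode(focus)) "" else focus,
                  title = one("dc:title"),
                  types = if (length(types)) types else otURI("ota:Unspecified"),
                  instanceOf = one("bo:instanceOf"),
                  parameters = params)
    },
    Task = {
      status <- one("ot:hasStatus")
      otTask(id = sub(".*/task/", "", focus),
             status = status,
             resultUri = one("ot:resultURI"),
             errorMessage = one("ot:errorReport"),
             created = as.numeric(one("dc:date")))
    })
}
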