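## The REST-style request dispatcher: Table-of-routes binding of the eight
## resource families to the store and algorithm layers, with content
## negotiation, form-encoded parameters and the asynchronous task protocol.
## It is an in-process HTTP analogue: requests are (method, uri, headers,
## body) and responses are (status, headers, body).

.rdfDialect <- function(ctype) {
  d <- .rdfMimes[normalizeMime(ctype %||% "application/rdf+xml")]
  if (is.na(d)) "rdfxml" else unname(d)
}

otResponse <- function(status, body = "", contentType = "text/plain") {
  structure(list(status = status, headers = list(`Content-Type` = contentType),
                 body = body), class = "otResponse")
}

#' @export
print.otResponse <- function(x, ...) {
  cat("HTTP", x$status, "-", x$headers[["Content-Type"]], "\n")
  cat(substr(paste(x$body, collapse = "\n"), 1, 400), "\n")
  invisible(x)
}

parseQueryString <- function(q) {
  if (is.null(q) || !nzchar(q)) return(list())
  parts <- strsplit(q, "&", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    key <- utils::URLdecode(kv[1])
    val <- if (length(kv) > 1L)
      utils::URLdecode(paste(kv[-1], collapse = "=")) else ""
    out[[key]] <- c(out[[key]], val)
  }
  out
}

parseFormBody <- function(body) {
  if (is.null(body) || !nzchar(paste(body, collapse = "")))
    return(list())
  parseQueryString(gsub("\\s+$", "", paste(body, collapse = "&")))
}

## serialize an RDFGraph response honoring Accept (RDF dialects only)
.graphResponse <- function(graph, accept, kind = "resource") {
  b <- tryCatch(resolveMime(accept, kind), error = function(e) e)
  if (inherits(b, "otHTTPError")) return(otResponse(406, conditionMessage(b)))
  if (!b$format %in% c("rdfxml", "n3", "turtle"))
    return(otResponse(406, paste("not an RDF representation:", b$mime)))
  otResponse(200, serializeGraph(graph, b$format), b$mime)
}

## full dataset graph: dataset + features + minimal typing of their sources
datasetGraph <- function(store, d) {
  g <- otTriples(d)
  feats <- datasetFeatures(store, d)
  for (f in feats) g <- graphUnion(g, otTriples(f))
  for (f in feats) {
    if (!length(f@source)) next
    cls <- if (grepl("/algorithm/", f@source)) "ot:Algorithm"
           else if (grepl("/model/", f@source)) "ot:Model"
           else "ot:Dataset"
    g <- graphUnion(g, rdfGraph(triple(f@source, otURI("rdf:type"), otURI(cls))))
  }
  ## type the compounds as well
  curis <- unique(vapply(d@entries, function(e) compoundBaseUri(e@compound), ""))
  for (cu in curis)
    g <- graphUnion(g, rdfGraph(triple(cu, otURI("rdf:type"), otURI("ot:Compound"))))
  g
}

.datasetResponse <- function(store, d, accept) {
  b <- tryCatch(resolveMime(accept, "dataset"), error = function(e) e)
  if (inherits(b, "otHTTPError")) return(otResponse(406, conditionMessage(b)))
  if (b$format %in% c("rdfxml", "n3", "turtle"))
    return(otResponse(200, serializeGraph(datasetGraph(store, d), b$format),
                      b$mime))
  feats <- datasetFeatures(store, d)
  txt <- writeDatasetAs(d, b$format, features = feats,
                        compoundFor = function(u) compoundStructure(store, u))
  otResponse(200, txt, b$mime)
}

.uriListResponse <- function(uris, status = 200)
  otResponse(status, paste0(paste(uris, collapse = "\n"), "\n"),
             "text/uri-list")

## job submission helper: validated params -> 202 + task URI
.acceptTask <- function(store, stages) {
  id <- submitJob(store, stages)
  .uriListResponse(storeUri(store, "task", id), 202)
}

#' Dispatch one REST request against a store
#'
#' Routes the eight resource families (compound, feature, dataset,
#' algorithm, model, task, query, ontology when a registry is attached)
#' plus the admin/database endpoint. Algorithm and model POSTs always
#' return 202 with a task URI; dataset/compound/feature POSTs are
#' synchronous and return the new resource URI as text/uri-list.
#'
#' @param store an OTStore.
#' @param method HTTP verb.
#' @param uriString absolute or path-only request URI (query string allowed).
#' @param headers named list; \code{Accept} and \code{Content-Type} are used.
#' @param body request body (form-encoded parameters for POSTs to
#'   algorithm/model/admin, payload text otherwise).
#' @return an \code{otResponse}: list with status, headers, body.
#' @export
dispatch <- function(store, method, uriString, headers = list(), body = NULL) {
  accept <- headers[["Accept"]] %||% headers[["accept"]]
  ctype <- headers[["Content-Type"]] %||% headers[["content-type"]]
  res <- tryCatch(
    .route(store, toupper(method), uriString, accept, ctype, body),
    otHTTPError = function(e) otResponse(e$status, conditionMessage(e)),
    error = function(e) otResponse(500, conditionMessage(e)))
  if (store@env$autorun) taskRunAll(store)
  res
}

.route <- function(store, method, uriString, accept, ctype, body) {
  root <- serviceRoot(store)
  path <- uriString
  if (startsWith(path, root)) path <- substring(path, nchar(root) + 1L)
  else {
    path <- sub("^https?://[^/]+", "", path)
    pfx <- paste0("/", store@env$service)
    if (startsWith(path, paste0(pfx, "/")) || path == pfx)
      path <- substring(path, nchar(pfx) + 1L)
  }
  q <- NULL
  if (grepl("?", path, fixed = TRUE)) {
    q <- sub("^[^?]*\\?", "", path)
    path <- sub("\\?.*", "", path)
  }
  params <- parseQueryString(q)
  segs <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  family <- if (length(segs)) segs[1] else ""
  id <- if (length(segs) > 1L) segs[2] else NULL
  form <- if (identical(method, "POST") &&
              (is.null(ctype) || startsWith(ctype %||% "",
                                            "application/x-www-form-urlencoded")))
    parseFormBody(body) else list()

  notAllowed <- function(allowed)
    otResponse(405, paste("method not allowed; supported:",
                          paste(allowed, collapse = ", ")))

  switch(family,
    compound = {
      if (method == "POST" && is.null(id)) {
        u <- createCompound(store, body, ctype %||% "chemical/x-mdl-molfile")
        return(.uriListResponse(u))
      }
      if (is.null(id)) return(notAllowed("POST"))
      curi <- storeUri(store, "compound", paste(segs[-1], collapse = "/"))
      if (method == "GET") {
        s <- compoundStructure(store, curi)
        if (is.null(s)) return(otResponse(404, paste("unknown compound:", curi)))
        b <- resolveMime(accept, "compound")
        if (b$format %in% c("rdfxml", "n3", "turtle")) {
          g <- rdfGraph(triple(curi, otURI("rdf:type"), otURI("ot:Compound")))
          return(otResponse(200, serializeGraph(g, b$format), b$mime))
        }
        if (b$format == "uri-list") return(.uriListResponse(curi))
        return(otResponse(200, writeStructure(s, b$format), b$mime))
      }
      if (method == "PUT")
        return(.uriListResponse(updateCompound(store, curi, body,
                                               ctype %||% "chemical/x-mdl-molfile")))
      if (method == "DELETE") {
        deleteResource(store, curi)
        return(otResponse(200, "OK"))
      }
      notAllowed(c("GET", "PUT", "POST", "DELETE"))
    },
    feature = {
      if (method == "POST" && is.null(id)) {
        g <- parseGraph(body, .rdfDialect(ctype))
        f <- otFromGraph(g, expected = "Feature")
        f@uri <- ""  # server assigns the URI
        return(.uriListResponse(adoptFeature(store, f)))
      }
      if (is.null(id)) return(notAllowed("POST"))
      furi <- storeUri(store, "feature", id)
      f <- store@env$features[[furi]]
      if (method == "GET") {
        if (is.null(f)) return(otResponse(404, paste("unknown feature:", furi)))
        return(.graphResponse(otTriples(f), accept))
      }
      if (method == "PUT") {
        if (is.null(f)) return(otResponse(404, paste("unknown feature:", furi)))
        g <- parseGraph(body, .rdfDialect(ctype))
        nf <- otFromGraph(g, expected = "Feature")
        nf@uri <- furi
        store@env$features[[furi]] <- nf
        src <- if (length(nf@source)) nf@source else ""
        store@env$featureKey[paste(nf@title, src, sep = "\r")] <- furi
        return(.uriListResponse(furi))
      }
      if (method == "DELETE") {
        deleteResource(store, furi)
        return(otResponse(200, "OK"))
      }
      notAllowed(c("GET", "PUT", "POST", "DELETE"))
    },
    dataset = {
      if (method == "POST" && is.null(id)) {
        d <- createDataset(store, body, ctype %||% "chemical/x-mdl-sdfile")
        return(.uriListResponse(d@uri))
      }
      if (is.null(id)) return(notAllowed("POST"))
      duri <- storeUri(store, "dataset", id)
      if (method == "GET") {
        filter <- params[["feature_uris[]"]]
        d <- getDataset(store, duri, featureFilter = filter)
        return(.datasetResponse(store, d, accept))
      }
      if (method == "PUT")
        return(.uriListResponse(
          mergeIntoDataset(store, duri, body, ctype %||% "chemical/x-mdl-sdfile")))
      if (method == "DELETE") {
        deleteResource(store, duri)
        return(otResponse(200, "OK"))
      }
      notAllowed(c("GET", "PUT", "POST", "DELETE"))
    },
    algorithm = {
      if (is.null(id)) {
        if (method == "GET") return(.uriListResponse(listAlgorithms(store)))
        return(notAllowed("GET"))
      }
      auri <- storeUri(store, "algorithm", paste(segs[-1], collapse = "/"))
      rec <- algRecord(store, auri)
      if (is.null(rec))
        return(otResponse(404, paste("unknown algorithm:", auri)))
      if (method == "GET") return(.graphResponse(otTriples(rec$spec), accept))
      if (method == "POST") {
        dsUri <- form$dataset_uri %||% NULL
        if (rec$kind != "rule" && is.null(dsUri))
          stop(otCondition(400, "missing required parameter dataset_uri"))
        stages <- switch(rec$kind,
          descriptor = list(function(x) getDataset(store, dsUri),
                            function(x) calcDescriptors(store, auri, dsUri)),
          learner = list(function(x) getDataset(store, dsUri),
                         function(x) buildModel(store, auri, dsUri,
                                                form$prediction_feature %||% NULL,
                                                params = form)),
          rule = list(function(x) buildRuleModel(store, auri)),
          domain = list(function(x) getDataset(store, dsUri),
                        function(x) buildDomainModel(store, sub(".*/", "", auri),
                                                     dsUri, params = form)),
          superservice = {
            if (is.null(form$model_uri))
              stop(otCondition(400, "missing required parameter model_uri"))
            list(function(x) getDataset(store, dsUri),
                 function(x) superservice(store, form$model_uri, dsUri))
          },
          fingerprints = list(function(x) {
            d <- getDataset(store, dsUri)
            for (e in d@entries) {
              s <- compoundStructure(store, e@compound)
              if (!is.null(s))
                store@env$fpCache[[e@compound]] <- fingerprint(s)
            }
            dsUri
          }),
          smartsprop = list(function(x) {
            d <- getDataset(store, dsUri)
            for (e in d@entries) {
              s <- compoundStructure(store, e@compound)
              if (!is.null(s))
                store@env$keyCache[[e@compound]] <- table(s@atoms$element)
            }
            dsUri
          }))
        return(.acceptTask(store, stages))
      }
      notAllowed(c("GET", "POST"))
    },
    model = {
      if (is.null(id)) return(notAllowed("none"))
      muri <- storeUri(store, "model", id)
      if (method == "GET") {
        m <- store@env$models[[muri]]
        if (is.null(m)) return(otResponse(404, paste("unknown model:", muri)))
        return(.graphResponse(otTriples(m), accept))
      }
      if (method == "POST") {
        m <- store@env$models[[muri]]
        if (is.null(m)) return(otResponse(404, paste("unknown model:", muri)))
        dsUri <- form$dataset_uri %||% form$compound_uri %||% NULL
        if (is.null(dsUri))
          stop(otCondition(400, "missing required parameter dataset_uri"))
        return(.acceptTask(store, list(
          function(x) TRUE,
          function(x) applyModel(store, muri, dsUri))))
      }
      if (method == "DELETE") {
        deleteResource(store, muri)
        return(otResponse(200, "OK"))
      }
      notAllowed(c("GET", "POST", "DELETE"))
    },
    task = {
      if (is.null(id)) return(notAllowed("none"))
      t <- getTask(store, id)
      if (method == "GET") {
        if (is.null(t)) return(otResponse(404, paste("unknown task:", id)))
        return(switch(t@status,
          Completed = .uriListResponse(t@resultUri, 200),
          Cancelled = otResponse(200, paste("task", id, "Cancelled")),
          Error = otResponse(500, t@errorMessage),
          .uriListResponse(storeUri(store, "task", id), 202)))
      }
      if (method == "DELETE") {
        if (is.null(t)) return(otResponse(404, paste("unknown task:", id)))
        cancelTask(store, id)
        return(otResponse(200, "OK"))
      }
      notAllowed(c("GET", "DELETE"))
    },
    query = {
      if (method != "GET") return(notAllowed("GET"))
      if (length(segs) < 3L || segs[2] != "compound")
        return(otResponse(404, "unknown query resource"))
      identifier <- utils::URLdecode(segs[3])
      results <- if (length(segs) >= 4L) segs[4] else "all"
      if (!results %in% c("names", "smiles", "stdinchi", "stdinchikey", "all"))
        return(otResponse(400, paste("unknown results mode:", results)))
      d <- searchCompounds(store, identifier, results,
                           searchParam = params[["search"]] %||% NULL)
      ident <- function(u) {
        rec <- store@env$compounds[[localCompoundId(store, u)]]
        switch(results,
          names = rec$identifiers$name %||% "",
          smiles = rec$identifiers$smiles,
          stdinchi = rec$identifiers$inchi,
          stdinchikey = rec$identifiers$inchikey,
          all = u)
      }
      b <- tryCatch(resolveMime(accept, "compound"), error = function(e) e)
      if (inherits(b, "otHTTPError")) return(otResponse(406, conditionMessage(b)))
      if (b$format %in% c("rdfxml", "n3", "turtle"))
        return(.datasetResponse(store, d, accept))
      if (results != "all" || b$format %in% c("uri-list", "plain")) {
        lines <- vapply(entries(d), function(e)
          as.character(ident(e@compound)), "")
        return(otResponse(200, paste0(paste(lines, collapse = "\n"), "\n"),
                          b$mime))
      }
      .datasetResponse(store, d, accept)
    },
    admin = {
      if (length(segs) < 2L || segs[2] != "database")
        return(otResponse(404, "unknown admin resource"))
      if (method == "POST") {
        form <- parseFormBody(body)
        dbname <- trimws(form$dbname %||% "")
        if (!nzchar(dbname))
          return(otResponse(400, "missing dbname parameter"))
        if (!nzchar(trimws(form$user %||% "")))
          return(otResponse(401, "missing or bad credentials"))
        if (!is.null(store@env$dbname))
          return(otResponse(409, paste("database already exists:",
                                       store@env$dbname)))
        store@env$dbname <- dbname
        return(otResponse(200, dbname))
      }
      if (method == "GET") {
        if (is.null(store@env$dbname))
          return(otResponse(404, "no database created yet"))
        return(otResponse(200, store@env$dbname))
      }
      notAllowed(c("GET", "POST"))
    },
    ontology = {
      reg <- store@env$registry
      if (is.null(reg))
        return(otResponse(404, "no ontology service attached"))
      return(registryDispatch(reg, method, params,
                              if (identical(method, "POST"))
                                parseFormBody(body) else list()))
    },
    otResponse(404, paste("unknown resource:", uriString)))
}

#' Attach an ontology registry to a store's /ontology route
#' @param store an OTStore.
#' @param registry an \linkS4class{OTRegistry}.
#' @export
attachRegistry <- function(store, registry) {
  store@env$registry <- registry
  invisible(store)
}
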