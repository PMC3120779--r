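## The resource store: compounds, features, datasets, models and tasks with
## sequential ids, URI dereferencing, the feature auto-creation rule for
## file imports, query objects and cascade deletion. State lives in an
## environment slot so one store object can be threaded through the REST
## dispatcher.

#' Resource store
#'
#' Holds every local resource of one service instance. Resource URIs follow
#' \code{\{base\}/\{service\}/\{family\}/\{id\}} with sequential integer ids
#' (tasks use UUIDs).
#'
#' @slot env environment holding all mutable state.
#' @export
setClass("OTStore", representation(env = "environment"))

#' Create an empty resource store
#'
#' @param baseUri base URI of the service host.
#' @param service service prefix (defaults to "ambit2").
#' @param workers reserved; the task queue runs one cooperative worker.
#' @param autorun when TRUE, queued tasks are executed as soon as they are
#'   submitted (after the 202 response is composed); set FALSE to drive the
#'   queue manually with \code{\link{taskStep}}.
#' @return an \linkS4class{OTStore}.
#' @export
otStore <- function(baseUri = "http://localhost:8080", service = "ambit2",
                    workers = 1L, autorun = TRUE) {
  e <- new.env(parent = emptyenv())
  e$base <- sub("/$", "", baseUri)
  e$service <- service
  e$counters <- c(compound = 0L, conformer = 0L, dataset = 0L,
                  feature = 0L, model = 0L)
  e$compounds <- list()
  e$features <- list()
  e$featureKey <- character()   # "title\rsource" -> feature URI
  e$datasets <- list()
  e$models <- list()
  e$algorithms <- list()
  e$tasks <- list()
  e$taskQueue <- character()
  e$autorun <- isTRUE(autorun)
  e$dbname <- NULL
  e$invocations <- character()  # algorithm URIs invoked (instrumentation)
  st <- new("OTStore", env = e)
  registerBuiltinAlgorithms(st)
  st
}

setMethod("show", "OTStore", function(object) {
  e <- object@env
  cat("OTStore at", serviceRoot(object), "\n")
  cat(" ", length(e$compounds), "compounds,", length(e$features), "features,",
      length(e$datasets), "datasets,", length(e$models), "models,",
      length(e$algorithms), "algorithms,", length(e$tasks), "tasks\n")
})

#' Service root URI (base + service prefix)
#' @param store an OTStore.
#' @export
serviceRoot <- function(store) paste0(store@env$base, "/", store@env$service)

storeUri <- function(store, family, id)
  paste0(serviceRoot(store), "/", family, "/", id)

nextId <- function(store, family) {
  store@env$counters[[family]] <- store@env$counters[[family]] + 1L
  store@env$counters[[family]]
}

## strip an optional /conformer/{k} suffix to get the compound URI
compoundBaseUri <- function(uri) sub("/conformer/[0-9]+$", "", uri)

localCompoundId <- function(store, uri) {
  root <- paste0(serviceRoot(store), "/compound/")
  u <- compoundBaseUri(uri)
  if (!startsWith(u, root)) return(NA_character_)
  sub("/.*", "", substring(u, nchar(root) + 1L))
}

#' Look up the structure behind a compound or conformer URI
#'
#' @param store an OTStore.
#' @param uri compound or conformer URI.
#' @return a \linkS4class{Structure} or NULL for unknown/remote URIs.
#' @export
compoundStructure <- function(store, uri) {
  force(uri)
  id <- localCompoundId(store, uri)
  rec <- store@env$compounds[[id]]
  if (is.null(rec)) return(NULL)
  k <- if (grepl("/conformer/", uri))
    match(sub(".*/conformer/", "", uri), names(rec$conformers)) else 1L
  if (is.na(k)) return(NULL)
  rec$conformers[[k]]
}

.computeIdentifiers <- function(s) {
  ids <- list(
    formula = molecularFormula(s),
    smiles = tryCatch(canonicalSmiles(s), error = function(e) NA_character_),
    inchi = tryCatch(structureInChI(s), error = function(e) NA_character_),
    inchikey = tryCatch(structureInChIKey(s), error = function(e) NA_character_))
  nm <- s@properties[tolower(names(s@properties)) %in% c("name", "chemical name")]
  ids$name <- if (length(nm)) unname(nm[1]) else NA_character_
  reg <- s@properties[tolower(names(s@properties)) %in%
                        c("cas", "casrn", "registry", "regid")]
  ids$registry <- if (length(reg)) unname(reg[1]) else NA_character_
  ids
}

#' Create a compound resource
#'
#' Each POST creates a new compound (non-idempotent): a fresh sequential id
#' is assigned and identifiers (formula, canonical SMILES, InChI, InChIKey,
#' name) are derived from the first conformer.
#'
#' @param store an OTStore.
#' @param payload structure text.
#' @param mime payload format; must parse to exactly one structure
#'   (multi-record files belong to the dataset service).
#' @return the new compound URI.
#' @export
createCompound <- function(store, payload, mime) {
  structs <- readStructures(payload, mime)
  if (length(structs) != 1L)
    stop(otCondition(400, paste0("compound POST requires exactly one ",
                                 "structure, got ", length(structs),
                                 " (datasets take files)")))
  id <- nextId(store, "compound")
  cid <- nextId(store, "conformer")
  rec <- list(conformers = stats::setNames(structs, cid),
              identifiers = .computeIdentifiers(structs[[1]]))
  store@env$compounds[[as.character(id)]] <- rec
  storeUri(store, "compound", id)
}

#' Add a conformer to an existing compound (PUT semantics)
#'
#' @param store an OTStore.
#' @param uri compound URI.
#' @param payload,mime one structure.
#' @return the compound URI.
#' @export
updateCompound <- function(store, uri, payload, mime) {
  id <- localCompoundId(store, uri)
  if (is.na(id) || is.null(store@env$compounds[[id]]))
    stop(otCondition(404, paste("unknown compound:", uri)))
  structs <- readStructures(payload, mime)
  if (length(structs) != 1L)
    stop(otCondition(400, "compound PUT requires exactly one structure"))
  ## idempotent: an identical conformer (same InChI) is not duplicated
  rec <- store@env$compounds[[id]]
  newInchi <- tryCatch(structureInChI(structs[[1]]), error = function(e) "")
  have <- vapply(rec$conformers, function(s)
    tryCatch(structureInChI(s), error = function(e) ""), "")
  if (!newInchi %in% have) {
    cid <- nextId(store, "conformer")
    rec$conformers[[as.character(cid)]] <- structs[[1]]
    store@env$compounds[[id]] <- rec
  }
  uri
}

## feature auto-creation: (title, source) is a unique key
ensureFeature <- function(store, title, source, numeric = FALSE,
                          units = character(), sameAs = character()) {
  key <- paste(title, source, sep = "\r")
  hit <- store@env$featureKey[key]
  if (!is.na(hit)) return(unname(hit))
  id <- nextId(store, "feature")
  u <- storeUri(store, "feature", id)
  store@env$features[[u]] <- otFeature(uri = u, title = title, units = units,
                                       source = source, sameAs = sameAs,
                                       numeric = numeric)
  store@env$featureKey[key] <- u
  u
}

## register a feature carrying its own (possibly remote) URI, as supplied
## in client RDF: "the client has full control of the fields' representation"
adoptFeature <- function(store, feature) {
  u <- feature@uri
  if (!nzchar(u)) {
    id <- nextId(store, "feature")
    u <- storeUri(store, "feature", id)
    feature@uri <- u
  }
  store@env$features[[u]] <- feature
  src <- if (length(feature@source)) feature@source else ""
  store@env$featureKey[paste(feature@title, src, sep = "\r")] <- u
  u
}

.isDecimal <- function(x) grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$",
                                trimws(x))

#' Create a dataset resource from an uploaded file or RDF graph
#'
#' For non-RDF input one compound is created per record and one feature per
#' distinct field name, titled by the field name with \code{ot:hasSource}
#' set to the new dataset URI; the (title, source) pair is a unique key, so
#' re-encountering a field within the upload reuses its feature. A feature
#' is numeric iff every non-empty imported value parses as a decimal. For
#' RDF input the client's feature URIs and annotations are honored.
#'
#' @param store an OTStore.
#' @param payload file content.
#' @param mime chemical or RDF MIME type.
#' @param sourceFile optional originating file name (dc:source).
#' @return the persisted \linkS4class{OTDataset} (with URI assigned).
#' @export
createDataset <- function(store, payload, mime, sourceFile = character()) {
  fmt <- normalizeMime(mime)
  id <- nextId(store, "dataset")
  duri <- storeUri(store, "dataset", id)
  if (fmt %in% names(.rdfMimes)) {
    g <- parseGraph(payload, .rdfMimes[[fmt]])
    d <- otFromGraph(g, expected = "Dataset")
    tr <- statements(g)
    fnodes <- unique(tr$subject[tr$predicate == otURI("rdf:type") &
                                  tr$object == otURI("ot:Feature")])
    for (fn in fnodes)
      adoptFeature(store, otFromGraph(g, fn, "Feature"))
    d@uri <- duri
    store@env$datasets[[duri]] <- d
    return(d)
  }
  structs <- readStructures(payload, fmt)
  ## value typing scans the whole column before features are created
  fieldNames <- unique(unlist(lapply(structs, function(s) names(s@properties))))
  numericField <- vapply(fieldNames, function(fn) {
    vals <- unlist(lapply(structs, function(s) s@properties[fn]))
    vals <- vals[!is.na(vals) & nzchar(vals)]
    length(vals) > 0L && all(.isDecimal(vals))
  }, TRUE)
  furis <- stats::setNames(vapply(fieldNames, function(fn)
    ensureFeature(store, fn, duri, numeric = numericField[[fn]]), ""),
    fieldNames)
  entryList <- lapply(structs, function(s) {
    id <- nextId(store, "compound")
    cid <- nextId(store, "conformer")
    store@env$compounds[[as.character(id)]] <-
      list(conformers = stats::setNames(list(s), cid),
           identifiers = .computeIdentifiers(s))
    vals <- lapply(names(s@properties), function(fn) {
      raw <- s@properties[[fn]]
      otFeatureValue(furis[[fn]],
                     if (numericField[[fn]] && nzchar(trimws(raw)))
                       as.numeric(raw) else raw)
    })
    vals <- vals[!vapply(vals, is.null, TRUE)]
    otDataEntry(storeUri(store, "compound", id), vals)
  })
  d <- otDataset(uri = duri, sourceFile = sourceFile, entries = entryList)
  store@env$datasets[[duri]] <- d
  d
}

#' Merge new compounds and/or properties into a dataset (PUT semantics)
#'
#' Union semantics: existing entries and values are retained, records whose
#' structure (by InChI) is already present merge into the existing entry,
#' new structures append entries, new field names become new features.
#' Values are only ever added, never removed or overwritten, so an
#' identical PUT is a no-op.
#'
#' @param store an OTStore.
#' @param datasetUri existing dataset URI.
#' @param payload,mime as in \code{\link{createDataset}}.
#' @return the dataset URI.
#' @export
mergeIntoDataset <- function(store, datasetUri, payload, mime) {
  d <- store@env$datasets[[datasetUri]]
  if (is.null(d)) stop(otCondition(404, paste("unknown dataset:", datasetUri)))
  structs <- readStructures(payload, mime)
  fieldNames <- unique(unlist(lapply(structs, function(s) names(s@properties))))
  numericField <- vapply(fieldNames, function(fn) {
    vals <- unlist(lapply(structs, function(s) s@properties[fn]))
    vals <- vals[!is.na(vals) & nzchar(vals)]
    length(vals) > 0L && all(.isDecimal(vals))
  }, TRUE)
  furis <- stats::setNames(vapply(fieldNames, function(fn)
    ensureFeature(store, fn, datasetUri, numeric = numericField[[fn]]), ""),
    fieldNames)
  entryInchi <- vapply(d@entries, function(e) {
    s <- compoundStructure(store, e@compound)
    if (is.null(s)) "" else tryCatch(structureInChI(s), error = function(e2) "")
  }, "")
  for (s in structs) {
    si <- tryCatch(structureInChI(s), error = function(e) "@new")
    hit <- if (si != "@new") match(si, entryInchi) else NA_integer_
    mkVals <- function(existingFeats) {
      keep <- setdiff(names(s@properties), names(furis)[
        furis %in% existingFeats])
      lapply(keep, function(fn) {
        raw <- s@properties[[fn]]
        otFeatureValue(furis[[fn]],
                       if (numericField[[fn]] && nzchar(trimws(raw)))
                         as.numeric(raw) else raw)
      })
    }
    if (!is.na(hit)) {
      e <- d@entries[[hit]]
      have <- vapply(e@values, function(v) v@feature, "")
      e@values <- c(e@values, mkVals(have))
      d@entries[[hit]] <- e
    } else {
      id <- nextId(store, "compound")
      cid <- nextId(store, "conformer")
      store@env$compounds[[as.character(id)]] <-
        list(conformers = stats::setNames(list(s), cid),
             identifiers = .computeIdentifiers(s))
      d@entries[[length(d@entries) + 1L]] <-
        otDataEntry(storeUri(store, "compound", id), mkVals(character()))
      entryInchi <- c(entryInchi, si)
    }
  }
  store@env$datasets[[datasetUri]] <- d
  datasetUri
}

## resolve /model/{id}/predicted alias URIs inside a feature filter
resolveFeatureAlias <- function(store, uris) {
  unlist(lapply(uris, function(u) {
    m <- regmatches(u, regexec("^(.*/model/[^/?]+)/predicted$", u))[[1]]
    if (length(m)) {
      mod <- store@env$models[[m[2]]]
      if (!is.null(mod)) return(mod@predicted)
    }
    u
  }))
}

#' Retrieve a dataset, optionally filtered to selected features
#'
#' @param store an OTStore.
#' @param datasetUri dataset URI (query strings are stripped).
#' @param featureFilter optional feature URIs; \code{/model/\{id\}/predicted}
#'   aliases resolve to that model's predicted features; unknown URIs are
#'   ignored (entries are then listed without values).
#' @return an \linkS4class{OTDataset}.
#' @export
getDataset <- function(store, datasetUri, featureFilter = NULL) {
  ## force arguments before reading the environment: a caller may pass an
  ## expression whose evaluation mutates the store (lazy-evaluation hazard)
  force(datasetUri); force(featureFilter)
  d <- store@env$datasets[[sub("\\?.*", "", datasetUri)]]
  if (is.null(d)) stop(otCondition(404, paste("unknown dataset:", datasetUri)))
  if (is.null(featureFilter) && grepl("?", datasetUri, fixed = TRUE)) {
    ## a filter embedded in the URI query string applies as well
    q <- parseQueryString(sub("^[^?]*\\?", "", datasetUri))
    featureFilter <- q[["feature_uris[]"]]
  }
  if (is.null(featureFilter)) return(d)
  keep <- resolveFeatureAlias(store, featureFilter)
  d@entries <- lapply(d@entries, function(e) {
    e@values <- Filter(function(v) v@feature %in% keep, e@values)
    e
  })
  d
}

#' Features used by a dataset (for representation output)
#' @param store an OTStore.
#' @param d an OTDataset.
#' @return list of \linkS4class{OTFeature} (known features referenced by d).
#' @export
datasetFeatures <- function(store, d) {
  furis <- unique(unlist(lapply(d@entries, function(e)
    vapply(e@values, function(v) v@feature, ""))))
  feats <- store@env$features[furis[furis %in% names(store@env$features)]]
  ## remote features referenced only by values are represented minimally
  unknown <- setdiff(furis, names(store@env$features))
  c(unname(feats), lapply(unknown, function(u)
    otFeature(uri = u, title = u)))
}

#' Search compounds by identifier
#'
#' Case-insensitive exact match against stored identifiers (name, formula,
#' registry id, SMILES, InChI, InChIKey). The special identifier
#' \code{"url"} requires \code{searchParam} (a compound URI).
#'
#' @param store an OTStore.
#' @param identifier the search string or "url".
#' @param resultsMode one of names, smiles, stdinchi, stdinchikey, all
#'   (controls the representation, not the matching).
#' @param searchParam compound URI for identifier = "url".
#' @return an unpersisted \linkS4class{OTDataset} listing the matches.
#' @export
searchCompounds <- function(store, identifier,
                            resultsMode = c("all", "names", "smiles",
                                            "stdinchi", "stdinchikey"),
                            searchParam = NULL) {
  resultsMode <- match.arg(resultsMode)
  if (identical(tolower(identifier), "url")) {
    if (is.null(searchParam))
      stop(otCondition(400, "identifier 'url' requires a ?search= parameter"))
    id <- localCompoundId(store, searchParam)
    hits <- if (!is.na(id) && !is.null(store@env$compounds[[id]])) id
            else character()
  } else {
    q <- tolower(identifier)
    hits <- names(Filter(function(rec)
      q %in% tolower(stats::na.omit(unlist(rec$identifiers))),
      store@env$compounds))
  }
  entriesList <- lapply(hits, function(id)
    otDataEntry(storeUri(store, "compound", id), list()))
  otDataset(title = paste0("Query results: ", identifier), entries = entriesList)
}

#' Run a query through the batch-processing pipeline
#'
#' The query object is resolved to a stream of compound records; each record
#' is transformed by \code{processor} and immediately serialized by the
#' reporter for \code{mime}, so adding a query kind or an output format
#' never touches the pipeline itself.
#'
#' @param store an OTStore.
#' @param query list with \code{kind} (by_id, by_identifier, similarity,
#'   substructure) and kind-specific \code{parameters}.
#' @param processor function(compoundUri, Structure) returning the
#'   (possibly transformed) structure, or NULL to keep it as is.
#' @param mime output MIME for the reporter (uri-list, smiles, sdf, csv).
#' @return the serialized output text.
#' @export
batchProcess <- function(store, query, processor = NULL, mime = "uri-list") {
  kind <- query$kind
  p <- query$parameters %||% list()
  uris <- switch(kind,
    by_id = storeUri(store, "compound", p$id),
    by_identifier = vapply(entries(searchCompounds(store, p$identifier)),
                           function(e) e@compound, ""),
    similarity = {
      if (is.null(p$structure) || is.null(p$threshold))
        stop(otCondition(400, "similarity query needs structure + threshold"))
      qfp <- fingerprint(p$structure)
      ids <- names(store@env$compounds)
      sims <- vapply(ids, function(id) {
        s <- store@env$compounds[[id]]$conformers[[1]]
        tanimoto(qfp, fingerprint(s))
      }, 0)
      keep <- sims >= p$threshold
      storeUri(store, "compound", ids[keep][order(-sims[keep])])
    },
    substructure = {
      if (is.null(p$smarts))
        stop(otCondition(400, "substructure query needs a SMARTS pattern"))
      ids <- names(store@env$compounds)
      hits <- vapply(ids, function(id)
        smartsMatch(store@env$compounds[[id]]$conformers[[1]], p$smarts), TRUE)
      storeUri(store, "compound", ids[hits])
    },
    stop(otCondition(400, paste("unknown query kind:", kind))))
  if (!length(uris)) return("")
  out <- character()
  for (k in seq_along(uris)) {
    u <- uris[[k]]
    s <- compoundStructure(store, u)
    rec <- tryCatch({
      if (!is.null(processor)) {
        t <- processor(u, s)
        if (!is.null(t)) s <- t
      }
      switch(normalizeMime(mime),
        "text/uri-list" = u,
        "chemical/x-daylight-smiles" = paste0(canonicalSmiles(s), "\t", u),
        "chemical/x-mdl-sdfile" = sub("\n$", "", writeSDF(list(s), titles = u)),
        "text/csv" = paste0(u, ",", canonicalSmiles(s)),
        stop(otCondition(415, paste("unsupported reporter format:", mime))))
    }, error = function(e)
      stop(otCondition(500, paste0("processing failed at record ", k, " <",
                                   u, ">: ", conditionMessage(e)))))
    out <- c(out, rec)
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Delete a local resource with cascade integrity
#'
#' Deleting a dataset removes its entries and every feature whose source is
#' the dataset; deleting a feature removes its values everywhere (with a
#' warning when other datasets are affected); deleting a model removes the
#' features it predicts. Remote references are not checked.
#'
#' @param store an OTStore.
#' @param uriString resource URI.
#' @return invisible TRUE.
#' @export
deleteResource <- function(store, uriString) {
  e <- store@env
  root <- serviceRoot(store)
  m <- regmatches(uriString,
                  regexec(paste0("^", root, "/([a-z]+)/([^/?]+)"), uriString))[[1]]
  if (!length(m)) stop(otCondition(404, paste("not a local resource:", uriString)))
  family <- m[2]; id <- m[3]
  dropFeature <- function(furi, quiet = FALSE) {
    touched <- FALSE
    for (duri in names(e$datasets)) {
      d <- e$datasets[[duri]]
      changed <- FALSE
      d@entries <- lapply(d@entries, function(en) {
        n0 <- length(en@values)
        en@values <- Filter(function(v) v@feature != furi, en@values)
        if (length(en@values) != n0) changed <<- TRUE
        en
      })
      if (changed) { e$datasets[[duri]] <- d; touched <- TRUE }
    }
    if (touched && !quiet)
      warning("removed values of deleted feature <", furi,
              "> from dependent dataset(s)")
    e$featureKey <- e$featureKey[e$featureKey != furi]
    e$features[[furi]] <- NULL
  }
  switch(family,
    compound = {
      if (is.null(e$compounds[[id]]))
        stop(otCondition(404, paste("unknown compound:", uriString)))
      curi <- storeUri(store, "compound", id)
      e$compounds[[id]] <- NULL
      for (duri in names(e$datasets)) {
        d <- e$datasets[[duri]]
        d@entries <- Filter(function(en)
          compoundBaseUri(en@compound) != curi, d@entries)
        e$datasets[[duri]] <- d
      }
    },
    feature = {
      furi <- storeUri(store, "feature", id)
      if (is.null(e$features[[furi]]))
        stop(otCondition(404, paste("unknown feature:", uriString)))
      dropFeature(furi)
    },
    dataset = {
      duri <- storeUri(store, "dataset", id)
      if (is.null(e$datasets[[duri]]))
        stop(otCondition(404, paste("unknown dataset:", uriString)))
      e$datasets[[duri]] <- NULL
      owned <- names(Filter(function(f)
        length(f@source) && f@source == duri, e$features))
      for (furi in owned) dropFeature(furi, quiet = TRUE)
    },
    model = {
      muri <- storeUri(store, "model", id)
      if (is.null(e$models[[muri]]))
        stop(otCondition(404, paste("unknown model:", uriString)))
      predicted <- e$models[[muri]]@predicted
      e$models[[muri]] <- NULL
      for (furi in intersect(predicted, names(e$features)))
        dropFeature(furi, quiet = TRUE)
    },
    task = {
      if (is.null(e$tasks[[id]]))
        stop(otCondition(404, paste("unknown task:", uriString)))
      e$tasks[[id]] <- NULL
    },
    stop(otCondition(405, paste("resources of family", family,
                                "cannot be deleted"))))
  invisible(TRUE)
}

#' Snapshot checksum of the entire store state
#'
#' Used to assert that safe operations (GET) never mutate state.
#' @param store an OTStore.
#' @return md5 string of the serialized state.
#' @export
storeChecksum <- function(store) {
  tf <- tempfile()
  on.exit(unlink(tf))
  e <- store@env
  saveRDS(list(e$counters, e$compounds, e$features, e$featureKey,
               e$datasets, e$models, names(e$algorithms)), tf)
  unname(tools::md5sum(tf))
}
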