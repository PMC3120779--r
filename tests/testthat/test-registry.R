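localSetup <- function() {
  st <- newStore()
  reg <- makeRegressionDataset(st, 6, 2, noiseSd = 0, seed = 1)
  lr <- paste0(serviceRoot(st), "/algorithm/LR")
  muri <- buildModel(st, lr, reg$datasetUri, reg$target)
  registry <- otRegistry(fetcher = storeFetcher(st))
  attachRegistry(st, registry)
  list(st = st, registry = registry, muri = muri)
}

test_that("registration aggregates dereferenced RDF with per-URI provenance", {
  x <- localSetup()
  registerResource(x$registry, x$muri)
  tr <- statements(registryGraph(x$registry))
  expect_true(any(tr$subject == x$muri & tr$predicate == otURI("rdf:type") &
                    tr$object == otURI("ot:Model")))
  n1 <- length(registryGraph(x$registry))
  ## re-registration replaces, never duplicates
  registerResource(x$registry, x$muri)
  expect_equal(length(registryGraph(x$registry)), n1)
  ## unreachable resources leave the store untouched
  before <- length(registryGraph(x$registry))
  expect_error(registerResource(x$registry,
                                paste0(serviceRoot(x$st), "/model/999")),
               "registration failed")
  expect_equal(length(registryGraph(x$registry)), before)
})

test_that("deregistration removes the contribution and all mentions of the URI", {
  x <- localSetup()
  lrUri <- paste0(serviceRoot(x$st), "/algorithm/LR")
  registerResource(x$registry, x$muri)
  registerResource(x$registry, lrUri)
  deregisterResource(x$registry, x$muri)
  tr <- statements(registryGraph(x$registry))
  expect_false(any(tr$subject == x$muri | tr$object == x$muri))
  ## the other registration is intact
  expect_true(any(tr$subject == lrUri))
  ## idempotent on unknown URIs; round trip restores counts
  n0 <- length(registryGraph(x$registry))
  deregisterResource(x$registry, "http://unknown.example.org/z")
  expect_equal(length(registryGraph(x$registry)), n0)
  registerResource(x$registry, x$muri)
  deregisterResource(x$registry, x$muri)
  tr2 <- statements(registryGraph(x$registry))
  ## the LR graph never mentions the model, so the full count is restored
  expect_equal(nrow(tr2), n0)
})

test_that("the printed registry query finds both models over the printed graph", {
  ap11 <- appendixGraph("appendix11")
  reg <- otRegistry(fetcher = function(u) ap11$graph)
  registerResource(reg, "http://fixtures/appendix11")
  sols <- registryQuery(reg, appendixGraph("appendix10")$text)
  models <- unique(sols$Model)
  expect_setequal(models, c(
    "http://apps.ideaconsult.net:8080/ambit2/model/33",
    "http://opentox.informatik.tu-muenchen.de:8080/OpenTox-dev/model/TUMOpenToxModel_kNN_92"))
  ## both models share the training dataset in the underlying graph
  tr <- statements(registryGraph(reg))
  training <- tr$object[tr$predicate == otURI("ot:trainingDataset")]
  expect_equal(unique(training),
               "http://apps.ideaconsult.net:8080/ambit2/dataset/R545")
  expect_length(training, 2)

  ## restricting to Regression algorithms keeps only the LR-backed model
  q <- paste(
    "PREFIX ot: <http://www.opentox.org/api/1.1#>",
    "PREFIX ota: <http://www.opentox.org/algorithmTypes.owl#>",
    "PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>",
    "SELECT ?Model WHERE {",
    "  ?Model rdf:type ot:Model.",
    "  ?Model ot:algorithm ?alg.",
    "  ?alg rdf:type ota:Regression.",
    "}")
  expect_equal(registryQuery(reg, q)$Model,
               "http://apps.ideaconsult.net:8080/ambit2/model/33")
})

test_that("registry queries equal the same query over the union of graphs", {
  x <- localSetup()
  lrUri <- paste0(serviceRoot(x$st), "/algorithm/LR")
  registerResource(x$registry, x$muri)
  registerResource(x$registry, lrUri)
  union <- graphUnion(storeFetcher(x$st)(x$muri), storeFetcher(x$st)(lrUri))
  queries <- c(
    "SELECT ?s WHERE { ?s rdf:type ot:Model. }",
    "SELECT ?s ?t WHERE { ?s rdf:type ot:Algorithm. OPTIONAL { ?s dc:title ?t }. }",
    "SELECT ?m ?a WHERE { ?m ot:algorithm ?a. ?a rdf:type ota:Regression. }",
    "SELECT ?m WHERE { ?m rdf:type ot:Model. FILTER(?m != <http://x/y>) }")
  for (q in queries)
    expect_equal(registryQuery(x$registry, q), sparqlSelect(union, q), info = q)
  ## empty store: zero rows
  empty <- otRegistry()
  expect_equal(nrow(registryQuery(empty, queries[1])), 0)
})

test_that("the ontology REST surface supports GET/POST queries and DELETE", {
  x <- localSetup()
  registerResource(x$registry, x$muri)
  q <- "SELECT ?s WHERE { ?s rdf:type ot:Model. }"
  r <- dispatch(x$st, "GET", paste0("/ontology?query=",
                                    utils::URLencode(q, reserved = TRUE)))
  expect_equal(r$status, 200)
  expect_equal(r$headers[["Content-Type"]], "application/sparql-results+xml")
  doc <- xml2::read_xml(r$body)
  expect_equal(xml2::xml_length(xml2::xml_find_first(doc, ".//d1:results",
                                                     xml2::xml_ns(doc))), 1)
  ## POST body form for long queries
  r2 <- dispatch(x$st, "POST", "/ontology",
                 headers = list(`Content-Type` = "application/x-www-form-urlencoded"),
                 body = paste0("query=", utils::URLencode(q, reserved = TRUE)))
  expect_equal(r2$body, r$body)
  ## POST uri= registers; DELETE uri= deregisters
  lrUri <- paste0(serviceRoot(x$st), "/algorithm/LR")
  r3 <- dispatch(x$st, "POST", "/ontology",
                 headers = list(`Content-Type` = "application/x-www-form-urlencoded"),
                 body = paste0("uri=", utils::URLencode(lrUri, reserved = TRUE)))
  expect_equal(r3$status, 200)
  expect_true(any(statements(registryGraph(x$registry))$subject == lrUri))
  r4 <- dispatch(x$st, "DELETE", paste0("/ontology?uri=",
                                        utils::URLencode(lrUri, reserved = TRUE)))
  expect_equal(r4$status, 200)
  expect_false(any(statements(registryGraph(x$registry))$subject == lrUri))
  ## malformed query
  r5 <- dispatch(x$st, "GET", paste0("/ontology?query=",
                                     utils::URLencode("SELECT WHERE garbage",
                                                      reserved = TRUE)))
  expect_equal(r5$status, 400)
})
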