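postForm <- function(st, uriString, body)
  dispatch(st, "POST", uriString, body = body,
           headers = list(`Content-Type` = "application/x-www-form-urlencoded"))

test_that("the asynchronous task protocol follows 202 -> poll -> 200", {
  st <- newStore(autorun = FALSE)
  reg <- makeRegressionDataset(st, 10, 2, noiseSd = 0, seed = 1)
  lr <- paste0(serviceRoot(st), "/algorithm/LR")
  r <- postForm(st, lr, paste0("dataset_uri=", reg$datasetUri,
                               "&prediction_feature=",
                               utils::URLencode(reg$target, reserved = TRUE)))
  expect_equal(r$status, 202)
  taskUri <- trimws(r$body)
  expect_match(taskUri, "/task/[0-9a-f-]{36}$")
  expect_equal(r$headers[["Content-Type"]], "text/uri-list")
  ## worker paused: polling returns 202 with the same task URI
  p1 <- dispatch(st, "GET", taskUri)
  expect_equal(p1$status, 202)
  expect_equal(trimws(p1$body), taskUri)
  taskRunAll(st)
  p2 <- dispatch(st, "GET", taskUri)
  expect_equal(p2$status, 200)
  modelUri <- trimws(p2$body)
  expect_match(modelUri, "/model/[0-9]+$")
  ## apply the model through a second task
  r2 <- postForm(st, modelUri, paste0("dataset_uri=", reg$datasetUri))
  expect_equal(r2$status, 202)
  taskRunAll(st)
  p3 <- dispatch(st, "GET", trimws(r2$body))
  expect_equal(p3$status, 200)
  expect_match(trimws(p3$body), "feature_uris")
  ## the result URI dereferences to a single-column dataset
  rd <- dispatch(st, "GET", trimws(p3$body), headers = list(Accept = "text/n3"))
  expect_equal(rd$status, 200)
  g <- parseGraph(rd$body, "n3")
  expect_true(otURI("ot:Dataset") %in% statements(g)$object)
})

test_that("task submission validates inputs and is non-idempotent", {
  st <- newStore(autorun = FALSE)
  reg <- makeRegressionDataset(st, 6, 1, noiseSd = 0, seed = 2)
  lr <- paste0(serviceRoot(st), "/algorithm/LR")
  muri <- buildModel(st, lr, reg$datasetUri, reg$target)
  expect_equal(postForm(st, muri, "")$status, 400)
  expect_equal(length(st@env$tasks), 0)  # 400 before task creation
  r1 <- postForm(st, muri, paste0("dataset_uri=", reg$datasetUri))
  r2 <- postForm(st, muri, paste0("dataset_uri=", reg$datasetUri))
  expect_false(trimws(r1$body) == trimws(r2$body))
  expect_equal(dispatch(st, "GET", paste0(serviceRoot(st),
    "/task/00000000-0000-0000-0000-000000000000"))$status, 404)
})

test_that("task cancellation stops queued jobs and spares completed ones", {
  st <- newStore(autorun = FALSE)
  d <- createDataset(st, makeToySdf(3, seed = 1), "sdf")
  mw <- paste0(serviceRoot(st), "/algorithm/MolecularWeight")
  r <- postForm(st, mw, paste0("dataset_uri=", uri(d)))
  taskUri <- trimws(r$body)
  inv0 <- length(st@env$invocations)
  expect_equal(dispatch(st, "DELETE", taskUri)$status, 200)
  taskRunAll(st)
  g <- dispatch(st, "GET", taskUri)
  expect_equal(g$status, 200)
  expect_match(g$body, "Cancelled")
  expect_equal(length(st@env$invocations), inv0)  # the job never ran
  ## completed task: DELETE is a no-op
  r2 <- postForm(st, mw, paste0("dataset_uri=", uri(d)))
  taskRunAll(st)
  expect_equal(dispatch(st, "DELETE", trimws(r2$body))$status, 200)
  p <- dispatch(st, "GET", trimws(r2$body))
  expect_equal(p$status, 200)
  expect_match(trimws(p$body), "feature_uris")
  ## failing job surfaces as 500 with the message
  r3 <- postForm(st, mw, paste0("dataset_uri=", serviceRoot(st), "/dataset/999"))
  taskRunAll(st)
  p3 <- dispatch(st, "GET", trimws(r3$body))
  expect_equal(p3$status, 500)
  expect_match(p3$body, "unknown dataset")
})

test_that("representations are negotiated and resources dereference correctly", {
  st <- newStore()
  u <- trimws(dispatch(st, "POST", paste0(serviceRoot(st), "/compound"),
                       headers = list(`Content-Type` = "chemical/x-mdl-molfile"),
                       body = FORMALDEHYDE_MOL)$body)
  expect_match(u, "/compound/1$")
  smi <- dispatch(st, "GET", u,
                  headers = list(Accept = "chemical/x-daylight-smiles"))
  expect_equal(smi$status, 200)
  ref <- canonicalSmiles(fixtureStructure("O=C"))
  expect_equal(canonicalSmiles(readStructures(smi$body, "smiles")[[1]]), ref)
  ## default representation is RDF/XML
  rx <- dispatch(st, "GET", u)
  expect_equal(rx$headers[["Content-Type"]], "application/rdf+xml")
  expect_true(otURI("ot:Compound") %in% statements(parseGraph(rx$body, "rdfxml"))$object)
  expect_equal(dispatch(st, "GET", paste0(serviceRoot(st), "/compound/999999"))$status,
               404)
  expect_equal(dispatch(st, "GET", u,
                        headers = list(Accept = "application/pdf"))$status, 406)
  ## 405 for verbs not in the interface
  expect_equal(dispatch(st, "DELETE",
                        paste0(serviceRoot(st), "/algorithm/LR"))$status, 405)
  expect_equal(dispatch(st, "PUT",
                        paste0(serviceRoot(st), "/task/x"))$status, 405)
})

test_that("model predictions are addressable via the predicted-feature alias", {
  st <- newStore()
  reg <- makeRegressionDataset(st, 8, 1.5, noiseSd = 0, seed = 3)
  lr <- paste0(serviceRoot(st), "/algorithm/LR")
  muri <- buildModel(st, lr, reg$datasetUri, reg$target)
  applyModel(st, muri, reg$datasetUri)
  res <- dispatch(st, "GET", paste0(
    reg$datasetUri, "?feature_uris[]=",
    utils::URLencode(paste0(muri, "/predicted"), reserved = TRUE)),
    headers = list(Accept = "text/csv"))
  expect_equal(res$status, 200)
  lines <- strsplit(res$body, "\n")[[1]]
  expect_length(strsplit(lines[1], ",")[[1]], 2)  # URI + one column
  expect_length(lines, 9)
})

test_that("GET is safe and PUT is idempotent across the interface", {
  st <- newStore()
  d <- createDataset(st, makeToySdf(4, seed = 7), "sdf")
  before <- storeChecksum(st)
  for (u in c(paste0(serviceRoot(st), "/algorithm"), uri(d),
              listAlgorithms(st)[1:3],
              paste0(serviceRoot(st), "/compound/1")))
    dispatch(st, "GET", u, headers = list(Accept = "application/rdf+xml"))
  dispatch(st, "GET", uri(d), headers = list(Accept = "text/csv"))
  expect_equal(storeChecksum(st), before)
  ## PUT twice == PUT once
  payload <- makeToySdf(2, fields = "Canc", seed = 30)
  dispatch(st, "PUT", uri(d), body = payload,
           headers = list(`Content-Type` = "chemical/x-mdl-sdfile"))
  once <- storeChecksum(st)
  dispatch(st, "PUT", uri(d), body = payload,
           headers = list(`Content-Type` = "chemical/x-mdl-sdfile"))
  expect_equal(storeChecksum(st), once)
})

test_that("every successful create POST returns exactly one URI as text/uri-list", {
  st <- newStore(autorun = FALSE)
  responses <- list(
    dispatch(st, "POST", paste0(serviceRoot(st), "/compound"),
             headers = list(`Content-Type` = "chemical/x-mdl-molfile"),
             body = FORMALDEHYDE_MOL),
    dispatch(st, "POST", paste0(serviceRoot(st), "/dataset"),
             headers = list(`Content-Type` = "chemical/x-mdl-sdfile"),
             body = makeToySdf(3, seed = 2)),
    postForm(st, paste0(serviceRoot(st), "/algorithm/structuralalerts"), ""))
  for (r in responses) {
    expect_true(r$status %in% c(200, 202))
    expect_equal(r$headers[["Content-Type"]], "text/uri-list")
    lines <- strsplit(trimws(r$body), "\n")[[1]]
    expect_length(lines, 1)
    expect_match(lines, "^https?://")
  }
})

test_that("the compound query endpoint searches by identifier and url", {
  st <- newStore()
  u <- trimws(dispatch(st, "POST", paste0(serviceRoot(st), "/compound"),
                       headers = list(`Content-Type` = "chemical/x-daylight-smiles"),
                       body = "C=O formaldehyde\n")$body)
  r <- dispatch(st, "GET", paste0(serviceRoot(st), "/query/compound/formaldehyde/smiles"),
                headers = list(Accept = "chemical/x-daylight-smiles"))
  expect_equal(r$status, 200)
  expect_equal(canonicalSmiles(readStructures(r$body, "smiles")[[1]]),
               canonicalSmiles(fixtureStructure("C=O")))
  r2 <- dispatch(st, "GET", paste0(serviceRoot(st), "/query/compound/url/all?search=",
                                   utils::URLencode(u, reserved = TRUE)),
                 headers = list(Accept = "text/uri-list"))
  expect_match(r2$body, "/compound/1")
  r3 <- dispatch(st, "GET", paste0(serviceRoot(st), "/query/compound/nosuch/names"),
                 headers = list(Accept = "text/uri-list"))
  expect_equal(r3$status, 200)
  expect_equal(trimws(r3$body), "")
  expect_equal(dispatch(st, "GET", paste0(serviceRoot(st),
    "/query/compound/x/badmode"))$status, 400)
})

test_that("the admin endpoint creates the backing store exactly once", {
  st <- newStore()
  adm <- paste0(serviceRoot(st), "/admin/database")
  expect_equal(dispatch(st, "GET", adm)$status, 404)
  r <- postForm(st, adm, "dbname=ambit2&user=priv&pass=secret")
  expect_equal(r$status, 200)
  expect_equal(dispatch(st, "GET", adm)$body, "ambit2")
  expect_equal(postForm(st, adm, "dbname=ambit2&user=priv&pass=secret")$status, 409)
  expect_equal(postForm(newStore(), adm, "dbname=x")$status, 401)
})
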