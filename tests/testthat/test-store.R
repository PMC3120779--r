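test_that("compound POST is non-idempotent and assigns sequential URIs", {
  st <- newStore()
  u1 <- createCompound(st, FORMALDEHYDE_MOL, "mol")
  u2 <- createCompound(st, FORMALDEHYDE_MOL, "mol")
  expect_match(u1, "/compound/1$")
  expect_match(u2, "/compound/2$")
  s <- compoundStructure(st, u1)
  expect_equal(canonicalSmiles(s), canonicalSmiles(fixtureStructure("O=C")))
  ## multi-record payloads belong to the dataset service
  expect_error(createCompound(st, makeToySdf(2, seed = 1), "sdf"),
               "exactly one")
})

test_that("dataset import auto-creates features keyed by (title, source)", {
  st <- newStore()
  sdf <- makeToySdf(5, fields = "Canc", seed = 2)
  d1 <- createDataset(st, sdf, "sdf")
  d2 <- createDataset(st, sdf, "sdf")
  expect_false(uri(d1) == uri(d2))
  f1 <- datasetFeatures(st, d1)
  titles <- vapply(f1, function(f) f@title, "")
  canc <- f1[[which(titles == "Canc")]]
  expect_equal(canc@source, uri(d1))
  expect_true(canc@numeric)
  ## within one upload: one feature per distinct field name
  expect_equal(length(f1), length(unique(titles)))
  ## the second upload minted its own features (source differs)
  f2 <- datasetFeatures(st, d2)
  expect_false(any(vapply(f2, uri, "") %in% vapply(f1, uri, "")))
  ## 0-record file
  d0 <- createDataset(st, "", "sdf")
  expect_length(entries(d0), 0)
})

test_that("RDF dataset upload honors the client's feature representation", {
  st <- newStore()
  remoteF <- "http://remote.example.org/service/feature/77"
  g <- graphUnion(
    otTriples(otDataset(uri = "http://client/d", entries = list(
      otDataEntry("http://remote.example.org/service/compound/5",
                  list(otFeatureValue(remoteF, 1.5)))))),
    otTriples(otFeature(uri = remoteF, title = "client field", units = "mg",
                        numeric = TRUE)))
  d <- createDataset(st, serializeGraph(g, "rdfxml"), "application/rdf+xml")
  expect_length(entries(d), 1)
  f <- st@env$features[[remoteF]]
  expect_equal(f@title, "client field")
  expect_equal(f@units, "mg")
})

test_that("dataset PUT has union semantics and is idempotent", {
  st <- newStore()
  d <- createDataset(st, makeToySdf(2, fields = "Canc", seed = 3), "sdf")
  nFeat0 <- length(st@env$features)
  ## identical PUT: nothing changes
  mergeIntoDataset(st, uri(d), makeToySdf(2, fields = "Canc", seed = 3), "sdf")
  d2 <- getDataset(st, uri(d))
  expect_length(entries(d2), 2)
  expect_equal(length(st@env$features), nFeat0)
  ## a new structure appends an entry
  mol <- writeStructure(fixtureStructure("CCCCCCCCBr"), "sdf")
  mergeIntoDataset(st, uri(d), mol, "sdf")
  expect_length(entries(getDataset(st, uri(d))), 3)
  ## a new field on existing compounds: +1 feature, entry count unchanged
  sdf2 <- makeToySdf(2, fields = "Canc", seed = 3)
  sdf2 <- gsub(">  <Canc>", ">  <NewField>", sdf2, fixed = TRUE)
  nFeat1 <- length(st@env$features)
  mergeIntoDataset(st, uri(d), sdf2, "sdf")
  expect_length(entries(getDataset(st, uri(d))), 3)
  expect_equal(length(st@env$features), nFeat1 + 1L)
  expect_error(mergeIntoDataset(st, "http://x/dataset/99", mol, "sdf"),
               "unknown dataset")
})

test_that("feature filtering returns only requested columns, tolerantly", {
  st <- newStore()
  d <- createDataset(st, makeToySdf(4, seed = 5), "sdf")
  feats <- datasetFeatures(st, d)
  furis <- vapply(feats, uri, "")
  one <- getDataset(st, uri(d), featureFilter = furis[1])
  expect_true(all(vapply(entries(one), function(e) length(e@values) <= 1, TRUE)))
  all3 <- getDataset(st, uri(d), featureFilter = furis)
  expect_equal(
    vapply(entries(all3), function(e) length(e@values), 1L),
    vapply(entries(d), function(e) length(e@values), 1L))
  ## unknown feature URIs are ignored: compounds listed, zero values
  none <- getDataset(st, uri(d), featureFilter = "http://x/feature/999")
  expect_length(entries(none), 4)
  expect_true(all(vapply(entries(none), function(e) length(e@values) == 0, TRUE)))
})

test_that("identifier search matches case-insensitively and via compound URLs", {
  st <- newStore()
  u <- createCompound(st, "C=O formaldehyde\n", "smiles")
  inchi <- structureInChI(compoundStructure(st, u))
  hit <- searchCompounds(st, inchi)
  expect_length(entries(hit), 1)
  expect_equal(entries(hit)[[1]]@compound, u)
  expect_length(entries(searchCompounds(st, "FORMALDEHYDE")), 1)
  expect_length(entries(searchCompounds(st, "no-such-name")), 0)
  expect_length(entries(searchCompounds(st, "url", searchParam = u)), 1)
  expect_error(searchCompounds(st, "url"), "search")
})

test_that("similarity and substructure queries agree with brute-force scans", {
  st <- newStore()
  invisible(createDataset(st, makeToySdf(15, seed = 8), "sdf"))
  q <- fixtureStructure("c1ccccc1")
  out <- batchProcess(st, list(kind = "similarity",
                               parameters = list(structure = q, threshold = 0.5)))
  got <- strsplit(trimws(out), "\n")[[1]]
  ## oracle: score every stored compound, sort descending
  ids <- names(st@env$compounds)
  sims <- vapply(ids, function(id)
    tanimoto(fingerprint(q), fingerprint(st@env$compounds[[id]]$conformers[[1]])), 0)
  want <- paste0(serviceRoot(st), "/compound/", ids[sims >= 0.5][order(-sims[sims >= 0.5])])
  expect_equal(got, want)

  sub <- batchProcess(st, list(kind = "substructure",
                               parameters = list(smarts = "c1ccccc1")))
  gotS <- sort(strsplit(trimws(sub), "\n")[[1]])
  wantS <- sort(paste0(serviceRoot(st), "/compound/",
                       ids[vapply(ids, function(id)
                         smartsMatch(st@env$compounds[[id]]$conformers[[1]],
                                     "c1ccccc1"), TRUE)]))
  expect_equal(gotS, wantS)

  one <- batchProcess(st, list(kind = "by_id", parameters = list(id = ids[1])))
  expect_equal(trimws(one), paste0(serviceRoot(st), "/compound/", ids[1]))
})

test_that("deletes cascade to dependent features and values, sparing compounds", {
  st <- newStore()
  d <- createDataset(st, makeToySdf(3, seed = 4), "sdf")
  featUris <- vapply(datasetFeatures(st, d), uri, "")
  nComp <- length(st@env$compounds)
  deleteResource(st, uri(d))
  expect_null(st@env$datasets[[uri(d)]])
  expect_true(all(!featUris %in% names(st@env$features)))
  expect_equal(length(st@env$compounds), nComp)
  expect_error(getDataset(st, uri(d)), "unknown dataset")
  expect_error(deleteResource(st, uri(d)), "unknown dataset")

  ## deleting a feature referenced by values removes them with a warning
  d2 <- createDataset(st, makeToySdf(2, fields = "Canc", seed = 6), "sdf")
  furi <- vapply(datasetFeatures(st, d2), uri, "")
  furi <- furi[vapply(datasetFeatures(st, d2), function(f)
    f@title == "Canc", TRUE)]
  expect_warning(deleteResource(st, furi), "removed values")
  left <- getDataset(st, uri(d2))
  expect_false(any(unlist(lapply(entries(left), function(e)
    vapply(e@values, function(v) v@feature, "")) ) == furi))
})
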