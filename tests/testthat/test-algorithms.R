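test_that("the algorithm roster is stable and fully dereferenceable", {
  st <- newStore()
  algs <- listAlgorithms(st)
  expect_true(all(paste0(serviceRoot(st), "/algorithm/",
                         c("LR", "leverage", "superservice", "fptanimoto"))
                  %in% algs))
  expect_identical(algs, listAlgorithms(st))
  for (a in algs) {
    res <- dispatch(st, "GET", a, headers = list(Accept = "text/n3"))
    expect_equal(res$status, 200)
    g <- parseGraph(res$body, "n3")
    expect_true(otURI("ot:Algorithm") %in% statements(g)$object)
  }
})

test_that("descriptor calculation appends provenance-linked numeric features", {
  st <- newStore()
  u <- createCompound(st, FORMALDEHYDE_MOL, "mol")
  d <- createDataset(st, writeStructure(fixtureStructure("C=O"), "sdf"), "sdf")
  mw <- paste0(serviceRoot(st), "/algorithm/MolecularWeight")
  res <- calcDescriptors(st, mw, uri(d))
  expect_match(res, "feature_uris")
  feats <- datasetFeatures(st, getDataset(st, uri(d)))
  f <- feats[[which(vapply(feats, function(f) f@source[1] == mw, TRUE))]]
  expect_true(f@numeric)
  val <- entries(getDataset(st, uri(d), featureFilter = uri(f)))[[1]]@values[[1]]
  ## oracle: sum of atomic masses C + O + 2 H
  expect_equal(val@value, 12.011 + 15.999 + 2 * 1.008, tolerance = 0.01)

  ## heavy-atom count on methane
  d2 <- createDataset(st, writeStructure(fixtureStructure("C"), "sdf"), "sdf")
  hc <- paste0(serviceRoot(st), "/algorithm/HeavyAtomCount")
  r2 <- calcDescriptors(st, hc, uri(d2))
  v <- entries(getDataset(st, r2))[[1]]
  expect_equal(v@values[[1]]@value, 1)

  ## re-running reuses the feature and leaves values unchanged
  before <- storeChecksum(st)
  res2 <- calcDescriptors(st, mw, uri(d))
  expect_equal(res2, res)
  expect_equal(storeChecksum(st), before)
  expect_error(calcDescriptors(st, mw, NULL), "dataset_uri")
})

test_that("OLS recovers exact coefficients and k-means k=1 gives column means", {
  st <- newStore()
  ## 5 points with y = 2x + 1 exactly
  reg <- makeRegressionDataset(st, 5, 2, noiseSd = 0, seed = 1, intercept = 1)
  lr <- paste0(serviceRoot(st), "/algorithm/LR")
  muri <- buildModel(st, lr, reg$datasetUri, reg$target)
  coefs <- getModel(st, muri)@estimatorState$coefficients
  expect_equal(unname(coefs), c(1, 2), tolerance = 1e-9)
  ## model graph is dereferenceable and typed
  g <- otTriples(getModel(st, muri))
  expect_true(otURI("ot:Model") %in% statements(g)$object)

  ## applying to the training data recovers y
  res <- applyModel(st, muri, reg$datasetUri)
  pred <- entries(getDataset(st, sub("\\?.*", "", res),
                             featureFilter = getModel(st, muri)@predicted))
  got <- vapply(pred, function(e) e@values[[1]]@value, 0)
  expect_equal(got, unname(reg$y), tolerance = 1e-9)

  ## k-means with k = 1: the single centroid is the column means
  ## (filter to the original columns; predictions were appended above)
  km <- paste0(serviceRoot(st), "/algorithm/SimpleKMeans")
  kuri <- opentoxr:::filteredDatasetUri(reg$datasetUri,
                                        c(reg$features, reg$target))
  m2 <- buildModel(st, km, kuri, params = list(k = 1))
  centers <- getModel(st, m2)@estimatorState$centers
  X <- cbind(reg$X, reg$y)
  expect_equal(sort(unname(drop(centers))), sort(unname(colMeans(X))),
               tolerance = 1e-9)
})

test_that("the tree learner separates a linearly separable toy set exactly", {
  st <- newStore()
  ## two clusters on one descriptor, labels split at 0: an exhaustive
  ## split search would find any threshold in (-1, 1); accuracy must be 1
  duri <- storeUri <- paste0(serviceRoot(st), "/dataset/toy")
  x <- c(-3, -2.5, -2, -1.5, 2, 2.5, 3, 3.5)
  lab <- ifelse(x < 0, "inactive", "active")
  id <- opentoxr:::nextId(st, "dataset")
  duri <- paste0(serviceRoot(st), "/dataset/", id)
  fx <- opentoxr:::ensureFeature(st, "x", duri, numeric = TRUE)
  fy <- opentoxr:::ensureFeature(st, "class", duri, numeric = FALSE)
  ents <- lapply(seq_along(x), function(i)
    otDataEntry(paste0("http://remote/compound/", i),
                list(otFeatureValue(fx, x[i]), otFeatureValue(fy, lab[i]))))
  st@env$datasets[[duri]] <- otDataset(uri = duri, entries = ents)
  j48 <- paste0(serviceRoot(st), "/algorithm/J48")
  muri <- buildModel(st, j48, duri, fy)
  res <- applyModel(st, muri, duri)
  pred <- entries(getDataset(st, sub("\\?.*", "", res),
                             featureFilter = getModel(st, muri)@predicted))
  got <- vapply(pred, function(e) as.character(e@values[[1]]@value), "")
  expect_equal(got, lab)
  ## oracle: the best single split on x classifies perfectly
  splits <- (utils::head(sort(x), -1) + utils::tail(sort(x), -1)) / 2
  acc <- vapply(splits, function(s0)
    max(mean((x < s0) == (lab == "inactive")),
        mean((x < s0) == (lab == "active"))), 0)
  expect_equal(max(acc), 1)
})

test_that("rule models need no training data and label by first matching alert", {
  st <- newStore()
  alg <- paste0(serviceRoot(st), "/algorithm/structuralalerts")
  m1 <- buildRuleModel(st, alg)
  m2 <- buildRuleModel(st, alg)
  expect_false(m1 == m2)  # POST mints a new model every time
  model <- getModel(st, m1)
  expect_length(model@trainingDataset, 0)
  g <- otTriples(model)
  expect_false(any(statements(g)$predicate == otURI("ot:trainingDataset")))

  d <- createDataset(st, paste0(
    writeStructure(fixtureStructure("C=O"), "sdf"),
    writeStructure(fixtureStructure("C=CC=O"), "sdf"),
    writeStructure(fixtureStructure("CC"), "sdf")), "sdf")
  res <- applyModel(st, m1, uri(d))
  pred <- entries(getDataset(st, sub("\\?.*", "", res),
                             featureFilter = model@predicted))
  labs <- vapply(pred, function(e) as.character(e@values[[1]]@value), "")
  ## oracle: direct substructure matching per rule, first match wins
  expect_equal(labs, c("aldehyde/carbonyl alert", "Michael acceptor alert",
                       "no alert"))
})

test_that("leverage satisfies its analytic identities", {
  st <- newStore()
  reg <- makeRegressionDataset(st, 12, c(1, -2, 0.5), noiseSd = 0.3, seed = 7)
  filt <- getDataset(st, reg$datasetUri, featureFilter = reg$features)
  ## keep only x columns by building a filtered copy as its own dataset
  id <- opentoxr:::nextId(st, "dataset")
  duri <- paste0(serviceRoot(st), "/dataset/", id)
  st@env$datasets[[duri]] <- otDataset(uri = duri, entries = entries(filt))
  muri <- buildDomainModel(st, "leverage", duri)
  state <- getModel(st, muri)@estimatorState
  X <- cbind(1, reg$X)
  ## leverage of the training centroid = 1/n
  centroid <- colMeans(reg$X)
  h0 <- drop(t(c(1, centroid)) %*% state$xtxInverse %*% c(1, centroid))
  expect_equal(h0, 1 / nrow(reg$X), tolerance = 1e-9)
  ## training leverages sum to the number of parameters p
  H <- X %*% state$xtxInverse %*% t(X)
  expect_equal(sum(diag(H)), ncol(X), tolerance = 1e-9)
  ## scored through the model: flags and scores appear per entry
  res <- applyModel(st, muri, duri)
  pred <- entries(getDataset(st, sub("\\?.*", "", res),
                             featureFilter = getModel(st, muri)@predicted))
  expect_true(all(vapply(pred, function(e) length(e@values) == 2L, TRUE)))
})

test_that("Tanimoto similarity follows the set-bit formula", {
  a <- c(rep(TRUE, 4), rep(FALSE, 6))
  b <- c(TRUE, TRUE, rep(FALSE, 4), rep(TRUE, 4))
  expect_equal(tanimoto(a, b), 2 / (4 + 6 - 2))
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  s <- fixtureStructure("c1ccccc1O")
  expect_equal(tanimoto(fingerprint(s), fingerprint(s)), 1.0)
  expect_equal(tanimoto(logical(16), logical(16)), 0)
  set.seed(3)
  for (i in 1:10) {
    x <- stats::runif(64) > 0.5; y <- stats::runif(64) > 0.5
    expect_equal(tanimoto(x, y), tanimoto(y, x))
  }
  ## a training compound is in-domain of its own fingerprint set
  st <- newStore()
  d <- createDataset(st, makeToySdf(5, seed = 3), "sdf")
  muri <- buildDomainModel(st, "fptanimoto", uri(d))
  res <- applyModel(st, muri, uri(d))
  pred <- entries(getDataset(st, sub("\\?.*", "", res),
                             featureFilter = getModel(st, muri)@predicted))
  scores <- vapply(pred, function(e) as.numeric(e@values[[1]]@value), 0)
  flags <- vapply(pred, function(e) as.character(e@values[[2]]@value), "")
  expect_true(all(scores == 1.0))
  expect_true(all(flags == "in"))
})

test_that("substructure prescreen is a verified superset of true matches", {
  st <- newStore()
  invisible(createDataset(st, paste0(
    writeStructure(fixtureStructure("C=O"), "sdf"),
    writeStructure(fixtureStructure("C"), "sdf")), "sdf"))
  out <- substructurePrescreen(st, "C=O")
  expect_match(out$matches, "/compound/1$")
  expect_length(out$matches, 1)
  expect_true(all(out$matches %in% out$candidates))
  expect_length(substructurePrescreen(st, "[Se]")$matches, 0)
  expect_error(substructurePrescreen(st, "   "), "invalid SMARTS")

  ## containment property over a generated library and several patterns
  st2 <- newStore()
  invisible(createDataset(st2, makeToySdf(30, seed = 12), "sdf"))
  ids <- names(st2@env$compounds)
  for (pat in c("c1ccccc1", "C=O", "[OX2H]", "N", "CC(=O)")) {
    out <- substructurePrescreen(st2, pat)
    truth <- paste0(serviceRoot(st2), "/compound/",
                    ids[vapply(ids, function(id)
                      smartsMatch(st2@env$compounds[[id]]$conformers[[1]], pat),
                      TRUE)])
    expect_setequal(out$matches, truth)
    expect_true(all(truth %in% out$candidates), info = pat)
  }
})

test_that("the superservice reproduces the manual descriptor-then-predict chain", {
  buildPair <- function(seed) {
    st <- newStore()
    train <- createDataset(st, makeToySdf(6, seed = seed), "sdf")
    mw <- paste0(serviceRoot(st), "/algorithm/MolecularWeight")
    xl <- paste0(serviceRoot(st), "/algorithm/XLogP")
    calcDescriptors(st, mw, uri(train))
    calcDescriptors(st, xl, uri(train))
    ## synthesize a numeric target from the descriptors
    feats <- datasetFeatures(st, getDataset(st, uri(train)))
    srcs <- lapply(feats, function(f) f@source)
    dFeats <- vapply(feats, uri, "")[vapply(srcs, function(s)
      length(s) && grepl("/algorithm/", s), TRUE)]
    X <- opentoxr:::datasetMatrix(st, getDataset(st, uri(train)), dFeats)
    yuri <- opentoxr:::ensureFeature(st, "target", uri(train), numeric = TRUE)
    opentoxr:::appendValues(st, uri(train), yuri,
                            as.list(X %*% c(0.1, 3)))
    lr <- paste0(serviceRoot(st), "/algorithm/LR")
    muri <- buildModel(st, lr,
                       opentoxr:::filteredDatasetUri(uri(train),
                                                     c(dFeats, yuri)), yuri)
    list(st = st, muri = muri, seed = seed)
  }
  for (seed in c(21, 22)) {
    p <- buildPair(seed)
    st <- p$st
    ## fresh dataset lacking the descriptors
    fresh <- createDataset(st, makeToySdf(5, seed = seed + 100), "sdf")
    resSuper <- superservice(st, p$muri, uri(fresh))
    predF <- getModel(st, p$muri)@predicted
    superVals <- vapply(entries(getDataset(st, sub("\\?.*", "", resSuper),
                                           featureFilter = predF)),
                        function(e) e@values[[1]]@value, 0)
    ## manual chain on an identical second dataset
    fresh2 <- createDataset(st, makeToySdf(5, seed = seed + 100), "sdf")
    for (f in getModel(st, p$muri)@independent)
      calcDescriptors(st, st@env$features[[f]]@source, uri(fresh2))
    ## map manual predictions through the model applied to fresh2
    res2 <- applyModel(st, p$muri, uri(fresh2))
    manualVals <- vapply(entries(getDataset(st, sub("\\?.*", "", res2),
                                            featureFilter = predF)),
                         function(e) e@values[[1]]@value, 0)
    expect_equal(superVals, manualVals, tolerance = 1e-12)

    ## with descriptors present, nothing is recomputed
    n0 <- sum(grepl("/algorithm/", st@env$invocations))
    invisible(superservice(st, p$muri, uri(fresh)))
    descInvocations <- sum(grepl("/algorithm/", st@env$invocations)) - n0
    expect_equal(descInvocations, 0)
  }

  ## unresolvable descriptor: error before any computation
  st <- newStore()
  d <- createDataset(st, makeToySdf(4, fields = "Canc", seed = 2), "sdf")
  lr <- paste0(serviceRoot(st), "/algorithm/LR")
  feats <- datasetFeatures(st, getDataset(st, uri(d)))
  yuri <- vapply(feats, uri, "")[vapply(feats, function(f) f@title == "Canc", TRUE)]
  ## x feature whose source is the dataset itself, not an algorithm
  xuri <- opentoxr:::ensureFeature(st, "datasetSourced", uri(d), numeric = TRUE)
  opentoxr:::appendValues(st, uri(d), xuri, as.list(seq_len(4)))
  muri <- buildModel(st, lr,
                     opentoxr:::filteredDatasetUri(uri(d), c(xuri, yuri)), yuri)
  fresh <- createDataset(st, makeToySdf(3, fields = "Canc", seed = 5), "sdf")
  inv0 <- length(st@env$invocations)
  expect_error(superservice(st, muri, uri(fresh)), "not a local descriptor")
  expect_equal(length(st@env$invocations), inv0)
})

test_that("missing descriptor values skip the entry with a warning", {
  st <- newStore()
  reg <- makeRegressionDataset(st, 6, 2, noiseSd = 0, seed = 9)
  lr <- paste0(serviceRoot(st), "/algorithm/LR")
  muri <- buildModel(st, lr, reg$datasetUri, reg$target)
  ## knock out one entry's x value
  d <- getDataset(st, reg$datasetUri)
  e1 <- entries(d)[[1]]
  e1@values <- Filter(function(v) v@feature != reg$features[1], e1@values)
  d@entries[[1]] <- e1
  st@env$datasets[[reg$datasetUri]] <- d
  expect_warning(res <- applyModel(st, muri, reg$datasetUri), "skipped")
  pred <- entries(getDataset(st, sub("\\?.*", "", res),
                             featureFilter = getModel(st, muri)@predicted))
  expect_length(pred[[1]]@values, 0)
  expect_length(pred[[2]]@values, 1)
})
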