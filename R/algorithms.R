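## Algorithm and model machinery under the uniform processing paradigm:
## every invocation consumes resource URIs and returns a URI. The built-in
## roster is representative rather than exhaustive — descriptor calculators,
## an OLS regressor, k-means, a CART-style tree, a structural-alert rule
## model, applicability-domain scorers, fingerprints and the superservice.

algRecord <- function(store, uriString) {
  force(uriString)
  store@env$algorithms[[sub("\\?.*", "", uriString)]]
}

#' List registered algorithm URIs
#' @param store an OTStore.
#' @return character vector of algorithm URIs (stable order).
#' @export
listAlgorithms <- function(store) names(store@env$algorithms)

#' Algorithm description object
#' @param store an OTStore.
#' @param uriString algorithm URI.
#' @return the \linkS4class{OTAlgorithm} spec.
#' @export
algorithmSpec <- function(store, uriString) {
  rec <- algRecord(store, uriString)
  if (is.null(rec)) stop(otCondition(404, paste("unknown algorithm:", uriString)))
  rec$spec
}

## additive lipophilicity scheme: per-element heavy-atom contributions with
## a ring bonus; a deterministic stand-in for fragment-based cLogP
.clogpContrib <- c(C = 0.36, N = -0.60, O = -0.63, S = 0.25, P = -0.50,
                   F = 0.22, Cl = 0.65, Br = 0.85, I = 1.05, B = 0.20,
                   Si = 0.30)

clogpAdditive <- function(s) {
  heavy <- s@atoms$element[s@atoms$element != "H"]
  contrib <- .clogpContrib[heavy]
  contrib[is.na(contrib)] <- 0
  round(sum(contrib) + 0.18 * ringCount(s) -
          0.09 * sum(implicitHydrogens(s) == 0), 4)
}

registerBuiltinAlgorithms <- function(store) {
  e <- store@env
  add <- function(id, title, types, kind, instanceOf = character(),
                  parameters = .emptyParams(), ...) {
    u <- storeUri(store, "algorithm", id)
    e$algorithms[[u]] <- c(list(
      spec = otAlgorithm(uri = u, title = title,
                         types = vapply(types, otURI, ""),
                         instanceOf = instanceOf, parameters = parameters),
      kind = kind), list(...))
    u
  }
  param <- function(name, default = "", required = FALSE)
    data.frame(name = name, default = default, required = required,
               stringsAsFactors = FALSE)
  dsParam <- param("dataset_uri", required = TRUE)

  add("MolecularWeight", "Molecular weight", "ota:DescriptorCalculation",
      "descriptor", parameters = dsParam, compute = molecularWeight)
  add("HeavyAtomCount", "Heavy atom count", "ota:DescriptorCalculation",
      "descriptor", parameters = dsParam, compute = heavyAtomCount)
  add("RingCount", "Ring count", "ota:DescriptorCalculation",
      "descriptor", parameters = dsParam, compute = ringCount)
  add("XLogP", "XLogP", "ota:DescriptorCalculation", "descriptor",
      instanceOf = otURI("bo:xlogP"), parameters = dsParam,
      compute = clogpAdditive)

  add("LR", "Linear regression",
      c("ota:Supervised", "ota:EagerLearning", "ota:SingleTarget",
        "ota:Regression"),
      "learner", learnerKind = "regression",
      parameters = rbind(dsParam, param("prediction_feature", required = TRUE)))
  add("SimpleKMeans", "k-means clustering", "ota:Clustering",
      "learner", learnerKind = "clustering",
      parameters = rbind(dsParam, param("k", "2"), param("seed", "0")))
  add("J48", "Decision tree",
      c("ota:Supervised", "ota:EagerLearning", "ota:SingleTarget",
        "ota:Classification"),
      "learner", learnerKind = "classification",
      parameters = rbind(dsParam, param("prediction_feature", required = TRUE)))

  add("structuralalerts", "Structural alerts", "ota:RuleBased", "rule",
      rules = list(
        list(smarts = "C=CC=O", label = "Michael acceptor alert"),
        list(smarts = "[OX1]=C", label = "aldehyde/carbonyl alert")),
      defaultLabel = "no alert")

  for (m in c("leverage", "distanceEuclidean", "distanceCityBlock",
              "fptanimoto", "pcaRanges"))
    add(m, paste("Applicability domain:", m), "ota:ApplicabilityDomain",
        "domain", method = m,
        parameters = rbind(dsParam, if (m == "fptanimoto")
          param("threshold", "0.7") else NULL))

  add("fingerprints", "Structure fingerprints", "ota:DescriptorCalculation",
      "fingerprints", parameters = dsParam)
  add("smartsprop", "Substructure screening keys", "ota:DescriptorCalculation",
      "smartsprop", parameters = dsParam)
  add("superservice", "Descriptor-resolving prediction superservice",
      "ota:Superservice", "superservice",
      parameters = rbind(dsParam, param("model_uri", required = TRUE)))
  invisible(store)
}

## ---- numeric matrix extraction ----

datasetMatrix <- function(store, d, featureUris) {
  vals <- matrix(NA_real_, nrow = length(d@entries), ncol = length(featureUris),
                 dimnames = list(NULL, featureUris))
  for (i in seq_along(d@entries)) {
    for (v in d@entries[[i]]@values) {
      j <- match(v@feature, featureUris)
      if (!is.na(j))
        vals[i, j] <- suppressWarnings(as.numeric(v@value))
    }
  }
  vals
}

appendValues <- function(store, datasetUri, featureUri, values, overwrite = FALSE) {
  ## values: one per entry (NA skips the entry, logged by callers)
  d <- store@env$datasets[[datasetUri]]
  for (i in seq_along(d@entries)) {
    if (i > length(values) || is.na(values[[i]])) next
    e <- d@entries[[i]]
    have <- vapply(e@values, function(v) v@feature, "")
    hit <- match(featureUri, have)
    if (!is.na(hit)) {
      if (overwrite) e@values[[hit]] <- otFeatureValue(featureUri, values[[i]])
    } else {
      e@values[[length(e@values) + 1L]] <- otFeatureValue(featureUri, values[[i]])
    }
    d@entries[[i]] <- e
  }
  store@env$datasets[[datasetUri]] <- d
}

filteredDatasetUri <- function(datasetUri, featureUris)
  paste0(datasetUri, "?", paste0("feature_uris[]=",
                                 vapply(featureUris, utils::URLencode, "",
                                        reserved = TRUE), collapse = "&"))

#' Run a descriptor-calculation algorithm over a dataset
#'
#' Creates (or reuses, by the (title, source) key) a numeric feature whose
#' source is the algorithm URI, computes one value per compound, and stores
#' the values in the dataset. Structures that fail are skipped with a
#' warning. Re-running leaves existing values unchanged.
#'
#' @param store an OTStore.
#' @param algorithmUri a descriptor-calculation algorithm URI.
#' @param datasetUri the input dataset URI.
#' @return the result dataset URI: the input dataset filtered to the new
#'   feature.
#' @export
calcDescriptors <- function(store, algorithmUri, datasetUri) {
  rec <- algRecord(store, algorithmUri)
  if (is.null(rec)) stop(otCondition(404, paste("unknown algorithm:", algorithmUri)))
  if (rec$kind != "descriptor")
    stop(otCondition(400, paste(algorithmUri, "is not a descriptor algorithm")))
  if (is.null(datasetUri))
    stop(otCondition(400, "missing required parameter dataset_uri"))
  d <- getDataset(store, datasetUri)
  store@env$invocations <- c(store@env$invocations, algorithmUri)
  furi <- ensureFeature(store, rec$spec@title, algorithmUri, numeric = TRUE)
  vals <- lapply(d@entries, function(e) {
    s <- compoundStructure(store, e@compound)
    if (is.null(s)) return(NA_real_)
    tryCatch(as.numeric(rec$compute(s)), error = function(err) {
      warning("descriptor failed for <", e@compound, ">: ",
              conditionMessage(err))
      NA_real_
    })
  })
  appendValues(store, sub("\\?.*", "", datasetUri), furi, vals)
  filteredDatasetUri(sub("\\?.*", "", datasetUri), furi)
}

## ---- learners ----

.lsq <- function(X, y) {
  ## ordinary least squares with intercept via the stats fitter
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  fit$coefficients
}

deterministicKmeansInit <- function(x, k, seed = 0L) {
  n <- nrow(x)
  first <- (as.integer(seed) %% n) + 1L
  centers <- first
  while (length(centers) < k) {
    dmin <- apply(x, 1, function(r)
      min(vapply(centers, function(c0) sum((r - x[c0, ])^2), 0)))
    dmin[centers] <- -Inf
    centers <- c(centers, which.max(dmin))  # which.max tie-breaks lowest index
  }
  x[centers, , drop = FALSE]
}

#' Build a predictive model from a learning algorithm and a dataset
#'
#' Independent variables are the dataset's features minus the target;
#' the target becomes the dependent variable, and one new feature per
#' target (with the model as its source) is created to carry predictions.
#'
#' @param store an OTStore.
#' @param algorithmUri learner algorithm URI (LR, SimpleKMeans, J48).
#' @param datasetUri training dataset URI.
#' @param predictionFeature target feature URI (supervised learners).
#' @param params list of optional parameters (k, seed).
#' @return the new model URI.
#' @export
buildModel <- function(store, algorithmUri, datasetUri,
                       predictionFeature = NULL, params = list()) {
  rec <- algRecord(store, algorithmUri)
  if (is.null(rec)) stop(otCondition(404, paste("unknown algorithm:", algorithmUri)))
  if (rec$kind == "rule") return(buildRuleModel(store, algorithmUri))
  if (rec$kind != "learner")
    stop(otCondition(400, paste(algorithmUri, "is not a model-building algorithm")))
  if (is.null(datasetUri))
    stop(otCondition(400, "missing required parameter dataset_uri"))
  d <- getDataset(store, datasetUri)
  store@env$invocations <- c(store@env$invocations, algorithmUri)
  feats <- datasetFeatures(store, d)
  furis <- vapply(feats, uri, "")
  supervised <- rec$learnerKind %in% c("regression", "classification")
  if (supervised) {
    if (is.null(predictionFeature) || !predictionFeature %in% furis)
      stop(otCondition(400, "prediction_feature missing or not in dataset"))
    indep <- setdiff(furis, predictionFeature)
  } else indep <- furis
  numericOK <- vapply(feats, function(f) f@numeric, TRUE)
  names(numericOK) <- furis
  needNumeric <- if (rec$learnerKind == "classification") indep
                 else if (rec$learnerKind == "regression")
                   c(indep, predictionFeature)
                 else indep
  bad <- needNumeric[!numericOK[needNumeric]]
  if (length(bad) && rec$learnerKind != "classification")
    stop(otCondition(400, paste("non-numeric feature for numeric learner:",
                                bad[1])))
  if (length(bad))
    stop(otCondition(400, paste("non-numeric independent feature:", bad[1])))
  X <- datasetMatrix(store, d, indep)
  keep <- stats::complete.cases(X)
  mid <- nextId(store, "model")
  muri <- storeUri(store, "model", mid)
  state <- list(kind = rec$learnerKind, features = indep)
  title <- paste(rec$spec@title, "model", mid)
  dependent <- character()
  if (rec$learnerKind == "regression") {
    y <- datasetMatrix(store, d, predictionFeature)[, 1]
    keep <- keep & !is.na(y)
    state$coefficients <- .lsq(X[keep, , drop = FALSE], y[keep])
    dependent <- predictionFeature
  } else if (rec$learnerKind == "classification") {
    y <- factor(vapply(d@entries, function(e) {
      v <- Filter(function(v) v@feature == predictionFeature, e@values)
      if (length(v)) as.character(v[[1]]@value) else NA_character_
    }, ""))
    keep <- keep & !is.na(y)
    df <- data.frame(X[keep, , drop = FALSE], check.names = FALSE)
    names(df) <- paste0("f", seq_along(indep))
    df$.y <- droplevels(y[keep])
    state$tree <- rpart::rpart(.y ~ ., data = df, method = "class",
                               parms = list(split = "gini"),
                               control = rpart::rpart.control(
                                 minsplit = 4L, minbucket = 2L, cp = 0,
                                 xval = 0L))
    dependent <- predictionFeature
  } else {  # clustering
    k <- as.integer(params$k %||% 2L)
    seed <- as.integer(params$seed %||% 0L)
    init <- deterministicKmeansInit(X[keep, , drop = FALSE], k, seed)
    km <- stats::kmeans(X[keep, , drop = FALSE], centers = init,
                        iter.max = 100L, algorithm = "Lloyd")
    state$centers <- km$centers
  }
  targetTitle <- if (supervised)
    store@env$features[[predictionFeature]]@title else "cluster"
  predTitle <- paste0(targetTitle, " predicted by ", rec$spec@title)
  predFeature <- ensureFeature(store, predTitle, muri,
                               numeric = rec$learnerKind == "regression")
  model <- otModel(uri = muri, title = title, algorithm = algorithmUri,
                   trainingDataset = sub("\\?.*", "", datasetUri),
                   independent = indep, dependent = dependent,
                   predicted = predFeature, estimatorState = state)
  store@env$models[[muri]] <- model
  muri
}

#' Build a rule-based (structural alert) model
#'
#' Rule models carry fixed SMARTS rules instead of a fitted estimator, so no
#' training dataset is required; each POST mints a new model URI.
#'
#' @param store an OTStore.
#' @param algorithmUri a rule-model algorithm URI.
#' @return the new model URI.
#' @export
buildRuleModel <- function(store, algorithmUri) {
  rec <- algRecord(store, algorithmUri)
  if (is.null(rec) || rec$kind != "rule")
    stop(otCondition(404, paste("unknown rule algorithm:", algorithmUri)))
  store@env$invocations <- c(store@env$invocations, algorithmUri)
  mid <- nextId(store, "model")
  muri <- storeUri(store, "model", mid)
  predFeature <- ensureFeature(store, paste0(rec$spec@title, " outcome"), muri,
                               numeric = FALSE)
  model <- otModel(uri = muri, title = paste(rec$spec@title, "model", mid),
                   algorithm = algorithmUri, predicted = predFeature,
                   estimatorState = list(kind = "rule", rules = rec$rules,
                                         defaultLabel = rec$defaultLabel))
  store@env$models[[muri]] <- model
  muri
}

#' Build an applicability-domain model
#'
#' Methods: \code{leverage} (h = x' (X'X)^-1 x, in-domain when h <= 3p/n),
#' \code{distanceEuclidean} / \code{distanceCityBlock} (distance to the
#' training centroid, in-domain within the maximum training distance),
#' \code{fptanimoto} (maximum Tanimoto similarity to the training
#' fingerprints, in-domain at or above the threshold, default 0.7), and
#' \code{pcaRanges} (score hyper-rectangle of the components covering >= 95
#' percent of training variance).
#'
#' @param store an OTStore.
#' @param method method name (also the algorithm id).
#' @param datasetUri training dataset URI (numeric features only, except
#'   fptanimoto which uses the structures).
#' @param params list; \code{threshold} for fptanimoto.
#' @return the new model URI.
#' @export
buildDomainModel <- function(store, method, datasetUri, params = list()) {
  algorithmUri <- storeUri(store, "algorithm", method)
  rec <- algRecord(store, algorithmUri)
  if (is.null(rec) || rec$kind != "domain")
    stop(otCondition(404, paste("unknown domain method:", method)))
  d <- getDataset(store, datasetUri)
  store@env$invocations <- c(store@env$invocations, algorithmUri)
  feats <- datasetFeatures(store, d)
  furis <- vapply(feats, uri, "")
  numericF <- furis[vapply(feats, function(f) f@numeric, TRUE)]
  state <- list(kind = "domain", method = method, features = numericF)
  if (method == "fptanimoto") {
    fps <- lapply(d@entries, function(e) {
      s <- compoundStructure(store, e@compound)
      if (is.null(s)) NULL else fingerprint(s)
    })
    state$fingerprints <- Filter(Negate(is.null), fps)
    state$threshold <- as.numeric(params$threshold %||% 0.7)
    state$features <- character()
  } else {
    X <- datasetMatrix(store, d, numericF)
    X <- X[stats::complete.cases(X), , drop = FALSE]
    if (method == "leverage") {
      ## hat-matrix leverage on the intercept-augmented design, so that
      ## h(centroid) = 1/n and the training leverages sum to p
      Xa <- cbind(1, X)
      xtx <- crossprod(Xa)
      inv <- tryCatch(solve(xtx), error = function(e)
        stop(otCondition(400, paste("singular X'X; reduce correlated",
                                    "features before domain fitting"))))
      state$xtxInverse <- inv
      state$p <- ncol(Xa); state$n <- nrow(X)
      state$cutoff <- 3 * ncol(Xa) / nrow(X)
    } else if (method %in% c("distanceEuclidean", "distanceCityBlock")) {
      state$centroid <- colMeans(X)
      dist1 <- apply(X, 1, function(r)
        if (method == "distanceEuclidean") sqrt(sum((r - state$centroid)^2))
        else sum(abs(r - state$centroid)))
      state$maxDistance <- max(dist1)
    } else if (method == "pcaRanges") {
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
      varFrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      m <- which(varFrac >= 0.95)[1]
      scores <- pc$x[, seq_len(m), drop = FALSE]
      state$rotation <- pc$rotation[, seq_len(m), drop = FALSE]
      state$center <- pc$center
      state$low <- apply(scores, 2, min)
      state$high <- apply(scores, 2, max)
    }
  }
  mid <- nextId(store, "model")
  muri <- storeUri(store, "model", mid)
  scoreF <- ensureFeature(store, paste0(method, " score"), muri, numeric = TRUE)
  flagF <- ensureFeature(store, paste0(method, " domain"), muri, numeric = FALSE)
  model <- otModel(uri = muri, title = paste(method, "domain model", mid),
                   algorithm = algorithmUri,
                   trainingDataset = sub("\\?.*", "", datasetUri),
                   independent = state$features,
                   predicted = c(scoreF, flagF), estimatorState = state)
  store@env$models[[muri]] <- model
  muri
}

## score + flag for one descriptor row / structure under a domain model
.domainScore <- function(state, xrow, s = NULL) {
  switch(state$method,
    leverage = {
      xa <- c(1, xrow)
      h <- drop(t(xa) %*% state$xtxInverse %*% xa)
      list(score = h, flag = h <= state$cutoff)
    },
    distanceEuclidean = {
      d0 <- sqrt(sum((xrow - state$centroid)^2))
      list(score = d0, flag = d0 <= state$maxDistance)
    },
    distanceCityBlock = {
      d0 <- sum(abs(xrow - state$centroid))
      list(score = d0, flag = d0 <= state$maxDistance)
    },
    fptanimoto = {
      fp <- fingerprint(s)
      sims <- vapply(state$fingerprints, function(t0) tanimoto(fp, t0), 0)
      best <- if (length(sims)) max(sims) else 0
      list(score = best, flag = best >= state$threshold)
    },
    pcaRanges = {
      sc <- drop((xrow - state$center) %*% state$rotation)
      eps <- 1e-9
      list(score = max(pmax(state$low - sc, sc - state$high, 0)),
           flag = all(sc >= state$low - eps & sc <= state$high + eps))
    })
}

#' Apply a model to a dataset or single compound
#'
#' Appends one value of each predicted feature per input compound to the
#' input dataset (a single compound URI is first wrapped into a new
#' one-entry dataset); entries missing an independent value are skipped
#' with a warning.
#'
#' @param store an OTStore.
#' @param modelUri model URI.
#' @param inputUri dataset URI (optionally with a feature filter) or
#'   compound URI.
#' @return the result dataset URI: the input dataset filtered to the
#'   model's predicted features, in the
#'   \code{dataset/\{id\}?feature_uris[]=.../model/\{id\}/predicted} form.
#' @export
applyModel <- function(store, modelUri, inputUri) {
  model <- store@env$models[[modelUri]]
  if (is.null(model)) stop(otCondition(404, paste("unknown model:", modelUri)))
  if (is.null(inputUri))
    stop(otCondition(400, "missing required parameter dataset_uri"))
  if (grepl("/compound/", inputUri) && !grepl("/dataset/", inputUri)) {
    if (is.null(compoundStructure(store, inputUri)))
      stop(otCondition(404, paste("unknown compound:", inputUri)))
    id <- nextId(store, "dataset")
    duri <- storeUri(store, "dataset", id)
    store@env$datasets[[duri]] <-
      otDataset(uri = duri, entries = list(otDataEntry(inputUri, list())))
    inputUri <- duri
  }
  datasetUri <- sub("\\?.*", "", inputUri)
  d <- getDataset(store, datasetUri)
  state <- model@estimatorState
  needed <- model@independent
  if (length(needed)) {
    present <- unique(unlist(lapply(d@entries, function(e)
      vapply(e@values, function(v) v@feature, ""))))
    missing <- setdiff(needed, present)
    if (length(missing))
      stop(otCondition(400, paste0(
        "independent feature missing from input dataset: <", missing[1],
        ">; compute it first or use the superservice algorithm")))
  }
  store@env$invocations <- c(store@env$invocations, modelUri)
  X <- if (length(needed)) datasetMatrix(store, d, needed) else NULL
  preds <- vector("list", length(model@predicted))
  for (j in seq_along(preds)) preds[[j]] <- rep(NA, length(d@entries))
  for (i in seq_along(d@entries)) {
    xrow <- if (!is.null(X)) X[i, ] else NULL
    if (!is.null(xrow) && anyNA(xrow)) {
      warning("prediction skipped for <", d@entries[[i]]@compound,
              ">: missing descriptor value")
      next
    }
    out <- switch(state$kind,
      regression = {
        ## aliased (rank-deficient) coefficients are dropped, as in lm()
        co <- state$coefficients
        co[is.na(co)] <- 0
        drop(c(1, xrow) %*% co)
      },
      classification = {
        df <- data.frame(t(xrow))
        names(df) <- paste0("f", seq_along(needed))
        as.character(stats::predict(state$tree, df, type = "class"))
      },
      clustering = which.min(apply(state$centers, 1, function(c0)
        sum((xrow - c0)^2))),
      rule = {
        s <- compoundStructure(store, d@entries[[i]]@compound)
        if (is.null(s)) NA_character_ else {
          lab <- state$defaultLabel
          for (r in state$rules)
            if (smartsMatch(s, r$smarts)) { lab <- r$label; break }
          lab
        }
      },
      domain = {
        s <- if (state$method == "fptanimoto")
          compoundStructure(store, d@entries[[i]]@compound) else NULL
        sc <- .domainScore(state, xrow, s)
        list(sc$score, if (sc$flag) "in" else "out")
      })
    if (!is.list(out)) out <- list(out)
    for (j in seq_along(preds)) preds[[j]][[i]] <- out[[j]]
  }
  for (j in seq_along(model@predicted))
    appendValues(store, datasetUri, model@predicted[j], preds[[j]])
  paste0(datasetUri, "?feature_uris[]=",
         utils::URLencode(paste0(modelUri, "/predicted"), reserved = TRUE))
}

#' Superservice: resolve descriptors from provenance, then predict
#'
#' For every independent feature of the model that is absent from the input
#' dataset, the feature's \code{ot:hasSource} must point at a local
#' descriptor algorithm; those descriptors are computed first (features
#' already present are not recomputed), then the model is applied. The
#' result is value-identical to the manual descriptor-then-predict chain.
#'
#' @param store an OTStore.
#' @param modelUri model URI.
#' @param datasetUri input dataset URI.
#' @return the result dataset URI, as from \code{\link{applyModel}}.
#' @export
superservice <- function(store, modelUri, datasetUri) {
  model <- store@env$models[[modelUri]]
  if (is.null(model)) stop(otCondition(404, paste("unknown model:", modelUri)))
  d <- getDataset(store, datasetUri)
  present <- unique(unlist(lapply(d@entries, function(e)
    vapply(e@values, function(v) v@feature, ""))))
  missing <- setdiff(model@independent, present)
  ## resolve every source before launching any computation
  sources <- lapply(missing, function(furi) {
    f <- store@env$features[[furi]]
    src <- if (!is.null(f) && length(f@source)) f@source else ""
    rec <- algRecord(store, src)
    if (is.null(rec) || rec$kind != "descriptor")
      stop(otCondition(400, paste0(
        "cannot resolve descriptor for feature <", furi,
        ">: its source is not a local descriptor algorithm")))
    src
  })
  for (src in sources) calcDescriptors(store, src, datasetUri)
  applyModel(store, modelUri, datasetUri)
}

## ---- fingerprints, similarity, substructure ----

#' Path-based structure fingerprint
#'
#' FP2-style 1024-bit linear-fragment fingerprint (via OpenBabel), folded
#' to \code{nbits} when a shorter bitset is requested.
#'
#' @param s a \linkS4class{Structure}.
#' @param nbits bitset length (power of two up to 1024).
#' @return logical vector of length \code{nbits}.
#' @export
fingerprint <- function(s, nbits = 1024L) {
  smi <- canonicalSmiles(s)
  raw <- ChemmineOB::forEachMol("SMILES", paste0(smi, "\n"), function(mol)
    ChemmineOB::fingerprint_OB(list(mol), "FP2"))[[1]]
  bits <- raw != 0
  if (nbits < length(bits)) {
    folded <- rep(FALSE, nbits)
    for (k in seq_len(length(bits) / nbits))
      folded <- folded | bits[((k - 1L) * nbits + 1L):(k * nbits)]
    bits <- folded
  }
  bits
}

#' Tanimoto similarity of two bitsets
#'
#' c / (a + b - c) over set bits; 0 when both bitsets are empty.
#'
#' @param a,b logical bit vectors of equal length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  ca <- sum(a); cb <- sum(b); cc <- sum(a & b)
  if (ca + cb == 0) return(0)
  cc / (ca + cb - cc)
}

#' SMARTS substructure match
#'
#' @param s a \linkS4class{Structure}.
#' @param smarts SMARTS pattern.
#' @return TRUE when the pattern matches the structure.
#' @export
smartsMatch <- function(s, smarts) {
  smi <- canonicalSmiles(s)
  n <- tryCatch(
    ChemmineOB::forEachMol("SMILES", paste0(smi, "\n"), function(mol)
      ChemmineOB::smartsSearch_OB(list(mol), smarts,
                                  uniqueMatches = TRUE))[[1]],
    error = function(e)
      stop(otCondition(400, paste("invalid SMARTS pattern:", smarts))))
  n > 0
}

## conservative element-count requirements extracted from a SMARTS pattern;
## used only to prescreen (requirements are necessary conditions, so the
## candidate set is a superset of the true matches)
.smartsElementCounts <- function(smarts) {
  counts <- integer()
  bump <- function(el) {
    cur <- counts[el]
    counts[el] <<- if (is.na(cur)) 1L else cur + 1L
  }
  i <- 1L; n <- nchar(smarts)
  chars <- strsplit(smarts, "")[[1]]
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      depth <- 0L
      repeat {
        if (chars[j] == "[") depth <- depth + 1L
        if (chars[j] == "]") depth <- depth - 1L
        if (depth == 0L) break
        j <- j + 1L
        if (j > n) return(counts)  # malformed; require nothing more
      }
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      ## only simple primitives like [OX1], [CH3], [nH] are counted
      if (!grepl("[!,$*#&;~@]", body)) {
        m <- regmatches(body, regexec("^([A-Za-z][a-z]?)", body))[[1]]
        if (length(m)) {
          el <- m[2]
          el2 <- paste0(toupper(substring(el, 1, 1)), substring(el, 2))
          if (el2 %in% names(.elements)) bump(el2)
        }
      }
      i <- j + 1L; next
    }
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) { bump(two); i <- i + 2L; next }
    if (ch %in% c("C", "N", "O", "S", "P", "F", "I", "B")) { bump(ch); i <- i + 1L; next }
    if (ch %in% c("c", "n", "o", "s", "p")) { bump(toupper(ch)); i <- i + 1L; next }
    i <- i + 1L
  }
  counts
}

#' Substructure prescreen with superset guarantee
#'
#' Candidates are selected by cheap structural keys (element counts implied
#' by the pattern); every true match is guaranteed to be a candidate. The
#' returned set is verified by full SMARTS matching.
#'
#' @param store an OTStore.
#' @param smarts SMARTS pattern.
#' @param datasetUri dataset to search (NULL scans all compounds).
#' @return list with \code{candidates} and \code{matches} (compound URIs).
#' @export
substructurePrescreen <- function(store, smarts, datasetUri = NULL) {
  if (!nzchar(trimws(smarts)))
    stop(otCondition(400, "invalid SMARTS pattern: empty"))
  uris <- if (is.null(datasetUri)) {
    storeUri(store, "compound", names(store@env$compounds))
  } else {
    d <- getDataset(store, datasetUri)
    vapply(d@entries, function(e) e@compound, "")
  }
  req <- .smartsElementCounts(smarts)
  isCandidate <- function(s) {
    if (!length(req)) return(TRUE)
    have <- table(s@atoms$element)
    all(vapply(names(req), function(el)
      el %in% names(have) && have[[el]] >= req[[el]], TRUE))
  }
  cand <- uris[vapply(uris, function(u) {
    s <- compoundStructure(store, u)
    !is.null(s) && isCandidate(s)
  }, TRUE)]
  matches <- cand[vapply(cand, function(u)
    smartsMatch(compoundStructure(store, u), smarts), TRUE)]
  list(candidates = unname(cand), matches = unname(matches))
}

#' Model description object
#' @param store an OTStore.
#' @param uriString model URI.
#' @return the \linkS4class{OTModel}.
#' @export
getModel <- function(store, uriString) {
  force(uriString)
  m <- store@env$models[[sub("\\?.*", "", uriString)]]
  if (is.null(m)) stop(otCondition(404, paste("unknown model:", uriString)))
  m
}
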