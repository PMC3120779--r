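## Bundled RDF fixture texts (with a verified manifest of expected counts)
## and deterministic synthetic-data generators, so every module is testable
## offline.

.appendixFiles <- c(appendix1 = "appendix1.n3", appendix2 = "appendix2.n3",
                    appendix5 = "appendix5.n3", appendix7 = "appendix7.n3",
                    appendix8 = "appendix8.n3", appendix9 = "appendix9.n3",
                    appendix10 = "appendix10.rq", appendix11 = "appendix11.n3")

## expected counts per fixture, verified at test time; "repairs" records the
## minimal syntactic fixes applied to the printed texts (beyond the "=" to
## owl:sameAs normalization performed by the N3 reader)
.fixtureManifest <- list(
  appendix1 = list(triples = 6L, models = 1L, features = 1L, algorithms = 1L,
                   repairs = "stray '.' after feature subject; missing final '.'"),
  appendix2 = list(triples = 4L, algorithms = 1L, repairs = "none"),
  appendix5 = list(triples = 21L, datasets = 1L, entries = 2L, features = 1L,
                   values = c(2.74, 1.59),
                   compounds = paste0("http://apps.ideaconsult.net:8080/ambit2/",
                                      c("compound/147678/conformer/419677",
                                        "compound/2146/conformer/419678")),
                   repairs = "missing '<' before first compound URI"),
  appendix7 = list(triples = 22L, datasets = 1L, entries = 1L, features = 2L,
                   repairs = "none"),
  appendix8 = list(triples = 8L, datasets = 1L, features = 1L, repairs = "none"),
  appendix9 = list(triples = 15L, datasets = 1L, features = 3L,
                   repairs = "space in an example.org URI encoded as %20"),
  appendix10 = list(
    repairs = paste("kept verbatim; note its ota: prefix (algorithms.owl#)",
                    "and Regression URI (algorithmTypes.owl/#) do not match",
                    "the appendix11 data namespaces")),
  appendix11 = list(triples = 29L, models = 2L, algorithms = 1L, features = 1L,
                    repairs = "none"))

#' Bundled appendix fixture
#'
#' Returns the bundled RDF (or SPARQL) text together with its manifest
#' entry of expected counts. The texts follow the printed originals; the
#' N3 "=" shorthand is normalized to owl:sameAs when parsing, and any
#' further syntactic repair is recorded in the manifest.
#'
#' @param name one of appendix1, appendix2, appendix5, appendix7,
#'   appendix8, appendix9, appendix10 (a SPARQL query), appendix11.
#' @return list with \code{text}, \code{manifest}, and (for RDF fixtures)
#'   \code{graph}, the parsed \linkS4class{RDFGraph}.
#' @export
appendixGraph <- function(name) {
  if (!name %in% names(.appendixFiles))
    stop("unknown fixture: ", name, "; available: ",
         paste(names(.appendixFiles), collapse = ", "))
  path <- system.file("extdata", .appendixFiles[[name]], package = "opentoxr",
                      mustWork = TRUE)
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  out <- list(text = text, manifest = .fixtureManifest[[name]])
  if (name != "appendix10") out$graph <- parseGraph(text, "n3")
  out
}

## the 20-molecule structure pool shipped as a plain-text SDF; titles carry
## the compound names
poolStructures <- function() {
  path <- system.file("extdata", "molpool.sdf", package = "opentoxr",
                      mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0, utils::head(lines, -1) == "$$$$")))
  lapply(recs, function(rl) {
    s <- parseMolBlock(rl[rl != "$$$$"])
    s@properties <- c(Name = trimws(rl[1]))
    s
  })
}

## run code under a temporary RNG state seeded deterministically
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

#' Deterministic synthetic SDF generator
#'
#' Draws \code{n} structures from a fixed 20-molecule pool and attaches
#' generated data fields: a CPDBAS-style nominal outcome over
#' \{active, unspecified, inactive\} and/or an ISSCAN-style numeric "Canc"
#' score over \{1, 2, 3\}. Identical arguments give byte-identical output.
#'
#' @param n number of records (>= 0).
#' @param fields character subset of c("ActivityOutcome", "Canc").
#' @param seed RNG seed controlling both the structure draw and the field
#'   values.
#' @return SDF text.
#' @export
makeToySdf <- function(n, fields = c("ActivityOutcome", "Canc"), seed = 0L) {
  stopifnot(n >= 0)
  fields <- match.arg(fields, several.ok = TRUE)
  if (n == 0) return("")
  pool <- poolStructures()
  withSeed(seed, {
    idx <- sample.int(length(pool), n, replace = TRUE)
    structs <- lapply(seq_len(n), function(i) {
      s <- pool[[idx[i]]]
      props <- s@properties
      if ("ActivityOutcome" %in% fields)
        props["ActivityOutcome"] <- sample(c("active", "unspecified",
                                             "inactive"), 1L)
      if ("Canc" %in% fields)
        props["Canc"] <- as.character(sample(1:3, 1L))
      s@properties <- props
      s
    })
    writeSDF(structs, titles = vapply(structs, function(s)
      s@properties[["Name"]], ""))
  })
}

#' Deterministic synthetic regression dataset
#'
#' Builds a persisted dataset with numeric descriptor features x1..xp and a
#' response y = intercept + X beta + e, e ~ Normal(0, noiseSd). Compounds
#' are drawn from the structure pool (the descriptor columns are synthetic
#' and independent of the structures).
#'
#' @param store an OTStore to create the dataset in.
#' @param n number of entries (must exceed length(coefficients)).
#' @param coefficients slope vector beta (one per descriptor column).
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed RNG seed; identical arguments give an identical dataset.
#' @param intercept intercept term of the response.
#' @return list with \code{datasetUri}, \code{features} (the x feature
#'   URIs), \code{target} (the y feature URI), \code{X} and \code{y}.
#' @export
makeRegressionDataset <- function(store, n, coefficients, noiseSd = 0,
                                  seed = 0L, intercept = 1) {
  p <- length(coefficients)
  stopifnot(n > p)
  withSeed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    y <- intercept + drop(X %*% coefficients) + stats::rnorm(n, 0, noiseSd)
    pool <- poolStructures()
    id <- nextId(store, "dataset")
    duri <- storeUri(store, "dataset", id)
    xuris <- vapply(seq_len(p), function(j)
      ensureFeature(store, paste0("x", j), duri, numeric = TRUE), "")
    yuri <- ensureFeature(store, "y", duri, numeric = TRUE)
    entriesList <- lapply(seq_len(n), function(i) {
      cid <- nextId(store, "compound")
      cfid <- nextId(store, "conformer")
      s <- pool[[((i - 1L) %% length(pool)) + 1L]]
      ## identifiers trimmed to the cheap ones: synthetic descriptor rows
      ## do not need toolkit-derived structure identifiers
      store@env$compounds[[as.character(cid)]] <- list(
        conformers = stats::setNames(list(s), cfid),
        identifiers = list(name = unname(s@properties[["Name"]]),
                           formula = molecularFormula(s)))
      vals <- c(lapply(seq_len(p), function(j)
        otFeatureValue(xuris[j], X[i, j])),
        list(otFeatureValue(yuri, y[i])))
      otDataEntry(storeUri(store, "compound", cid), vals)
    })
    store@env$datasets[[duri]] <-
      otDataset(uri = duri, title = "synthetic regression dataset",
                entries = entriesList)
    list(datasetUri = duri, features = xuris, target = yuri, X = X, y = y)
  })
}
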