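## S4 domain types of the OpenTox resource model. Features annotate dataset
## columns with provenance; datasets are compound-by-feature value tables;
## models wire independent/dependent/predicted variables to an algorithm.

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Annotated property feature
#'
#' A feature is a property column: a title (dc:title), optional units
#' (ot:units), a provenance link to the dataset, algorithm or model that
#' produced it (ot:hasSource), ontology cross-links (owl:sameAs) and a flag
#' marking numeric features (the ot:NumericFeature subclass).
#'
#' @slot uri resource URI.
#' @slot title non-empty feature name.
#' @slot units optional unit string (length 0 when absent).
#' @slot source optional URI of the originating dataset/algorithm/model.
#' @slot sameAs zero or more equivalent-resource URIs.
#' @slot numeric TRUE when every value of the feature is a decimal.
#' @slot extra third-party statements about the feature, retained verbatim.
#' @export
setClass("OTFeature", representation(
  uri = "character", title = "character", units = "character",
  source = "character", sameAs = "character", numeric = "logical",
  extra = "data.frame"))

setValidity("OTFeature", function(object) {
  if (length(object@title) != 1L || !nzchar(object@title))
    return("feature title must be a non-empty string")
  if (length(object@source) > 1L) return("at most one source URI")
  if (length(object@source) == 1L &&
      !grepl("/(dataset|algorithm|model)s?(/|$)", object@source))
    return("feature source must be a dataset, algorithm, or model URI")
  TRUE
})

#' @rdname OTFeature-class
#' @param uri,title,units,source,sameAs,numeric,extra see slot documentation.
#' @return an OTFeature.
#' @export
otFeature <- function(uri = "", title, units = character(), source = character(),
                      sameAs = character(), numeric = FALSE,
                      extra = emptyTriples()) {
  new("OTFeature", uri = uri, title = title, units = units,
      source = source, sameAs = sameAs, numeric = numeric, extra = extra)
}

#' A single table cell: one feature value for one data entry
#'
#' @slot feature URI of the feature this value belongs to.
#' @slot value scalar; numeric for numeric features, character otherwise
#'   (text values such as "blank" or "active" are preserved verbatim).
#' @export
setClass("OTFeatureValue", representation(feature = "character", value = "ANY"))

#' @rdname OTFeatureValue-class
#' @param feature,value see slots.
#' @export
otFeatureValue <- function(feature, value)
  new("OTFeatureValue", feature = feature, value = value)

#' A dataset row: one compound with its feature values
#'
#' @slot compound compound (or conformer) URI.
#' @slot values list of \linkS4class{OTFeatureValue}, at most one per feature.
#' @export
setClass("OTDataEntry", representation(compound = "character", values = "list"))

#' @rdname OTDataEntry-class
#' @param compound,values see slots.
#' @export
otDataEntry <- function(compound, values = list()) {
  feats <- vapply(values, function(v) v@feature, "")
  if (anyDuplicated(feats)) {
    ## last-write-wins on duplicated (entry, feature) pairs
    warning("duplicate feature value(s) for ",
            paste(unique(feats[duplicated(feats)]), collapse = ", "),
            "; keeping the last")
    values <- values[!duplicated(feats, fromLast = TRUE)]
  }
  new("OTDataEntry", compound = compound, values = values)
}

#' Dataset: an ordered compound-by-feature value table
#'
#' @slot uri resource URI ("" for a not-yet-persisted or blank-node dataset).
#' @slot title optional title (dc:title).
#' @slot seeAlso optional cross-reference (rdfs:seeAlso).
#' @slot sourceFile optional originating file name (dc:source).
#' @slot entries ordered list of \linkS4class{OTDataEntry}.
#' @export
setClass("OTDataset", representation(
  uri = "character", title = "character", seeAlso = "character",
  sourceFile = "character", entries = "list"))

#' @rdname OTDataset-class
#' @param uri,title,seeAlso,sourceFile,entries see slots.
#' @export
otDataset <- function(uri = "", title = character(), seeAlso = character(),
                      sourceFile = character(), entries = list())
  new("OTDataset", uri = uri, title = title, seeAlso = seeAlso,
      sourceFile = sourceFile, entries = entries)

#' Algorithm description
#'
#' @slot uri resource URI.
#' @slot title algorithm name.
#' @slot types ontology classes of the algorithm (ota:* URIs), non-empty.
#' @slot instanceOf optional external ontology term (bo:instanceOf).
#' @slot parameters data.frame with columns name, default, required.
#' @export
setClass("OTAlgorithm", representation(
  uri = "character", title = "character", types = "character",
  instanceOf = "character", parameters = "data.frame"))

setValidity("OTAlgorithm", function(object)
  if (!length(object@types)) "algorithm types must be non-empty" else TRUE)

.emptyParams <- function()
  data.frame(name = character(), default = character(),
             required = logical(), stringsAsFactors = FALSE)

#' @rdname OTAlgorithm-class
#' @param uri,title,types,instanceOf,parameters see slots.
#' @export
otAlgorithm <- function(uri = "", title, types, instanceOf = character(),
                        parameters = .emptyParams())
  new("OTAlgorithm", uri = uri, title = title, types = types,
      instanceOf = instanceOf, parameters = parameters)

#' Predictive model
#'
#' @slot uri resource URI.
#' @slot title model name.
#' @slot algorithm URI of the generating algorithm.
#' @slot trainingDataset optional training dataset URI (rule-based models
#'   have none).
#' @slot independent,dependent,predicted feature URI vectors; predicted is
#'   non-empty (it holds the features that will carry this model's results).
#' @slot estimatorState opaque fitted-predictor payload (list).
#' @export
setClass("OTModel", representation(
  uri = "character", title = "character", algorithm = "character",
  trainingDataset = "character", independent = "character",
  dependent = "character", predicted = "character",
  estimatorState = "list"))

setValidity("OTModel", function(object)
  if (!length(object@predicted)) "model must declare predicted variables"
  else TRUE)

#' @rdname OTModel-class
#' @param uri,title,algorithm,trainingDataset,independent,dependent,predicted,estimatorState see slots.
#' @export
otModel <- function(uri = "", title, algorithm, trainingDataset = character(),
                    independent = character(), dependent = character(),
                    predicted, estimatorState = list())
  new("OTModel", uri = uri, title = title, algorithm = algorithm,
      trainingDataset = trainingDataset, independent = independent,
      dependent = dependent, predicted = predicted,
      estimatorState = estimatorState)

TASK_STATUSES <- c("Queued", "Running", "Cancelled", "Error", "Completed")

#' Asynchronous job handle
#'
#' @slot id UUID string.
#' @slot status one of Queued, Running, Cancelled, Error, Completed.
#' @slot resultUri result URI, set iff status is Completed.
#' @slot errorMessage set iff status is Error.
#' @slot created,completed timestamps (numeric epoch seconds; completed has
#'   length 0 while the job is unfinished).
#' @export
setClass("OTTask", representation(
  id = "character", status = "character", resultUri = "character",
  errorMessage = "character", created = "numeric", completed = "numeric"))

setValidity("OTTask", function(object) {
  if (!object@status %in% TASK_STATUSES)
    return(paste("unknown task status:", object@status))
  if ((object@status == "Completed") != (length(object@resultUri) == 1L))
    return("resultUri must be set iff status is Completed")
  if ((object@status == "Error") != (length(object@errorMessage) == 1L))
    return("errorMessage must be set iff status is Error")
  TRUE
})

otTask <- function(id, status = "Queued", resultUri = character(),
                   errorMessage = character(),
                   created = as.numeric(Sys.time()), completed = numeric())
  new("OTTask", id = id, status = status, resultUri = resultUri,
      errorMessage = errorMessage, created = created, completed = completed)

## ---- accessors ----

#' Resource URI
#' @param x a domain object.
#' @export
setGeneric("uri", function(x) standardGeneric("uri"))

#' @rdname uri
#' @export
setMethod("uri", "OTFeature", function(x) x@uri)
#' @rdname uri
#' @export
setMethod("uri", "OTDataset", function(x) x@uri)
#' @rdname uri
#' @export
setMethod("uri", "OTAlgorithm", function(x) x@uri)
#' @rdname uri
#' @export
setMethod("uri", "OTModel", function(x) x@uri)

#' Dataset entries
#' @param x an OTDataset.
#' @export
entries <- function(x) x@entries

setMethod("show", "OTFeature", function(object) {
  cat("OTFeature <", object@uri, ">: \"", object@title, "\"",
      if (object@numeric) " [numeric]" else "",
      if (length(object@units)) paste0(" (", object@units, ")") else "",
      "\n", sep = "")
  if (length(object@source)) cat("  source:", object@source, "\n")
  if (length(object@sameAs)) cat("  sameAs:", paste(object@sameAs, collapse = ", "), "\n")
})

setMethod("show", "OTDataset", function(object) {
  cat("OTDataset <", object@uri, ">",
      if (length(object@title)) paste0(" \"", object@title, "\"") else "",
      ": ", length(object@entries), " entries\n", sep = "")
})

setMethod("show", "OTModel", function(object) {
  cat("OTModel <", object@uri, ">: \"", object@title, "\"\n", sep = "")
  cat("  algorithm:", object@algorithm, "\n")
  if (length(object@trainingDataset))
    cat("  trainingDataset:", object@trainingDataset, "\n")
  cat("  independent:", length(object@independent),
      "| dependent:", length(object@dependent),
      "| predicted:", length(object@predicted), "\n")
})

setMethod("show", "OTTask", function(object) {
  cat("OTTask", object@id, "-", object@status,
      if (length(object@resultUri)) paste0("-> ", object@resultUri) else "",
      "\n")
})
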