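## Chemical-MIME bindings and content negotiation. The service works as a
## format converter: each resource kind has a set of readable/writable MIME
## types, and GET representations are chosen by the Accept header with
## application/rdf+xml as the mandatory default.

.rdfMimes <- c("application/rdf+xml" = "rdfxml",
               "text/n3" = "n3",
               "application/x-turtle" = "turtle")

.structMimes <- c("chemical/x-mdl-sdfile" = "sdf",
                  "chemical/x-mdl-molfile" = "mol",
                  "chemical/x-daylight-smiles" = "smiles",
                  "chemical/x-inchi" = "inchi")

.datasetMimes <- c(.rdfMimes, .structMimes["chemical/x-mdl-sdfile"],
                   "text/x-arff" = "arff",
                   "text/uri-list" = "uri-list",
                   "text/csv" = "csv",
                   "text/plain" = "plain")

#' Registered MIME bindings
#'
#' @param kind resource kind: "dataset", "compound", "resource" (RDF-only
#'   resources: feature, algorithm, model, task).
#' @return data.frame with columns mime, format, direction.
#' @export
mimeBindings <- function(kind = c("dataset", "compound", "resource")) {
  kind <- match.arg(kind)
  tab <- switch(kind,
    dataset = .datasetMimes,
    compound = c(.rdfMimes, .structMimes, "text/uri-list" = "uri-list"),
    resource = c(.rdfMimes, "text/uri-list" = "uri-list"))
  data.frame(mime = names(tab), format = unname(tab),
             direction = "both", stringsAsFactors = FALSE)
}

## short format aliases accepted anywhere a mime is expected
.mimeAlias <- c(sdf = "chemical/x-mdl-sdfile", mol = "chemical/x-mdl-molfile",
                smiles = "chemical/x-daylight-smiles",
                inchi = "chemical/x-inchi", csv = "text/csv",
                arff = "text/x-arff", n3 = "text/n3",
                turtle = "application/x-turtle", rdfxml = "application/rdf+xml",
                "uri-list" = "text/uri-list", plain = "text/plain")

normalizeMime <- function(mime) {
  m <- tolower(trimws(mime))
  if (m %in% names(.mimeAlias)) .mimeAlias[[m]] else m
}

#' Choose a representation for an Accept header
#'
#' Parses the Accept header (with q-values), and returns the
#' highest-precedence supported binding; an absent header or \code{*&#47;*}
#' selects the mandatory application/rdf+xml representation.
#'
#' @param acceptHeader the Accept header string, or NULL/NA when absent.
#' @param kind resource kind, see \code{\link{mimeBindings}}.
#' @return one row of the binding table (mime + format).
#' @export
resolveMime <- function(acceptHeader = NULL,
                        kind = c("dataset", "compound", "resource")) {
  kind <- match.arg(kind)
  reg <- mimeBindings(kind)
  if (is.null(acceptHeader) || is.na(acceptHeader) ||
      !nzchar(trimws(acceptHeader)))
    return(reg[reg$mime == "application/rdf+xml", ])
  parts <- strsplit(acceptHeader, ",", fixed = TRUE)[[1]]
  cand <- do.call(rbind, lapply(parts, function(p) {
    bits <- strsplit(trimws(p), ";", fixed = TRUE)[[1]]
    q <- 1
    qs <- grep("^\\s*q=", bits[-1], value = TRUE)
    if (length(qs)) q <- suppressWarnings(as.numeric(sub(".*q=", "", qs[1])))
    data.frame(mime = normalizeMime(bits[1]), q = if (is.na(q)) 1 else q,
               stringsAsFactors = FALSE)
  }))
  cand <- cand[order(-cand$q), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    m <- cand$mime[i]
    if (m %in% c("*/*", "*")) return(reg[reg$mime == "application/rdf+xml", ])
    if (m %in% reg$mime) return(reg[reg$mime == m, ])
  }
  stop(otCondition(406, paste("no supported representation among:",
                              acceptHeader)))
}

## condition constructor carrying an HTTP-style status for the REST layer
otCondition <- function(status, message) {
  structure(class = c("otHTTPError", "error", "condition"),
            list(message = message, call = NULL, status = status))
}

#' Read chemical structures from a payload
#'
#' @param payload text content (character; vectors are joined by newline).
#' @param mime one of the registered readable MIME types (or short alias):
#'   SDF, MOL, SMILES list, or CSV with a SMILES column.
#' @return list of \linkS4class{Structure}, record order preserved; SDF
#'   data fields are captured verbatim into properties.
#' @export
readStructures <- function(payload, mime) {
  text <- paste(payload, collapse = "\n")
  fmt <- normalizeMime(mime)
  if (!nzchar(trimws(text)) &&
      fmt %in% c(.mimeAlias[c("sdf", "smiles", "csv")])) return(list())
  switch(fmt,
    "chemical/x-mdl-sdfile" = parseSDF(text),
    "chemical/x-mdl-molfile" = list(parseMolBlock(strsplit(text, "\n")[[1]])),
    "chemical/x-daylight-smiles" = {
      lines <- trimws(strsplit(text, "\n")[[1]])
      lines <- lines[nzchar(lines)]
      lapply(seq_along(lines), function(i) {
        tok <- strsplit(lines[i], "[ \t]+")[[1]]
        s <- tryCatch(structureFromSmiles(tok[1]), error = function(e)
          stop(otCondition(400, paste0("unparseable SMILES record ", i, ": ",
                                       tok[1]))))
        if (length(tok) > 1L)
          s@properties <- c(Name = paste(tok[-1], collapse = " "))
        s
      })
    },
    "text/csv" = {
      df <- utils::read.csv(textConnection(text), stringsAsFactors = FALSE,
                            check.names = FALSE)
      scol <- which(tolower(names(df)) == "smiles")
      if (!length(scol))
        stop(otCondition(400, "CSV payload lacks a SMILES column"))
      lapply(seq_len(nrow(df)), function(i) {
        s <- tryCatch(structureFromSmiles(df[i, scol[1]]), error = function(e)
          stop(otCondition(400, paste("unparseable record", i))))
        props <- as.character(df[i, -scol[1], drop = TRUE])
        names(props) <- names(df)[-scol[1]]
        s@properties <- props[nzchar(names(props))]
        s
      })
    },
    stop(otCondition(415, paste("unregistered input format:", mime))))
}

#' Write a single structure in a chemical MIME format
#'
#' @param s a \linkS4class{Structure}.
#' @param mime smiles, inchi, mol or sdf (or the chemical/* MIME names).
#' @return text representation; re-reading it yields the same molecular
#'   graph (canonical forms; string equality across toolkits is not implied).
#' @export
writeStructure <- function(s, mime) {
  switch(normalizeMime(mime),
    "chemical/x-daylight-smiles" = canonicalSmiles(s),
    "chemical/x-inchi" = structureInChI(s),
    "chemical/x-mdl-molfile" = paste0(writeMolBlock(s), "\n"),
    "chemical/x-mdl-sdfile" = writeSDF(list(s)),
    stop(otCondition(415, paste("unsupported structure format:", mime))))
}

#' Write a dataset representation
#'
#' Entry-streaming serializer: entries are formatted and flushed to the
#' connection one at a time, so the number of simultaneously buffered
#' entries is constant in the dataset size.
#'
#' @param d an \linkS4class{OTDataset}.
#' @param features list of \linkS4class{OTFeature} giving the columns
#'   (ordered by feature URI on output).
#' @param compoundFor function(uri) returning the \linkS4class{Structure}
#'   for a compound URI (or NULL).
#' @param mime sdf, csv, arff, uri-list or plain.
#' @param con connection to stream into; when NULL the text is returned.
#' @param instrument optional environment; its \code{peak} field receives
#'   the maximum number of entries buffered at any point.
#' @return the serialized text (invisibly when streaming to \code{con}).
#' @export
writeDatasetAs <- function(d, mime, features = list(), compoundFor = NULL,
                           con = NULL, instrument = NULL) {
  fmt <- normalizeMime(mime)
  collect <- is.null(con)
  if (collect) {
    buf <- file(tempfile(), open = "w+")
    on.exit(close(buf), add = TRUE)
    con <- buf
  }
  held <- 0L
  note <- function(delta) {
    held <<- held + delta
    if (!is.null(instrument))
      instrument$peak <- max(instrument$peak %||% 0L, held)
  }
  ord <- order(vapply(features, uri, ""))
  features <- features[ord]
  furis <- vapply(features, uri, "")
  ftitles <- vapply(features, function(f) f@title, "")
  fnum <- vapply(features, function(f) f@numeric, TRUE)
  rowValues <- function(e) {
    vals <- rep(NA_character_, length(furis))
    for (v in e@values) {
      i <- match(v@feature, furis)
      if (!is.na(i)) vals[i] <- formatValue(v@value)
    }
    vals
  }
  quoteCsv <- function(x) {
    x[is.na(x)] <- ""
    need <- grepl("[\",\n]", x)
    x[need] <- paste0("\"", gsub("\"", "\"\"", x[need]), "\"")
    x
  }
  switch(fmt,
    "text/uri-list" = , "text/plain" = {
      for (e in d@entries) {
        note(1L)
        writeLines(e@compound, con)
        note(-1L)
      }
    },
    "text/csv" = {
      writeLines(paste(c("URI", quoteCsv(ftitles)), collapse = ","), con)
      for (e in d@entries) {
        note(1L)
        writeLines(paste(quoteCsv(c(e@compound, rowValues(e))), collapse = ","),
                   con)
        note(-1L)
      }
    },
    "text/x-arff" = {
      writeLines(paste0("@relation ",
                        if (length(d@title)) gsub("\\s+", "_", d@title)
                        else "dataset"), con)
      writeLines("@attribute URI string", con)
      for (i in seq_along(features)) {
        if (fnum[i]) {
          writeLines(paste0("@attribute \"", ftitles[i], "\" numeric"), con)
        } else {
          vals <- unique(unlist(lapply(d@entries, function(e)
            stats::na.omit(rowValues(e)[i]))))
          writeLines(paste0("@attribute \"", ftitles[i], "\" {",
                            paste(sort(vals), collapse = ","), "}"), con)
        }
      }
      writeLines("@data", con)
      for (e in d@entries) {
        note(1L)
        vals <- rowValues(e)
        vals[is.na(vals)] <- "?"
        vals[!fnum & vals != "?"] <- paste0("\"", vals[!fnum & vals != "?"], "\"")
        writeLines(paste(c(paste0("\"", e@compound, "\""), vals),
                         collapse = ","), con)
        note(-1L)
      }
    },
    "chemical/x-mdl-sdfile" = {
      if (is.null(compoundFor))
        stop("SDF output requires a compound structure lookup")
      for (e in d@entries) {
        note(1L)
        s <- compoundFor(e@compound)
        if (is.null(s)) { note(-1L); next }
        vals <- rowValues(e)
        props <- stats::setNames(vals[!is.na(vals)], ftitles[!is.na(vals)])
        s@properties <- props
        writeLines(sub("\n$", "", writeSDF(list(s), titles = e@compound)), con)
        note(-1L)
      }
    },
    stop(otCondition(415, paste("unsupported dataset format:", mime))))
  flush(con)
  if (collect) {
    seek(con, 0)
    paste0(paste(readLines(con), collapse = "\n"), "\n")
  } else invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
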