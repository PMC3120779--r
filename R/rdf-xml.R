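## RDF/XML reading and writing, built on xml2. RDF/XML is the mandatory
## interchange representation; the writer emits flat rdf:Description nodes
## and the reader additionally accepts typed node elements.

.splitURI <- function(uri) {
  ## split into (namespace, NCName local part) for XML element naming
  m <- regmatches(uri, regexec("^(.*[#/])([A-Za-z_][A-Za-z0-9_.-]*)$", uri))[[1]]
  if (length(m)) c(m[2], m[3]) else NULL
}

writeRDFXML <- function(graph) {
  tr <- statements(graph)
  ## collect namespaces: built-ins plus any needed for foreign predicates
  extra <- character()
  nsFor <- function(uri) {
    sp <- .splitURI(uri)
    if (is.null(sp)) stop("predicate URI not XML-serializable: ", uri)
    known <- names(OT_NS)[OT_NS == sp[1]]
    if (length(known)) return(c(known[1], sp[2]))
    if (!sp[1] %in% extra) extra[length(extra) + 1L] <<- sp[1]
    c(paste0("ns", match(sp[1], extra)), sp[2])
  }
  preds <- unique(tr$predicate)
  pmap <- stats::setNames(lapply(preds, nsFor), preds)
  nss <- OT_NS
  if (length(extra))
    nss <- c(nss, stats::setNames(extra, paste0("ns", seq_along(extra))))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  escAttr <- function(x) gsub("\"", "&quot;", esc(x), fixed = TRUE)
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           paste0("<rdf:RDF",
                  paste0(vapply(names(nss), function(p)
                    paste0(" xmlns:", p, "=\"", nss[[p]], "\""), ""),
                    collapse = ""), ">"))
  for (s in unique(tr$subject)) {
    rows <- tr[tr$subject == s, , drop = FALSE]
    sattr <- if (isBnode(s)) paste0("rdf:nodeID=\"", substring(s, 3), "\"")
             else paste0("rdf:about=\"", escAttr(s), "\"")
    out <- c(out, paste0("  <rdf:Description ", sattr, ">"))
    for (i in seq_len(nrow(rows))) {
      pm <- pmap[[rows$predicate[i]]]
      tag <- paste0(pm[1], ":", pm[2])
      o <- rows$object[i]
      line <- switch(rows$type[i],
        uri = paste0("    <", tag, " rdf:resource=\"", escAttr(o), "\"/>"),
        bnode = paste0("    <", tag, " rdf:nodeID=\"", substring(o, 3), "\"/>"),
        literal = {
          dt <- rows$dtype[i]
          dta <- if (is.na(dt)) "" else paste0(" rdf:datatype=\"", escAttr(dt), "\"")
          paste0("    <", tag, dta, ">", esc(o), "</", tag, ">")
        })
      out <- c(out, line)
    }
    out <- c(out, "  </rdf:Description>")
  }
  paste(c(out, "</rdf:RDF>", ""), collapse = "\n")
}

parseRDFXML <- function(text) {
  doc <- xml2::read_xml(text)
  rdfns <- OT_NS[["rdf"]]
  rows <- list()
  emit <- function(s, p, o, type, dtype = NA_character_)
    rows[[length(rows) + 1L]] <<- triple(s, p, o, type, dtype)
  nodeSubject <- function(node) {
    about <- xml2::xml_attr(node, "about")
    nid <- xml2::xml_attr(node, "nodeID")
    if (!is.na(about)) about
    else if (!is.na(nid)) paste0("_:", nid)
    else paste0("_:x", xml2::xml_path(node))
  }
  for (node in xml2::xml_children(doc)) {
    s <- nodeSubject(node)
    qn <- xml2::xml_name(node, ns = xml2::xml_ns(doc))
    if (qn != "rdf:Description") {
      ## typed node element: element name is the rdf:type
      nsmap <- xml2::xml_ns(doc)
      parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
      cls <- if (length(parts) == 2L && parts[1] %in% names(nsmap))
        paste0(nsmap[[parts[1]]], parts[2]) else qn
      emit(s, otURI("rdf:type"), cls, "uri")
    }
    for (child in xml2::xml_children(node)) {
      qn <- xml2::xml_name(child, ns = xml2::xml_ns(doc))
      nsmap <- xml2::xml_ns(doc)
      parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
      p <- if (length(parts) == 2L && parts[1] %in% names(nsmap))
        paste0(nsmap[[parts[1]]], parts[2])
      else stop("unqualified property element: ", qn)
      res <- xml2::xml_attr(child, "resource")
      nid <- xml2::xml_attr(child, "nodeID")
      dt <- xml2::xml_attr(child, "datatype")
      if (!is.na(res)) emit(s, p, res, "uri")
      else if (!is.na(nid)) emit(s, p, paste0("_:", nid), "bnode")
      else emit(s, p, xml2::xml_text(child), "literal",
                if (is.na(dt)) NA_character_ else dt)
    }
  }
  rdfGraph(do.call(rbind, c(list(emptyTriples()), rows)))
}
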