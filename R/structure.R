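## Chemical structures and the MDL V2000 connection-table formats.
## SMILES/InChI interconversion is delegated to OpenBabel (ChemmineOB);
## the V2000 reader/writer is implemented here so that single-atom records
## and verbatim SDF data fields are handled exactly.

.elements <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.065, Cl = 35.453, Br = 79.904, I = 126.904,
  Na = 22.990, K = 39.098, Li = 6.941, Ca = 40.078, Mg = 24.305, Fe = 55.845,
  Zn = 65.38, Se = 78.971, As = 74.922)

.defaultValence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                     S = 2, Cl = 1, Br = 1, I = 1)

#' Chemical structure
#'
#' A molecular graph: atoms (element, formal charge, optional 3D
#' coordinates), bonds (1-based atom index pairs with order, as in MOL
#' connection tables) and named text properties (SDF data fields).
#'
#' @slot atoms data.frame with columns element, charge, x, y, z.
#' @slot bonds data.frame with columns a1, a2, order.
#' @slot properties named character vector of data fields.
#' @export
setClass("Structure", representation(
  atoms = "data.frame", bonds = "data.frame", properties = "character"))

setValidity("Structure", function(object) {
  if (nrow(object@bonds)) {
    idx <- c(object@bonds$a1, object@bonds$a2)
    if (any(idx < 1L | idx > nrow(object@atoms)))
      return("bond endpoints must reference existing atoms")
  }
  bad <- setdiff(object@atoms$element, names(.elements))
  if (length(bad)) return(paste("unknown element symbol(s):",
                                paste(bad, collapse = ", ")))
  TRUE
})

.emptyAtoms <- function()
  data.frame(element = character(), charge = integer(),
             x = numeric(), y = numeric(), z = numeric(),
             stringsAsFactors = FALSE)

.emptyBonds <- function()
  data.frame(a1 = integer(), a2 = integer(), order = integer())

#' @rdname Structure-class
#' @param atoms,bonds,properties see slots.
#' @export
structureNew <- function(atoms = .emptyAtoms(), bonds = .emptyBonds(),
                         properties = character()) {
  new("Structure", atoms = atoms, bonds = bonds,
      properties = properties)
}

setMethod("show", "Structure", function(object) {
  cat("Structure:", nrow(object@atoms), "atoms,", nrow(object@bonds), "bonds")
  if (length(object@properties))
    cat(";", length(object@properties), "data fields")
  cat("\n")
})

#' Number of heavy (non-hydrogen) atoms
#' @param s a Structure.
#' @export
heavyAtomCount <- function(s) sum(s@atoms$element != "H")

implicitHydrogens <- function(s) {
  if (!nrow(s@atoms)) return(integer())
  orders <- numeric(nrow(s@atoms))
  if (nrow(s@bonds)) {
    ## aromatic MOL bonds (order 4) count 1.5 towards valence
    eff <- ifelse(s@bonds$order == 4L, 1.5, s@bonds$order)
    for (i in seq_len(nrow(s@bonds))) {
      orders[s@bonds$a1[i]] <- orders[s@bonds$a1[i]] + eff[i]
      orders[s@bonds$a2[i]] <- orders[s@bonds$a2[i]] + eff[i]
    }
  }
  ## standard-valence model for neutral organics; charged atoms get no
  ## implicit hydrogens beyond the valence balance
  val <- .defaultValence[s@atoms$element]
  val[is.na(val)] <- 0
  pmax(0L, as.integer(round(val - orders)))
}

#' Molecular weight (implicit hydrogens included)
#' @param s a Structure.
#' @export
molecularWeight <- function(s) {
  sum(.elements[s@atoms$element]) + sum(implicitHydrogens(s)) * .elements[["H"]]
}

#' Number of rings (cyclomatic number of the molecular graph)
#' @param s a Structure.
#' @export
ringCount <- function(s) {
  n <- nrow(s@atoms)
  if (!n) return(0L)
  ## connected components by union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(s@bonds))) {
    r1 <- find(s@bonds$a1[i]); r2 <- find(s@bonds$a2[i])
    if (r1 != r2) parent[r1] <- r2
  }
  comps <- length(unique(vapply(seq_len(n), find, 1L)))
  nrow(s@bonds) - n + comps
}

## ---- MDL V2000 ----

parseMolBlock <- function(lines) {
  if (length(lines) < 4L) stop("truncated MOL block")
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("invalid counts line: ", counts)
  atoms <- .emptyAtoms()
  if (na > 0) {
    al <- lines[5:(4 + na)]
    atoms <- data.frame(
      element = trimws(substr(al, 32, 34)),
      charge = 0L,
      x = as.numeric(substr(al, 1, 10)),
      y = as.numeric(substr(al, 11, 20)),
      z = as.numeric(substr(al, 21, 30)),
      stringsAsFactors = FALSE)
    ## legacy charge column: 4=+1 is coded specially; M CHG overrides below
    ccol <- suppressWarnings(as.integer(substr(al, 37, 39)))
    ccol[is.na(ccol)] <- 0L
    atoms$charge <- ifelse(ccol == 0L, 0L, 4L - ccol)
  }
  bonds <- .emptyBonds()
  if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9)))
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) atoms$charge[f[2 * j]] <- f[2 * j + 1]
  }
  structureNew(atoms, bonds)
}

writeMolBlock <- function(s, title = "") {
  fmtA <- function(i) sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              s@atoms$x[i], s@atoms$y[i], s@atoms$z[i],
                              s@atoms$element[i])
  fmtB <- function(i) sprintf("%3d%3d%3d  0  0  0  0",
                              s@bonds$a1[i], s@bonds$a2[i], s@bonds$order[i])
  lines <- c(title, "  opentoxr", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(s@atoms), nrow(s@bonds)),
             vapply(seq_len(nrow(s@atoms)), fmtA, ""),
             vapply(seq_len(nrow(s@bonds)), fmtB, ""))
  chg <- which(s@atoms$charge != 0L)
  if (length(chg))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, s@atoms$charge[chg]),
                                    collapse = "")))
  paste(c(lines, "M  END"), collapse = "\n")
}

parseSDF <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  if (!length(lines) || all(!nzchar(trimws(lines)))) return(list())
  recs <- split(lines, cumsum(c(0, utils::head(lines, -1) == "$$$$")))
  out <- list()
  for (ri in seq_along(recs)) {
    rl <- recs[[ri]]
    rl <- rl[rl != "$$$$"]
    if (!length(rl) || all(!nzchar(trimws(rl)))) next
    endIdx <- grep("^M  END", rl)
    if (!length(endIdx)) stop("unparseable SDF record ", ri, ": no M END")
    s <- tryCatch(parseMolBlock(rl[seq_len(endIdx[1])]),
                  error = function(e)
                    stop("unparseable SDF record ", ri, ": ",
                         conditionMessage(e)))
    ## data fields: "> <name>" followed by value lines up to a blank line
    props <- character()
    di <- grep("^>", rl)
    for (d in di) {
      name <- sub("^>.*<([^>]*)>.*$", "\\1", rl[d])
      j <- d + 1L
      vals <- character()
      while (j <= length(rl) && nzchar(trimws(rl[j]))) {
        vals <- c(vals, rl[j]); j <- j + 1L
      }
      props[name] <- paste(vals, collapse = "\n")
    }
    s@properties <- props
    out[[length(out) + 1L]] <- s
  }
  out
}

writeSDF <- function(structures, titles = NULL) {
  paste0(paste(vapply(seq_along(structures), function(i) {
    s <- structures[[i]]
    block <- writeMolBlock(s, title = if (!is.null(titles)) titles[i] else "")
    fields <- ""
    if (length(s@properties))
      fields <- paste0(paste0(">  <", names(s@properties), ">\n",
                              s@properties, "\n", collapse = "\n"), "\n")
    paste0(block, "\n", fields, "$$$$")
  }, ""), collapse = "\n"), "\n")
}

## ---- OpenBabel-backed conversions ----

.obConvert <- function(from, to, text) {
  out <- suppressWarnings(ChemmineOB::convertFormat(from, to, text))
  if (!length(out) || !nzchar(trimws(out[1])))
    stop("conversion ", from, " -> ", to, " failed")
  out
}

#' Canonical SMILES of a structure
#' @param s a Structure.
#' @export
canonicalSmiles <- function(s) {
  out <- .obConvert("MOL", "CAN", paste0(writeMolBlock(s), "\n"))
  trimws(strsplit(out, "[\t\n]")[[1]][1])
}

#' Standard InChI of a structure
#' @param s a Structure.
#' @export
structureInChI <- function(s) {
  out <- .obConvert("MOL", "INCHI", paste0(writeMolBlock(s), "\n"))
  ln <- grep("^InChI=", strsplit(out, "\n")[[1]], value = TRUE)
  if (!length(ln)) stop("InChI conversion failed")
  trimws(ln[1])
}

#' Standard InChIKey of a structure
#' @param s a Structure.
#' @export
structureInChIKey <- function(s) {
  out <- .obConvert("MOL", "INCHIKEY", paste0(writeMolBlock(s), "\n"))
  trimws(strsplit(out, "\n")[[1]][1])
}

structureFromSmiles <- function(smiles) {
  mol <- .obConvert("SMI", "MOL", paste0(smiles, "\n"))
  parseMolBlock(strsplit(mol, "\n")[[1]])
}

#' Molecular formula (Hill order, implicit hydrogens included)
#' @param s a Structure.
#' @export
molecularFormula <- function(s) {
  counts <- table(s@atoms$element)
  nh <- sum(implicitHydrogens(s)) + sum(s@atoms$element == "H")
  counts <- counts[names(counts) != "H"]
  ord <- c("C", sort(setdiff(names(counts), "C")))
  parts <- character()
  for (el in ord) {
    if (!el %in% names(counts)) next
    n <- counts[[el]]
    parts <- c(parts, paste0(el, if (n > 1) n else ""))
    if (el == "C" && nh > 0)
      parts <- c(parts, paste0("H", if (nh > 1) nh else ""))
  }
  if (!"C" %in% names(counts) && nh > 0)
    parts <- c(parts, paste0("H", if (nh > 1) nh else ""))
  paste(parts, collapse = "")
}
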