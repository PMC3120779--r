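## shared fixtures: tiny structures, random dataset generator and a
## brute-force graph-isomorphism oracle used to validate the fast matcher

newStore <- function(...) otStore(...)

fixtureStructure <- function(smiles) readStructures(smiles, "smiles")[[1]]

FORMALDEHYDE_MOL <- paste0(
  "formaldehyde\n  test\n\n",
  "  2  1  0  0  0  0  0  0  0  0999 V2000\n",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0\n",
  "    1.2000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0\n",
  "  1  2  2  0  0  0  0\nM  END\n")

## random dataset with mixed numeric/text values under a fixed seed
randomDataset <- function(seed, maxCompounds = 50, maxFeatures = 10) {
  set.seed(seed)
  nc <- sample.int(maxCompounds, 1)
  nf <- sample.int(maxFeatures, 1)
  numeric <- sample(c(TRUE, FALSE), nf, replace = TRUE)
  furis <- paste0("http://h/ambit2/feature/", seq_len(nf))
  ents <- lapply(seq_len(nc), function(i) {
    present <- which(stats::runif(nf) > 0.2)
    vals <- lapply(present, function(j)
      otFeatureValue(furis[j], if (numeric[j]) round(stats::rnorm(1), 4)
                     else sample(c("active", "inactive", "blank", "x,y\"z"), 1)))
    otDataEntry(paste0("http://h/ambit2/compound/", i), vals)
  })
  otDataset(uri = paste0("http://h/ambit2/dataset/", seed),
            title = paste("random dataset", seed), entries = ents)
}

## exhaustive blank-node matching; only usable on small graphs
bruteForceIso <- function(a, b) {
  ta <- unique(statements(a)); tb <- unique(statements(b))
  if (nrow(ta) != nrow(tb)) return(FALSE)
  bn <- function(tr) unique(c(tr$subject[startsWith(tr$subject, "_:")],
                              tr$object[tr$type == "bnode"]))
  ba <- bn(ta); bb <- bn(tb)
  if (length(ba) != length(bb)) return(FALSE)
  key <- function(tr, map) {
    s <- tr$subject; o <- tr$object
    i <- startsWith(s, "_:"); s[i] <- map[s[i]]
    i <- tr$type == "bnode"; o[i] <- map[o[i]]
    sort(paste(s, tr$predicate, o, tr$type, tr$dtype))
  }
  target <- key(tb, stats::setNames(bb, bb))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(r) c(v[i], r))))
  }
  if (!length(ba)) return(identical(key(ta, character()), target))
  for (p in perms(bb))
    if (identical(key(ta, stats::setNames(p, ba)), target)) return(TRUE)
  FALSE
}
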