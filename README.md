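# opentoxr

An in-process R implementation of the OpenTox resource model for predictive
toxicology. QSAR workflows keep re-implementing the same plumbing: parse an
SDF, compute descriptors, fit a model, predict, and lose the provenance of
every step along the way. The OpenTox architecture solves this by making
every participant — chemical compound, property feature, dataset, algorithm,
predictive model, asynchronous task — an addressable resource with a URI,
manipulated through four uniform verbs (GET/POST/PUT/DELETE) and
interchangeable as an RDF graph. `opentoxr` implements that architecture for
R users: a resource store, a REST-style dispatcher with chemical-MIME
content negotiation, a task queue, and an aggregating SPARQL registry, all
testable offline in a single R session.

## The resource model

A dataset is a compound-by-feature table:

* `ot:Dataset --ot:dataEntry--> ot:DataEntry --ot:compound--> compound URI`
* `ot:DataEntry --ot:values--> ot:FeatureValue { ot:feature, ot:value }`
* `ot:Feature { dc:title, ot:units, ot:hasSource, owl:sameAs }`

`ot:hasSource` carries provenance: a feature points at the dataset it was
imported from, or at the algorithm/model that computed it. A model
(`ot:Model`) wires `ot:independentVariables`, `ot:dependentVariables` and
`ot:predictedVariables` to features and records its `ot:algorithm` and
`ot:trainingDataset`, so the entire chain "prediction → model → training
data → descriptors → structures" is machine-walkable.

Processing is uniform: every algorithm or model invocation reads a dataset
URI, computes, stores the result as a new dataset representation, and
returns a URI — never content. Long computations return `202 Accepted` and
a task URI whose status (`Queued`, `Running`, `Cancelled`, `Error`,
`Completed`) is polled by GET.

Built-in algorithms (a representative roster, extension is configuration):
descriptors (molecular weight, heavy-atom count, ring count, an additive
XLogP-style lipophilicity scheme), learners (OLS regression `LR`, k-means
`SimpleKMeans`, CART-style tree `J48`), a structural-alert rule model,
applicability-domain scorers (`leverage` with the 3p/n cutoff, centroid
distances, `fptanimoto` fingerprint similarity, `pcaRanges`), substructure
prescreening with a superset guarantee, and the `superservice`, which
resolves a model's missing descriptors from feature provenance before
predicting.

## Worked example

```r
library(opentoxr)
st <- otStore()

## import a small SDF with an ISSCAN-style numeric "Canc" field
sdf <- makeToySdf(6, fields = "Canc", seed = 42)
r <- dispatch(st, "POST", "/ambit2/dataset",
              headers = list(`Content-Type` = "chemical/x-mdl-sdfile"),
              body = sdf)
cat(r$status, trimws(r$body), "\n")
#> 200 http://localhost:8080/ambit2/dataset/1

## descriptor calculation: POST to the algorithm returns a task (202)
r2 <- dispatch(st, "POST", "/ambit2/algorithm/XLogP",
               headers = list(`Content-Type` = "application/x-www-form-urlencoded"),
               body = paste0("dataset_uri=", trimws(r$body)))
cat(r2$status, trimws(r2$body), "\n")
#> 202 http://localhost:8080/ambit2/task/c7372031-5f2e-f9b4-e30f-e88820a1cd87

## polling the completed task yields the result dataset URI (200)
r3 <- dispatch(st, "GET", trimws(r2$body))
cat(r3$status, trimws(r3$body), "\n")
#> 200 http://localhost:8080/ambit2/dataset/1?feature_uris[]=http%3A%2F%2Flocalhost%3A8080%2Fambit2%2Ffeature%2F3

## the same resource negotiates into any registered representation
r4 <- dispatch(st, "GET", trimws(r3$body), headers = list(Accept = "text/csv"))
cat(r4$body)
#> URI,XLogP
#> http://localhost:8080/ambit2/compound/1,0
#> http://localhost:8080/ambit2/compound/2,0
#> http://localhost:8080/ambit2/compound/3,0.36
#> http://localhost:8080/ambit2/compound/4,1.62
#> http://localhost:8080/ambit2/compound/5,-0.36
#> http://localhost:8080/ambit2/compound/6,2.34
```

The first column lists the dereferenceable compound URIs; the second the
computed lipophilicity score, stored as an `ot:FeatureValue` of a feature
whose `ot:hasSource` is the XLogP algorithm URI — GET the same URI with
`Accept: text/n3` to see the full RDF graph.

Model building and prediction follow the same pattern: POST
`dataset_uri` + `prediction_feature` to `/algorithm/LR` to obtain a model
URI, then POST a `dataset_uri` to the model URI to obtain predictions as a
filtered dataset URI. `registerResource()` / `registryQuery()` aggregate
the RDF of any set of resources into a registry queryable with SPARQL
SELECT.

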