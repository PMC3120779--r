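Package: opentoxr
Title: Resource-Oriented Predictive-Toxicology Services with RDF Interchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-process implementation of the OpenTox resource model for
    predictive toxicology: chemical compounds, annotated property features,
    datasets, descriptor and machine-learning algorithms, predictive models and
    asynchronous tasks, each addressable by URI and interchangeable as RDF
    graphs (RDF/XML, Turtle, N3). Includes a format-conversion layer over
    chemical MIME types (SDF, MOL, SMILES, InChI, CSV, ARFF), a REST-style
    request dispatcher with content negotiation and a task queue, an
    aggregating triple registry with a SPARQL SELECT endpoint, and a
    deterministic synthetic-data generator for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    ChemmineOB,
    rpart
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'rdf-graph.R'
    'rdf-turtle.R'
    'rdf-xml.R'
    'rdf-serialize.R'
    'ot-classes.R'
    'ot-rdf.R'
    'structure.R'
    'mime.R'
    'store.R'
    'algorithms.R'
    'tasks.R'
    'rest.R'
    'sparql.R'
    'registry.R'
    'fixtures.R'
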