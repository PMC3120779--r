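---
title: "Resource-oriented predictive toxicology: the models and design behind opentoxr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource-oriented predictive toxicology: the models and design behind opentoxr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opentoxr)
```

## The information model

`opentoxr` treats every participant of a QSAR workflow as an addressable
resource. The central structure is the dataset: an ordered list of data
entries, each relating one compound (or one conformer of a compound) to a
set of feature values. Features are first-class resources, not column
names: each carries a human-readable title (`dc:title`), optional units
(`ot:units`), provenance (`ot:hasSource`, whose range is a dataset,
algorithm or model) and ontology cross-links (`owl:sameAs`, e.g. to ECHA
endpoint individuals). Numeric features are typed as `ot:NumericFeature`
and their values serialize as `xsd:double`; everything else is kept as a
verbatim `xsd:string` — a deliberate choice that preserves data-entry
conventions such as the literal value `"blank"` found in public
carcinogenicity collections.

Two consequences follow. First, arbitrary SDF fields can be imported
without a schema: on upload, one feature is auto-created per distinct
field name, titled by the field name, with the new dataset as its source,
and the (title, source) pair acts as a unique key so a field seen twice in
one upload maps to one feature. Second, because computed features point at
the algorithm or model that produced them, the full chain *prediction →
model → training dataset → descriptors → structures* is machine-walkable
from any result URI.

When data arrive as RDF rather than a chemical file, the client's own
feature URIs and annotations are adopted unchanged — the uploader controls
the semantics of its columns.

## The processing paradigm

All computation follows one three-step scheme: read a dataset (or
compound) representation from a URI; process; write the result as a new
dataset representation and return its URI. Algorithms and models only ever
exchange URIs — the body of a successful POST to a compound, dataset,
algorithm or model resource is exactly one URI in `text/uri-list`.
Model building creates an `ot:Model` whose independent variables are the
training dataset's features minus the target, whose dependent variable is
the target, and whose predicted variables are freshly minted features
sourced to the model. Predictions are addressable as the input dataset
filtered to the predicted feature, using the
`dataset/{id}?feature_uris[]=.../model/{id}/predicted` alias; the alias is
resolved inside the feature filter (the printed protocol examples use it
only there, so we did not make it independently dereferenceable).

POSTs to algorithm and model resources are always asynchronous here: the
response is `202 Accepted` with a task URI, even for fast jobs. The
underlying queue is a cooperative single worker: jobs are lists of stage
closures executed FIFO, with the cancellation flag checked between stages.
This uniformity (rather than switching between synchronous and task
responses by job size) keeps clients to a single code path; dataset upload
remains synchronous, as uploads carry their own payload. With
`otStore(autorun = TRUE)` (the default) queued tasks run as soon as the
202 response has been composed, which preserves the observable protocol
while staying single-threaded; `autorun = FALSE` exposes the queue to
step-by-step control (`taskStep()`), which the tests use to observe
`Queued` states and cancellation.

## Algorithms

The roster is representative rather than exhaustive — the architectural
point is the uniform wrapping, and adding an algorithm is configuration:

* **Descriptors**: molecular weight (standard atomic masses, implicit
  hydrogens filled by a standard-valence model), heavy-atom count,
  ring count (cyclomatic number), and an additive XLogP-style
  lipophilicity score (per-element heavy-atom contributions, a ring bonus
  of 0.18 per ring and a penalty of 0.09 per fully substituted heavy atom,
  rounded to 4 decimals). The additive scheme is deterministic and
  monotone in composition; it is a demonstration descriptor, not a
  validated lipophilicity predictor.
* **Learners**: ordinary least squares (`LR`), k-means (`SimpleKMeans`)
  and a CART-style classification tree (`J48`, Gini splits, minimum leaf
  size 2, pruning disabled). OLS is fitted by the QR-based `stats`
  fitter; aliased coefficients from rank-deficient designs are dropped at
  prediction time, exactly as `lm()` treats them. k-means is initialized
  by deterministic farthest-point seeding: the seed parameter selects the
  first center (`seed mod n + 1`), subsequent centers maximize the minimum
  squared distance to the chosen set with ties broken by lowest row index,
  and Lloyd iterations run from that start — so results are reproducible
  from `(data, k, seed)` alone.
* **Rule models**: an ordered list of SMARTS alerts applied first-match-
  wins with a default label; built by POST without a training dataset, so
  the resulting `ot:Model` has no `ot:trainingDataset` triple and empty
  variable wiring except the predicted outcome feature. The shipped
  demonstration model flags Michael acceptors (`C=CC=O`) before generic
  carbonyls (`[OX1]=C`).
* **Applicability domains**: `leverage` computes h = x'(X'X)⁻¹x on the
  intercept-augmented design, so the training centroid has leverage 1/n
  and training leverages sum to the parameter count p; the in-domain
  cutoff is the conventional 3p/n. The distance methods flag points
  beyond the maximum training distance to the centroid; `fptanimoto`
  flags compounds whose best Tanimoto similarity to the training
  fingerprints falls below the threshold (default 0.7, the conventional
  similarity cutoff); `pcaRanges` keeps the score hyper-rectangle of the
  principal components covering at least 95% of training variance. Each
  domain model predicts two features: a numeric score and an in/out flag.
* **Substructure prescreen**: element counts implied by the SMARTS
  pattern are used as necessary conditions (anything not provably
  required — bracket atoms with disjunctions, negations or recursion —
  contributes nothing), so the candidate set is a guaranteed superset of
  the true matches, which are then verified by full SMARTS matching.
* **Superservice**: resolves each missing independent feature through its
  `ot:hasSource`; every source must be a local descriptor algorithm, and
  resolution is validated for all features before any computation starts.
  One level of resolution is supported — if a descriptor's source were
  itself a model, we fail rather than recurse, since unbounded provenance
  recursion has no termination guarantee.

## RDF serialization

Triples live in a plain data frame (subject, predicate, object, object
kind, literal datatype); Turtle/N3 and RDF/XML readers and writers are
implemented in the package (RDF/XML on top of xml2). The N3 `=` shorthand
is accepted on input and normalized to `owl:sameAs`; output always spells
`owl:sameAs` so that every serialization is valid Turtle. Data entries and
feature values are emitted as blank nodes; datasets, features, algorithms
and models are named nodes on output, while blank dataset nodes (as occur
in filtered views) are accepted on input. Graph comparison is exact
isomorphism: ground triples as sets, blank nodes matched by iterative
signature refinement with exhaustive backtracking over signature ties (the
test suite validates this matcher against a brute-force permutation
oracle on small graphs).

The bundled fixture texts follow the printed protocol excerpts they
document; a manifest records for each the expected statement and entity
counts, plus the minimal syntactic repairs that were needed (a stray
statement terminator, a missing angle bracket, a space inside a URI), and
the fixture tests verify the manifest on every run. One fixture is kept
verbatim although its namespaces are internally inconsistent (its
algorithm-type prefix and its Regression class URI cannot match the
companion data fixture); the regression-restricted query checks therefore
use the data fixture's namespace, and the manifest notes the discrepancy.

## The registry

The ontology registry aggregates the RDF of registered resources into one
queryable store, tagging each triple with the URI that contributed it.
Registration dereferences the URI through a pluggable fetcher (wired to a
local store's dispatcher by default, standing in for remote HTTP GET);
re-registration replaces the previous contribution, and a failed fetch
leaves the store untouched. Deregistration removes the URI's contribution
*and* every triple in other contributions whose subject or object equals
the URI — the broadest defensible reading of "all triples that refer to a
given URI"; a narrower subject-only reading would leave dangling object
references. The SPARQL engine supports SELECT with basic graph patterns,
nested OPTIONAL, FILTER (equality, inequality, regex) and DISTINCT —
sufficient for model-discovery queries — and results serialize as
`application/sparql-results+xml`. The tests hold the registry to an
oracle: every query must return exactly what the same query returns over
the in-memory union of the registered graphs.

## Synthetic data

`makeToySdf()` draws structures from a fixed pool of twenty small organic
molecules (shipped as a plain-text SDF with hand-checkable connection
tables) and attaches generated fields emulating the two public
carcinogenicity conventions the resource model must handle: a nominal
outcome over {active, unspecified, inactive} and a numeric score over
{1, 2, 3}. `makeRegressionDataset()` builds datasets with Gaussian
descriptor columns and a linear response y = 1 + Xβ + ε for learner
calibration. Both are pure functions of their arguments (seeded,
byte-stable). What these generators do *not* emulate: real descriptor
distributions (correlated, heavy-tailed), measurement error structure,
activity cliffs, or large-scale class imbalance — so passing tests
demonstrate the correctness of the machinery (import, provenance, model
wiring, protocol semantics), not predictive performance on real
toxicology data.

## Numerical choices and degenerate inputs

* Feature typing: numeric iff every non-empty imported value parses as a
  decimal; one non-numeric value makes the whole column textual.
* Duplicate feature values for one (entry, feature) pair: last write
  wins, with a warning.
* Dataset PUT is pure union: existing values are never overwritten or
  removed, which also makes PUT idempotent. Records are matched to
  existing entries by InChI.
* Compound PUT appends a conformer unless an identical structure (by
  InChI) is already present.
* Entries missing an independent value are skipped by prediction with a
  warning rather than failing the whole batch.
* Singular X'X in domain fitting is an error advising feature reduction;
  rank-deficient OLS is tolerated via dropped aliased coefficients.
* Unknown feature URIs in a filter are ignored (tolerant reader);
  deleting a feature cascades to its values with a warning; deleting a
  dataset removes the features it sourced; remote references are never
  checked.
* Tanimoto similarity of two empty bitsets is defined as 0.

## Problem sizes used in the checks

The shipped verification uses deliberately small instances chosen to
exercise every code path: serialization round trips on randomized datasets
of up to 50 compounds and 10 features across all three dialects (100 in
the acceptance script, 10 per dialect in the unit suite, plus the fixture
graphs); OLS recovery at n = 200 and noise 0.1 over 100 seeds (40 in the
unit suite); 20 superservice/manual-chain pairs; a 100-record library for
the prescreen checks; a 10,000-entry dataset for the streaming-writer
buffering assertion. Statistical acceptance (3-standard-error coverage of
the OLS slope in at least 95% of seeds) follows the usual Monte-Carlo
convention for a 99.7% interval.

## Known limitations

The store is an in-memory environment with sequential ids — suitable for
analysis sessions and testing, not for concurrent multi-user service (the
architecture keeps the backend abstract; a relational backend would slot
in behind the same operations). The dispatcher is an in-process HTTP
analogue: it implements routes, verbs, status codes and content
negotiation, but does not open a network socket. SMILES canonicalization,
InChI and SMARTS matching delegate to OpenBabel, so canonical strings are
toolkit-specific (all identity checks are by graph equivalence, never
string equality across toolkits). The SPARQL subset excludes CONSTRUCT,
ASK, property paths and aggregation. No authentication or authorization
layer is provided.
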