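PREFIX ot:   <http://www.opentox.org/api/1.1#>
PREFIX ota:   <http://www.opentox.org/algorithms.owl#>
PREFIX owl:   <http://www.w3.org/2002/07/owl#>
PREFIX dc:   <http://purl.org/dc/elements/1.1/>
PREFIX rdfs:   <http://www.w3.org/2000/01/rdf-schema#>
PREFIX rdf:   <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX otee:   <http://www.opentox.org/echaEndpoints.owl#>
   SELECT ?Model ?algorithm ?xvars ?descriptorAlgorithms ?yvars ?endpoints ?predicted
      WHERE {
      ?Model rdf:type ot:Model.
   OPTIONAL {?Model dc:title ?title }.
   OPTIONAL {
      ?Model ot:algorithm ?algorithm.
      ?algorithm rdf:type <http://www.opentox.org/algorithmTypes.owl/#Regression>.
   }.
   OPTIONAL {
      ?Model ot:independentVariables ?xvars.
      OPTIONAL {?xvars ot:hasSource ?descriptorAlgorithms. }.
   }.
   OPTIONAL {
      ?Model ot:dependentVariables ?yvars.
      OPTIONAL {?yvars owl:sameAs ?endpoints. }.
   }.
   OPTIONAL {
      ?Model ot:predictedVariables ?predicted.
      OPTIONAL {?predictions owl:sameAs ?endpoints. }.
   }.
}
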