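# Model representation (N3). Repairs vs the printed text: removed a stray "."
# after the feature subject URI and added the missing final "." .
@prefix ot:   <http://www.opentox.org/api/1.1#>.
@prefix dc:   <http://purl.org/dc/elements/1.1/>.
@prefix rdfs:   <http://www.w3.org/2000/01/rdf-schema#>.
<http://apps.ideaconsult.net:8080/ambit2/model/9>
   a   ot:Model ;
   dc:title "XLogP" ;
   ot:algorithm
<http://apps.ideaconsult.net:8080/ambit2/algorithm/org.openscience.cdk.qsar.descriptors.molecular.XLogPDescriptor>;
   ot:predictedVariables
      <http://apps.ideaconsult.net:8080/ambit2/feature/22114>.
<http://apps.ideaconsult.net:8080/ambit2/feature/22114>
   a   ot:Feature.
<http://apps.ideaconsult.net:8080/ambit2/algorithm/org.openscience.cdk.qsar.descriptors.molecular.XLogPDescriptor>
   a   ot:Algorithm.
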