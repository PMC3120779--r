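# Algorithm representation (N3), as printed.
@prefix ot:   <http://www.opentox.org/api/1.1#>.
@prefix dc:   <http://purl.org/dc/elements/1.1/>.
@prefix rdfs:   <http://www.w3.org/2000/01/rdf-schema#>.
@prefix bo:   <http://www.blueobelisk.org/ontologies/chemoinformatics-algorithms/#>.
@prefix xsd:   <http://www.w3.org/2001/XMLSchema#>.
@prefix ota:   <http://www.opentox.org/algorithmTypes.owl#>.
<http://apps.ideaconsult.net:8080/ambit2/algorithm/org.openscience.cdk.qsar.descriptors.molecular.XLogPDescriptor>
   a   ot:Algorithm, ota:DescriptorCalculation ;
   dc:title "XLogP"^^xsd:string ;
   bo:instanceOf bo:xlogP.
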