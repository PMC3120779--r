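# Prediction-results dataset excerpt (N3): a blank dataset node with two data
# entries. Repairs vs the printed text: restored the missing "<" before the
# first compound URI; "=" normalized to owl:sameAs.
@prefix ot:   <http://www.opentox.org/api/1.1#>.
@prefix dc:   <http://purl.org/dc/elements/1.1/>.
@prefix:   <http://apps.ideaconsult.net:8080/ambit2/>.
@prefix rdfs:   <http://www.w3.org/2000/01/rdf-schema#>.
@prefix owl:   <http://www.w3.org/2002/07/owl#>.
@prefix xsd:   <http://www.w3.org/2001/XMLSchema#>.
@prefix rdf:   <http://www.w3.org/1999/02/22-rdf-syntax-ns#>.
@prefix otee:   <http://www.opentox.org/echaEndpoints.owl#>.
[] a   ot:Dataset ;
   ot:dataEntry
      [a   ot:DataEntry ;
       ot:compound <http://apps.ideaconsult.net:8080/ambit2/compound/147678/conformer/419677> ;
       ot:values
         [a   ot:FeatureValue ;
          ot:feature <http://apps.ideaconsult.net:8080/ambit2/feature/22114> ;
          ot:value "2.74"^^xsd:double
         ]
      ] ;
   ot:dataEntry
      [a   ot:DataEntry ;
       ot:compound <http://apps.ideaconsult.net:8080/ambit2/compound/2146/conformer/419678> ;
       ot:values
         [a   ot:FeatureValue ;
          ot:feature <http://apps.ideaconsult.net:8080/ambit2/feature/22114> ;
          ot:value "1.59"^^xsd:double
         ]
      ].
<http://apps.ideaconsult.net:8080/ambit2/algorithm/org.openscience.cdk.qsar.descriptors.molecular.XLogPDescriptor>
   a   ot:Algorithm.
<http://apps.ideaconsult.net:8080/ambit2/feature/22114>
   a   ot:Feature, ot:NumericFeature ;
   dc:title "XLogP" ;
   ot:hasSource
<http://apps.ideaconsult.net:8080/ambit2/algorithm/org.openscience.cdk.qsar.descriptors.molecular.XLogPDescriptor> ;
   =   otee:ENDPOINT_Octanol-water_partition_coefficient.
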