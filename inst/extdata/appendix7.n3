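# Single CPDBAS entry (N3); "=" normalized to owl:sameAs by the reader.
@prefix ot:   <http://www.opentox.org/api/1.1#>.
@prefix dc:   <http://purl.org/dc/elements/1.1/>.
@prefix:   <http://apps.ideaconsult.net:8080/ambit2/>.
@prefix otee:   <http://www.opentox.org/echaEndpoints.owl#>.
@prefix rdfs:   <http://www.w3.org/2000/01/rdf-schema#>.
@prefix owl:   <http://www.w3.org/2002/07/owl#>.
@prefix xsd:   <http://www.w3.org/2001/XMLSchema#>.
@prefix ac:   <http://apps.ideaconsult.net:8080/ambit2/compound/>.
@prefix ad:   <http://apps.ideaconsult.net:8080/ambit2/dataset/>.
@prefix rdf:   <http://www.w3.org/1999/02/22-rdf-syntax-ns#>.
@prefix af:   <http://apps.ideaconsult.net:8080/ambit2/feature/>.
af:21611
   a   ot:Feature ;
   dc:title "ActivityOutcome_CPDBAS_Mutagenicity" ;
   ot:hasSource ad:10 ;
   =   otee:Mutagenicity.
af:21604
   a   ot:Feature ;
   dc:title "TD50_Dog_mg" ;
   ot:hasSource ad:10 ;
   ot:units "mg" ;
   =   otee:ENDPOINT_Carcinogenicity.
ac:144089
   a   ot:Compound.
ad:10
   a   ot:Dataset ;
   ot:dataEntry
      [ a   ot:DataEntry ;
       ot:compound ac:144089 ;
       ot:values
         [a   ot:FeatureValue ;
          ot:feature af:21604 ;
          ot:value "blank"^^xsd:string
         ] ;
       ot:values
         [a   ot:FeatureValue ;
          ot:feature af:21611 ;
          ot:value "active"^^xsd:string
         ]
      ].
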