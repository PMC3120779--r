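# "Canc" field of the ISSCAN dataset (N3); prefixes as in appendix 7.
@prefix ot:   <http://www.opentox.org/api/1.1#>.
@prefix dc:   <http://purl.org/dc/elements/1.1/>.
@prefix otee:   <http://www.opentox.org/echaEndpoints.owl#>.
@prefix rdfs:   <http://www.w3.org/2000/01/rdf-schema#>.
@prefix ad:   <http://apps.ideaconsult.net:8080/ambit2/dataset/>.
@prefix af:   <http://apps.ideaconsult.net:8080/ambit2/feature/>.
ad:9 a ot:Dataset ;
   rdfs:seeAlso "http://www.epa.gov/NCCT/dsstox/sdf_isscan_external.html" ;
   dc:source "ISSCAN_v3a_1153_19Sept08.1222179139.sdf" ;
   dc:title "ISSCAN: Istituto Superiore di Sanita, CHEMICAL CARCINOGENS: STRUCTURES AND EXPERIMENTAL DATA".
af:21573
   a ot:Feature ;
   dc:title "Canc" ;
   ot:hasSource ad:9 ;
   =   otee:ENDPOINT_Carcinogenicity.
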