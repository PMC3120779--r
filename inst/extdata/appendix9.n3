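# Subset of CPDBAS fields (N3); prefixes as in appendix 7. Repair vs the
# printed text: the IUPAC-name ontology URI contains a space in print,
# replaced by %20 here.
@prefix ot:   <http://www.opentox.org/api/1.1#>.
@prefix dc:   <http://purl.org/dc/elements/1.1/>.
@prefix otee:   <http://www.opentox.org/echaEndpoints.owl#>.
@prefix rdfs:   <http://www.w3.org/2000/01/rdf-schema#>.
@prefix ad:   <http://apps.ideaconsult.net:8080/ambit2/dataset/>.
@prefix af:   <http://apps.ideaconsult.net:8080/ambit2/feature/>.
af:21603
   a   ot:Feature ;
   dc:title "STRUCTURE_MolecularWeight" ;
   ot:hasSource ad:10 ;
   =   <http://example.org#an-ontology-entry-representing-molecular-weight>.
af:21607
   a   ot:Feature ;
   dc:title "STRUCTURE_ChemicalName_IUPAC" ;
   ot:hasSource ad:10 ;
   =   <http://example.org#an-ontology-entry-representing-IUPAC%20name>.
af:21610
   a   ot:Feature ;
   dc:title "ActivityOutcome_CPDBAS_Rat" ;
   ot:hasSource ad:10 ;
   =   otee:ENDPOINT_Carcinogenicity.
ad:10
   a   ot:Dataset ;
   rdfs:seeAlso "http://www.epa.gov/NCCT/dsstox/sdf_cpdbas.html" ;
   dc:title "CPDBAS: Carcinogenic Potency Database Summary Tables - All Species".
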