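# Two remote models sharing a training dataset (N3), as printed.
@prefix:   <http://apps.ideaconsult.net:8080/ambit2/>.
@prefix ot:   <http://www.opentox.org/api/1.1#>.
@prefix dc:   <http://purl.org/dc/elements/1.1/>.
@prefix tuma:   <http://opentox.informatik.tu-muenchen.de:8080/OpenTox-dev/algorithm/>.
@prefix tumm:   <http://opentox.informatik.tu-muenchen.de:8080/OpenTox-dev/model/>.
@prefix ota:   <http://www.opentox.org/algorithmTypes.owl#>.
@prefix otee:   <http://www.opentox.org/echaEndpoints.owl#>.
@prefix bo:   <http://www.blueobelisk.org/ontologies/chemoinformatics-algorithms/#>.
@prefix rdfs:   <http://www.w3.org/2000/01/rdf-schema#>.
@prefix am:   <http://apps.ideaconsult.net:8080/ambit2/model/>.
@prefix owl:   <http://www.w3.org/2002/07/owl#>.
@prefix xsd:   <http://www.w3.org/2001/XMLSchema#>.
@prefix ac:   <http://apps.ideaconsult.net:8080/ambit2/compound/>.
@prefix rdf:   <http://www.w3.org/1999/02/22-rdf-syntax-ns#>.
@prefix ad:   <http://apps.ideaconsult.net:8080/ambit2/dataset/>.
@prefix ag:   <http://apps.ideaconsult.net:8080/ambit2/algorithm/>.
@prefix af:   <http://apps.ideaconsult.net:8080/ambit2/feature/>.
tumm:TUMOpenToxModel_kNN_92
   a   ot:Model ;
   dc:title "OpenTox model created with TUM's kNNregression model learning web service." ;
   ot:algorithm tuma:kNNregression ;
   ot:dependentVariables
      af:22200 ;
   ot:independentVariables
      af:22213, af:22137, af:22252, af:22127 ;
   ot:predictedVariables
      af:27501 ;
   ot:trainingDataset ad:R545.
am:33
   a   ot:Model ;
   dc:title "Caco-2 Cell Permeability" ;
   ot:algorithm ag:LR ;
   ot:dependentVariables
      af:22200 ;
   ot:independentVariables
      af:22213, af:22137, af:22252, af:22127 ;
   ot:predictedVariables
      af:26182 ;
   ot:trainingDataset ad:R545.
ag:LR
   a   ot:Algorithm, ota:Supervised, ota:EagerLearning, ota:SingleTarget, ota:Regression;
   dc:title "Linear regression"^^xsd:string.
af:22127
   a   ot:Feature ;
   dc:title "FPSA-2" ;
   ot:hasSource
<http://apps.ideaconsult.net:8080/ambit2/algorithm/org.openscience.cdk.qsar.descriptors.molecular.CPSADescriptor>.
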