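PREFIX mcf: <http://anatkb.example.org/mcf#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
SELECT ?bone WHERE {
  ?sart rdfs:subClassOf mcf:Sartorius .
  ?tendon mcf:PartOf ?sart .
  ?tendon rdfs:subClassOf mcf:Tendon .
  ?tendon mcf:InsertOn ?bone .
}
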