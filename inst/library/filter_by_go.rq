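# Filter the proteins given on standard input (bound to ?in1) by a Gene
# Ontology class annotation, returning the matching proteins with labels.
# $1: GO class ID (local name, e.g. GO_0045202)
PREFIX fv: <http://purl.example.org/fixture/vocab#>
PREFIX fxg: <http://purl.example.org/fixture/go/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
SELECT ?in1 ?label
WHERE {
  ?in1 fv:goClass fxg:$1 .
  ?in1 rdfs:label ?label .
}
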