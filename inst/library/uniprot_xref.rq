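# Cross-references of the proteins given on standard input (bound to ?in1)
# restricted to one target database.
# $1: a SPARQL string literal naming the database, e.g. "PDB"
PREFIX fv: <http://purl.example.org/fixture/vocab#>
SELECT ?in1 ?xref
WHERE {
  ?in1 fv:seeAlso ?xref .
  ?xref fv:database $1 .
}
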