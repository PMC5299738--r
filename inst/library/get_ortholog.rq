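# Members of the ortholog group(s) containing one protein.
# $1: protein entry ID (local name)
PREFIX fv: <http://purl.example.org/fixture/vocab#>
PREFIX fxp: <http://purl.example.org/fixture/protein/>
SELECT ?member
WHERE {
  ?group fv:member fxp:$1 .
  ?group fv:member ?member .
}
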