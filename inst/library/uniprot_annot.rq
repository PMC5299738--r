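# Annotation dump for one protein entry.
# $1: protein entry ID (local name, e.g. P00007)
PREFIX fxp: <http://purl.example.org/fixture/protein/>
SELECT ?p ?o
WHERE {
  fxp:$1 ?p ?o .
}
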