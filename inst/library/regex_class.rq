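# Classes whose label matches a regular expression. Usable against any
# endpoint that labels its classes with rdfs:label.
# $1: a SPARQL string literal holding the pattern, quotes included,
#     e.g. "^apolipoprotein"
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
SELECT ?class ?label
WHERE {
  ?class rdfs:label ?label .
  FILTER regex(?label, $1)
}
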