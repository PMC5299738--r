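# Differentially expressed proteins for one sample condition, with the
# probe showing the signal and the publication describing the experiment.
# $1: condition class ID (local name, e.g. EFO_0000249)
PREFIX fv: <http://purl.example.org/fixture/vocab#>
PREFIX fxc: <http://purl.example.org/fixture/condition/>
SELECT ?protein ?probe ?pubmed
WHERE {
  ?probe fv:diffExpressedIn fxc:$1 .
  ?probe fv:refersTo ?protein .
  ?probe fv:pubmed ?pubmed .
}
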