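# sparqlpipe

A composable SPARQL client for the Unix command line, written as an R
package. It targets the situation common in life-science data
integration: the data you need is spread over several RDF triple stores
(protein annotation, ortholog groups, expression atlases, ...), each
behind its own SPARQL endpoint, and writing federated SPARQL by hand is
the main obstacle to using them.

`sparqlpipe` removes that obstacle three ways:

1. **Shortcut mode** generates a complete `SELECT` query around a single
   triple pattern `s p o` from command-line options: `-S` fixes the
   subject, `-P` the predicate (property paths like
   `up:organism/up:scientificName` are accepted), `-O` the object, `-L`
   adds a `LIMIT`. Unspecified positions become the projected variables
   `?s ?p ?o`.
2. **Template mode** resolves a SPARQL template by name from a local or
   remote library (or a file path or URI), and substitutes positional
   parameters into `$1, $2, ...` placeholders — placeholders inside
   string literals and IRIs are never touched, and `$12` is placeholder
   twelve, not `$1` followed by `2`.
3. **Pipe federation**: each invocation writes its variable bindings as
   TSV on stdout and reads a TSV binding table on stdin. Selected input
   columns are injected into the downstream query as a SPARQL `VALUES`
   block (deduplicated, chunked at `--chunk-size` rows per request), so
   `stage1 endpointA ... | stage2 endpointB ...` computes the same
   multiset of rows as the nested-loop join over the two endpoints.

Endpoint nicknames, prefix declarations (used both to expand
`label:local` arguments and to abbreviate IRIs in output with `-a`) and
template library roots come from layered configuration files; `-q`
prints the generated query without contacting any endpoint.

The package also ships its test bench as first-class code: a seeded
synthetic RDF fixture generator (`build_fixture()`) emulating
protein-annotation, ortholog and differential-expression stores at toy
scale, an in-process evaluator for the SPARQL subset the client emits
(`evaluate_query()`), a nested-loop join oracle (`oracle_join()`), and a
loopback SPARQL Protocol server (`serve_loopback()`) so end-to-end HTTP
runs work fully offline.

## Worked example

Serve two toy graphs over loopback HTTP and run the classic two-stage
pipeline — ortholog lookup on one endpoint, label lookup on another:

```r
library(sparqlpipe)
orth <- build_fixture("ortholog_db", 12, seed = 2, group_sizes = c(4, 4, 4))
prot <- build_fixture("protein_annot", 12, seed = 3)
srv <- serve_loopback(list(mbgd = orth, uniprot = prot))
cfg <- tempfile()
writeLines(c(sprintf("ENDPOINT mbgd %s", endpoint_url(srv, "mbgd")),
             sprintf("ENDPOINT uniprot %s", endpoint_url(srv, "uniprot"))), cfg)
```

then from a shell (`sparqlpipe` is the script in `exec/`):

```sh
$ sparqlpipe mbgd get_ortholog P00005 --config $cfg
member
<http://purl.example.org/fixture/protein/P00005>
<http://purl.example.org/fixture/protein/P00006>
<http://purl.example.org/fixture/protein/P00008>
<http://purl.example.org/fixture/protein/P00011>

$ sparqlpipe mbgd get_ortholog P00005 --config $cfg | \
  sparqlpipe uniprot -S 1 -P rdfs:label --config $cfg
s	o
<http://purl.example.org/fixture/protein/P00005>	mitochondrial permease 5
<http://purl.example.org/fixture/protein/P00006>	mitochondrial permease 6
<http://purl.example.org/fixture/protein/P00008>	mitochondrial transporter 8
<http://purl.example.org/fixture/protein/P00011>	membrane transporter 11
```

The first command instantiates the `get_ortholog` template (`$1` ←
`P00005`) and prints the group members; the second reads column 1 of
that output, injects the four IRIs as a `VALUES (?s) { ... }` block into
the generated `?s rdfs:label ?o` query, and prints one label per member.
Adding `-q` to either command prints the query it would send instead of
executing it; `-a` abbreviates output IRIs (e.g.
`http://www.w3.org/2000/01/rdf-schema#label` → `rdfs:label`).

Exit codes are stable per error class: configuration 2, query
generation 3, endpoint/template resolution 4, transport 5, data
format 6.

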