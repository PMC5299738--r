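---
title: "Composing SPARQL queries across endpoints: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composing SPARQL queries across endpoints: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparqlpipe)
```

## The problem

Biological knowledge published as RDF lives behind many independent
SPARQL endpoints. A question as simple as "which orthologs of this
protein carry a given GO annotation" spans two or three of them, and the
standard answer — a federated SPARQL query with `SERVICE` sub-queries —
is exactly the kind of code most users cannot or will not write.
`sparqlpipe` replaces that with three smaller mechanisms: generating
one-pattern queries from options, instantiating reusable query
templates, and composing per-endpoint queries through Unix pipes by
transferring variable bindings.

## Shortcut queries

A shortcut invocation describes one triple pattern. Each of `-S`, `-P`,
`-O` either fixes a position to a constant or leaves it a variable; the
fixed variables are always `?s`, `?p`, `?o`, which makes the downstream
join target predictable for pipe composition and for anyone reading
`-q` output. Only unspecified (or input-bound) positions are projected,
in subject–predicate–object order. Tokens classify in a fixed order:
bare decimal integers are input-column references; `<...>` or
`http(s)://...` are IRIs; a predicate containing a path operator
(`/ | ^ * + ? ( )`) outside a bracketed IRI is a property path;
`label:local` with a declared label is a prefixed name — an *undeclared*
label is an error rather than a silent literal, because that case is
almost always a typo; an explicitly double-quoted token is a literal
with the quotes stripped (this is also the escape hatch for passing a
numeric literal, since bare integers mean columns); everything else is a
plain literal.

Three design points were genuinely open and were settled as follows.

* **No implicit LIMIT.** `-L` is honored when given; otherwise the query
  is unlimited. Silent truncation corrupts pipelines, and endpoints
  impose their own caps anyway.
* **All-constant patterns** (`-S`, `-P` and `-O` all fixed) would have
  an empty projection, which SPARQL forbids. The generator emits
  `SELECT (COUNT(*) AS ?n)` over the pattern instead, so `0` versus
  `>= 1` signals absence/presence while the TSV contract is preserved.
* **Prefix minimality.** The generated prologue declares exactly the
  prefix labels used in the body — queries stay copy-pasteable and
  self-contained.

The correctness contract is oracle equivalence: on a fixture graph the
generated query's solutions must equal a brute-force scan of the triple
set filtered by the fixed positions, for all eight fixed/unfixed
combinations. The test suite and the acceptance script both assert this
on a 50-entity store.

## Templates and placeholders

Templates are plain SPARQL files with `$N` placeholders, resolved in a
fixed order: existing file path, configured library directories
(`<name>.rq`, then `<name>`), prefixed URI against a library prefix,
then absolute URI; local resolution never touches the network.
Placeholders are recognized *outside* string literals, IRIs and
comments only, with the longest digit run winning, so `$12` can never be
misread as `$1` followed by `2`. Substitution is simultaneous and
verbatim: parameters may be bare IDs, prefixed names, IRIs or quoted
literals, because only the template author knows the lexical form the
insertion point requires. One consequence worth stating plainly: a
template that needs a *string* parameter (a regex pattern, a database
name) documents that the caller passes the quotes, e.g.
`regex_class '"^apolipoprotein"'` — auto-quoting was rejected because it
would make IRI-valued parameters impossible, and a `$1` inside a quoted
string is by definition inert.

After substitution the engine checks that unmasked braces and
parentheses balance and that no placeholder survives; a full grammar
check is deliberately left to the endpoint (or, in tests, to an
independent SPARQL parser), since templates may use any SPARQL 1.1
construct, not just the subset the fixture evaluator understands.

## Pipe federation via VALUES injection

A downstream invocation reads a TSV binding table on stdin. In shortcut
mode, `-S 1` binds column 1 to `?s` (similarly `-P`/`-O`); templates opt
in by using the reserved variables `?in1, ?in2, ...`. The bound columns
are deduplicated preserving first occurrence, split into chunks of at
most `--chunk-size` rows (default 100, chosen to keep request URLs and
bodies comfortably under typical endpoint limits), and each chunk
becomes one outgoing query with a `VALUES (?v1 ... ?vk) { ... }` block
inserted at the head of the outermost WHERE group. The concatenation of
chunk results is the logical result; chunk size must not change it, and
the tests assert invariance for sizes 1, 3 and 100.

This VALUES-based design was chosen over per-row query rewriting (one
HTTP round trip per binding — unacceptable) and over `SERVICE`-clause
rewriting (requires the *endpoint* to federate, which is exactly what
pipe composition avoids). Deduplication matches the "list of IDs"
intuition of piped output: VALUES duplicates would multiply join rows.

TSV erases RDF term types, so input tokens are re-classified: declared
prefixed names stay prefixed names (abbreviated output from an upstream
`-a` stage round-trips), bracketed or `http(s)` tokens become IRIs,
everything else a quoted literal. The first stdin line is taken as a
header only when every field looks like a variable name *and* at least
one of them is referenced by the downstream query; `--no-in-header`
forces data. A stray header that fails the second condition is thus
carried as a data row — it serializes as a literal, which cannot match
an IRI-subject pattern, so join results are unaffected; the rule keeps
`cut -f1` output and headered TSV both usable without flags.

The semantic reference for all of this is `oracle_join()`: evaluate the
upstream query, then for each distinct binding evaluate the downstream
query with the join variable substituted, and union the solutions. The
end-to-end tests run the real command-line launcher against loopback
HTTP servers and compare multisets against this oracle, never against
hand-written expectations.

## The synthetic fixtures and what they do (not) show

`build_fixture()` generates three graph shapes under one project-owned
namespace (`http://purl.example.org/fixture/...`): `protein_annot`
(per protein: one `rdfs:label`, one organism link whose organism carries
a scientific name, 1–3 GO-class links with labeled classes, 0–2
cross-references tagged with a database name), `ortholog_db` (the same
protein namespace partitioned into member-linked groups, default size
4), and `expression_db` (probes linked to one of three labeled disease
conditions, to a protein, and to a PubMed-style literal). Organism,
GO-count and cross-reference choices are uniform draws from a seeded
generator; roughly one protein in seven is deterministically named
`apolipoprotein <X>` so regex searches over labels always have hits.
Default scales are desk-sized (a few dozen entities; the largest graph
in the tests is a 50-entity, ~300-triple store) — large enough to make
multiset bugs visible, small enough that the whole suite runs in
seconds. `rdfs:label` is the one real-world predicate reused, because
label lookup and label abbreviation are part of the documented
behavior; everything else is deliberately *not* the real UniProt/MBGD
vocabulary, so the tests cannot be mistaken for fidelity to external
schemas.

Passing tests therefore show that query generation, substitution,
binding transfer and protocol handling are correct over well-formed
RDF with IRI subjects and modest result sizes. They do not show
robustness to the quirks of production endpoints: result paging,
timeouts under load, blank-node-heavy data, named graphs, or
datatype-sensitive joins (TSV re-classification types every unrecognized
token as a plain string literal).

## The in-process evaluator and loopback server

No R SPARQL engine was available to the package, so the fixture
evaluator is hand-written for exactly the subset the client emits:
`SELECT [DISTINCT]` with variable projection, `*` or `COUNT(*)`; basic
graph patterns including variable predicates; property paths
(`/`, `|`, `^`, `*`, `+`, `?`, grouping — closures computed by fixpoint
iteration, which is fine at fixture scale); `VALUES`; `FILTER regex`
(mapped to PCRE with the `i` flag honored); and `LIMIT`. Filters are
collected and applied at the end of the group, matching SPARQL's
group-level filter scope. Solutions are multisets; `sort_solutions`
orders rows lexicographically over canonical term strings so the
loopback server is byte-stable across identical requests. Terms travel
internally as canonical SPARQL lexical strings (`<iri>`,
`"literal"@lang`, `"literal"^^<dt>`), which reduces joins to string
equality.

The loopback server (`serve_loopback()`) runs that evaluator behind a
real HTTP listener in a background R process, speaking the SPARQL 1.1
Protocol: GET and form-encoded POST, JSON and XML result formats
negotiated from the Accept header, `406` for unsupported formats, `400`
for unparseable queries. The client picks GET when the URL-encoded
request stays within 2000 bytes and POST otherwise; both paths are
exercised against the server. The independent cross-checks are kept
separate from the implementation: result-format writers/parsers are
tested JSON-against-XML, and generated queries are checked against an
external SPARQL 1.1 grammar in the test suite.

## Configuration

Configuration is line-oriented (`PREFIX label: <iri>`,
`ENDPOINT nickname url`, `LIBRARY name root [prefix:]`, `#` comments),
merged builtin < user files < `--config` flags with last-writer-wins per
key — human-diffable, and PREFIX lines are copy-pasteable into SPARQL.
Abbreviation uses the longest matching declared namespace (later
declaration wins ties), and refuses to abbreviate when the remainder
contains whitespace, `/` or `#`, since emitting an unparseable prefixed
name would corrupt downstream queries; the expand∘abbreviate round trip
is asserted over a thousand generated pairs plus nested-namespace
adversarial cases. The builtin layer declares well-known W3C prefixes,
example endpoint nicknames pointing at public services (never contacted
by any test), the packaged template library, and the fixture namespace
prefixes used in demos.

## Numerical and procedural choices, summarized

* Scales: fixtures of 12–50 entities; 1000 round-trip pairs; 200
  generated templates; chunk sizes 1/3/100 — each the smallest size that
  distinguishes the failure mode it guards (chunk 1 exercises maximal
  chunking, 100 the no-chunking path).
* HTTP timeout 60 s default, no retries: pipeline failures should be
  loud and fast.
* Errors are classed conditions mapped to stable exit codes
  (config 2, generation 3, resolution 4, transport 5, format 6), and
  diagnostics go to stderr only, so stdout remains a clean TSV stream.
* `-q` is guaranteed network-free; tests enforce this with a transport
  spy.

## Known limitations

Shortcut mode covers exactly one triple pattern (by design — anything
richer belongs in a template). The evaluator's SPARQL subset excludes
`OPTIONAL`, `UNION`, subqueries and aggregation beyond `COUNT(*)`;
templates using those run fine against real endpoints but cannot be
oracle-tested in-process. Binding transfer reads the whole stdin table
before the first outgoing query (no streaming), and TSV output drops
literal datatype/language annotations unless `--raw-terms` is given.
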