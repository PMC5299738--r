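Package: sparqlpipe
Title: Composable SPARQL Client with Query Shortcuts, Templates and
    Pipe-Based Federation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A command-line oriented SPARQL client for querying RDF
    databases without writing SPARQL by hand.  Shortcut options (-S, -P,
    -O, -L) generate a SELECT query around a single triple pattern;
    templates with positional placeholders ($1, $2, ...) are resolved from
    local libraries or fetched by URI and instantiated with parameters;
    and multiple invocations against distinct endpoints compose through
    Unix pipes by transferring variable bindings as tab-separated values,
    injected into the downstream query as a VALUES block.  Ships layered
    endpoint/prefix configuration, URI abbreviation for readable output, a
    seeded synthetic RDF fixture generator with an in-process SPARQL
    evaluator, and a loopback SPARQL Protocol server for offline
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    curl,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    callr,
    httpuv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
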