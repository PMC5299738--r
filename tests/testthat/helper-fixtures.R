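# Shared test utilities: multiset comparison, an independent SPARQL 1.1
# grammar check (Python rdflib), loopback endpoint helpers, and a fake
# in-process transport backed by the fixture evaluator.

ms <- function(result) sparqlpipe:::results_multiset(result)

expect_same_multiset <- function(a, b) {
  expect_identical(ms(a), ms(b))
}

# Independent SPARQL 1.1 parser: rdflib's grammar, run out of process.
rdflib_parses <- function(query) {
  qf <- tempfile(fileext = ".rq")
  writeLines(query, qf)
  on.exit(unlink(qf))
  script <- sprintf(
    "from rdflib.plugins.sparql import prepareQuery; prepareQuery(open(%s).read())",
    deparse(qf))
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  is.null(status) || status == 0L
}

anon_endpoint <- function(url) {
  resolve_endpoint(url, sparqlpipe:::empty_config())
}

# Transport that evaluates against an in-memory graph instead of HTTP.
graph_transport <- function(graph, format = c("json", "xml")) {
  format <- match.arg(format)
  function(url, query, accept) {
    res <- evaluate_query(graph, query, sort_solutions = TRUE)
    if (format == "json") {
      list(status = 200L, type = "application/sparql-results+json",
           body = as.character(write_results_json(res)))
    } else {
      list(status = 200L, type = "application/sparql-results+xml",
           body = write_results_xml(res))
    }
  }
}

# Run the installed command-line launcher as a real child process.
run_cli_exec <- function(args, input = NULL) {
  script <- system.file("exec", "sparqlpipe", package = "sparqlpipe")
  if (!nzchar(script)) script <- file.path("..", "..", "exec", "sparqlpipe")
  out <- suppressWarnings(system2(
    "Rscript", c(script, shQuote(args)),
    stdout = TRUE, stderr = FALSE,
    input = input,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, out = as.character(out))
}

# Loopback server with deferred shutdown tied to the calling frame.
local_loopback <- function(graphs, env = parent.frame()) {
  srv <- serve_loopback(graphs)
  withr::defer(stop_server(srv), envir = env)
  srv
}

# Config file redirecting endpoint nicknames at a loopback server.
local_loopback_config <- function(srv, nicknames = srv$graphs,
                                  env = parent.frame()) {
  path <- tempfile(fileext = ".config")
  writeLines(vapply(nicknames, function(nm) {
    sprintf("ENDPOINT %s %s", nm, endpoint_url(srv, nm))
  }, character(1)), path)
  withr::defer(unlink(path), envir = env)
  path
}
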