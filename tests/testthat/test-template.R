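# Independent tokenizer oracle: strip string literals, IRIs and comments
# with a character scanner written differently from the implementation
# (regex-based removal), then count $N tokens.
oracle_count <- function(text) {
  stripped <- gsub("'''.*?'''|\"\"\".*?\"\"\"", "", text, perl = TRUE)
  stripped <- gsub("'(?:[^'\\\\]|\\\\.)*'|\"(?:[^\"\\\\]|\\\\.)*\"", "", stripped, perl = TRUE)
  stripped <- gsub("<[^<> ]*>", "", stripped, perl = TRUE)
  stripped <- gsub("#[^\n]*", "", stripped, perl = TRUE)
  hits <- regmatches(stripped, gregexpr("\\$[0-9]+", stripped))[[1]]
  if (!length(hits)) 0L else max(as.integer(sub("\\$", "", hits)))
}

test_that("placeholder counting ignores strings and IRIs, max index wins", {
  expect_identical(count_placeholders("SELECT ?x WHERE { ?x a $1 . ?x ?p $1 . ?x ?q $2 }"), 2L)
  expect_identical(count_placeholders("SELECT ?x WHERE { ?x ?p \"$1\" }"), 0L)
  expect_identical(count_placeholders("SELECT ?x WHERE { ?x ?p ?o }"), 0L)
  expect_identical(count_placeholders("# $9 in a comment\nSELECT $12 WHERE { $1 }"), 12L)
  expect_identical(count_placeholders("?x <http://ex.org/$3> $2"), 2L)
})

test_that("placeholder counting agrees with a tokenizer oracle on generated templates", {
  set.seed(4711)
  pieces <- c("?x", "?y", "a", "<http://ex.org/p$7>", "\"lit $5\"", "'lit $6'",
              "$1", "$2", "$3", "$12", ".", "{", "}", "# note $8\n", "rdfs:label")
  for (i in 1:200) {
    text <- paste(sample(pieces, sample(3:12, 1), replace = TRUE), collapse = " ")
    expect_identical(count_placeholders(text), oracle_count(text))
  }
})

test_that("substitution is verbatim, simultaneous, and index-exact", {
  t1 <- sparqlpipe:::new_template("inline", "SELECT ?p ?o WHERE { fxp:$1 ?p ?o }")
  q <- substitute_params(t1, "P02649")
  expect_match(q, "fxp:P02649", fixed = TRUE)
  expect_false(grepl("$1", q, fixed = TRUE))
  # no placeholders: identity
  t0 <- sparqlpipe:::new_template("inline", "SELECT ?s WHERE { ?s ?p ?o }")
  expect_identical(substitute_params(t0, character(0)), t0$text)
  # $12 is placeholder 12, not $1 followed by 2
  t12 <- sparqlpipe:::new_template("inline", "{ $1 $12 }")
  expect_error(substitute_params(t12, "only-one"), class = "sp_generation_error")
  out <- substitute_params(t12, as.character(1:12))
  expect_identical(out, "{ 1 12 }")
  # position-faithful: permuting params permutes the output
  tp <- sparqlpipe:::new_template("inline", "{ $1 $2 }")
  expect_identical(substitute_params(tp, c("A", "B")), "{ A B }")
  expect_identical(substitute_params(tp, c("B", "A")), "{ B A }")
  # placeholders inside strings survive untouched
  ts <- sparqlpipe:::new_template("inline", "{ ?s ?p \"$1\" . ?s ?q $1 }")
  expect_identical(substitute_params(ts, "X"), "{ ?s ?p \"$1\" . ?s ?q X }")
})

test_that("after substitution no placeholder remains outside strings and IRIs", {
  set.seed(99)
  for (i in 1:50) {
    n_ph <- sample(1:4, 1)
    body <- paste(sample(c(paste0("$", 1:n_ph), "?x", "\"keep $1\"", "p:q"),
                         8, replace = TRUE), collapse = " ")
    tpl <- sparqlpipe:::new_template("inline", paste0("{ ", body, " }"))
    out <- substitute_params(tpl, rep("T", tpl$placeholder_count))
    expect_identical(count_placeholders(out), 0L)
  }
})

test_that("template resolution prefers local files, then libraries, then URIs", {
  cfg <- load_config()
  # packaged library entry
  t <- resolve_template("uniprot_annot", cfg,
                        fetcher = function(url) stop("network touched"))
  expect_identical(t$placeholder_count, 1L)
  expect_match(t$source, "uniprot_annot\\.rq$")
  # a local file of the same name wins
  withr::local_dir(withr::local_tempdir())
  writeLines("SELECT ?s WHERE { ?s ?p $1 }", "uniprot_annot")
  t2 <- resolve_template("uniprot_annot", cfg,
                         fetcher = function(url) stop("network touched"))
  expect_match(t2$text, "\\$1")
  expect_false(grepl("\\.rq$", t2$source))
  # prefixed template URI expands against the library prefix and is fetched
  fetched <- NULL
  fake_fetch <- function(url) {
    fetched <<- url
    "SELECT ?member WHERE { ?g ?m fxp:$1 }"
  }
  t3 <- resolve_template("mbgdl:get_ortholog_remote", cfg, fetcher = fake_fetch)
  expect_identical(fetched, "http://mbgd.genome.ad.jp/sparql/library/get_ortholog_remote")
  expect_identical(t3$placeholder_count, 1L)
  # absolute URI
  t4 <- resolve_template("http://templates.example/q.rq", cfg, fetcher = fake_fetch)
  expect_identical(fetched, "http://templates.example/q.rq")
  # nothing anywhere
  err <- expect_error(resolve_template("no_such_template", cfg,
                                       fetcher = function(url) stop("no")),
                      class = "sp_resolution_error")
  expect_match(conditionMessage(err), "no_such_template")
})

test_that("remote fetch failures surface as transport errors with the URL", {
  cfg <- load_config()
  err <- expect_error(
    resolve_template("mbgdl:anything", cfg,
                     fetcher = function(url) {
                       sparqlpipe:::sp_stop("sp_transport_error",
                                            "fetch failed for %s: HTTP %d", url, 404L)
                     }),
    class = "sp_transport_error")
  expect_match(conditionMessage(err), "404")
})

test_that("fetched templates can be cached content-addressed on request", {
  cache <- withr::local_tempdir()
  calls <- 0L
  srv <- local_loopback(list(g = rdf_graph()))
  # the ping route serves a stable body; good enough to exercise the cache
  url <- paste0(srv$base, "/ping")
  f <- http_fetcher(cache_dir = cache)
  first <- f(url)
  expect_identical(first, "ok")
  expect_length(list.files(cache), 1L)
  # second fetch is served from the cache even if the server goes away
  stop_server(srv)
  Sys.sleep(0.2)
  expect_identical(f(url), "ok")
})
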