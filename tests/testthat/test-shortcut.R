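pm_std <- function() {
  load_config()$prefixes
}

test_that("argument tokens classify by the documented rules", {
  pm <- pm_std()
  expect_identical(classify_term("uniprot:P02649", "subject", pm)$kind, "prefixed_name")
  expect_identical(classify_term("up:organism/up:scientificName", "predicate", pm)$kind,
                   "property_path")
  t <- classify_term("1", "subject", pm)
  expect_identical(t$kind, "column_ref")
  expect_identical(t$column, 1L)
  expect_identical(classify_term("^apolipoprotein", "object", pm)$kind, "literal")
  expect_identical(classify_term("<http://example.org/x>", "object", pm)$kind, "iri")
  expect_identical(classify_term("https://example.org/x", "subject", pm)$kind, "iri")
  # explicit quoting turns a numeric-looking token into a literal
  lit <- classify_term("\"42\"", "object", pm)
  expect_identical(lit$kind, "literal")
  expect_identical(lit$text, "42")
  # a typo'd prefix is an error, not silently a literal
  expect_error(classify_term("uniprto:P02649", "subject", pm),
               class = "sp_generation_error")
})

test_that("terms serialize to valid SPARQL tokens", {
  expect_identical(serialize_term(sparqlpipe:::new_term("iri", "http://ex.org/a")),
                   "<http://ex.org/a>")
  expect_identical(serialize_term(sparqlpipe:::new_term("prefixed_name", "rdfs:label")),
                   "rdfs:label")
  expect_identical(serialize_term(sparqlpipe:::new_term("literal", "say \"hi\"")),
                   "\"say \\\"hi\\\"\"")
})

test_that("generated queries have the documented pattern, projection and prefixes", {
  pm <- pm_std()
  q <- build_query(shortcut_spec(subject = classify_term("uniprot:P02649", "subject", pm)), pm)
  expect_match(q, "uniprot:P02649 \\?p \\?o", all = FALSE)
  expect_match(q, "SELECT \\?p \\?o")
  expect_match(q, "PREFIX uniprot:")
  expect_false(grepl("PREFIX rdfs:", q))

  q0 <- build_query(shortcut_spec(), pm)
  expect_match(q0, "\\?s \\?p \\?o")
  expect_match(q0, "SELECT \\?s \\?p \\?o")
  expect_false(grepl("PREFIX", q0))

  qp <- build_query(shortcut_spec(
    subject = classify_term("uniprot:P02649", "subject", pm),
    predicate = classify_term("up:organism/up:scientificName", "predicate", pm)), pm)
  expect_match(qp, "up:organism/up:scientificName", fixed = TRUE)
  expect_match(qp, "SELECT \\?o")
})

test_that("declared prefixes equal the labels actually used in the body", {
  pm <- pm_std()
  specs <- list(
    shortcut_spec(subject = classify_term("uniprot:P02649", "subject", pm)),
    shortcut_spec(predicate = classify_term("rdfs:label", "predicate", pm)),
    shortcut_spec(subject = classify_term("uniprot:P02649", "subject", pm),
                  predicate = classify_term("up:organism/up:scientificName",
                                            "predicate", pm)),
    shortcut_spec(object = classify_term("some plain text", "object", pm))
  )
  for (spec in specs) {
    q <- build_query(spec, pm)
    declared <- regmatches(q, gregexpr("PREFIX ([A-Za-z0-9_.-]+):", q))[[1]]
    declared <- sub("^PREFIX ", "", sub(":$", "", declared))
    body <- sub(".*SELECT", "", q)
    used <- regmatches(body, gregexpr("[A-Za-z][A-Za-z0-9_.-]*(?=:)", body, perl = TRUE))[[1]]
    used <- intersect(unique(used), names(unclass(pm)))
    expect_setequal(declared, used)
  }
})

test_that("an all-constant pattern yields a COUNT presence query", {
  pm <- pm_std()
  g <- build_fixture("protein_annot", 5, seed = 11)
  triple <- g[1, ]
  spec <- shortcut_spec(subject = classify_term(triple$s, "subject", pm),
                        predicate = classify_term(triple$p, "predicate", pm),
                        object = classify_term(triple$o, "object", pm))
  q <- build_query(spec, pm)
  expect_match(q, "SELECT \\(COUNT\\(\\*\\) AS \\?n\\)")
  res <- evaluate_query(g, q)
  expect_identical(res$solutions[[1]]$n$value, "1")
  # absent triple counts zero
  spec2 <- shortcut_spec(subject = classify_term("<http://nowhere.example/x>", "subject", pm),
                         predicate = classify_term(triple$p, "predicate", pm),
                         object = classify_term(triple$o, "object", pm))
  res2 <- evaluate_query(g, build_query(spec2, pm))
  expect_identical(res2$solutions[[1]]$n$value, "0")
})

test_that("shortcut queries match the brute-force scan for all 8 S/P/O combinations", {
  pm <- pm_std()
  g <- build_fixture("protein_annot", 12, seed = 7)
  anchor <- g[25, ]  # one concrete triple supplies the fixed constants
  for (mask in 0:7) {
    fix_s <- bitwAnd(mask, 1L) > 0L
    fix_p <- bitwAnd(mask, 2L) > 0L
    fix_o <- bitwAnd(mask, 4L) > 0L
    spec <- shortcut_spec(
      subject = if (fix_s) classify_term(anchor$s, "subject", pm),
      predicate = if (fix_p) classify_term(anchor$p, "predicate", pm),
      object = if (fix_o) classify_term(anchor$o, "object", pm))
    q <- build_query(spec, pm)
    res <- evaluate_query(g, q)
    hit <- sparqlpipe:::scan_triples(g,
      s = if (fix_s) anchor$s, p = if (fix_p) anchor$p, o = if (fix_o) anchor$o)
    if (mask == 7L) {
      expect_identical(res$solutions[[1]]$n$value, as.character(nrow(hit)))
    } else {
      keep <- c("s", "p", "o")[!c(fix_s, fix_p, fix_o)]
      want <- sort(do.call(paste, c(unname(as.list(hit[keep])), sep = "\t")))
      expect_identical(ms(res), want)
    }
  }
})

test_that("LIMIT yields exactly min(k, total) rows and never more", {
  pm <- pm_std()
  g <- build_fixture("protein_annot", 8, seed = 9)
  total <- nrow(g)
  for (k in c(1L, 5L, total + 50L)) {
    q <- build_query(shortcut_spec(limit = k), pm)
    expect_identical(length(evaluate_query(g, q)), min(k, total))
  }
  expect_error(shortcut_spec(limit = 0), class = "sp_generation_error")
})

test_that("duplicate input columns across positions are rejected", {
  pm <- pm_std()
  expect_error(
    shortcut_spec(subject = classify_term("1", "subject", pm),
                  object = classify_term("1", "object", pm)),
    class = "sp_generation_error")
  # distinct columns are fine
  expect_s3_class(
    shortcut_spec(subject = classify_term("1", "subject", pm),
                  object = classify_term("2", "object", pm)),
    "shortcut_spec")
})
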