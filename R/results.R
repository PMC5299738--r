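# Result sets and RDF terms.
#
# Internally, terms travel as canonical SPARQL lexical strings:
#   IRIs       "<http://...>"
#   literals   "\"text\"" with optional @lang or ^^<datatype>
#   blank node "_:label"
# This makes triple matching plain string equality and keeps the fixture
# evaluator simple.

rdf_term <- function(kind, value, datatype = NULL, language = NULL) {
  stopifnot(kind %in% c("iri", "literal", "bnode"))
  if (!is.null(datatype) && !is.null(language)) {
    sp_stop("sp_format_error", "a literal cannot carry both datatype and language")
  }
  structure(list(kind = kind, value = value, datatype = datatype,
                 language = language), class = "rdf_term")
}

canon_iri <- function(iri) paste0("<", iri, ">")

canon_literal <- function(value, datatype = NULL, language = NULL) {
  out <- paste0("\"", escape_sparql_string(value), "\"")
  if (!is.null(language)) out <- paste0(out, "@", language)
  else if (!is.null(datatype)) out <- paste0(out, "^^<", datatype, ">")
  out
}

unescape_sparql_string <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    chars <- strsplit(x[[k]], "", fixed = TRUE)[[1]]
    res <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      if (chars[[i]] == "\\" && i < length(chars)) {
        nxt <- chars[[i + 1L]]
        res <- c(res, switch(nxt, n = "\n", t = "\t", r = "\r", nxt))
        i <- i + 2L
      } else {
        res <- c(res, chars[[i]])
        i <- i + 1L
      }
    }
    out[[k]] <- paste(res, collapse = "")
  }
  out
}

# Canonical string -> rdf_term.
parse_canonical_term <- function(s) {
  if (is.na(s)) return(NULL)
  if (startsWith(s, "<")) return(rdf_term("iri", substr(s, 2L, nchar(s) - 1L)))
  if (startsWith(s, "_:")) return(rdf_term("bnode", substr(s, 3L, nchar(s))))
  if (startsWith(s, "\"")) {
    m <- regmatches(s, regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:@([A-Za-z][A-Za-z0-9-]*)|\\^\\^<([^<>]*)>)?$',
                               s))[[1]]
    if (length(m)) {
      lang <- if (nzchar(m[[3]])) m[[3]] else NULL
      dt <- if (nzchar(m[[4]])) m[[4]] else NULL
      return(rdf_term("literal", unescape_sparql_string(m[[2]]),
                      datatype = dt, language = lang))
    }
  }
  # bare token: treat as plain literal
  rdf_term("literal", s)
}

term_canonical <- function(term) {
  switch(term$kind,
    iri = canon_iri(term$value),
    literal = canon_literal(term$value, term$datatype, term$language),
    bnode = paste0("_:", term$value)
  )
}

#' Construct a SPARQL result set
#'
#' @param variables Ordered character vector of variable names (no `?`).
#' @param solutions List of solutions; each solution is a named list of
#'   `rdf_term`s over a subset of `variables` (unbound variables simply
#'   absent).
#' @return A `sparql_results` object.
#' @export
result_set <- function(variables, solutions = list()) {
  for (sol in solutions) {
    extra <- setdiff(names(sol), variables)
    if (length(extra)) {
      sp_stop("sp_format_error", "solution binds undeclared variable(s): %s",
              paste(extra, collapse = ", "))
    }
  }
  structure(list(variables = variables, solutions = solutions),
            class = "sparql_results")
}

#' @export
print.sparql_results <- function(x, ...) {
  cat(sprintf("<sparql_results: %d variable(s), %d solution(s)>\n",
              length(x$variables), length(x$solutions)))
  cat(serialize_tsv(x, with_header = TRUE))
  invisible(x)
}

#' @export
length.sparql_results <- function(x) length(x$solutions)

# Solutions as a data.frame of canonical term strings (NA = unbound).
results_frame <- function(result) {
  vars <- result$variables
  cols <- lapply(vars, function(v) {
    vapply(result$solutions, function(sol) {
      if (is.null(sol[[v]])) NA_character_ else term_canonical(sol[[v]])
    }, character(1))
  })
  names(cols) <- vars
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
}

frame_to_results <- function(df) {
  vars <- names(df)
  sols <- lapply(seq_len(nrow(df)), function(i) {
    sol <- list()
    for (v in vars) {
      t <- parse_canonical_term(df[[v]][[i]])
      if (!is.null(t)) sol[[v]] <- t
    }
    sol
  })
  result_set(vars, sols)
}

# Multiset fingerprint used by tests and oracles: sorted canonical rows.
results_multiset <- function(result) {
  df <- results_frame(result)
  if (!nrow(df)) return(character(0))
  rows <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
  sort(rows)
}

#' Serialize a result set as tab-separated values
#'
#' One header line of variable names (optional), then one line per solution
#' in order. IRIs are angle-bracketed, or abbreviated to prefixed names via
#' [abbreviate_uri()] when `abbreviate` is set; plain literal values are
#' emitted bare, suitable for line-oriented Unix tools (`raw_terms` keeps
#' the full SPARQL lexical form instead); unbound variables become empty
#' fields. A literal containing a tab or newline is an error rather than
#' silent corruption.
#'
#' @param result A `sparql_results`.
#' @param abbreviate Abbreviate IRIs using `prefixes`?
#' @param prefixes A `prefix_map` (required when `abbreviate`).
#' @param with_header Emit the header line?
#' @param raw_terms Emit full SPARQL lexical forms (quoted literals with
#'   datatype/language tags)?
#' @return A single string of tab-separated lines.
#' @export
serialize_tsv <- function(result, abbreviate = FALSE, prefixes = NULL,
                          with_header = TRUE, raw_terms = FALSE) {
  field <- function(term) {
    if (is.null(term)) return("")
    if (term$kind == "literal") {
      if (grepl("[\t\n\r]", term$value)) {
        sp_stop("sp_format_error",
                "literal contains a tab or newline and cannot be written as TSV")
      }
      if (raw_terms) return(canon_literal(term$value, term$datatype, term$language))
      return(term$value)
    }
    if (term$kind == "bnode") return(paste0("_:", term$value))
    if (abbreviate) return(abbreviate_uri(term$value, prefixes))
    canon_iri(term$value)
  }
  lines <- character(0)
  if (with_header) lines <- paste(result$variables, collapse = "\t")
  body <- vapply(result$solutions, function(sol) {
    paste(vapply(result$variables, function(v) field(sol[[v]]), character(1)),
          collapse = "\t")
  }, character(1))
  all_lines <- c(lines, body)
  if (!length(all_lines)) return("")
  paste0(paste(all_lines, collapse = "\n"), "\n")
}
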