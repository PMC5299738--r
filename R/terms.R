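# Classification of shortcut argument tokens into RDF terms and their
# serialization as SPARQL tokens.

path_operator_re <- "[/|^*+?()]"

new_term <- function(kind, text, column = NA_integer_) {
  structure(list(kind = kind, text = text, column = column), class = "sparql_term")
}

#' Classify a shortcut argument as an RDF term
#'
#' Classification rules, in order: a bare decimal integer is a reference to
#' that column of the standard-input binding table; angle-bracketed or bare
#' `http(s)://` tokens are IRIs; a predicate-position token containing a
#' property-path operator outside a bracketed IRI is a property path; a
#' `label:local` token with a declared label is a prefixed name (an
#' undeclared label is an error, surfacing typos rather than silently
#' producing a literal); an explicitly double-quoted token is a literal with
#' the quotes stripped; anything else is a plain literal.
#'
#' @param token Non-empty argument text.
#' @param position One of `"subject"`, `"predicate"`, `"object"`.
#' @param prefixes A `prefix_map`.
#' @return A `sparql_term` with fields `kind`, `text`, `column`.
#' @export
classify_term <- function(token, position = c("subject", "predicate", "object"),
                          prefixes = prefix_map()) {
  position <- match.arg(position)
  stopifnot(nzchar(token))
  if (grepl("^[0-9]+$", token)) {
    return(new_term("column_ref", token, column = as.integer(token)))
  }
  if (grepl("^<[^<>]*>$", token)) {
    return(new_term("iri", substr(token, 2L, nchar(token) - 1L)))
  }
  if (grepl("^https?://", token)) {
    return(new_term("iri", token))
  }
  if (position == "predicate") {
    outside <- gsub("<[^<>]*>", "", token)
    if (grepl(path_operator_re, outside)) {
      return(new_term("property_path", token))
    }
  }
  if (grepl("^\".*\"$", token)) {
    return(new_term("literal", substr(token, 2L, nchar(token) - 1L)))
  }
  m <- regmatches(token, regexec("^([A-Za-z][A-Za-z0-9_.-]*):([^[:space:]]*)$", token))[[1]]
  if (length(m) == 3L) {
    if (!m[[2]] %in% names(unclass(prefixes))) {
      sp_stop("sp_generation_error",
              "term '%s' looks like a prefixed name but prefix '%s' is not declared",
              token, m[[2]])
    }
    return(new_term("prefixed_name", token))
  }
  new_term("literal", token)
}

escape_sparql_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

#' Serialize a term as a SPARQL token
#'
#' IRIs are angle-bracketed, prefixed names and property paths pass through
#' verbatim, literals are double-quoted with string escaping, variables and
#' column references become `?name` (`?inN` for column N).
#'
#' @param term A `sparql_term`.
#' @return SPARQL token text.
#' @export
serialize_term <- function(term) {
  switch(term$kind,
    iri = paste0("<", term$text, ">"),
    prefixed_name = term$text,
    property_path = term$text,
    literal = paste0("\"", escape_sparql_string(term$text), "\""),
    variable = paste0("?", term$text),
    column_ref = paste0("?in", term$column),
    sp_stop("sp_generation_error", "cannot serialize term of kind '%s'", term$kind)
  )
}

# Prefix labels used by a term (prefixed names, and prefixed-name components
# of property paths), restricted to declared labels.
term_prefix_labels <- function(term, prefixes) {
  declared <- names(unclass(prefixes))
  if (is.null(term)) return(character(0))
  if (term$kind == "prefixed_name") {
    lab <- sub(":.*$", "", term$text)
    return(intersect(lab, declared))
  }
  if (term$kind == "property_path") {
    bare <- gsub("<[^<>]*>", "", term$text)
    parts <- strsplit(bare, path_operator_re)[[1]]
    labs <- sub(":.*$", "", parts[grepl(":", parts)])
    return(intersect(unique(labs), declared))
  }
  character(0)
}
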