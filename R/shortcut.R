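# Shortcut mode: translate -S/-P/-O/-L style options into a complete SPARQL
# SELECT query around a single triple pattern.

#' Build a shortcut request
#'
#' Captures the parsed shortcut-mode options: optional subject, predicate
#' and object terms (see [classify_term()]), an optional row limit, and the
#' output flags.
#'
#' @param subject,predicate,object Optional `sparql_term`s.
#' @param limit Optional positive integer row limit.
#' @param abbreviate Abbreviate IRIs in TSV output?
#' @param show_query_only Print the generated query instead of executing?
#' @param distinct Add DISTINCT to the projection?
#' @return A `shortcut_spec`.
#' @export
shortcut_spec <- function(subject = NULL, predicate = NULL, object = NULL,
                          limit = NULL, abbreviate = FALSE,
                          show_query_only = FALSE, distinct = FALSE) {
  if (!is.null(limit)) {
    limit <- as.integer(limit)
    if (is.na(limit) || limit < 1L) {
      sp_stop("sp_generation_error", "-L LIMIT must be a positive integer")
    }
  }
  cols <- vapply(list(subject, predicate, object),
                 function(t) if (!is.null(t) && t$kind == "column_ref") t$column else NA_integer_,
                 integer(1))
  cols <- cols[!is.na(cols)]
  if (anyDuplicated(cols)) {
    sp_stop("sp_generation_error",
            "column references in -S/-P/-O must name distinct input columns")
  }
  structure(list(subject = subject, predicate = predicate, object = object,
                 limit = limit, abbreviate = abbreviate,
                 show_query_only = show_query_only, distinct = distinct),
            class = "shortcut_spec")
}

shortcut_position_vars <- c(subject = "s", predicate = "p", object = "o")

# Column bindings implied by column_ref terms: data.frame(column, variable),
# where the variable is the fixed positional name ?s/?p/?o.
shortcut_column_bindings <- function(spec) {
  out <- data.frame(column = integer(0), variable = character(0),
                    stringsAsFactors = FALSE)
  for (pos in names(shortcut_position_vars)) {
    t <- spec[[pos]]
    if (!is.null(t) && t$kind == "column_ref") {
      out <- rbind(out, data.frame(column = t$column,
                                   variable = shortcut_position_vars[[pos]],
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Generate a SPARQL query from a shortcut request
#'
#' The WHERE clause is the single triple pattern with the fixed variables
#' `?s`, `?p`, `?o` standing for unspecified (or column-reference)
#' positions; exactly those variables are projected, in subject, predicate,
#' object order. Only the prefixes actually used in the query body are
#' declared. When all three positions are constants the query degenerates
#' to `SELECT (COUNT(*) AS ?n)` over the pattern, so the output signals
#' presence (>= 1) or absence (0) while remaining a valid SELECT.
#'
#' @param spec A `shortcut_spec`.
#' @param prefixes A `prefix_map` supplying namespace declarations.
#' @return SPARQL query text.
#' @examples
#' pm <- prefix_map("uniprot", "http://purl.uniprot.org/uniprot/")
#' s <- classify_term("uniprot:P02649", "subject", pm)
#' cat(build_query(shortcut_spec(subject = s), pm))
#' @export
build_query <- function(spec, prefixes) {
  tokens <- character(3)
  projected <- character(0)
  labels <- character(0)
  for (i in seq_along(shortcut_position_vars)) {
    pos <- names(shortcut_position_vars)[[i]]
    var <- shortcut_position_vars[[i]]
    t <- spec[[pos]]
    if (is.null(t) || t$kind == "column_ref") {
      tokens[[i]] <- paste0("?", var)
      projected <- c(projected, paste0("?", var))
    } else {
      tokens[[i]] <- serialize_term(t)
      labels <- c(labels, term_prefix_labels(t, prefixes))
    }
  }
  labels <- unique(labels)
  decls <- vapply(labels, function(l) {
    sprintf("PREFIX %s: <%s>", l, prefix_lookup(prefixes, l))
  }, character(1))
  proj <- if (length(projected)) {
    paste0(if (spec$distinct) "DISTINCT " else "", paste(projected, collapse = " "))
  } else {
    "(COUNT(*) AS ?n)"
  }
  q <- c(decls,
         paste0("SELECT ", proj),
         "WHERE {",
         paste0("  ", tokens[[1]], " ", tokens[[2]], " ", tokens[[3]], " ."),
         "}")
  if (!is.null(spec$limit)) q <- c(q, paste0("LIMIT ", spec$limit))
  paste0(paste(q, collapse = "\n"), "\n")
}
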