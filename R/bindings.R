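# Pipe composition: read a TSV binding stream and inject selected columns
# into a downstream query as a VALUES block.

#' Read a TSV binding table
#'
#' Splits lines on tabs. With `expect_header = TRUE` the first line supplies
#' variable names (a leading `?` is stripped); with `NA` the first line is
#' taken as a header exactly when every field matches a variable-name
#' pattern (the caller layers the "referenced downstream" condition on
#' top). Ragged rows are an error with the offending line number; an empty
#' stream is an empty table.
#'
#' @param lines Character vector of input lines (no trailing newlines).
#' @param expect_header `TRUE`, `FALSE`, or `NA` for pattern-based detection.
#' @return A `binding_table`: list with `header` (character or `NULL`) and
#'   `rows` (list of character vectors of equal arity).
#' @export
read_bindings <- function(lines, expect_header = FALSE) {
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (!length(lines)) {
    return(structure(list(header = NULL, rows = list()), class = "binding_table"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; restore arity
  fields <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    want <- lengths(regmatches(lines[[i]], gregexpr("\t", lines[[i]], fixed = TRUE))) + 1L
    c(f, rep("", want - length(f)))
  })
  header <- NULL
  if (is.na(expect_header)) {
    expect_header <- all(grepl("^\\??[A-Za-z_][A-Za-z0-9_]*$", fields[[1]]))
  }
  if (isTRUE(expect_header)) {
    header <- sub("^\\?", "", fields[[1]])
    fields <- fields[-1L]
  }
  if (length(fields)) {
    arity <- length(fields[[1]])
    bad <- which(lengths(fields) != arity)
    if (length(bad)) {
      sp_stop("sp_format_error",
              "ragged TSV input: line %d has %d field(s), expected %d",
              bad[[1]] + as.integer(isTRUE(expect_header)),
              length(fields[[bad[[1]]]]), arity)
    }
    if (!is.null(header) && length(header) != arity) {
      sp_stop("sp_format_error", "TSV header arity %d differs from row arity %d",
              length(header), arity)
    }
  }
  structure(list(header = header, rows = fields), class = "binding_table")
}

# Re-classify a TSV token as a SPARQL VALUES term. TSV erases RDF term
# types, so abbreviated output from an upstream stage must round-trip:
# declared prefixed names stay prefixed names, bracketed or http(s) tokens
# are IRIs, everything else is a quoted literal.
tsv_token_to_sparql <- function(token, prefixes) {
  if (grepl("^<[^<>]*>$", token)) return(token)
  if (grepl("^https?://[^[:space:]]+$", token)) return(canon_iri(token))
  m <- regmatches(token, regexec("^([A-Za-z][A-Za-z0-9_.-]*):([^[:space:]]*)$", token))[[1]]
  if (length(m) == 3L && m[[2]] %in% names(unclass(prefixes))) return(token)
  paste0("\"", escape_sparql_string(token), "\"")
}

#' Inject input bindings into a query as VALUES blocks
#'
#' Rows restricted to the bound columns are deduplicated (first-occurrence
#' order), split into chunks of at most `chunk_size`, and each chunk is
#' turned into one copy of the query with a
#' `VALUES (?v1 ... ?vk) { (...) ... }` block inserted at the start of the
#' outermost WHERE group. The concatenation of all chunk results is the
#' logical result, independent of `chunk_size`.
#'
#' @param query SPARQL query text referencing the bound variables.
#' @param bindings Data frame with columns `column` (1-based input column)
#'   and `variable` (the variable it binds, no `?`).
#' @param table A `binding_table`.
#' @param prefixes A `prefix_map` used to recognize prefixed names in the
#'   input.
#' @param chunk_size Maximum VALUES rows per outgoing query.
#' @return Character vector of query texts; empty when the table has no
#'   rows (the caller then emits empty output without contacting the
#'   endpoint).
#' @export
inject_values <- function(query, bindings, table, prefixes, chunk_size = 100L) {
  stopifnot(chunk_size >= 1L)
  if (!nrow(bindings)) return(query)
  qvars <- query_variables(query)
  missing_vars <- setdiff(bindings$variable, qvars)
  if (length(missing_vars)) {
    sp_stop("sp_generation_error",
            "bound variable(s) not referenced in query: %s",
            paste(paste0("?", missing_vars), collapse = ", "))
  }
  if (!length(table$rows)) return(character(0))
  arity <- length(table$rows[[1]])
  if (any(bindings$column > arity)) {
    sp_stop("sp_generation_error",
            "input has %d column(s) but column %d was referenced",
            arity, max(bindings$column))
  }
  tuples <- vapply(table$rows, function(r) {
    paste(r[bindings$column], collapse = "\t")
  }, character(1))
  tuples <- tuples[!duplicated(tuples)]
  pos <- first_group_opening(query)
  if (is.na(pos)) {
    sp_stop("sp_generation_error", "query has no group to inject VALUES into:\n%s", query)
  }
  head_txt <- substr(query, 1L, pos)
  tail_txt <- substr(query, pos + 1L, nchar(query))
  varlist <- paste(paste0("?", bindings$variable), collapse = " ")
  chunks <- split(tuples, ceiling(seq_along(tuples) / chunk_size))
  vapply(chunks, function(chunk) {
    rows <- vapply(strsplit(chunk, "\t", fixed = TRUE), function(vals) {
      vals <- c(vals, rep("", length(bindings$column) - length(vals)))
      paste0("    (", paste(vapply(vals, tsv_token_to_sparql, character(1),
                                   prefixes = prefixes), collapse = " "), ")")
    }, character(1))
    paste0(head_txt, "\n  VALUES (", varlist, ") {\n",
           paste(rows, collapse = "\n"), "\n  }", tail_txt)
  }, character(1), USE.NAMES = FALSE)
}
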