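# SPARQL 1.1 Protocol client: execute a query over HTTP and parse
# application/sparql-results+json or +xml into a result set.

sparql_accept <- "application/sparql-results+json, application/sparql-results+xml"

# GET for small queries, POST (form-encoded) beyond this URL length.
sparql_get_limit <- 2000L

#' Plan the HTTP request for a query (method selection)
#'
#' Pure helper: a query is sent by GET when the URL-encoded request URL
#' stays within 2000 bytes, by form-encoded POST otherwise.
#'
#' @param url Endpoint URL.
#' @param query SPARQL query text.
#' @return List with `method` ("GET"/"POST"), `url`, and for POST the
#'   request `body`.
#' @export
plan_request <- function(url, query) {
  encoded <- utils::URLencode(query, reserved = TRUE)
  full <- paste0(url, if (grepl("\\?", url)) "&" else "?", "query=", encoded)
  if (nchar(full, type = "bytes") <= sparql_get_limit) {
    list(method = "GET", url = full, body = NULL)
  } else {
    list(method = "POST", url = url, body = paste0("query=", encoded))
  }
}

#' HTTP transport over the SPARQL Protocol
#'
#' Returns a transport function suitable for [execute_query()]; kept
#' separate so tests can substitute a spy or an in-process fake. No
#' automatic retries: pipelines should fail fast and visibly.
#'
#' @param timeout Request timeout in seconds.
#' @return Function `(url, query, accept) -> list(status, type, body)`.
#' @export
http_transport <- function(timeout = 60) {
  force(timeout)
  function(url, query, accept) {
    req <- plan_request(url, query)
    h <- curl::new_handle(timeout = timeout)
    curl::handle_setheaders(h, Accept = accept)
    if (req$method == "POST") {
      curl::handle_setopt(h, post = TRUE, postfields = req$body)
      curl::handle_setheaders(h, Accept = accept,
                              `Content-Type` = "application/x-www-form-urlencoded")
    }
    resp <- tryCatch(curl::curl_fetch_memory(req$url, handle = h),
                     error = function(e) {
                       sp_stop("sp_transport_error", "request to %s failed: %s",
                               url, conditionMessage(e))
                     })
    type <- ""
    hdrs <- curl::parse_headers_list(resp$headers)
    if (!is.null(hdrs[["content-type"]])) type <- hdrs[["content-type"]]
    list(status = resp$status_code, type = type, body = rawToChar(resp$content))
  }
}

#' Execute a SPARQL query against an endpoint
#'
#' Sends the query per the SPARQL 1.1 Protocol, negotiating JSON then XML
#' results, and parses the response into a [result_set()].
#'
#' @param endpoint An `endpoint_spec` (see [resolve_endpoint()]).
#' @param query Non-empty SPARQL query text.
#' @param transport Transport function; defaults to real HTTP
#'   ([http_transport()]).
#' @return A `sparql_results`.
#' @export
execute_query <- function(endpoint, query, transport = http_transport()) {
  stopifnot(nzchar(query))
  resp <- transport(endpoint$url, query, sparql_accept)
  if (resp$status < 200L || resp$status >= 300L) {
    sp_stop("sp_transport_error", "endpoint %s returned HTTP %d: %s",
            endpoint$url, resp$status,
            substr(paste(resp$body, collapse = " "), 1L, 500L))
  }
  base_type <- tolower(sub(";.*$", "", resp$type))
  if (grepl("json", base_type)) return(parse_results_json(resp$body))
  if (grepl("xml", base_type)) return(parse_results_xml(resp$body))
  sp_stop("sp_format_error",
          "cannot parse results of content type '%s'", resp$type)
}

json_binding_to_term <- function(b) {
  kind <- switch(b$type,
                 uri = "iri",
                 literal = ,
                 `typed-literal` = "literal",
                 bnode = "bnode",
                 sp_stop("sp_format_error", "unknown term type '%s' in JSON results", b$type))
  rdf_term(kind, b$value,
           datatype = b[["datatype"]],
           language = b[["xml:lang"]])
}

#' Parse SPARQL Results JSON
#'
#' @param text JSON text in the `application/sparql-results+json` format.
#' @return A `sparql_results`.
#' @export
parse_results_json <- function(text) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) {
                    sp_stop("sp_format_error", "unparseable JSON results: %s",
                            conditionMessage(e))
                  })
  vars <- unname(vapply(doc$head$vars, identity, character(1)))
  sols <- lapply(doc$results$bindings, function(binding) {
    lapply(binding, json_binding_to_term)
  })
  result_set(vars, sols)
}

#' Parse SPARQL Results XML
#'
#' @param text XML text in the `application/sparql-results+xml` format.
#' @return A `sparql_results`.
#' @export
parse_results_xml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) {
                    sp_stop("sp_format_error", "unparseable XML results: %s",
                            conditionMessage(e))
                  })
  ns <- c(sr = "http://www.w3.org/2005/sparql-results#")
  vars <- xml2::xml_attr(xml2::xml_find_all(doc, ".//sr:head/sr:variable", ns), "name")
  results <- xml2::xml_find_all(doc, ".//sr:results/sr:result", ns)
  sols <- lapply(results, function(res) {
    bindings <- xml2::xml_find_all(res, "./sr:binding", ns)
    sol <- list()
    for (b in bindings) {
      name <- xml2::xml_attr(b, "name")
      child <- xml2::xml_child(b)
      tag <- xml2::xml_name(child)
      sol[[name]] <- switch(tag,
        uri = rdf_term("iri", xml2::xml_text(child)),
        literal = {
          dt <- xml2::xml_attr(child, "datatype")
          lang <- xml2::xml_attr(child, "lang")
          rdf_term("literal", xml2::xml_text(child),
                   datatype = if (is.na(dt)) NULL else dt,
                   language = if (is.na(lang)) NULL else lang)
        },
        bnode = rdf_term("bnode", xml2::xml_text(child)),
        sp_stop("sp_format_error", "unknown term element <%s> in XML results", tag)
      )
    }
    sol
  })
  result_set(vars, sols)
}

term_to_json <- function(term) {
  out <- switch(term$kind,
                iri = list(type = "uri", value = term$value),
                literal = list(type = "literal", value = term$value),
                bnode = list(type = "bnode", value = term$value))
  if (!is.null(term$datatype)) out$datatype <- term$datatype
  if (!is.null(term$language)) out[["xml:lang"]] <- term$language
  out
}

#' Serialize a result set as SPARQL Results JSON
#'
#' @param result A `sparql_results`.
#' @return JSON text.
#' @export
write_results_json <- function(result) {
  doc <- list(
    head = list(vars = I(result$variables)),
    results = list(bindings = lapply(result$solutions, function(sol) {
      lapply(sol, term_to_json)
    }))
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Serialize a result set as SPARQL Results XML
#'
#' @param result A `sparql_results`.
#' @return XML text.
#' @export
write_results_xml <- function(result) {
  out <- c('<?xml version="1.0"?>',
           '<sparql xmlns="http://www.w3.org/2005/sparql-results#">',
           "  <head>",
           sprintf('    <variable name="%s"/>', xml_escape(result$variables)),
           "  </head>",
           "  <results>")
  for (sol in result$solutions) {
    out <- c(out, "    <result>")
    for (name in names(sol)) {
      term <- sol[[name]]
      inner <- switch(term$kind,
        iri = sprintf("<uri>%s</uri>", xml_escape(term$value)),
        bnode = sprintf("<bnode>%s</bnode>", xml_escape(term$value)),
        literal = {
          attrs <- ""
          if (!is.null(term$datatype)) {
            attrs <- sprintf(' datatype="%s"', xml_escape(term$datatype))
          } else if (!is.null(term$language)) {
            attrs <- sprintf(' xml:lang="%s"', xml_escape(term$language))
          }
          sprintf("<literal%s>%s</literal>", attrs, xml_escape(term$value))
        })
      out <- c(out, sprintf('      <binding name="%s">%s</binding>',
                            xml_escape(name), inner))
    }
    out <- c(out, "    </result>")
  }
  out <- c(out, "  </results>", "</sparql>")
  paste(out, collapse = "\n")
}
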