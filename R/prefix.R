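# Ordered prefix label -> namespace IRI map, with CURIE expansion and
# longest-match abbreviation.

#' Create a prefix map
#'
#' A prefix map is an ordered set of (label, namespace IRI) pairs driving
#' both expansion of prefixed names (`rdfs:label` ->
#' `http://www.w3.org/2000/01/rdf-schema#label`) and abbreviation of IRIs in
#' query output. Later declarations of the same label override earlier ones
#' while keeping the later position (last writer wins).
#'
#' @param labels Character vector of prefix labels (no trailing colon).
#' @param namespaces Character vector of absolute namespace IRIs, same length.
#' @return An object of class `prefix_map`.
#' @examples
#' pm <- prefix_map("rdfs", "http://www.w3.org/2000/01/rdf-schema#")
#' expand_term("rdfs:label", pm)
#' @export
prefix_map <- function(labels = character(), namespaces = character()) {
  stopifnot(length(labels) == length(namespaces))
  pm <- structure(character(0), class = "prefix_map")
  for (i in seq_along(labels)) pm <- prefix_add(pm, labels[[i]], namespaces[[i]])
  pm
}

#' Add or override one prefix declaration
#'
#' @param pm A `prefix_map`.
#' @param label Prefix label without the trailing colon.
#' @param namespace Absolute namespace IRI.
#' @return The updated `prefix_map`.
#' @export
prefix_add <- function(pm, label, namespace) {
  if (grepl("[[:space:]:]", label)) {
    sp_stop("sp_config_error", "invalid prefix label: '%s'", label)
  }
  if (!is_absolute_iri(namespace)) {
    sp_stop("sp_config_error", "prefix '%s': namespace is not an absolute IRI: '%s'",
            label, namespace)
  }
  v <- unclass(pm)
  v <- v[names(v) != label]
  v[[label]] <- namespace
  structure(v, class = "prefix_map")
}

#' @export
print.prefix_map <- function(x, ...) {
  v <- unclass(x)
  if (!length(v)) cat("<empty prefix map>\n")
  else cat(sprintf("PREFIX %s: <%s>", names(v), v), sep = "\n")
  invisible(x)
}

is_absolute_iri <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) && !grepl("[[:space:]<>\"{}|\\\\`]", x)
}

prefix_lookup <- function(pm, label) {
  v <- unclass(pm)
  if (!label %in% names(v)) {
    sp_stop("sp_generation_error", "undeclared prefix label: '%s'", label)
  }
  v[[label]]
}

#' Expand a prefixed name or bracketed IRI to an absolute IRI
#'
#' Prefixed names of the form `label:local` expand by concatenating the
#' declared namespace and the local part; `<...>` loses its brackets; a bare
#' absolute IRI passes through unchanged.
#'
#' @param token The term text to expand.
#' @param prefixes A `prefix_map`.
#' @return The absolute IRI as a plain string.
#' @export
expand_term <- function(token, prefixes) {
  if (grepl("^<.*>$", token)) return(substr(token, 2L, nchar(token) - 1L))
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", token)) return(token)
  m <- regmatches(token, regexec("^([A-Za-z][A-Za-z0-9_.-]*):(.*)$", token))[[1]]
  if (length(m) == 3L) {
    return(paste0(prefix_lookup(prefixes, m[[2]]), m[[3]]))
  }
  sp_stop("sp_generation_error", "cannot expand term: '%s'", token)
}

# Conservative SPARQL local-part check: abbreviation must never emit a
# prefixed name that would not parse downstream.
valid_local_part <- function(x) {
  !grepl("[[:space:]/#<>\"{}|\\\\`^]", x)
}

#' Abbreviate an IRI to a prefixed name where a declared namespace matches
#'
#' The longest declared namespace that is a prefix of `iri` wins; if two
#' labels declare the same namespace the later declaration wins. When no
#' namespace matches, or the remainder would not be a valid local part, the
#' IRI is returned unchanged wrapped in angle brackets. Total function: it
#' never errors.
#'
#' @param iri Absolute IRI string (no brackets).
#' @param prefixes A `prefix_map`.
#' @return A prefixed name `label:local`, or `<iri>`.
#' @examples
#' pm <- prefix_map("rdfs", "http://www.w3.org/2000/01/rdf-schema#")
#' abbreviate_uri("http://www.w3.org/2000/01/rdf-schema#label", pm)
#' @export
abbreviate_uri <- function(iri, prefixes) {
  v <- unclass(prefixes)
  best_label <- NULL
  best_len <- -1L
  for (i in seq_along(v)) {
    ns <- v[[i]]
    if (startsWith(iri, ns)) {
      rest <- substr(iri, nchar(ns) + 1L, nchar(iri))
      if (!valid_local_part(rest)) next
      # strictly longer namespace wins; equal length (duplicate namespace
      # under two labels) resolves to the later declaration
      if (nchar(ns) >= best_len) {
        best_len <- nchar(ns)
        best_label <- names(v)[[i]]
      }
    }
  }
  if (is.null(best_label)) return(paste0("<", iri, ">"))
  paste0(best_label, ":", substr(iri, best_len + 1L, nchar(iri)))
}
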