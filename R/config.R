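# Layered configuration: endpoint nicknames, prefix declarations, template
# library roots. Line-oriented file format:
#
#   PREFIX label: <iri>
#   ENDPOINT nickname url
#   LIBRARY name root [prefix_label:]
#
# '#' begins a comment. Later layers (and later lines) override earlier ones
# per key; merging is last-writer-wins and associative.

endpoint_spec <- function(nickname, url, formats = c("json", "xml")) {
  if (!is.na(nickname) &&
      (grepl("[[:space:]]", nickname) || grepl("://", nickname, fixed = TRUE))) {
    sp_stop("sp_config_error", "invalid endpoint nickname: '%s'", nickname)
  }
  if (!grepl("^https?://", url)) {
    sp_stop("sp_config_error", "endpoint '%s': url must be absolute http(s): '%s'",
            if (is.na(nickname)) url else nickname, url)
  }
  structure(list(nickname = nickname, url = url, formats = formats),
            class = "endpoint_spec")
}

template_library <- function(name, root, prefix_label = NA_character_) {
  if (!dir.exists(root) && !is_absolute_iri(root)) {
    sp_stop("sp_config_error",
            "library '%s': root is neither an existing directory nor an absolute IRI: '%s'",
            name, root)
  }
  structure(list(name = name, root = root, prefix_label = prefix_label),
            class = "template_library")
}

empty_config <- function() {
  structure(list(prefixes = prefix_map(), endpoints = list(), libraries = list()),
            class = "sparql_config")
}

#' @export
print.sparql_config <- function(x, ...) {
  cat(sprintf("<sparql_config: %d prefixes, %d endpoints, %d libraries>\n",
              length(unclass(x$prefixes)), length(x$endpoints), length(x$libraries)))
  invisible(x)
}

# Built-in layer: well-known W3C prefixes, the endpoint nicknames used in the
# documentation examples, the packaged template library, and the prefixes of
# the packaged demo fixture vocabulary. Networked endpoints are examples
# only; nothing in the package contacts them.
builtin_config <- function() {
  cfg <- empty_config()
  pfx <- list(
    rdf     = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs    = "http://www.w3.org/2000/01/rdf-schema#",
    owl     = "http://www.w3.org/2002/07/owl#",
    xsd     = "http://www.w3.org/2001/XMLSchema#",
    dcterms = "http://purl.org/dc/terms/",
    skos    = "http://www.w3.org/2004/02/skos/core#",
    up      = "http://purl.uniprot.org/core/",
    uniprot = "http://purl.uniprot.org/uniprot/",
    taxon   = "http://purl.uniprot.org/taxonomy/",
    efo     = "http://www.ebi.ac.uk/efo/",
    obo     = "http://purl.obolibrary.org/obo/",
    mbgdl   = "http://mbgd.genome.ad.jp/sparql/library/",
    fv      = paste0(fixture_base_default, "vocab#"),
    fxp     = paste0(fixture_base_default, "protein/"),
    fxg     = paste0(fixture_base_default, "go/"),
    fxc     = paste0(fixture_base_default, "condition/"),
    fxo     = paste0(fixture_base_default, "organism/"),
    fxr     = paste0(fixture_base_default, "probe/")
  )
  for (lab in names(pfx)) cfg$prefixes <- prefix_add(cfg$prefixes, lab, pfx[[lab]])
  cfg$endpoints <- list(
    uniprot = endpoint_spec("uniprot", "https://sparql.uniprot.org/sparql"),
    mbgd    = endpoint_spec("mbgd", "http://mbgd.genome.ad.jp/sparql"),
    atlas   = endpoint_spec("atlas", "https://www.ebi.ac.uk/rdf/services/sparql")
  )
  libdir <- system.file("library", package = "sparqlpipe")
  cfg$libraries <- list(
    mbgd = template_library("mbgd", "http://mbgd.genome.ad.jp/sparql/library/", "mbgdl")
  )
  if (nzchar(libdir)) {
    cfg$libraries$builtin <- template_library("builtin", libdir)
  }
  cfg
}

apply_config_line <- function(cfg, line, path, lineno) {
  # '#' starts a comment only at line start or after whitespace, so that
  # namespace IRIs ending in '#' survive
  bare <- sub("(^|[[:space:]])#.*$", "\\1", line)
  bare <- trimws(bare)
  if (!nzchar(bare)) return(cfg)
  parts <- strsplit(bare, "[[:space:]]+")[[1]]
  kw <- toupper(parts[[1]])
  err <- function(msg) {
    sp_stop("sp_config_error", "%s:%d: %s: '%s'", path, lineno, msg, line)
  }
  if (kw == "PREFIX") {
    if (length(parts) != 3L) err("PREFIX needs 'label: <iri>'")
    label <- sub(":$", "", parts[[2]])
    if (!grepl(":$", parts[[2]])) err("prefix label must end with ':'")
    iri <- sub("^<(.*)>$", "\\1", parts[[3]])
    cfg$prefixes <- prefix_add(cfg$prefixes, label, iri)
  } else if (kw == "ENDPOINT") {
    if (length(parts) != 3L) err("ENDPOINT needs 'nickname url'")
    cfg$endpoints[[parts[[2]]]] <- endpoint_spec(parts[[2]], parts[[3]])
  } else if (kw == "LIBRARY") {
    if (!length(parts) %in% c(3L, 4L)) err("LIBRARY needs 'name root [prefix_label:]'")
    plab <- if (length(parts) == 4L) sub(":$", "", parts[[4]]) else NA_character_
    cfg$libraries[[parts[[2]]]] <- template_library(parts[[2]], parts[[3]], plab)
    if (!is.na(plab) && is_absolute_iri(parts[[3]])) {
      cfg$prefixes <- prefix_add(cfg$prefixes, plab, parts[[3]])
    }
  } else {
    err("unknown directive")
  }
  cfg
}

#' Load and merge layered configuration
#'
#' Merges the built-in layer (well-known prefixes, example endpoint
#' nicknames, the packaged template library) with user configuration files,
#' later paths overriding earlier ones per key.
#'
#' @param paths Character vector of configuration file paths, lowest
#'   precedence first.
#' @param include_builtins Include the built-in layer underneath the files?
#' @return A `sparql_config` with elements `prefixes`, `endpoints`,
#'   `libraries`.
#' @export
load_config <- function(paths = character(), include_builtins = TRUE) {
  cfg <- if (include_builtins) builtin_config() else empty_config()
  for (path in paths) {
    if (!file.exists(path) || dir.exists(path)) {
      sp_stop("sp_config_error", "configuration file not readable: '%s'", path)
    }
    lines <- readLines(path, warn = FALSE)
    for (i in seq_along(lines)) cfg <- apply_config_line(cfg, lines[[i]], path, i)
  }
  cfg
}

# Default user-layer search order (existing files only).
default_config_paths <- function() {
  cands <- c(file.path(Sys.getenv("HOME"), ".sparqlpipe", "config"),
             "./sparqlpipe.config")
  cands[file.exists(cands)]
}

#' Resolve an endpoint nickname or URL
#'
#' A string containing `://` is taken as an endpoint URL directly (anonymous
#' endpoint); anything else is looked up among the configured nicknames.
#'
#' @param name_or_url Nickname or absolute URL.
#' @param config A `sparql_config`.
#' @return An `endpoint_spec`.
#' @export
resolve_endpoint <- function(name_or_url, config) {
  stopifnot(nzchar(name_or_url))
  if (grepl("://", name_or_url, fixed = TRUE)) {
    return(endpoint_spec(NA_character_, name_or_url))
  }
  ep <- config$endpoints[[name_or_url]]
  if (is.null(ep)) {
    sp_stop("sp_resolution_error",
            "unknown endpoint nickname '%s' (known: %s)",
            name_or_url, paste(names(config$endpoints), collapse = ", "))
  }
  ep
}
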