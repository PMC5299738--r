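# Template mode: resolve a SPARQL template by library name, file path or
# (prefixed) URI, and instantiate positional $N placeholders.

new_template <- function(source, text) {
  structure(list(source = source, text = text,
                 placeholder_count = count_placeholders(text)),
            class = "sparql_template")
}

#' @export
print.sparql_template <- function(x, ...) {
  cat(sprintf("<sparql_template from %s, %d placeholder(s)>\n",
              x$source, x$placeholder_count))
  cat(x$text)
  invisible(x)
}

#' Count positional placeholders in a template
#'
#' Returns the largest N such that `$N` occurs in the text outside string
#' literals, IRIs and comments; 0 if there is none. Multi-digit indices are
#' supported and matched longest-first, so `$12` is placeholder 12, never
#' `$1` followed by `2`.
#'
#' @param text SPARQL template text.
#' @return Non-negative integer.
#' @export
count_placeholders <- function(text) {
  ph <- find_placeholders(text)
  if (!nrow(ph)) 0L else max(ph$index)
}

#' Default remote template fetcher (plain HTTP GET)
#'
#' @param cache_dir Optional directory for content-addressed caching of
#'   fetched templates; `NULL` disables caching.
#' @return A function `(url) -> character scalar` raising a transport error
#'   on failure.
#' @export
http_fetcher <- function(cache_dir = NULL) {
  force(cache_dir)
  function(url) {
    cache_file <- NULL
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
      cache_file <- file.path(cache_dir, paste0("t-", substr(digest_hex(url), 1, 16)))
      if (file.exists(cache_file)) {
        return(paste(readLines(cache_file, warn = FALSE), collapse = "\n"))
      }
    }
    resp <- tryCatch(curl::curl_fetch_memory(url),
                     error = function(e) {
                       sp_stop("sp_transport_error", "fetch failed for %s: %s",
                               url, conditionMessage(e))
                     })
    if (resp$status_code < 200L || resp$status_code >= 300L) {
      sp_stop("sp_transport_error", "fetch failed for %s: HTTP %d",
              url, resp$status_code)
    }
    text <- rawToChar(resp$content)
    if (!is.null(cache_file)) writeLines(text, cache_file)
    text
  }
}

# Small stable string hash for cache file names (no digest dependency).
digest_hex <- function(x) {
  bytes <- utf8ToInt(x)
  h <- c(2166136261, 40389)
  for (b in bytes) {
    h <- (h * 16777619 + b) %% 2^31
  }
  paste0(sprintf("%08x", as.integer(h[1])), sprintf("%08x", as.integer(h[2])))
}

#' Resolve a template name to its SPARQL text
#'
#' Resolution order, first hit wins:
#' 1. an existing local file path;
#' 2. an entry in a configured local library directory (file `<name>.rq`,
#'    then `<name>`);
#' 3. a prefixed name whose label matches a configured library prefix (or
#'    any declared prefix), expanded to an IRI and fetched;
#' 4. an absolute IRI, fetched.
#'
#' Local resolution never touches the network.
#'
#' @param name Template name, path, prefixed URI or absolute URI.
#' @param config A `sparql_config`.
#' @param fetcher Remote fetch function `(url) -> text`; see [http_fetcher()].
#' @return A `sparql_template`.
#' @export
resolve_template <- function(name, config, fetcher = http_fetcher()) {
  stopifnot(nzchar(name))
  searched <- character(0)
  if (file.exists(name) && !dir.exists(name)) {
    return(new_template(normalizePath(name),
                        paste(readLines(name, warn = FALSE), collapse = "\n")))
  }
  searched <- c(searched, paste0("file:", name))
  for (lib in config$libraries) {
    if (!dir.exists(lib$root)) next
    for (cand in c(file.path(lib$root, paste0(name, ".rq")),
                   file.path(lib$root, name))) {
      if (file.exists(cand) && !dir.exists(cand)) {
        return(new_template(cand, paste(readLines(cand, warn = FALSE), collapse = "\n")))
      }
      searched <- c(searched, cand)
    }
  }
  m <- regmatches(name, regexec("^([A-Za-z][A-Za-z0-9_.-]*):([^[:space:]]*)$", name))[[1]]
  if (length(m) == 3L && !grepl("^https?$", m[[2]])) {
    label <- m[[2]]
    base <- NULL
    for (lib in config$libraries) {
      if (!is.na(lib$prefix_label) && lib$prefix_label == label &&
          is_absolute_iri(lib$root)) {
        base <- lib$root
      }
    }
    if (is.null(base) && label %in% names(unclass(config$prefixes))) {
      base <- prefix_lookup(config$prefixes, label)
    }
    if (!is.null(base)) {
      url <- paste0(base, m[[3]])
      return(new_template(url, fetcher(url)))
    }
    searched <- c(searched, paste0("prefix:", label))
  }
  if (grepl("^https?://", name)) {
    return(new_template(name, fetcher(name)))
  }
  if (grepl("^<https?://.*>$", name)) {
    url <- substr(name, 2L, nchar(name) - 1L)
    return(new_template(url, fetcher(url)))
  }
  sp_stop("sp_resolution_error",
          "template '%s' not found; searched: %s",
          name, paste(searched, collapse = ", "))
}

#' Instantiate a template with positional parameters
#'
#' Every `$N` outside string literals and IRIs is replaced by the Nth
#' parameter; replacement is simultaneous and index-exact. Parameters are
#' inserted verbatim (they may be bare IDs, prefixed names, IRIs or quoted
#' literals, as the template's context requires), so quoting is the
#' caller's and template author's contract.
#'
#' @param template A `sparql_template`.
#' @param params Character vector of parameters; must cover the template's
#'   placeholder count.
#' @return Instantiated SPARQL query text.
#' @export
substitute_params <- function(template, params = character()) {
  need <- template$placeholder_count
  if (length(params) < need) {
    sp_stop("sp_generation_error",
            "template %s expects %d parameter(s), got %d",
            template$source, need, length(params))
  }
  ph <- find_placeholders(template$text)
  text <- template$text
  if (nrow(ph)) {
    ph <- ph[order(ph$start, decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(ph))) {
      text <- paste0(substr(text, 1L, ph$start[[i]] - 1L),
                     params[[ph$index[[i]]]],
                     substr(text, ph$end[[i]] + 1L, nchar(text)))
    }
  }
  check_query_shape(text)
  text
}
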