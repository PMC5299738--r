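# Loopback SPARQL Protocol endpoint: serves fixture graphs over real HTTP
# on 127.0.0.1 so end-to-end tests and demos exercise the full client path
# without any network. Runs in a background R process (callr + httpuv),
# started only on explicit request.

parse_query_string <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  qs <- sub("^\\?", "", qs)
  parts <- strsplit(qs, "&", fixed = TRUE)[[1]]
  out <- list()
  for (part in parts) {
    kv <- strsplit(part, "=", fixed = TRUE)[[1]]
    if (!length(kv)) next
    key <- utils::URLdecode(kv[[1]])
    val <- if (length(kv) > 1L) {
      utils::URLdecode(chartr("+", " ", paste(kv[-1L], collapse = "=")))
    } else ""
    out[[key]] <- val
  }
  out
}

# Rook/httpuv application answering the SPARQL Protocol for a named list of
# graphs at /<name>/sparql. Internal, but callable in-process for tests.
server_app <- function(graphs) {
  force(graphs)
  respond <- function(status, type, body) {
    list(status = status, headers = list("Content-Type" = type), body = body)
  }
  function(req) {
    path <- req$PATH_INFO
    if (identical(path, "/ping")) return(respond(200L, "text/plain", "ok"))
    m <- regmatches(path, regexec("^/([^/]+)/sparql$", path))[[1]]
    if (length(m) != 2L || !m[[2]] %in% names(graphs)) {
      return(respond(404L, "text/plain", "no such endpoint"))
    }
    graph <- graphs[[m[[2]]]]
    query <- NULL
    if (identical(req$REQUEST_METHOD, "GET")) {
      query <- parse_query_string(req$QUERY_STRING)[["query"]]
    } else if (identical(req$REQUEST_METHOD, "POST")) {
      body <- rawToChar(req$rook.input$read())
      ctype <- req$CONTENT_TYPE
      if (!is.null(ctype) && grepl("application/sparql-query", ctype, fixed = TRUE)) {
        query <- body
      } else {
        query <- parse_query_string(body)[["query"]]
      }
    } else {
      return(respond(405L, "text/plain", "method not allowed"))
    }
    if (is.null(query) || !nzchar(query)) {
      return(respond(400L, "text/plain", "missing query parameter"))
    }
    accept <- req$HTTP_ACCEPT
    if (is.null(accept) || !nzchar(accept)) accept <- "*/*"
    want_json <- grepl("sparql-results\\+json|application/json|\\*/\\*", accept)
    want_xml <- grepl("sparql-results\\+xml|application/xml|text/xml", accept)
    if (!want_json && !want_xml) {
      return(respond(406L, "text/plain", "unsupported Accept"))
    }
    res <- tryCatch(evaluate_query(graph, query, sort_solutions = TRUE),
                    error = function(e) e)
    if (inherits(res, "error")) {
      return(respond(400L, "text/plain", conditionMessage(res)))
    }
    if (want_json) {
      respond(200L, "application/sparql-results+json",
              as.character(write_results_json(res)))
    } else {
      respond(200L, "application/sparql-results+xml", write_results_xml(res))
    }
  }
}

#' Serve fixture graphs as a loopback SPARQL endpoint
#'
#' Starts a background R process answering the SPARQL 1.1 Protocol (GET and
#' POST, JSON and XML results) on a free loopback port. Each graph is
#' served at `http://127.0.0.1:<port>/<name>/sparql`. The server evaluates
#' queries with [evaluate_query()] with sorted solutions, so repeated
#' identical requests are byte-identical.
#'
#' @param graphs Named list of `rdf_graph`s; at least one.
#' @param port Port to bind; by default a random free port.
#' @param startup_timeout Seconds to wait for the server to answer.
#' @return A `sparql_loopback` handle; see [endpoint_url()] and
#'   [stop_server()].
#' @export
serve_loopback <- function(graphs, port = NULL, startup_timeout = 15) {
  stopifnot(length(graphs) >= 1L, !is.null(names(graphs)))
  for (pkg in c("callr", "httpuv")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      sp_stop("sp_config_error", "the loopback server needs the '%s' package", pkg)
    }
  }
  if (is.null(port)) port <- httpuv::randomPort()
  files <- vapply(names(graphs), function(nm) {
    f <- tempfile(fileext = ".ttl")
    write_graph(graphs[[nm]], f)
    f
  }, character(1))
  proc <- callr::r_bg(
    function(port, files) {
      graphs <- lapply(files, sparqlpipe::read_graph)
      app <- getFromNamespace("server_app", "sparqlpipe")(graphs)
      httpuv::runServer("127.0.0.1", port, list(call = app))
    },
    args = list(port = port, files = as.list(files)),
    libpath = .libPaths(),
    supervise = TRUE
  )
  base <- sprintf("http://127.0.0.1:%d", port)
  deadline <- Sys.time() + startup_timeout
  ok <- FALSE
  while (Sys.time() < deadline) {
    if (!proc$is_alive()) break
    up <- tryCatch({
      r <- curl::curl_fetch_memory(paste0(base, "/ping"),
                                   handle = curl::new_handle(timeout = 2))
      r$status_code == 200L
    }, error = function(e) FALSE)
    if (up) { ok <- TRUE; break }
    Sys.sleep(0.1)
  }
  if (!ok) {
    err <- tryCatch(proc$read_all_error(), error = function(e) "")
    try(proc$kill(), silent = TRUE)
    sp_stop("sp_transport_error", "loopback server failed to start on port %d%s",
            port, if (nzchar(err)) paste0(": ", err) else "")
  }
  structure(list(process = proc, port = port, base = base,
                 graphs = names(graphs)),
            class = "sparql_loopback")
}

#' Endpoint URL for a graph served by a loopback handle
#'
#' @param server A `sparql_loopback`.
#' @param name Graph name.
#' @return The endpoint URL string.
#' @export
endpoint_url <- function(server, name) {
  stopifnot(name %in% server$graphs)
  sprintf("%s/%s/sparql", server$base, name)
}

#' Stop a loopback server
#'
#' @param server A `sparql_loopback`.
#' @return Invisibly `TRUE`.
#' @export
stop_server <- function(server) {
  try(server$process$kill(), silent = TRUE)
  invisible(TRUE)
}

#' @export
print.sparql_loopback <- function(x, ...) {
  cat(sprintf("<loopback SPARQL endpoint on %s: %s>\n",
              x$base, paste(x$graphs, collapse = ", ")))
  invisible(x)
}
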