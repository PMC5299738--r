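# In-process evaluator for a subset of SPARQL 1.1 SELECT, used by the
# fixture endpoint and the loopback server. Supported: PREFIX prologue;
# SELECT [DISTINCT] (vars | * | (COUNT(*) AS ?v)); basic graph patterns
# with variable predicates; property paths (/, |, ^, *, +, ?, grouping);
# VALUES blocks; FILTER regex(...); LIMIT. Everything the package's own
# query generator and shipped templates emit stays inside this subset.

sparql_token_patterns <- list(
  c("WS",      "^[ \t\r\n]+"),
  c("COMMENT", "^#[^\n]*"),
  c("IRIREF",  "^<[^<>\"{}|^`\\\\[:space:]]*>"),
  c("VAR",     "^\\?[A-Za-z_][A-Za-z0-9_]*"),
  c("STRING",  "^\"(?:[^\"\\\\\n]|\\\\.)*\"|^'(?:[^'\\\\\n]|\\\\.)*'"),
  c("DTSEP",   "^\\^\\^"),
  c("LANGTAG", "^@[A-Za-z]+(?:-[A-Za-z0-9]+)*"),
  c("PNAME",   "^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.%-]*"),
  c("NAME",    "^[A-Za-z][A-Za-z0-9_]*"),
  c("NUM",     "^[0-9]+(?:\\.[0-9]+)?"),
  c("PUNCT",   "^[{}().;,|/^*+?=!]")
)

sparql_tokenize <- function(text) {
  toks <- vector("list", 64L)
  nt <- 0L
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    matched <- FALSE
    for (pat in sparql_token_patterns) {
      m <- regexpr(pat[[2]], rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        if (!pat[[1]] %in% c("WS", "COMMENT")) {
          nt <- nt + 1L
          if (nt > length(toks)) toks <- c(toks, vector("list", length(toks)))
          toks[[nt]] <- list(type = pat[[1]], text = substr(text, pos, pos + len - 1L))
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      sp_stop("sp_generation_error",
              "SPARQL parse error: unexpected character '%s' at offset %d",
              substr(text, pos, pos), pos)
    }
  }
  toks[seq_len(nt)]
}

# --- parser ------------------------------------------------------------

new_parser <- function(text) {
  st <- new.env(parent = emptyenv())
  st$toks <- sparql_tokenize(text)
  st$i <- 1L
  st$prefixes <- list()
  st
}

p_peek <- function(st, k = 0L) {
  i <- st$i + k
  if (i > length(st$toks)) NULL else st$toks[[i]]
}

p_next <- function(st) {
  t <- p_peek(st)
  if (is.null(t)) sp_stop("sp_generation_error", "SPARQL parse error: unexpected end of query")
  st$i <- st$i + 1L
  t
}

p_is_kw <- function(tok, kw) {
  !is.null(tok) && tok$type == "NAME" && toupper(tok$text) == kw
}

p_is_punct <- function(tok, ch) {
  !is.null(tok) && tok$type == "PUNCT" && tok$text == ch
}

p_expect_punct <- function(st, ch) {
  t <- p_next(st)
  if (!(t$type == "PUNCT" && t$text == ch)) {
    sp_stop("sp_generation_error", "SPARQL parse error: expected '%s', got '%s'", ch, t$text)
  }
  t
}

p_expand_pname <- function(st, text) {
  m <- regmatches(text, regexec("^([^:]*):(.*)$", text))[[1]]
  lab <- m[[2]]
  if (!lab %in% names(st$prefixes)) {
    sp_stop("sp_generation_error", "SPARQL parse error: undeclared prefix '%s:'", lab)
  }
  paste0(st$prefixes[[lab]], m[[3]])
}

p_term <- function(st) {
  t <- p_next(st)
  if (t$type == "VAR") return(list(k = "var", name = substr(t$text, 2L, nchar(t$text))))
  if (t$type == "IRIREF") return(list(k = "const", canon = t$text))
  if (t$type == "PNAME") {
    return(list(k = "const", canon = canon_iri(p_expand_pname(st, t$text))))
  }
  if (p_is_kw(t, "A")) {
    return(list(k = "const",
                canon = canon_iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")))
  }
  if (t$type == "STRING") {
    inner <- substr(t$text, 2L, nchar(t$text) - 1L)
    lang <- NULL
    dt <- NULL
    nxt <- p_peek(st)
    if (!is.null(nxt) && nxt$type == "LANGTAG") {
      lang <- substr(p_next(st)$text, 2L, 100L)
    } else if (!is.null(nxt) && nxt$type == "DTSEP") {
      p_next(st)
      dtok <- p_next(st)
      dt <- if (dtok$type == "IRIREF") substr(dtok$text, 2L, nchar(dtok$text) - 1L)
            else p_expand_pname(st, dtok$text)
    }
    return(list(k = "const",
                canon = canon_literal(unescape_sparql_string(inner), dt, lang)))
  }
  if (t$type == "NUM") {
    dt <- if (grepl(".", t$text, fixed = TRUE))
      "http://www.w3.org/2001/XMLSchema#decimal"
    else "http://www.w3.org/2001/XMLSchema#integer"
    return(list(k = "const", canon = canon_literal(t$text, dt)))
  }
  sp_stop("sp_generation_error", "SPARQL parse error: unexpected token '%s'", t$text)
}

p_path_primary <- function(st) {
  t <- p_peek(st)
  if (p_is_punct(t, "(")) {
    p_next(st)
    inner <- p_path_alt(st)
    p_expect_punct(st, ")")
    return(inner)
  }
  if (p_is_punct(t, "^")) {
    p_next(st)
    return(list(type = "inv", x = p_path_primary(st)))
  }
  t <- p_next(st)
  iri <- if (t$type == "IRIREF") substr(t$text, 2L, nchar(t$text) - 1L)
         else if (t$type == "PNAME") p_expand_pname(st, t$text)
         else if (p_is_kw(t, "A")) "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
         else sp_stop("sp_generation_error",
                      "SPARQL parse error: bad path element '%s'", t$text)
  list(type = "link", iri = canon_iri(iri))
}

p_path_elt <- function(st) {
  x <- p_path_primary(st)
  t <- p_peek(st)
  if (p_is_punct(t, "*")) { p_next(st); x <- list(type = "star", x = x) }
  else if (p_is_punct(t, "+")) { p_next(st); x <- list(type = "plus", x = x) }
  else if (p_is_punct(t, "?")) { p_next(st); x <- list(type = "opt", x = x) }
  x
}

p_path_seq <- function(st) {
  parts <- list(p_path_elt(st))
  while (p_is_punct(p_peek(st), "/")) {
    p_next(st)
    parts[[length(parts) + 1L]] <- p_path_elt(st)
  }
  if (length(parts) == 1L) parts[[1]] else list(type = "seq", parts = parts)
}

p_path_alt <- function(st) {
  parts <- list(p_path_seq(st))
  while (p_is_punct(p_peek(st), "|")) {
    p_next(st)
    parts[[length(parts) + 1L]] <- p_path_seq(st)
  }
  if (length(parts) == 1L) parts[[1]] else list(type = "alt", parts = parts)
}

p_values <- function(st) {
  t <- p_peek(st)
  vars <- character(0)
  if (p_is_punct(t, "(")) {
    p_next(st)
    while (!p_is_punct(p_peek(st), ")")) {
      v <- p_next(st)
      if (v$type != "VAR") sp_stop("sp_generation_error", "SPARQL parse error in VALUES variables")
      vars <- c(vars, substr(v$text, 2L, nchar(v$text)))
    }
    p_next(st)
    single <- FALSE
  } else {
    v <- p_next(st)
    if (v$type != "VAR") sp_stop("sp_generation_error", "SPARQL parse error in VALUES")
    vars <- substr(v$text, 2L, nchar(v$text))
    single <- TRUE
  }
  p_expect_punct(st, "{")
  rows <- list()
  while (!p_is_punct(p_peek(st), "}")) {
    if (single) {
      tok <- p_peek(st)
      if (p_is_kw(tok, "UNDEF")) { p_next(st); rows[[length(rows) + 1L]] <- NA_character_ }
      else rows[[length(rows) + 1L]] <- p_term(st)$canon
    } else {
      p_expect_punct(st, "(")
      row <- character(0)
      while (!p_is_punct(p_peek(st), ")")) {
        tok <- p_peek(st)
        if (p_is_kw(tok, "UNDEF")) { p_next(st); row <- c(row, NA_character_) }
        else row <- c(row, p_term(st)$canon)
      }
      p_next(st)
      if (length(row) != length(vars)) {
        sp_stop("sp_generation_error", "SPARQL parse error: VALUES row arity mismatch")
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  p_next(st)
  list(type = "values", vars = vars, rows = rows)
}

# FILTER regex(?v, "pat"[, "flags"]) or FILTER (regex(str(?v), ...)).
p_filter_body <- function(st) {
  wrapped <- FALSE
  if (p_is_punct(p_peek(st), "(") && p_is_kw(p_peek(st, 1L), "REGEX")) {
    p_next(st)
    wrapped <- TRUE
  }
  fn <- p_next(st)
  if (!p_is_kw(fn, "REGEX")) {
    sp_stop("sp_generation_error",
            "SPARQL parse error: only FILTER regex(...) is supported, got '%s'", fn$text)
  }
  p_expect_punct(st, "(")
  t <- p_next(st)
  if (p_is_kw(t, "STR")) {
    p_expect_punct(st, "(")
    t <- p_next(st)
    p_expect_punct(st, ")")
  }
  if (t$type != "VAR") sp_stop("sp_generation_error", "SPARQL parse error: regex needs a variable")
  var <- substr(t$text, 2L, nchar(t$text))
  p_expect_punct(st, ",")
  pat_tok <- p_next(st)
  if (pat_tok$type != "STRING") {
    sp_stop("sp_generation_error", "SPARQL parse error: regex needs a string pattern")
  }
  pattern <- unescape_sparql_string(substr(pat_tok$text, 2L, nchar(pat_tok$text) - 1L))
  flags <- ""
  if (p_is_punct(p_peek(st), ",")) {
    p_next(st)
    f_tok <- p_next(st)
    flags <- substr(f_tok$text, 2L, nchar(f_tok$text) - 1L)
  }
  p_expect_punct(st, ")")
  if (wrapped) p_expect_punct(st, ")")
  list(type = "filter", var = var, pattern = pattern, flags = flags)
}

p_group <- function(st) {
  p_expect_punct(st, "{")
  elements <- list()
  repeat {
    t <- p_peek(st)
    if (is.null(t)) sp_stop("sp_generation_error", "SPARQL parse error: unterminated group")
    if (p_is_punct(t, "}")) { p_next(st); break }
    if (p_is_kw(t, "VALUES")) {
      p_next(st)
      elements[[length(elements) + 1L]] <- p_values(st)
    } else if (p_is_kw(t, "FILTER")) {
      p_next(st)
      elements[[length(elements) + 1L]] <- p_filter_body(st)
    } else if (p_is_punct(t, ".")) {
      p_next(st)
    } else {
      s <- p_term(st)
      ptok <- p_peek(st)
      pred <- if (!is.null(ptok) && ptok$type == "VAR") {
        p_next(st)
        list(k = "var", name = substr(ptok$text, 2L, nchar(ptok$text)))
      } else {
        list(k = "path", path = p_path_alt(st))
      }
      o <- p_term(st)
      elements[[length(elements) + 1L]] <- list(type = "triple", s = s, p = pred, o = o)
    }
  }
  elements
}

#' Parse a SPARQL SELECT query (evaluator subset)
#'
#' @param text SPARQL query text.
#' @return Parsed query structure (prefixes, projection, pattern elements,
#'   limit). Used by [evaluate_query()]; exposed for inspection.
#' @export
parse_sparql <- function(text) {
  st <- new_parser(text)
  repeat {
    t <- p_peek(st)
    if (p_is_kw(t, "PREFIX")) {
      p_next(st)
      ns_tok <- p_next(st)
      if (ns_tok$type != "PNAME") {
        sp_stop("sp_generation_error", "SPARQL parse error: bad prefix declaration")
      }
      lab <- sub(":.*$", "", ns_tok$text)
      iri_tok <- p_next(st)
      if (iri_tok$type != "IRIREF") {
        sp_stop("sp_generation_error", "SPARQL parse error: prefix needs an IRI")
      }
      st$prefixes[[lab]] <- substr(iri_tok$text, 2L, nchar(iri_tok$text) - 1L)
    } else if (p_is_kw(t, "BASE")) {
      p_next(st); p_next(st)
    } else break
  }
  t <- p_next(st)
  if (!p_is_kw(t, "SELECT")) {
    sp_stop("sp_generation_error", "SPARQL parse error: only SELECT queries are supported")
  }
  distinct <- FALSE
  if (p_is_kw(p_peek(st), "DISTINCT")) { p_next(st); distinct <- TRUE }
  proj <- list(kind = "vars", vars = character(0))
  repeat {
    t <- p_peek(st)
    if (!is.null(t) && t$type == "VAR") {
      p_next(st)
      proj$vars <- c(proj$vars, substr(t$text, 2L, nchar(t$text)))
    } else if (p_is_punct(t, "*")) {
      p_next(st)
      proj <- list(kind = "star")
      break
    } else if (p_is_punct(t, "(")) {
      p_next(st)
      fn <- p_next(st)
      if (!p_is_kw(fn, "COUNT")) {
        sp_stop("sp_generation_error", "SPARQL parse error: only COUNT(*) is supported")
      }
      p_expect_punct(st, "(")
      p_expect_punct(st, "*")
      p_expect_punct(st, ")")
      as_tok <- p_next(st)
      if (!p_is_kw(as_tok, "AS")) {
        sp_stop("sp_generation_error", "SPARQL parse error: expected AS in COUNT projection")
      }
      v <- p_next(st)
      p_expect_punct(st, ")")
      proj <- list(kind = "count", var = substr(v$text, 2L, nchar(v$text)))
      break
    } else break
  }
  if (p_is_kw(p_peek(st), "WHERE")) p_next(st)
  elements <- p_group(st)
  limit <- NULL
  while (!is.null(p_peek(st))) {
    t <- p_next(st)
    if (p_is_kw(t, "LIMIT")) {
      limit <- as.integer(p_next(st)$text)
    } else {
      sp_stop("sp_generation_error", "SPARQL parse error: unexpected trailing token '%s'", t$text)
    }
  }
  list(prefixes = st$prefixes, distinct = distinct, projection = proj,
       elements = elements, limit = limit)
}

# --- evaluation --------------------------------------------------------

empty_frame <- function(cols) {
  out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                       stringsAsFactors = FALSE, check.names = FALSE)
  out
}

join_frames <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  common <- intersect(names(a), names(b))
  if (!length(common)) {
    if (!nrow(a) || !nrow(b)) return(empty_frame(union(names(a), names(b))))
    return(merge(a, b, by = NULL))
  }
  merge(a, b, by = common)
}

eval_path_pairs <- function(graph, path) {
  df <- function(from, to) data.frame(from = from, to = to, stringsAsFactors = FALSE)
  switch(path$type,
    link = {
      hit <- graph$p == path$iri
      df(graph$s[hit], graph$o[hit])
    },
    inv = {
      x <- eval_path_pairs(graph, path$x)
      df(x$to, x$from)
    },
    seq = {
      acc <- eval_path_pairs(graph, path$parts[[1]])
      for (part in path$parts[-1]) {
        nxt <- eval_path_pairs(graph, part)
        m <- merge(acc, nxt, by.x = "to", by.y = "from")
        acc <- df(m$from, m$to.y)
      }
      acc
    },
    alt = {
      do.call(rbind, lapply(path$parts, eval_path_pairs, graph = graph))
    },
    star = ,
    plus = {
      base <- unique(eval_path_pairs(graph, path$x))
      acc <- base
      repeat {
        step <- merge(acc, base, by.x = "to", by.y = "from")
        step <- unique(df(step$from, step$to.y))
        grown <- unique(rbind(acc, step))
        if (nrow(grown) == nrow(acc)) break
        acc <- grown
      }
      if (path$type == "star") {
        nodes <- unique(c(graph$s, graph$o))
        acc <- unique(rbind(acc, df(nodes, nodes)))
      }
      acc
    },
    opt = {
      nodes <- unique(c(graph$s, graph$o))
      unique(rbind(eval_path_pairs(graph, path$x), df(nodes, nodes)))
    },
    sp_stop("sp_generation_error", "unsupported path element '%s'", path$type)
  )
}

# Bind a candidate frame's positional columns against term specs.
constrain_positions <- function(cand, specs) {
  for (posname in names(specs)) {
    spec <- specs[[posname]]
    if (spec$k == "const") {
      cand <- cand[cand[[posname]] == spec$canon, , drop = FALSE]
    }
  }
  varpos <- list()  # variable name -> first positional column carrying it
  for (posname in names(specs)) {
    spec <- specs[[posname]]
    if (spec$k == "var") {
      if (!is.null(varpos[[spec$name]])) {
        cand <- cand[cand[[varpos[[spec$name]]]] == cand[[posname]], , drop = FALSE]
      } else {
        varpos[[spec$name]] <- posname
      }
    }
  }
  if (!length(varpos)) {
    # all-constant pattern: keep multiplicity via a 0-column frame
    return(data.frame(row.names = seq_len(nrow(cand))))
  }
  as.data.frame(lapply(varpos, function(pos) cand[[pos]]),
                stringsAsFactors = FALSE, check.names = FALSE)
}

eval_triple <- function(graph, tr) {
  if (tr$p$k == "var") {
    cand <- data.frame(sx = graph$s, px = graph$p, ox = graph$o,
                       stringsAsFactors = FALSE)
    specs <- list(sx = tr$s, px = list(k = "var", name = tr$p$name), ox = tr$o)
  } else {
    pairs <- eval_path_pairs(graph, tr$p$path)
    cand <- data.frame(sx = pairs$from, ox = pairs$to, stringsAsFactors = FALSE)
    specs <- list(sx = tr$s, ox = tr$o)
  }
  constrain_positions(cand, specs)
}

apply_filter <- function(df, flt) {
  if (is.null(df) || !flt$var %in% names(df)) {
    sp_stop("sp_generation_error", "FILTER references unbound variable ?%s", flt$var)
  }
  vals <- vapply(df[[flt$var]], function(canon) {
    t <- parse_canonical_term(canon)
    if (is.null(t)) NA_character_ else t$value
  }, character(1))
  keep <- grepl(flt$pattern, vals, perl = TRUE,
                ignore.case = grepl("i", flt$flags, fixed = TRUE))
  keep[is.na(keep)] <- FALSE
  df[keep, , drop = FALSE]
}

#' Evaluate a SPARQL SELECT query over an in-memory graph
#'
#' Reference evaluator for the supported subset (see [parse_sparql()]).
#' Solutions form a multiset; with `sort_solutions` rows are ordered
#' lexicographically over their canonical term strings, which makes
#' serialized output byte-stable for tests.
#'
#' @param graph An `rdf_graph` (see [build_fixture()]).
#' @param query SPARQL query text.
#' @param sort_solutions Sort rows for deterministic output?
#' @return A `sparql_results`.
#' @export
evaluate_query <- function(graph, query, sort_solutions = FALSE) {
  ast <- parse_sparql(query)
  df <- NULL
  filters <- list()
  for (el in ast$elements) {
    if (el$type == "triple") {
      df <- join_frames(df, eval_triple(graph, el))
    } else if (el$type == "values") {
      rows <- el$rows
      vdf <- if (!length(rows)) empty_frame(el$vars)
      else {
        mat <- do.call(rbind, lapply(rows, function(r) as.character(r)))
        out <- as.data.frame(mat, stringsAsFactors = FALSE)
        names(out) <- el$vars
        out
      }
      df <- join_frames(df, vdf)
    } else if (el$type == "filter") {
      filters[[length(filters) + 1L]] <- el
    }
  }
  if (is.null(df)) df <- data.frame(row.names = 1L)  # empty group: one empty solution
  for (flt in filters) df <- apply_filter(df, flt)

  proj <- ast$projection
  if (proj$kind == "count") {
    df <- data.frame(stats::setNames(list(canon_literal(
      as.character(nrow(df)), "http://www.w3.org/2001/XMLSchema#integer")),
      proj$var), stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    vars <- if (proj$kind == "star") names(df) else proj$vars
    out <- list()
    for (v in vars) {
      out[[v]] <- if (v %in% names(df)) df[[v]] else rep(NA_character_, nrow(df))
    }
    df <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
    if (!length(vars)) df <- data.frame(row.names = seq_len(nrow(df)))
  }
  if (ast$distinct) df <- unique(df)
  if (sort_solutions && ncol(df) > 0L && nrow(df) > 1L) {
    key <- do.call(paste, c(unname(as.list(df)), sep = ""))
    df <- df[order(key, method = "radix"), , drop = FALSE]
  }
  if (!is.null(ast$limit)) df <- utils::head(df, ast$limit)
  frame_to_results(df)
}
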