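# Seeded synthetic RDF fixtures emulating, at toy scale, the shapes of the
# databases the client is meant to query: a protein-annotation store
# (labels, organisms, GO-class links, cross-references), an ortholog-group
# store sharing the protein namespace, and a differential-expression store
# linking probes to condition classes and proteins. All structure is drawn
# from a seeded generator, so a (kind, n_entities, seed) triple always
# yields the identical triple set.

fixture_base_default <- "http://purl.example.org/fixture/"

#' Construct an RDF graph from canonical term columns
#'
#' @param s,p,o Character vectors of canonical term strings (`<iri>` or
#'   quoted literal). Duplicated triples are dropped: a graph is a set.
#' @return An `rdf_graph` (a data frame with columns `s`, `p`, `o`).
#' @export
rdf_graph <- function(s = character(), p = character(), o = character()) {
  df <- unique(data.frame(s = s, p = p, o = o, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("rdf_graph", "data.frame")
  df
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat(sprintf("<rdf_graph: %d triple(s)>\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fixture_vocab <- function(base) {
  v <- paste0(base, "vocab#")
  list(
    label          = canon_iri("http://www.w3.org/2000/01/rdf-schema#label"),
    organism       = canon_iri(paste0(v, "organism")),
    scientificName = canon_iri(paste0(v, "scientificName")),
    goClass        = canon_iri(paste0(v, "goClass")),
    seeAlso        = canon_iri(paste0(v, "seeAlso")),
    database       = canon_iri(paste0(v, "database")),
    member         = canon_iri(paste0(v, "member")),
    diffExpressedIn = canon_iri(paste0(v, "diffExpressedIn")),
    refersTo       = canon_iri(paste0(v, "refersTo")),
    pubmed         = canon_iri(paste0(v, "pubmed"))
  )
}

fixture_protein_iri <- function(base, i) canon_iri(sprintf("%sprotein/P%05d", base, i))

fixture_go_pool <- data.frame(
  id = c("GO_0045202", "GO_0005634", "GO_0016020",
         "GO_0005737", "GO_0005524", "GO_0008152"),
  label = c("synapse", "nucleus", "membrane",
            "cytoplasm", "ATP binding", "metabolic process"),
  stringsAsFactors = FALSE
)

fixture_organisms <- data.frame(
  id = c("O1", "O2", "O3"),
  name = c("Homo sapiens", "Mus musculus", "Synechococcus elongatus"),
  stringsAsFactors = FALSE
)

fixture_conditions <- data.frame(
  id = c("EFO_0000249", "EFO_0002508", "EFO_0000400"),
  label = c("alzheimer's disease", "parkinson's disease", "diabetes mellitus"),
  stringsAsFactors = FALSE
)

fixture_noun_pool <- c("kinase", "transporter", "receptor", "hydrolase",
                       "synthase", "permease", "chaperone", "lipase")
fixture_adj_pool <- c("putative", "membrane", "mitochondrial", "ribosomal",
                      "periplasmic", "secreted")

#' Generate a seeded synthetic RDF fixture graph
#'
#' Three kinds are available. `protein_annot`: every protein gets one
#' label, an organism link (the organism carries a scientific name), one to
#' three GO-class links (GO classes carry labels), and zero to two
#' cross-references tagged with a target-database name; roughly one protein
#' in seven is named `apolipoprotein <X>` so that regular-expression
#' searches over labels have guaranteed hits. `ortholog_db`: proteins from
#' the same namespace partitioned into ortholog groups with member links.
#' `expression_db`: microarray-style probes linked to a disease condition
#' class (conditions carry labels), to a protein IRI in the shared
#' namespace, and to a PubMed-style literal.
#'
#' The generator is deterministic: the same `(kind, n_entities, seed)`
#' always yields triple-set-identical graphs. Per-category triple counts
#' are recorded in `attr(graph, "bookkeeping")`.
#'
#' @param kind One of `"protein_annot"`, `"ortholog_db"`, `"expression_db"`.
#' @param n_entities Number of primary entities (proteins, proteins, probes).
#' @param seed Integer seed.
#' @param base Namespace base IRI under which all fixture entities live.
#' @param group_sizes Optional integer vector of ortholog group sizes
#'   (must sum to `n_entities`); by default groups of four are cut.
#' @return An `rdf_graph`.
#' @examples
#' g <- build_fixture("protein_annot", 10, seed = 1)
#' nrow(g)
#' @export
build_fixture <- function(kind = c("protein_annot", "ortholog_db", "expression_db"),
                          n_entities, seed, base = fixture_base_default,
                          group_sizes = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_entities >= 1L)
  voc <- fixture_vocab(base)
  with_preserved_seed(seed, {
    s <- character(0); p <- character(0); o <- character(0)
    emit <- function(su, pr, ob) {
      s <<- c(s, su); p <<- c(p, pr); o <<- c(o, ob)
    }
    book <- list()
    if (kind == "protein_annot") {
      n_label <- 0L; n_org <- 0L; n_go <- 0L; n_xref <- 0L; n_xref_db <- 0L
      orgs_used <- integer(0); gos_used <- character(0)
      for (i in seq_len(n_entities)) {
        prot <- fixture_protein_iri(base, i)
        lab <- if (i %% 7L == 3L) {
          paste("apolipoprotein", LETTERS[(i %% 26L) + 1L])
        } else {
          paste(sample(fixture_adj_pool, 1L), sample(fixture_noun_pool, 1L),
                sprintf("%d", i))
        }
        emit(prot, voc$label, canon_literal(lab)); n_label <- n_label + 1L
        k <- sample.int(nrow(fixture_organisms), 1L)
        orgs_used <- union(orgs_used, k)
        emit(prot, voc$organism, canon_iri(paste0(base, "organism/", fixture_organisms$id[[k]])))
        n_org <- n_org + 1L
        ngo <- sample.int(3L, 1L)
        gsel <- sample.int(nrow(fixture_go_pool), ngo)
        gos_used <- union(gos_used, fixture_go_pool$id[gsel])
        for (g in gsel) {
          emit(prot, voc$goClass, canon_iri(paste0(base, "go/", fixture_go_pool$id[[g]])))
          n_go <- n_go + 1L
        }
        nx <- sample.int(3L, 1L) - 1L
        for (x in seq_len(nx)) {
          db <- sample(c("PDB", "EMBL", "RefSeq"), 1L)
          xref <- canon_iri(sprintf("%sxref/%s/X%05d_%d", base, db, i, x))
          emit(prot, voc$seeAlso, xref); n_xref <- n_xref + 1L
          emit(xref, voc$database, canon_literal(db)); n_xref_db <- n_xref_db + 1L
        }
      }
      for (k in sort(orgs_used)) {
        emit(canon_iri(paste0(base, "organism/", fixture_organisms$id[[k]])),
             voc$scientificName, canon_literal(fixture_organisms$name[[k]]))
      }
      for (gid in fixture_go_pool$id[fixture_go_pool$id %in% gos_used]) {
        emit(canon_iri(paste0(base, "go/", gid)), voc$label,
             canon_literal(fixture_go_pool$label[fixture_go_pool$id == gid]))
      }
      book <- list(labels = n_label, organism_links = n_org,
                   scientific_names = length(orgs_used), go_links = n_go,
                   go_labels = length(gos_used), xref_links = n_xref,
                   xref_databases = n_xref_db)
    } else if (kind == "ortholog_db") {
      if (is.null(group_sizes)) {
        group_sizes <- rep(4L, n_entities %/% 4L)
        if (n_entities %% 4L) group_sizes <- c(group_sizes, n_entities %% 4L)
      }
      if (sum(group_sizes) != n_entities) {
        sp_stop("sp_config_error", "group_sizes must sum to n_entities")
      }
      members <- sample.int(n_entities)  # random partition of the protein indices
      at <- 1L
      for (gi in seq_along(group_sizes)) {
        grp <- canon_iri(sprintf("%sgroup/G%04d", base, gi))
        for (m in members[at:(at + group_sizes[[gi]] - 1L)]) {
          emit(grp, voc$member, fixture_protein_iri(base, m))
        }
        at <- at + group_sizes[[gi]]
      }
      book <- list(groups = length(group_sizes), member_links = n_entities)
    } else {
      conds_used <- character(0)
      for (i in seq_len(n_entities)) {
        probe <- canon_iri(sprintf("%sprobe/PR%05d", base, i))
        k <- sample.int(nrow(fixture_conditions), 1L)
        conds_used <- union(conds_used, fixture_conditions$id[[k]])
        emit(probe, voc$diffExpressedIn,
             canon_iri(paste0(base, "condition/", fixture_conditions$id[[k]])))
        emit(probe, voc$refersTo,
             fixture_protein_iri(base, sample.int(n_entities, 1L)))
        emit(probe, voc$pubmed, canon_literal(sprintf("PMID:%07d", 1000000L + i)))
      }
      for (cid in fixture_conditions$id[fixture_conditions$id %in% conds_used]) {
        emit(canon_iri(paste0(base, "condition/", cid)), voc$label,
             canon_literal(fixture_conditions$label[fixture_conditions$id == cid]))
      }
      book <- list(probes = n_entities, condition_labels = length(conds_used))
    }
    g <- rdf_graph(s, p, o)
    attr(g, "bookkeeping") <- book
    g
  })
}

# --- Turtle subset I/O -------------------------------------------------

#' Write a graph as Turtle (N-Triples subset)
#'
#' One triple per line with full IRIs and quoted literals; valid Turtle,
#' loadable by any RDF toolkit and by [read_graph()].
#'
#' @param graph An `rdf_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  lines <- sprintf("%s %s %s .", graph$s, graph$p, graph$o)
  writeLines(lines, path)
  invisible(path)
}

#' Read a graph written by [write_graph()]
#'
#' @param path Turtle (N-Triples subset) file path.
#' @return An `rdf_graph`.
#' @export
read_graph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec(
    '^(<[^<>]*>)[ \t]+(<[^<>]*>)[ \t]+(<[^<>]*>|"(?:[^"\\\\]|\\\\.)*"(?:@[A-Za-z-]+|\\^\\^<[^<>]*>)?)[ \t]*\\.$',
    lines))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) {
    sp_stop("sp_format_error", "%s:%d: cannot parse triple line: '%s'",
            path, bad[[1]], lines[[bad[[1]]]])
  }
  rdf_graph(vapply(m, `[[`, character(1), 2L),
            vapply(m, `[[`, character(1), 3L),
            vapply(m, `[[`, character(1), 4L))
}

# --- oracles -----------------------------------------------------------

# Brute-force scan of a graph filtered by fixed S/P/O positions; the oracle
# the shortcut generator is tested against. NULL = unconstrained.
scan_triples <- function(graph, s = NULL, p = NULL, o = NULL) {
  keep <- rep(TRUE, nrow(graph))
  if (!is.null(s)) keep <- keep & graph$s == s
  if (!is.null(p)) keep <- keep & graph$p == p
  if (!is.null(o)) keep <- keep & graph$o == o
  graph[keep, , drop = FALSE]
}

#' Nested-loop join oracle for pipe-composed queries
#'
#' Reference semantics for transferring bindings between piped queries:
#' evaluate `query_a` on `graph_a`; for each distinct value of
#' `feed_column` in its results, evaluate `query_b` on `graph_b` with every
#' occurrence of `?join_variable` replaced by that value; union all
#' solutions, with the join variable re-attached as a bound column. Pipe
#' execution through VALUES injection must reproduce this multiset.
#'
#' @param graph_a,graph_b `rdf_graph`s.
#' @param query_a Upstream SPARQL query text.
#' @param query_b Downstream query text referencing `?join_variable`.
#' @param join_variable Variable name (no `?`) substituted in `query_b`.
#' @param feed_column Column of `query_a`'s results feeding the join
#'   (defaults to the first projected variable).
#' @return A `sparql_results` over `query_b`'s variables.
#' @export
oracle_join <- function(graph_a, query_a, graph_b, query_b, join_variable,
                        feed_column = NULL) {
  up <- evaluate_query(graph_a, query_a)
  updf <- results_frame(up)
  if (is.null(feed_column)) feed_column <- up$variables[[1]]
  vals <- unique(updf[[feed_column]])
  vals <- vals[!is.na(vals)]
  frames <- list()
  for (v in vals) {
    q <- replace_variable(query_b, join_variable, v,
                          from = first_group_opening(query_b))
    res <- evaluate_query(graph_b, q)
    df <- results_frame(res)
    if (join_variable %in% names(df)) df[[join_variable]] <- rep(v, nrow(df))
    frames[[length(frames) + 1L]] <- df
  }
  if (!length(frames)) {
    return(result_set(parse_sparql(query_b)$projection$vars, list()))
  }
  frame_to_results(do.call(rbind, frames))
}

# Splice `value` over every unmasked ?var occurrence at or after position
# `from` (no regex replacement, so backslashes in canonical literals
# survive intact). Substituting only inside the WHERE group keeps the
# SELECT projection list intact; the projected variable simply comes back
# unbound and the caller re-attaches the substituted value.
replace_variable <- function(text, var, value, from = 1L) {
  pat <- paste0("\\?", var, "(?![A-Za-z0-9_])")
  hits <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (hits[[1]] == -1L) return(text)
  mask <- mask_positions(text)
  lens <- attr(hits, "match.length")
  keep <- !mask[as.integer(hits)] & as.integer(hits) >= from
  starts <- as.integer(hits)[keep]
  lens <- lens[keep]
  for (i in rev(seq_along(starts))) {
    text <- paste0(substr(text, 1L, starts[[i]] - 1L), value,
                   substr(text, starts[[i]] + lens[[i]], nchar(text)))
  }
  text
}
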