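# Character-level masking of SPARQL text: marks positions inside string
# literals, IRIREFs and comments so that placeholder substitution, VALUES
# insertion and variable scans never touch quoted content.

mask_positions <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  mask <- logical(n)
  bad_iri_chars <- c(" ", "\t", "\n", "\r", "<", ">", "\"", "{", "}", "|", "\\", "`", "^")
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "#") {
      j <- i
      while (j <= n && chars[[j]] != "\n") j <- j + 1L
      mask[i:(j - 1L)] <- TRUE
      i <- j
      next
    }
    if (ch == "'" || ch == "\"") {
      q <- ch
      long <- i + 2L <= n && chars[[i + 1L]] == q && chars[[i + 2L]] == q
      dlen <- if (long) 3L else 1L
      j <- i + dlen
      while (j <= n) {
        if (chars[[j]] == "\\") { j <- j + 2L; next }
        if (chars[[j]] == q &&
            (!long || (j + 2L <= n && chars[[j + 1L]] == q && chars[[j + 2L]] == q))) break
        j <- j + 1L
      }
      end <- min(n, j + dlen - 1L)
      mask[i:end] <- TRUE
      i <- end + 1L
      next
    }
    if (ch == "<") {
      j <- i + 1L
      ok <- FALSE
      while (j <= n) {
        if (chars[[j]] == ">") { ok <- TRUE; break }
        if (chars[[j]] %in% bad_iri_chars) break
        j <- j + 1L
      }
      if (ok) {
        mask[i:j] <- TRUE
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  mask
}

# All $N placeholder occurrences outside masked regions.
find_placeholders <- function(text) {
  hits <- gregexpr("\\$[0-9]+", text)[[1]]
  out <- data.frame(start = integer(0), end = integer(0), index = integer(0))
  if (hits[[1]] == -1L) return(out)
  mask <- mask_positions(text)
  lens <- attr(hits, "match.length")
  keep <- !mask[as.integer(hits)]
  starts <- as.integer(hits)[keep]
  lens <- lens[keep]
  if (!length(starts)) return(out)
  data.frame(
    start = starts,
    end = starts + lens - 1L,
    index = as.integer(substring(text, starts + 1L, starts + lens - 1L))
  )
}

# Variable names (?foo -> "foo") referenced outside strings/IRIs/comments.
query_variables <- function(text) {
  hits <- gregexpr("\\?[A-Za-z_][A-Za-z0-9_]*", text)[[1]]
  if (hits[[1]] == -1L) return(character(0))
  mask <- mask_positions(text)
  lens <- attr(hits, "match.length")
  keep <- !mask[as.integer(hits)]
  starts <- as.integer(hits)[keep]
  lens <- lens[keep]
  unique(substring(text, starts + 1L, starts + lens - 1L))
}

# Position just after the first unmasked "{" (the outermost group opening),
# or NA if none.
first_group_opening <- function(text) {
  mask <- mask_positions(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  idx <- which(chars == "{" & !mask)
  if (!length(idx)) return(NA_integer_)
  idx[[1]]
}

# Cheap well-formedness check on instantiated queries: unmasked braces and
# parentheses must balance and no placeholder may remain.
check_query_shape <- function(text) {
  mask <- mask_positions(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (pair in list(c("{", "}"), c("(", ")"))) {
    depth <- cumsum((chars == pair[[1]] & !mask) - (chars == pair[[2]] & !mask))
    if (any(depth < 0L) || depth[[length(depth)]] != 0L) {
      sp_stop("sp_generation_error",
              "instantiated query has unbalanced '%s%s':\n%s",
              pair[[1]], pair[[2]], text)
    }
  }
  invisible(TRUE)
}
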