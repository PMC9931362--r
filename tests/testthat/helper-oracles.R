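# Independent brute-force oracles.  Each deliberately uses a different
# algorithm than the implementation it checks.

# Closure oracle: forward depth-first search from every node, asking
# whether it reaches the root through the given relations.
oracle_closure <- function(kb, root, relations = c("P279", "P31")) {
  e <- kb$edges[kb$edges$property %in% relations, , drop = FALSE]
  adj <- split(e$to, e$from)
  reaches_root <- function(x) {
    stack <- adj[[x]] %||% character()
    seen <- character()
    while (length(stack)) {
      cur <- stack[[1]]; stack <- stack[-1]
      if (cur == root) return(TRUE)
      if (cur %in% seen) next
      seen <- c(seen, cur)
      stack <- c(stack, adj[[cur]] %||% character())
    }
    FALSE
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  nodes <- names(kb$entities)
  sort(nodes[vapply(nodes, reaches_root, logical(1))])
}

# PageRank oracle: direct solution of the stationary linear system
# v = (1-d)/n + d (P^T + (1/n) 1 dangling^T) v.
oracle_pagerank <- function(kb, damping = 0.85) {
  ids <- names(kb$entities)
  n <- length(ids)
  e <- unique(kb$edges[kb$edges$from %in% ids & kb$edges$to %in% ids,
                       c("from", "to")])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(e)) A[cbind(e$from, e$to)] <- 1
  outdeg <- rowSums(A)
  P <- A / ifelse(outdeg > 0, outdeg, 1)
  dangling <- as.numeric(outdeg == 0)
  M <- t(P) + matrix(1 / n, n, n) %*% diag(dangling, n)
  v <- solve(diag(n) - damping * M, rep((1 - damping) / n, n))
  stats::setNames(v / sum(v), ids)
}

# Tagger oracle: scan every substring, keep boundary-aligned index hits.
oracle_tag <- function(text, index) {
  n <- nchar(text, type = "chars")
  chars <- if (n > 0) strsplit(text, "")[[1]] else character()
  is_word <- function(i) {
    if (i < 1 || i > n) return(FALSE)
    grepl("(*UCP)^\\w$", chars[i], perl = TRUE)
  }
  begins <- integer(); ends <- integer(); surfaces <- character()
  cands <- list()
  for (i in seq_len(n)) {
    if (!is_word(i) || is_word(i - 1)) next
    for (j in i:n) {
      if (!is_word(j) || is_word(j + 1)) next
      s <- substring(text, i, j)
      ids <- index_lookup(index, s)
      if (length(ids)) {
        begins <- c(begins, i - 1L); ends <- c(ends, j)
        surfaces <- c(surfaces, s)
        cands[[length(cands) + 1L]] <- ids
      }
    }
  }
  if (!length(begins)) {
    out <- data.frame(begin = integer(), end = integer(),
                      surface = character(), stringsAsFactors = FALSE)
    out$candidates <- list()
    return(out)
  }
  ord <- order(begins, -(ends - begins))
  out <- data.frame(begin = begins[ord], end = ends[ord],
                    surface = surfaces[ord], stringsAsFactors = FALSE)
  out$candidates <- cands[ord]
  out
}

# Per-character mask oracle.
oracle_mask <- function(spans, length) {
  covered <- integer()
  for (p in seq_len(length) - 1L) {
    inside <- any(spans$begin <= p & p < spans$end)
    if (inside) covered <- c(covered, p)
  }
  covered
}

# A small dictionary kb + index for tagger tests.
dictionary_index <- function(terms, lang = "de") {
  ents <- lapply(seq_along(terms), function(i)
    mk_entity(sprintf("T%03d", i), label = terms[[i]][1],
              aliases = terms[[i]][-1], lang = lang))
  kb <- new_kb(ents)
  build_index(kb, names(kb$entities), lang)
}
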