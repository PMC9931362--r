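# Dictionary tagging: term index over labels/aliases of the selected
# entities, and token-boundary-aligned mention detection (the candidate
# generation half of entity linking).

word_runs <- function(text) {
  m <- gregexpr("(*UCP)\\w+", text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Acronym heuristic: short all-caps surfaces (<= 4 chars with at least one
# uppercase letter and no lowercase) stay case-sensitive so code-like terms
# are not destroyed by lowercasing; everything else matches case-insensitively.
is_case_sensitive_surface <- function(s) {
  nchar(s, type = "chars") <= 4L & s == toupper(s) &
    grepl("(*UCP)\\p{Lu}", s, perl = TRUE)
}

#' Build a term index over selected entities
#'
#' Indexes the build language's label and every alias of each selected
#' entity.  Matching is case-insensitive except for short all-caps
#' surfaces (acronym heuristic), which remain case-sensitive; the policy
#' identifier is recorded in the index.  Entities without a label or alias
#' in the language contribute nothing; an empty resulting index is an
#' error.
#'
#' @param kb A `medlinkr_kb`.
#' @param selected Character vector of selected entity ids (ids missing
#'   from the kb are skipped with a warning).
#' @param language Language code for labels/aliases.
#' @return Object of class `medlinkr_index`.
#' @export
build_index <- function(kb, selected, language = "de") {
  missing <- setdiff(selected, names(kb$entities))
  if (length(missing))
    warning("selected ids missing from kb, skipped: ",
            paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  ci <- list(); cs <- list()
  for (id in intersect(selected, names(kb$entities))) {
    e <- kb$entities[[id]]
    surfaces <- c(unname(e$labels[language]), unlist(e$aliases[language],
                                                    use.names = FALSE))
    surfaces <- surfaces[!is.na(surfaces) & nzchar(surfaces)]
    for (s in surfaces) {
      if (is_case_sensitive_surface(s)) cs[[s]] <- c(cs[[s]], id)
      else { key <- tolower(s); ci[[key]] <- c(ci[[key]], id) }
    }
  }
  ci <- lapply(ci, function(v) sort(unique(v)))
  cs <- lapply(cs, function(v) sort(unique(v)))
  if (length(ci) + length(cs) == 0L)
    stop("term index is empty: nothing to tag")
  max_tokens <- max(vapply(c(names(ci), names(cs)),
                           function(s) nrow(word_runs(s)), integer(1)), 1L)
  structure(list(ci = list2env(ci, hash = TRUE, parent = emptyenv()),
                 cs = list2env(cs, hash = TRUE, parent = emptyenv()),
                 max_tokens = max_tokens,
                 language = language,
                 normalization = "lower-except-short-acronyms"),
            class = "medlinkr_index")
}

#' @export
print.medlinkr_index <- function(x, ...) {
  cat(sprintf("<medlinkr_index: %d surfaces (%s), language %s>\n",
              length(ls(x$ci)) + length(ls(x$cs)), x$normalization,
              x$language), sep = "")
  invisible(x)
}

index_n_terms <- function(index) length(ls(index$ci)) + length(ls(index$cs))

index_surfaces <- function(index) sort(c(ls(index$ci), ls(index$cs)))

#' Look up a surface string in a term index
#'
#' @param index A `medlinkr_index`.
#' @param surface Candidate surface string from a text.
#' @return Sorted character vector of candidate entity ids (may be empty).
#' @export
index_lookup <- function(index, surface) {
  out <- character()
  key <- tolower(surface)
  if (exists(key, envir = index$ci, inherits = FALSE))
    out <- get(key, envir = index$ci)
  if (exists(surface, envir = index$cs, inherits = FALSE))
    out <- union(out, get(surface, envir = index$cs))
  sort(out)
}

#' Detect candidate mentions in text
#'
#' Finds every token-boundary-aligned occurrence of an indexed surface
#' (multi-token surfaces included).  Overlapping matches are all returned;
#' resolution is deferred to disambiguation.  The result is sorted by span
#' start, then by decreasing length.  Offsets are 0-based half-open code
#' points.
#'
#' @param text Document string.
#' @param index A `medlinkr_index`.
#' @return `data.frame` with `begin`, `end`, `surface` and a list-column
#'   `candidates` of entity-id vectors.
#' @export
tag_mentions <- function(text, index) {
  empty <- data.frame(begin = integer(), end = integer(),
                      surface = character(), stringsAsFactors = FALSE)
  empty$candidates <- list()
  if (is.na(text) || !nzchar(text)) return(empty)
  runs <- word_runs(text)
  if (nrow(runs) == 0L) return(empty)
  begins <- integer(); ends <- integer(); surfaces <- character()
  cands <- list()
  for (i in seq_len(nrow(runs))) {
    for (j in i:min(nrow(runs), i + index$max_tokens - 1L)) {
      s <- substring(text, runs$start[i], runs$end[j])
      ids <- index_lookup(index, s)
      if (length(ids)) {
        begins <- c(begins, runs$start[i] - 1L)
        ends <- c(ends, runs$end[j])
        surfaces <- c(surfaces, s)
        cands[[length(cands) + 1L]] <- ids
      }
    }
  }
  if (length(begins) == 0L) return(empty)
  ord <- order(begins, -(ends - begins))
  out <- data.frame(begin = begins[ord], end = ends[ord],
                    surface = surfaces[ord], stringsAsFactors = FALSE)
  out$candidates <- cands[ord]
  out
}
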