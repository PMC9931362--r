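# Linguistic post-filtering of annotations.  The tagger contract is any
# function text -> data.frame(begin, end, token, pos) with coarse PoS
# labels; the shipped adapter is a rule-based German heuristic (nouns are
# capitalized; a stop list catches capitalized function words), and tests
# use a deterministic stub.

GERMAN_FUNCTION_WORDS <- c(
  "der", "die", "das", "den", "dem", "des", "ein", "eine", "einen",
  "einem", "einer", "eines", "und", "oder", "aber", "nicht", "kein",
  "keine", "mit", "ohne", "bei", "nach", "vor", "von", "zu", "im", "in",
  "am", "an", "auf", "er", "sie", "es", "wir", "ihr", "ist", "sind",
  "war", "waren", "wird", "wurde", "hat", "hatte", "dies", "diese",
  "dieser", "dieses", "jede", "jeder", "alle", "als", "auch", "dann",
  "wegen", "sowie")

#' Rule-based German part-of-speech heuristic
#'
#' Coarse tagger usable without a pretrained pipeline: tokens on the
#' function-word stop list are tagged `DET`/`X`-like function words
#' (`DET`), numeric tokens `NUM`, capitalized tokens `NOUN` (German nouns
#' are capitalized), everything else `X`.  Any function with the same
#' signature can replace it.
#'
#' @param text Document text.
#' @return `data.frame` with `begin`, `end` (0-based half-open), `token`,
#'   `pos`.
#' @export
heuristic_pos_tagger <- function(text) {
  runs <- word_runs(text)
  tokens <- substring(text, runs$start, runs$end)
  pos <- vapply(tokens, function(tok) {
    if (tolower(tok) %in% GERMAN_FUNCTION_WORDS) return("DET")
    if (grepl("^[0-9]+$", tok)) return("NUM")
    first <- substring(tok, 1L, 1L)
    if (first == toupper(first) && first != tolower(first)) return("NOUN")
    "X"
  }, character(1), USE.NAMES = FALSE)
  data.frame(begin = runs$start - 1L, end = runs$end, token = tokens,
             pos = pos, stringsAsFactors = FALSE)
}

#' Noun-evidence filter rule
#'
#' The default shipped rule: keep an annotation iff at least one token
#' overlapping its span is tagged `NOUN` or `PROPN`.  This removes
#' artifacts such as a lone determiner being linked.
#'
#' @param span Length-2 numeric `(begin, end)`.
#' @param tags `data.frame` of overlapping tokens (`begin`, `end`,
#'   `token`, `pos`).
#' @return Logical: keep the annotation?
#' @export
noun_rule <- function(span, tags) {
  any(tags$pos %in% c("NOUN", "PROPN"))
}

#' Filter annotations by a linguistic rule
#'
#' Applies a pure predicate over each annotation span and the PoS-tagged
#' tokens overlapping it; annotations failing the rule are removed, all
#' others are untouched.  Composing calls with different rules is
#' conjunction.
#'
#' @param doc A `medlinkr_doc`.
#' @param tags Token/PoS `data.frame` covering the document, or `NULL` to
#'   run `tagger` on the text.
#' @param rule Filter rule (default [noun_rule()]).
#' @param tagger Tagger used when `tags` is `NULL`.
#' @return The filtered `medlinkr_doc`.
#' @export
pos_filter <- function(doc, tags = NULL, rule = noun_rule,
                       tagger = heuristic_pos_tagger) {
  if (is.null(tags)) tags <- tagger(doc$text)
  ann <- doc$annotations
  if (nrow(ann) == 0L) return(doc)
  keep <- vapply(seq_len(nrow(ann)), function(i) {
    overlap <- tags[tags$begin < ann$end[i] & tags$end > ann$begin[i], ,
                    drop = FALSE]
    isTRUE(rule(c(ann$begin[i], ann$end[i]), overlap))
  }, logical(1))
  annotated_doc(doc$doc_id, doc$text, ann[keep, , drop = FALSE])
}
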