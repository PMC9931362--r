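# NIF 2.0 serialization (Turtle).  One nif:Context resource per document
# carrying the string content and begin/end indices, one nif:Phrase
# resource per annotation carrying the anchor text, indices, the entity
# identity reference and (optionally) an external concept-code reference.
# The reader accepts exactly this scoped subset; no general Turtle parser
# is attempted.

NIF_PREFIXES <- c(
  nif = "http://persistence.uni-leipzig.org/nlp2rdf/ontologies/nif-core#",
  itsrdf = "http://www.w3.org/2005/11/its/rdf#",
  xsd = "http://www.w3.org/2001/XMLSchema#")

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

ttl_unescape <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    chars <- strsplit(s, "")[[1]]
    buf <- character(); j <- 1L
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\\" = "\\", "\"" = "\"", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, chars[j]); j <- j + 1L
      }
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

iri_encode <- function(x) {
  vapply(x, function(s) utils::URLencode(s, reserved = TRUE), character(1),
         USE.NAMES = FALSE)
}

#' Write a corpus to NIF 2.0 Turtle
#'
#' Serializes a list of annotated documents: a `nif:Context` per document
#' (`nif:isString`, `nif:beginIndex`, `nif:endIndex`) and a `nif:Phrase`
#' per annotation (`nif:anchorOf`, indices, `nif:referenceContext`,
#' `itsrdf:taIdentRef` pointing at the entity IRI, and
#' `itsrdf:taClassRef` for an external concept code when present).
#' `read_nif(write_nif(corpus))` is the identity on document ids, texts,
#' spans, entity ids and codes.
#'
#' @param corpus List of `medlinkr_doc`.
#' @param path Output file; if `NULL`, the Turtle text is returned.
#' @param base_iri Base IRI for document resources.
#' @param entity_base_iri Base IRI prefixed to entity ids.
#' @param code_base_iri Base IRI prefixed to external concept codes.
#' @return `path` (invisibly) or the Turtle text.
#' @export
write_nif <- function(corpus, path = NULL,
                      base_iri = "http://example.org/corpus/",
                      entity_base_iri = "http://www.wikidata.org/entity/",
                      code_base_iri = "http://example.org/code/") {
  lines <- c(sprintf("@prefix %s: <%s> .", names(NIF_PREFIXES), NIF_PREFIXES), "")
  for (doc in corpus) {
    n <- nchar(doc$text, type = "chars")
    ctx <- sprintf("<%s%s#char=0,%d>", base_iri, iri_encode(doc$doc_id), n)
    lines <- c(lines,
               paste0(ctx, " a nif:Context , nif:String ;"),
               sprintf("  nif:isString \"%s\" ;", ttl_escape(doc$text)),
               sprintf("  nif:beginIndex \"0\"^^xsd:nonNegativeInteger ;"),
               sprintf("  nif:endIndex \"%d\"^^xsd:nonNegativeInteger .", n),
               "")
    ann <- doc$annotations
    for (i in seq_len(nrow(ann))) {
      res <- sprintf("<%s%s#char=%d,%d>", base_iri, iri_encode(doc$doc_id),
                     ann$begin[i], ann$end[i])
      surface <- substring(doc$text, ann$begin[i] + 1L, ann$end[i])
      body <- c(paste0(res, " a nif:Phrase ;"),
                sprintf("  nif:referenceContext %s ;", ctx),
                sprintf("  nif:anchorOf \"%s\" ;", ttl_escape(surface)),
                sprintf("  nif:beginIndex \"%d\"^^xsd:nonNegativeInteger ;",
                        ann$begin[i]),
                sprintf("  nif:endIndex \"%d\"^^xsd:nonNegativeInteger ;",
                        ann$end[i]),
                sprintf("  itsrdf:taIdentRef <%s%s> ;",
                        entity_base_iri, iri_encode(ann$entity[i])))
      code <- if (!is.null(ann$code)) ann$code[i] else NA_character_
      if (!is.na(code))
        body <- c(body, sprintf("  itsrdf:taClassRef <%s%s> ;",
                                code_base_iri, iri_encode(code)))
      body[length(body)] <- sub(" ;$", " .", body[length(body)])
      lines <- c(lines, body, "")
    }
  }
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

parse_char_iri <- function(iri, base_iri) {
  frag <- sub("^<", "", sub(">$", "", iri))
  frag <- sub(paste0("^", gsub("([.+?^$(){}|\\[\\]\\\\])", "\\\\\\1", base_iri)),
              "", frag)
  m <- regmatches(frag, regexec("^(.*)#char=([0-9]+),([0-9]+)$", frag))[[1]]
  if (length(m) != 4L) return(NULL)
  list(doc_id = utils::URLdecode(m[2]), begin = as.integer(m[3]),
       end = as.integer(m[4]))
}

ttl_string_value <- function(rest) {
  m <- regmatches(rest, regexec("^\"((?:[^\"\\\\]|\\\\.)*)\"", rest, perl = TRUE))[[1]]
  if (length(m) != 2L) return(NULL)
  ttl_unescape(m[2])
}

#' Read a corpus from NIF 2.0 Turtle
#'
#' Parses the subset emitted by [write_nif()].  Unparsable resource blocks
#' raise an error naming the offending resource.
#'
#' @param src Path to a Turtle file, or Turtle text.
#' @inheritParams write_nif
#' @return List of `medlinkr_doc`.
#' @export
read_nif <- function(src, base_iri = "http://example.org/corpus/",
                     entity_base_iri = "http://www.wikidata.org/entity/",
                     code_base_iri = "http://example.org/code/") {
  lines <- if (length(src) == 1L && !grepl("\n", src) && file.exists(src))
    readLines(src, encoding = "UTF-8", warn = FALSE)
  else unlist(strsplit(src, "\n", fixed = TRUE))
  lines <- lines[!grepl("^@prefix", lines)]
  subj_idx <- grep("^<", lines)
  contexts <- list()   # doc_id -> list(text, length)
  phrases <- list()    # list of (doc_id, begin, end, entity, code)
  for (bi in seq_along(subj_idx)) {
    from <- subj_idx[bi]
    to <- if (bi < length(subj_idx)) subj_idx[bi + 1L] - 1L else length(lines)
    block <- lines[from:to]
    block <- block[nzchar(trimws(block))]
    subject <- sub("^(<[^>]*>).*$", "\\1", block[1])
    loc <- parse_char_iri(subject, base_iri)
    if (is.null(loc))
      stop("unparsable NIF resource: ", subject)
    is_context <- grepl("nif:Context", block[1], fixed = TRUE)
    props <- trimws(block[-1])
    get_prop <- function(name) {
      hit <- props[startsWith(props, name)]
      if (length(hit) == 0L) return(NULL)
      trimws(sub(paste0("^", name), "", hit[1]))
    }
    if (is_context) {
      val <- get_prop("nif:isString")
      if (is.null(val)) stop("unparsable NIF resource (no nif:isString): ", subject)
      text <- ttl_string_value(val)
      if (is.null(text)) stop("unparsable NIF resource (bad string): ", subject)
      contexts[[loc$doc_id]] <- text
    } else {
      ident <- get_prop("itsrdf:taIdentRef")
      if (is.null(ident))
        stop("unparsable NIF resource (no itsrdf:taIdentRef): ", subject)
      entity_iri <- sub("^<", "", sub(">.*$", "", ident))
      entity <- utils::URLdecode(sub(paste0("^", gsub("([.+?^$(){}|\\[\\]\\\\])",
                                                      "\\\\\\1", entity_base_iri)),
                                     "", entity_iri))
      code <- NA_character_
      cls <- get_prop("itsrdf:taClassRef")
      if (!is.null(cls)) {
        code_iri <- sub("^<", "", sub(">.*$", "", cls))
        code <- utils::URLdecode(sub(paste0("^", gsub("([.+?^$(){}|\\[\\]\\\\])",
                                                      "\\\\\\1", code_base_iri)),
                                     "", code_iri))
      }
      phrases[[length(phrases) + 1L]] <-
        list(doc_id = loc$doc_id, begin = loc$begin, end = loc$end,
             entity = entity, code = code)
    }
  }
  docs <- list()
  for (doc_id in names(contexts)) {
    ph <- Filter(function(p) p$doc_id == doc_id, phrases)
    ann <- if (length(ph)) {
      data.frame(begin = vapply(ph, `[[`, integer(1), "begin"),
                 end = vapply(ph, `[[`, integer(1), "end"),
                 entity = vapply(ph, `[[`, character(1), "entity"),
                 code = vapply(ph, `[[`, character(1), "code"),
                 stringsAsFactors = FALSE)
    } else NULL
    docs[[length(docs) + 1L]] <- annotated_doc(doc_id, contexts[[doc_id]], ann)
  }
  docs
}
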