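#' Construct a wiki page
#'
#' @param title Page title.
#' @param text Wikitext source.
#' @return Object of class `medlinkr_page` with fields `title`, `text`,
#'   `is_redirect`, `redirect_target`.
#' @export
new_page <- function(title, text) {
  stopifnot(is.character(title), length(title) == 1L, nzchar(title))
  text <- paste(text, collapse = "\n")
  redir <- NA_character_
  is_redir <- grepl("^#REDIRECT", trimws(text), ignore.case = TRUE)
  if (is_redir) {
    m <- regmatches(text, regexec("\\[\\[([^]|#]+)", text))[[1]]
    if (length(m) == 2L) redir <- trimws(m[2]) else is_redir <- FALSE
  }
  structure(list(title = title, text = text, is_redirect = is_redir,
                 redirect_target = redir),
            class = "medlinkr_page")
}

#' Read / write the pages file dialect
#'
#' Pages are stored as plain UTF-8 text: a line `%%PAGE <title>` starts a
#' page; all following lines until the next `%%PAGE` line are its wikitext.
#' Page text must not itself contain a line starting with `%%PAGE `.
#'
#' @param path File path.
#' @return `read_pages` returns a list of `medlinkr_page`.
#' @export
read_pages <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  starts <- grep("^%%PAGE ", lines)
  if (length(starts) == 0L) return(list())
  ends <- c(starts[-1] - 1L, length(lines))
  pages <- lapply(seq_along(starts), function(i) {
    title <- sub("^%%PAGE ", "", lines[starts[i]])
    body <- if (ends[i] > starts[i]) lines[(starts[i] + 1L):ends[i]] else ""
    new_page(title, paste(body, collapse = "\n"))
  })
  pages
}

#' @rdname read_pages
#' @param pages List of `medlinkr_page`.
#' @export
write_pages <- function(pages, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (p in pages) {
    writeLines(paste0("%%PAGE ", p$title), con)
    writeLines(p$text, con)
  }
  invisible(path)
}

strip_delimited <- function(text, open, close) {
  # removes possibly nested open...close blocks wholesale
  repeat {
    pat <- paste0(open, "(?:(?!", open, ")(?!", close, ").)*", close)
    new <- gsub(pat, "", text, perl = TRUE)
    if (identical(new, text)) return(new)
    text <- new
  }
}

#' Render wikitext to plain text with pagelink spans
#'
#' Supports the declared wikitext subset: `[[T]]` renders as "T",
#' `[[T|s]]` as "s", `[[T#Sec|s]]` as "s" with target T and anchor Sec.
#' Templates (`{{...}}`) and tables (`{|...|}`) are stripped wholesale;
#' bold/italic quotes and HTML-style tags are removed while their visible
#' text is kept.  Unbalanced link brackets are left as literal text with a
#' warning.  All offsets are 0-based half-open counts of Unicode code
#' points over the rendered text.
#'
#' @param page A `medlinkr_page` (not a redirect) or a wikitext string.
#' @return List with `text` (rendered plain text) and `links`
#'   (`data.frame`: `begin`, `end`, `target`, `anchor`, `surface`).
#' @export
render_plaintext <- function(page) {
  text <- if (inherits(page, "medlinkr_page")) {
    if (page$is_redirect) stop("cannot render a redirect page")
    page$text
  } else page
  text <- strip_delimited(text, "\\{\\|", "\\|\\}")
  text <- strip_delimited(text, "\\{\\{", "\\}\\}")
  text <- gsub("'''", "", text, fixed = TRUE)
  text <- gsub("''", "", text, fixed = TRUE)
  text <- gsub("<[^<>]+>", "", text)
  if (lengths(regmatches(text, gregexpr("[[", text, fixed = TRUE))) !=
      lengths(regmatches(text, gregexpr("]]", text, fixed = TRUE))))
    warning("unbalanced link brackets; treating stray brackets as literal text",
            call. = FALSE)
  m <- gregexpr("\\[\\[([^][|]*)(\\|[^][]*)?\\]\\]", text, perl = TRUE)[[1]]
  out <- character(); pos <- 0L
  begins <- integer(); ends <- integer()
  targets <- character(); anchors <- character(); surfaces <- character()
  last <- 1L
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      start <- m[i]; len <- lens[i]
      pre <- substring(text, last, start - 1L)
      out <- c(out, pre); pos <- pos + nchar(pre, type = "chars")
      inner <- substring(text, start + 2L, start + len - 3L)
      parts <- strsplit(inner, "|", fixed = TRUE)[[1]]
      raw_target <- if (length(parts) >= 1L) parts[1] else ""
      surface <- if (length(parts) >= 2L) paste(parts[-1], collapse = "|") else NA
      anchor <- NA_character_
      if (grepl("#", raw_target, fixed = TRUE)) {
        tp <- strsplit(raw_target, "#", fixed = TRUE)[[1]]
        target <- tp[1]
        anchor <- paste(tp[-1], collapse = "#")
      } else target <- raw_target
      if (is.na(surface)) surface <- target
      out <- c(out, surface)
      begins <- c(begins, pos)
      pos <- pos + nchar(surface, type = "chars")
      ends <- c(ends, pos)
      targets <- c(targets, trimws(target))
      anchors <- c(anchors, anchor)
      surfaces <- c(surfaces, surface)
      last <- start + len
    }
  }
  out <- c(out, substring(text, last, nchar(text)))
  list(text = paste(out, collapse = ""),
       links = data.frame(begin = begins, end = ends, target = targets,
                          anchor = anchors, surface = surfaces,
                          stringsAsFactors = FALSE))
}

#' Resolve redirect chains to canonical titles
#'
#' Transitive resolution with cycle detection.  Titles are processed in
#' sorted order with memoization; a cycle resolves every member to the
#' first-encountered member of that cycle (deterministic) and logs a
#' warning.  Non-redirect titles map to themselves; redirect targets
#' without a page record are kept as canonical titles.
#'
#' @param pages List of `medlinkr_page`.
#' @return Named character vector: title -> canonical title.
#' @export
resolve_redirects <- function(pages) {
  titles <- vapply(pages, function(p) p$title, character(1))
  target <- stats::setNames(vapply(pages, function(p)
    if (p$is_redirect) p$redirect_target else NA_character_, character(1)), titles)
  resolved <- stats::setNames(rep(NA_character_, length(titles)), titles)
  for (t in sort(titles)) {
    if (!is.na(resolved[[t]])) next
    chain <- character()
    cur <- t
    repeat {
      memo <- if (cur %in% names(resolved)) resolved[[cur]] else NA_character_
      if (!is.na(memo)) { final <- memo; break }
      if (cur %in% chain) {
        warning("redirect cycle detected at '", cur,
                "'; resolving cycle to its first-encountered member",
                call. = FALSE)
        final <- cur
        break
      }
      chain <- c(chain, cur)
      nxt <- if (cur %in% names(target)) target[[cur]] else NA_character_
      if (is.na(nxt)) { final <- cur; break }
      cur <- nxt
    }
    for (c_ in chain) resolved[[c_]] <- final
  }
  resolved
}

#' Map wiki page titles to entities via sitelinks
#'
#' An entity claims a title when its sitelink for `site` equals the title.
#' Sitelinks carrying a `#` section anchor denote finer-granular concepts
#' than the page and are ignored, so the mapping stays injective on its
#' image.  When several anchor-free entities claim one title, the
#' lexicographically smallest entity id wins and the conflict is logged.
#'
#' @param kb A `medlinkr_kb`.
#' @param titles Character vector of page titles to map.
#' @param site Wiki site code, e.g. `"dewiki"`.
#' @return Named character vector: title -> entity id (unclaimed titles are
#'   absent).
#' @export
map_pages_to_entities <- function(kb, titles, site = "dewiki") {
  claims <- list()
  for (e in kb$entities) {
    sl <- e$sitelinks[site]
    if (length(sl) == 0L || is.na(sl)) next
    if (grepl("#", sl, fixed = TRUE)) next  # fine-granular: ignore
    if (sl %in% titles) claims[[sl]] <- c(claims[[sl]], e$id)
  }
  out <- character()
  for (title in names(claims)) {
    ids <- sort(claims[[title]])
    if (length(ids) > 1L)
      message("title '", title, "' claimed by ", length(ids),
              " entities; keeping ", ids[1])
    out[[title]] <- ids[1]
  }
  out
}

#' Rule-based sentence splitter
#'
#' Default splitter for corpus synthesis: sentence boundaries at terminal
#' punctuation (`.`, `!`, `?`) followed by whitespace or end of text,
#' except after a stop list of common German abbreviations.  Returns
#' trimmed sentence spans (0-based, half-open, code points).  Any function
#' with the same signature can be plugged in instead.
#'
#' @param text Document text.
#' @param abbreviations Abbreviation stop list (matched before the period).
#' @return `data.frame` with `begin`, `end`.
#' @export
split_sentences <- function(text,
                            abbreviations = c("z.B", "Dr", "Prof", "bzw",
                                              "ca", "Nr", "u.a", "evtl",
                                              "ggf", "inkl", "mg", "Tbl")) {
  n <- nchar(text, type = "chars")
  if (n == 0L) return(data.frame(begin = integer(), end = integer()))
  chars <- strsplit(text, "")[[1]]
  boundary <- integer()
  for (i in seq_len(n)) {
    if (!chars[i] %in% c(".", "!", "?")) next
    if (i < n && !grepl("^\\s$", chars[i + 1L])) next
    if (chars[i] == ".") {
      prefix <- substring(text, max(1L, i - 8L), i - 1L)
      word <- sub(".*[ \t\n]", "", prefix)
      if (word %in% abbreviations) next
    }
    boundary <- c(boundary, i)
  }
  if (length(boundary) == 0L || boundary[length(boundary)] < n)
    boundary <- c(boundary, n)
  begins <- integer(); ends <- integer()
  start <- 1L
  for (b in boundary) {
    s <- start; e <- b
    while (s <= e && grepl("^\\s$", chars[s])) s <- s + 1L
    while (e >= s && grepl("^\\s$", chars[e])) e <- e - 1L
    if (s <= e) { begins <- c(begins, s - 1L); ends <- c(ends, e) }
    start <- b + 1L
  }
  data.frame(begin = begins, end = ends)
}

#' Construct an annotated document
#'
#' A document text plus entity-linked character spans.  Offsets are 0-based
#' half-open counts of Unicode code points.  Annotations must lie within
#' the text, must not overlap, and are kept sorted by `begin`.
#'
#' @param doc_id Stable document identifier.
#' @param text Document text.
#' @param annotations `data.frame` with columns `begin`, `end`, `entity`
#'   and optionally `surface`, `score`, `code`.
#' @return Object of class `medlinkr_doc`.
#' @export
annotated_doc <- function(doc_id, text, annotations = NULL) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    annotations <- data.frame(begin = integer(), end = integer(),
                              entity = character(), surface = character(),
                              stringsAsFactors = FALSE)
  } else {
    annotations <- annotations[order(annotations$begin, annotations$end), ,
                               drop = FALSE]
    rownames(annotations) <- NULL
    n <- nchar(text, type = "chars")
    if (any(annotations$begin < 0L) || any(annotations$end > n) ||
        any(annotations$end <= annotations$begin))
      stop("annotation span out of bounds in document ", doc_id)
    if (nrow(annotations) > 1L &&
        any(annotations$begin[-1L] < annotations$end[-nrow(annotations)]))
      stop("overlapping annotations in document ", doc_id)
    if (any(!nzchar(annotations$entity)))
      stop("empty entity id in document ", doc_id)
    if (is.null(annotations$surface))
      annotations$surface <- substring(text, annotations$begin + 1L,
                                       annotations$end)
  }
  structure(list(doc_id = doc_id, text = text, annotations = annotations),
            class = "medlinkr_doc")
}

#' @export
print.medlinkr_doc <- function(x, ...) {
  cat(sprintf("<medlinkr_doc %s: %d chars, %d annotations>\n",
              x$doc_id, nchar(x$text, type = "chars"), nrow(x$annotations)))
  invisible(x)
}

#' Synthesize a weakly annotated corpus from wiki pages
#'
#' For every non-redirect page the wikitext is rendered, each pagelink
#' target is resolved through the redirect map and mapped to an entity via
#' its sitelink, and the link is kept iff that entity is in `selected`.
#' One annotated document is emitted per sentence containing at least one
#' kept link, with spans rebased to the sentence; all other sentences are
#' dropped.  Document ids are `"<page title>#<sentence index>"`.
#'
#' @param kb A `medlinkr_kb`.
#' @param pages List of `medlinkr_page`.
#' @param selected Character vector of selected entity ids.
#' @param site Wiki site code for sitelink matching.
#' @param splitter Sentence splitter function (`text` -> `data.frame` with
#'   `begin`, `end`).
#' @return List of `medlinkr_doc`; attribute `"report"` counts total,
#'   kept, unmapped and unselected links.
#' @export
synthesize_corpus <- function(kb, pages, selected, site = "dewiki",
                              splitter = split_sentences) {
  redirects <- resolve_redirects(pages)
  content <- Filter(function(p) !p$is_redirect, pages)
  rendered <- lapply(content, render_plaintext)
  # map both page titles and (resolved) link targets: an entity's sitelink
  # can claim a linked title whose page content is not part of the input
  targets <- unlist(lapply(rendered, function(r) r$links$target),
                    use.names = FALSE)
  targets <- vapply(unique(c(vapply(content, `[[`, character(1), "title"),
                             targets)),
                    function(t) if (t %in% names(redirects)) redirects[[t]]
                    else t, character(1))
  emap <- map_pages_to_entities(kb, unique(targets), site)
  docs <- list()
  n_total <- 0L; n_kept <- 0L; n_unmapped <- 0L; n_unselected <- 0L
  n_straddle <- 0L
  for (pi in seq_along(content)) {
    p <- content[[pi]]
    r <- rendered[[pi]]
    links <- r$links
    n_total <- n_total + nrow(links)
    if (nrow(links) > 0L) {
      canon <- vapply(links$target, function(t)
        if (t %in% names(redirects)) redirects[[t]] else t, character(1))
      eid <- vapply(canon, function(t)
        if (t %in% names(emap)) emap[[t]] else NA_character_, character(1))
      n_unmapped <- n_unmapped + sum(is.na(eid))
      keep <- !is.na(eid) & eid %in% selected
      n_unselected <- n_unselected + sum(!is.na(eid) & !eid %in% selected)
      links <- links[keep, , drop = FALSE]
      links$entity <- eid[keep]
    } else links$entity <- character()
    sents <- splitter(r$text)
    for (k in seq_len(nrow(sents))) {
      sb <- sents$begin[k]; se <- sents$end[k]
      inside <- links$begin >= sb & links$end <= se
      n_straddle <- n_straddle + sum(links$begin < se & links$end > sb & !inside)
      if (!any(inside)) next
      ann <- links[inside, , drop = FALSE]
      docs[[length(docs) + 1L]] <- annotated_doc(
        doc_id = paste0(p$title, "#", k),
        text = substring(r$text, sb + 1L, se),
        annotations = data.frame(begin = ann$begin - sb, end = ann$end - sb,
                                 entity = ann$entity, surface = ann$surface,
                                 stringsAsFactors = FALSE))
      n_kept <- n_kept + nrow(ann)
    }
  }
  attr(docs, "report") <- list(links_total = n_total, links_kept = n_kept,
                               links_unmapped = n_unmapped,
                               links_unselected = n_unselected,
                               links_straddling_sentences = n_straddle,
                               documents = length(docs))
  docs
}
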