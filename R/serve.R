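# Minimal HTTP annotation endpoint over base-R server sockets.  POST plain
# text to any path to receive the annotation JSON; the artifact is loaded
# once and treated as read-only, so concurrent clients see the same
# results as sequential ones.

read_http_request <- function(con, max_bytes) {
  raw <- raw()
  deadline <- Sys.time() + 10
  repeat {
    chunk <- readBin(con, what = "raw", n = 4096L)
    raw <- c(raw, chunk)
    hdr_end <- find_header_end(raw)
    if (!is.na(hdr_end)) break
    if (length(raw) > max_bytes || Sys.time() > deadline) return(NULL)
    if (length(chunk) == 0L) Sys.sleep(0.01)
  }
  header_txt <- rawToChar(raw[seq_len(hdr_end - 1L)])
  lines <- strsplit(header_txt, "\r\n", fixed = TRUE)[[1]]
  req_line <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (length(req_line) < 2L) return(NULL)
  clen <- 0L
  for (h in lines[-1]) {
    if (grepl("^content-length:", h, ignore.case = TRUE))
      clen <- suppressWarnings(as.integer(trimws(sub("^[^:]*:", "", h))))
  }
  if (is.na(clen)) return(NULL)
  if (clen > max_bytes)
    return(list(method = req_line[1], body = NULL, too_large = TRUE,
                limit = max_bytes))
  body <- raw[seq.int(hdr_end + 4L, length.out = length(raw) - hdr_end - 3L)]
  while (length(body) < clen && Sys.time() < deadline) {
    chunk <- readBin(con, what = "raw", n = clen - length(body))
    if (length(chunk) == 0L) { Sys.sleep(0.01); next }
    body <- c(body, chunk)
  }
  list(method = req_line[1], path = req_line[2],
       body = rawToChar(body), too_large = FALSE)
}

find_header_end <- function(raw) {
  if (length(raw) < 4L) return(NA_integer_)
  crlf <- which(raw == as.raw(13L))
  for (i in crlf) {
    if (i + 3L <= length(raw) &&
        identical(raw[i:(i + 3L)], as.raw(c(13L, 10L, 13L, 10L))))
      return(i)
  }
  NA_integer_
}

http_response <- function(status, body, content_type = "application/json") {
  payload <- charToRaw(enc2utf8(body))
  head <- paste0("HTTP/1.1 ", status, "\r\n",
                 "Content-Type: ", content_type, "; charset=utf-8\r\n",
                 "Content-Length: ", length(payload), "\r\n",
                 "Connection: close\r\n\r\n")
  c(charToRaw(head), payload)
}

handle_http_request <- function(req, artifact, max_bytes) {
  if (is.null(req))
    return(http_response("400 Bad Request",
                         canonical_json(list(error = "malformed request"))))
  if (isTRUE(req$too_large))
    return(http_response("413 Payload Too Large",
                         canonical_json(list(error = paste0(
                           "payload exceeds limit of ", req$limit, " bytes")))))
  if (req$method != "POST")
    return(http_response("405 Method Not Allowed",
                         canonical_json(list(error = "POST plain text to annotate"))))
  doc <- annotate_with_artifact(artifact, req$body)
  http_response("200 OK", doc_to_json(doc, artifact$fingerprint))
}

#' Serve the annotation endpoint over HTTP
#'
#' Starts a minimal blocking HTTP server: POST plain text (any path) to
#' receive the annotation JSON produced by [annotate_with_artifact()] --
#' the same code path as the CLI.  The server is stateless; the artifact
#' is read-only.  Oversized payloads are rejected with status 413 and the
#' limit stated.
#'
#' @param artifact A `medlinkr_artifact` or path to a saved artifact.
#' @param port TCP port to listen on.
#' @param max_requests Stop after this many requests (default unlimited;
#'   finite values support scripted use).
#' @param max_bytes Payload size limit in bytes.
#' @return Number of requests served, invisibly.
#' @export
serve <- function(artifact, port, max_requests = Inf, max_bytes = 1048576L) {
  if (is.character(artifact)) artifact <- load_artifact(artifact)
  stopifnot(inherits(artifact, "medlinkr_artifact"))
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  served <- 0
  while (served < max_requests) {
    # non-blocking: readBin must return whatever bytes are available
    con <- socketAccept(srv, blocking = FALSE, open = "a+b", timeout = 30)
    resp <- tryCatch({
      req <- read_http_request(con, max_bytes)
      handle_http_request(req, artifact, max_bytes)
    }, error = function(e)
      http_response("500 Internal Server Error",
                    canonical_json(list(error = conditionMessage(e)))))
    writeBin(resp, con)
    flush(con)
    close(con)
    served <- served + 1
  }
  invisible(served)
}
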