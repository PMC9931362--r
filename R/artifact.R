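# Deployable build artifact: one container bundling the knowledge base,
# term index, unigram language model, PageRank scores, scorer and config
# fingerprint -- everything the runtime stage needs for instant
# deployment.

ARTIFACT_VERSION <- "1.0.0"

canonical_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

md5_of_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f, useBytes = TRUE)
  unname(tools::md5sum(f))
}

artifact_fingerprint <- function(config, index, lm, pr, scorer) {
  payload <- list(
    config = config,
    index_surfaces = index_surfaces(index),
    lm = list(total = lm$total, vocab = lm$vocab_size,
              smoothing = lm$smoothing,
              count_sum = unname(sum(lm$counts))),
    pr = signif(unname(pr$scores[order(names(pr$scores))]), 12),
    scorer = list(w = signif(scorer$weights, 12),
                  b = signif(scorer$bias, 12)))
  md5_of_string(canonical_json(payload))
}

#' Run the build stage
#'
#' Executes the full pipeline: parse the dump, select entities by the
#' profile, synthesize the weakly annotated corpus from the pages, fit
#' the unigram language model, compute PageRank, build the term index and
#' train the scorer.  Returns the deployable artifact; the build report
#' (counts per stage) is attached as attribute `"report"`.
#'
#' @param dump_path Knowledge-dump file.
#' @param pages_path Pages file.
#' @param profile A `medlinkr_profile` or path to a profile YAML.
#' @param pagerank_damping,pagerank_iterations PageRank parameters.
#' @param lm_smoothing Language-model pseudo-count.
#' @param n,window,lambda Propagation/graph parameters.
#' @param threshold Default NIL threshold stored in the artifact.
#' @param seed Integer seed recorded in the config.
#' @param site Wiki site code for sitelink matching.
#' @return Object of class `medlinkr_artifact`.
#' @export
build_annotator <- function(dump_path, pages_path, profile = medical_profile(),
                            pagerank_damping = 0.85,
                            pagerank_iterations = 50L, lm_smoothing = 1,
                            n = 2L, window = 5L, lambda = 1, threshold = 0,
                            seed = 1L, site = "dewiki") {
  if (is.character(profile)) profile <- read_profile(profile)
  for (p in c(dump_path, pages_path))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  kb <- parse_dump(dump_path, language = profile$language)
  selected <- select_entities(kb, profile)
  pages <- read_pages(pages_path)
  corpus <- synthesize_corpus(kb, pages, selected, site = site)
  lm <- fit_lm(kb, selected, profile$language, smoothing = lm_smoothing)
  pr <- kb_pagerank(kb, damping = pagerank_damping,
                    iterations = pagerank_iterations)
  index <- build_index(kb, selected, profile$language)
  scorer <- train_scorer(corpus, kb, index, lm, pr, n = n, window = window,
                         lambda = lambda, seed = seed)
  config <- list(language = profile$language,
                 statement_properties = profile$statement_properties,
                 closure_roots = profile$closure_roots,
                 pagerank_damping = pagerank_damping,
                 pagerank_iterations = as.integer(pagerank_iterations),
                 lm_smoothing = lm_smoothing, n = as.integer(n),
                 window = as.integer(window), lambda = lambda,
                 threshold = threshold, seed = as.integer(seed),
                 site = site,
                 dump_md5 = unname(tools::md5sum(dump_path)),
                 pages_md5 = unname(tools::md5sum(pages_path)))
  art <- structure(list(version = ARTIFACT_VERSION,
                        config = config,
                        kb = kb, index = index, lm = lm, pr = pr,
                        scorer = scorer,
                        fingerprint = artifact_fingerprint(config, index, lm,
                                                           pr, scorer)),
                   class = "medlinkr_artifact")
  attr(art, "report") <- list(
    entities_parsed = length(kb$entities),
    reference_edges = nrow(kb$edges),
    entities_selected = length(selected),
    pages = length(pages),
    corpus_documents = length(corpus),
    corpus_annotations = sum(vapply(corpus, function(d)
      nrow(d$annotations), integer(1))),
    index_terms = index_n_terms(index),
    lm_vocabulary = lm$vocab_size,
    training_positives = scorer$n_pos,
    training_negatives = scorer$n_neg)
  art
}

#' @export
print.medlinkr_artifact <- function(x, ...) {
  cat(sprintf("<medlinkr_artifact v%s fingerprint %s: %d entities, %d terms>\n",
              x$version, x$fingerprint, length(x$kb$entities),
              index_n_terms(x$index)))
  invisible(x)
}

#' Save / load a build artifact
#'
#' The artifact is one container file; the loader refuses artifacts whose
#' major version differs from the running package's artifact version.
#'
#' @param artifact A `medlinkr_artifact`.
#' @param path File path.
#' @export
save_artifact <- function(artifact, path) {
  stopifnot(inherits(artifact, "medlinkr_artifact"))
  saveRDS(artifact, path)
  invisible(path)
}

#' @rdname save_artifact
#' @export
load_artifact <- function(path) {
  if (!file.exists(path)) stop("artifact path does not exist: ", path)
  art <- readRDS(path)
  if (!inherits(art, "medlinkr_artifact"))
    stop("not a medlinkr artifact: ", path)
  major <- function(v) strsplit(v, ".", fixed = TRUE)[[1]][1]
  if (major(art$version) != major(ARTIFACT_VERSION))
    stop("incompatible artifact version ", art$version,
         " (this package builds ", ARTIFACT_VERSION, ")")
  art
}

#' Annotate text with a build artifact
#'
#' Runtime-stage entry point: runs the full annotation pipeline with the
#' artifact's components, optionally applies the noun post-filter, and
#' returns the annotated document.
#'
#' @param artifact A `medlinkr_artifact`.
#' @param text Input text.
#' @param threshold NIL threshold (defaults to the build config value).
#' @param apply_pos_filter Apply the default noun rule?
#' @param doc_id Document identifier.
#' @return A `medlinkr_doc`.
#' @export
annotate_with_artifact <- function(artifact, text,
                                   threshold = artifact$config$threshold,
                                   apply_pos_filter = FALSE,
                                   doc_id = "doc") {
  stopifnot(inherits(artifact, "medlinkr_artifact"))
  doc <- annotate_text(text, artifact$kb, artifact$index, artifact$lm,
                       artifact$pr, artifact$scorer, threshold = threshold,
                       doc_id = doc_id)
  if (apply_pos_filter) doc <- pos_filter(doc)
  doc
}

#' Serialize an annotated document to the annotation JSON schema
#'
#' @param doc A `medlinkr_doc`.
#' @param fingerprint Build fingerprint to embed (optional).
#' @return JSON string.
#' @export
doc_to_json <- function(doc, fingerprint = NULL) {
  ann <- doc$annotations
  anns <- lapply(seq_len(nrow(ann)), function(i) {
    out <- list(begin = ann$begin[i], end = ann$end[i],
                surface = ann$surface[i], entity = ann$entity[i])
    if (!is.null(ann$score)) out$score <- ann$score[i]
    out
  })
  payload <- list(doc_id = doc$doc_id, text = doc$text, annotations = anns)
  if (!is.null(fingerprint)) payload$fingerprint <- fingerprint
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
}
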