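# Character-level binary-segmentation evaluation: annotation spans define
# a segmentation mask over the document, and precision/recall/F1 are
# computed on the per-character masks of ground truth and prediction.

#' Build a segmentation mask from spans
#'
#' Union of 0-based half-open character intervals over a document of the
#' given length.
#'
#' @param spans `data.frame` with `begin`, `end` (or a 2-column matrix).
#' @param length Document length in characters.
#' @return Object of class `medlinkr_mask`: `length` and `covered`
#'   (sorted 0-based positions).
#' @export
to_mask <- function(spans, length) {
  if (is.matrix(spans)) spans <- data.frame(begin = spans[, 1], end = spans[, 2])
  covered <- integer()
  for (i in seq_len(nrow(spans))) {
    b <- spans$begin[i]; e <- spans$end[i]
    if (b < 0 || e > length) stop("span [", b, ",", e, ") out of bounds for length ", length)
    if (e > b) covered <- c(covered, seq.int(b, e - 1L))
  }
  structure(list(length = as.integer(length),
                 covered = sort(unique(as.integer(covered)))),
            class = "medlinkr_mask")
}

doc_mask <- function(doc) {
  to_mask(doc$annotations, nchar(doc$text, type = "chars"))
}

#' Character-level segmentation precision, recall and F1
#'
#' Counts per-character true/false positives and false negatives between
#' two masks of equal length.  Conventions: an empty ratio (0/0) counts as
#' 1, so identical empty masks score F1 = 1 while an empty prediction
#' against a non-empty ground truth scores 0.
#'
#' @param gt,pred `medlinkr_mask` objects of equal length.
#' @return Named numeric vector `(precision, recall, f1)`.
#' @export
segmentation_scores <- function(gt, pred) {
  if (gt$length != pred$length)
    stop("mask length mismatch: ", gt$length, " vs ", pred$length)
  tp <- length(intersect(gt$covered, pred$covered))
  fp <- length(setdiff(pred$covered, gt$covered))
  fn <- length(setdiff(gt$covered, pred$covered))
  precision <- if (tp + fp == 0L) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Filter ground truth to concept codes known to the knowledge base
#'
#' Removes ground-truth annotations whose external concept code (e.g. a
#' UMLS CUI) is not in `known_codes`; documents are retained even when
#' emptied.  Annotations without a code are treated as unknown.
#'
#' @param gt_docs List of `medlinkr_doc` whose annotations carry a `code`
#'   column.
#' @param known_codes Character vector of known codes.
#' @return Filtered corpus.
#' @export
filtered_ground_truth <- function(gt_docs, known_codes) {
  lapply(gt_docs, function(doc) {
    ann <- doc$annotations
    if (nrow(ann) == 0L) return(doc)
    code <- if (!is.null(ann$code)) ann$code else rep(NA_character_, nrow(ann))
    keep <- !is.na(code) & code %in% known_codes
    annotated_doc(doc$doc_id, doc$text, ann[keep, , drop = FALSE])
  })
}

#' Evaluate predicted annotations against a ground-truth corpus
#'
#' Pairs documents by id, computes per-document segmentation scores, a
#' micro average over the concatenated masks and a macro average of the
#' per-document F1.  In `"filtered"` mode the ground truth is first
#' reduced to annotations with codes in `known_codes`.
#'
#' @param gt_docs,pred_docs Lists of `medlinkr_doc` with matching ids.
#' @param mode `"raw"` or `"filtered"`.
#' @param known_codes Known concept codes (filtered mode).
#' @return List with `per_document` (`data.frame`), `micro`, `macro`.
#' @export
evaluate_corpus <- function(gt_docs, pred_docs, mode = c("raw", "filtered"),
                            known_codes = character()) {
  mode <- match.arg(mode)
  gt_ids <- vapply(gt_docs, `[[`, character(1), "doc_id")
  pred_ids <- vapply(pred_docs, `[[`, character(1), "doc_id")
  unmatched <- c(setdiff(gt_ids, pred_ids), setdiff(pred_ids, gt_ids))
  if (length(unmatched))
    stop("unmatched document ids: ", paste(unmatched, collapse = ", "))
  if (mode == "filtered") gt_docs <- filtered_ground_truth(gt_docs, known_codes)
  names(pred_docs) <- pred_ids
  rows <- list(); tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(gt_docs)) {
    gt <- gt_docs[[i]]
    pred <- pred_docs[[gt$doc_id]]
    gm <- doc_mask(gt); pm <- doc_mask(pred)
    s <- segmentation_scores(gm, pm)
    tp <- tp + length(intersect(gm$covered, pm$covered))
    fp <- fp + length(setdiff(pm$covered, gm$covered))
    fn <- fn + length(setdiff(gm$covered, pm$covered))
    rows[[i]] <- data.frame(doc_id = gt$doc_id, precision = s["precision"],
                            recall = s["recall"], f1 = s["f1"],
                            stringsAsFactors = FALSE)
  }
  per_doc <- do.call(rbind, rows)
  rownames(per_doc) <- NULL
  precision <- if (tp + fp == 0L) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(per_document = per_doc,
       micro = c(precision = precision, recall = recall, f1 = f1),
       macro = c(f1 = if (is.null(per_doc)) NA_real_ else mean(per_doc$f1)))
}
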