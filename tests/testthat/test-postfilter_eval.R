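# Deterministic stub tagger: a fixed token/PoS table per text, so the
# filter tests do not depend on the heuristic adapter.
stub_tagger <- function(table) {
  function(text) table
}

test_that("the noun rule removes determiner-only annotations and keeps nouns", {
  text <- "Das Medikament wirkt."
  tags <- data.frame(begin = c(0L, 4L, 15L), end = c(3L, 14L, 20L),
                     token = c("Das", "Medikament", "wirkt"),
                     pos = c("DET", "NOUN", "X"), stringsAsFactors = FALSE)
  doc <- annotated_doc("d", text,
                       data.frame(begin = c(0L, 4L), end = c(3L, 14L),
                                  entity = c("Q99", "Q1"),
                                  stringsAsFactors = FALSE))
  out <- pos_filter(doc, tags = tags)
  expect_equal(out$annotations$entity, "Q1")     # "Das" artifact removed
  # permissive rule: identity on annotations
  all_pass <- pos_filter(doc, tags = tags, rule = function(span, t) TRUE)
  expect_equal(nrow(all_pass$annotations), 2L)
  # rules never add annotations; composition behaves as conjunction
  none <- pos_filter(out, tags = tags, rule = function(span, t) FALSE)
  expect_equal(nrow(none$annotations), 0L)
})

test_that("the heuristic German tagger feeds the default rule sensibly", {
  tags <- heuristic_pos_tagger("Das Medikament wirkt bei 5 mg.")
  expect_equal(tags$pos[tags$token == "Das"], "DET")
  expect_equal(tags$pos[tags$token == "Medikament"], "NOUN")
  expect_equal(tags$pos[tags$token == "5"], "NUM")
  doc <- annotated_doc("d", "Das Medikament wirkt.",
                       data.frame(begin = c(0L, 4L), end = c(3L, 14L),
                                  entity = c("Q99", "Q1"),
                                  stringsAsFactors = FALSE))
  expect_equal(pos_filter(doc)$annotations$entity, "Q1")
})

test_that("masks are interval unions matching the per-character oracle", {
  m <- to_mask(data.frame(begin = c(0L, 2L), end = c(3L, 5L)), 10L)
  expect_equal(m$covered, 0:4)
  expect_equal(to_mask(data.frame(begin = integer(), end = integer()),
                       5L)$covered, integer())
  expect_error(to_mask(data.frame(begin = 0L, end = 11L), 10L), "bounds")
  set.seed(13)
  for (trial in 1:20) {
    len <- sample(5:60, 1)
    k <- sample(0:6, 1)
    b <- sort(sample(0:(len - 1), k, replace = TRUE))
    spans <- data.frame(begin = b,
                        end = pmin(len, b + sample(1:8, k, replace = TRUE)))
    expect_equal(to_mask(spans, len)$covered, oracle_mask(spans, len))
  }
})

test_that("segmentation scores match hand-computed values", {
  len <- 30L
  mask <- function(...) to_mask(data.frame(...), len)
  ident <- mask(begin = c(0L, 10L), end = c(5L, 15L))
  expect_equal(segmentation_scores(ident, ident),
               c(precision = 1, recall = 1, f1 = 1))
  disjoint_a <- mask(begin = 0L, end = 5L)
  disjoint_b <- mask(begin = 10L, end = 15L)
  expect_equal(segmentation_scores(disjoint_a, disjoint_b),
               c(precision = 0, recall = 0, f1 = 0))
  # gt 10 chars, pred covers 8 of them plus 2 others -> P = R = F1 = 0.8
  gt <- mask(begin = 0L, end = 10L)
  pred <- mask(begin = c(2L, 20L), end = c(10L, 22L))
  expect_equal(segmentation_scores(gt, pred),
               c(precision = 0.8, recall = 0.8, f1 = 0.8))
  # empty conventions
  empty <- mask(begin = integer(), end = integer())
  expect_equal(segmentation_scores(empty, empty)[["f1"]], 1)
  expect_equal(segmentation_scores(gt, empty)[["f1"]], 0)
  # one-sided containment: P 1, R 0.5, F1 2/3
  half <- mask(begin = 0L, end = 5L)
  expect_equal(segmentation_scores(gt, half),
               c(precision = 1, recall = 0.5, f1 = 2 / 3))
  expect_error(segmentation_scores(gt, to_mask(data.frame(begin = 0L, end = 1L),
                                               10L)), "length")
})

test_that("swapping gt and pred exchanges precision and recall", {
  set.seed(29)
  for (trial in 1:15) {
    len <- 40L
    rspans <- function() {
      k <- sample(1:4, 1)
      b <- sample(0:(len - 2), k)
      data.frame(begin = b, end = pmin(len, b + sample(1:6, k, replace = TRUE)))
    }
    a <- to_mask(rspans(), len); b <- to_mask(rspans(), len)
    sab <- segmentation_scores(a, b); sba <- segmentation_scores(b, a)
    expect_equal(sab[["precision"]], sba[["recall"]])
    expect_equal(sab[["recall"]], sba[["precision"]])
    expect_equal(sab[["f1"]], sba[["f1"]])
  }
})

test_that("trimming predicted characters outside gt never lowers F1", {
  len <- 30L
  gt <- to_mask(data.frame(begin = 5L, end = 15L), len)
  wide <- to_mask(data.frame(begin = 2L, end = 18L), len)
  trimmed <- to_mask(data.frame(begin = 5L, end = 15L), len)
  expect_gte(segmentation_scores(gt, trimmed)[["f1"]],
             segmentation_scores(gt, wide)[["f1"]])
})

test_that("filtered ground truth removes exactly the unknown-code annotations", {
  mk_gt <- function(codes) {
    n <- length(codes)
    annotated_doc("d", paste(rep("wort", n + 1), collapse = " "),
                  data.frame(begin = (seq_len(n) - 1L) * 5L,
                             end = (seq_len(n) - 1L) * 5L + 4L,
                             entity = sprintf("Q%d", seq_len(n)),
                             code = codes, stringsAsFactors = FALSE))
  }
  docs <- list(mk_gt(c("C1", "C2", "C3")), mk_gt(c("C4", NA)))
  out <- filtered_ground_truth(docs, known_codes = c("C1", "C3"))
  expect_equal(out[[1]]$annotations$code, c("C1", "C3"))
  expect_equal(nrow(out[[2]]$annotations), 0L)   # document kept, emptied
  expect_length(out, 2L)
  # all known -> identity; none known -> all removed
  same <- filtered_ground_truth(docs[1], known_codes = c("C1", "C2", "C3"))
  expect_equal(nrow(same[[1]]$annotations), 3L)
  none <- filtered_ground_truth(docs[1], known_codes = character())
  expect_equal(nrow(none[[1]]$annotations), 0L)
})

test_that("a known-code subset of planted codes survives exactly (90-of-309 style)", {
  set.seed(41)
  codes <- sprintf("C%07d", sample.int(9999999, 309))
  known <- sample(codes, 90)
  docs <- lapply(1:20, function(i) {
    k <- sample(10:20, 1)
    cs <- sample(codes, k)
    annotated_doc(sprintf("d%d", i),
                  paste(rep("w", 6 * k), collapse = " "),
                  data.frame(begin = (seq_len(k) - 1L) * 2L,
                             end = (seq_len(k) - 1L) * 2L + 1L,
                             entity = sprintf("Q%d", seq_len(k)),
                             code = cs, stringsAsFactors = FALSE))
  })
  out <- filtered_ground_truth(docs, known)
  for (i in seq_along(docs)) {
    got <- out[[i]]$annotations$code
    if (is.null(got)) got <- character()   # all removed: empty frame
    expect_equal(got,
                 docs[[i]]$annotations$code[docs[[i]]$annotations$code %in% known])
  }
})

test_that("corpus evaluation reports per-document, micro and macro scores", {
  gt <- list(
    annotated_doc("d1", "0123456789",
                  data.frame(begin = 0L, end = 5L, entity = "Q1",
                             stringsAsFactors = FALSE)),
    annotated_doc("d2", "0123456789",
                  data.frame(begin = 0L, end = 4L, entity = "Q2",
                             stringsAsFactors = FALSE)))
  pred_same <- gt
  ev <- evaluate_corpus(gt, pred_same)
  expect_equal(unname(ev$micro["f1"]), 1)
  pred_empty <- lapply(gt, function(d) annotated_doc(d$doc_id, d$text))
  ev0 <- evaluate_corpus(gt, pred_empty)
  expect_equal(unname(ev0$micro["f1"]), 0)
  # hand-computed micro scores: d1 pred [0,5) exact; d2 pred [2,8):
  # TP = 5 + 2 = 7, FP = 0 + 4 = 4, FN = 0 + 2 = 2
  pred_mix <- list(gt[[1]],
                   annotated_doc("d2", "0123456789",
                                 data.frame(begin = 2L, end = 8L,
                                            entity = "Q2",
                                            stringsAsFactors = FALSE)))
  evm <- evaluate_corpus(gt, pred_mix)
  expect_equal(unname(evm$micro["precision"]), 7 / 11)
  expect_equal(unname(evm$micro["recall"]), 7 / 9)
  expect_equal(unname(evm$micro["f1"]),
               2 * (7 / 11) * (7 / 9) / (7 / 11 + 7 / 9))
  expect_equal(nrow(evm$per_document), 2L)
  expect_equal(unname(evm$macro["f1"]),
               mean(evm$per_document$f1))
  expect_error(evaluate_corpus(gt, pred_mix[1]), "unmatched")
})

test_that("filtered evaluation mode reduces the ground truth before scoring", {
  gt <- list(annotated_doc("d1", "0123456789",
                           data.frame(begin = c(0L, 6L), end = c(3L, 9L),
                                      entity = c("Q1", "Q2"),
                                      code = c("C1", "C2"),
                                      stringsAsFactors = FALSE)))
  pred <- list(annotated_doc("d1", "0123456789",
                             data.frame(begin = 0L, end = 3L, entity = "Q1",
                                        stringsAsFactors = FALSE)))
  raw <- evaluate_corpus(gt, pred, mode = "raw")
  expect_lt(unname(raw$micro["f1"]), 1)
  filt <- evaluate_corpus(gt, pred, mode = "filtered", known_codes = "C1")
  expect_equal(unname(filt$micro["f1"]), 1)
})
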