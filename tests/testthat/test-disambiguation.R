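lm_fixture_kb <- function() {
  new_kb(list(
    mk_entity("Q1", label = "Opioid", aliases = "Opioide",
              statements = list(st_lit("P2892", "C1"), st_lit("P699", "D1"),
                                st_lit("P486", "M1")),
              sitelinks = c(dewiki = "Opioid", enwiki = "Opioid")),
    mk_entity("Q2", label = "Laktulose")))
}

test_that("unigram probabilities follow the additive-smoothing closed form", {
  kb <- new_kb(list(mk_entity("Q1", label = "wort")))
  lm0 <- fit_lm(kb, "Q1", "de", smoothing = 0)
  expect_equal(mention_prob(lm0, "wort"), 1)      # single token, no smoothing
  expect_equal(surprisal(lm0, "wort"), 0)
  lm1 <- fit_lm(kb, "Q1", "de", smoothing = 1)
  # seen: (1+1)/(1 + 1*(1+1)); unseen: 1/(1 + 1*(1+1))
  expect_equal(mention_prob(lm1, "wort"), 2 / 3)
  expect_equal(mention_prob(lm1, "neu"), 1 / 3)
  kb2 <- new_kb(list(mk_entity("Q1", label = "a a a b")))
  lm2 <- fit_lm(kb2, "Q1", "de")
  expect_gt(mention_prob(lm2, "a"), mention_prob(lm2, "b"))
  # multi-token mention: product of token probabilities
  expect_equal(mention_prob(lm2, "a b"),
               mention_prob(lm2, "a") * mention_prob(lm2, "b"))
  expect_error(fit_lm(new_kb(list(mk_entity("Q9"))), "Q9", "de"), "no label")
})

test_that("the local feature vector is the documented 5-tuple", {
  kb <- lm_fixture_kb()
  # stand-in models with exact known values
  lm <- structure(list(counts = c(opioid = 1), total = 2, vocab_size = 1,
                       smoothing = 0, language = "de"),
                  class = "medlinkr_lm")   # p(opioid) = 1/2
  pr <- structure(list(scores = c(Q1 = 0.25, Q2 = 0.75), damping = 0.85,
                       iterations = 50L), class = "medlinkr_pagerank")
  f <- local_features("Opioid", "Q1", kb, lm, pr)
  expect_equal(f, c(-log(0.5), log(0.25), 3, 2, 1), tolerance = 1e-12)
  f2 <- local_features("Laktulose", "Q2", kb, lm, pr)
  expect_equal(f2[3:5], c(0, 0, 1))   # no statements, no sitelinks
  expect_equal(f2[5], 1)
  expect_error(local_features("x", "Qzz", kb, lm, pr), "Qzz")
})

graph_fixture <- function() {
  # Q1-Q2 directly linked; Q3 and Q4 share the common neighbor Q5;
  # Q6 is isolated.
  kb <- new_kb(list(
    mk_entity("Q1", statements = list(st_ent("P1", "Q2"))),
    mk_entity("Q2"),
    mk_entity("Q3", statements = list(st_ent("P1", "Q5"))),
    mk_entity("Q4", statements = list(st_ent("P1", "Q5"))),
    mk_entity("Q5"),
    mk_entity("Q6")))
  kb
}

mentions_of <- function(cands) {
  n <- length(cands)
  out <- data.frame(begin = seq_len(n) * 10L, end = seq_len(n) * 10L + 5L,
                    surface = sprintf("m%d", seq_len(n)),
                    stringsAsFactors = FALSE)
  out$candidates <- cands
  out
}

test_that("mention-graph weights encode direct links and shared neighbors", {
  kb <- graph_fixture()
  g <- build_mention_graph(mentions_of(list("Q1", "Q2")), kb)
  expect_equal(g$M[1, 2], 2)           # direct link counted from both sides
  g2 <- build_mention_graph(mentions_of(list("Q3", "Q4")), kb)
  expect_equal(g2$M[1, 2], 1)          # one common neighbor, no direct link
  g3 <- build_mention_graph(mentions_of(list("Q1", "Q6")), kb)
  expect_equal(g3$M[1, 2], 0)          # unrelated pair
  # direct pair weighs more than unlinked pair in the same graph
  g4 <- build_mention_graph(mentions_of(list("Q1", "Q2", "Q6")), kb)
  expect_gt(g4$M[1, 2], g4$M[1, 3])
})

test_that("the stochastic matrix is row-normalized with self-loop smoothing", {
  kb <- graph_fixture()
  g <- build_mention_graph(mentions_of(list(c("Q1", "Q3"), "Q2", "Q4")), kb)
  expect_equal(nrow(g$nodes), 4L)      # sum of candidates over mentions
  expect_true(isSymmetric(g$M))
  expect_true(all(diag(g$M) == 0))
  expect_equal(unname(rowSums(g$stochastic)), rep(1, 4), tolerance = 1e-9)
  # nodes of the same mention are never connected
  same <- which(g$nodes$mention == 1L)
  expect_equal(g$M[same[1], same[2]] , 0)
  # single mention: stochastic matrix is the identity
  g1 <- build_mention_graph(mentions_of(list(c("Q1", "Q2"))), kb)
  expect_equal(g1$stochastic, diag(2))
})

test_that("the neighbor window limits which mentions connect", {
  kb <- graph_fixture()
  cands <- list("Q1", "Q2", "Q1", "Q2", "Q1", "Q2", "Q1", "Q2")
  g <- build_mention_graph(mentions_of(cands), kb, window = 2L)
  expect_equal(g$M[1, 2], 2)   # distance 1: direct KB link, counted twice
  expect_equal(g$M[1, 3], 1)   # distance 2: same entity, shared neighbor Q2
  expect_equal(g$M[1, 4], 0)   # distance 3: beyond the window
  expect_equal(g$M[1, 6], 0)
})

test_that("propagation obeys its fixed points and the hand-computed product", {
  F0 <- matrix(c(1, 2, 3, 4, 5,
                 5, 4, 3, 2, 1), nrow = 2, byrow = TRUE)
  g_id <- list(nodes = data.frame(mention = 1:2, entity = c("a", "b")),
               stochastic = diag(2))
  expect_length(propagate(F0, g_id, n = 0L), 1L)
  t_id <- propagate(F0, g_id, n = 3L)
  for (Fk in t_id) expect_equal(as.matrix(Fk), F0)
  g_mix <- list(nodes = g_id$nodes,
                stochastic = matrix(0.5, 2, 2))
  t_mix <- propagate(F0, g_mix, n = 1L)
  expect_equal(as.matrix(t_mix[[2]]),
               rbind(colMeans(F0), colMeans(F0)))
  expect_error(propagate(F0[1, , drop = FALSE], g_id), "match")
})

test_that("propagated entries stay within the column extrema of FM0", {
  set.seed(5)
  kb <- random_kb(30)
  for (trial in 1:10) {
    k <- sample(2:6, 1)
    cands <- lapply(seq_len(k), function(i)
      sample(names(kb$entities), sample(1:3, 1)))
    g <- build_mention_graph(mentions_of(cands), kb, window = 3L)
    nn <- nrow(g$nodes)
    F0 <- matrix(stats::rnorm(nn * 5), nn, 5)
    expect_equal(unname(rowSums(g$stochastic)), rep(1, nn), tolerance = 1e-9)
    tensor <- propagate(F0, g, n = 3L)
    for (Fk in tensor) {
      Fk <- as.matrix(Fk)
      for (col in 1:5) {
        expect_gte(min(Fk[, col]), min(F0[, col]) - 1e-12)
        expect_lte(max(Fk[, col]), max(F0[, col]) + 1e-12)
      }
    }
  }
})

# A tiny separable world: alias "Dupla" is shared by QA and QB; context
# mention "Kontext" (entity QC) is a KB neighbor of QA only.
separable_world <- function() {
  kb <- new_kb(list(
    mk_entity("QA", label = "Alpha", aliases = "Dupla",
              statements = list(st_lit("P2892", "C1"), st_ent("P2175", "QC"))),
    mk_entity("QB", label = "Beta", aliases = "Dupla",
              statements = list(st_lit("P2892", "C2"), st_ent("P2175", "QD"))),
    mk_entity("QC", label = "Kontext",
              statements = list(st_lit("P2892", "C3"), st_lit("P1", "x"),
                                st_lit("P2", "y"), st_lit("P3", "z")),
              sitelinks = c(dewiki = "Kontext", enwiki = "K")),
    mk_entity("QD", label = "Gegenpol",
              statements = list(st_lit("P2892", "C4"), st_lit("P1", "x"),
                                st_lit("P2", "y"), st_lit("P3", "z")),
              sitelinks = c(dewiki = "Gegenpol", enwiki = "G"))))
  sel <- c("QA", "QB", "QC", "QD")
  idx <- build_index(kb, sel, "de")
  lm <- fit_lm(kb, sel, "de")
  pr <- kb_pagerank(kb)
  docs <- c(
    lapply(1:6, function(i) annotated_doc(
      sprintf("a%d", i), "Gabe von Dupla neben Kontext heute.",
      data.frame(begin = c(9L, 21L), end = c(14L, 28L),
                 entity = c("QA", "QC"), stringsAsFactors = FALSE))),
    lapply(1:6, function(i) annotated_doc(
      sprintf("b%d", i), "Gabe von Dupla neben Gegenpol heute.",
      data.frame(begin = c(9L, 21L), end = c(14L, 29L),
                 entity = c("QB", "QD"), stringsAsFactors = FALSE))))
  list(kb = kb, sel = sel, idx = idx, lm = lm, pr = pr, docs = docs)
}

test_that("the scorer separates a constructed ambiguous fixture perfectly", {
  w <- separable_world()
  scorer <- train_scorer(w$docs, w$kb, w$idx, w$lm, w$pr)
  expect_equal(scorer$n_pos, 24L)
  expect_equal(scorer$n_neg, 12L)
  # ranking accuracy on the training corpus itself
  correct <- 0L; total <- 0L
  for (d in w$docs) {
    pred <- annotate_text(d$text, w$kb, w$idx, w$lm, w$pr, scorer,
                          threshold = -Inf, doc_id = d$doc_id)
    for (i in seq_len(nrow(d$annotations))) {
      total <- total + 1L
      hit <- pred$annotations[pred$annotations$begin == d$annotations$begin[i], ]
      if (nrow(hit) == 1 && hit$entity == d$annotations$entity[i])
        correct <- correct + 1L
    }
  }
  expect_equal(correct, total)
})

test_that("training is deterministic and invariant to example order", {
  w <- separable_world()
  s1 <- train_scorer(w$docs, w$kb, w$idx, w$lm, w$pr, seed = 1L)
  s2 <- train_scorer(w$docs, w$kb, w$idx, w$lm, w$pr, seed = 1L)
  expect_identical(s1$weights, s2$weights)
  expect_identical(s1$bias, s2$bias)
  s3 <- train_scorer(rev(w$docs), w$kb, w$idx, w$lm, w$pr, seed = 1L)
  expect_equal(s3$weights, s1$weights, tolerance = 1e-6)
  expect_equal(s3$bias, s1$bias, tolerance = 1e-6)
})

test_that("the linear scorer agrees in sign with an independent SVM on the fixture", {
  skip_if_not_installed("e1071")
  w <- separable_world()
  scorer <- train_scorer(w$docs, w$kb, w$idx, w$lm, w$pr)
  # rebuild the standardized training matrix the same way and compare
  # decisions with e1071's linear SVM
  X <- NULL; y <- integer()
  for (d in w$docs) {
    mentions <- tag_mentions(d$text, w$idx)
    feats <- medlinkr:::document_features(mentions, w$kb, w$lm, w$pr,
                                          n = 2L, window = 5L, lambda = 1)
    for (i in seq_len(nrow(d$annotations))) {
      mi <- which(mentions$begin == d$annotations$begin[i])
      for (r in which(feats$nodes$mention == mi)) {
        X <- rbind(X, feats$X[r, ])
        y <- c(y, if (feats$nodes$entity[r] == d$annotations$entity[i]) 1L else -1L)
      }
    }
  }
  keep <- apply(X, 2, stats::sd) > 0
  fit <- e1071::svm(X[, keep], factor(y), kernel = "linear", scale = TRUE)
  svm_pred <- as.integer(as.character(stats::predict(fit, X[, keep])))
  own_pred <- ifelse(score_nodes(scorer, X) >= 0, 1L, -1L)
  expect_equal(own_pred, svm_pred)
})

test_that("a corpus without ambiguity degenerates with a warning, not an error", {
  kb <- new_kb(list(mk_entity("Q1", label = "Opioid",
                              statements = list(st_lit("P2892", "C1")))))
  idx <- build_index(kb, "Q1", "de")
  lm <- fit_lm(kb, "Q1", "de")
  pr <- kb_pagerank(kb)
  docs <- list(annotated_doc("d1", "Gabe von Opioid.",
                             data.frame(begin = 9L, end = 15L, entity = "Q1",
                                        stringsAsFactors = FALSE)))
  expect_warning(s <- train_scorer(docs, kb, idx, lm, pr), "no negative")
  expect_s3_class(s, "medlinkr_scorer")
})

test_that("annotate keeps the argmax above threshold and resolves overlaps", {
  w <- separable_world()
  scorer <- train_scorer(w$docs, w$kb, w$idx, w$lm, w$pr)
  expect_equal(nrow(annotate_text("", w$kb, w$idx, w$lm, w$pr,
                                  scorer)$annotations), 0L)
  d <- annotate_text("Kontext", w$kb, w$idx, w$lm, w$pr, scorer,
                     threshold = -Inf)
  expect_equal(d$annotations$entity, "QC")
  # context decides the ambiguous alias
  dA <- annotate_text("Gabe von Dupla neben Kontext heute.",
                      w$kb, w$idx, w$lm, w$pr, scorer, threshold = -Inf)
  expect_equal(dA$annotations$entity[dA$annotations$surface == "Dupla"], "QA")
  dB <- annotate_text("Gabe von Dupla neben Gegenpol heute.",
                      w$kb, w$idx, w$lm, w$pr, scorer, threshold = -Inf)
  expect_equal(dB$annotations$entity[dB$annotations$surface == "Dupla"], "QB")
  # spans never overlap nor exceed bounds
  for (doc in list(dA, dB)) {
    a <- doc$annotations
    expect_true(all(a$begin >= 0 & a$end <= nchar(doc$text)))
    if (nrow(a) > 1)
      expect_true(all(a$begin[-1] >= a$end[-nrow(a)]))
  }
})

test_that("raising the NIL threshold never adds annotations", {
  w <- separable_world()
  scorer <- train_scorer(w$docs, w$kb, w$idx, w$lm, w$pr)
  text <- "Gabe von Dupla neben Kontext und Gegenpol heute."
  counts <- vapply(c(-Inf, -1, 0, 1, 5, Inf), function(th)
    nrow(annotate_text(text, w$kb, w$idx, w$lm, w$pr, scorer,
                       threshold = th)$annotations), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("overlapping dictionary matches resolve to non-overlapping output", {
  kb <- new_kb(list(
    mk_entity("Q1", label = "Diabetes mellitus",
              statements = list(st_lit("P2892", "C1"))),
    mk_entity("Q2", label = "Diabetes",
              statements = list(st_lit("P2892", "C2")))))
  idx <- build_index(kb, c("Q1", "Q2"), "de")
  lm <- fit_lm(kb, c("Q1", "Q2"), "de")
  pr <- kb_pagerank(kb)
  docs <- list(annotated_doc("d", "Der Diabetes mellitus ist chronisch.",
                             data.frame(begin = 4L, end = 21L, entity = "Q1",
                                        stringsAsFactors = FALSE)))
  expect_warning(s <- train_scorer(docs, kb, idx, lm, pr), "no negative")
  out <- annotate_text("Der Diabetes mellitus ist chronisch.",
                       kb, idx, lm, pr, s, threshold = -Inf)
  a <- out$annotations
  expect_true(all(a$begin[-1] >= a$end[-nrow(a)]) || nrow(a) <= 1)
})
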