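# Disambiguation: local candidate features, mention-graph construction
# with knowledge-base reachability edge weights, n-step feature propagation
# along the row-stochastic adjacency, and a linear max-margin scorer.

#' Local candidate feature vector
#'
#' The five local features of a (mention, candidate) pair:
#' `(-log p(w), log PR(e), stmd(e), sl(e), 1)` -- the surprisal of the
#' mention surface under the unigram label model, the log PageRank of the
#' candidate, its statement count, its sitelink count, and a constant one.
#'
#' @param surface Mention surface string.
#' @param candidate Candidate entity id (must exist in `kb`).
#' @param kb A `medlinkr_kb`.
#' @param lm A `medlinkr_lm`.
#' @param pr A `medlinkr_pagerank`.
#' @return Numeric vector of length 5.
#' @export
local_features <- function(surface, candidate, kb, lm, pr) {
  e <- kb$entities[[candidate]]
  if (is.null(e)) stop("unknown candidate entity id: ", candidate)
  unname(c(surprisal(lm, surface),
           log_pagerank(pr, candidate),
           n_statements(e),
           n_sitelinks(e),
           1))
}

kb_neighbor_sets <- function(kb, ids) {
  e <- kb$edges
  nb <- lapply(stats::setNames(ids, ids), function(id) {
    unique(c(e$to[e$from == id], e$from[e$to == id]))
  })
  nb
}

#' Build the mention graph
#'
#' One node per (mention, candidate) pair.  Edges connect nodes of
#' distinct mentions at most `window` positions apart in mention order;
#' the weight between nodes a, b with entities ea, eb is
#' `[eb in N1(ea)] + [ea in N1(eb)] + |N1(ea) intersect N1(eb)|` where
#' `N1(e)` is the set of entities adjacent to e (either direction) in the
#' knowledge-base reference graph -- a first-order surrogate for the
#' probability of the two candidates reaching each other or a common third
#' entity.  A uniform self-loop mass `lambda` is added to every node
#' before row normalization, so the stochastic matrix is always defined.
#'
#' @param mentions Mention `data.frame` from [tag_mentions()] (sorted by
#'   span).
#' @param kb A `medlinkr_kb`.
#' @param window Number of neighboring mentions on each side to connect.
#' @param lambda Self-loop mass added before normalization.
#' @return Object of class `medlinkr_mention_graph`: `nodes`
#'   (`data.frame`: `mention`, `entity`), `M` (symmetric weight matrix,
#'   zero diagonal), `stochastic` (row-normalized `M` + `lambda` I).
#' @export
build_mention_graph <- function(mentions, kb, window = 5L, lambda = 1) {
  nodes <- if (nrow(mentions) == 0L) {
    data.frame(mention = integer(), entity = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_len(nrow(mentions)), function(i)
      data.frame(mention = i, entity = mentions$candidates[[i]],
                 stringsAsFactors = FALSE)))
  }
  n <- nrow(nodes)
  M <- matrix(0, n, n)
  if (n > 0L) {
    nb <- kb_neighbor_sets(kb, unique(nodes$entity))
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (b <= a) next
        if (nodes$mention[a] == nodes$mention[b]) next
        if (abs(nodes$mention[a] - nodes$mention[b]) > window) next
        ea <- nodes$entity[a]; eb <- nodes$entity[b]
        w <- (eb %in% nb[[ea]]) + (ea %in% nb[[eb]]) +
          length(intersect(nb[[ea]], nb[[eb]]))
        M[a, b] <- w; M[b, a] <- w
      }
    }
  }
  S <- M + diag(lambda, n)
  S <- S / rowSums(S)
  structure(list(nodes = nodes, M = M, stochastic = S, lambda = lambda,
                 window = as.integer(window)),
            class = "medlinkr_mention_graph")
}

#' Propagate features along the mention graph
#'
#' Computes the contextualized feature tensor `(FM0, FM1, ..., FMn)` with
#' `FMk = S FMk-1`, where `S` is the row-stochastic adjacency of the
#' mention graph.  Each propagated entry is a convex combination of the
#' corresponding input column, so entries stay within the column extrema
#' of `FM0`.
#'
#' @param features Matrix `FM0`, one row per mention-graph node.
#' @param graph A `medlinkr_mention_graph` with matching node count.
#' @param n Number of propagation steps (n = 0 returns just `FM0`).
#' @return List of `n + 1` matrices.
#' @export
propagate <- function(features, graph, n = 2L) {
  features <- as.matrix(features)
  if (nrow(features) != nrow(graph$nodes))
    stop("feature row count (", nrow(features),
         ") does not match mention-graph node count (", nrow(graph$nodes), ")")
  out <- vector("list", n + 1L)
  out[[1L]] <- features
  for (k in seq_len(n)) out[[k + 1L]] <- graph$stochastic %*% out[[k]]
  out
}

#' Fit the linear max-margin candidate scorer
#'
#' For every annotated mention in the training corpus whose span is
#' reproduced by the dictionary tagger, the linked entity is a positive
#' example and every other dictionary candidate for the same span a
#' negative.  Features are the flattened rows of the propagated feature
#' tensor, standardized per feature.  The scorer minimizes the L2-penalized
#' squared-hinge loss `0.5 ||w||^2 + C sum max(0, 1 - y f(x))^2` by BFGS
#' from a zero start: the objective is smooth and convex, so training is
#' deterministic and invariant to example order.
#'
#' @param corpus List of `medlinkr_doc` (training documents).
#' @param kb,index,lm,pr Build artifacts from the same build.
#' @param n Propagation steps.
#' @param window Mention-graph neighbor window.
#' @param lambda Mention-graph self-loop mass.
#' @param cost Soft-margin cost C.
#' @param seed Integer seed recorded with the scorer (the fit itself is
#'   deterministic).
#' @return Object of class `medlinkr_scorer`.
#' @export
train_scorer <- function(corpus, kb, index, lm, pr, n = 2L, window = 5L,
                         lambda = 1, cost = 1, seed = 1L) {
  X <- NULL; y <- integer()
  n_pos <- 0L; n_neg <- 0L
  for (doc in corpus) {
    mentions <- tag_mentions(doc$text, index)
    if (nrow(mentions) == 0L) next
    feats <- document_features(mentions, kb, lm, pr, n = n, window = window,
                               lambda = lambda)
    ann <- doc$annotations
    for (i in seq_len(nrow(ann))) {
      mi <- which(mentions$begin == ann$begin[i] & mentions$end == ann$end[i])
      if (length(mi) == 0L) next
      mi <- mi[1L]
      rows <- which(feats$nodes$mention == mi)
      for (r in rows) {
        lab <- if (feats$nodes$entity[r] == ann$entity[i]) 1L else -1L
        if (lab == 1L) n_pos <- n_pos + 1L else n_neg <- n_neg + 1L
        X <- rbind(X, feats$X[r, ])
        y <- c(y, lab)
      }
    }
  }
  if (is.null(X) || n_pos == 0L)
    stop("no positive training examples: corpus spans are not reproduced by the index")
  if (n_neg == 0L)
    warning("no negative examples (no ambiguity in corpus); ",
            "scorer degenerates to prior-like scoring", call. = FALSE)
  center <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd)
  scale_[!is.finite(scale_) | scale_ < 1e-12] <- 1
  Z <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  d <- ncol(Z)
  obj <- function(theta) {
    w <- theta[1:d]; b <- theta[d + 1L]
    f <- drop(Z %*% w) + b
    slack <- pmax(0, 1 - y * f)
    0.5 * sum(w^2) + cost * sum(slack^2)
  }
  grad <- function(theta) {
    w <- theta[1:d]; b <- theta[d + 1L]
    f <- drop(Z %*% w) + b
    slack <- pmax(0, 1 - y * f)
    coef <- -2 * cost * y * slack
    c(w + drop(crossprod(Z, coef)), sum(coef))
  }
  fit <- stats::optim(rep(0, d + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(list(weights = fit$par[1:d], bias = fit$par[d + 1L],
                 center = center, scale = scale_,
                 n = as.integer(n), window = as.integer(window),
                 lambda = lambda, cost = cost, seed = as.integer(seed),
                 n_pos = n_pos, n_neg = n_neg),
            class = "medlinkr_scorer")
}

#' Score mention-graph node features
#'
#' Affine score of the standardized flattened tensor rows.
#'
#' @param scorer A `medlinkr_scorer`.
#' @param X Matrix of flattened node features (one row per node).
#' @return Numeric score vector.
#' @export
score_nodes <- function(scorer, X) {
  if (ncol(X) != length(scorer$weights))
    stop("feature dimension mismatch: scorer expects ", length(scorer$weights))
  Z <- sweep(sweep(X, 2L, scorer$center), 2L, scorer$scale, "/")
  drop(Z %*% scorer$weights) + scorer$bias
}

# Per-document pipeline shared by training and annotation.
document_features <- function(mentions, kb, lm, pr, n, window, lambda) {
  graph <- build_mention_graph(mentions, kb, window = window, lambda = lambda)
  if (nrow(graph$nodes) == 0L)
    return(list(nodes = graph$nodes, X = matrix(numeric(), 0L, 5L * (n + 1L))))
  F0 <- t(vapply(seq_len(nrow(graph$nodes)), function(i)
    local_features(mentions$surface[graph$nodes$mention[i]],
                   graph$nodes$entity[i], kb, lm, pr), numeric(5)))
  tensor <- propagate(F0, graph, n = n)
  list(nodes = graph$nodes, X = do.call(cbind, tensor))
}

#' Annotate a text with entity links
#'
#' Full runtime pipeline: dictionary tagging, local features, mention
#' graph, propagation, scoring.  Per mention the best-scoring candidate is
#' kept if its score reaches `threshold`, otherwise the mention is dropped
#' (NIL).  Overlapping surviving mentions are resolved greedily by score,
#' then span length, then leftmost position; the output spans are
#' non-overlapping and sorted.
#'
#' @param text Document text.
#' @param kb,index,lm,pr,scorer Build artifacts from the same build.
#' @param threshold NIL threshold (default 0, the decision boundary; use
#'   `-Inf` to keep every argmax candidate).
#' @param doc_id Identifier for the returned document.
#' @return A `medlinkr_doc` whose annotations carry `entity`, `surface`
#'   and `score`.
#' @export
annotate_text <- function(text, kb, index, lm, pr, scorer, threshold = 0,
                          doc_id = "doc") {
  mentions <- tag_mentions(text, index)
  if (nrow(mentions) == 0L) return(annotated_doc(doc_id, text))
  feats <- document_features(mentions, kb, lm, pr, n = scorer$n,
                             window = scorer$window, lambda = scorer$lambda)
  scores <- score_nodes(scorer, feats$X)
  picks <- lapply(seq_len(nrow(mentions)), function(mi) {
    rows <- which(feats$nodes$mention == mi)
    # argmax candidate; ties broken by lexicographically smallest entity id
    ord <- rows[order(-scores[rows], feats$nodes$entity[rows])]
    best <- ord[1L]
    if (scores[best] < threshold) return(NULL)
    data.frame(begin = mentions$begin[mi], end = mentions$end[mi],
               surface = mentions$surface[mi],
               entity = feats$nodes$entity[best],
               score = scores[best], stringsAsFactors = FALSE)
  })
  picks <- do.call(rbind, picks)
  if (is.null(picks) || nrow(picks) == 0L) return(annotated_doc(doc_id, text))
  ord <- order(-picks$score, -(picks$end - picks$begin), picks$begin)
  chosen <- picks[0, ]
  for (i in ord) {
    row <- picks[i, ]
    if (nrow(chosen) == 0L ||
        all(row$end <= chosen$begin | row$begin >= chosen$end))
      chosen <- rbind(chosen, row)
  }
  annotated_doc(doc_id, text, chosen)
}
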