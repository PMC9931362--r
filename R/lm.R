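# Unigram language model over the labels and aliases of the selected
# entities, used for the surprisal term -log p(w) of the local feature
# vector.  Token probabilities use additive smoothing; the probability of
# a multi-token mention is the product of its token probabilities
# (unigram independence).

lm_tokenize <- function(x) {
  toks <- regmatches(x, gregexpr("(*UCP)\\w+", x, perl = TRUE))
  tolower(unlist(toks, use.names = FALSE))
}

#' Fit the unigram language model
#'
#' Token counts are accumulated over the labels and aliases (in the build
#' language) of the selected entities; tokens are lowercased.  With
#' pseudo-count `smoothing` = a, vocabulary size V and total mass N, a
#' seen token has probability (count + a) / (N + a (V + 1)) and an unseen
#' token a / (N + a (V + 1)), so unseen tokens keep positive probability
#' whenever a > 0.
#'
#' @param kb A `medlinkr_kb`.
#' @param selected Character vector of selected entity ids.
#' @param language Language code.
#' @param smoothing Additive pseudo-count (default 1).
#' @return Object of class `medlinkr_lm`.
#' @export
fit_lm <- function(kb, selected, language = "de", smoothing = 1) {
  surfaces <- unlist(lapply(intersect(selected, names(kb$entities)),
                            function(id) {
    e <- kb$entities[[id]]
    c(unname(e$labels[language]), unlist(e$aliases[language], use.names = FALSE))
  }), use.names = FALSE)
  surfaces <- surfaces[!is.na(surfaces) & nzchar(surfaces)]
  toks <- lm_tokenize(surfaces)
  if (length(toks) == 0L) stop("no label tokens available for language ", language)
  counts <- table(toks)
  structure(list(counts = stats::setNames(as.numeric(counts), names(counts)),
                 total = length(toks),
                 vocab_size = length(counts),
                 smoothing = smoothing,
                 language = language),
            class = "medlinkr_lm")
}

#' Token and mention probabilities under the unigram model
#'
#' `lm_token_prob` returns smoothed per-token probabilities;
#' `mention_prob` the product over the mention's tokens; `surprisal` the
#' negative log of that product.
#'
#' @param lm A `medlinkr_lm`.
#' @param tokens Character vector of tokens (lowercased internally).
#' @return Numeric vector of probabilities in (0, 1].
#' @export
lm_token_prob <- function(lm, tokens) {
  cnt <- lm$counts[tolower(tokens)]
  cnt[is.na(cnt)] <- 0
  denom <- lm$total + lm$smoothing * (lm$vocab_size + 1)
  unname((cnt + lm$smoothing) / denom)
}

#' @rdname lm_token_prob
#' @param mention Mention surface string.
#' @export
mention_prob <- function(lm, mention) {
  toks <- lm_tokenize(mention)
  if (length(toks) == 0L) return(lm_token_prob(lm, "")[1])
  prod(lm_token_prob(lm, toks))
}

#' @rdname lm_token_prob
#' @export
surprisal <- function(lm, mention) -log(mention_prob(lm, mention))
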