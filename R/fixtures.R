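# Deterministic generator of synthetic knowledge dumps, wiki pages and
# annotated corpora with known ground truth.  Every module and the
# end-to-end pipeline are testable on its output without downloads.
#
# The generated world: a medication-rooted subclass hierarchy plus
# directly coded entities (UMLS CUI / Disease Ontology / MeSH statement
# properties), ambiguous alias pairs whose members are distinguishable
# only through planted context entities (shared knowledge-base
# neighbors mentioned in the same sentence), redirect pages, and
# section-anchored sitelinks.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 127 + stage * 9973) %% 2147483629 + 1)
}

#' Specify a synthetic fixture
#'
#' Declares the shape of the generated world.  Defaults are the package's
#' standard study conditions (see the methods vignette for the rationale).
#'
#' @param seed Integer master seed; all randomness flows from it through
#'   per-stage derived seeds, so sub-generators are independent of call
#'   order.
#' @param n_entities Total entity count.
#' @param n_medical Entities carrying selection features (root + subclass
#'   tree + coded entities + ambiguous pair members + context hubs).
#' @param subclass_depth,subclass_branching Shape of the medication-rooted
#'   subclass hierarchy.
#' @param n_aliases Aliases per entity.
#' @param ambiguity_rate Fraction of alias slots occupied by surfaces
#'   shared by two entities.
#' @param n_pages Content wiki pages.
#' @param links_per_page Planted pagelinks (sentences) per page.
#' @param sentence_length_range Filler tokens per sentence, `c(min, max)`.
#' @return Object of class `medlinkr_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_entities = 400L, n_medical = 200L,
                         subclass_depth = 3L, subclass_branching = 3L,
                         n_aliases = 2L, ambiguity_rate = 0.15,
                         n_pages = 160L, links_per_page = 4L,
                         sentence_length_range = c(5L, 12L)) {
  spec <- list(seed = as.integer(seed), n_entities = as.integer(n_entities),
               n_medical = as.integer(n_medical),
               subclass_depth = as.integer(subclass_depth),
               subclass_branching = as.integer(subclass_branching),
               n_aliases = as.integer(n_aliases),
               ambiguity_rate = ambiguity_rate,
               n_pages = as.integer(n_pages),
               links_per_page = as.integer(links_per_page),
               sentence_length_range = as.integer(sentence_length_range))
  if (any(unlist(spec[c("n_entities", "n_medical", "subclass_depth",
                        "subclass_branching", "n_aliases", "n_pages",
                        "links_per_page")]) <= 0L))
    stop("all fixture counts must be positive")
  if (ambiguity_rate < 0 || ambiguity_rate > 1)
    stop("ambiguity_rate must lie in [0, 1]")
  n_tree <- sum(spec$subclass_branching^seq_len(spec$subclass_depth))
  n_pairs <- floor(ambiguity_rate * spec$n_entities * spec$n_aliases / 2)
  n_hubs <- if (n_pairs > 0L) 12L else 0L
  if (n_pairs > 0L && spec$n_entities < 4L)
    stop("infeasible spec: ambiguity requires at least 4 entities")
  if (1L + n_tree + 2L * n_pairs + n_hubs > spec$n_medical)
    stop("infeasible spec: n_medical too small for tree (", n_tree,
         "), ambiguous pairs (", 2L * n_pairs, ") and context hubs (",
         n_hubs, ")")
  if (spec$n_medical > spec$n_entities)
    stop("infeasible spec: n_medical exceeds n_entities")
  if (n_pairs > 0L && spec$n_pages < 2L * n_pairs + n_hubs)
    stop("infeasible spec: n_pages must cover ambiguous pair members and ",
         "context hubs (need >= ", 2L * n_pairs + n_hubs, ")")
  spec$n_tree <- n_tree
  spec$n_pairs <- as.integer(n_pairs)
  spec$n_hubs <- n_hubs
  structure(spec, class = "medlinkr_fixture_spec")
}

FILLER_SYLLABLES <- c("la", "re", "mi", "to", "sa", "ne", "vu", "ki", "do", "fa")
TERM_SYLLABLES <- c("zol", "cort", "vex", "tra", "dex", "phen", "mab",
                    "gluc", "pram", "stat", "zin", "ryl", "bex", "lor", "tid")

make_words <- function(n, syllables, min_s = 2L, max_s = 3L,
                       capitalize = FALSE) {
  pool <- character()
  tries <- 0L
  while (length(pool) < n && tries < 60L) {
    k <- sample(min_s:max_s, n, replace = TRUE)
    w <- vapply(k, function(m)
      paste(sample(syllables, m, replace = TRUE), collapse = ""), character(1))
    pool <- unique(c(pool, w))
    tries <- tries + 1L
  }
  if (length(pool) < n)
    pool <- c(pool, paste0(pool[1], seq_len(n - length(pool))))
  out <- pool[seq_len(n)]
  if (capitalize)
    out <- paste0(toupper(substring(out, 1L, 1L)), substring(out, 2L))
  out
}

#' Generate a synthetic fixture
#'
#' Writes a knowledge dump (one JSON record per line, in the dump dialect
#' read by [parse_dump()]) and a pages file (the dialect of
#' [read_pages()]), and returns the ground truth.  The same seed yields
#' byte-identical files.  Ambiguous aliases are planted together with
#' context entities (knowledge-base neighbors of the intended entity,
#' mentioned in the same sentence) so the intended link is recoverable by
#' the local-features-plus-propagation model.
#'
#' @param spec A `medlinkr_fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return List with `spec`, `dump_path`, `pages_path` and `truth`
#'   (`selected_ids`, `page_entity_map`, `planted_links`,
#'   `intended_disambiguation`, `counts`).
#' @export
generate_fixture <- function(spec, dir = tempfile("medlinkr_fixture_")) {
  stopifnot(inherits(spec, "medlinkr_fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  # ---- entity roles -------------------------------------------------------
  n_tree <- spec$n_tree; n_pairs <- spec$n_pairs; n_hubs <- spec$n_hubs
  n_members <- 2L * n_pairs
  n_anchor <- if (spec$n_medical - (1L + n_tree + n_members + n_hubs) >= 2L)
    2L else 0L
  n_extra_med <- spec$n_medical - 1L - n_tree - n_members - n_hubs - n_anchor
  n_plain <- spec$n_entities - spec$n_medical

  ids <- c("Q12140", sprintf("Q%05d", 20000L + seq_len(spec$n_entities - 1L)))
  root_id <- ids[1]
  idx <- 2L
  take <- function(k) {
    if (k == 0L) return(character())
    out <- ids[idx:(idx + k - 1L)]
    idx <<- idx + k
    out
  }
  tree_ids <- take(n_tree)
  member_ids <- take(n_members)
  hub_ids <- take(n_hubs)
  anchor_ids <- take(n_anchor)
  extra_med_ids <- take(n_extra_med)
  plain_ids <- take(n_plain)

  # ---- vocabulary ---------------------------------------------------------
  n_terms_needed <- spec$n_entities * (1L + spec$n_aliases) + n_pairs + 64L
  terms <- with_seed(stage_seed(spec$seed, 1L), {
    t <- make_words(n_terms_needed, TERM_SYLLABLES, capitalize = TRUE)
    f <- make_words(160L, FILLER_SYLLABLES, min_s = 2L, max_s = 4L)
    f <- setdiff(f, tolower(t))
    list(terms = t, fillers = f)
  })
  fillers <- terms$fillers
  term_pool <- terms$terms
  tidx <- 0L
  next_terms <- function(k) {
    if (k == 0L) return(character())
    out <- term_pool[(tidx + 1L):(tidx + k)]
    tidx <<- tidx + k
    out
  }

  all_ids <- c(root_id, tree_ids, member_ids, hub_ids, anchor_ids,
               extra_med_ids, plain_ids)
  labels <- stats::setNames(c("Medikament", next_terms(length(all_ids) - 1L)),
                            all_ids)
  aliases <- with_seed(stage_seed(spec$seed, 2L), {
    al <- lapply(all_ids, function(id) next_terms(spec$n_aliases))
    names(al) <- all_ids
    al
  })
  shared_surfaces <- next_terms(n_pairs)
  pairs <- if (n_pairs > 0L)
    data.frame(a = member_ids[seq_len(n_pairs) * 2L - 1L],
               b = member_ids[seq_len(n_pairs) * 2L],
               surface = shared_surfaces, stringsAsFactors = FALSE)
  else data.frame(a = character(), b = character(), surface = character())
  for (i in seq_len(n_pairs)) {
    aliases[[pairs$a[i]]][1L] <- pairs$surface[i]
    aliases[[pairs$b[i]]][1L] <- pairs$surface[i]
  }

  # ---- statements and sitelinks ------------------------------------------
  statements <- stats::setNames(vector("list", length(all_ids)), all_ids)
  sitelinks <- stats::setNames(vector("list", length(all_ids)), all_ids)
  add_st <- function(id, property, value, is_entity = FALSE) {
    statements[[id]][[length(statements[[id]]) + 1L]] <<-
      list(property = property, value = value, is_entity = is_entity)
  }
  add_st(root_id, "P2892", "C0013227")
  # subclass tree: node i's parent is the root for the first level, else an
  # earlier tree node, giving chains of length up to subclass_depth
  parents <- character(n_tree)
  level_of <- integer(n_tree)
  li <- 0L
  for (d in seq_len(spec$subclass_depth)) {
    for (b in seq_len(spec$subclass_branching^d)) {
      li <- li + 1L
      if (li > n_tree) break
      if (d == 1L) {
        parents[li] <- root_id
      } else {
        prev_level <- which(level_of == d - 1L)
        parents[li] <- tree_ids[prev_level[(b - 1L) %% length(prev_level) + 1L]]
      }
      level_of[li] <- d
    }
  }
  for (i in seq_len(n_tree)) add_st(tree_ids[i], "P279", parents[i], TRUE)

  hub_assign <- with_seed(stage_seed(spec$seed, 3L), {
    lapply(seq_len(n_pairs), function(i) {
      hs <- sample(hub_ids, 4L)
      list(a = hs[1:2], b = hs[3:4])
    })
  })
  coded_props <- c("P699", "P2892", "P486", "P672")
  with_seed(stage_seed(spec$seed, 4L), {
    for (i in seq_len(n_pairs)) {
      for (side in c("a", "b")) {
        id <- pairs[[side]][i]
        add_st(id, "P2892", sprintf("C%07d", sample.int(9999999L, 1L)))
        for (h in hub_assign[[i]][[side]]) add_st(id, "P2175", h, TRUE)
      }
    }
    for (id in hub_ids) {
      add_st(id, "P699", sprintf("DOID:%d", sample.int(99999L, 1L)))
      for (k in seq_len(11L))
        add_st(id, "P2176", sprintf("lit%d", sample.int(999L, 1L)))
    }
    for (id in c(anchor_ids, extra_med_ids)) {
      p <- sample(coded_props, 1L)
      v <- switch(p, P699 = sprintf("DOID:%d", sample.int(99999L, 1L)),
                  P2892 = sprintf("C%07d", sample.int(9999999L, 1L)),
                  P486 = sprintf("D%06d", sample.int(999999L, 1L)),
                  P672 = sprintf("C%02d.%03d", sample.int(26L, 1L),
                                 sample.int(999L, 1L)))
      add_st(id, p, v)
    }
    for (id in plain_ids) {
      if (stats::runif(1) < 0.6)
        add_st(id, "P31", sample(plain_ids, 1L), TRUE)
    }
  })

  # ---- pages --------------------------------------------------------------
  page_pool <- c(member_ids, hub_ids, tree_ids, extra_med_ids)
  n_unsel_pages <- min(5L, n_plain)
  page_entities <- c(page_pool[seq_len(min(spec$n_pages, length(page_pool)))],
                     plain_ids[seq_len(n_unsel_pages)])
  for (id in page_entities) sitelinks[[id]][["dewiki"]] <- labels[[id]]
  for (id in hub_ids) {
    sitelinks[[id]][["enwiki"]] <- labels[[id]]
    sitelinks[[id]][["frwiki"]] <- labels[[id]]
  }
  for (id in member_ids)
    if (is.null(sitelinks[[id]][["dewiki"]]))
      sitelinks[[id]][["dewiki"]] <- labels[[id]]
  if (n_anchor > 0L && length(page_entities) > 0L)
    for (i in seq_len(n_anchor))
      sitelinks[[anchor_ids[i]]][["dewiki"]] <-
        paste0(labels[[page_entities[1]]], "#Abschnitt", i)

  content_ids <- intersect(page_entities,
                           names(Filter(function(s) !is.null(s[["dewiki"]]) &&
                                          !grepl("#", s[["dewiki"]]),
                                        sitelinks)))
  content_titles <- unname(labels[content_ids])
  selected_truth <- sort(c(root_id, tree_ids, member_ids, hub_ids,
                           anchor_ids, extra_med_ids))

  redirect_map <- with_seed(stage_seed(spec$seed, 5L), {
    # redirect pages: alias title -> canonical page, for a fifth of pages
    cand <- content_ids[!content_ids %in% c(pairs$a, pairs$b)]
    cand <- cand[seq_len(min(length(cand), ceiling(length(content_ids) / 5)))]
    rm_ <- stats::setNames(unname(labels[cand]),
                           vapply(cand, function(id) aliases[[id]][spec$n_aliases],
                                  character(1)))
    rm_[!names(rm_) %in% content_titles & nzchar(names(rm_))]
  })

  linkable <- setdiff(content_ids, plain_ids[seq_len(n_unsel_pages)])
  amb_prob <- if (n_pairs > 0L) min(0.5, 2 * spec$ambiguity_rate) else 0
  sent_range <- spec$sentence_length_range

  planted <- list()
  pages <- list()
  with_seed(stage_seed(spec$seed, 6L), {
    for (pi in seq_along(content_ids)) {
      title <- content_titles[pi]
      rendered_sents <- character()
      wiki_sents <- character()
      si <- 0L
      for (li2 in seq_len(spec$links_per_page)) {
        si <- si + 1L
        ambiguous <- stats::runif(1) < amb_prob
        n_fill <- sample(sent_range[1]:sent_range[2], 1L)
        fill <- sample(fillers, n_fill, replace = TRUE)
        links <- list()   # (surface, target_title, entity, ambiguous, intended)
        if (ambiguous) {
          pr_ <- sample.int(n_pairs, 1L)
          side <- sample(c("a", "b"), 1L)
          intended <- pairs[[side]][pr_]
          ctx <- hub_assign[[pr_]][[side]]
          links[[1]] <- list(surface = pairs$surface[pr_],
                             target = unname(labels[intended]),
                             entity = intended, ambiguous = TRUE)
          for (h in ctx)
            links[[length(links) + 1L]] <-
              list(surface = unname(labels[h]), target = unname(labels[h]),
                   entity = h, ambiguous = FALSE)
        } else {
          ent <- sample(linkable, 1L)
          target <- unname(labels[ent])
          via_redirect <- FALSE
          hit <- names(redirect_map)[redirect_map == target]
          if (length(hit) && stats::runif(1) < 0.5) {
            target <- hit[1]
            via_redirect <- TRUE
          }
          links[[1]] <- list(surface = unname(labels[ent]), target = target,
                             entity = ent, ambiguous = FALSE,
                             via_redirect = via_redirect)
        }
        # occasionally link an unselected page: the link must be dropped
        if (n_unsel_pages > 0L && !ambiguous && stats::runif(1) < 0.25) {
          ent <- plain_ids[sample.int(n_unsel_pages, 1L)]
          links[[length(links) + 1L]] <-
            list(surface = unname(labels[ent]), target = unname(labels[ent]),
                 entity = ent, ambiguous = FALSE)
        }
        # assemble the sentence: link i goes after slots[i] filler tokens
        slots <- sort(sample.int(n_fill + 1L, length(links))) - 1L
        tokens <- list()
        fill_i <- 0L
        link_i <- 0L
        while (fill_i < n_fill || link_i < length(links)) {
          if (link_i < length(links) &&
              (slots[link_i + 1L] <= fill_i || fill_i == n_fill)) {
            link_i <- link_i + 1L
            tokens[[length(tokens) + 1L]] <- links[[link_i]]
          } else {
            fill_i <- fill_i + 1L
            tokens[[length(tokens) + 1L]] <- list(filler = fill[fill_i])
          }
        }
        pos <- 0L
        rendered_parts <- character(); wiki_parts <- character()
        for (ti in seq_along(tokens)) {
          tk <- tokens[[ti]]
          if (!is.null(tk$filler)) {
            word <- tk$filler
            if (ti == 1L)
              word <- paste0(toupper(substring(word, 1L, 1L)),
                             substring(word, 2L))
            rendered_parts <- c(rendered_parts, word)
            wiki_parts <- c(wiki_parts, word)
            pos <- pos + nchar(word, type = "chars") + 1L
          } else {
            wik <- if (identical(tk$surface, tk$target) &&
                       stats::runif(1) < 0.5)
              paste0("[[", tk$target, "]]")
            else paste0("[[", tk$target, "|", tk$surface, "]]")
            rendered_parts <- c(rendered_parts, tk$surface)
            wiki_parts <- c(wiki_parts, wik)
            planted[[length(planted) + 1L]] <- data.frame(
              page = title, sentence_index = si, begin = pos,
              end = pos + nchar(tk$surface, type = "chars"),
              surface = tk$surface, entity = tk$entity,
              ambiguous = tk$ambiguous,
              selected = tk$entity %in% selected_truth,
              stringsAsFactors = FALSE)
            pos <- pos + nchar(tk$surface, type = "chars") + 1L
          }
        }
        rendered_sents[si] <- paste0(paste(rendered_parts, collapse = " "), ".")
        wiki_sents[si] <- paste0(paste(wiki_parts, collapse = " "), ".")
        # occasionally a filler-only sentence (must be dropped downstream)
        if (stats::runif(1) < 0.3) {
          si <- si + 1L
          extra <- sample(fillers, sample(sent_range[1]:sent_range[2], 1L),
                          replace = TRUE)
          extra[1] <- paste0(toupper(substring(extra[1], 1L, 1L)),
                             substring(extra[1], 2L))
          rendered_sents[si] <- paste0(paste(extra, collapse = " "), ".")
          wiki_sents[si] <- rendered_sents[si]
        }
      }
      pages[[length(pages) + 1L]] <-
        new_page(title, paste(wiki_sents, collapse = " "))
    }
  })
  for (rt in names(redirect_map))
    pages[[length(pages) + 1L]] <-
      new_page(rt, paste0("#REDIRECT [[", redirect_map[[rt]], "]]"))

  # ---- write dump ---------------------------------------------------------
  records <- vapply(all_ids, function(id) {
    st <- statements[[id]]
    claims <- list()
    for (s in st) {
      v <- if (s$is_entity) list(id = s$value) else s$value
      claims[[s$property]] <- c(claims[[s$property]], list(v))
    }
    sl <- lapply(sitelinks[[id]], function(t) list(title = t))
    rec <- list(id = id, type = "item",
                labels = stats::setNames(
                  list(list(language = "de", value = unname(labels[[id]]))), "de"),
                descriptions = stats::setNames(
                  list(list(language = "de", value = paste("Beschreibung", id))), "de"),
                aliases = stats::setNames(
                  list(lapply(aliases[[id]], function(a)
                    list(language = "de", value = a))), "de"),
                claims = claims,
                sitelinks = sl)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  dump_path <- file.path(dir, "dump.jsonl")
  writeLines(records, dump_path, useBytes = FALSE)
  pages_path <- file.path(dir, "pages.txt")
  write_pages(pages, pages_path)

  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(page = character(), sentence_index = integer(),
               begin = integer(), end = integer(), surface = character(),
               entity = character(), ambiguous = logical(),
               selected = logical(), stringsAsFactors = FALSE)
  n_edges <- sum(vapply(statements, function(st)
    sum(vapply(st, function(s) isTRUE(s$is_entity), logical(1))), integer(1)))
  truth <- list(
    selected_ids = selected_truth,
    page_entity_map = stats::setNames(content_ids, content_titles),
    planted_links = planted,
    intended_disambiguation = planted[planted$ambiguous, , drop = FALSE],
    ambiguous_pairs = pairs,
    counts = list(
      entities = length(all_ids),
      edges = n_edges,
      statements = sum(vapply(statements, length, integer(1))),
      sitelinks = sum(vapply(sitelinks, length, integer(1))),
      pages = length(pages),
      redirects = length(redirect_map),
      planted_links = nrow(planted),
      ambiguous_links = sum(planted$ambiguous),
      kept_links = sum(planted$selected)))
  list(spec = spec, dir = dir, dump_path = dump_path,
       pages_path = pages_path, truth = truth)
}

#' Build train/test corpora from a fixture (ambiguity benchmark)
#'
#' Generates a fixture, runs the full knowledge-base and corpus-synthesis
#' pipeline on it, and splits the resulting weakly annotated corpus by
#' page (never by sentence, to avoid leakage between splits).
#'
#' @param spec A `medlinkr_fixture_spec`; must yield at least 20 ambiguous
#'   planted links.
#' @param train_fraction Fraction of pages assigned to the training split.
#' @param seed Split seed (defaults to a seed derived from the spec seed).
#' @return List with `train`, `test` (lists of `medlinkr_doc`), `truth`,
#'   `kb`, `selected`, `profile`, `train_pages`, `test_pages`.
#' @export
ambiguity_benchmark <- function(spec, train_fraction = 0.8, seed = NULL) {
  fx <- generate_fixture(spec)
  if (fx$truth$counts$ambiguous_links < 20L)
    stop("too few ambiguous links (", fx$truth$counts$ambiguous_links,
         "); enlarge the fixture spec")
  kb <- parse_dump(fx$dump_path)
  profile <- medical_profile()
  selected <- select_entities(kb, profile)
  pages <- read_pages(fx$pages_path)
  corpus <- synthesize_corpus(kb, pages, selected)
  page_of <- vapply(corpus, function(d) sub("#[0-9]+$", "", d$doc_id),
                    character(1))
  all_pages <- sort(unique(page_of))
  if (is.null(seed)) seed <- stage_seed(spec$seed, 7L)
  train_pages <- with_seed(seed, {
    n_train <- ceiling(train_fraction * length(all_pages))
    sort(sample(all_pages, n_train))
  })
  test_pages <- setdiff(all_pages, train_pages)
  list(train = corpus[page_of %in% train_pages],
       test = corpus[page_of %in% test_pages],
       truth = fx$truth, kb = kb, selected = selected, profile = profile,
       train_pages = train_pages, test_pages = test_pages)
}

#' Run the end-to-end disambiguation benchmark
#'
#' Trains the full pipeline on the benchmark's training split and
#' evaluates on the held-out pages: disambiguation accuracy over the
#' ambiguous planted links (predicted entity at the ground-truth span
#' versus the intended entity; missing predictions count as errors) and
#' micro segmentation F1 over the held-out documents containing no
#' ambiguous link.
#'
#' @param spec A `medlinkr_fixture_spec`.
#' @param train_fraction Fraction of pages used for training.
#' @param n Propagation steps.
#' @param window Mention-graph neighbor window.
#' @param threshold NIL threshold used at annotation time.
#' @return List with `accuracy`, `n_ambiguous_test`, `micro_f1_unambiguous`,
#'   `n_unambiguous_docs`, `scorer`, `benchmark`.
#' @export
linking_benchmark_eval <- function(spec, train_fraction = 0.8, n = 2L,
                                   window = 5L, threshold = 0) {
  bm <- ambiguity_benchmark(spec, train_fraction)
  index <- build_index(bm$kb, bm$selected, bm$profile$language)
  lm <- fit_lm(bm$kb, bm$selected, bm$profile$language)
  pr <- kb_pagerank(bm$kb)
  scorer <- train_scorer(bm$train, bm$kb, index, lm, pr, n = n,
                         window = window)
  preds <- lapply(bm$test, function(d)
    annotate_text(d$text, bm$kb, index, lm, pr, scorer,
                  threshold = threshold, doc_id = d$doc_id))
  names(preds) <- vapply(preds, `[[`, character(1), "doc_id")
  tl <- bm$truth$planted_links
  tl$doc_id <- paste0(tl$page, "#", tl$sentence_index)
  amb <- tl[tl$ambiguous & tl$page %in% bm$test_pages, , drop = FALSE]
  correct <- 0L
  for (i in seq_len(nrow(amb))) {
    p <- preds[[amb$doc_id[i]]]
    if (is.null(p)) next
    hit <- p$annotations[p$annotations$begin == amb$begin[i] &
                           p$annotations$end == amb$end[i], , drop = FALSE]
    if (nrow(hit) == 1L && hit$entity == amb$entity[i])
      correct <- correct + 1L
  }
  amb_doc_ids <- unique(tl$doc_id[tl$ambiguous])
  gt_unamb <- Filter(function(d) !d$doc_id %in% amb_doc_ids, bm$test)
  pred_unamb <- preds[vapply(gt_unamb, `[[`, character(1), "doc_id")]
  ev <- if (length(gt_unamb))
    evaluate_corpus(gt_unamb, unname(pred_unamb)) else NULL
  list(accuracy = if (nrow(amb)) correct / nrow(amb) else NA_real_,
       n_ambiguous_test = nrow(amb),
       micro_f1_unambiguous = if (is.null(ev)) NA_real_ else
         unname(ev$micro["f1"]),
       n_unambiguous_docs = length(gt_unamb),
       scorer = scorer, benchmark = bm)
}
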