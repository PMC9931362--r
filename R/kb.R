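#' Construct a knowledge-base entity
#'
#' An entity is one item of the knowledge base: an opaque identifier plus
#' per-language labels, aliases and descriptions, a sequence of statements
#' (property/value pairs, where a value is either a reference to another
#' entity or an opaque literal), and sitelinks pointing to wiki page titles.
#'
#' @param id Non-empty identifier string, e.g. `"Q12140"`.
#' @param labels Named character vector, language code -> preferred label.
#' @param aliases Named list, language code -> character vector of aliases.
#' @param descriptions Named character vector, language code -> short text.
#' @param statements A `data.frame` with columns `property`, `value`,
#'   `is_entity` (logical: does `value` reference another entity id?), or a
#'   list of `list(property=, value=, is_entity=)` triples.
#' @param sitelinks Named character vector, wiki site code -> page title
#'   (titles may carry a `#`-separated section anchor).
#' @return An object of class `medlinkr_entity`.
#' @export
new_entity <- function(id, labels = character(), aliases = list(),
                       descriptions = character(), statements = NULL,
                       sitelinks = character()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("entity id must be a non-empty string")
  if (is.null(statements)) {
    statements <- data.frame(property = character(), value = character(),
                             is_entity = logical(), stringsAsFactors = FALSE)
  } else if (!is.data.frame(statements)) {
    statements <- do.call(rbind, lapply(statements, function(s) {
      data.frame(property = s$property, value = as.character(s$value),
                 is_entity = isTRUE(s$is_entity), stringsAsFactors = FALSE)
    }))
    if (is.null(statements))
      statements <- data.frame(property = character(), value = character(),
                               is_entity = logical(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("property", "value", "is_entity") %in% names(statements)))
  structure(list(id = id,
                 labels = labels,
                 aliases = aliases,
                 descriptions = descriptions,
                 statements = statements,
                 sitelinks = sitelinks),
            class = "medlinkr_entity")
}

#' Number of statements / sitelinks of an entity
#'
#' Plain counts used as local candidate features (`stmd` and `sl`).
#'
#' @param entity A `medlinkr_entity`.
#' @return Non-negative integer.
#' @export
n_statements <- function(entity) nrow(entity$statements)

#' @rdname n_statements
#' @export
n_sitelinks <- function(entity) length(entity$sitelinks)

#' Construct a knowledge base from entities
#'
#' The knowledge base is the entity store plus the directed reference graph:
#' an edge a -> b exists whenever some statement of a has entity value b.
#' Dangling targets (ids without a record) are kept in the edge table --
#' dump subsets are routinely incomplete -- but treated as absent nodes by
#' graph algorithms.
#'
#' @param entities List of `medlinkr_entity` objects.
#' @return An object of class `medlinkr_kb` with fields `entities` (named
#'   list) and `edges` (`data.frame` with `from`, `to`, `property`).
#' @export
new_kb <- function(entities = list()) {
  ids <- vapply(entities, function(e) e$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate entity ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(entities) <- ids
  edges <- derive_edges(entities)
  structure(list(entities = entities, edges = edges), class = "medlinkr_kb")
}

derive_edges <- function(entities) {
  parts <- lapply(entities, function(e) {
    st <- e$statements
    st <- st[st$is_entity, , drop = FALSE]
    if (nrow(st) == 0L) return(NULL)
    data.frame(from = e$id, to = st$value, property = st$property,
               stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L)
    return(data.frame(from = character(), to = character(),
                      property = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' @export
print.medlinkr_kb <- function(x, ...) {
  cat(sprintf("<medlinkr_kb: %d entities, %d reference edges>\n",
              length(x$entities), nrow(x$edges)))
  invisible(x)
}

kb_entity <- function(kb, id) {
  e <- kb$entities[[id]]
  if (is.null(e)) stop("unknown entity id: ", id)
  e
}

#' Parse a line-oriented knowledge dump
#'
#' Reads the WikiData JSON-dump dialect: UTF-8 text with one JSON object per
#' line.  The bracket-and-comma decoration of full dumps (`[` / `]` lines,
#' trailing commas) is tolerated and stripped.  Records must carry `id` and
#' `type`; records whose type is not `"item"` are skipped.  Claim values
#' given as objects with an `id` field are entity references; anything else
#' is stored as an opaque literal.  Malformed lines are skipped and counted;
#' a duplicate id replaces the earlier record with a warning.
#'
#' @param src Path to a dump file, or a character vector of dump lines.
#' @param language Language code recorded with the result (parsing itself is
#'   language-independent).
#' @return A `medlinkr_kb`; attribute `"report"` holds the parse report
#'   (`n_lines`, `n_records`, `n_skipped`, `n_malformed`, `n_duplicates`).
#' @export
parse_dump <- function(src, language = "de") {
  lines <- if (length(src) == 1L && !grepl("\n", src) && file.exists(src))
    readLines(src, encoding = "UTF-8", warn = FALSE) else src
  entities <- list()
  n_malformed <- 0L; n_skipped <- 0L; n_dup <- 0L; n_records <- 0L
  for (line in lines) {
    line <- trimws(line)
    if (line %in% c("", "[", "]")) next
    line <- sub(",$", "", line)
    rec <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$id) || !nzchar(rec$id %||% "")) {
      n_malformed <- n_malformed + 1L
      next
    }
    if (!identical(rec$type %||% "item", "item")) {
      n_skipped <- n_skipped + 1L
      next
    }
    ent <- entity_from_record(rec)
    if (!is.null(entities[[ent$id]])) {
      n_dup <- n_dup + 1L
      warning("duplicate entity id in dump (last record wins): ", ent$id,
              call. = FALSE)
    }
    entities[[ent$id]] <- ent
    n_records <- n_records + 1L
  }
  kb <- new_kb(unname(entities))
  attr(kb, "report") <- list(n_lines = length(lines), n_records = n_records,
                             n_skipped = n_skipped, n_malformed = n_malformed,
                             n_duplicates = n_dup, language = language)
  kb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

value_of <- function(x) {
  if (is.list(x) && !is.null(x$value)) as.character(x$value) else as.character(x)
}

entity_from_record <- function(rec) {
  labels <- vapply(rec$labels %||% list(), value_of, character(1))
  descriptions <- vapply(rec$descriptions %||% list(), value_of, character(1))
  aliases <- lapply(rec$aliases %||% list(), function(v)
    vapply(v, value_of, character(1)))
  props <- character(); vals <- character(); is_ent <- logical()
  for (p in names(rec$claims %||% list())) {
    for (snak in rec$claims[[p]]) {
      if (is.list(snak) && !is.null(snak$id)) {
        props <- c(props, p); vals <- c(vals, as.character(snak$id))
        is_ent <- c(is_ent, TRUE)
      } else {
        lit <- if (is.list(snak))
          as.character(jsonlite::toJSON(snak, auto_unbox = TRUE))
        else as.character(snak)
        props <- c(props, p); vals <- c(vals, lit); is_ent <- c(is_ent, FALSE)
      }
    }
  }
  sitelinks <- vapply(rec$sitelinks %||% list(), function(x)
    if (is.list(x)) as.character(x$title) else as.character(x), character(1))
  new_entity(rec$id, labels = labels, aliases = aliases,
             descriptions = descriptions,
             statements = data.frame(property = props, value = vals,
                                     is_entity = is_ent,
                                     stringsAsFactors = FALSE),
             sitelinks = sitelinks)
}

#' n-degree subclass/instance closure
#'
#' Returns every entity connected to `root` by a chain of statements whose
#' properties lie in `relations` (chains of any length, e.g. an opioid that
#' is a subclass of an analgesic that is a subclass of the medication root).
#' The root itself is excluded unless it reaches itself through a cycle.
#' Terminates on cyclic graphs; the result is independent of traversal
#' order.  An unknown root yields the empty set.
#'
#' @param kb A `medlinkr_kb`.
#' @param root Root entity id.
#' @param relations Character vector of property ids to traverse
#'   (default: subclass-of `P279` and instance-of `P31`).
#' @return Character vector of entity ids (sorted).
#' @export
subclass_closure <- function(kb, root, relations = c("P279", "P31")) {
  e <- kb$edges
  e <- e[e$property %in% relations, , drop = FALSE]
  if (nrow(e) == 0L) return(character())
  # reverse adjacency: for target t, which sources point at t?
  rev_adj <- split(e$from, e$to)
  visited <- character()
  frontier <- root
  root_in <- FALSE
  while (length(frontier)) {
    preds <- unique(unlist(rev_adj[frontier], use.names = FALSE))
    if (is.null(preds)) break
    if (root %in% preds) root_in <- TRUE
    new <- setdiff(preds, c(visited, root))
    visited <- c(visited, new)
    frontier <- new
  }
  out <- visited
  if (root_in) out <- union(out, root)
  sort(out)
}

#' Create an entity-selection profile
#'
#' A profile declares which entities belong to the indexed knowledge-base
#' subset: entities carrying at least one statement with a listed property
#' (e.g. a UMLS CUI `P2892`, Disease Ontology `P699`, MeSH descriptor
#' `P486`, MeSH tree code `P672`), united with the subclass/instance
#' closures of the listed roots.
#'
#' @param language Wiki language code used downstream for labels, aliases
#'   and sitelinks.
#' @param statement_properties Character vector of property ids.
#' @param closure_roots List of `list(root = <entity-id>,
#'   relations = <character vector of property ids>)`.
#' @return An object of class `medlinkr_profile`.
#' @export
new_profile <- function(language = "de",
                        statement_properties = character(),
                        closure_roots = list()) {
  if (length(statement_properties) == 0L && length(closure_roots) == 0L)
    stop("profile must declare at least one selection rule")
  if (any(!nzchar(statement_properties)))
    stop("empty property id in statement_properties")
  closure_roots <- lapply(closure_roots, function(r) {
    stopifnot(is.character(r$root), nzchar(r$root))
    list(root = r$root,
         relations = as.character(r$relations %||% c("P279", "P31")))
  })
  structure(list(language = language,
                 statement_properties = as.character(statement_properties),
                 closure_roots = closure_roots),
            class = "medlinkr_profile")
}

#' Default medical selection profile
#'
#' Selects entities with Disease Ontology (P699), UMLS CUI (P2892), MeSH
#' descriptor (P486) or MeSH tree code (P672) statements, plus the full
#' subclass closure of the medication item Q12140 via subclass-of (P279).
#' Instance-of (P31) participation is configurable via `relations`.
#'
#' @param language Wiki language code.
#' @param relations Relations used for the closure root.
#' @return A `medlinkr_profile`.
#' @export
medical_profile <- function(language = "de", relations = "P279") {
  new_profile(language = language,
              statement_properties = c("P699", "P2892", "P486", "P672"),
              closure_roots = list(list(root = "Q12140",
                                        relations = relations)))
}

#' Read / write a profile config file
#'
#' Profiles are stored as human-editable YAML with keys `language`,
#' `statement_properties` and `closure_roots` (a list of `root` /
#' `relations` entries).
#'
#' @param path File path.
#' @return `read_profile` returns a `medlinkr_profile`.
#' @export
read_profile <- function(path) {
  y <- yaml::read_yaml(path)
  new_profile(language = y$language %||% "de",
              statement_properties = as.character(y$statement_properties %||% character()),
              closure_roots = y$closure_roots %||% list())
}

#' @rdname read_profile
#' @param profile A `medlinkr_profile`.
#' @export
write_profile <- function(profile, path) {
  yaml::write_yaml(list(language = profile$language,
                        statement_properties = profile$statement_properties,
                        closure_roots = profile$closure_roots), path)
  invisible(path)
}

rule_matches <- function(kb, profile) {
  rules <- list()
  for (p in profile$statement_properties) {
    hit <- vapply(kb$entities, function(e) p %in% e$statements$property,
                  logical(1))
    rules[[paste0("statement:", p)]] <- names(kb$entities)[hit]
  }
  for (r in profile$closure_roots) {
    rules[[paste0("closure:", r$root, "[", paste(r$relations, collapse = ","), "]")]] <-
      intersect(subclass_closure(kb, r$root, r$relations), names(kb$entities))
  }
  rules
}

#' Select entities according to a profile
#'
#' Union of all rule matches: entities with at least one statement whose
#' property is listed, and entities in the subclass/instance closure of any
#' listed root.  Deterministic; monotone in the rule set.
#'
#' @param kb A `medlinkr_kb`.
#' @param profile A `medlinkr_profile`.
#' @return Sorted character vector of selected entity ids.
#' @export
select_entities <- function(kb, profile) {
  sort(unique(unlist(rule_matches(kb, profile), use.names = FALSE)))
}

#' Per-rule selection statistics
#'
#' Reports, for each profile rule in declaration order, the number of
#' entities it matches and its marginal gain over the union of the
#' preceding rules, plus the total selected count.
#'
#' @inheritParams select_entities
#' @return List with `rules` (`data.frame`: `rule`, `count`, `gain`) and
#'   `total`.
#' @export
selection_stats <- function(kb, profile) {
  rules <- rule_matches(kb, profile)
  seen <- character()
  rows <- lapply(names(rules), function(nm) {
    ids <- rules[[nm]]
    gain <- length(setdiff(ids, seen))
    seen <<- union(seen, ids)
    data.frame(rule = nm, count = length(ids), gain = gain,
               stringsAsFactors = FALSE)
  })
  list(rules = do.call(rbind, rows), total = length(seen))
}

#' PageRank over the knowledge-base reference graph
#'
#' Power iteration with uniform teleportation.  The graph is restricted to
#' non-dangling nodes (edges to absent entity records are dropped); parallel
#' edges are collapsed.  Mass of nodes without out-edges is redistributed
#' uniformly each step, so the scores always sum to one.
#'
#' @param kb A `medlinkr_kb` with at least one entity.
#' @param damping Damping factor in (0,1); default 0.85.
#' @param iterations Number of power-iteration steps; default 50.
#' @param tol Early-exit threshold on the L1 change per step.
#' @return Object of class `medlinkr_pagerank`: `scores` (named numeric
#'   summing to 1), `damping`, `iterations`.
#' @export
kb_pagerank <- function(kb, damping = 0.85, iterations = 50L, tol = 0) {
  ids <- names(kb$entities)
  n <- length(ids)
  if (n == 0L) stop("empty knowledge base: no graph to rank")
  stopifnot(damping > 0, damping < 1)
  e <- kb$edges[kb$edges$from %in% ids & kb$edges$to %in% ids, , drop = FALSE]
  e <- unique(e[, c("from", "to")])
  v <- rep(1 / n, n)
  if (nrow(e) > 0L) {
    A <- Matrix::sparseMatrix(i = match(e$from, ids), j = match(e$to, ids),
                              x = 1, dims = c(n, n))
    outdeg <- Matrix::rowSums(A)
    P <- Matrix::Diagonal(x = ifelse(outdeg > 0, 1 / outdeg, 0)) %*% A
    dangling <- outdeg == 0
    for (k in seq_len(iterations)) {
      v_new <- (1 - damping) / n +
        damping * (as.numeric(Matrix::crossprod(P, v)) + sum(v[dangling]) / n)
      delta <- sum(abs(v_new - v))
      v <- v_new
      if (delta < tol) break
    }
  }
  v <- v / sum(v)
  structure(list(scores = stats::setNames(v, ids), damping = damping,
                 iterations = as.integer(iterations)),
            class = "medlinkr_pagerank")
}

#' Log PageRank score with floor
#'
#' Log-domain access for the local feature vector; scores are floored at
#' `floor` so isolated or unknown entities stay finite.
#'
#' @param pr A `medlinkr_pagerank`.
#' @param id Entity id(s).
#' @param floor Lower bound applied before the log.
#' @return Numeric vector of log scores.
#' @export
log_pagerank <- function(pr, id, floor = 1e-12) {
  s <- unname(pr$scores[id])
  s[is.na(s)] <- 0
  log(pmax(s, floor))
}
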