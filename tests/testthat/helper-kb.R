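# Small constructors shared across tests.

mk_entity <- function(id, label = NULL, aliases = character(),
                      statements = list(), sitelinks = character(),
                      lang = "de") {
  lab <- if (is.null(label)) character() else stats::setNames(label, lang)
  al <- if (length(aliases)) stats::setNames(list(aliases), lang) else list()
  new_entity(id, labels = lab, aliases = al, statements = statements,
             sitelinks = sitelinks)
}

st_ent <- function(property, id) list(property = property, value = id,
                                      is_entity = TRUE)
st_lit <- function(property, v) list(property = property, value = v,
                                     is_entity = FALSE)

# A fixture spec small enough for fast unit tests: shallow subclass tree,
# few pages, mild ambiguity.
small_fixture_spec <- function(seed = 5, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_entities = 80L, n_medical = 60L,
         subclass_depth = 2L, subclass_branching = 2L,
         n_pages = 40L, links_per_page = 3L, ambiguity_rate = 0.1),
    list(...))
  do.call(fixture_spec, args)
}

# Random KB over n nodes with edges drawn under `relations`; cycles allowed.
random_kb <- function(n, p_edge = 0.03, relations = c("P279", "P31"),
                      other_relation_rate = 0.2) {
  ids <- sprintf("N%03d", seq_len(n))
  ents <- lapply(ids, function(id) {
    k <- stats::rbinom(1, n, p_edge)
    if (k == 0) return(mk_entity(id, label = id))
    to <- sample(ids, k, replace = TRUE)
    rel <- ifelse(stats::runif(k) < other_relation_rate, "P999",
                  sample(relations, k, replace = TRUE))
    mk_entity(id, label = id,
              statements = Map(st_ent, rel, to))
  })
  new_kb(ents)
}
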