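Package: medlinkr
Title: Dictionary-Based Medical Entity Linking from Collaborative
    Knowledge Bases
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a filtered medical knowledge base from WikiData-style
    JSON dumps, synthesizes weakly annotated training corpora from wiki
    pagelinks (NIF 2.0 Turtle), and performs feature-based entity linking:
    dictionary mention tagging over indexed labels and aliases, local
    features combining unigram-language-model surprisal, PageRank
    centrality, statement and sitelink counts, graph feature propagation
    along a row-stochastic mention-graph adjacency, and a linear
    max-margin scorer.  Includes linguistic post-filtering of annotations,
    character-level binary-segmentation evaluation, a deterministic
    synthetic fixture generator, a command-line interface and a minimal
    HTTP annotation endpoint.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
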