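# medlinkr

Dictionary-based medical entity linking from collaborative knowledge
bases, in R.

Clinical and biomedical research needs structured information that often
exists only as free text — and for non-English languages there are few
tools that work without large annotated corpora or licensed
terminologies. `medlinkr` is a complete, trainable entity-linking (EL)
toolkit built entirely from open, WikiData/Wikipedia-style data: it
filters a knowledge dump down to a medical subset, synthesizes a weakly
annotated training corpus from wiki pagelinks, and links text mentions
to knowledge-base entities with an interpretable feature-based model.
It is aimed at medical-informatics groups who want an annotation service
they can rebuild for their own language and entity scope.

## The model

Entity linking maps spans of a document to entities:
ω\_s = δ\[s\], ε\_s = link(ω\_s), ε\_s ∈ Ω. The pipeline decomposes this
into candidate generation and disambiguation:

1. **Entity selection.** A declarative *profile* picks the linkable
   subset of the knowledge base Ω: entities carrying a Disease Ontology
   (P699), UMLS CUI (P2892), MeSH descriptor (P486) or MeSH tree code
   (P672) statement, united with the full subclass closure (P279, to any
   depth) of the medication item Q12140.
2. **Candidate generation.** Labels and aliases of the selected entities
   are indexed; every token-boundary-aligned occurrence of an indexed
   surface becomes a mention with all matching entities as candidates.
3. **Local features.** Each (mention ω, candidate ε) pair gets
   F(ω, ε) = (−log p(ω), log PR(ε), stmd(ε), sl(ε), 1): surprisal under
   a smoothed unigram model over entity labels, log PageRank on the
   knowledge-base reference graph, statement count, sitelink count, and
   a constant.
4. **Context propagation.** Candidates of neighboring mentions form a
   weighted graph (weights from first-order knowledge-base reachability:
   direct links and shared neighbors, plus a self-loop); local features
   are propagated n steps along the row-stochastic adjacency M̃, giving
   the tensor (FM₀, …, FMₙ).
5. **Scoring.** A linear max-margin classifier (squared hinge, L2
   penalty) trained on the weak-supervision corpus scores every
   candidate; per mention the argmax survives if it clears the NIL
   threshold, and survivors are resolved to non-overlapping spans.
6. **Post-filtering and evaluation.** A pluggable PoS rule drops
   implausible annotations (default: must overlap a noun token), and
   quality is measured as character-level binary segmentation
   precision/recall/F1 between annotation masks.

See `vignettes/medlinkr-methods.Rmd` for assumptions, parameter
defaults, and limitations.

## Worked example

Everything below runs offline: the fixture generator writes a synthetic
knowledge dump and wiki pages with known ground truth.

```r
library(medlinkr)

fx <- generate_fixture(fixture_spec(seed = 7))
kb <- parse_dump(fx$dump_path)
selection_stats(kb, medical_profile())
#>                   rule count gain
#> 1       statement:P699    16   16
#> 2      statement:P2892   128  128
#> 3       statement:P486     6    6
#> 4       statement:P672    11   11
#> 5 closure:Q12140[P279]    39   39
#> total selected: 200
```

Each selection rule contributes entities the others miss (the last row
is the n-degree subclass closure of the medication root). Build the
deployable artifact — parse, select, synthesize the pagelink corpus, fit
the language model and PageRank, index terms, train the scorer:

```r
art <- build_annotator(fx$dump_path, fx$pages_path, medical_profile(), seed = 7)
art
#> <medlinkr_artifact v1.0.0 fingerprint 8360e230f935f5a564b6e59400ac3811: 400 entities, 540 terms>
```

Annotate a sentence containing the ambiguous surface "Rylstatphen"
(an alias of both Q20154 and Q20155) next to a disambiguating context
term:

```r
doc <- annotate_with_artifact(art, "Therapie mit Rylstatphen neben Phenvex begonnen.")
doc$annotations
#>   begin end     surface entity     score
#> 1    13  24 Rylstatphen Q20154 0.6251915
#> 2    31  38     Phenvex Q20170 0.6114917
```

Both mentions are linked with positive margin scores; the ambiguous
alias resolves to Q20154 because its propagated features carry the
context entity's evidence (Q20155 is connected to different neighbors).
Held-out performance on the benchmark split (by page, 80/20):

```r
res <- linking_benchmark_eval(fixture_spec(seed = 7))
#> held-out disambiguation accuracy: 1.000 on 36 ambiguous links
#> held-out micro segmentation F1 (unambiguous docs): 1.000
```

A command-line interface wraps the same functions
(`inst/cli/medlinkr.R` with subcommands `fixtures`, `build`, `annotate`,
`evaluate`, `serve`); `serve` exposes a minimal HTTP endpoint that
returns the same JSON as `annotate` for POSTed plain text. An example
profile config documenting the schema is at
`inst/extdata/profile-medical.yaml`.

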