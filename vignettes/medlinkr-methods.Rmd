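---
title: "Methods: feature-based medical entity linking in medlinkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-based medical entity linking in medlinkr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medlinkr)
```

## The problem

Clinical and biomedical free text — discharge letters, findings, trial
reports — carries most of its information in unstructured form.  Entity
linking (EL) turns such text into structured data by detecting mentions
$\omega_s = \delta[s]$ (spans $s$ of a document $\delta$) and mapping each
to an entity $\epsilon \in \Omega$ of a knowledge base, or to NIL when no
entity applies.  medlinkr implements a complete, trainable EL pipeline for
this setting that needs no pretrained neural models and no proprietary
terminology licence: the knowledge base is a filtered subset of a
collaborative WikiData-style dump, and the training corpus is synthesized
from wiki pagelinks as weak supervision.

The pipeline has a *build stage* (knowledge-base filtering, corpus
synthesis, model fitting, term indexing — everything bundled into one
deployable artifact) and a *runtime stage* (dictionary tagging,
disambiguation, post-filtering) sharing one code path between the R API,
the command-line interface and the HTTP endpoint.

## Knowledge-base model and entity selection

An **entity** carries per-language labels, aliases and descriptions, a
sequence of statements (property/value pairs, where values may reference
other entities), and sitelinks to wiki page titles.  Entity-valued
statements induce the directed **reference graph**; edges to ids without a
record are kept for statement counting but treated as absent nodes by
graph algorithms, because dump subsets are routinely incomplete.

Which entities are *linkable* is declared by a **profile**: a union of

* statement rules — e.g. the entity has a Disease Ontology (P699), UMLS
  CUI (P2892), MeSH descriptor (P486) or MeSH tree code (P672) statement;
* closure rules — the entity reaches a root (e.g. medication, Q12140)
  through a chain of subclass-of (P279) and/or instance-of (P31)
  statements, to any depth.

The union form matters because collaborative knowledge bases are
incomplete: each rule contributes entities the others miss, and
`selection_stats()` reports the marginal gain of each rule.  Widely cited
identifier sources print both a property and an item id for the
medication concept; medlinkr treats medication as the *item* `Q12140`
reached via the *property* `P279`, and makes the relation set per root
configurable (`P31` may be included at build time or reserved for
evaluation-time filtering — both are supported because usage conventions
differ between deployments).

`subclass_closure()` excludes the root itself unless a cycle leads back
to it, terminates on cyclic graphs, and is order-independent; it is
property-tested against an independent forward-reachability oracle.

## Local candidate features

For each (mention, candidate) pair the local feature vector is

$$F(\omega, \epsilon) = \big(-\log p(\omega),\; \log PR(\epsilon),\;
stmd(\epsilon),\; sl(\epsilon),\; 1\big)$$

* $p(\omega)$ — probability of the mention under a **unigram language
  model** over the labels and aliases of the selected entities, with
  additive smoothing (pseudo-count $a$, default 1): a seen token has
  probability $(c + a)/(N + a(V{+}1))$, an unseen token
  $a/(N + a(V{+}1))$, and a multi-token mention the product of its token
  probabilities.  The surprisal term makes rare (informative) surfaces
  score differently from frequent, unspecific ones.
* $PR(\epsilon)$ — PageRank of the candidate on the reference graph:
  power iteration with damping 0.85 and 50 iterations by default (the
  standard convention; both are exposed in the config), uniform teleport,
  dangling-node mass redistributed uniformly.  Scores sum to one to
  within $10^{-9}$ and are floored at $10^{-12}$ before the log so
  isolated entities stay finite.
* $stmd(\epsilon)$, $sl(\epsilon)$ — statement and sitelink counts, plain
  popularity/completeness priors.
* the trailing constant 1 gives the linear model a per-step bias under
  propagation.

## Mention graph and feature propagation

Candidates of nearby mentions disambiguate each other.  All
(mention, candidate) pairs of a document become nodes of a weighted
graph; nodes of distinct mentions at most `window` positions apart
(default 5 on each side — documents here are sentences, so this
effectively connects all mentions in a sentence) are joined with weight

$$w(a, b) = [\epsilon_b \in N_1(\epsilon_a)] + [\epsilon_a \in
N_1(\epsilon_b)] + |N_1(\epsilon_a) \cap N_1(\epsilon_b)|$$

where $N_1(\epsilon)$ is the set of entities adjacent to $\epsilon$ in
the reference graph, in either direction.  This counting form is a
declared first-order surrogate for the probability that two candidates
reach each other or a common third entity: reachability is deliberately
limited to first-order connectivity to stay cheap and interpretable.  A
uniform self-loop mass $\lambda = 1$ is added to every node so the
row-normalized matrix $\tilde{M}$ is always defined; a document with a
single mention therefore has $\tilde{M} = I$.

Stacked local features $FM_0$ are propagated for $n$ steps,
$FM_k = \tilde{M} FM_{k-1}$, giving the contextualized tensor
$(FM_0, \ldots, FM_n)$.  Each propagated entry is a convex combination of
its column, so entries stay within the column extrema of $FM_0$ — a
tested invariant.  The default $n = 2$ passes context one hop beyond
direct neighbours; $n$ is configurable and $n = 0$ disables context
entirely.

## Scoring and annotation

The flattened tensor rows ($5(n{+}1)$ features per node) are standardized
with location/scale fitted on training data, then scored by a linear
max-margin classifier minimizing L2-penalized squared-hinge loss
$\tfrac12\lVert w\rVert^2 + C \sum \max(0, 1 - y f(x))^2$.  The objective
is smooth and strictly convex in $w$, so a quasi-Newton fit from a zero
start is deterministic and invariant to example order — two properties
the tests assert exactly.  Standardization is applied to the flattened
tensor at the classifier (not to $FM_0$ before propagation); the choice
is recorded in the artifact.

Training examples come from the weakly annotated corpus: for every
annotated span that the dictionary tagger reproduces, the linked entity
is a positive and every other candidate for the same span a negative.  A
corpus without ambiguity yields no negatives; the scorer then degenerates
to prior-like scoring with a warning rather than an error.

At annotation time each mention keeps its best-scoring candidate if the
score reaches the NIL threshold (default 0, the decision boundary), else
the mention is dropped.  Overlapping survivors are resolved greedily by
score, then span length, then leftmost position; ties between candidates
break toward the lexicographically smallest entity id.  Output spans are
sorted and non-overlapping, and raising the threshold can only remove
annotations.

## Weak supervision from pagelinks

Author-inserted `[[Target|surface]]` pagelinks are treated as mention
annotations: a page maps to an entity when the entity's anchor-free
sitelink equals the (redirect-resolved) title.  Sitelinks with a `#`
section anchor point at concepts finer than the page and are ignored, so
the title→entity mapping stays injective; ties among anchor-free
claimants resolve to the smallest entity id, logged.  Only sentences
containing at least one link to a *selected* entity are kept, each as one
training document with spans rebased to the sentence.  Authors typically
link only the first occurrence of a concept on a page, so page-level
extraction would plant many false negatives; sentence-level extraction
is the mitigation, reproduced here.  Only author links become
annotations — no propagation of labels to repeated unlinked mentions.

Offsets everywhere are 0-based, half-open, counted in Unicode code
points, matching the NIF begin/end convention; corpora are serialized as
NIF 2.0 Turtle (context resources with the document string, phrase
resources with anchor, indices, entity IRI and optional concept-code
IRI), and `read_nif(write_nif(x))` is the identity on ids, texts, spans,
entities and codes.

The wikitext support is a declared subset: links with optional surface
and section anchor, redirects, bold/italic markup, HTML-style tags
(removed, visible text kept), templates and tables (stripped wholesale,
including pagelinks inside them — counted rather than guessed at).
Unbalanced link brackets stay literal text with a warning.

## Pluggable NLP components

Sentence splitting and part-of-speech tagging are contracts, not
dependencies: any `text -> spans` splitter and any
`text -> (token spans, coarse PoS)` tagger can be plugged in, so a
model-based pipeline can replace the defaults in deployments that have
one.  The shipped splitter is rule-based (terminal punctuation plus a
German abbreviation stop list), and the shipped tagger is a rule-based
German heuristic (capitalized tokens are nouns unless on a
function-word stop list; digits are numerals).  Tests use a
deterministic stub tagger so filter semantics are tested independently
of any adapter.  The default post-filter rule keeps an annotation iff at
least one overlapping token is tagged NOUN or PROPN, which removes the
classic lone-determiner artifact ("Das" linked as an entity); rule
composition is conjunction.

Term matching is case-insensitive except for short all-caps surfaces
(at most 4 characters, e.g. drug codes), which remain case-sensitive —
naive lowercasing destroys code-like terms, and the policy identifier is
recorded in the index.  Matches must start and end at Unicode word
boundaries; diacritics are preserved, and there is deliberately no
stemming, lemmatization or fuzzy matching: the dictionary approach
cannot detect inflected or misspelled forms, a known limitation of
label-based EL (a spell-checking front end would be the remedy, out of
scope here).

## Evaluation protocol

Comparing annotations across non-isomorphic terminologies invites
mapping artifacts, so evaluation is reduced to **character-level binary
segmentation**: annotation spans define a per-character mask, and
precision/recall/F1 are computed on the ground-truth and predicted
masks.  Empty/empty masks score F1 = 1; an empty prediction against a
non-empty truth scores 0.  Whitespace characters count (the simplest
defensible reading of character-level; configurable exclusion would be a
trivial mask transform).  Averaging is done both ways:
*micro* over concatenated masks (the default headline number) and
*macro* over per-document F1 — the choice between them is genuinely open,
so both are reported.  A *filtered* mode first removes ground-truth
annotations whose external concept code (e.g. UMLS CUI) is unknown to
the knowledge base, quantifying how much of the gap is missing
cross-references rather than tagging errors.  Whether predictions are
noun-filtered before scoring is a runtime flag; both pipelines run.

## The synthetic world

`generate_fixture()` creates a complete, self-consistent world with known
ground truth: a knowledge dump in the JSON-lines dialect, wiki pages with
planted pagelinks, redirects, section-anchored sitelinks, and an
ambiguity benchmark.  Default study conditions: 400 entities of which
200 carry selection features (a medication-rooted subclass tree of depth
3 and branching 3, directly coded entities, 60 ambiguous alias pairs and
12 high-degree context entities), 2 aliases per entity with 15% of alias
slots shared, 160 content pages with 4 planted links each and sentences
of 5–12 filler tokens.  These sizes keep a full build-train-evaluate
cycle under a few seconds on one core while leaving hundreds of
ambiguous links for the held-out benchmark.

Each ambiguous surface is shared by exactly two entities with *equalized
local features* (same statement and sitelink counts, similar PageRank),
so local evidence cannot separate them; the intended entity is planted
with two of its knowledge-base neighbours mentioned in the same sentence.
Correct disambiguation therefore requires the propagated context
features — the mechanism the model claims to provide — and held-out
accuracy measures exactly that.  Filler vocabulary and term vocabulary
are disjoint by construction, so every indexed surface occurrence is a
planted link.

What the generator does *not* emulate: natural German morphology and
inflection, annotation noise, surface forms absent from labels/aliases,
and document-length discourse structure.  Passing tests on this world
show the machinery is correct and the context mechanism works; they do
not predict absolute scores on real clinical text.

All randomness flows from one integer seed through per-stage derived
seeds, so sub-generators are independent of call order and the same seed
yields byte-identical files.  The benchmark split is by *page*, never by
sentence, to avoid leakage between training and test.

## Numerical choices and degenerate inputs

* PageRank: early exit on an L1 change below `tol` (default off); the
  linear-solve comparison tests pass a larger iteration budget because
  the power-iteration error decays as $0.85^k$.
* Log floors: $10^{-12}$ on PageRank scores; language-model smoothing
  keeps unseen tokens positive whenever $a > 0$.
* Standard-deviation floors of $10^{-12}$ in feature standardization
  (constant features scale to 1).
* Duplicate dump ids: last record wins, with a warning — deterministic
  for line-ordered input.  Malformed dump lines are skipped and counted.
* Redirect cycles resolve every member to the first member encountered
  in a sorted-title scan (deterministic) and are logged.
* Empty inputs: empty text tags to an empty mention list; an empty
  knowledge base refuses PageRank; an empty term index refuses to build.

## Artifact and interfaces

The build stage outputs a single container bundling knowledge base, term
index, language model, PageRank scores, scorer and config; its
fingerprint is an MD5 over the canonical JSON of config, input digests,
sorted index surfaces and rounded model parameters, so identical inputs
give identical fingerprints and the loader refuses artifacts from a
different major version.  The CLI (`fixtures`, `build`, `annotate`,
`evaluate`, `serve`) and the minimal HTTP endpoint (POST plain text,
receive annotation JSON; oversized payloads rejected with the limit
stated) are thin wrappers over the same exported functions.

## Known limitations

Dictionary recall is bounded by label/alias coverage; imprecise aliases
(a famous example: a cosmological item carrying the word "all" as an
alias) can only be suppressed by the scorer and the PoS filter, not by
deeper semantics.  The edge-weight functional form is a surrogate stated
qualitatively by the underlying method; its counting realization is
documented and tested but not canonical.  Scores are not comparable with
other EL engines' internal scores.  Scale targets are desk-sized builds
(~10^4 entities); nothing here is tuned for full-dump processing.
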