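---
title: "Extracting chemical-induced disease relations with cidrex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting chemical-induced disease relations with cidrex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidrex)
```

## The problem

Curated chemical–disease knowledge (as collected, for instance, in the
Comparative Toxicogenomics Database) lags far behind the literature.
Chemical-induced disease (CID) extraction automates one slice of that
curation: given a PubMed title and abstract whose chemical and disease
mentions are already recognized and normalized to MeSH concept identifiers,
decide for every (chemical, disease) identifier pair whether the document
asserts a mechanistic or biomarker relation.  The decision is at *document*
level — the same entity can be mentioned many times — while the linguistic
evidence is local to mentions.  `cidrex` therefore classifies mention pairs
and merges the verdicts.

## Mention-pair instances

A document with $m$ chemical and $n$ disease mentions has $m \times n$
candidate pairs.  Most are noise, so the pool is pruned with heuristic
filters before any learning happens.

**Intra-sentence level.**  A pair whose mentions share a sentence is kept
when its token distance is strictly less than $k$; mentions inside
parentheses are ignored; and when several mention pairs realize the same
(chemical entity, disease entity) combination in one sentence, only the
nearest pair survives.  The token distance is the index difference between
the later mention's first token and the earlier mention's last token, so
immediately adjacent mentions are at distance 1.  The default $k = 10$ is
the package's standing configuration; both printed worked-example distances
(3 and 5) fall well inside it and the discarded combination of the same
document sits exactly at 10, which the strict inequality excludes.

**Inter-sentence level.**  Entity pairs in which *both* members already
participate in some intra-sentence instance are not considered again across
sentences; for the remaining pairs the mention combination with the
smallest sentence distance is kept, subject to distance $< n$ (default 3).
This reading of the exclusion rule — "at least one member uninvolved" — is
the one consistent with the worked example, where a chemical with
intra-sentence instances still pairs across sentences with a disease that
has none.

**General concepts.**  Identifiers on a stoplist (by default D064420,
"Drug-Related Side Effects and Adverse Reactions") never form instances:
the task concerns disease-specific relations.

Mention fields may carry several identifiers joined by `|`; each identifier
spawns its own candidate.  The unknown marker `-1` produces none.

## Distant labels and hypernym filtering

No mention-level annotation exists, so an instance is labeled positive iff
the document's gold relation set contains its identifier pair.  These
distant labels are noisy in both directions; they are nevertheless what the
classifier trains on, and what the approximate mention-level evaluation
scores against.

One systematic source of harmful negatives is MeSH's hierarchy.
Annotation guidelines prefer the most specific disease, so a document that
relates a chemical to two specific cardiac conditions will leave the pair
with their common ancestor ("cardiac dysfunction") unannotated — even when
it appears in a textbook `Chemical-induced Disease` pattern in the title.
Training on that pair as a negative teaches the model that its strongest
positive pattern is negative.  The hypernym filter therefore removes a
negative instance $(c, d)$ when a positive $(c, d')$ exists in the same
document with $d$ a hypernym of $d'$ (and symmetrically on the chemical
side, which mirrors the disease-side rule and can be disabled).  Hypernymy
is decided purely on tree numbers: $a$ is a hypernym of $b$ iff some tree
number of $a$ is a proper dot-boundary prefix of some tree number of $b$.
Concepts missing from the vocabulary are conservatively never hypernyms.
Removed negatives are *not* relabeled positive.

The same rule applied to the system's own document-level output
("post-processing") removes predictions made redundant by a more specific
co-predicted pair.  Both filters return subsets of their input and are
idempotent, which the test suite checks on generated corpora.

## Features

Instances are represented as sparse sets of `TEMPLATE=value` strings,
namespaced `I:` (intra) / `X:` (inter) so the two models can never share
weights accidentally.

* **Intra-sentence lexical (36 templates).**  Mention text, bag-of-words
  and head POS for both mentions; verb-in-between templates keyed on the
  number of verbs strictly between the mentions (none / exactly one / two
  or more, with first/last/other verb and lemma values); word-in-between
  templates keyed the same way on all tokens; two tokens of context before
  the first and after the second mention in text order, with `<S>`/`</S>`
  sentinels at sentence edges; and a flag for instances in the title.
  The mutual exclusions (e.g. `WBNULL` never together with a first/last
  word value) are structural and property-tested.
* **Intra-sentence dependency (9 templates).**  Label paths from the
  sentence root to each mention head, the undirected shortest label path
  between the heads (plain and direction-tagged), the token sequence on
  that path with endpoints generalized to `CHEMICAL`/`DISEASE`, verb lemmas
  on the path, and flags for directly connected heads and for a head that
  is itself the root.  Paths longer than 8 edges collapse to a `LONG`
  sentinel to bound feature-space growth.
* **Inter-sentence lexical (10 templates).**  Mention bag-of-words and POS,
  sentence distance (raw plus a 1/2/3+ bucket, keeping the label space
  small for a sparse model), document frequencies of the two entities
  (capped at "5+"), only-chemical / only-disease flags, and a flag for both
  sentences sharing a text block (e.g. an `OBSERVATIONS:` section of a
  structured abstract).

A registry check guarantees that every emitted string instantiates a known
template.  For multi-token mentions the head token is the token whose
dependency head lies outside the mention (rightmost token as fallback when
no parse is present); "first/second mention" is always text order,
irrespective of the chemical/disease roles.

## Annotation backends

All features need tokens, sentences, POS and lemmas; the dependency
templates additionally need a parse.  `cidrex` fixes only the *contract*:
a backend maps raw text to sentence spans and tagged tokens (plus optional
dependency trees) deterministically.  Three implementations ship:

* `stub_annotator()` — the default, fully self-contained: the block
  tokenizer (maximal letter/digit runs or single punctuation marks),
  sentence splitting on `.?!` followed by whitespace and a capital or
  digit (the title/abstract boundary always splits), POS from a small
  closed lexicon plus suffix rules (a token is a verb when its stem,
  after stripping `-ed/-ing/-s`, is in the verb lexicon), and lemmas from
  an exception table plus suffix stripping.  With `dependencies = TRUE` it
  adds a deterministic "verb-star" tree (first verb as root, everything
  attached to it) so the dependency templates are exercised without a
  parser.
* `read_annotation_tsv()` — loads pre-computed annotations (tokens, POS,
  lemmas, dependency edges) from a line-oriented TSV, so corpora parsed
  with a full external tool chain can be used unchanged.
* Hand-built `dependency_graph()` objects for targeted tests.

Sentence boundaries that would split an entity mention are repaired by
merging the adjacent sentences (logged); `mask_mentions()` implements the
`Doc_{pmid}_{start}_{end}_{Type}` renaming convention that protects
multi-word mentions from being fragmented by an external parser, and
`unmask_mentions()` restores the original text and offsets exactly.

## The classifier

The maximum-entropy model is binary logistic regression over the indicator
features, fit as a ridge-penalized likelihood with `glmnet` (`alpha = 0`,
no standardization, tolerance `1e-10` at the end of a short decreasing
penalty path).  The penalty strength is 1.0 on the summed-log-likelihood
scale (`lambda = 1/n` in per-observation terms): close enough to the
maximum-likelihood fit to classify a separable training set perfectly,
while keeping the weights finite.  The decision threshold is 0.5; both are
configuration knobs.  Training is deterministic — no resampling, no random
initialization — so a fixed corpus always yields identical models, and the
models serialize to a versioned flat text file.

Training requires both classes.  When a level's training data is
single-class (common for the inter-sentence level on corpora whose
relations are all expressed within sentences), `cid_train_model()` refuses
with advice, and the pipeline substitutes a constant-probability fallback
model for that level.

Document-level merging is the disjunction rule: an entity pair is positive
iff at least one of its instances (either level) is positive, with the
maximum posterior as the pair score.  Merging is monotone: flipping an
instance to positive can only add document-level relations.

## Synthetic corpora

`generate_corpus(synth_config(...))` produces seeded PubTator-style corpora
for testing and calibration.  Each document samples 1–2 chemical and 1–3
disease concepts from fixed pools with MeSH-shaped identifiers and
tree numbers; each (chemical, disease) pair becomes a gold relation with
probability `relation_rate` (default 0.3, giving the roughly one-relation-
per-document density typical of curated abstracts).  Planted positives
always co-occur once with a trigger verb ("induced", "caused", "produced")
strictly between the mentions at token distance 3; non-related pairs
co-occur with neutral wording (`cooccur_rate = 0.7`) or, with probability
`noise_rate`, with a spurious trigger, which makes the task non-separable
and exercises the probabilistic machinery.  With probability
`hypernym_pair_rate` a document mentions a more general ancestor of a
related disease next to the chemical, so both hypernym filters fire on
realistic input.  Entities that would otherwise go unmentioned get a
standalone sentence, which is what creates inter-sentence candidates.

What the generator deliberately does *not* emulate: the lexical diversity
and length of real abstracts, NER noise, coordination and anaphora, and
inter-sentence positives requiring discourse inference.  A passing
recovery test therefore demonstrates that the pipeline's plumbing —
construction, filtering, featurization, learning, merging — is correct and
deterministic, not that the feature set reaches any particular accuracy on
real literature.

## Problem sizes and numerical choices

The test suite runs the full pipeline on 200 generated documents
(150 train / 50 held out), where the noise-free configuration is recovered
with F1 = 100%; unit tests use 10–80 documents.  These sizes were chosen to
make every structural property (round trips, monotonicity, idempotence,
determinism) observable with comfortable margins while keeping the suite
fast.  Ties in nearest-pair selection break deterministically by earliest
chemical then disease offset; 0/0 ratios in precision/recall/F are defined
as 0; F is computed from unrounded precision and recall and rounded only
for reporting, which is the convention that reproduces the
benchmark-table arithmetic checked in the tests.

## Known limitations

* The distant labels inherit annotation inconsistencies; mention-level
  scores are approximations by construction.
* The stub tagger's verb lexicon is small and English-only; real corpora
  should come with pre-computed annotations via the TSV interface.
* Dependency features require an external parse to be informative; the
  verb-star stub only exercises the code path.
* No coreference: inter-sentence relations that need an anaphoric bridge
  ("adverse events ... were diarrhea") are out of reach of the lexical
  inter-sentence templates.
* The corpus-scale accuracy of the approach on real data depends on the
  external annotation quality and is not measured by this package's tests.
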