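---
title: "Marked-text phenotype extraction and HPO normalization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marked-text phenotype extraction and HPO normalization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomark)
```

## The task and the division of labor

The pipeline maps short organ-system observations from dysmorphology
physical examinations to Human Phenotype Ontology (HPO) concepts with
character-level boundaries. A generative language model is good at
*finding* the abnormal phenotypes in such text but unreliable at two
things the task requires exactly: ontology identifiers (which it
hallucinates) and character offsets (which it miscounts). phenomark
therefore splits the work: the model only ever produces natural
language — a preferred HPO term and the observation text with the
entity marked in square brackets — and deterministic post-processing
recovers offsets by parsing and resolves identifiers by dictionary
matching. Every component downstream of the model is exact,
testable, and independent of which model produced the response.

## The marked-text span codec

An entity's span is communicated by repeating the observation with
`[` and `]` around the mention; a discontinuous mention gets one
bracket pair per segment. Offsets are recovered by walking the
marked string: a segment starts at the number of non-bracket
characters preceding its `[` and ends before its `]`. All offsets
are 0-based with exclusive end — the only convention under which the
printed reference examples are self-consistent (`synophrys` at 14–23
inside `EYES: partial synophrys, …`), and the tests verify it by
substring extraction.

Because brackets carry meaning, input text is pre-processed by
replacing pre-existing square brackets with round ones. The
substitution is one character for one character, so text length and
therefore every gold offset survive pre-processing.

Parsing a model response applies discard rules rather than repair:

* **text mismatch** — the unmarked text differs from the input.
  Models occasionally "fix" typos or append stray characters
  (`HEAD: +cephalohematoma` returned as `HEAD: +cephalohematoma+`);
  any realignment would risk silently wrong boundaries, so the row
  is dropped and logged. One tolerance is allowed: differences that
  vanish when whitespace runs are collapsed, provided the original
  itself has no whitespace runs — then offsets still index the
  original exactly. Anything further is rejected.
* **out of bounds** — a recovered offset past the end of the input
  is never emitted as a span.
* **no brackets / unbalanced brackets** — a row marking nothing, or
  whose brackets do not pair (nesting included), carries no span.

Discarded rows are kept in the output with their reason (for audit,
and because a discarded row's *preferred term* may still normalize),
but carry no spans. Rows with an empty preferred-term cell are kept
for the same symmetric reason. The codec round trip
(`recover_spans(mark_text(t, s)) == (t, s)`) is property-tested on
random texts and span sets.

## Prompt construction

Prompts follow the three-role chat shape: a short fixed system
instruction (task context only — behavioral detail is conveyed by
examples), a user message per observation, and assistant messages
holding a two-column pipe-delimited table of preferred term and
marked observation. Entity-table rows are ordered by first-segment
start: the source material never fixes a row order, and a
deterministic serialization makes training records and replay tests
byte-stable. For an observation with no findings the assistant
message is the header line alone; the reference material never
prints its empty-table format, so "no data rows = no entities" was
chosen as the convention the parser and renderer share, and it is
what the negative few-shot examples teach.

## Few-shot example selection

Each request gets 25 examples assembled in three steps: the 15
annotated training observations most similar to the query, 5 curated
"tricky" examples registered for the query's organ header
(demonstrating discontinuous spans, modifier exclusion and
organ-header annotation), and the 5 most similar *negative*
(finding-free) observations. The assembled list is shuffled with a
seeded Fisher–Yates so no category clusters at a fixed position;
the seed lives in `selection_config` because reproducibility demands
one and the source material states no policy. Ties in the top-k
break by pool order, again for reproducibility. When a pool runs
short, everything available is taken and the shortfall logged. The
negatives reuse the same similarity function as step 1 — the natural
reading of "most similar negative examples" — but the embedder is an
injected argument, so the choice is overridable.

Similarity is the cosine of mean token vectors. The default
embedder derives each token's vector deterministically from a hash
of the token, which keeps the package fully offline and its tests
reproducible while preserving the algorithm's structure (identical
texts score 1, disjoint vocabularies score near 0). It is *not* a
semantic embedding: with pretrained vectors, "similar" means
topically similar; with hashed vectors it means lexically similar.
Any provider with the same signature — tokens in, matrix of row
vectors out — can be injected where semantic similarity matters.

## Concept normalization

The dictionary maps normalized keys to HPO ids from three sources:
ontology preferred terms, ontology synonyms, and annotated training
surfaces. Keys are case-folded, edge-punctuation-stripped,
whitespace-collapsed, and Porter-stemmed token by token. The Porter
stemmer is implemented in the package (verified against the
published sample vocabulary) and is injectable; any English suffix
stemmer of the same family serves, since the dictionary only needs
both sides of a lookup normalized identically. Key collisions
resolve by source precedence `training_surface > hpo_preferred >
hpo_synonym`: task annotations are the behavior being matched, so
they outrank the ontology's naming when the two disagree (the
corpus-specific reading of an ambiguous surface wins). Excluded
concepts — modifier concepts and unobservable concepts, supplied as
a one-id-per-line file because the task organizers' 5219-concept
list is not published — are dropped from every source, so no
normalization can ever return an excluded id.

Normalization is two lookups with an early exit: observed term
first, preferred term only on a miss. `observed_only` mode disables
the second lookup; it mechanically yields a subset of the two-step
mode's resolutions (higher precision, lower recall), a property the
tests check on every corrupted replay run.

## Curation

Consistency passes over gold data mirror the dataset-update
procedure: span-inconsistency detection flags concepts annotated
with surfaces that differ only by leading/trailing modifier tokens
("mild", "slightly", "prominent", …; lexicon configurable);
concept-inconsistency detection flags case-folded surfaces mapped to
multiple ids. Concept repair supports a majority policy (rewrite to
the most frequent id; ties flagged and left alone) and a manual map;
span repair is manual-map only, because the reference procedure
reviewed spans by hand and automatic boundary rewriting is exactly
the failure mode the parser is built to avoid. Merge rules replace
co-occurring concepts with a combined concept whose span set is the
segment union (coalescing touching segments). Normal-polarity
findings are removed last: they are unscored, and keeping them would
teach the model to extract them. The full pass is idempotent and
never touches observation texts. The surface form of a
discontinuous annotation is its segment substrings joined by single
spaces, everywhere in the package.

## Evaluation

Micro-averaged P/R/F1 under three settings: `normalization_only`
(id agreement), `overlapping` (id + at least one shared character),
`strict` (id + identical span sets). The reference scores are
corpus-level and do not specify a pairing procedure, so matching is
per-observation, one-to-one, and greedy with both sides sorted by
first span start — the standard choice for entity tasks — which
makes counts invariant to input order; a flag additionally controls
whether id-less predictions count as false positives in the span
settings (default: excluded, since the task scores id+span pairs).
Identical duplicate predictions are deduplicated before scoring.
`tp(strict) ≤ tp(overlapping) ≤ tp(normalization_only)` holds by
construction and is asserted over randomized inputs.

## The synthetic corpus generator

All tests run against generated corpora, so the generator is
first-class code. It emulates the *structural* features the
pipeline exercises, with defaults equal to the real datasets'
published statistics where such statistics exist:

| parameter | default | basis |
|---|---|---|
| empty observation rate | 0.12 | reference dataset statistic |
| discontinuous span rate | 0.14 | reference dataset statistic |
| concepts per observation (corpus-wide mean) | 1.49 | reference dataset statistic |
| organ systems | 20 headers | reference dataset statistic |
| modifier rate | 0.15 | chosen: frequent enough to exercise modifier exclusion |
| paraphrase rate | 0.30 | chosen: enough mass on the preferred-term path to make mode differences visible |
| normal-finding rate | 0.11 | chosen to match the share of normal annotations removed in the reference curation (~11%) |

Observation counts per concept draw from a zero-truncated Poisson
whose rate is solved numerically so the corpus-wide mean (empty
observations counted as zero) hits the configured value. Modifier
words are injected before findings but excluded from gold
boundaries; discontinuous findings split a multi-word term around an
uninvolved side word (`low-set left ear` pattern); paraphrased
surfaces substitute a stem-distinct paraphrase for the term's head
adjective, so they cannot accidentally hit an ontology key — which
gives the generator its closed-world guarantee: a dictionary built
from the mini-ontology *plus* the corpus' own training surfaces
normalizes 100% of gold findings, enabling the exact F1 = 1.0
end-to-end baseline under gold replay. The mini-ontology embeds
four real HPO concepts as fixed fixtures (including the
neck-skin pair whose synonymy makes the concept-inconsistency
example work) and generates the rest from a vocabulary whose three
adjective columns (preferred / paraphrase / synonym) are pairwise
stem-disjoint by construction.

What the generator does **not** emulate: clinical spelling noise,
abbreviations, negation phrasing, inter-annotator variance beyond
the injected inconsistency patterns, and the semantic coherence of
header and finding (a generated eye observation may carry a chin
finding). Passing tests therefore demonstrate the pipeline's
mechanical correctness — codec, selection, normalization, scoring —
not clinical-grade extraction quality, which depends on the live
model behind the backend interface.

## Backends and determinism

The pipeline treats the model as a black box behind a one-method
contract. The mock replay backend answers from a gold index and can
corrupt responses the way real models were observed to fail
(character edits outside brackets, stray appended characters,
dropped rows), each mode seeded and deterministic. Live-API
plumbing (a thin `curl`-based adapter, temperature 0 for
reproducibility since no decoding parameters are prescribed) and
remote fine-tune initiation are interface stubs by design: they are
vendor-side operations, not part of the algorithm, and are never
exercised by tests. Retries (3 attempts, exponential backoff) are
plumbing chosen here, not prescribed anywhere.

Every stochastic component takes an explicit seed (generator,
shuffle, corruption), and RNG state is saved and restored around
internal draws, so a fixed configuration reproduces outputs
byte-for-byte — asserted in the tests by serializing two independent
runs.

## Problem sizes

The test suite generates corpora of 25–150 observations per module
test, 500 observations for the end-to-end perfect-replay check,
10,000 random cases for the codec round-trip property, and 100
corrupted-replay runs of a 40-observation corpus for the
monotonicity properties. These sizes give the binomial rate checks
±3-percentage-point resolution and exercise every structural feature
many times over while keeping the whole suite around a minute.

## Known limitations

* Dictionary matching is exact after key normalization; there is no
  fuzzy or embedding-based retrieval, so an unseen surface whose
  preferred-term suggestion is also unseen simply fails to
  normalize (by design — that trade-off is the method).
* The whitespace-collapse tolerance in the parser cannot rescue a
  response when the *original* text contains whitespace runs; such
  rows are discarded as mismatches.
* Token budgeting against specific model context limits is out of
  scope; the 25-example budget is a fixed default, not enforced
  against a tokenizer.
* The hash embedder makes similarity lexical, not semantic; real
  deployments should inject pretrained vectors.
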