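---
title: "Multi-topic assignment with formal concept analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-topic assignment with formal concept analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcatopics)
```

`fcatopics` assigns multiple health topics to consumer health questions
by combining concept-level semantic annotation with Formal Concept
Analysis (FCA). This vignette is the package's account of the method:
what is computed, under which assumptions, which knobs matter, and
where the design was genuinely open.

## The substrate: formal contexts

Everything in the pipeline is expressed over formal contexts
(*O*, *A*, *R*): objects, attributes, and a binary incidence relation.
The two derivation operators map an attribute set to the objects
carrying all of its attributes, and an object set to the attributes
shared by all of its objects. Composing them gives the closure *A''*: a
selection's *implicants* — attributes that follow from it in this
dataset. A formal concept is a closed pair (extent, intent).

```{r}
ctx <- example_fixture("cui_question_context")
concept_of(ctx, c("C0232908"))
```

Four contexts are chained: category-topic (manually curated, loaded as
data), topic-subject, CUI-question, and the derived topic-question
context that drives retrieval. Identifiers are compared by exact,
case-sensitive string equality throughout, since CUIs and topic labels
are canonical strings.

Lattice enumeration uses NextClosure in lectic order over the attribute
roster. The choice is deliberate: it visits every intent exactly once
with no duplicate bookkeeping, and its output order is a deterministic
function of the context, which makes results reproducible and directly
comparable against the test suite's independent oracle (brute-force
closure of every attribute subset). Concept counts can be exponential
in the worst case; the contexts this package targets are sparse with a
small attribute dimension, where enumeration is cheap. Incidence is
stored as pairs plus per-object and per-attribute adjacency, so
derivation costs are proportional to the rows involved, not to |O|x|A|.

## Annotation

The annotator interface is deliberately pluggable. Real deployments of
this method rely on a licensed biomedical annotator and vocabulary
(MetaMap over UMLS); neither can be redistributed, and published
descriptions rarely pin down annotator versions or options. The package
therefore accepts any external annotation table (question, CUI, field,
count) and ships a dictionary matcher for self-contained use:
case-insensitive, whitespace/punctuation-tokenised, longest-match-wins,
non-overlapping, left-to-right. Longest-match with a fixed scan order
was chosen over alternatives (maximal coverage, overlap-allowing) for
one reason: determinism. Subject and body are annotated separately
because the subject carries disproportionate signal and the
subject-route assignment uses it alone.

Semantic-type exclusion removes a concept only when *all* of its types
are excluded; a mixed-typed concept still carries topical information.
The default exclusion list contains exactly four types --
"Quantitative Concept", "Intellectual Product", "Geographic Area",
"Organization" -- and is user-extensible through
`pipeline_config()`. Concepts that cannot be resolved in the lexicon
are retained with a warning rather than dropped: when annotations come
from an external annotator, the local lexicon may legitimately not
cover them, and silently discarding them would bias the cascade.

## The concept-filtering cascade

Steps, in order, with their tunables (all exposed in
`pipeline_config()`):

| step | operation | parameter | default |
|------|-----------|-----------|---------|
| 1 | semantic-type exclusion | `excluded_semantic_types` | the 4 types above |
| 2 | TF-IDF top-k per question | `k` | 5 |
| 3 | term-strength filter | `min_term_strength` | 2 |
| 4 | vocabulary whitelist | `vocabulary` | none (skipped) |

TF is a concept's occurrence count in a question (subject + body)
normalised by all concept occurrences there; IDF is log(N / n_c). The
logarithm base only rescales weights and cannot change any ranking, so
the top-k step is base-invariant; the natural log is declared so that
reported weights are reproducible. Ties at the k-th rank are broken by
weight descending, then CUI ascending, keeping exactly k -- again pure
determinism, there is no principled winner among tied concepts.

The term-strength index of a concept C is the h-index of its
co-occurrence counts: with co-occurring concepts C_i sharing N_i
questions with C, the strength is the largest n such that at least n of
the N_i are >= n. It rewards concepts embedded in a *web* of repeated
co-occurrence rather than merely frequent ones, and is bounded by both
the number of co-occurring concepts and the largest N_i. The default
threshold of 2 removes concepts that lack even two co-occurrents with
two shared questions each. One consequence worth noting: a concept
whose only strong partner is a single other concept has strength 1, no
matter how often the pair co-occurs -- strength >= 2 requires at least
two distinct partners.

Co-occurrence is computed on the CUI-sets that survive step 2, because
the cascade is sequential: each step sees its predecessor's output.
Computing it on pre-TF-IDF sets is a defensible alternative (the
ordering is not forced by the definitions); sensitivity analyses can
pass precomputed profiles into `filter_by_term_strength()` to try it.

Step 4 is driven by a user-supplied CUI list (e.g. a consumer health
vocabulary export) and is skipped when none is configured, since such
vocabularies are licensed resources.

The cascade never adds a concept to any question, and `filter_cuis()`
returns a per-step trace of distinct-concept counts -- the package's
tests assert that the trace is non-increasing.

## Topic assignment

**Subject route.** Each topic has key CUIs plus an expanded CUI-set
(synonyms and transitive descendants collected from a user-supplied
concept graph; traversal is breadth-first with a visited set, so cyclic
inputs terminate). A question gets every topic whose CUI-set intersects
its subject CUI-set. An optional rule table expresses hierarchical
relationships between topic labels (`implies`, applied to a fixed
point, then `suppresses`); it defaults to empty because no canonical
rule set exists for an arbitrary topic inventory -- it is an extension
point, not a guess.

**Voting route.** Each question starts with its original single
archive topic. The question's CUI-set determines a formal concept of
the CUI-question context; within the concept's extent, the questions
whose CUI-set is *exactly* the probe's CUI-set each cast one vote for
their original topic, and topics with at least `min_votes` (default 2)
votes are added to every question in the extent. Two design choices
matter here:

* Votes come only from exact CUI-set matches, and only their
  *original* topics are counted -- never previously inferred ones.
  This makes the procedure provably order-independent (the final
  assignment is a union of per-CUI-set contributions that do not
  interact), and re-running it on its own output is a fixed point. The
  tests assert both properties under random permutations.
* Topics with exactly one vote never win, even when one vote is the
  maximum tally. A single question's filing decision is treated as
  evidence about that question, not about its neighbourhood.

The two routes are combined by per-question union -- commutative,
idempotent -- and the result materialises as the topic-question
context, with one incidence per assigned label.

## Evaluation

Example-based metrics macro-average per-question terms
(|YnZ|/|Z|, |YnZ|/|Y|, 2|YnZ|/(|Z|+|Y|)); traditional micro metrics
pool TP/FN/FP over all questions. Both families are reported side by
side because they disagree exactly when label counts are skewed: a
single question with many reference labels dominates pooled recall but
is one example among m in the macro average. The package's worked
fixture (`example_fixture("eval_examples")`) is constructed to show
this contrast, and the test suite asserts it.

Conventions, chosen where the definitions are silent:

* An empty prediction for a question with a nonempty reference set
  scores per-example precision 0 (the conservative reading; the
  quotient is otherwise undefined). Empty reference sets are not
  evaluated at all -- non-informative questions should be excluded
  beforehand via the `exclude` argument, not scored as empty.
* A traditional rate with a zero denominator is reported as `NaN`
  rather than silently coerced.
* Displayed values are rounded to 3 decimals; internal computation and
  test comparisons use full precision.

Inter-annotator agreement uses pairwise example-based F1 (one annotator
as reference, restricted to shared examples; F1 is symmetric in the
pair). Chance-corrected kappa is deliberately not offered: it assumes
one label per item. The per-topic breakdown restricts examples to those
whose reference or prediction mentions the topic; the restriction rule
is configurable (`restrict` argument) because no single convention is
canonical for per-topic views of multi-label metrics, and the breakdown
is reported as descriptive output, not a headline metric.

## Conjunctive navigation

`select_categories()` and `select_topics()` expose the navigation
engine headlessly: selection in, state out (JSON via the CLI's
`explore`). Selecting facets narrows the extent conjunctively;
the closure of the selection is reported as implied facets (adding one
cannot change the extent -- the tests assert this idempotence), and
facets whose addition would empty the extent are flagged unavailable.
Every reachable state is a formal concept of the context, which the
tests verify against full enumeration on small random contexts. No GUI
is built; the computable substance of such an interface is the context
algebra, and that is what the package provides.

## The synthetic-corpus generator

`synthetic_spec()` + `generate_corpus()` produce corpora with known
multi-topic ground truth: topics own concept pools (disjoint by
default, overlapping via `n_shared_cuis`); each question draws one or
more true topics, mentions `subject_mentions` concepts per true topic
in its subject, repeats them plus further topic concepts in the body
(`body_mentions`), and optionally adds noise-concept mentions
(`noise_cui_rate`) or corrupts mentions (`annotation_miss_rate`). The
original single-topic label is one true topic chosen uniformly,
emulating an archive that files each question once; the ground truth
records all true topics. All randomness flows from one seed, and a
fixed spec reproduces the files byte-for-byte.

Defaults (50 topics, 8 concepts per topic, 2000 questions, 1 concept
per topic in the subject, 2 in the body, no noise) are sized to a
mid-sized question archive slice while keeping every question's
distinct-concept count at or below the TF-IDF default k = 5, so the
cascade's behaviour is driven by term strength rather than truncation.

What the generator emulates: concept-sharing structure between
questions of the same topic, subject/body asymmetry, repeated key
concepts, single-topic originals drawn from multi-topic truth. What it
does not emulate: natural-language variability, annotator errors
beyond uniform misses, ambiguous concepts spanning topics, topic
inventories with semantic hierarchy, and realistic concept frequency
distributions (pool draws are uniform, not Zipfian). Consequently,
passing recovery tests demonstrates the *pipeline logic* -- that the
routes recover exactly the structure they are designed to read off --
not performance on real archives, which depends on annotation quality
and vocabulary coverage.

## Validation problem sizes

The package validates itself at sizes chosen to exercise every code
path while keeping the default suite fast: lattice enumeration against
the subset-closure oracle on 200 random contexts up to 10x10 plus a
thousand random Galois-law draws; term strength against two independent
characterisations on a thousand random profiles (up to 50 entries,
counts up to 100); and end-to-end recovery on a seeded 50-topic,
2000-question zero-noise corpus with two true topics per question,
where the subject route must recover truth exactly (F1 = 1), and the
combined method must beat the single-topic baseline's example-based
recall without losing more than 0.05 precision.

## Known limitations

* The dictionary annotator is a stand-in: no word-sense
  disambiguation, negation handling, or variant generation. Serious
  use should import external annotations.
* Concept-lattice enumeration is exponential in the worst case; it is
  intended for the small, dense navigation contexts (tens of
  attributes), not for the CUI-question context, which the pipeline
  never enumerates in full -- assignment only ever computes one
  concept per distinct CUI-set.
* The voting route can only ever add topics that occur as original
  labels of exact CUI-set duplicates; corpora with few duplicate
  CUI-sets gain little from it (the subject route is then the main
  source of new labels).
* Per-topic metric breakdowns depend on a configurable example
  restriction and should be compared only under a fixed convention.
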