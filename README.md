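# fcatopics

Multi-topic assignment and conjunctive navigation for consumer health
questions with Formal Concept Analysis.

## The problem

Community question-answering archives for consumer health (the kind
where laypeople ask experts about medications, symptoms, or pregnancy)
traditionally file each question under a **single** topic, even though
most questions are relevant to several. A question about asthma
medication while breastfeeding is invisible to anyone browsing the
"Breast Feeding" topic if it was filed under "Asthma". Assigning every
question its full set of relevant topics is a multi-label
classification problem, and solving it is the prerequisite for
*navigational exploration*: drilling down through categories and topics
to the questions lying at their intersection, instead of formulating a
search query.

`fcatopics` implements an unsupervised, knowledge-driven pipeline for
this problem, aimed at health-informatics researchers and curators of
question archives:

1. **Concept annotation.** Question subjects and bodies are mapped to
   biomedical concept identifiers (UMLS-style CUIs) by a pluggable
   annotator: a built-in dictionary matcher (longest match,
   case-insensitive, non-overlapping), or any external annotator whose
   output is imported as a TSV.
2. **Concept filtering.** Uninformative concepts are removed in a
   four-step cascade: semantic-type exclusion; per-question TF-IDF
   top-*k* selection (*k* = 5); a **term-strength index** — for a
   concept *C* with co-occurring concepts *C₁…C_k* sharing *N₁…N_k*
   questions with *C*, the largest *n* such that *n* of the *Nᵢ* are at
   least *n* (the h-index of the co-occurrence counts); concepts with
   strength < 2 are dropped; and an optional vocabulary whitelist.
3. **Formal Concept Analysis.** The surviving per-question CUI-sets
   form a formal context (questions × concepts). For a context
   (*O*, *A*, *R*), the derivation operators map attribute sets to the
   objects carrying all of them and back; a **formal concept** is a
   closed (extent, intent) pair. The package provides the derivation
   operators, closures, and full lattice enumeration (NextClosure).
4. **Topic assignment.** Two routes, then their union:
   * *subject route* — a question gets every topic whose (graph-expanded)
     CUI-set intersects its subject's CUI-set;
   * *voting route* — each question's CUI-set determines a formal
     concept of the CUI-question context; the questions in its extent
     with *exactly* that CUI-set each vote for their original archive
     topic, and topics with ≥ 2 votes are added to every question in
     the extent (single-vote topics never win).
5. **Evaluation.** Example-based multi-label metrics — with reference
   set *Yᵢ* and prediction *Zᵢ*, P = mean(|Yᵢ∩Zᵢ|/|Zᵢ|),
   R = mean(|Yᵢ∩Zᵢ|/|Yᵢ|), F₁ = mean(2|Yᵢ∩Zᵢ|/(|Zᵢ|+|Yᵢ|)) — alongside
   traditional micro-averaged metrics, plus pairwise-F₁
   inter-annotator agreement.
6. **Navigation.** A headless conjunctive navigation engine over the
   chained category-topic and topic-question contexts: selecting facets
   narrows to the intersection of their extents and reports implied
   (closure) and unavailable facets.

A seeded synthetic-corpus generator with known multi-topic ground truth
supports validation without any licensed vocabulary or proprietary
archive.

## Worked example

The package ships its reference examples as built-in fixtures. The
concept-extent voting scheme on an eight-question subcontext with three
concepts ("conceived", "Metrorrhagia", "period"):

```r
library(fcatopics)

ctx <- example_fixture("cui_question_context")
ctx
#> <formal_context> 8 objects x 3 attributes, 18 incidences

final <- vote_assign(ctx, example_fixture("original_topics"))
final
#> # A tibble: 12 × 2
#>    question_id topic
#>  1 Q1          Gynecology
#>  2 Q2          Pregnancy
#>  3 Q3          Pregnancy
#>  4 Q4          Gynecology
#>  5 Q4          Pregnancy
#>  ...
#> 10 Q7          Pregnancy
#> 11 Q7          Women's Health
#> 12 Q8          Gynecology
```

Q4, Q6 and Q7 gain "Gynecology" because the four questions whose
CUI-set is exactly {Metrorrhagia, period} vote 3–1 for it; Q7
additionally gains "Pregnancy" from the {conceived, Metrorrhagia}
voters. Questions keep their original topics; nothing is removed. The
resulting topic-question context then drives conjunctive retrieval:

```r
tq <- build_topic_question_context(final)
select_topics(tq, c("Gynecology", "Pregnancy"))
#> [1] "Q4" "Q7"
```

Evaluating a prediction against a reference standard, on the four
worked examples (one of which has ten reference labels):

```r
ex <- example_fixture("eval_examples")
ev <- evaluate_assignment(ex$reference, ex$predicted)
ev
#> <ml_eval> 4 examples
#>   example-based: P 0.875  R 0.775  F1 0.792
#>   traditional:   TP 6  FN 9  FP 1  P 0.857  R 0.400  F1 0.545
```

The gap between the two families is the point: pooled (traditional)
recall is dominated by the single ten-label question, while the
example-based macro average treats it as one example among four.
`tidy(ev)` returns the per-example terms, `glance(ev)` a one-row
summary, and `autoplot(ev)` a per-example chart.

A command-line surface wraps the same functions
(`exec/fcatopics annotate | filter | build-context | assign | evaluate |
explore | simulate | fixtures`); small demonstration inputs live in
`inst/extdata/`.

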