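---
title: "Methods: dictionary annotation, termhood scoring, and clinical context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary annotation, termhood scoring, and clinical context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinannotate)
```

## The problem

Clinical free text — discharge summaries, death certificates, progress
notes — carries conditions, drugs and procedures that structured fields
miss. Dictionary-based concept recognition links substrings of a note to
concept identifiers of a medical terminology, producing annotations that
downstream systems can index, code or mine. Two things make clinical text
special compared to the biomedical literature: many mentions are *negated*,
*about someone other than the patient*, or *historical* ("no sign of
metastasis", "mother had breast cancer", "history of poliovirus"), and
annotation consumers usually want only the most salient concepts, not every
single-word hit. `clinannotate` is a self-contained engine for this chain:
recognize, expand, filter by semantic group, contextualize, score, filter
by score, serialize.

## Recognition model

Matching is purely syntactic and whole-token. One normalization is applied
to labels (at index time) and documents (at match time): tokens are maximal
runs of Unicode letters/digits, lowercased; hyphens and apostrophes split;
all other punctuation is invisible. A label matches wherever its normalized
token sequence equals a *contiguous* token sequence of the document, and
the annotation span covers the original characters from first to last
matched token. All matches are returned, including nested and overlapping
ones ("breast cancer" also yields "cancer" if both are labels);
`filter_longest_only()` (CLI `--longest-only`) post-filters to spans not
strictly contained in longer spans. There is deliberately no stemming,
abbreviation expansion or spelling correction: "cells" does not match
"cell". Offsets are 0-based and end-exclusive over code points everywhere
internally and in BRAT output; only the JSON writer converts to the 1-based
inclusive convention of NCBO-style services, in one pair of functions
(`span_to_ncbo()` / `span_from_ncbo()`).

Hierarchy expansion adds, for each direct annotation, annotations for
is_a ancestors up to a configurable distance `d`, recorded as
`expansion_distance` so scoring can discount them. Cross-ontology mapping
expansion is out of scope — there is no mapping store in a standalone
engine.

## Scoring

Three algorithms, all attaching one score per concept per document (every
annotation of a concept carries the concept total, since the purpose is
ranking concepts for a document):

* **old** — weight sums: each annotation contributes `weight_pref` (10),
  `weight_syn` (8), or `weight_expanded(d) = max(10 - d, 1)`. Additive:
  duplicating the annotations doubles the score.
* **cvalue** — the concept total is the sum over its distinct directly
  matched terms of the match-type weight times the term's C-Value.
* **cvalueh** — as cvalue, plus `weight_expanded(d) × CV(term)` for
  expanded annotations.

The C-Value of a matched term $a$ with word length $|a|$ and document
frequency $f(a)$ is

$$CV(a) = \log_2(|a| + 1)\; f(a)$$

when no longer matched term nests it, and otherwise

$$CV(a) = \log_2(|a|+1)\Big(f(a) - \tfrac{1}{|T_a|}\sum_{b \in T_a} f(b)\Big),$$

floored at zero, where $T_a$ is the set of longer matched terms containing
$a$ as a contiguous token subsequence. Numerical choices worth stating:

* the classical $\log_2|a|$ length factor zeroes out single-word terms,
  which must still be rankable here, hence the $+1$ offset;
* $f(a)$ counts **distinct annotated spans** of the term — a span
  annotated with two concepts that share a label is one occurrence of the
  term, not two — and includes occurrences nested inside longer matched
  terms;
* the weights are conventions with sane defaults, not empirical constants;
  they are configurable in `score_config()`.

Score filtering has two modes. `absolute` keeps `score >= threshold`.
`percentile` computes the threshold-th percentile of the score multiset by
the **nearest-rank** method and keeps scores at or above it, ties
included, so a 90 threshold keeps the top 10% of the score distribution.
We read "top X% of the score distribution" as a property of score
*values*; the alternative reading — the highest-scored annotations holding
the top X% of cumulative score *mass* — is implemented behind
`percentile_basis = "mass"` but is not the default, because only the
value-based reading makes "a score in the top 10%" a predicate of a score.

## Clinical context

Context detection is a trigger/scope algorithm in the NegEx/ConText
family. Every annotation defaults to affirmed / patient / recent. Within
the sentence an annotation occupies, trigger phrases from a lexicon open
directional scopes:

* a **forward** trigger ("denies", "no sign of") scopes from the token
  after it to the sentence end;
* a **backward** trigger ("is ruled out") scopes from the sentence start
  to the token before it;
* any scope is cut short at the first **colon** or **termination term**
  ("but", "however") between trigger and boundary.

An annotation inside a negation scope becomes negated; experiencer and
temporality work the same way with their own categories. Scope runs to the
sentence end (ConText behavior) rather than a fixed token window; a
`window` argument optionally caps it. Design points the algorithm family
leaves open, fixed here:

* **pseudo phrases** ("no increase", "not ruled out") silence a trigger
  they strictly contain — but only a trigger of their *own category*,
  matching how the public term lists are organized per category;
* a trigger whose characters overlap an annotation's own span never
  modifies that annotation (so a dictionary that contains "history of
  poliovirus" as a label does not mark that annotation historical by its
  own tokens);
* if both a historical and a hypothetical scope cover an annotation,
  **historical wins** — a documented tie-break, not a claim about
  clinical ground truth;
* multiple triggers of one category are idempotent, so no precedence is
  needed within a category.

The sentence splitter breaks at `.`, `!`, `?` and at a newline followed by
whitespace or end of text; an abbreviation list ("dr", "mr", "mrs", "vs",
"e.g", "i.e") suppresses splits, and a period glued to a following
letter/digit is treated as word-internal (this is what keeps the *first*
period of "e.g." from splitting — the abbreviation list alone only covers
the final one). An annotation spanning a sentence boundary (possible
because punctuation is invisible to matching) is a per-document error, not
silently mis-scoped.

The shipped lexicon (`inst/extdata/context_triggers.txt`, ~160 entries) is
distilled from the public NegEx/ConText term lists and is replaceable via
`load_trigger_lexicon(path)`; it is a floor, not the ceiling, of what a
production deployment would use.

## Semantic groups

Concepts carry fine-grained semantic type codes ("T047"); a pipe-delimited
table in the NLM SemGroups layout maps types to coarse groups ("DISO",
"CHEM"). The table ships as *data*, not code — the shipped file is a
distilled subset of the standard assignments covering common types, and
the full NLM file drops in unchanged. Filtering retains annotations whose
concept has at least one type in a requested group; concepts without
semantic types are dropped while a group filter is active, which is the
behavior a coarse-grained restriction implies.

## Pipeline order

`run_pipeline()` applies: recognition → hierarchy expansion → group/type
filter → context detection → scoring → score filter → longest-only. Group
filtering precedes context detection because it is cheap and context is
per-sentence work; the order is a documented convention of this engine
(the original service does not print its internal order). Context
detection and scoring default **off**, so the default pipeline is exactly
the plain recognizer.

## The synthetic corpus generator

Licensed clinical corpora cannot ship, so the evaluation harness runs on
generated data. `generate_corpus()` builds a vocabulary of 1–3-word labels
from a closed pool of invented pseudo-medical tokens, each concept drawing
from its own disjoint token slice — so labels never nest each other, never
collide with filler text, and never contain trigger words. Mentions are
planted in template sentences; with stated probabilities a mention is
wrapped in a negation / experiencer / historical template whose trigger
comes from the shipped lexicon, and the wrapped value is recorded as gold.
Defaults (5 concepts, 10 notes, 2 mentions per note, all wrap
probabilities 0, synonym probability 0.5) are the sizes the acceptance
properties state; they are deliberately small enough to be exhaustively
checkable.

What the generator emulates: exact-span mention structure, sentence-local
context cues, distractor sentences, reproducibility from a seed. What it
does **not** emulate: morphological variation, misspellings,
abbreviations, ambiguous terms, triggers at non-template positions,
cross-sentence discourse. A green closed-loop test therefore establishes
that the chain is lossless and the context algorithm correct *on its own
stated semantics* — it does not estimate performance on real clinical
text, which the original service's published evaluation addresses and
which requires licensed corpora this package cannot include.

Evaluation is micro pooled precision/recall/F1. Span mode requires exact
(doc, start, end, concept) identity with each gold record matched once;
partial-overlap credit is deliberately not the default since campaigns
differ on it. Context mode reports accuracy over gold-matched spans plus
P/R/F1 of the non-default class. Edge conventions: precision is 1 with no
predictions, recall 1 with no gold, F1 0 when both components are 0.

## Known limitations

* Whole-token matching misses morphological variants ("cells" vs "cell");
  this is a property of the recognizer family, not an accident.
* The SKOS reader handles the minimal profile (prefLabel, altLabel,
  broader, @prefix) — enough for custom dictionary vocabularies, not a
  Turtle parser.
* Literal `|` in labels is unsupported (it is the multi-value separator of
  the dictionary TSV).
* One terminology per run; `--ontologies` restricts by the concept
  `source` field rather than addressing a multi-ontology store.
* RDF output is a Web-Annotation-*like* shape in a local vocabulary; it is
  valid N-Triples but claims no vocabulary conformance.
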