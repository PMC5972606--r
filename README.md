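# clinannotate

Dictionary-based annotation of clinical and biomedical free text, in R,
with the post-processing steps that make annotations usable on clinical
notes: **termhood scoring** (C-Value based), **clinical context
detection** (negation, experiencer, temporality via a ConText-style
trigger/scope algorithm), **semantic-group filtering**, and export to
**BRAT standoff, RDF (N-Triples), JSON and TSV**. It is aimed at
informaticians who need a self-contained, auditable annotator they can
run on sensitive text in-house, with a terminology of their own.

## What it computes

Given a terminology (concept id, preferred label, synonyms, semantic
types, is_a parents), the recognizer finds every occurrence where the
normalized token sequence of a label equals a contiguous token sequence
of the document (case- and punctuation-insensitive, whole tokens only,
nested matches kept). Annotations of a concept are then scored; the
C-Value of a matched term *a* with word length |a| and frequency f(a) is

    CV(a) = log2(|a|+1) · f(a)                                   (not nested)
    CV(a) = log2(|a|+1) · ( f(a) − (1/|T_a|) Σ_{b∈T_a} f(b) )    (nested in T_a)

so longer multi-word terms outscore short ones at equal frequency, and a
term occurring only inside longer matched terms scores low. Percentile
filtering by the nearest-rank method keeps, e.g. at threshold 90, the
annotations whose scores sit in the top 10% of the score distribution.
Context detection assigns each annotation negated/affirmed,
patient/other, recent/historical/hypothetical from trigger phrases with
directional scopes that end at a colon or a termination term ("but").

## Worked example

```r
library(clinannotate)

tmp <- tempfile(fileext = ".tsv")
writeLines(c(
  "id\tpref_label\tsynonyms\tsemantic_types\tparents\tsource",
  "C1\tbreast cancer\tcancer of the breast\tT047\t\tDEMO",
  "C2\tmetastasis\t\tT191\t\tDEMO",
  "C3\tchest pain\t\tT184\t\tDEMO"), tmp)
term <- load_terminology(tmp, "tsv")

cfg <- pipeline_config(term, negation = TRUE, experiencer = TRUE,
                       temporality = TRUE, score_algorithm = "cvalue")
res <- run_pipeline(cfg, c(note1 = paste(
  "Mother had breast cancer. No sign of metastasis.",
  "Chest pain since this morning.")))
res[[1]]$annotations[, c("concept_id", "start", "end", "surface",
                         "score", "negation", "experiencer", "temporality")]
```

prints

```
  concept_id start end       surface    score negation experiencer temporality
1         C1    11  24 breast cancer 15.84963 affirmed       other      recent
2         C2    37  47    metastasis 10.00000  negated     patient      recent
3         C3    49  59    Chest pain 15.84963 affirmed     patient      recent
```

Reading it: every concept was found at its exact character span (0-based,
end-exclusive). "breast cancer" is affirmed but attributed to the
*mother*, not the patient; "metastasis" is negated by the "no sign of"
trigger; "chest pain" keeps all defaults. The two-word terms score
10·log2(3) ≈ 15.85 against 10·log2(2) = 10 for the single-word term at
equal frequency — the scoring favours longer, more specific terms.

The same chain runs from the shell:

```sh
exec/clinannotate --dict dict.tsv --input notes/ \
  --negation --experiencer --temporality \
  --score cvalue --confidence-threshold 90 \
  --semantic-groups DISO --format brat --output-dir out/
```

## Evaluation harness

Licensed clinical corpora cannot be redistributed, so the package ships a
synthetic corpus generator with planted gold annotations
(`generate_corpus()`) and a micro P/R/F1/accuracy evaluator
(`evaluate()`); the closed-loop property — default pipeline on a
generated corpus recovers the gold exactly — is part of the acceptance
suite. See `vignettes/annotation-methods.Rmd` for what that does and does
not establish.

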