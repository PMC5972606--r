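#' Synthetic gold corpora
#'
#' Licensed clinical corpora cannot ship with the package, so the
#' evaluation harness runs on generated stand-ins: a synthetic terminology
#' whose labels are built from a closed pool of invented pseudo-medical
#' tokens (so labels can never collide with filler text or trigger
#' phrases), and clinical-note-like documents in which mentions of those
#' labels are planted inside template sentences. With stated
#' probabilities a mention is wrapped in a negation / experiencer /
#' historical template drawn from the shipped trigger lexicon, and the
#' wrapped context value is recorded as gold. Distractor sentences contain
#' no dictionary label. Generation is fully reproducible from the seed.
#'
#' @param n_concepts vocabulary size (>= 1).
#' @param n_notes number of documents.
#' @param mentions_per_note planted mentions per document.
#' @param p_negation,p_experiencer,p_historical probability that a mention
#'   is wrapped in the corresponding context template (mutually exclusive;
#'   their sum must be <= 1).
#' @param p_distractor probability of inserting a label-free distractor
#'   sentence after each mention sentence.
#' @param p_synonym probability that a concept carries a synonym (built
#'   from its own reserved tokens; synonyms are never planted).
#' @param len_probs probabilities of a concept label having 1, 2 or 3
#'   words.
#' @param seed integer seed.
#' @return list with elements `terminology` (a [load_terminology()]-style
#'   object) and `corpus` (class `gold_corpus`: `documents`, a named
#'   character vector of texts; `gold`, a data frame with doc_id, start,
#'   end, concept_id, negation, experiencer, temporality; and `params`).
#' @export
generate_corpus <- function(n_concepts = 5, n_notes = 10,
                            mentions_per_note = 2,
                            p_negation = 0, p_experiencer = 0,
                            p_historical = 0, p_distractor = 0,
                            p_synonym = 0.5,
                            len_probs = c(0.3, 0.5, 0.2),
                            seed = 42L) {
  stopifnot(n_concepts >= 1, n_notes >= 1, mentions_per_note >= 1,
            p_negation >= 0, p_experiencer >= 0, p_historical >= 0,
            p_negation + p_experiencer + p_historical <= 1,
            p_distractor >= 0, p_distractor <= 1)
  # closed token pool: invented pseudo-medical words, disjoint from every
  # filler/template/trigger word by construction
  pre <- c("zorb", "flex", "card", "nephr", "gastr", "pulm", "derm",
           "oste", "hepat", "neur", "vasc", "lymph", "chondr", "myel",
           "fibr", "angi")
  suf <- c("axitis", "onoma", "ulexia", "osis", "emia", "opathy",
           "itosis", "algium", "ectomia", "uritis")
  pool <- as.vector(outer(pre, suf, paste0))
  need <- n_concepts * 5L   # up to 3 label tokens + 2 synonym tokens
  if (need > length(pool)) {
    stop("token pool too small for ", n_concepts,
         " concepts (need ", need, " tokens, have ", length(pool), ")")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  pool <- sample(pool)
  concepts <- vector("list", n_concepts)
  for (i in seq_len(n_concepts)) {
    toks <- pool[((i - 1) * 5 + 1):(i * 5)]
    len <- sample(1:3, 1, prob = len_probs)
    syn <- if (stats::runif(1) < p_synonym) {
      paste(toks[4:5], collapse = " ")
    } else character()
    concepts[[i]] <- new_concept(
      id = sprintf("SYN:%03d", i),
      pref_label = paste(toks[seq_len(len)], collapse = " "),
      synonyms = syn,
      semantic_types = sample(c("T047", "T184", "T121", "T037"), 1),
      source = "synthetic")
  }
  term <- build_terminology(concepts)

  plain_tpl <- c("Examination shows %s today.",
                 "Assessment documents %s this visit.",
                 "The record lists %s at admission.")
  neg_tpl <- c("There is no sign of %s.",
               "The patient denies %s.")
  exp_tpl <- c("Mother had %s.",
               "Father had %s.")
  hist_tpl <- c("History of %s was noted.",
                "History of %s per old chart.")
  distractor <- c("The ward round proceeded as planned.",
                  "Routine observations were recorded overnight.",
                  "The care team discussed discharge planning.")
  gold <- list()
  texts <- character(n_notes)
  ids <- sprintf("note%03d", seq_len(n_notes))
  for (d in seq_len(n_notes)) {
    text <- ""
    append_sentence <- function(txt, sentence) {
      if (nzchar(txt)) paste0(txt, " ", sentence) else sentence
    }
    for (m in seq_len(mentions_per_note)) {
      cp <- concepts[[sample.int(n_concepts, 1)]]
      label <- cp$pref_label
      u <- stats::runif(1)
      if (u < p_negation) {
        tpl <- sample(neg_tpl, 1)
        ctx <- c("negated", "patient", "recent")
      } else if (u < p_negation + p_experiencer) {
        tpl <- sample(exp_tpl, 1)
        ctx <- c("affirmed", "other", "recent")
      } else if (u < p_negation + p_experiencer + p_historical) {
        tpl <- sample(hist_tpl, 1)
        ctx <- c("affirmed", "patient", "historical")
      } else {
        tpl <- sample(plain_tpl, 1)
        ctx <- c("affirmed", "patient", "recent")
      }
      sentence <- sprintf(tpl, label)
      prefix_len <- nchar(sub("%s.*$", "", tpl))
      base <- if (nzchar(text)) nchar(text) + 1L else 0L
      start <- base + prefix_len
      gold[[length(gold) + 1L]] <- data.frame(
        doc_id = ids[d], start = start, end = start + nchar(label),
        concept_id = cp$id, negation = ctx[1], experiencer = ctx[2],
        temporality = ctx[3], stringsAsFactors = FALSE)
      text <- append_sentence(text, sentence)
      if (stats::runif(1) < p_distractor) {
        text <- append_sentence(text, sample(distractor, 1))
      }
    }
    texts[d] <- text
  }
  gold <- do.call(rbind, c(gold, list(make.row.names = FALSE)))
  corpus <- structure(
    list(documents = stats::setNames(texts, ids), gold = gold,
         params = list(n_concepts = n_concepts, n_notes = n_notes,
                       mentions_per_note = mentions_per_note,
                       p_negation = p_negation,
                       p_experiencer = p_experiencer,
                       p_historical = p_historical,
                       p_distractor = p_distractor,
                       p_synonym = p_synonym, len_probs = len_probs,
                       seed = seed)),
    class = "gold_corpus")
  list(terminology = term, corpus = corpus)
}

#' Write a gold corpus as BRAT .txt/.ann pairs
#'
#' Emits one `.txt`/`.ann` pair per document via [write_brat()], so the
#' harness exercises the same readers and writers as real data.
#'
#' @param corpus a `gold_corpus`.
#' @param dir output directory (created if needed).
#' @return invisibly the vector of files written.
#' @export
write_gold_brat <- function(corpus, dir) {
  stopifnot(inherits(corpus, "gold_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (id in names(corpus$documents)) {
    text <- corpus$documents[[id]]
    g <- corpus$gold[corpus$gold$doc_id == id, , drop = FALSE]
    anns <- if (nrow(g) == 0) empty_annotations() else data.frame(
      concept_id = g$concept_id, start = g$start, end = g$end,
      surface = substr(rep(text, nrow(g)), g$start + 1L, g$end),
      match_type = "PREF", negation = g$negation,
      experiencer = g$experiencer, temporality = g$temporality,
      stringsAsFactors = FALSE)
    sd <- scored_document(id, text, as_annotations(anns))
    out <- write_brat(sd)
    writeLines(out$txt, file.path(dir, paste0(id, ".txt")), sep = "",
               useBytes = TRUE)
    writeLines(out$ann, file.path(dir, paste0(id, ".ann")), sep = "",
               useBytes = TRUE)
    files <- c(files, file.path(dir, paste0(id, c(".txt", ".ann"))))
  }
  invisible(files)
}

eval_result <- function(tp, fp, fn, accuracy = NA_real_) {
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, accuracy = accuracy),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("P=%.1f%% R=%.1f%% F1=%.1f%%", 100 * x$precision,
              100 * x$recall, 100 * x$f1))
  if (!is.na(x$accuracy)) cat(sprintf(" A=%.1f%%", 100 * x$accuracy))
  cat(sprintf("  (tp=%d fp=%d fn=%d)\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Evaluate predictions against a gold corpus
#'
#' Micro-averaged precision, recall and F1 pooled across documents.
#' \describe{
#'   \item{spans}{a prediction is a true positive iff its (doc_id, start,
#'     end, concept_id) exactly matches a gold record, each gold record
#'     matched at most once.}
#'   \item{concepts}{document-level coding: per-document concept-set
#'     comparison, pooled.}
#'   \item{context}{over gold-matched spans, accuracy (fraction whose
#'     predicted value of `dimension` equals gold) plus P/R/F1 of the
#'     non-default class of that dimension.}
#' }
#' Conventions: precision is 1 when there are no predictions, recall 1
#' when there is no gold, F1 0 when both are 0.
#'
#' @param pred list of [scored_document()] (pipeline output).
#' @param gold a `gold_corpus`.
#' @param mode `"spans"`, `"concepts"` or `"context"`.
#' @param dimension for `mode = "context"`: `"negation"`,
#'   `"experiencer"` or `"temporality"`.
#' @param positive_class for `mode = "context"`: the non-default class
#'   scored with P/R/F1 (defaults to negated / other / historical).
#' @return an `eval_result`: tp, fp, fn, precision, recall, f1 and (for
#'   context mode) accuracy, as proportions in `[0, 1]`.
#' @export
evaluate <- function(pred, gold, mode = c("spans", "concepts", "context"),
                     dimension = c("negation", "experiencer",
                                   "temporality"),
                     positive_class = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(gold, "gold_corpus"))
  known <- names(gold$documents)
  pred_ids <- vapply(pred, `[[`, character(1), "doc_id")
  unknown <- setdiff(pred_ids, known)
  if (length(unknown) > 0) {
    stop("prediction doc_id(s) not in gold corpus: ",
         paste(unknown, collapse = ", "))
  }
  g <- gold$gold
  pieces <- Filter(Negate(is.null), lapply(pred, function(sd) {
    if (nrow(sd$annotations) == 0) return(NULL)
    cbind(doc_id = sd$doc_id, sd$annotations)
  }))
  pred_rows <- if (length(pieces) == 0) {
    cbind(doc_id = character(), empty_annotations())
  } else {
    do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  }
  if (mode == "concepts") {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (id in known) {
      pset <- unique(pred_rows$concept_id[pred_rows$doc_id == id])
      gset <- unique(g$concept_id[g$doc_id == id])
      tp <- tp + length(intersect(pset, gset))
      fp <- fp + length(setdiff(pset, gset))
      fn <- fn + length(setdiff(gset, pset))
    }
    return(eval_result(tp, fp, fn))
  }
  pkey <- paste(pred_rows$doc_id, pred_rows$start, pred_rows$end,
                pred_rows$concept_id)
  gkey <- paste(g$doc_id, g$start, g$end, g$concept_id)
  if (mode == "spans") {
    # exact-key matching: maximum bipartite matching degenerates to
    # per-key multiset intersection
    tab_p <- table(pkey); tab_g <- table(gkey)
    common <- intersect(names(tab_p), names(tab_g))
    tp <- sum(pmin(tab_p[common], tab_g[common]))
    return(eval_result(as.integer(tp), as.integer(length(pkey) - tp),
                       as.integer(length(gkey) - tp)))
  }
  # context mode: compare the dimension over gold-matched spans (first
  # prediction per key wins; keys are unique in generated corpora)
  dimension <- match.arg(dimension)
  if (is.null(positive_class)) {
    positive_class <- c(negation = "negated", experiencer = "other",
                        temporality = "historical")[[dimension]]
  }
  idx <- match(gkey, pkey)
  matched <- !is.na(idx)
  if (!any(matched)) return(eval_result(0L, 0L, sum(!matched), NA_real_))
  gv <- g[[dimension]][matched]
  pv <- pred_rows[[dimension]][idx[matched]]
  accuracy <- mean(pv == gv, na.rm = FALSE)
  tp <- sum(pv == positive_class & gv == positive_class, na.rm = TRUE)
  fp <- sum(pv == positive_class & gv != positive_class, na.rm = TRUE)
  fn <- sum(pv != positive_class & gv == positive_class, na.rm = TRUE)
  eval_result(as.integer(tp), as.integer(fp), as.integer(fn), accuracy)
}
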