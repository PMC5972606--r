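test_that("generate_corpus plants the requested mentions reproducibly", {
  g <- generate_corpus(n_concepts = 5, n_notes = 10, mentions_per_note = 2,
                       seed = 9)
  expect_length(g$terminology$concepts, 5)
  expect_length(g$corpus$documents, 10)
  expect_equal(nrow(g$corpus$gold), 20)
  expect_true(all(g$corpus$gold$negation == "affirmed"))
  expect_true(all(g$corpus$gold$experiencer == "patient"))
  expect_true(all(g$corpus$gold$temporality == "recent"))
  # gold spans satisfy span fidelity
  for (i in seq_len(nrow(g$corpus$gold))) {
    r <- g$corpus$gold[i, ]
    text <- g$corpus$documents[[r$doc_id]]
    expect_identical(substr(text, r$start + 1, r$end),
                     g$terminology$concepts[[r$concept_id]]$pref_label)
  }
  # same seed twice -> identical corpora
  g2 <- generate_corpus(n_concepts = 5, n_notes = 10,
                        mentions_per_note = 2, seed = 9)
  expect_identical(g$corpus, g2$corpus)
  expect_identical(g$terminology$concepts, g2$terminology$concepts)
})

test_that("wrap probabilities force the recorded gold context", {
  g <- generate_corpus(n_concepts = 3, n_notes = 5, mentions_per_note = 2,
                       p_negation = 1, seed = 13)
  expect_true(all(g$corpus$gold$negation == "negated"))
  g <- generate_corpus(n_concepts = 3, n_notes = 5, mentions_per_note = 2,
                       p_historical = 1, seed = 13)
  expect_true(all(g$corpus$gold$temporality == "historical"))
  expect_error(generate_corpus(n_concepts = 500), "token pool too small")
})

test_that("gold corpora round-trip through the BRAT writers", {
  g <- generate_corpus(n_concepts = 4, n_notes = 3, mentions_per_note = 2,
                       p_negation = 0.5, seed = 17)
  dir <- withr::local_tempdir()
  write_gold_brat(g$corpus, dir)
  for (id in names(g$corpus$documents)) {
    txt <- readChar(file.path(dir, paste0(id, ".txt")), nchars = 1e6)
    ann <- readChar(file.path(dir, paste0(id, ".ann")), nchars = 1e6)
    back <- read_brat(txt, ann, doc_id = id)
    want <- g$corpus$gold[g$corpus$gold$doc_id == id, , drop = FALSE]
    expect_equal(back$annotations$start, want$start)
    expect_equal(back$annotations$concept_id, want$concept_id)
    expect_equal(back$annotations$negation, want$negation)
  }
})

make_pred <- function(gold, docs) {
  # predictions exactly equal to gold
  lapply(names(docs), function(id) {
    g <- gold[gold$doc_id == id, , drop = FALSE]
    anns <- if (nrow(g) == 0) empty_annotations() else
      as_annotations(data.frame(
        concept_id = g$concept_id, start = g$start, end = g$end,
        surface = substr(rep(docs[[id]], nrow(g)), g$start + 1, g$end),
        match_type = "PREF", negation = g$negation,
        experiencer = g$experiencer, temporality = g$temporality,
        stringsAsFactors = FALSE))
    scored_document(id, docs[[id]], anns)
  })
}

test_that("evaluate: exact agreement gives P = R = F1 = 100%", {
  g <- generate_corpus(n_concepts = 4, n_notes = 6, mentions_per_note = 2,
                       seed = 19)
  pred <- make_pred(g$corpus$gold, g$corpus$documents)
  r <- evaluate(pred, g$corpus, mode = "spans")
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  r2 <- evaluate(pred, g$corpus, mode = "concepts")
  expect_equal(r2$f1, 1)
  expect_error(
    evaluate(list(scored_document("nope", "x")), g$corpus, "spans"),
    "doc_id")
})

test_that("evaluate arithmetic: half right is 50/50/50", {
  g <- generate_corpus(n_concepts = 3, n_notes = 1, mentions_per_note = 2,
                       seed = 23)
  gold <- g$corpus$gold
  doc <- g$corpus$documents[[1]]
  # keep the first gold record, add one spurious prediction
  keep <- gold[1, ]
  anns <- as_annotations(data.frame(
    concept_id = c(keep$concept_id, "SYN:999"),
    start = c(keep$start, 0L), end = c(keep$end, 3L),
    surface = c(substr(doc, keep$start + 1, keep$end), substr(doc, 1, 3)),
    match_type = "PREF"))
  pred <- list(scored_document(keep$doc_id, doc, anns))
  r <- evaluate(pred, g$corpus, mode = "spans")
  expect_equal(r$tp, 1L); expect_equal(r$fp, 1L); expect_equal(r$fn, 1L)
  expect_equal(c(r$precision, r$recall, r$f1), c(0.5, 0.5, 0.5))
})

test_that("span matching equals a brute-force bipartite matching oracle", {
  set.seed(29)
  for (rep in 1:20) {
    keys <- sprintf("d%d %d %d K%d", sample(1:2, 8, TRUE),
                    sample(0:3, 8, TRUE), sample(4:6, 8, TRUE),
                    sample(1:3, 8, TRUE))
    pred_keys <- sample(keys, sample.int(8, 1), replace = TRUE)
    gold_keys <- sample(keys, sample.int(8, 1), replace = TRUE)
    tab_p <- table(pred_keys); tab_g <- table(gold_keys)
    common <- intersect(names(tab_p), names(tab_g))
    fast <- sum(pmin(tab_p[common], tab_g[common]))
    expect_equal(as.integer(fast),
                 oracle_match_count(pred_keys, gold_keys))
  }
})

test_that("context-mode evaluation reports accuracy over matched spans", {
  g <- generate_corpus(n_concepts = 3, n_notes = 4, mentions_per_note = 2,
                       p_negation = 1, seed = 31)
  pred <- make_pred(g$corpus$gold, g$corpus$documents)
  r <- evaluate(pred, g$corpus, mode = "context", dimension = "negation")
  expect_equal(r$accuracy, 1)
  expect_equal(r$f1, 1)
  # flip every prediction to affirmed: accuracy 0, recall 0
  for (i in seq_along(pred)) pred[[i]]$annotations$negation <- "affirmed"
  r0 <- evaluate(pred, g$corpus, mode = "context", dimension = "negation")
  expect_equal(r0$accuracy, 0)
  expect_equal(r0$recall, 0)
})

test_that("metrics are invariant under document permutation", {
  g <- generate_corpus(n_concepts = 4, n_notes = 6, mentions_per_note = 2,
                       seed = 37)
  pred <- make_pred(g$corpus$gold, g$corpus$documents)
  r1 <- evaluate(pred, g$corpus, mode = "spans")
  r2 <- evaluate(rev(pred), g$corpus, mode = "spans")
  expect_identical(r1, r2)
})
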