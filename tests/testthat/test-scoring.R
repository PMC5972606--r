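test_that("compute_cvalue implements the nested-term formula", {
  # single un-nested single-word term: log2(2) * 1 = 1
  cv <- compute_cvalue(term_stats(anns_for_terms("metastasis", 1L)))
  expect_equal(unname(cv["metastasis"]), 1.0)

  # 'breast cancer' f=3 nested only in 'metastatic breast cancer' f=1
  anns <- anns_for_terms(c("breast cancer", "metastatic breast cancer"),
                         c(3L, 1L))
  cv <- compute_cvalue(term_stats(anns))
  expect_equal(unname(cv["metastatic breast cancer"]), log2(4) * 1)
  expect_equal(unname(cv["breast cancer"]), log2(3) * (3 - 1))

  # floor case: f(a) equal to the mean of the parents' frequencies
  anns <- anns_for_terms(c("pain", "chest pain", "leg pain"), c(3L, 2L, 4L))
  cv <- compute_cvalue(term_stats(anns))
  expect_equal(unname(cv["pain"]), 0)

  expect_length(compute_cvalue(term_stats(empty_annotations())), 0)
})

test_that("compute_cvalue equals an independent implementation on random sets", {
  vocab <- c("acute", "chronic", "pain", "chest", "left", "severe", "leg")
  set.seed(11)
  for (rep in 1:40) {
    k <- sample(2:15, 1)
    terms <- unique(vapply(seq_len(k), function(i) {
      paste(sample(vocab, sample.int(3, 1)), collapse = " ")
    }, character(1)))
    freqs <- sample.int(5, length(terms), replace = TRUE)
    got <- compute_cvalue(term_stats(anns_for_terms(terms, freqs)))
    want <- oracle_cvalue(terms, freqs)
    expect_equal(got[sort(names(got))], want[sort(names(want))])
  }
})

test_that("score_annotations: old algorithm sums match-type weights", {
  term <- make_term(list(id = "C1", pref = "cancer", syn = "carcinoma"))
  idx <- build_match_index(term)
  expect_equal(score_annotations(annotate_direct("cancer", idx),
                                 score_config("old"))$score, 10)
  expect_equal(score_annotations(annotate_direct("carcinoma", idx),
                                 score_config("old"))$score, 8)
  # per concept: both annotations of C1 share the concept total 10 + 8
  both <- score_annotations(annotate_direct("cancer and carcinoma", idx),
                            score_config("old"))
  expect_equal(both$score, c(18, 18))
})

test_that("old-score additivity: duplicating annotations doubles scores", {
  term <- fixture_term()
  idx <- build_match_index(term)
  a <- annotate_direct("breast cancer near metastasis", idx)
  once <- score_annotations(a, score_config("old"))
  twice <- score_annotations(rbind(a, a), score_config("old"))
  expect_equal(twice$score[seq_len(nrow(a))], 2 * once$score)
})

test_that("cvalue scoring weights the C-Value by match type", {
  term <- make_term(list(id = "C1", pref = "breast cancer"))
  a <- annotate_direct("breast cancer", build_match_index(term))
  s <- score_annotations(a, score_config("cvalue"))
  expect_equal(s$score, 10 * log2(3))
})

test_that("cvalueh adds distance-decayed contributions for expansions", {
  term <- make_term(list(id = "C1", pref = "ductal carcinoma",
                         parents = "C2"),
                    list(id = "C2", pref = "neoplasm"))
  idx <- build_match_index(term)
  ex <- expand_hierarchy(annotate_direct("ductal carcinoma", idx), term, 1)
  s <- score_annotations(ex, score_config("cvalueh"))
  # C1: direct, 10 * log2(3); C2: expanded only, (10 - 1) * log2(3)
  expect_equal(unique(s$score[s$concept_id == "C1"]), 10 * log2(3))
  expect_equal(unique(s$score[s$concept_id == "C2"]), 9 * log2(3))
  # plain cvalue ignores the expanded annotation entirely
  s0 <- score_annotations(ex, score_config("cvalue"))
  expect_equal(unique(s0$score[s0$concept_id == "C2"]), 0)
})

test_that("multi-word terms outscore single-word terms at equal frequency", {
  set.seed(23)
  vocab <- c("renal", "acute", "failure", "distal", "left", "ulcer")
  for (rep in 1:100) {
    f <- sample.int(5, 1)
    long_toks <- sample(vocab, sample(2:3, 1))
    short_tok <- sample(setdiff(vocab, long_toks), 1)
    anns <- anns_for_terms(c(paste(long_toks, collapse = " "), short_tok),
                           c(f, f))
    s <- score_annotations(anns, score_config("cvalue"))
    long_score <- s$score[s$concept_id == "T01"][1]
    short_score <- s$score[s$concept_id == "T02"][1]
    expect_gt(long_score, short_score)
  }
})

test_that("filter_by_score implements nearest-rank percentile and ties", {
  anns <- as_annotations(data.frame(
    concept_id = paste0("C", 1:5), start = 0:4, end = 1:5,
    surface = letters[1:5], match_type = "PREF",
    score = c(10, 5, 3, 1, 1)))
  top <- filter_by_score(anns, "percentile", 90)
  expect_equal(top$score, 10)
  # absolute threshold 0 is the identity
  expect_identical(filter_by_score(anns, "absolute", 0), anns)
  # percentile 0 is the identity
  expect_identical(filter_by_score(anns, "percentile", 0), anns)
  # all-equal scores: ties at the percentile are all retained
  anns$score <- rep(4, 5)
  expect_equal(nrow(filter_by_score(anns, "percentile", 90)), 5)
  # unscored annotations are a state error
  anns$score <- NA_real_
  expect_error(filter_by_score(anns, "absolute", 1), "score")
})

test_that("retained set shrinks monotonically as the threshold rises", {
  set.seed(31)
  anns <- as_annotations(data.frame(
    concept_id = paste0("C", 1:20), start = 0:19, end = 1:20,
    surface = rep("x", 20), match_type = "PREF",
    score = round(stats::runif(20, 0, 50))))
  sizes <- vapply(seq(0, 100, by = 10), function(th) {
    nrow(filter_by_score(anns, "percentile", th))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1], 20)
})
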