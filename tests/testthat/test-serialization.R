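test_that("write_brat emits T, A and N lines per the standoff grammar", {
  text <- "history of breast cancer"
  anns <- as_annotations(data.frame(
    concept_id = "C1", start = 11L, end = 24L, surface = "breast cancer",
    match_type = "PREF", negation = "negated", experiencer = "patient",
    temporality = "recent"))
  sd <- scored_document("d1", text, anns)
  term <- fixture_term()
  map <- load_semantic_groups()
  out <- write_brat(sd, group_of = brat_group_resolver(term, map),
                    term = term)
  expect_identical(out$txt, text)
  lines <- strsplit(out$ann, "\n")[[1]]
  expect_equal(lines[1], "T1\tDISO 11 24\tbreast cancer")
  expect_equal(lines[2], "A1\tNegated T1")
  expect_equal(lines[3], "N1\tReference T1 DICT:C1\tbreast cancer")

  # zero annotations: empty .ann, text verbatim
  empty <- write_brat(scored_document("d2", text))
  expect_identical(empty$txt, text)
  expect_identical(empty$ann, "")

  # no resolver -> generic Entity label
  plain <- write_brat(sd)
  expect_match(strsplit(plain$ann, "\n")[[1]][1], "^T1\tEntity 11 24")
})

test_that("read_brat inverts write_brat and checks integrity", {
  text <- "mother had breast cancer"
  anns <- as_annotations(data.frame(
    concept_id = c("C1", "C2"), start = c(11L, 18L), end = c(24L, 24L),
    surface = c("breast cancer", "cancer"), match_type = "PREF",
    negation = "affirmed", experiencer = c("other", "patient"),
    temporality = "recent"))
  sd <- scored_document("d1", text, anns)
  out <- write_brat(sd)
  back <- read_brat(out$txt, out$ann, doc_id = "d1")
  expect_identical(back$text, text)
  expect_identical(back$annotations[, c("concept_id", "start", "end",
                                        "surface", "negation",
                                        "experiencer", "temporality")],
                   anns[, c("concept_id", "start", "end", "surface",
                            "negation", "experiencer", "temporality")])
  # corrupted offsets make the surface disagree: integrity error naming
  # the id
  bad <- sub("11 24", "10 24", out$ann, fixed = TRUE)
  expect_error(read_brat(out$txt, bad), "T1")
  # unknown line types are skipped with a warning
  expect_warning(read_brat(out$txt, paste0(out$ann, "R1\tweird\n")),
                 "skipping")
})

test_that("BRAT round-trip preserves spans, labels and attributes", {
  set.seed(59)
  for (rep in 1:20) {
    sd <- random_scored_document(sprintf("doc%02d", rep))
    out <- write_brat(sd)
    back <- read_brat(out$txt, out$ann, doc_id = sd$doc_id)
    cols <- c("concept_id", "start", "end", "surface", "negation",
              "experiencer", "temporality")
    expect_identical(back$annotations[, cols], sd$annotations[, cols])
    # write(read(x)) is byte-identical: labels and attributes survive
    again <- write_brat(back)
    expect_identical(again$ann, out$ann)
    # writers are pure
    expect_identical(write_brat(sd)$ann, out$ann)
  }
})

test_that("JSON uses 1-based inclusive from/to and inverts exactly", {
  conv <- span_to_ncbo(11L, 24L)
  expect_equal(conv, list(from = 12L, to = 24L))
  expect_equal(span_from_ncbo(conv$from, conv$to),
               list(start = 11L, end = 24L))

  expect_identical(write_json(scored_document("d", "text")), "[]")

  set.seed(61)
  for (rep in 1:20) {
    sd <- random_scored_document(sprintf("doc%02d", rep))
    parsed <- jsonlite::fromJSON(write_json(sd), simplifyVector = FALSE)
    got <- do.call(rbind, lapply(parsed, function(rec) {
      do.call(rbind, lapply(rec$annotations, function(a) {
        back <- span_from_ncbo(a$from, a$to)
        data.frame(concept_id = rec$annotatedConcept$id,
                   start = back$start, end = back$end, surface = a$text,
                   stringsAsFactors = FALSE)
      }))
    }))
    got <- got[order(got$start, got$end, got$concept_id), , drop = FALSE]
    want <- sd$annotations[order(sd$annotations$start, sd$annotations$end,
                                 sd$annotations$concept_id),
                           c("concept_id", "start", "end", "surface")]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("RDF output is N-Triples with the fixed emission rule", {
  sd <- scored_document("d1", "breast cancer", as_annotations(data.frame(
    concept_id = "C1", start = 0L, end = 13L, surface = "breast cancer",
    match_type = "PREF", score = 2.5, negation = "negated",
    experiencer = "patient", temporality = "recent")))
  nt <- write_rdf(sd, "http://example.org/a/")
  lines <- strsplit(nt, "\n")[[1]]
  # 2 document triples + 10 per annotation
  expect_length(lines, 12)
  # every line parses against an N-Triples line grammar (subject IRI,
  # predicate IRI, IRI or literal object, terminal dot)
  nt_line <- paste0(
    "^<[^>]+> <[^>]+> ",
    "(<[^>]+>|\"(\\\\.|[^\"\\\\])*\"(\\^\\^<[^>]+>)?) \\.$")
  expect_true(all(grepl(nt_line, lines)))
  expect_true(any(grepl("\"negated\"", lines)))
  expect_true(any(grepl("\"2.5\"", lines, fixed = TRUE)))

  # zero annotations: document node only
  nt0 <- write_rdf(scored_document("d2", "x"))
  expect_length(strsplit(nt0, "\n")[[1]], 2)
  expect_error(write_rdf(sd, "not an iri"), "base_iri")
  # literals are escaped
  sd2 <- scored_document("d3", "say \"hi\"", as_annotations(data.frame(
    concept_id = "C1", start = 5L, end = 7L, surface = "hi",
    match_type = "PREF")))
  expect_true(all(grepl(nt_line, strsplit(write_rdf(sd2), "\n")[[1]])))
})

test_that("TSV output has a header plus one row per annotation", {
  sd <- scored_document("d1", "breast cancer", as_annotations(data.frame(
    concept_id = "C1", start = 0L, end = 13L, surface = "breast cancer",
    match_type = "PREF", score = 1.5, negation = "negated",
    experiencer = "patient", temporality = "recent")))
  lines <- strsplit(write_tsv(sd), "\n")[[1]]
  expect_length(lines, 2)
  expect_equal(lines[2],
               "d1\tC1\t0\t13\tbreast cancer\tPREF\t1.5\tnegated\tpatient\trecent")
  expect_length(strsplit(write_tsv(scored_document("d", "x")), "\n")[[1]], 1)
  set.seed(67)
  sd <- random_scored_document("r")
  expect_length(strsplit(write_tsv(sd), "\n")[[1]],
                nrow(sd$annotations) + 1)
})
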