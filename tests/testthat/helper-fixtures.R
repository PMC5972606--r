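# Shared fixtures and independent oracles for the test suite.

# Build a terminology in code (no files): concepts given as
# list(id =, pref =, syn =, types =, parents =)
make_term <- function(...) {
  specs <- list(...)
  tmp <- withr::local_tempfile(fileext = ".tsv",
                               .local_envir = parent.frame())
  join <- function(x) paste(x, collapse = "|")
  rows <- vapply(specs, function(s) {
    paste(s$id, s$pref, join(s$syn %||% character()),
          join(s$types %||% character()),
          join(s$parents %||% character()),
          s$source %||% "test", sep = "\t")
  }, character(1))
  writeLines(c("id\tpref_label\tsynonyms\tsemantic_types\tparents\tsource",
               rows), tmp)
  load_terminology(tmp, "tsv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent recognizer oracle: test every (i, j) token window of the
# document against every label of the terminology
oracle_annotate <- function(doc, term) {
  toks <- clinannotate::normalize(doc)
  idx <- term$label_index
  hits <- list()
  if (nrow(toks) > 0 && nrow(idx) > 0) {
    label_toks <- strsplit(idx$label, " ", fixed = TRUE)
    # windows longer than the longest label cannot match any label, so the
    # scan over all (i, j) windows may stop there and stay exhaustive
    max_len <- max(lengths(label_toks))
    for (i in seq_len(nrow(toks))) {
      for (j in i:min(nrow(toks), i + max_len - 1L)) {
        window <- toks$token[i:j]
        for (r in seq_len(nrow(idx))) {
          if (length(label_toks[[r]]) == length(window) &&
              all(label_toks[[r]] == window)) {
            hits[[length(hits) + 1L]] <- data.frame(
              concept_id = idx$concept_id[r], start = toks$start[i],
              end = toks$end[j], match_type = idx$match_type[r],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(concept_id = character(), start = integer(),
                      end = integer(), match_type = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  # PREF beats SYN on the same span+concept
  out <- out[order(out$start, out$end, out$concept_id, out$match_type), ,
             drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end", "concept_id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# random dictionary + document instances for oracle equivalence
random_instance <- function(n_labels = 30, n_doc_tokens = 200) {
  vocab <- c("alpha", "beta", "gamma", "delta", "omega", "zeta", "kappa",
             "sigma", "theta", "lambda")
  n_lab <- sample.int(n_labels, 1)
  labels <- unique(vapply(seq_len(n_lab), function(i) {
    paste(sample(vocab, sample.int(3, 1), replace = TRUE), collapse = " ")
  }, character(1)))
  specs <- lapply(seq_along(labels), function(i) {
    list(id = sprintf("R%02d", i), pref = labels[i])
  })
  term <- do.call(make_term, specs)
  punct <- c(" ", " ", " ", ", ", ". ", "; ", " - ")
  doc <- paste0(
    paste0(sample(vocab, sample.int(n_doc_tokens, 1), replace = TRUE),
           sample(punct, sample.int(n_doc_tokens, 1), replace = TRUE),
           collapse = ""))
  list(term = term, doc = doc)
}

# --- independent C-Value oracle on a term multiset given as a data frame
# term / freq. Nesting is decided by space-padded substring containment,
# a different mechanism than the implementation's token-vector scan.
oracle_cvalue <- function(terms, freqs) {
  pad <- paste0(" ", terms, " ")
  nwords <- lengths(strsplit(terms, " ", fixed = TRUE))
  out <- numeric(length(terms))
  for (i in seq_along(terms)) {
    parents <- which(nwords > nwords[i] &
                       vapply(pad, function(p) grepl(pad[i], p,
                                                     fixed = TRUE),
                              logical(1)))
    base <- log2(nwords[i] + 1)
    out[i] <- if (length(parents) == 0) {
      base * freqs[i]
    } else {
      max(0, base * (freqs[i] - sum(freqs[parents]) / length(parents)))
    }
  }
  stats::setNames(out, terms)
}

# annotations carrying the given terms with the given occurrence counts,
# laid out in a synthetic document so term_stats() sees exactly them
anns_for_terms <- function(terms, freqs) {
  doc_parts <- character(); anns <- list(); offset <- 0L
  for (i in seq_along(terms)) {
    for (k in seq_len(freqs[i])) {
      anns[[length(anns) + 1L]] <- data.frame(
        concept_id = sprintf("T%02d", i), start = offset,
        end = offset + nchar(terms[i]), surface = terms[i],
        match_type = "PREF", stringsAsFactors = FALSE)
      offset <- offset + nchar(terms[i]) + 1L
    }
  }
  as_annotations(do.call(rbind, anns))
}

# --- brute-force maximum bipartite matching oracle for span evaluation:
# recursion over gold records (small instances only)
oracle_match_count <- function(pred_keys, gold_keys) {
  best <- 0L
  recurse <- function(g, used) {
    if (g > length(gold_keys)) {
      best <<- max(best, sum(used >= 0))
      return(invisible())
    }
    cand <- which(pred_keys == gold_keys[g])
    cand <- setdiff(cand, used[used >= 0])
    for (p in cand) recurse(g + 1L, c(used, p))
    recurse(g + 1L, c(used, -1L))   # leave this gold unmatched
  }
  recurse(1L, integer())
  best
}

# shortest ancestor distances by exhaustive path enumeration on a parent
# map (id -> character vector of parents); independent of the BFS
oracle_ancestor_distances <- function(parents_of, id) {
  dists <- new.env(parent = emptyenv())
  walk <- function(node, d, path) {
    for (p in parents_of[[node]] %||% character()) {
      if (p %in% path) next
      cur <- dists[[p]]
      if (is.null(cur) || d + 1L < cur) dists[[p]] <- d + 1L
      walk(p, d + 1L, c(path, p))
    }
  }
  walk(id, 0L, id)
  out <- unlist(as.list(dists))
  if (is.null(out)) integer() else out[order(names(out))]
}

# randomized scored documents for serialization round-trip tests
random_scored_document <- function(doc_id) {
  words <- sample(c("alpha", "beta", "gamma", "delta", "omega"), 30,
                  replace = TRUE)
  text <- paste(words, collapse = " ")
  toks <- clinannotate::normalize(text)
  n <- sample.int(6, 1)
  i <- sort(sample.int(nrow(toks) - 1, n))
  j <- pmin(i + sample.int(3, n, replace = TRUE) - 1L, nrow(toks))
  anns <- data.frame(
    concept_id = sprintf("K%d", sample.int(9, n, replace = TRUE)),
    start = toks$start[i], end = toks$end[j],
    surface = substr(rep(text, n), toks$start[i] + 1L, toks$end[j]),
    match_type = sample(c("PREF", "SYN"), n, replace = TRUE),
    score = round(stats::runif(n, 0, 20), 3),
    negation = sample(c("affirmed", "negated"), n, replace = TRUE),
    experiencer = sample(c("patient", "other"), n, replace = TRUE),
    temporality = sample(c("recent", "historical", "hypothetical"), n,
                         replace = TRUE),
    stringsAsFactors = FALSE)
  scored_document(doc_id, text, as_annotations(anns))
}

# tiny default terminology used across files
fixture_term <- function() {
  make_term(
    list(id = "C1", pref = "breast cancer",
         syn = "cancer of the breast", types = "T047"),
    list(id = "C2", pref = "cancer", types = "T191", parents = "C1"),
    list(id = "C3", pref = "metastasis", types = "T191"),
    list(id = "C4", pref = "chest pain", types = "T184"),
    list(id = "C5", pref = "aspirin", types = "T121"))
}
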