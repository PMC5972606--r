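#' Tokenize text for matching
#'
#' The single normalization used everywhere labels and documents meet:
#' tokens are maximal runs of Unicode letters and digits, lowercased, with
#' their original 0-based end-exclusive code-point offsets. Hyphens and
#' apostrophes split (each side becomes its own token); all punctuation is
#' invisible to matching.
#'
#' @param text character scalar.
#' @return data frame with columns `token`, `start`, `end` (zero rows for
#'   empty text).
#' @export
normalize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[\\p{L}\\p{N}]+", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(token = tolower(regmatches(text, list(m))[[1]]),
             start = starts, end = starts + lens,
             stringsAsFactors = FALSE)
}

# normalized form of a label: its token sequence joined by single spaces
normalize_label <- function(label) {
  paste(normalize(label)$token, collapse = " ")
}

#' Build a match index from a terminology
#'
#' Indexes every normalized label of the terminology by its first token so
#' that document scanning is linear in document length times candidate
#' labels per token.
#'
#' @param term terminology.
#' @return object of class `match_index`.
#' @export
build_match_index <- function(term) {
  stopifnot(inherits(term, "terminology"))
  idx <- term$label_index
  env <- new.env(parent = emptyenv(), size = max(2L, nrow(idx)))
  if (nrow(idx) > 0) {
    token_lists <- strsplit(idx$label, " ", fixed = TRUE)
    firsts <- vapply(token_lists, `[[`, character(1), 1)
    for (i in seq_len(nrow(idx))) {
      key <- firsts[i]
      entry <- list(tokens = token_lists[[i]],
                    concept_id = idx$concept_id[i],
                    match_type = idx$match_type[i])
      env[[key]] <- c(env[[key]], list(entry))
    }
  }
  structure(list(by_first_token = env, terminology = term),
            class = "match_index")
}

#' Direct dictionary annotation of a document
#'
#' Finds every occurrence (including nested and overlapping ones) where the
#' normalized token sequence of a terminology label equals a contiguous
#' token sequence of the document. The annotation span runs from the first
#' matched token's start to the last matched token's end in the original
#' text. When the same span and concept is reachable through both a
#' preferred label and a synonym, a single PREF annotation is kept. Output
#' is sorted by (start, -length, concept_id) and is deterministic.
#'
#' @param doc document text.
#' @param index match index from [build_match_index()].
#' @return annotation data frame (`expansion_distance` all 0).
#' @export
annotate_direct <- function(doc, index) {
  stopifnot(inherits(index, "match_index"))
  toks <- normalize(doc)
  n <- nrow(toks)
  if (n == 0) return(empty_annotations())
  hits_concept <- character(); hits_start <- integer()
  hits_end <- integer(); hits_type <- character()
  env <- index$by_first_token
  for (i in seq_len(n)) {
    cands <- env[[toks$token[i]]]
    if (is.null(cands)) next
    for (cand in cands) {
      k <- length(cand$tokens)
      if (i + k - 1L > n) next
      if (all(toks$token[i:(i + k - 1L)] == cand$tokens)) {
        hits_concept <- c(hits_concept, cand$concept_id)
        hits_start <- c(hits_start, toks$start[i])
        hits_end <- c(hits_end, toks$end[i + k - 1L])
        hits_type <- c(hits_type, cand$match_type)
      }
    }
  }
  if (length(hits_concept) == 0) return(empty_annotations())
  anns <- data.frame(concept_id = hits_concept, start = hits_start,
                     end = hits_end,
                     surface = substr(rep(doc, length(hits_start)),
                                      hits_start + 1L, hits_end),
                     match_type = hits_type, stringsAsFactors = FALSE)
  # same span+concept via PREF and SYN: keep PREF
  anns <- anns[order(anns$start, anns$end, anns$concept_id,
                     anns$match_type), , drop = FALSE]
  anns <- anns[!duplicated(anns[, c("start", "end", "concept_id")]),
               , drop = FALSE]
  sort_annotations(as_annotations(anns))
}

#' Expand annotations along the is_a hierarchy
#'
#' For each direct annotation and each ancestor of its concept at distance
#' d <= `max_depth`, adds an annotation with the same span and surface, the
#' ancestor's concept id, the inherited match type, and
#' `expansion_distance = d`. Duplicate span+concept pairs keep the minimal
#' distance.
#'
#' @param anns annotation data frame (direct annotations).
#' @param term terminology containing every annotated concept.
#' @param max_depth expansion depth; 0 returns the input unchanged.
#' @return annotation data frame including the expanded annotations.
#' @export
expand_hierarchy <- function(anns, term, max_depth = 0L) {
  stopifnot(inherits(term, "terminology"), max_depth >= 0)
  anns <- as_annotations(anns)
  unknown <- setdiff(anns$concept_id, names(term$concepts))
  if (length(unknown) > 0) {
    stop("unknown concept id(s) in annotations: ",
         paste(unknown, collapse = ", "))
  }
  if (max_depth == 0L || nrow(anns) == 0) return(anns)
  direct <- anns[anns$expansion_distance == 0L, , drop = FALSE]
  anc_cache <- lapply(unique(direct$concept_id), ancestors, term = term,
                      max_depth = max_depth)
  names(anc_cache) <- unique(direct$concept_id)
  extra <- lapply(seq_len(nrow(direct)), function(i) {
    anc <- anc_cache[[direct$concept_id[i]]]
    if (nrow(anc) == 0) return(NULL)
    out <- direct[rep(i, nrow(anc)), , drop = FALSE]
    out$concept_id <- anc$id
    out$expansion_distance <- anc$distance
    out
  })
  out <- do.call(rbind, c(list(anns), extra, list(make.row.names = FALSE)))
  # dedupe span+concept at minimal distance
  out <- out[order(out$start, out$end, out$concept_id,
                   out$expansion_distance), , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end", "concept_id")]),
             , drop = FALSE]
  sort_annotations(out)
}

#' Keep only annotations not contained in a longer annotation
#'
#' Post-filter mirroring the CLI `--longest-only` flag: drops every
#' annotation whose span is strictly contained in another annotation's
#' span (containment is by span only, regardless of concept).
#'
#' @param anns annotation data frame.
#' @return filtered annotation data frame, order preserved.
#' @export
filter_longest_only <- function(anns) {
  anns <- as_annotations(anns)
  if (nrow(anns) <= 1) return(anns)
  keep <- vapply(seq_len(nrow(anns)), function(i) {
    contained <- anns$start <= anns$start[i] & anns$end >= anns$end[i] &
      (anns$end - anns$start) > (anns$end[i] - anns$start[i])
    !any(contained)
  }, logical(1))
  out <- anns[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
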