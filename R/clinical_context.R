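#' Sentence splitting
#'
#' Splits a document at '.', '!', '?', and at a newline followed by
#' whitespace or end of text. A configurable abbreviation list suppresses
#' splits after known abbreviations ("Dr.", "e.g.", ...). Offsets are
#' exact 0-based end-exclusive code-point positions; a document with no
#' boundary is returned as a single sentence. Leading/trailing whitespace
#' between sentences belongs to no sentence.
#'
#' @param doc document text.
#' @param abbreviations lowercased abbreviation tokens (without the final
#'   period) after which a '.' does not end a sentence.
#' @return data frame with columns `start`, `end`, `text` (zero rows for
#'   empty input).
#' @export
split_sentences <- function(doc,
                            abbreviations = c("dr", "mr", "mrs", "vs",
                                              "e.g", "i.e")) {
  stopifnot(is.character(doc), length(doc) == 1)
  n <- nchar(doc)
  out_start <- integer(); out_end <- integer()
  if (n > 0) {
    chars <- strsplit(doc, "", fixed = TRUE)[[1]]
    abbreviations <- tolower(abbreviations)
    sent_start <- NA_integer_  # 0-based start of current sentence
    i <- 1L
    close_sentence <- function(end0) {
      if (!is.na(sent_start) && end0 > sent_start) {
        out_start <<- c(out_start, sent_start)
        out_end <<- c(out_end, end0)
      }
      sent_start <<- NA_integer_
    }
    while (i <= n) {
      ch <- chars[i]
      if (is.na(sent_start) && !grepl("^\\s$", ch)) sent_start <- i - 1L
      boundary <- FALSE
      if (ch %in% c("!", "?")) {
        boundary <- TRUE
      } else if (ch == ".") {
        # a period glued to a following letter/digit is word-internal
        # ("e.g.", "i.e.", decimal points), never a boundary
        if (i < n && grepl("^[\\p{L}\\p{N}]$", chars[i + 1L], perl = TRUE)) {
          i <- i + 1L
          next
        }
        # word immediately before the period, including internal periods so
        # "e.g." is seen as "e.g"
        j <- i - 1L
        while (j >= 1 && grepl("^[\\p{L}\\p{N}.]$", chars[j], perl = TRUE)) {
          j <- j - 1L
        }
        before <- tolower(paste(chars[seq_len(i - 1L)][seq.int(j + 1L,
                          length.out = i - 1L - j)], collapse = ""))
        before <- sub("\\.$", "", before)
        if (!(before %in% abbreviations)) boundary <- TRUE
      } else if (ch == "\n") {
        if (i == n || grepl("^\\s$", chars[i + 1L])) boundary <- TRUE
      }
      if (boundary) {
        end0 <- if (ch == "\n") i - 1L else i  # newline itself excluded
        close_sentence(end0)
      }
      i <- i + 1L
    }
    close_sentence(n)
  }
  data.frame(start = out_start, end = out_end,
             text = substr(rep(doc, length(out_start)), out_start + 1L,
                           out_end),
             stringsAsFactors = FALSE)
}

#' Load a trigger lexicon for context detection
#'
#' Pipe-delimited rows `phrase|category|role|direction`; `#` starts a
#' comment. Categories: negation, experiencer_other, historical,
#' hypothetical. Roles: trigger (opens a scope), pseudo (a longer phrase
#' that suppresses a trigger reading), termination (closes a scope).
#' Directions (trigger role only): forward, backward, both.
#'
#' @param path lexicon file; defaults to the lexicon shipped with the
#'   package, distilled from the public NegEx/ConText term lists.
#' @return data frame of class `trigger_lexicon` with columns `phrase`
#'   (normalized), `category`, `role`, `direction`.
#' @export
load_trigger_lexicon <- function(path = default_lexicon_path()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad) > 0) {
    stop("malformed trigger lexicon row(s): ",
         paste(lines[bad], collapse = "; "))
  }
  lex <- data.frame(phrase = vapply(parts, function(p) normalize_label(p[1]),
                                    character(1)),
                    category = trimws(vapply(parts, `[[`, character(1), 2)),
                    role = trimws(vapply(parts, `[[`, character(1), 3)),
                    direction = trimws(vapply(parts, `[[`, character(1), 4)),
                    stringsAsFactors = FALSE)
  # termination rows may carry '-' placeholders; category/direction ignored
  lex$category[lex$role == "termination"] <- ""
  lex$direction[lex$role == "termination"] <- ""
  ok_cat <- c("negation", "experiencer_other", "historical", "hypothetical")
  stopifnot(all(lex$category %in% ok_cat | lex$role == "termination"),
            all(lex$role %in% c("trigger", "pseudo", "termination")),
            all(lex$direction %in% c("forward", "backward", "both", "")))
  lex <- lex[nzchar(lex$phrase), , drop = FALSE]
  rownames(lex) <- NULL
  class(lex) <- c("trigger_lexicon", class(lex))
  lex
}

#' @rdname load_trigger_lexicon
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "context_triggers.txt", package = "clinannotate",
              mustWork = TRUE)
}

# locate every lexicon phrase occurrence in a token table; returns token
# index ranges [i, j] plus character spans
find_phrase_occurrences <- function(toks, lex) {
  if (nrow(toks) == 0 || nrow(lex) == 0) {
    return(data.frame(lex_row = integer(), tok_from = integer(),
                      tok_to = integer(), start = integer(),
                      end = integer()))
  }
  phrase_toks <- strsplit(lex$phrase, " ", fixed = TRUE)
  out <- vector("list", 0)
  for (r in seq_len(nrow(lex))) {
    p <- phrase_toks[[r]]
    k <- length(p)
    limit <- nrow(toks) - k + 1L
    if (limit < 1) next
    for (i in seq_len(limit)) {
      if (all(toks$token[i:(i + k - 1L)] == p)) {
        out[[length(out) + 1L]] <- data.frame(
          lex_row = r, tok_from = i, tok_to = i + k - 1L,
          start = toks$start[i], end = toks$end[i + k - 1L])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(lex_row = integer(), tok_from = integer(),
                      tok_to = integer(), start = integer(),
                      end = integer()))
  }
  do.call(rbind, out)
}

#' Detect clinical context of annotations
#'
#' ConText-style post-processing of the sentence each annotation appears
#' in. Every annotation starts at the defaults affirmed / patient /
#' recent. Within a sentence, trigger phrases are located with the same
#' normalization as the recognizer; a forward trigger's scope runs from
#' the token after the trigger to the end of the sentence, cut short at
#' the first colon or termination term; a backward trigger's scope runs
#' from the start of the sentence (or the nearest preceding colon or
#' termination term) to the token before the trigger. Annotations whose
#' span falls inside a scope take the trigger's category value (negation
#' -> negated, experiencer_other -> other, historical -> historical,
#' hypothetical -> hypothetical; historical wins over hypothetical when
#' both apply). A trigger occurrence contained in a longer pseudo-phrase
#' occurrence is inert, and triggers overlapping an annotation's own span
#' never modify that annotation.
#'
#' @param doc document text.
#' @param anns annotation data frame with valid spans in `doc`.
#' @param lexicon a [load_trigger_lexicon()] table.
#' @param dimensions which context dimensions to set; the others are left
#'   at their defaults.
#' @param window optional scope cap in tokens (default `Inf`: ConText
#'   behavior, scope to sentence end).
#' @return the annotations with `negation`, `experiencer`, `temporality`
#'   set for the requested dimensions.
#' @export
apply_context <- function(doc, anns, lexicon = load_trigger_lexicon(),
                          dimensions = c("negation", "experiencer",
                                         "temporality"),
                          window = Inf) {
  dimensions <- match.arg(dimensions, several.ok = TRUE)
  anns <- as_annotations(anns)
  check_span_fidelity(anns, doc)
  if ("negation" %in% dimensions) anns$negation <- "affirmed"
  if ("experiencer" %in% dimensions) anns$experiencer <- "patient"
  if ("temporality" %in% dimensions) anns$temporality <- "recent"
  if (nrow(anns) == 0) return(anns)
  sents <- split_sentences(doc)
  sent_of <- vapply(seq_len(nrow(anns)), function(i) {
    hit <- which(sents$start <= anns$start[i] & anns$start[i] < sents$end)
    if (length(hit) == 0) {
      stop("annotation at [", anns$start[i], ",", anns$end[i],
           ") is not covered by any sentence")
    }
    if (anns$end[i] > sents$end[hit[1]]) {
      stop("annotation at [", anns$start[i], ",", anns$end[i],
           ") crosses a sentence boundary")
    }
    hit[1]
  }, integer(1))
  cat_value <- c(negation = "negated", experiencer_other = "other",
                 historical = "historical", hypothetical = "hypothetical")
  cat_dim <- c(negation = "negation", experiencer_other = "experiencer",
               historical = "temporality", hypothetical = "temporality")
  for (s in unique(sent_of)) {
    stext <- sents$text[s]
    toks <- normalize(stext)
    if (nrow(toks) == 0) next
    toks$start <- toks$start + sents$start[s]   # document offsets
    toks$end <- toks$end + sents$start[s]
    occ <- find_phrase_occurrences(toks, lexicon)
    if (nrow(occ) == 0) next
    role <- lexicon$role[occ$lex_row]
    # pseudo suppression: a trigger occurrence token-contained in a longer
    # pseudo occurrence is inert
    pseudo <- occ[role == "pseudo", , drop = FALSE]
    trig <- occ[role == "trigger", , drop = FALSE]
    if (nrow(trig) > 0 && nrow(pseudo) > 0) {
      inert <- vapply(seq_len(nrow(trig)), function(i) {
        any(pseudo$tok_from <= trig$tok_from[i] &
              pseudo$tok_to >= trig$tok_to[i] &
              (pseudo$tok_to - pseudo$tok_from) >
                (trig$tok_to[i] - trig$tok_from[i]) &
              lexicon$category[pseudo$lex_row] ==
                lexicon$category[trig$lex_row[i]])
      }, logical(1))
      trig <- trig[!inert, , drop = FALSE]
    }
    if (nrow(trig) == 0) next
    term_occ <- occ[role == "termination", , drop = FALSE]
    # colons close scopes just like termination terms; model each colon as
    # a zero-width stop at its character position
    colon_pos <- gregexpr(":", stext, fixed = TRUE)[[1]]
    stops_start <- c(term_occ$start,
                     if (colon_pos[1] != -1) colon_pos - 1L + sents$start[s])
    stops_end <- c(term_occ$end,
                   if (colon_pos[1] != -1) colon_pos + sents$start[s])
    ann_rows <- which(sent_of == s)
    for (t in seq_len(nrow(trig))) {
      lexrow <- lexicon[trig$lex_row[t], ]
      dim <- cat_dim[[lexrow$category]]
      if (!(dim %in% dimensions)) next
      dirs <- if (lexrow$direction == "both") c("forward", "backward")
              else lexrow$direction
      for (dir in dirs) {
        if (dir == "forward") {
          scope_from <- trig$end[t]
          after <- stops_start[stops_start >= trig$end[t]]
          scope_to <- if (length(after) > 0) min(after) else sents$end[s]
          if (is.finite(window)) {
            in_scope <- which(toks$start >= scope_from)
            if (length(in_scope) > window) {
              scope_to <- min(scope_to, toks$end[in_scope[window]])
            }
          }
        } else {
          scope_to <- trig$start[t]
          before <- stops_end[stops_end <= trig$start[t]]
          scope_from <- if (length(before) > 0) max(before) else sents$start[s]
          if (is.finite(window)) {
            in_scope <- which(toks$end <= scope_to & toks$start >= scope_from)
            if (length(in_scope) > window) {
              scope_from <- max(scope_from,
                                toks$start[in_scope[length(in_scope) -
                                                      window + 1L]])
            }
          }
        }
        if (scope_from >= scope_to) next
        for (a in ann_rows) {
          if (anns$start[a] >= scope_from && anns$end[a] <= scope_to &&
              # trigger overlapping the annotation's own span is ignored
              !(trig$start[t] < anns$end[a] && trig$end[t] > anns$start[a])) {
            val <- cat_value[[lexrow$category]]
            if (dim == "temporality" && anns$temporality[a] == "historical" &&
                val == "hypothetical") {
              next  # historical beats hypothetical
            }
            anns[[dim]][a] <- val
          }
        }
      }
    }
  }
  anns
}
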