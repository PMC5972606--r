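#' Annotation tables
#'
#' Annotations are plain data frames with one row per recognized concept
#' occurrence. Character offsets follow the BRAT standoff convention
#' throughout the package: 0-based start, end-exclusive, counted over
#' Unicode code points. `surface` is always the exact slice
#' `substr(text, start + 1, end)` of the source document.
#'
#' Columns:
#' \describe{
#'   \item{concept_id}{character, terminology concept identifier}
#'   \item{start,end}{integer, 0-based end-exclusive code-point offsets}
#'   \item{surface}{character, exact matched slice of the document}
#'   \item{match_type}{character, `"PREF"` or `"SYN"`}
#'   \item{expansion_distance}{integer, 0 for direct matches, is_a distance
#'     for hierarchy-expanded annotations}
#'   \item{score}{numeric, `NA` until a scoring algorithm has run}
#'   \item{negation}{character, `"affirmed"`/`"negated"` or `NA` (unset)}
#'   \item{experiencer}{character, `"patient"`/`"other"` or `NA`}
#'   \item{temporality}{character, `"recent"`/`"historical"`/`"hypothetical"`
#'     or `NA`}
#' }
#'
#' @param n number of blank rows to allocate.
#' @return a zero-or-more row annotation data frame with the columns above.
#' @export
empty_annotations <- function(n = 0L) {
  data.frame(
    concept_id = character(n),
    start = integer(n),
    end = integer(n),
    surface = character(n),
    match_type = character(n),
    expansion_distance = integer(n),
    score = rep(NA_real_, n),
    negation = rep(NA_character_, n),
    experiencer = rep(NA_character_, n),
    temporality = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
}

ANN_COLS <- names(empty_annotations())

#' Coerce a data frame to a full annotation table
#'
#' Fills in missing optional columns (score, context dimensions) with their
#' unset value and orders the columns canonically.
#'
#' @param df data frame with at least concept_id/start/end/surface/match_type.
#' @return annotation data frame.
#' @export
as_annotations <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("concept_id", "start", "end", "surface", "match_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(df$expansion_distance)) df$expansion_distance <- 0L
  if (is.null(df$score)) df$score <- NA_real_
  for (col in c("negation", "experiencer", "temporality")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$expansion_distance <- as.integer(df$expansion_distance)
  df$score <- as.numeric(df$score)
  rownames(df) <- NULL
  df[, ANN_COLS]
}

#' Check span fidelity of annotations against a document
#'
#' Verifies `0 <= start < end <= nchar(text)` and that each `surface` equals
#' the corresponding document slice.
#'
#' @param anns annotation data frame.
#' @param text source document.
#' @return invisibly `TRUE`; stops with an integrity error otherwise.
#' @export
check_span_fidelity <- function(anns, text) {
  if (nrow(anns) == 0) return(invisible(TRUE))
  n <- nchar(text)
  bad <- anns$start < 0L | anns$start >= anns$end | anns$end > n
  if (any(bad)) {
    stop("annotation span out of bounds at row(s) ",
         paste(which(bad), collapse = ", "))
  }
  slice <- substr(rep(text, nrow(anns)), anns$start + 1L, anns$end)
  bad <- slice != anns$surface
  if (any(bad)) {
    stop("annotation surface disagrees with document slice at row(s) ",
         paste(which(bad), collapse = ", "))
  }
  invisible(TRUE)
}

# canonical annotation ordering: by start, longest first, then concept id for
# full determinism
sort_annotations <- function(anns) {
  if (nrow(anns) == 0) return(anns)
  o <- order(anns$start, -(anns$end - anns$start), anns$concept_id,
             anns$expansion_distance, anns$match_type)
  out <- anns[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a scored document
#'
#' The unit all serialization writers consume: a document identifier, its
#' text, and the final annotation table after recognition, context
#' detection, scoring and filtering.
#'
#' @param doc_id document identifier (used in TSV/RDF output and evaluation).
#' @param text document text.
#' @param annotations annotation data frame; span fidelity is enforced.
#' @return object of class `scored_document`.
#' @export
scored_document <- function(doc_id, text, annotations = empty_annotations()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1,
            is.character(text), length(text) == 1)
  annotations <- as_annotations(annotations)
  check_span_fidelity(annotations, text)
  structure(list(doc_id = doc_id, text = text, annotations = annotations),
            class = "scored_document")
}

#' @export
print.scored_document <- function(x, ...) {
  cat("<scored_document> ", x$doc_id, ": ", nchar(x$text), " chars, ",
      nrow(x$annotations), " annotations\n", sep = "")
  invisible(x)
}
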