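#' Offset conventions
#'
#' Internally (and in BRAT output) spans are 0-based with an exclusive
#' end. The JSON output follows the NCBO convention of 1-based inclusive
#' `from`/`to` positions. These two helpers are the single place the
#' conversion lives; they are exact inverses on valid spans.
#'
#' @param start,end internal offsets.
#' @param from,to NCBO-style positions.
#' @return a list with the converted pair.
#' @export
span_to_ncbo <- function(start, end) {
  list(from = start + 1L, to = end)
}

#' @rdname span_to_ncbo
#' @export
span_from_ncbo <- function(from, to) {
  list(start = from - 1L, end = to)
}

context_attr_name <- c(negated = "Negated", other = "ExperiencerOther",
                       historical = "Historical",
                       hypothetical = "Hypothetical")

#' Write a document to BRAT standoff
#'
#' Produces the `.txt` content (the text verbatim) and the `.ann` content
#' with, per annotation k: a text-bound line
#' `T{k}\t{Label} {start} {end}\t{surface}` (Label is the semantic group
#' from `group_of` when resolvable, else "Entity"), one attribute line
#' `A{j}\t{Dim} T{k}` per non-default context value (Negated,
#' ExperiencerOther, Historical, Hypothetical), and a normalization line
#' `N{j}\tReference T{k} DICT:{concept_id}\t{pref_label}`. Offsets are the
#' package-wide 0-based end-exclusive convention, which is also BRAT's.
#'
#' @param sd a [scored_document()].
#' @param group_of optional resolver `function(concept_id) -> label or NA`
#'   (see [brat_group_resolver()]).
#' @param term optional terminology used to emit preferred labels on N
#'   lines; the surface form is used when absent.
#' @return list with elements `txt` and `ann` (single strings; lines
#'   separated by `\n`).
#' @export
write_brat <- function(sd, group_of = NULL, term = NULL) {
  stopifnot(inherits(sd, "scored_document"))
  anns <- sd$annotations
  check_span_fidelity(anns, sd$text)
  t_lines <- character(nrow(anns))
  a_lines <- character(); n_lines <- character()
  j <- 0L
  for (k in seq_len(nrow(anns))) {
    label <- if (!is.null(group_of)) group_of(anns$concept_id[k]) else NA
    if (is.na(label) || !nzchar(label)) label <- "Entity"
    t_lines[k] <- sprintf("T%d\t%s %d %d\t%s", k, label, anns$start[k],
                          anns$end[k], anns$surface[k])
    for (val in c(anns$negation[k], anns$experiencer[k],
                  anns$temporality[k])) {
      if (!is.na(val) && val %in% names(context_attr_name)) {
        j <- j + 1L
        a_lines <- c(a_lines, sprintf("A%d\t%s T%d", j,
                                      context_attr_name[[val]], k))
      }
    }
  }
  pref <- function(cid, fallback) {
    cp <- if (!is.null(term)) term$concepts[[cid]] else NULL
    if (is.null(cp)) fallback else cp$pref_label
  }
  n_lines <- vapply(seq_len(nrow(anns)), function(k) {
    sprintf("N%d\tReference T%d DICT:%s\t%s", k, k, anns$concept_id[k],
            pref(anns$concept_id[k], anns$surface[k]))
  }, character(1))
  ann <- paste(c(t_lines, a_lines, n_lines), collapse = "\n")
  if (nzchar(ann)) ann <- paste0(ann, "\n")
  list(txt = sd$text, ann = ann)
}

#' Resolver from concept semantic types to a BRAT entity label
#'
#' @param term terminology.
#' @param map a [load_semantic_groups()] object.
#' @return `function(concept_id)` returning the group abbreviation of the
#'   concept's first mapped semantic type, or `NA` when none maps.
#' @export
brat_group_resolver <- function(term, map) {
  force(term); force(map)
  function(concept_id) {
    cp <- term$concepts[[concept_id]]
    if (is.null(cp)) return(NA_character_)
    grp <- group_of_type(map, cp$semantic_types)
    grp <- grp[!is.na(grp)]
    if (length(grp) == 0) NA_character_ else grp[1]
  }
}

#' Read a BRAT standoff document
#'
#' Inverse of [write_brat()] for round-trip tests and gold corpora.
#' Context attributes are applied on top of the defaults
#' (affirmed/patient/recent); concept ids are taken from `DICT:` N lines
#' (the T id itself is used when no N line exists). Unknown line types are
#' skipped with a warning. A T line whose surface disagrees with the text
#' slice is an integrity error.
#'
#' @param txt document text (content of the .txt file).
#' @param ann content of the .ann file.
#' @param doc_id document identifier for the resulting object.
#' @return a [scored_document()].
#' @export
read_brat <- function(txt, ann, doc_id = "doc") {
  lines <- strsplit(ann, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  t_ids <- character(); starts <- integer(); ends <- integer()
  surfaces <- character(); concept <- character()
  neg <- character(); exp <- character(); tmp <- character()
  row_of <- function(tid) match(tid, t_ids)
  for (line in lines) {
    if (startsWith(line, "T")) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      start <- as.integer(mid[2]); end <- as.integer(mid[3])
      surface <- if (length(parts) >= 3) parts[3] else ""
      slice <- substr(txt, start + 1L, end)
      if (slice != surface) {
        stop("BRAT integrity error: ", parts[1],
             " surface does not match text slice")
      }
      t_ids <- c(t_ids, parts[1])
      starts <- c(starts, start); ends <- c(ends, end)
      surfaces <- c(surfaces, surface)
      concept <- c(concept, parts[1])  # provisional; N line may override
      neg <- c(neg, "affirmed"); exp <- c(exp, "patient")
      tmp <- c(tmp, "recent")
    } else if (startsWith(line, "A")) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      fields <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      i <- row_of(fields[2])
      if (is.na(i)) next
      switch(fields[1],
             Negated = neg[i] <- "negated",
             ExperiencerOther = exp[i] <- "other",
             Historical = tmp[i] <- "historical",
             Hypothetical = tmp[i] <- "hypothetical")
    } else if (startsWith(line, "N")) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      fields <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      i <- row_of(fields[2])
      if (is.na(i)) next
      ref <- fields[3]
      concept[i] <- sub("^DICT:", "", ref)
    } else {
      warning("skipping unrecognized BRAT line: ", line, call. = FALSE)
    }
  }
  anns <- data.frame(concept_id = concept, start = starts, end = ends,
                     surface = surfaces, match_type = "PREF",
                     negation = neg, experiencer = exp, temporality = tmp,
                     stringsAsFactors = FALSE)
  if (length(t_ids) == 0) anns <- empty_annotations()
  scored_document(doc_id, txt, as_annotations(anns))
}

nt_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

#' Write annotations as RDF N-Triples
#'
#' Models each annotation in a Web-Annotation-like shape (target document,
#' start/end selector, exact surface form, concept body, score, one
#' property per context dimension) without claiming vocabulary
#' conformance. Emission is fixed at 10 triples per annotation: rdf:type,
#' target, start, end, exact, body, score, negation, experiencer,
#' temporality; unset context dimensions are emitted at their defaults and
#' an unset score as 0. With zero annotations only the document node
#' triples are emitted.
#'
#' @param sd a [scored_document()].
#' @param base_iri absolute IRI prefix (e.g. "http://example.org/ann/");
#'   must parse as `scheme://` or `scheme:`.
#' @return N-Triples content as a single string, one triple per line.
#' @export
write_rdf <- function(sd, base_iri = "http://example.org/annotation/") {
  stopifnot(inherits(sd, "scored_document"))
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", base_iri)) {
    stop("base_iri must be an absolute IRI prefix: ", base_iri)
  }
  v <- function(name) paste0("<", base_iri, "vocab#", name, ">")
  doc_iri <- paste0("<", base_iri, "document/", sd$doc_id, ">")
  rdf_type <- "<http://www.w3.org/1999/02/22-rdf-syntax-ns#type>"
  xsd <- function(x, type) {
    paste0("\"", x, "\"^^<http://www.w3.org/2001/XMLSchema#", type, ">")
  }
  lit <- function(x) paste0("\"", nt_escape(x), "\"")
  lines <- c(
    paste(doc_iri, rdf_type, v("AnnotatedDocument"), "."),
    paste(doc_iri, v("documentId"), lit(sd$doc_id), ".")
  )
  anns <- sd$annotations
  orv <- function(x, default) ifelse(is.na(x), default, x)
  for (k in seq_len(nrow(anns))) {
    a_iri <- paste0("<", base_iri, "annotation/", sd$doc_id, "/", k, ">")
    lines <- c(lines,
      paste(a_iri, rdf_type, v("Annotation"), "."),
      paste(a_iri, v("target"), doc_iri, "."),
      paste(a_iri, v("start"), xsd(anns$start[k], "integer"), "."),
      paste(a_iri, v("end"), xsd(anns$end[k], "integer"), "."),
      paste(a_iri, v("exact"), lit(anns$surface[k]), "."),
      paste(a_iri, v("body"), lit(anns$concept_id[k]), "."),
      paste(a_iri, v("score"),
            xsd(format(orv(anns$score[k], 0), scientific = FALSE), "decimal"),
            "."),
      paste(a_iri, v("negation"), lit(orv(anns$negation[k], "affirmed")), "."),
      paste(a_iri, v("experiencer"), lit(orv(anns$experiencer[k], "patient")),
            "."),
      paste(a_iri, v("temporality"), lit(orv(anns$temporality[k], "recent")),
            ".")
    )
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write annotations as JSON
#'
#' One record per annotated concept with its score and the list of its
#' annotations; `from`/`to` follow the NCBO convention (1-based inclusive,
#' see [span_to_ncbo()]). Context fields are emitted as-is (`null` when
#' unset).
#'
#' @param sd a [scored_document()].
#' @param term optional terminology used to fill `prefLabel` (surface form
#'   of the first annotation when absent).
#' @param pretty pretty-print the JSON.
#' @return JSON content as a single string (an array; `[]` for a document
#'   without annotations).
#' @export
write_json <- function(sd, term = NULL, pretty = FALSE) {
  stopifnot(inherits(sd, "scored_document"))
  anns <- sd$annotations
  if (nrow(anns) == 0) {
    return(as.character(jsonlite::toJSON(list(), auto_unbox = TRUE,
                                         pretty = pretty)))
  }
  records <- lapply(unique(anns$concept_id), function(cid) {
    rows <- anns[anns$concept_id == cid, , drop = FALSE]
    cp <- if (!is.null(term)) term$concepts[[cid]] else NULL
    pref <- if (!is.null(cp)) cp$pref_label else rows$surface[1]
    score <- rows$score[1]
    list(
      annotatedConcept = list(id = cid, prefLabel = pref),
      score = if (is.na(score)) NULL else score,
      annotations = lapply(seq_len(nrow(rows)), function(i) {
        conv <- span_to_ncbo(rows$start[i], rows$end[i])
        list(from = conv$from, to = conv$to,
             matchType = rows$match_type[i], text = rows$surface[i],
             negationContext = if (is.na(rows$negation[i])) NULL
                               else rows$negation[i],
             experiencerContext = if (is.na(rows$experiencer[i])) NULL
                                  else rows$experiencer[i],
             temporalityContext = if (is.na(rows$temporality[i])) NULL
                                  else rows$temporality[i])
      })
    )
  })
  as.character(jsonlite::toJSON(records, auto_unbox = TRUE, pretty = pretty,
                                null = "null", digits = NA))
}

#' Write annotations as TSV
#'
#' Flat evaluation-friendly output: a header plus one row per annotation
#' with doc_id, concept_id, start, end, surface, match_type, score,
#' negation, experiencer, temporality.
#'
#' @param sd a [scored_document()].
#' @return TSV content as a single string.
#' @export
write_tsv <- function(sd) {
  stopifnot(inherits(sd, "scored_document"))
  anns <- sd$annotations
  header <- paste(c("doc_id", "concept_id", "start", "end", "surface",
                    "match_type", "score", "negation", "experiencer",
                    "temporality"), collapse = "\t")
  if (nrow(anns) == 0) return(paste0(header, "\n"))
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  rows <- paste(sd$doc_id, anns$concept_id, anns$start, anns$end,
                anns$surface, anns$match_type, fmt(anns$score),
                fmt(anns$negation), fmt(anns$experiencer),
                fmt(anns$temporality), sep = "\t")
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}
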