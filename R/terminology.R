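#' Terminologies
#'
#' A terminology is the dictionary the recognizer matches against: a set of
#' concepts, each with an identifier, a preferred label, optional synonyms,
#' optional semantic-type codes (e.g. "T047") and optional is_a parents.
#' Internally it holds a `concepts` map (id -> concept) and a `label_index`
#' mapping every normalized label to the concept it names, tagged PREF or
#' SYN.
#'
#' The canonical on-disk format is a TSV with header columns
#' `id`, `pref_label`, `synonyms`, `semantic_types`, `parents`, `source`;
#' multi-valued cells use `|` as separator (literal pipes in labels are not
#' supported). A minimal SKOS Turtle reader (skos:prefLabel, skos:altLabel,
#' skos:broader) is also provided.
#'
#' @name terminology
NULL

new_concept <- function(id, pref_label, synonyms = character(),
                        semantic_types = character(), parents = character(),
                        source = "") {
  stopifnot(nzchar(id), nzchar(pref_label))
  synonyms <- unique(synonyms[nzchar(synonyms)])
  synonyms <- setdiff(synonyms, pref_label)    # pref_label never a synonym
  parents <- unique(parents[nzchar(parents)])
  if (id %in% parents) {
    stop("concept '", id, "' lists itself as a parent")
  }
  list(id = id, pref_label = pref_label, synonyms = synonyms,
       semantic_types = unique(semantic_types[nzchar(semantic_types)]),
       parents = parents, source = source)
}

build_terminology <- function(concept_list) {
  ids <- vapply(concept_list, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate concept id(s): ", paste(dup, collapse = ", "))
  }
  names(concept_list) <- ids
  # dangling parents are dropped with a warning, per the load contract
  for (id in ids) {
    par <- concept_list[[id]]$parents
    dangling <- setdiff(par, ids)
    if (length(dangling) > 0) {
      warning("concept '", id, "': dropping dangling parent id(s) ",
              paste(dangling, collapse = ", "), call. = FALSE)
      concept_list[[id]]$parents <- setdiff(par, dangling)
    }
  }
  idx <- label_index_of(concept_list)
  structure(list(concepts = concept_list, label_index = idx),
            class = "terminology")
}

label_index_of <- function(concept_list) {
  if (length(concept_list) == 0) {
    return(data.frame(label = character(), concept_id = character(),
                      match_type = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(concept_list, function(cp) {
    labels <- c(cp$pref_label, cp$synonyms)
    types <- c("PREF", rep("SYN", length(cp$synonyms)))
    norm <- vapply(labels, normalize_label, character(1), USE.NAMES = FALSE)
    keep <- nzchar(norm)
    data.frame(label = norm[keep], concept_id = cp$id,
               match_type = types[keep], stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(idx)) {
    idx <- data.frame(label = character(), concept_id = character(),
                      match_type = character(), stringsAsFactors = FALSE)
  }
  # same normalized label for the same concept via pref and synonym: keep PREF
  idx <- idx[order(idx$label, idx$concept_id, idx$match_type), , drop = FALSE]
  idx <- idx[!duplicated(idx[, c("label", "concept_id")]), , drop = FALSE]
  rownames(idx) <- NULL
  idx
}

#' @export
print.terminology <- function(x, ...) {
  cat("<terminology> ", length(x$concepts), " concepts, ",
      nrow(x$label_index), " indexed labels\n", sep = "")
  invisible(x)
}

split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

#' Load a terminology from disk
#'
#' @param path file path.
#' @param format `"tsv"` (canonical dictionary format, see
#'   [terminology]) or `"skos"` (minimal Turtle subset using
#'   skos:prefLabel / skos:altLabel / skos:broader).
#' @return a validated `terminology` object. Labels are deduplicated,
#'   synonyms equal to the preferred label dropped, and dangling parent ids
#'   removed with a warning.
#' @export
load_terminology <- function(path, format = c("tsv", "skos")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("terminology file not found: ", path)
  switch(format,
         tsv = load_terminology_tsv(path),
         skos = load_terminology_skos(path))
}

load_terminology_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "", encoding = "UTF-8")
  required <- c("id", "pref_label", "synonyms", "semantic_types",
                "parents", "source")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("dictionary TSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  concepts <- lapply(seq_len(nrow(df)), function(i) {
    new_concept(id = df$id[i], pref_label = df$pref_label[i],
                synonyms = split_multi(df$synonyms[i]),
                semantic_types = split_multi(df$semantic_types[i]),
                parents = split_multi(df$parents[i]),
                source = df$source[i])
  })
  build_terminology(concepts)
}

#' Write a terminology to the canonical TSV format
#'
#' Inverse of `load_terminology(format = "tsv")`: reloading the written file
#' yields an equal concept map.
#'
#' @param term terminology.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_terminology_tsv <- function(term, path) {
  stopifnot(inherits(term, "terminology"))
  join <- function(x) paste(x, collapse = "|")
  rows <- vapply(term$concepts, function(cp) {
    paste(cp$id, cp$pref_label, join(cp$synonyms), join(cp$semantic_types),
          join(cp$parents), cp$source, sep = "\t")
  }, character(1))
  header <- "id\tpref_label\tsynonyms\tsemantic_types\tparents\tsource"
  writeLines(c(header, unname(rows)), path, useBytes = TRUE)
  invisible(path)
}

# Minimal SKOS Turtle reader. Supports the profile actually needed for
# custom dictionary vocabularies: one subject per statement group,
# skos:prefLabel / skos:altLabel string literals, skos:broader IRI objects,
# "a skos:Concept" typing, @prefix declarations, and ';'/',' continuation
# punctuation. Anything else is ignored.
load_terminology_skos <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  prefixes <- c(skos = "http://www.w3.org/2004/02/skos/core#")
  acc <- new.env(parent = emptyenv())
  get_node <- function(id) {
    if (is.null(acc[[id]])) {
      acc[[id]] <- list(id = id, pref = NA_character_, alt = character(),
                        broader = character())
    }
    acc[[id]]
  }
  expand_iri <- function(tok) {
    if (grepl("^<.*>$", tok)) return(substr(tok, 2, nchar(tok) - 1))
    m <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9_-]*)?:(.*)$", tok))[[1]]
    if (length(m) == 3 && !is.na(prefixes[m[2]])) {
      return(paste0(prefixes[[m[2]]], m[3]))
    }
    tok
  }
  text <- paste(lines, collapse = "\n")
  text <- gsub("(?m)^\\s*#.*$", "", text, perl = TRUE)
  # tokenizer: IRIs, string literals (with optional language tag), @prefix,
  # punctuation, 'a', prefixed names
  toks <- regmatches(text, gregexpr(
    "<[^>]*>|\"(?:[^\"\\\\]|\\\\.)*\"(?:@[A-Za-z-]+)?|@prefix|[;,.]|\\ba\\b|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.%/#-]*|[A-Za-z][A-Za-z0-9_-]*:",
    text, perl = TRUE))[[1]]
  unquote <- function(tok) {
    tok <- sub("@[A-Za-z-]+$", "", tok)
    tok <- substr(tok, 2, nchar(tok) - 1)
    tok <- gsub("\\\\\"", "\"", tok)
    gsub("\\\\\\\\", "\\\\", tok)
  }
  skos_ns <- "http://www.w3.org/2004/02/skos/core#"
  subject <- NULL
  predicate <- NULL
  state <- "subject"
  i <- 1
  while (i <= length(toks)) {
    tok <- toks[i]
    if (tok == "@prefix") {
      pfx <- sub(":$", "", toks[i + 1])
      prefixes[pfx] <- substr(toks[i + 2], 2, nchar(toks[i + 2]) - 1)
      i <- i + 4   # skip "@prefix name: <iri> ."
      next
    }
    if (tok == ".") {
      state <- "subject"; subject <- NULL; predicate <- NULL
    } else if (tok == ";") {
      state <- "predicate"; predicate <- NULL
    } else if (tok == ",") {
      state <- "object"
    } else if (state == "subject") {
      subject <- expand_iri(tok)
      acc[[subject]] <- get_node(subject)
      state <- "predicate"
    } else if (state == "predicate") {
      predicate <- if (tok == "a") "rdf:type" else expand_iri(tok)
      state <- "object"
    } else {  # object position
      node <- get_node(subject)
      if (identical(predicate, paste0(skos_ns, "prefLabel")) &&
          startsWith(tok, "\"")) {
        if (is.na(node$pref)) node$pref <- unquote(tok)
      } else if (identical(predicate, paste0(skos_ns, "altLabel")) &&
                 startsWith(tok, "\"")) {
        node$alt <- c(node$alt, unquote(tok))
      } else if (identical(predicate, paste0(skos_ns, "broader"))) {
        node$broader <- c(node$broader, expand_iri(tok))
      }
      acc[[subject]] <- node
    }
    i <- i + 1
  }
  ids <- ls(acc)
  nodes <- lapply(ids, function(id) acc[[id]])
  nodes <- Filter(function(n) !is.na(n$pref), nodes)
  known <- vapply(nodes, `[[`, character(1), "id")
  concepts <- lapply(nodes, function(n) {
    new_concept(id = n$id, pref_label = n$pref, synonyms = n$alt,
                parents = intersect(unique(n$broader), known),
                source = "skos")
  })
  build_terminology(concepts)
}

#' Transitive is_a ancestors of a concept
#'
#' Breadth-first traversal of the parent graph. Each ancestor is reported
#' once, at its minimum distance; cycles are handled with a visited set.
#'
#' @param term terminology.
#' @param id concept id (must exist).
#' @param max_depth maximum distance to traverse (>= 1).
#' @return data frame with columns `id` and `distance` (>= 1), ordered by
#'   distance then id. Zero rows if the concept has no parents.
#' @export
ancestors <- function(term, id, max_depth = .Machine$integer.max) {
  stopifnot(inherits(term, "terminology"), max_depth >= 1)
  if (is.null(term$concepts[[id]])) stop("unknown concept id: ", id)
  visited <- id
  frontier <- id
  out_id <- character()
  out_d <- integer()
  d <- 0L
  while (length(frontier) > 0 && d < max_depth) {
    d <- d + 1L
    nxt <- unique(unlist(lapply(frontier, function(x) term$concepts[[x]]$parents),
                         use.names = FALSE))
    nxt <- setdiff(nxt, visited)
    if (length(nxt) == 0) break
    nxt <- sort(nxt)
    out_id <- c(out_id, nxt)
    out_d <- c(out_d, rep(d, length(nxt)))
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  data.frame(id = out_id, distance = out_d, stringsAsFactors = FALSE)
}
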