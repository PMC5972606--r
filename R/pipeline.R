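#' Pipeline configuration
#'
#' Bundles every knob of the annotation chain. Defaults replicate the
#' plain recognizer: no expansion, no context detection, no scoring, no
#' filtering — each feature is opt-in, mirroring the request parameters of
#' annotation Web services this engine emulates.
#'
#' @param terminology a `terminology` object or a path to a dictionary
#'   TSV.
#' @param terminology_format `"tsv"` or `"skos"` when `terminology` is a
#'   path.
#' @param semantic_group_map a `semantic_group_map`, a path, or `NULL`
#'   (default table is loaded lazily when group filtering is requested).
#' @param trigger_lexicon a `trigger_lexicon`, a path, or `NULL` (default
#'   lexicon, loaded lazily when a context dimension is enabled).
#' @param ontologies optional character vector of vocabulary names: the
#'   terminology is restricted to concepts whose `source` is listed
#'   (parents falling outside the restriction are dropped silently).
#' @param expand_depth is_a expansion depth (default 0 = off).
#' @param negation,experiencer,temporality logical context toggles
#'   (default `FALSE`).
#' @param score_algorithm `"none"`, `"old"`, `"cvalue"` or `"cvalueh"`.
#' @param score_threshold absolute score threshold or `NULL`.
#' @param confidence_threshold percentile threshold in \[0, 100\] or
#'   `NULL`. At most one of the two thresholds may be set.
#' @param groups semantic-group filter (character vector or `NULL`).
#' @param types semantic-type filter (character vector or `NULL`).
#' @param longest_only drop annotations strictly contained in longer ones.
#' @param context_window optional scope cap in tokens (default `Inf`).
#' @param seed random seed recorded for fixture generation.
#' @param log_level `"quiet"` or `"info"` (per-stage annotation counts).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(terminology,
                            terminology_format = "tsv",
                            semantic_group_map = NULL,
                            trigger_lexicon = NULL,
                            ontologies = NULL,
                            expand_depth = 0L,
                            negation = FALSE, experiencer = FALSE,
                            temporality = FALSE,
                            score_algorithm = c("none", "old", "cvalue",
                                                "cvalueh"),
                            score_threshold = NULL,
                            confidence_threshold = NULL,
                            groups = NULL, types = NULL,
                            longest_only = FALSE,
                            context_window = Inf,
                            seed = NULL,
                            log_level = c("quiet", "info")) {
  score_algorithm <- match.arg(score_algorithm)
  log_level <- match.arg(log_level)
  stopifnot(expand_depth >= 0)
  if (!is.null(score_threshold) && !is.null(confidence_threshold)) {
    stop("at most one of score_threshold and confidence_threshold ",
         "may be set")
  }
  if (!is.null(confidence_threshold)) {
    stopifnot(confidence_threshold >= 0, confidence_threshold <= 100)
  }
  if (is.character(terminology)) {
    terminology <- load_terminology(terminology, terminology_format)
  }
  stopifnot(inherits(terminology, "terminology"))
  if (!is.null(ontologies)) {
    keep <- Filter(function(cp) cp$source %in% ontologies,
                   terminology$concepts)
    if (length(keep) == 0) {
      stop("no concepts left after restricting to vocabularies: ",
           paste(ontologies, collapse = ", "))
    }
    terminology <- suppressWarnings(build_terminology(unname(keep)))
  }
  if (is.character(semantic_group_map)) {
    semantic_group_map <- load_semantic_groups(semantic_group_map)
  }
  if (is.character(trigger_lexicon)) {
    trigger_lexicon <- load_trigger_lexicon(trigger_lexicon)
  }
  dims <- c("negation", "experiencer", "temporality")[
    c(negation, experiencer, temporality)]
  if (length(dims) > 0 && is.null(trigger_lexicon)) {
    trigger_lexicon <- load_trigger_lexicon()
  }
  if (!is.null(groups) && is.null(semantic_group_map)) {
    semantic_group_map <- load_semantic_groups()
  }
  structure(list(terminology = terminology,
                 semantic_group_map = semantic_group_map,
                 trigger_lexicon = trigger_lexicon,
                 expand_depth = as.integer(expand_depth),
                 dimensions = dims,
                 score_algorithm = score_algorithm,
                 score_threshold = score_threshold,
                 confidence_threshold = confidence_threshold,
                 groups = groups, types = types,
                 longest_only = isTRUE(longest_only),
                 context_window = context_window,
                 seed = seed, log_level = log_level),
            class = "pipeline_config")
}

#' Run the full annotation chain
#'
#' Stages run in a fixed, observable order: direct recognition -> is_a
#' expansion -> semantic group/type filtering -> context detection
#' (enabled dimensions only) -> scoring -> score filtering -> longest-only
#' filtering. Disabling a stage is exactly the identity on the annotation
#' stream. A stage error aborts that document with a diagnostic; other
#' documents proceed.
#'
#' @param cfg a [pipeline_config()].
#' @param docs named character vector or list of `(doc_id, text)` pairs
#'   (a named character vector uses its names as doc ids).
#' @return list of [scored_document()] objects, one per successfully
#'   processed document, with a `failures` attribute naming the documents
#'   (if any) that errored.
#' @export
run_pipeline <- function(cfg, docs) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.list(docs) && !is.null(docs$doc_id)) docs <- list(docs)
  if (is.character(docs)) {
    ids <- names(docs)
    if (is.null(ids)) ids <- paste0("doc", seq_along(docs))
    docs <- Map(function(i, t) list(doc_id = i, text = t), ids,
                unname(docs))
  }
  index <- build_match_index(cfg$terminology)
  info <- function(...) {
    if (cfg$log_level == "info") message(...)
  }
  failures <- character()
  out <- list()
  for (d in docs) {
    res <- tryCatch({
      anns <- annotate_direct(d$text, index)
      info(d$doc_id, ": recognizer -> ", nrow(anns))
      if (cfg$expand_depth > 0) {
        anns <- expand_hierarchy(anns, cfg$terminology, cfg$expand_depth)
        info(d$doc_id, ": expansion -> ", nrow(anns))
      }
      if (!is.null(cfg$groups)) {
        anns <- filter_by_group(anns, cfg$terminology,
                                cfg$semantic_group_map, cfg$groups)
        info(d$doc_id, ": group filter -> ", nrow(anns))
      }
      if (!is.null(cfg$types)) {
        anns <- filter_by_type(anns, cfg$terminology, cfg$types)
        info(d$doc_id, ": type filter -> ", nrow(anns))
      }
      if (length(cfg$dimensions) > 0) {
        anns <- apply_context(d$text, anns, cfg$trigger_lexicon,
                              dimensions = cfg$dimensions,
                              window = cfg$context_window)
        info(d$doc_id, ": context -> ", nrow(anns))
      }
      if (cfg$score_algorithm != "none") {
        anns <- score_annotations(anns, score_config(cfg$score_algorithm))
        if (!is.null(cfg$score_threshold)) {
          anns <- filter_by_score(anns, "absolute", cfg$score_threshold)
        } else if (!is.null(cfg$confidence_threshold)) {
          anns <- filter_by_score(anns, "percentile",
                                  cfg$confidence_threshold)
        }
        info(d$doc_id, ": scoring/filter -> ", nrow(anns))
      }
      if (cfg$longest_only) {
        anns <- filter_longest_only(anns)
        info(d$doc_id, ": longest-only -> ", nrow(anns))
      }
      scored_document(d$doc_id, d$text, anns)
    }, error = function(e) {
      warning("document '", d$doc_id, "' failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) failures <- c(failures, d$doc_id)
    else out[[length(out) + 1L]] <- res
  }
  attr(out, "failures") <- failures
  out
}

#' Serialize pipeline results to disk
#'
#' @param results list of [scored_document()] from [run_pipeline()].
#' @param format one of `"json"`, `"brat"`, `"rdf"`, `"tsv"`.
#' @param output_dir directory (created if needed).
#' @param term optional terminology for preferred labels.
#' @param group_of optional resolver for BRAT labels.
#' @return invisibly the vector of files written.
#' @export
write_results <- function(results, format = c("json", "brat", "rdf", "tsv"),
                          output_dir = ".", term = NULL, group_of = NULL) {
  format <- match.arg(format)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (sd in results) {
    base <- file.path(output_dir, sd$doc_id)
    if (format == "brat") {
      out <- write_brat(sd, group_of = group_of, term = term)
      writeLines(out$txt, paste0(base, ".txt"), sep = "", useBytes = TRUE)
      writeLines(out$ann, paste0(base, ".ann"), sep = "", useBytes = TRUE)
      files <- c(files, paste0(base, ".txt"), paste0(base, ".ann"))
    } else {
      content <- switch(format,
                        json = write_json(sd, term = term, pretty = TRUE),
                        rdf = write_rdf(sd),
                        tsv = write_tsv(sd))
      ext <- switch(format, json = ".json", rdf = ".nt", tsv = ".tsv")
      writeLines(content, paste0(base, ext), sep = "", useBytes = TRUE)
      files <- c(files, paste0(base, ext))
    }
  }
  invisible(files)
}
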