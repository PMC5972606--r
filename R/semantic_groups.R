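#' Load a semantic-group mapping table
#'
#' Reads a pipe-delimited table in the NLM SemGroups layout,
#' `GroupAbbrev|GroupName|TypeCode|TypeName`, mapping fine-grained semantic
#' type codes (e.g. "T047") to coarse semantic groups (e.g. "DISO",
#' Disorders). The mapping is data, not code: the package ships a default
#' table under `inst/extdata/` and any file in the same layout (including
#' the official NLM SemGroups file) can be dropped in.
#'
#' @param path mapping file; defaults to the table shipped with the
#'   package.
#' @return object of class `semantic_group_map`: list with `forward`
#'   (data frame type_code -> group_abbrev/group_name) and `groups`
#'   (named list group_abbrev -> character vector of type codes).
#' @export
load_semantic_groups <- function(path = default_semgroups_path()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad) > 0) {
    stop("malformed semantic-group row at line ", lineno[bad[1]], ": ",
         lines[bad[1]])
  }
  fwd <- data.frame(
    group_abbrev = vapply(parts, `[[`, character(1), 1),
    group_name = vapply(parts, `[[`, character(1), 2),
    type_code = vapply(parts, `[[`, character(1), 3),
    type_name = vapply(parts, `[[`, character(1), 4),
    stringsAsFactors = FALSE)
  dup <- fwd$type_code[duplicated(fwd$type_code)]
  for (tc in unique(dup)) {
    grp <- unique(fwd$group_abbrev[fwd$type_code == tc])
    if (length(grp) > 1) {
      stop("type code ", tc, " assigned to multiple groups: ",
           paste(grp, collapse = ", "))
    }
  }
  fwd <- fwd[!duplicated(fwd$type_code), , drop = FALSE]
  rownames(fwd) <- NULL
  groups <- split(fwd$type_code, fwd$group_abbrev)
  structure(list(forward = fwd, groups = groups),
            class = "semantic_group_map")
}

#' @rdname load_semantic_groups
#' @export
default_semgroups_path <- function() {
  system.file("extdata", "semantic_groups.txt", package = "clinannotate",
              mustWork = TRUE)
}

#' Group of a semantic type code
#'
#' @param map a [load_semantic_groups()] object.
#' @param type_codes character vector of type codes.
#' @return character vector of group abbreviations (`NA` for unmapped
#'   codes).
#' @export
group_of_type <- function(map, type_codes) {
  stopifnot(inherits(map, "semantic_group_map"))
  idx <- match(type_codes, map$forward$type_code)
  map$forward$group_abbrev[idx]
}

#' Filter annotations by semantic group
#'
#' Retains annotations whose concept carries at least one semantic type
#' mapping to one of the requested groups. Concepts with no semantic types
#' are dropped while filtering is active. Order is preserved; the filter is
#' idempotent.
#'
#' @param anns annotation data frame.
#' @param term terminology containing every annotated concept.
#' @param map a [load_semantic_groups()] object.
#' @param groups non-empty character vector of group abbreviations.
#' @return filtered annotation data frame.
#' @export
filter_by_group <- function(anns, term, map, groups) {
  stopifnot(inherits(term, "terminology"),
            inherits(map, "semantic_group_map"),
            length(groups) > 0)
  unknown <- setdiff(groups, names(map$groups))
  if (length(unknown) > 0) {
    stop("unknown semantic group(s): ", paste(unknown, collapse = ", "),
         "; known groups: ", paste(sort(names(map$groups)), collapse = ", "))
  }
  anns <- as_annotations(anns)
  if (nrow(anns) == 0) return(anns)
  wanted_types <- unique(unlist(map$groups[groups], use.names = FALSE))
  keep <- vapply(anns$concept_id, function(cid) {
    cp <- term$concepts[[cid]]
    if (is.null(cp)) stop("unknown concept id in annotations: ", cid)
    length(intersect(cp$semantic_types, wanted_types)) > 0
  }, logical(1), USE.NAMES = FALSE)
  out <- anns[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter annotations by semantic type code
#'
#' Type-level counterpart of [filter_by_group()]: retains annotations
#' whose concept carries at least one of the requested type codes.
#'
#' @param anns annotation data frame.
#' @param term terminology.
#' @param types non-empty character vector of type codes (e.g. "T047").
#' @return filtered annotation data frame, order preserved.
#' @export
filter_by_type <- function(anns, term, types) {
  stopifnot(inherits(term, "terminology"), length(types) > 0)
  anns <- as_annotations(anns)
  if (nrow(anns) == 0) return(anns)
  keep <- vapply(anns$concept_id, function(cid) {
    cp <- term$concepts[[cid]]
    if (is.null(cp)) stop("unknown concept id in annotations: ", cid)
    length(intersect(cp$semantic_types, types)) > 0
  }, logical(1), USE.NAMES = FALSE)
  out <- anns[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
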