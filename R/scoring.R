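#' Scoring configuration
#'
#' Three scoring algorithms are available, all favouring longer multi-word
#' term annotations over shorter or single-word ones:
#' \describe{
#'   \item{old}{match-type weight sums: each annotation contributes
#'     `weight_pref` (preferred-label match), `weight_syn` (synonym match)
#'     or `weight_expanded(d)` (hierarchy-expanded at distance d); a
#'     concept's score is the sum over its annotations.}
#'   \item{cvalue}{termhood-weighted: a concept's score is the sum, over
#'     the distinct matched terms of its direct annotations, of the
#'     match-type weight times the term's C-Value.}
#'   \item{cvalueh}{as `cvalue`, with hierarchy-expanded annotations also
#'     contributing `weight_expanded(d)` times the C-Value of their term.}
#' }
#' Scores attach per concept per document: every annotation of a concept
#' carries the concept's total.
#'
#' @param algorithm `"old"`, `"cvalue"` or `"cvalueh"`.
#' @param weight_pref weight of a preferred-label match (default 10).
#' @param weight_syn weight of a synonym match (default 8); must not exceed
#'   `weight_pref`.
#' @param weight_expanded function of expansion distance d giving the weight
#'   of an expanded annotation; default `max(10 - d, 1)`, non-increasing.
#' @return object of class `score_config`.
#' @export
score_config <- function(algorithm = c("old", "cvalue", "cvalueh"),
                         weight_pref = 10, weight_syn = 8,
                         weight_expanded = function(d) pmax(10 - d, 1)) {
  algorithm <- match.arg(algorithm)
  stopifnot(weight_pref > 0, weight_syn > 0, weight_pref >= weight_syn,
            is.function(weight_expanded))
  structure(list(algorithm = algorithm, weight_pref = weight_pref,
                 weight_syn = weight_syn, weight_expanded = weight_expanded),
            class = "score_config")
}

#' Per-term occurrence statistics for one document
#'
#' Collects, over the direct annotations of one document, each distinct
#' normalized matched term with its word length, its occurrence frequency
#' (all occurrences count, including those nested inside longer matched
#' terms), and the set of longer matched terms that contain it as a
#' contiguous token subsequence.
#'
#' @param anns annotation data frame (only `expansion_distance == 0` rows
#'   are used).
#' @return data frame with columns `term`, `nwords`, `freq` and a list
#'   column `parents` (character vectors of nesting terms).
#' @export
term_stats <- function(anns) {
  anns <- as_annotations(anns)
  direct <- anns[anns$expansion_distance == 0L, , drop = FALSE]
  if (nrow(direct) == 0) {
    return(data.frame(term = character(), nwords = integer(),
                      freq = integer(), parents = I(list()),
                      stringsAsFactors = FALSE))
  }
  terms <- vapply(direct$surface, normalize_label, character(1),
                  USE.NAMES = FALSE)
  # frequency counts occurrences by distinct span (the same span annotated
  # with several concepts is still one occurrence of the term)
  span_key <- paste(direct$start, direct$end, terms)
  uniq_spans <- !duplicated(span_key)
  tab <- table(terms[uniq_spans])
  term_names <- sort(names(tab))
  tok_lists <- strsplit(term_names, " ", fixed = TRUE)
  nwords <- lengths(tok_lists)
  parents <- lapply(seq_along(term_names), function(i) {
    cand <- term_names[nwords > nwords[i]]
    cand[vapply(cand, function(p) {
      is_token_subseq(tok_lists[[i]], strsplit(p, " ", fixed = TRUE)[[1]])
    }, logical(1))]
  })
  data.frame(term = term_names, nwords = as.integer(nwords),
             freq = as.integer(tab[term_names]), parents = I(parents),
             stringsAsFactors = FALSE)
}

# is `a` a contiguous subsequence of `b`?
is_token_subseq <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na >= nb) return(FALSE)
  for (i in seq_len(nb - na + 1)) {
    if (all(b[i:(i + na - 1)] == a)) return(TRUE)
  }
  FALSE
}

#' C-Value of each matched term
#'
#' For a term a of |a| words with document frequency f(a), not nested in
#' any longer matched term:
#' \deqn{CV(a) = \log_2(|a| + 1) \cdot f(a)}
#' and when a is nested in the set T_a of longer matched terms:
#' \deqn{CV(a) = \log_2(|a|+1) \left(f(a) -
#'   \frac{1}{|T_a|}\sum_{b \in T_a} f(b)\right)}
#' floored at 0. The `|a| + 1` offset gives single-word terms a nonzero
#' length factor so they can still be ranked.
#'
#' @param stats term statistics from [term_stats()].
#' @return named numeric vector, term -> C-Value (empty for empty stats).
#' @export
compute_cvalue <- function(stats) {
  if (nrow(stats) == 0) return(stats::setNames(numeric(), character()))
  freq_of <- stats::setNames(stats$freq, stats$term)
  cv <- vapply(seq_len(nrow(stats)), function(i) {
    base <- log2(stats$nwords[i] + 1)
    parents <- stats$parents[[i]]
    f <- stats$freq[i]
    if (length(parents) == 0) {
      base * f
    } else {
      max(0, base * (f - mean(freq_of[parents])))
    }
  }, numeric(1))
  stats::setNames(cv, stats$term)
}

#' Score annotations of one document
#'
#' Sets the `score` column on every annotation according to the configured
#' algorithm (see [score_config()]). All annotations of the same concept
#' share the concept's total score.
#'
#' @param anns annotation data frame of one document.
#' @param cfg a [score_config()].
#' @return the annotations with `score` set (>= 0 everywhere).
#' @export
score_annotations <- function(anns, cfg) {
  if (!inherits(cfg, "score_config")) {
    stop("cfg must be a score_config object")
  }
  anns <- as_annotations(anns)
  if (nrow(anns) == 0) return(anns)
  terms <- vapply(anns$surface, normalize_label, character(1),
                  USE.NAMES = FALSE)
  concept_score <- switch(
    cfg$algorithm,
    old = {
      w <- ifelse(anns$expansion_distance > 0L,
                  cfg$weight_expanded(anns$expansion_distance),
                  ifelse(anns$match_type == "PREF", cfg$weight_pref,
                         cfg$weight_syn))
      tapply(w, anns$concept_id, sum)
    },
    cvalue = ,
    cvalueh = {
      cv <- compute_cvalue(term_stats(anns))
      per_concept <- vapply(unique(anns$concept_id), function(cid) {
        rows <- anns$concept_id == cid
        total <- 0
        # direct contributions: one per distinct matched term, match-type
        # weighted
        drows <- which(rows & anns$expansion_distance == 0L)
        if (length(drows) > 0) {
          dterm <- terms[drows]
          first <- drows[!duplicated(dterm)]
          w <- ifelse(anns$match_type[first] == "PREF", cfg$weight_pref,
                      cfg$weight_syn)
          total <- total + sum(w * cv[terms[first]])
        }
        if (cfg$algorithm == "cvalueh") {
          erows <- which(rows & anns$expansion_distance > 0L)
          if (length(erows) > 0) {
            # one contribution per distinct (term, distance), distance-decayed
            key <- paste(terms[erows], anns$expansion_distance[erows])
            first <- erows[!duplicated(key)]
            w <- cfg$weight_expanded(anns$expansion_distance[first])
            cvt <- cv[terms[first]]
            cvt[is.na(cvt)] <- 0   # expanded-only term absent from stats
            total <- total + sum(w * cvt)
          }
        }
        total
      }, numeric(1))
      per_concept
    },
    stop("unknown scoring algorithm: ", cfg$algorithm)
  )
  anns$score <- as.numeric(concept_score[anns$concept_id])
  anns
}

#' Filter scored annotations by threshold
#'
#' Absolute mode retains annotations with `score >= threshold`. Percentile
#' mode computes the threshold-th percentile P of the multiset of
#' annotation scores by the nearest-rank method and retains annotations
#' with `score >= P`; ties at P are all retained, so e.g. a 90 threshold
#' keeps the annotations whose scores sit in the top 10% of the score
#' distribution. An alternative reading ("mass") retains the
#' highest-scoring annotations accounting for the top (100 - threshold)%
#' of the cumulative score mass (tie-extended); it is provided behind
#' `percentile_basis` and is not the default.
#'
#' @param anns scored annotation data frame (every row must carry a score).
#' @param mode `"absolute"` or `"percentile"`.
#' @param threshold absolute score, or percentile in `[0, 100]`.
#' @param percentile_basis `"value"` (nearest-rank over score values,
#'   default) or `"mass"` (cumulative score mass).
#' @return filtered annotations, input order preserved.
#' @export
filter_by_score <- function(anns, mode = c("absolute", "percentile"),
                            threshold,
                            percentile_basis = c("value", "mass")) {
  mode <- match.arg(mode)
  percentile_basis <- match.arg(percentile_basis)
  anns <- as_annotations(anns)
  if (nrow(anns) == 0) return(anns)
  if (anyNA(anns$score)) {
    stop("annotations carry no score; run score_annotations() first")
  }
  keep <- if (mode == "absolute") {
    anns$score >= threshold
  } else {
    stopifnot(threshold >= 0, threshold <= 100)
    if (threshold == 0) {
      rep(TRUE, nrow(anns))
    } else if (percentile_basis == "value") {
      sorted <- sort(anns$score)
      rank <- ceiling(threshold / 100 * length(sorted))
      anns$score >= sorted[rank]
    } else {
      # retain the top scores whose cumulative mass is within the top
      # (100 - threshold)% of total score mass, extended across ties
      sorted <- sort(anns$score, decreasing = TRUE)
      total <- sum(sorted)
      if (total == 0) {
        rep(TRUE, nrow(anns))
      } else {
        cum <- cumsum(sorted) / total
        k <- which(cum >= (100 - threshold) / 100)[1]
        anns$score >= sorted[k]
      }
    }
  }
  out <- anns[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
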