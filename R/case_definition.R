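#' Case-definition clauses
#'
#' A clause is the atomic unit of a computable case definition: "at least
#' `min_count` matches of a pattern within a rolling window, in a set of
#' source tables". Patterns are code prefixes (so "627" covers 627 and all
#' its sub-codes, "G03CA" covers G03CA03 etc.) or free-text unigrams /
#' adjacent bigrams.
#'
#' @param match_kind one of "code_prefix", "text_unigram", "text_bigram".
#' @param pattern non-empty code prefix or (lower-case) n-gram.
#' @param min_count minimum number of matching records (>= 1).
#' @param window_months 12, 24, or "whole_chart". A windowed clause requires
#'   some `min_count` matching records whose earliest and latest dates lie
#'   within a rolling 365/730-day span. `min_count = 1` implies
#'   "whole_chart".
#' @param scope subset of the five source tables searched.
#' @return Object of class `clause`.
#' @export
clause <- function(match_kind, pattern, min_count = 1L,
                   window_months = "whole_chart", scope = .sources) {
  match_kind <- match.arg(match_kind,
                          c("code_prefix", "text_unigram", "text_bigram"))
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a non-empty string")
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 1L) stop("min_count must be >= 1")
  window_months <- as.character(window_months)
  if (!window_months %in% c("12", "24", "whole_chart"))
    stop('window_months must be 12, 24 or "whole_chart"')
  if (min_count == 1L && window_months != "whole_chart")
    stop("min_count = 1 requires window_months = whole_chart")
  scope <- as.character(scope)
  bad <- setdiff(scope, .sources)
  if (length(bad) > 0L || length(scope) == 0L)
    stop("scope must be a non-empty subset of: ",
         paste(.sources, collapse = ", "))
  if (match_kind == "text_bigram" &&
      length(strsplit(pattern, " ", fixed = TRUE)[[1L]]) != 2L)
    stop('a text_bigram pattern must be two space-separated tokens')
  structure(list(match_kind = match_kind,
                 pattern = if (match_kind == "code_prefix")
                   normalize_code(pattern) else tolower(pattern),
                 min_count = min_count,
                 window_months = window_months,
                 scope = sort(unique(scope))),
            class = "clause")
}

#' @export
print.clause <- function(x, ...) {
  win <- if (x$window_months == "whole_chart") "whole chart"
         else paste0("within ", x$window_months, " months")
  cat(sprintf(">=%d x %s \"%s\" %s [%s]\n", x$min_count, x$match_kind,
              x$pattern, win, paste(x$scope, collapse = ",")))
  invisible(x)
}

#' Case definitions
#'
#' An OR-combination of clauses: a chart is flagged as a case when at least
#' one clause is satisfied. Evaluation is monotone - adding records to a
#' chart can only turn a non-case verdict into a case verdict.
#'
#' @param ... `clause` objects (or a single list of them).
#' @return Object of class `case_definition`.
#' @export
case_definition <- function(...) {
  clauses <- list(...)
  if (length(clauses) == 1L && !inherits(clauses[[1L]], "clause"))
    clauses <- clauses[[1L]]
  if (length(clauses) == 0L) stop("a case definition needs >= 1 clause")
  ok <- vapply(clauses, inherits, logical(1), what = "clause")
  if (!all(ok)) stop("all elements must be clause objects")
  structure(list(clauses = clauses, combination = "or"),
            class = "case_definition")
}

#' @export
print.case_definition <- function(x, ...) {
  cat("<case_definition> OR of", length(x$clauses), "clause(s):\n")
  for (cl in x$clauses) { cat("  - "); print(cl) }
  invisible(x)
}

#' Normalize a clinical code for prefix matching
#'
#' Strips dots and whitespace and upper-cases, so ICD-9 "627.2" matches the
#' prefix "627" and ATC matching is case-insensitive.
#'
#' @param code character vector.
#' @return Normalized character vector.
#' @export
normalize_code <- function(code) {
  toupper(gsub("[. ]", "", code))
}

## Dates (sorted) of the records in a records table that match a clause.
## Each record contributes at most one match.
clause_match_dates <- function(records, cl, lexicon, target_terms) {
  recs <- records[records$source %in% cl$scope, , drop = FALSE]
  if (nrow(recs) == 0L) return(as.Date(character(0)))
  if (cl$match_kind == "code_prefix") {
    hit <- startsWith(normalize_code(recs$code), cl$pattern) & nzchar(recs$code)
  } else {
    hit <- rep(FALSE, nrow(recs))
    cand <- which(nzchar(recs$free_text))
    for (i in cand) {
      toks <- feature_tokens(recs$free_text[i], lexicon, target_terms)
      hit[i] <- cl$pattern %in% extract_ngrams(toks)
    }
  }
  sort(recs$date[hit])
}

## TRUE iff >= min_count of the sorted dates fall in the rolling window.
dates_satisfy <- function(dates, min_count, window_months) {
  n <- length(dates)
  if (n < min_count) return(FALSE)
  if (window_months == "whole_chart") return(TRUE)
  wd <- .window_days[[window_months]]
  span <- as.numeric(dates[seq.int(min_count, n)] -
                     dates[seq.int(1L, n - min_count + 1L)])
  any(span <= wd)
}

#' Evaluate one clause against one patient chart
#'
#' A clause holds when at least `min_count` in-scope records match its
#' pattern - code-prefix match on the normalized code, or n-gram membership
#' in the record's negation-filtered free-text - with the earliest and
#' latest of some `min_count` of them no more than the rolling window
#' apart (365 days for 12 months, 730 for 24; "whole_chart" imposes no
#' date constraint).
#'
#' @param chart a `patient_chart`.
#' @param cl a `clause`.
#' @param lexicon,target_terms negation filtering configuration.
#' @return Logical scalar. An empty chart is always `FALSE`.
#' @export
evaluate_clause <- function(chart, cl,
                            lexicon = default_negation_lexicon(),
                            target_terms = default_target_terms()) {
  stopifnot(inherits(chart, "patient_chart"), inherits(cl, "clause"))
  d <- clause_match_dates(chart$records, cl, lexicon, target_terms)
  dates_satisfy(d, cl$min_count, cl$window_months)
}

#' Evaluate a case definition against one patient chart
#'
#' @param chart a `patient_chart`.
#' @param definition a `case_definition`.
#' @inheritParams evaluate_clause
#' @return Logical scalar: TRUE iff any clause is satisfied.
#' @export
evaluate_definition <- function(chart, definition,
                                lexicon = default_negation_lexicon(),
                                target_terms = default_target_terms()) {
  stopifnot(inherits(definition, "case_definition"))
  for (cl in definition$clauses)
    if (evaluate_clause(chart, cl, lexicon, target_terms)) return(TRUE)
  FALSE
}

## Vectorized clause evaluation over a whole cohort; returns a named logical
## vector over all patients (FALSE for patients without matching records).
evaluate_clause_cohort <- function(cohort, cl,
                                   lexicon = default_negation_lexicon(),
                                   target_terms = default_target_terms()) {
  stopifnot(inherits(cohort, "emr_cohort"), inherits(cl, "clause"))
  ids <- cohort$patients$patient_id
  out <- setNames(rep(FALSE, length(ids)), ids)
  recs <- cohort$records[source %in% cl$scope]
  if (nrow(recs) == 0L) return(out)
  if (cl$match_kind == "code_prefix") {
    hits <- recs[nzchar(code) & startsWith(normalize_code(code), cl$pattern),
                 .(patient_id, date)]
  } else {
    ## cheap literal prefilter, then exact token-level check
    first_tok <- strsplit(cl$pattern, " ", fixed = TRUE)[[1L]][1L]
    cand <- recs[grepl(first_tok, tolower(free_text), fixed = TRUE)]
    if (nrow(cand) == 0L) return(out)
    keep <- vapply(cand$free_text, function(tx) {
      cl$pattern %in% extract_ngrams(feature_tokens(tx, lexicon, target_terms))
    }, logical(1), USE.NAMES = FALSE)
    hits <- cand[keep, .(patient_id, date)]
  }
  if (nrow(hits) == 0L) return(out)
  sat <- hits[order(date),
              .(ok = dates_satisfy(date, cl$min_count, cl$window_months)),
              by = patient_id]
  out[sat$patient_id] <- sat$ok
  out
}

#' Evaluate a case definition over a whole cohort
#'
#' @param cohort an `emr_cohort`.
#' @param definition a `case_definition`.
#' @inheritParams evaluate_clause
#' @return Named logical vector over the cohort's patients.
#' @export
evaluate_definition_cohort <- function(cohort, definition,
                                       lexicon = default_negation_lexicon(),
                                       target_terms = default_target_terms()) {
  stopifnot(inherits(definition, "case_definition"))
  verdict <- setNames(rep(FALSE, nrow(cohort$patients)),
                      cohort$patients$patient_id)
  for (cl in definition$clauses)
    verdict <- verdict | evaluate_clause_cohort(cohort, cl, lexicon,
                                                target_terms)
  verdict
}

#' Write / read a case definition as a portable YAML document
#'
#' @param definition a `case_definition`.
#' @param path file path.
#' @return `write_case_definition` returns `path` invisibly;
#'   `read_case_definition` returns the `case_definition`.
#' @export
write_case_definition <- function(definition, path) {
  stopifnot(inherits(definition, "case_definition"))
  doc <- list(combination = "or",
              clauses = lapply(definition$clauses, function(cl)
                list(match_kind = cl$match_kind, pattern = cl$pattern,
                     min_count = cl$min_count,
                     window_months = cl$window_months, scope = cl$scope)))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_case_definition
#' @export
read_case_definition <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$clauses)) stop("no clauses found in ", path)
  case_definition(lapply(doc$clauses, function(x)
    clause(x$match_kind, x$pattern, x$min_count, x$window_months, x$scope)))
}
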