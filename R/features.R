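## Feature engineering: every code prefix and free-text n-gram, each in four
## temporal variants, as binary patient-level features.

variant_params <- function(variant) {
  switch(variant,
    ge1_whole_chart = list(min_count = 1L, window_months = "whole_chart"),
    ge2_12mo        = list(min_count = 2L, window_months = "12"),
    ge2_24mo        = list(min_count = 2L, window_months = "24"),
    ge2_whole_chart = list(min_count = 2L, window_months = "whole_chart"),
    stop("unknown variant: ", variant))
}

## base-feature long table: one row per (record, base feature), carrying the
## record date so temporal variants can be derived by grouping
feature_long_table <- function(cohort, lexicon, target_terms,
                               icd9_min_prefix = 3L,
                               atc_prefix_lengths = c(3L, 4L, 5L, 7L)) {
  recs <- cohort$records
  parts <- list()

  ## --- code-prefix features -------------------------------------------
  ## ICD-9 features are scoped to the three diagnosis tables, ATC features
  ## to medications; prefixes at every depth realize "or any sub-codes"
  icd <- recs[code_system == "ICD9CM" & nzchar(code) &
              source %in% .diag_sources]
  if (nrow(icd) > 0L) {
    norm <- normalize_code(icd$code)
    for (L in seq.int(icd9_min_prefix, max(nchar(norm)))) {
      idx <- which(nchar(norm) >= L)
      if (length(idx) == 0L) next
      parts[[length(parts) + 1L]] <- data.table(
        patient_id = icd$patient_id[idx],
        feat = paste0("icd9:", substr(norm[idx], 1L, L)),
        date = icd$date[idx])
    }
  }
  atc <- recs[code_system == "ATC" & nzchar(code) & source == "medication"]
  if (nrow(atc) > 0L) {
    norm <- normalize_code(atc$code)
    for (L in atc_prefix_lengths) {
      idx <- which(nchar(norm) >= L)
      if (length(idx) == 0L) next
      parts[[length(parts) + 1L]] <- data.table(
        patient_id = atc$patient_id[idx],
        feat = paste0("atc:", substr(norm[idx], 1L, L)),
        date = atc$date[idx])
    }
  }

  ## --- bag-of-words features ------------------------------------------
  txt <- recs[nzchar(free_text)]
  if (nrow(txt) > 0L) {
    toks <- tokenize_many(txt$free_text, lexicon, target_terms)
    n_uni <- lengths(toks)
    keep <- n_uni > 0L
    if (any(keep)) {
      toks <- toks[keep]
      ids <- txt$patient_id[keep]
      dates <- txt$date[keep]
      uni <- lapply(toks, unique)
      parts[[length(parts) + 1L]] <- data.table(
        patient_id = rep(ids, lengths(uni)),
        feat = paste0("uni:", unlist(uni, use.names = FALSE)),
        date = rep(dates, lengths(uni)))
      bi <- lapply(toks, function(tk) {
        n <- length(tk)
        if (n < 2L) character(0) else unique(paste(tk[-n], tk[-1L]))
      })
      nb <- lengths(bi)
      if (any(nb > 0L)) {
        parts[[length(parts) + 1L]] <- data.table(
          patient_id = rep(ids, nb),
          feat = paste0("bi:", unlist(bi, use.names = FALSE)),
          date = rep(dates, nb))
      }
    }
  }
  if (length(parts) == 0L)
    return(data.table(patient_id = character(0), feat = character(0),
                      date = as.Date(character(0))))
  rbindlist(parts)
}

## vectorized tokenize + negation filter over many texts
tokenize_many <- function(texts, lexicon, target_terms) {
  x <- tolower(texts)
  x <- gsub("[^a-z0-9?]+", " ", x)
  toks <- strsplit(trimws(x), " +", perl = FALSE)
  target_re <- paste(target_terms, collapse = "|")
  needs_filter <- grepl(target_re, x)
  out <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    tk <- sub("^\\?+", "", tk)
    tk <- tk[nzchar(tk)]
    if (needs_filter[i] && length(tk) > 0L)
      tk <- filter_negated_tokens(tk, lexicon, target_terms)
    tk <- sub("\\?$", "", tk)
    out[[i]] <- tk[nzchar(tk)]
  }
  out
}

#' Build the binary temporal feature matrix of a cohort
#'
#' Generates, for every code prefix (ICD-9 at every depth from
#' `icd9_min_prefix` characters, ATC at the classification level boundaries)
#' and every free-text unigram and adjacent bigram (after negation
#' filtering), four binary temporal variants: at least one instance anywhere
#' in the chart, at least two within 12 months, at least two within 24
#' months, and at least two anywhere in the chart. Features present in fewer
#' than `min_support` patients are dropped.
#'
#' @param cohort an `emr_cohort`.
#' @param min_support minimum number of distinct patients a feature must
#'   occur in to be retained (default 10).
#' @param lexicon,target_terms negation filtering configuration.
#' @param icd9_min_prefix shortest ICD-9 prefix generated (default 3).
#' @param atc_prefix_lengths ATC prefix depths generated (default the
#'   anatomical/therapeutic/chemical level boundaries 3, 4, 5, 7).
#' @return Object of class `feature_matrix`: integer 0/1 `values`
#'   (patients x features), a `specs` data.frame mapping each column to its
#'   (match_kind, pattern, variant, scope) provenance, `patient_ids`, and
#'   `n_features_prefilter`, the number of distinct feature-variants seen
#'   before minimum-support filtering.
#' @export
build_feature_matrix <- function(cohort, min_support = 10L,
                                 lexicon = default_negation_lexicon(),
                                 target_terms = default_target_terms(),
                                 icd9_min_prefix = 3L,
                                 atc_prefix_lengths = c(3L, 4L, 5L, 7L)) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (nrow(cohort$patients) == 0L) stop("cohort has no patients")
  long <- feature_long_table(cohort, lexicon, target_terms,
                             icd9_min_prefix, atc_prefix_lengths)
  ids <- sort(cohort$patients$patient_id)

  if (nrow(long) > 0L) {
    per <- long[order(date),
                .(n_rec = .N,
                  min_gap = if (.N > 1L) min(diff(as.numeric(date))) else Inf),
                by = .(patient_id, feat)]
    fv <- rbindlist(list(
      per[, .(patient_id, feat, variant = "ge1_whole_chart")],
      per[n_rec >= 2L, .(patient_id, feat, variant = "ge2_whole_chart")],
      per[min_gap <= 730, .(patient_id, feat, variant = "ge2_24mo")],
      per[min_gap <= 365, .(patient_id, feat, variant = "ge2_12mo")]))
    n_pre <- nrow(unique(fv[, .(feat, variant)]))
    supp <- fv[, .(support = .N), by = .(feat, variant)]
    keep <- supp[support >= min_support]
    fv <- merge(fv, keep[, .(feat, variant)], by = c("feat", "variant"))
  } else {
    fv <- data.table(patient_id = character(0), feat = character(0),
                     variant = character(0))
    n_pre <- 0L
  }

  fv[, name := paste0(feat, "|", variant)]
  cols <- sort(unique(fv$name))
  values <- matrix(0L, nrow = length(ids), ncol = length(cols),
                   dimnames = list(ids, cols))
  if (nrow(fv) > 0L)
    values[cbind(match(fv$patient_id, ids), match(fv$name, cols))] <- 1L

  specs <- parse_feature_names(cols)
  structure(list(patient_ids = ids, specs = specs, values = values,
                 n_features_prefilter = n_pre,
                 min_support = as.integer(min_support)),
            class = "feature_matrix")
}

parse_feature_names <- function(cols) {
  if (length(cols) == 0L)
    return(data.frame(name = character(0), match_kind = character(0),
                      pattern = character(0), variant = character(0),
                      scope = character(0)))
  base <- sub("\\|[^|]+$", "", cols)
  variant <- sub("^.*\\|", "", cols)
  tag <- sub(":.*$", "", base)
  pattern <- sub("^[a-z0-9]+:", "", base)
  match_kind <- c(icd9 = "code_prefix", atc = "code_prefix",
                  uni = "text_unigram", bi = "text_bigram")[tag]
  scope <- ifelse(tag == "icd9", .diag_scope_string,
                  ifelse(tag == "atc", "medication", .text_scope_string))
  data.frame(name = cols, match_kind = unname(match_kind),
             pattern = pattern, variant = variant, scope = scope,
             stringsAsFactors = FALSE)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", length(x$patient_ids), " patients x ",
      ncol(x$values), " features (", x$n_features_prefilter,
      " before min-support ", x$min_support, ")\n", sep = "")
  invisible(x)
}

#' Convert a feature-matrix column back into a clause
#'
#' Every feature is, by construction, evaluable as a rule-engine clause;
#' this is what makes a trained tree translatable into a case definition.
#'
#' @param spec one row of a `feature_matrix`'s `specs` data.frame (or a
#'   feature name plus the specs table).
#' @return A `clause`.
#' @export
spec_to_clause <- function(spec) {
  stopifnot(is.data.frame(spec), nrow(spec) == 1L)
  vp <- variant_params(spec$variant)
  clause(spec$match_kind, spec$pattern, vp$min_count, vp$window_months,
         strsplit(spec$scope, "+", fixed = TRUE)[[1L]])
}

#' Ad hoc feature importance for prescreening
#'
#' `(TP - FP) / P`: the number of cases with the feature minus the number of
#' non-cases with it, over the number of cases. A feature present in every
#' case and no non-case scores 1; one equally common in both classes scores
#' about 0; one concentrated in non-cases scores negative.
#'
#' @param column binary 0/1 vector (one feature across patients).
#' @param labels "case"/"non_case" labels aligned with `column`.
#' @return Numeric score.
#' @export
adhoc_importance <- function(column, labels) {
  labels <- as.character(labels)
  stopifnot(length(column) == length(labels))
  is_case <- labels == "case"
  P <- sum(is_case)
  if (P == 0L) stop("no cases in labels; importance undefined")
  (sum(column[is_case]) - sum(column[!is_case])) / P
}

## vectorized over all columns of a 0/1 matrix
adhoc_importance_matrix <- function(values, labels) {
  is_case <- as.character(labels) == "case"
  P <- sum(is_case)
  if (P == 0L) stop("no cases in labels; importance undefined")
  tp <- colSums(values[is_case, , drop = FALSE])
  fp <- colSums(values[!is_case, , drop = FALSE])
  (tp - fp) / P
}

## column names of the k best columns by ad hoc importance,
## ties broken by lexicographic name (stable)
prescreen_columns <- function(values, labels, k) {
  score <- adhoc_importance_matrix(values, labels)
  nm <- colnames(values)
  ord <- order(-score, nm)
  nm[ord[seq_len(min(k, length(nm)))]]
}

#' Prescreen a feature matrix to the top-k features
#'
#' Retains the `k` columns with the highest [adhoc_importance()] score; ties
#' at the cutoff are broken by lexicographic feature name so the result is
#' stable. With fewer than `k` columns the matrix is returned unchanged.
#'
#' @param fm a `feature_matrix`.
#' @param labels "case"/"non_case" labels aligned with `fm$patient_ids`.
#' @param k number of features to keep (default 300).
#' @return The reduced `feature_matrix`.
#' @export
prescreen_top_k <- function(fm, labels, k = 300L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (ncol(fm$values) == 0L) stop("feature matrix has no columns")
  keep <- prescreen_columns(fm$values, labels, k)
  fm$values <- fm$values[, keep, drop = FALSE]
  fm$specs <- fm$specs[match(keep, fm$specs$name), , drop = FALSE]
  rownames(fm$specs) <- NULL
  fm
}

#' Persist / load a feature matrix as plain text
#'
#' The matrix is written as a sparse triplet CSV (`patient_id`,
#' `feature_name`, value 1) plus a feature dictionary CSV with the
#' provenance of every column.
#'
#' @param fm a `feature_matrix`.
#' @param dir output directory (created if needed).
#' @return `write_feature_matrix` returns `dir` invisibly;
#'   `read_feature_matrix` the reconstructed `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, dir) {
  stopifnot(inherits(fm, "feature_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(fm$values == 1L, arr.ind = TRUE)
  trip <- data.frame(patient_id = fm$patient_ids[idx[, 1L]],
                     feature_name = colnames(fm$values)[idx[, 2L]],
                     value = 1L)
  trip <- trip[order(trip$patient_id, trip$feature_name), ]
  write.csv(trip, file.path(dir, "feature_triplets.csv"), row.names = FALSE)
  write.csv(fm$specs, file.path(dir, "feature_dictionary.csv"),
            row.names = FALSE)
  write.csv(data.frame(patient_id = fm$patient_ids),
            file.path(dir, "feature_patients.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(dir) {
  trip <- read.csv(file.path(dir, "feature_triplets.csv"),
                   colClasses = c("character", "character", "integer"))
  specs <- read.csv(file.path(dir, "feature_dictionary.csv"),
                    colClasses = "character")
  ids <- read.csv(file.path(dir, "feature_patients.csv"),
                  colClasses = "character")$patient_id
  cols <- specs$name
  values <- matrix(0L, length(ids), length(cols),
                   dimnames = list(ids, cols))
  if (nrow(trip) > 0L)
    values[cbind(match(trip$patient_id, ids),
                 match(trip$feature_name, cols))] <- 1L
  structure(list(patient_ids = ids, specs = specs, values = values,
                 n_features_prefilter = NA_integer_,
                 min_support = NA_integer_),
            class = "feature_matrix")
}
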