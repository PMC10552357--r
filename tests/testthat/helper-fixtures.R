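# in-code fixtures and independent oracles used across the suite

rec <- function(pid, src, date, sys = "none", code = "", text = "") {
  data.frame(patient_id = pid, source = src, date = as.Date(date),
             code_system = sys, code = code, free_text = text,
             stringsAsFactors = FALSE)
}

mk_cohort <- function(recs, labels = NULL, ages = NULL) {
  ids <- sort(unique(recs$patient_id))
  patients <- data.frame(patient_id = ids,
                         age_years = if (is.null(ages)) 52L else ages,
                         sex = "F",
                         label = if (is.null(labels)) "unlabelled"
                                 else unname(labels[ids]),
                         stringsAsFactors = FALSE)
  emr_cohort(recs, patients)
}

mk_chart <- function(recs) {
  patient_chart(mk_cohort(recs), recs$patient_id[1L])
}

# a chart holding only ICD-9 627* billing codes at the given dates
chart_627 <- function(dates, src = "billing") {
  recs <- do.call(rbind, lapply(seq_along(dates), function(i)
    rec("p1", src, dates[i], "ICD9CM", "627.2")))
  mk_chart(recs)
}

# brute-force window oracle: a clause holds iff SOME size-min_count subset
# of the matching record dates spans at most the window
bf_window_satisfied <- function(dates, min_count, window_months) {
  dates <- sort(as.Date(dates))
  n <- length(dates)
  if (n < min_count) return(FALSE)
  if (window_months == "whole_chart") return(TRUE)
  wd <- c("12" = 365, "24" = 730)[[window_months]]
  subs <- utils::combn(n, min_count)
  any(apply(subs, 2L, function(ix)
    as.numeric(max(dates[ix]) - min(dates[ix])) <= wd))
}

# independent code matcher (deliberately separate from the package's)
bf_match_dates_code <- function(chart, prefix, scope) {
  r <- as.data.frame(chart$records)
  r <- r[r$source %in% scope & nzchar(r$code), ]
  norm <- toupper(gsub("\\.| ", "", r$code))
  r$date[substr(norm, 1L, nchar(prefix)) == toupper(prefix)]
}

# Fleiss kappa by explicit pairwise-agreement counting
bf_fleiss <- function(ratings) {
  r <- rowSums(ratings)[1L]
  n_pairs <- choose(r, 2)
  P_i <- apply(ratings, 1L, function(x) sum(choose(x, 2)) / n_pairs)
  p_j <- colSums(ratings) / sum(ratings)
  Pe <- sum(p_j^2)
  (mean(P_i) - Pe) / (1 - Pe)
}

# small labelled cohort with a perfectly separating planted rule
small_planted_cohort <- function(n = 300, seed = 42, ...) {
  generate_cohort(cohort_config(n, seed = seed, reviewer_error_rate = 0,
                                unclassifiable_rate = 0, ...))
}
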