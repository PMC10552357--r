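#' The planted ground-truth phenotype rule
#'
#' The rule the synthetic generator plants: at least two ICD-9 627* diagnosis
#' records (billing, encounter diagnosis or problem list) within a rolling
#' 24-month window, OR at least one ATC G03CA* (natural and semisynthetic
#' estrogens) prescription anywhere in the chart.
#'
#' @return A `case_definition`.
#' @export
default_planted_definition <- function() {
  case_definition(
    clause("code_prefix", "627", min_count = 2L, window_months = "24",
           scope = .diag_sources),
    clause("code_prefix", "G03CA", min_count = 1L,
           window_months = "whole_chart", scope = "medication")
  )
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: women aged 45-60,
#' ~19% case prevalence, multi-year charts with overdispersed per-patient
#' record counts, chronic-condition distractor codes, negated/uncertain
#' menopause text, sub-threshold signal in non-cases, and a panel of
#' imperfect chart reviewers.
#'
#' @param n_patients number of patients.
#' @param prevalence true case prevalence (default 0.19, the preliminary
#'   search estimate the study design used).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @param date_start,date_end chart date span (default a 10-year window).
#' @param planted_definition the ground-truth `case_definition` every case
#'   chart is built to satisfy and every non-case chart to fail.
#' @param text_noise_rate probability that a non-case chart carries one
#'   isolated affirmative target-term mention in free-text (default 0.10).
#' @param negation_rate probability that a non-case chart carries a negated
#'   or uncertain target-term construction (default 0.30).
#' @param subthreshold_rate probability that a non-case chart carries
#'   sub-threshold code signal: a single 627* code, or a pair more than 24
#'   months apart (default 0.10; a single code or prescription alone is not
#'   diagnostic).
#' @param g03_distractor_rate probability that any chart carries a non-CA
#'   G03 prescription (hormonal contraceptives etc.), so coarser ATC
#'   prefixes are strictly noisier than G03CA (default 0.05).
#' @param affirmative_text_rate probability that a case chart also carries
#'   affirmative menopause free-text (default 0.5).
#' @param reviewer_error_rate per-reviewer independent label-flip
#'   probability (default 0.025, calibrated so the expected Fleiss kappa of
#'   the panel is about 0.84, good-to-excellent agreement; must be < 0.5).
#' @param n_reviewers reviewer panel size (default 5).
#' @param unclassifiable_rate probability a chart is marked unclassifiable
#'   (default 1/2776, one chart in a 2,776-chart review).
#' @param records_mean,records_dispersion negative-binomial mean and
#'   dispersion of per-patient background record counts (default mean 15,
#'   size 1.5 over the 10-year span).
#' @param vocab_size size of the background free-text vocabulary, sampled
#'   Zipf-like so common words recur and rare words abound (default 2000).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          prevalence = 0.19,
                          seed = 1L,
                          date_start = as.Date("2011-01-01"),
                          date_end = as.Date("2020-12-31"),
                          planted_definition = default_planted_definition(),
                          text_noise_rate = 0.10,
                          negation_rate = 0.30,
                          subthreshold_rate = 0.10,
                          g03_distractor_rate = 0.05,
                          affirmative_text_rate = 0.5,
                          reviewer_error_rate = 0.025,
                          n_reviewers = 5L,
                          unclassifiable_rate = 1 / 2776,
                          records_mean = 15,
                          records_dispersion = 1.5,
                          vocab_size = 2000L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) stop("n_patients must be >= 1")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)")
  for (r in c(text_noise_rate, negation_rate, subthreshold_rate,
              g03_distractor_rate, affirmative_text_rate,
              unclassifiable_rate))
    if (!is.numeric(r) || r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (reviewer_error_rate < 0 || reviewer_error_rate >= 0.5)
    stop("reviewer_error_rate must lie in [0, 0.5)")
  date_start <- as.Date(date_start); date_end <- as.Date(date_end)
  if (is.na(date_start) || is.na(date_end) || date_end < date_start)
    stop("invalid date span")
  stopifnot(inherits(planted_definition, "case_definition"))
  span_days <- as.numeric(date_end - date_start)
  windowed <- any(vapply(planted_definition$clauses,
                         function(cl) cl$window_months != "whole_chart",
                         logical(1)))
  if (windowed && span_days < 730)
    stop("planted definition is not satisfiable: date span shorter than ",
         "the 24-month clause window")
  structure(list(n_patients = n_patients, prevalence = prevalence,
                 seed = as.integer(seed), date_start = date_start,
                 date_end = date_end,
                 planted_definition = planted_definition,
                 text_noise_rate = text_noise_rate,
                 negation_rate = negation_rate,
                 subthreshold_rate = subthreshold_rate,
                 g03_distractor_rate = g03_distractor_rate,
                 affirmative_text_rate = affirmative_text_rate,
                 reviewer_error_rate = reviewer_error_rate,
                 n_reviewers = as.integer(n_reviewers),
                 unclassifiable_rate = unclassifiable_rate,
                 records_mean = records_mean,
                 records_dispersion = records_dispersion,
                 vocab_size = as.integer(vocab_size)),
            class = "cohort_config")
}

## deterministic pseudo-clinical vocabulary (pronounceable 2-3 syllable words)
make_vocab <- function(n) {
  cons <- c("b", "c", "d", "f", "g", "h", "k", "l", "m", "n",
            "p", "r", "s", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  two <- as.vector(outer(syl, syl, paste0))
  three <- as.vector(outer(two[seq_len(60L)], syl, paste0))
  words <- unique(c(two, three))
  words <- setdiff(words, c("meno", "pausa"))  # keep clear of target terms
  if (n > length(words)) stop("vocab_size too large")
  words[seq_len(n)]
}

sample_words <- function(vocab, weights, k) {
  sample(vocab, k, replace = TRUE, prob = weights)
}

rand_dates <- function(k, start, end) {
  start + floor(runif(k) * (as.numeric(end - start) + 1))
}

#' Generate a labelled synthetic primary-care cohort
#'
#' Builds a five-table chart extract with a planted ground-truth phenotype:
#' every true case satisfies the planted case definition (627* diagnosis
#' pairs within window and/or G03CA* prescriptions, plus optional
#' affirmative text), every true non-case fails it but carries chronic-
#' condition distractor codes, negated/uncertain target-term text, and
#' sub-threshold signal. A simulated reviewer panel then produces the
#' reference-standard labels and an agreement table.
#'
#' @param config a `cohort_config`.
#' @return A `synthetic_cohort` (also an `emr_cohort`) with components
#'   `records`, `patients` (consensus reference labels in `label`), `truth`
#'   (named vector of planted case/non_case), `ratings` (subjects x
#'   categories reviewer count table) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  truth <- setNames(ifelse(runif(n) < config$prevalence, "case", "non_case"),
                    ids)
  age <- sample(45:60, n, replace = TRUE)

  vocab <- make_vocab(config$vocab_size)
  vw <- 1 / seq_along(vocab)^0.8
  vw <- vw / sum(vw)
  noise_text <- function(k_words) {
    vapply(k_words, function(k)
      paste(sample_words(vocab, vw, k), collapse = " "), character(1))
  }

  chronic <- chronic_condition_codes()
  atc_distractors <- c("C09AA05", "N06AB04", "A10BA02", "C10AA01", "N02BE01",
                       "R03AC02", "M01AE01", "A02BC01", "C07AB02", "N05BA04")
  g03_non_ca <- c("G03AC06", "G03BA03", "G03CB01", "G03XC01")
  referral_specialties <- c("gynecology", "cardiology", "dermatology",
                            "endocrinology", "neurology", "psychiatry",
                            "orthopedics", "urology")
  icd_suffix <- c("", ".1", ".2", ".4", ".9")

  parts <- list()
  add <- function(pid, source, date, code_system, code, text) {
    parts[[length(parts) + 1L]] <<- data.table(
      patient_id = pid, source = source, date = as.Date(date, origin = "1970-01-01"),
      code_system = code_system, code = code, free_text = text)
  }

  ## ---- background records (both classes) -----------------------------
  n_rec <- pmax(1L, rnbinom(n, size = config$records_dispersion,
                            mu = config$records_mean))
  N <- sum(n_rec)
  pid <- rep(ids, n_rec)
  src <- sample(.sources, N, replace = TRUE,
                prob = c(0.30, 0.28, 0.15, 0.17, 0.10))
  dts <- rand_dates(N, config$date_start, config$date_end)
  code_system <- rep("none", N)
  code <- rep("", N)
  text <- rep("", N)

  is_diag <- src %in% .diag_sources
  has_code <- is_diag & runif(N) < 0.5
  k_code <- sum(has_code)
  if (k_code > 0L) {
    fam <- sample(chronic$code, k_code, replace = TRUE)
    code[has_code] <- paste0(fam, sample(icd_suffix, k_code, replace = TRUE))
    code_system[has_code] <- "ICD9CM"
  }
  needs_text <- (is_diag & (!has_code | runif(N) < 0.6))
  k_text <- sum(needs_text)
  if (k_text > 0L)
    text[needs_text] <- noise_text(sample(1:4, k_text, replace = TRUE))

  is_med <- src == "medication"
  k_med <- sum(is_med)
  if (k_med > 0L) {
    code[is_med] <- sample(atc_distractors, k_med, replace = TRUE)
    code_system[is_med] <- "ATC"
  }
  is_ref <- src == "referral"
  k_ref <- sum(is_ref)
  if (k_ref > 0L)
    text[is_ref] <- sample(referral_specialties, k_ref, replace = TRUE)

  add(pid, src, dts, code_system, code, text)

  ## ---- non-CA G03 distractor prescriptions (both classes) ------------
  g03_pat <- ids[runif(n) < config$g03_distractor_rate]
  if (length(g03_pat) > 0L)
    add(g03_pat, "medication",
        rand_dates(length(g03_pat), config$date_start, config$date_end),
        "ATC", sample(g03_non_ca, length(g03_pat), replace = TRUE), "")

  ## ---- planted case signal -------------------------------------------
  case_ids <- ids[truth == "case"]
  affirm_terms <- c("menopausal symptoms", "postmenopausal",
                    "menopause", "climacteric symptoms")
  span_days <- as.numeric(config$date_end - config$date_start)
  for (cid in case_ids) {
    mode <- sample(c("icd_pair", "estrogen", "both"), 1L,
                   prob = c(0.30, 0.45, 0.25))
    if (mode %in% c("icd_pair", "both")) {
      gap <- runif(1, 30, 700)
      anchor <- config$date_start +
        floor(runif(1) * max(1, span_days - gap))
      k_extra <- sample(0:1, 1L, prob = c(0.7, 0.3))
      d <- c(anchor, anchor + round(gap))
      if (k_extra > 0L) d <- c(d, anchor + round(runif(1, 0, gap)))
      add(cid, sample(.diag_sources, length(d), replace = TRUE), d,
          "ICD9CM", paste0("627", sample(icd_suffix, length(d), replace = TRUE)),
          "")
    }
    if (mode %in% c("estrogen", "both")) {
      k <- 1L + (runif(1) < 0.4)
      add(cid, rep("medication", k),
          rand_dates(k, config$date_start, config$date_end), "ATC",
          paste0("G03CA", sample(c("03", "04", "57"), k, replace = TRUE)), "")
    }
    if (runif(1) < config$affirmative_text_rate) {
      k <- 1L + (runif(1) < 0.4)
      add(cid, sample(.diag_sources, k, replace = TRUE),
          rand_dates(k, config$date_start, config$date_end), "none", "",
          paste(sample(affirm_terms, k, replace = TRUE),
                noise_text(rep(1L, k))))
    }
  }

  ## ---- non-case noise --------------------------------------------------
  noncase_ids <- ids[truth == "non_case"]
  lexicon <- default_negation_lexicon()
  neg_terms <- c("menopause", "menopausal", "climacteric")
  for (nid in noncase_ids) {
    if (runif(1) < config$subthreshold_rate) {
      distant_ok <- span_days >= 800
      if (distant_ok && runif(1) < 0.5) {
        gap <- runif(1, 760, min(span_days, 1600))
        anchor <- config$date_start +
          floor(runif(1) * max(1, span_days - gap))
        add(nid, sample(.diag_sources, 2L, replace = TRUE),
            c(anchor, anchor + round(gap)), "ICD9CM",
            paste0("627", sample(icd_suffix, 2L, replace = TRUE)), "")
      } else {
        add(nid, sample(.diag_sources, 1L),
            rand_dates(1L, config$date_start, config$date_end), "ICD9CM",
            paste0("627", sample(icd_suffix, 1L)), "")
      }
    }
    if (runif(1) < config$negation_rate) {
      tpl <- sample(unclass(lexicon), 1L)
      construction <- gsub("{term}", sample(neg_terms, 1L), tpl, fixed = TRUE)
      add(nid, sample(.diag_sources, 1L),
          rand_dates(1L, config$date_start, config$date_end), "none", "",
          construction)
    }
    if (runif(1) < config$text_noise_rate) {
      add(nid, sample(.diag_sources, 1L),
          rand_dates(1L, config$date_start, config$date_end), "none", "",
          paste(sample(neg_terms, 1L), noise_text(2L)))
    }
  }

  records <- rbindlist(parts)
  rev <- simulate_reviewers(truth, config)
  patients <- data.table(patient_id = ids, age_years = age, sex = "F",
                         label = unname(rev$labels[ids]))
  cohort <- emr_cohort(records, patients)
  cohort$truth <- truth
  cohort$ratings <- rev$ratings
  cohort$config <- config
  class(cohort) <- c("synthetic_cohort", class(cohort))

  ## construction guarantee: the planted rule separates truth perfectly
  verdict <- evaluate_definition_cohort(cohort, config$planted_definition)
  stopifnot(all(verdict[truth == "case"]),
            !any(verdict[truth == "non_case"]))
  cohort
}

#' Simulate a reviewer panel over true labels
#'
#' Each reviewer independently flips each true label with probability
#' `reviewer_error_rate`; the consensus label is the majority vote, with a
#' small configured fraction of charts marked unclassifiable (and majority
#' ties, possible only with an even panel, also unclassifiable).
#'
#' @param truth named character vector of true "case"/"non_case" labels.
#' @param config a `cohort_config` (fields `reviewer_error_rate`,
#'   `n_reviewers`, `unclassifiable_rate` are used).
#' @return List with `labels` (named consensus labels, possibly
#'   "unclassifiable") and `ratings` (subjects x 2 count matrix suitable for
#'   [fleiss_kappa()]).
#' @export
simulate_reviewers <- function(truth, config) {
  n <- length(truth)
  r <- config$n_reviewers
  is_case <- truth == "case"
  flips <- matrix(runif(n * r) < config$reviewer_error_rate, n, r)
  says_case <- ifelse(flips, !is_case, is_case)
  votes_case <- rowSums(says_case)
  ratings <- cbind(case = votes_case, non_case = r - votes_case)
  rownames(ratings) <- names(truth)
  labels <- ifelse(votes_case * 2 == r, "unclassifiable",
                   ifelse(votes_case * 2 > r, "case", "non_case"))
  labels[runif(n) < config$unclassifiable_rate] <- "unclassifiable"
  names(labels) <- names(truth)
  list(labels = labels, ratings = ratings)
}
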