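#' EMR cohort containers
#'
#' An `emr_cohort` bundles the five-table chart extract of a study sample:
#' a long table of dated clinical records plus one row of demographics (and
#' an optional reference-standard label) per patient. Records mirror the
#' source tables of a primary-care sentinel-network extract: billing claims,
#' encounter diagnoses, the health-condition/problem list, prescribed
#' medications, and referrals.
#'
#' @param records data.frame with columns `patient_id`, `source` (one of
#'   billing, encounter_diagnosis, health_condition, medication, referral),
#'   `date` (Date or ISO-8601 string), `code_system` (ICD9CM, ATC or none),
#'   `code`, `free_text`. `code` and `free_text` may be empty but not both.
#' @param patients data.frame with columns `patient_id`, `age_years`, `sex`
#'   and optionally `label` (case, non_case, unclassifiable, unlabelled).
#' @return An object of class `emr_cohort`.
#' @export
emr_cohort <- function(records, patients) {
  records <- as.data.table(records)
  patients <- as.data.table(patients)
  req <- c("patient_id", "source", "date", "code_system", "code", "free_text")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L)
    stop("records table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c("patient_id", "age_years", "sex"), names(patients))
  if (length(miss) > 0L)
    stop("patients table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"label" %in% names(patients)) patients$label <- "unlabelled"

  records[, patient_id := as.character(patient_id)]
  records[, date := as.Date(date)]
  for (col in c("source", "code_system", "code", "free_text"))
    set(records, j = col, value = as.character(records[[col]]))
  records[is.na(code), code := ""]
  records[is.na(free_text), free_text := ""]
  validate_records(records)

  patients[, patient_id := as.character(patient_id)]
  patients[, age_years := as.integer(age_years)]
  bad <- setdiff(unique(patients$label),
                 c("case", "non_case", "unclassifiable", "unlabelled"))
  if (length(bad) > 0L)
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  orphan <- setdiff(unique(records$patient_id), patients$patient_id)
  if (length(orphan) > 0L)
    stop(length(orphan), " record patient_id(s) absent from patients table")

  setcolorder(records, req)
  setkey(records, patient_id, date)
  structure(list(records = records, patients = patients),
            class = "emr_cohort")
}

validate_records <- function(records) {
  bad <- which(!records$source %in% .sources)
  if (length(bad) > 0L)
    stop("invalid source at record row(s) ", paste(head(bad, 5), collapse = ", "))
  bad <- which(!records$code_system %in% c("ICD9CM", "ATC", "none"))
  if (length(bad) > 0L)
    stop("invalid code_system at record row(s) ", paste(head(bad, 5), collapse = ", "))
  bad <- which(records$code == "" & records$free_text == "")
  if (length(bad) > 0L)
    stop("record row(s) with neither code nor free_text: ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(is.na(records$date))
  if (length(bad) > 0L)
    stop("invalid date at record row(s) ", paste(head(bad, 5), collapse = ", "))
  bad <- which(records$code_system == "ATC" & records$source != "medication")
  if (length(bad) > 0L)
    stop("ATC codes outside the medication table at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(records$source == "referral" & records$code != "")
  if (length(bad) > 0L)
    stop("referral records must be free-text only; offending row(s) ",
         paste(head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.emr_cohort <- function(x, ...) {
  lab <- table(x$patients$label)
  cat("<emr_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$records), " records\n", sep = "")
  cat("  labels:", paste(names(lab), lab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Extract one patient chart
#'
#' @param cohort an `emr_cohort`.
#' @param id a patient identifier present in the cohort.
#' @return A `patient_chart`: the patient's demographics, label and records
#'   sorted by ascending date.
#' @export
patient_chart <- function(cohort, id) {
  stopifnot(inherits(cohort, "emr_cohort"))
  id <- as.character(id)
  row <- cohort$patients[patient_id == id]
  if (nrow(row) == 0L) stop("unknown patient_id: ", id)
  recs <- cohort$records[patient_id == id][order(date)]
  structure(list(patient_id = id,
                 age_years = row$age_years[1L],
                 sex = row$sex[1L],
                 label = row$label[1L],
                 records = recs),
            class = "patient_chart")
}

#' @export
print.patient_chart <- function(x, ...) {
  cat("<patient_chart> ", x$patient_id, " (", x$sex, ", ", x$age_years,
      "y, label=", x$label, "): ", nrow(x$records), " records\n", sep = "")
  invisible(x)
}

#' Restrict a cohort to a subset of patients
#'
#' @param cohort an `emr_cohort`.
#' @param ids patient identifiers to keep.
#' @return The restricted `emr_cohort` (other components, e.g. ground truth
#'   of a synthetic cohort, are subset alongside).
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "emr_cohort"))
  ids <- as.character(ids)
  out <- cohort
  out$patients <- cohort$patients[patient_id %in% ids]
  out$records <- cohort$records[patient_id %in% ids]
  if (!is.null(out$truth)) out$truth <- out$truth[names(out$truth) %in% ids]
  out
}

#' Labelled patient ids of a cohort
#'
#' Patients labelled `case` or `non_case`; `unclassifiable` and `unlabelled`
#' charts are excluded from every validity computation.
#'
#' @param cohort an `emr_cohort`.
#' @return Character vector of patient ids.
#' @export
labelled_ids <- function(cohort) {
  cohort$patients[label %in% c("case", "non_case"), patient_id]
}

#' Cohort age / comorbidity summary
#'
#' Descriptive counts by age band (45-49, 50-54, 55-60) and by number of
#' distinct chronic-condition code families present in the chart (0, 1, 2,
#' 3+). Chronic conditions are recognised by ICD-9 code-family prefix from
#' `chronic_condition_codes()`.
#'
#' @param cohort an `emr_cohort`.
#' @return data.frame with columns `band`, `group`, `n`; band counts within
#'   each group sum to the number of patients.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "emr_cohort"))
  age <- cohort$patients$age_years
  age_band <- cut(age, breaks = c(-Inf, 49, 54, Inf),
                  labels = c("45-49", "50-54", "55-60"))
  age_tab <- table(factor(age_band, levels = c("45-49", "50-54", "55-60")))

  fams <- chronic_condition_codes()$code
  recs <- cohort$records[code_system == "ICD9CM" & code != ""]
  ncond <- integer(nrow(cohort$patients))
  names(ncond) <- cohort$patients$patient_id
  if (nrow(recs) > 0L) {
    norm <- normalize_code(recs$code)
    fam_hit <- rep(NA_character_, length(norm))
    for (f in fams) fam_hit[startsWith(norm, f)] <- f
    hits <- data.table(patient_id = recs$patient_id, fam = fam_hit)[!is.na(fam)]
    if (nrow(hits) > 0L) {
      cnt <- hits[, .(k = uniqueN(fam)), by = patient_id]
      ncond[cnt$patient_id] <- cnt$k
    }
  }
  cond_band <- cut(ncond, breaks = c(-Inf, 0, 1, 2, Inf),
                   labels = c("0", "1", "2", "3+"))
  cond_tab <- table(cond_band)

  rbind(
    data.frame(group = "age_years", band = names(age_tab),
               n = as.integer(age_tab)),
    data.frame(group = "n_chronic_conditions", band = names(cond_tab),
               n = as.integer(cond_tab))
  )
}

#' Chronic-condition distractor code families
#'
#' Eleven ICD-9 code families for chronic conditions commonly used as
#' validated surveillance definitions (chronic kidney disease, COPD,
#' dementia, depression, diabetes, dyslipidemia, epilepsy, herpes zoster,
#' hypertension, osteoarthritis, parkinsonism). Used both as the default
#' synthetic distractor pool and by [cohort_summary()].
#'
#' @return data.frame with columns `condition`, `code_system`, `code`.
#' @export
chronic_condition_codes <- function() {
  data.frame(
    condition = c("chronic_kidney_disease", "copd", "dementia", "depression",
                  "diabetes_mellitus", "dyslipidemia", "epilepsy",
                  "herpes_zoster", "hypertension", "osteoarthritis",
                  "parkinsonism"),
    code_system = "ICD9CM",
    code = c("585", "496", "290", "311", "250", "272", "345", "053", "401",
             "715", "332"),
    stringsAsFactors = FALSE
  )
}
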