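## Cohort I/O: one delimited text file per source table, plus demographics,
## labels, and (for synthetic cohorts) truth, reviewer ratings and a
## reproducibility manifest.

.record_columns <- c("patient_id", "date", "code_system", "code", "free_text")

#' Write / read a cohort as a directory of CSV tables
#'
#' Writes one UTF-8 CSV per source table (`billing.csv`,
#' `encounter_diagnosis.csv`, `health_condition.csv`, `medication.csv`,
#' `referral.csv`; columns patient_id, date (ISO-8601), code_system, code,
#' free_text), a demographics table `patients.csv` (patient_id, birth_year,
#' sex), a label table `labels.csv` (patient_id, label), and - for
#' synthetic cohorts - `truth.csv`, `ratings.csv` and a `manifest.yaml`
#' recording the seed, the reference year used to convert ages to birth
#' years, and a config fingerprint.
#'
#' @param cohort an `emr_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` the
#'   reconstructed cohort.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "emr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref_year <- if (!is.null(cohort$config))
    as.integer(format(cohort$config$date_end, "%Y"))
  else if (nrow(cohort$records) > 0L)
    as.integer(format(max(cohort$records$date), "%Y"))
  else
    as.integer(format(Sys.Date(), "%Y"))

  for (src in .sources) {
    tab <- cohort$records[source == src,
                          .(patient_id, date = format(date, "%Y-%m-%d"),
                            code_system, code, free_text)]
    write.csv(tab[order(patient_id, date)],
              file.path(dir, paste0(src, ".csv")), row.names = FALSE)
  }
  pats <- cohort$patients[order(patient_id),
                          .(patient_id, birth_year = ref_year - age_years,
                            sex)]
  write.csv(pats, file.path(dir, "patients.csv"), row.names = FALSE)
  write.csv(cohort$patients[order(patient_id), .(patient_id, label)],
            file.path(dir, "labels.csv"), row.names = FALSE)
  if (!is.null(cohort$truth))
    write.csv(data.frame(patient_id = names(cohort$truth),
                         truth = unname(cohort$truth))[
                order(names(cohort$truth)), ],
              file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(cohort$ratings))
    write.csv(data.frame(patient_id = rownames(cohort$ratings),
                         case = cohort$ratings[, "case"],
                         non_case = cohort$ratings[, "non_case"]),
              file.path(dir, "ratings.csv"), row.names = FALSE)
  manifest <- list(reference_year = ref_year,
                   n_patients = nrow(cohort$patients))
  if (!is.null(cohort$config)) {
    manifest$seed <- cohort$config$seed
    manifest$config_fingerprint <- config_fingerprint(cohort$config)
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

read_table_checked <- function(path, required) {
  tab <- read.csv(path, colClasses = "character")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0L)
    stop(basename(path), " is missing required column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  parts <- lapply(.sources, function(src) {
    path <- file.path(dir, paste0(src, ".csv"))
    if (!file.exists(path)) stop("missing source table: ", basename(path))
    tab <- read_table_checked(path, .record_columns)
    if (nrow(tab) > 0L) tab$source <- src else tab$source <- character(0)
    tab
  })
  records <- rbindlist(parts)
  pats <- read_table_checked(file.path(dir, "patients.csv"),
                             c("patient_id", "birth_year", "sex"))
  labs <- read_table_checked(file.path(dir, "labels.csv"),
                             c("patient_id", "label"))
  manifest_path <- file.path(dir, "manifest.yaml")
  ref_year <- if (file.exists(manifest_path))
    yaml::read_yaml(manifest_path)$reference_year
  else if (nrow(records) > 0L)
    as.integer(substr(max(records$date), 1L, 4L))
  else
    as.integer(format(Sys.Date(), "%Y"))

  patients <- merge(pats, labs, by = "patient_id", all.x = TRUE)
  patients$age_years <- ref_year - as.integer(patients$birth_year)
  patients$label[is.na(patients$label)] <- "unlabelled"
  patients <- patients[, c("patient_id", "age_years", "sex", "label")]
  cohort <- emr_cohort(records, patients)

  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    tr <- read_table_checked(truth_path, c("patient_id", "truth"))
    cohort$truth <- setNames(tr$truth, tr$patient_id)
  }
  ratings_path <- file.path(dir, "ratings.csv")
  if (file.exists(ratings_path)) {
    ra <- read_table_checked(ratings_path,
                             c("patient_id", "case", "non_case"))
    m <- cbind(case = as.integer(ra$case),
               non_case = as.integer(ra$non_case))
    rownames(m) <- ra$patient_id
    cohort$ratings <- m
  }
  cohort
}

## small deterministic fingerprint of a serializable object (manifest use
## only; not a cryptographic hash)
config_fingerprint <- function(x) {
  x$planted_definition <- lapply(x$planted_definition$clauses, unclass)
  raw <- serialize(x, NULL, version = 2)
  v <- as.double(raw)
  sprintf("%d-%.0f-%.0f", length(v), sum(v),
          sum(v * (seq_along(v) %% 997)) %% 2^31)
}
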