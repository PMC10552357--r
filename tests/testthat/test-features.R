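# cohort where feature support can be controlled exactly: k patients carry
# one hypertension code each (plus a shared anchor code so every patient
# has a record)
support_cohort <- function(k, n = 12) {
  ids <- sprintf("s%02d", seq_len(n))
  recs <- do.call(rbind, c(
    lapply(ids, function(p) rec(p, "billing", "2019-01-01", "ICD9CM", "250")),
    lapply(ids[seq_len(k)], function(p)
      rec(p, "billing", "2019-06-01", "ICD9CM", "401"))))
  mk_cohort(recs)
}

test_that("minimum support keeps features in >= 10 patients, drops 9", {
  fm9 <- build_feature_matrix(support_cohort(9), min_support = 10)
  fm10 <- build_feature_matrix(support_cohort(10), min_support = 10)
  expect_false("icd9:401|ge1_whole_chart" %in% colnames(fm9$values))
  expect_true("icd9:401|ge1_whole_chart" %in% colnames(fm10$values))
  # support counts patients, not records
  dup <- support_cohort(9)
  extra <- rec("s01", "billing", "2019-07-01", "ICD9CM", "401")
  dup$records <- data.table::rbindlist(list(dup$records, extra))
  fm <- build_feature_matrix(dup, min_support = 10)
  expect_false("icd9:401|ge1_whole_chart" %in% colnames(fm$values))
})

test_that("temporal variants respect counts and windows", {
  # 10 background patients push the 627 features past min_support
  base <- do.call(rbind, lapply(sprintf("b%02d", 1:10), function(p)
    rbind(rec(p, "billing", "2019-01-01", "ICD9CM", "627"),
          rec(p, "billing", "2019-02-01", "ICD9CM", "627"))))
  one <- rec("x1", "billing", "2019-01-01", "ICD9CM", "627")
  pair13mo <- rbind(rec("x2", "billing", "2018-01-01", "ICD9CM", "627"),
                    rec("x2", "billing", "2019-02-01", "ICD9CM", "627"))
  fm <- build_feature_matrix(mk_cohort(rbind(base, one, pair13mo)),
                             min_support = 1)
  v <- fm$values
  expect_equal(v["x1", "icd9:627|ge1_whole_chart"], 1L)
  expect_equal(v["x1", "icd9:627|ge2_whole_chart"], 0L)
  expect_equal(v["x1", "icd9:627|ge2_24mo"], 0L)
  # 396 days apart: inside 24 months, outside 12
  expect_equal(v["x2", "icd9:627|ge2_24mo"], 1L)
  expect_equal(v["x2", "icd9:627|ge2_12mo"], 0L)
  expect_equal(v["x2", "icd9:627|ge2_whole_chart"], 1L)
})

test_that("ad hoc importance is (TP - FP) / P and scale-invariant", {
  col <- c(rep(1, 10), rep(0, 90), rep(1, 2), rep(0, 98))
  labs <- c(rep("case", 100), rep("non_case", 100))
  expect_equal(adhoc_importance(col, labs), 0.08)
  expect_equal(adhoc_importance(rep(1, 200), labs), 0)   # TP == FP
  expect_equal(adhoc_importance(c(rep(1, 100), rep(0, 100)), labs), 1)
  # duplicating the whole cohort leaves the score unchanged
  expect_equal(adhoc_importance(rep(col, 2), rep(labs, 2)),
               adhoc_importance(col, labs))
  expect_error(adhoc_importance(col, rep("non_case", 200)), "no cases")
})

test_that("prescreen keeps top-k by score with lexicographic ties", {
  set.seed(12)
  n <- 40
  labs <- c(rep("case", 12), rep("non_case", 28))
  vals <- cbind(
    planted = c(rep(1L, 12), rep(0L, 28)),         # score 1.0
    tie_a = c(rep(1L, 6), rep(0L, 34)),            # score 0.5
    tie_b = c(rep(1L, 6), rep(0L, 34)),            # score 0.5
    noise = sample(0:1, n, replace = TRUE))
  rownames(vals) <- sprintf("p%02d", 1:n)
  fm <- structure(list(patient_ids = rownames(vals),
                       specs = data.frame(name = colnames(vals)),
                       values = vals, n_features_prefilter = 4L,
                       min_support = 1L),
                  class = "feature_matrix")
  # k larger than the column count keeps everything
  expect_equal(ncol(prescreen_top_k(fm, labs, k = 300)$values), 4)
  # the perfectly-scoring planted column survives any k >= 1
  expect_true("planted" %in% colnames(prescreen_top_k(fm, labs, 1)$values))
  # tie at the cutoff: lexicographically smaller name wins
  kept3 <- colnames(prescreen_top_k(fm, labs, 2)$values)
  expect_true("tie_a" %in% kept3)
  expect_false("tie_b" %in% kept3)
  # never removes a column scoring strictly above the k-th highest
  sc <- apply(vals, 2, adhoc_importance, labels = labs)
  for (k in 1:3) {
    kept <- colnames(prescreen_top_k(fm, labs, k)$values)
    kth <- sort(sc, decreasing = TRUE)[k]
    expect_true(all(names(sc)[sc > kth] %in% kept))
  }
})

test_that("every matrix column is reproducible from raw charts as a clause", {
  co <- small_planted_cohort(n = 120, seed = 77)
  fm <- build_feature_matrix(co, min_support = 5)
  expect_gt(ncol(fm$values), 20)
  set.seed(3)
  take <- sample(ncol(fm$values), min(40, ncol(fm$values)))
  for (j in take) {
    spec <- fm$specs[j, , drop = FALSE]
    cl <- spec_to_clause(spec)
    verdict <- phenoforge:::evaluate_clause_cohort(co, cl)[fm$patient_ids]
    expect_equal(unname(as.integer(verdict)), unname(fm$values[, j]),
                 info = spec$name)
  }
})

test_that("feature space before min-support reaches the expected scale", {
  co <- generate_cohort(cohort_config(2776, seed = 2024))
  fm <- build_feature_matrix(co)
  expect_gte(fm$n_features_prefilter, 1e4)
  expect_lte(fm$n_features_prefilter, 1e5)
  expect_true(all(colSums(fm$values) >= 10))
  expect_true(all(fm$values %in% c(0L, 1L)))
})

test_that("feature matrices round-trip through the sparse-triplet format", {
  co <- small_planted_cohort(n = 60, seed = 5)
  fm <- build_feature_matrix(co, min_support = 3)
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_feature_matrix(fm, dir)
  back <- read_feature_matrix(dir)
  expect_equal(back$values, fm$values)
  expect_equal(back$specs$name, fm$specs$name)
})
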