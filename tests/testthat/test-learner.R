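# tiny deterministic feature matrix with a perfectly separating column and
# assorted noise, for exercising the learner without a full cohort
toy_matrix <- function(n = 200, p_case = 0.25, seed = 1) {
  set.seed(seed)
  y <- ifelse(runif(n) < p_case, "case", "non_case")
  ids <- sprintf("t%03d", seq_len(n))
  X <- cbind(
    signal = as.integer(y == "case"),
    half = as.integer(y == "case" & runif(n) < 0.5),
    allzero = 0L,
    matrix(as.integer(runif(n * 12) < 0.3), n, 12,
           dimnames = list(NULL, sprintf("noise%02d", 1:12))))
  rownames(X) <- ids
  specs <- data.frame(name = colnames(X), match_kind = "code_prefix",
                      pattern = colnames(X), variant = "ge1_whole_chart",
                      scope = "billing")
  fm <- structure(list(patient_ids = ids, specs = specs, values = X,
                       n_features_prefilter = ncol(X), min_support = 1L),
                  class = "feature_matrix")
  list(fm = fm, y = setNames(y, ids))
}

test_that("train/validation split gives near-equal disjoint halves", {
  ids <- sprintf("p%04d", 1:2775)
  sp <- split_train_validation(ids, seed = 3)
  expect_length(sp$train_test, 1388)
  expect_length(sp$validation, 1387)
  expect_length(intersect(sp$train_test, sp$validation), 0)
  expect_setequal(c(sp$train_test, sp$validation), ids)
  expect_identical(sp, split_train_validation(ids, seed = 3))
  expect_false(identical(sp$train_test,
                         split_train_validation(ids, seed = 4)$train_test))
  sp2 <- split_train_validation(c("a", "b"), seed = 1)
  expect_length(sp2$train_test, 1)
  expect_length(sp2$validation, 1)
})

test_that("the leakage audit rejects any overlap", {
  expect_true(audit_no_leakage(c("a", "b"), c("c", "d")))
  expect_error(audit_no_leakage(c("a", "b"), c("b", "c")), "leakage")
})

test_that("stratified folds balance case counts to within one", {
  labs <- c(rep("case", 100), rep("non_case", 400))
  f <- stratified_folds(labs, 10, seed = 1)
  per_fold <- table(f, labs)
  expect_true(all(per_fold[, "case"] == 10))
  expect_true(all(per_fold[, "non_case"] == 40))

  labs <- c(rep("case", 101), rep("non_case", 403))
  per_fold <- table(stratified_folds(labs, 10, seed = 2), labs)
  expect_lte(diff(range(per_fold[, "case"])), 1)
  expect_lte(diff(range(per_fold[, "non_case"])), 1)

  expect_error(stratified_folds(labs, 1), ">= 2")
  expect_error(stratified_folds(c(rep("case", 3), rep("non_case", 50)), 10),
               "smaller than k")
  expect_error(stratified_folds(rep("case", 30), 3), "both classes")
})

test_that("resampling meets its class-balance postconditions", {
  tm <- toy_matrix(seed = 2)
  X <- tm$fm$values
  X100_400 <- X[rep(1:200, length.out = 500), ]
  y100_400 <- c(rep("case", 100), rep("non_case", 400))

  un <- resample(X100_400, y100_400, "random_under", seed = 5)
  expect_equal(unname(table(un$y)), c(100, 100), ignore_attr = TRUE)
  expect_equal(nrow(un$X), 200)

  ov <- resample(X100_400, y100_400, "random_over", seed = 5)
  expect_equal(sum(ov$y == "case"), 400)
  expect_equal(sum(ov$y == "non_case"), 400)

  cb <- resample(X100_400, y100_400, "combined", seed = 5)
  expect_equal(sum(cb$y == "case"), 200)      # round(sqrt(100 * 400))
  expect_equal(sum(cb$y == "non_case"), 200)

  no <- resample(X100_400, y100_400, "none")
  expect_identical(no$X, X100_400)
  expect_identical(no$y, y100_400)
})

test_that("both reducers keep a label-copy column and kBF drops dead ones", {
  tm <- toy_matrix(n = 300, seed = 3)
  X <- tm$fm$values
  y <- unname(tm$y)
  expect_equal(reduce_features(X, y, "RFE", ncol(X)), colnames(X))
  for (red in c("RFE", "kBF")) {
    kept <- reduce_features(X, y, red, 4)
    expect_length(kept, 4)
    expect_true("signal" %in% kept)
  }
  # a constant all-zero column (score 0) is eliminated before any
  # informative column
  kept <- reduce_features(X, y, "kBF", 10L)
  expect_false("allzero" %in% kept)
  expect_true(all(c("signal", "half") %in% kept))
})

test_that("the chi-squared scorer matches a hand-computed oracle", {
  tm <- toy_matrix(n = 250, seed = 4)
  X <- tm$fm$values
  y <- unname(tm$y)
  sc <- phenoforge:::chi2_scores(X, y)
  for (j in c("signal", "half", "noise03")) {
    # oracle: chi-squared statistic of observed per-class feature totals
    # against expectations from the class priors
    obs <- c(sum(X[y == "case", j]), sum(X[y == "non_case", j]))
    expt <- sum(X[, j]) * c(mean(y == "case"), mean(y == "non_case"))
    expect_equal(unname(sc[j]), sum((obs - expt)^2 / expt), tolerance = 1e-12)
  }
  expect_equal(unname(sc["allzero"]), 0)
})

test_that("the combination table collapses order duplicates of 'none'", {
  cfg <- learner_config(grid = reduced_grid())
  tab <- combination_table(cfg)
  expect_equal(nrow(tab), 14)
  expect_equal(sum(tab$sampling == "none"), 2)
  expect_length(unique(tab$label), 14)
  cfg2 <- learner_config(grid = reduced_grid(), sampling_methods = "none")
  expect_equal(nrow(combination_table(cfg2)), 2)
})

test_that("learner config validates its grids", {
  expect_error(learner_config(grid = list()), "non-empty")
  expect_error(learner_config(outer_folds = 1), ">= 2")
  expect_length(default_grid(), 192)
  expect_length(reduced_grid(), 4)
})

test_that("nested CV separates a planted signal and keeps fold shape", {
  tm <- toy_matrix(n = 240, p_case = 0.25, seed = 6)
  cfg <- learner_config(grid = make_grid(max_depth = 4), top_k = 10,
                        target_count = 5, seed = 6)
  res <- nested_cv(tm$fm, tm$y, cfg)
  expect_s3_class(res, "cv_results")
  expect_length(res, 14)
  f1 <- vapply(res, `[[`, numeric(1), "mean_f1")
  expect_true(any(f1 == 1))  # the signal column is perfectly separable
  for (r in res) expect_equal(nrow(r$per_fold), 10)
  # deterministic given the seed
  res2 <- nested_cv(tm$fm, tm$y, cfg)
  expect_equal(as.data.frame(res2), as.data.frame(res))
})

test_that("permuted labels yield chance-level F1", {
  tm <- toy_matrix(n = 240, p_case = 0.25, seed = 8)
  set.seed(88)
  yperm <- setNames(sample(unname(tm$y)), names(tm$y))
  cfg <- learner_config(grid = make_grid(max_depth = 3),
                        sampling_methods = "none", reducers = "kBF",
                        top_k = 10, target_count = 5, seed = 8)
  res <- nested_cv(tm$fm, yperm, cfg)
  # chance F1 sits near the positive-class prevalence, far below the
  # planted-signal score of 1
  expect_lt(mean(vapply(res, `[[`, numeric(1), "mean_f1"), na.rm = TRUE), 0.6)
})

test_that("best-combination selection maximizes F1 with documented ties", {
  mk <- function(label, f1, sn, ppv)
    structure(list(label = label, mean_f1 = f1, mean_sn = sn,
                   mean_ppv = ppv), class = "combination_result")
  one <- mk("only", 0.5, 0.5, 0.5)
  expect_equal(select_best_combination(list(one))$label, "only")
  res <- list(mk("a", 0.720, 0.9, 0.6), mk("b", 0.799, 0.81, 0.79))
  expect_equal(select_best_combination(res)$label, "b")
  res <- list(mk("a", 0.75, 0.8, 0.7), mk("b", 0.75, 0.9, 0.6))
  expect_equal(select_best_combination(res)$label, "b")
  res <- list(mk("a", 0.75, 0.9, 0.7), mk("b", 0.75, 0.9, 0.6))
  expect_equal(select_best_combination(res)$label, "a")
})

test_that("final trees expose normalized importances and readable rules", {
  tm <- toy_matrix(n = 240, seed = 9)
  cfg <- learner_config(grid = make_grid(max_depth = 4), top_k = 10,
                        target_count = 5, seed = 9)
  combo <- structure(list(sampling = "none", reducer = "kBF",
                          order = "reduce_then_sample", label = "kBF;None",
                          hp_mode = cfg$grid[[1L]]),
                     class = "combination_result")
  tree <- train_final_tree(tm$fm, tm$y, combo, cfg)
  expect_equal(sum(tree$importances), 1, tolerance = 1e-9)
  # the separating column takes all the importance in a depth-1 tree
  expect_equal(unname(tree$importances["signal"]), 1, tolerance = 1e-9)
  expect_gte(length(tree$rules), 2)
  verdicts <- vapply(tree$rules, `[[`, character(1), "verdict")
  expect_setequal(unique(verdicts), c("case", "non_case"))

  # constant labels produce a single leaf with no splits
  fit <- phenoforge:::fit_cart(tm$fm$values,
                               rep("non_case", nrow(tm$fm$values)),
                               cfg$grid[[1L]])
  expect_length(phenoforge:::cart_importances(fit), 0)
  rules <- phenoforge:::cart_rules(fit)
  expect_length(rules, 1)
  expect_length(rules[[1]]$conditions, 0)
})

test_that("candidate definitions count s singletons plus choose(s,2) pairs", {
  specs <- data.frame(name = sprintf("icd9:%03d|ge1_whole_chart", 1:12),
                      match_kind = "code_prefix",
                      pattern = sprintf("%03d", 1:12),
                      variant = "ge1_whole_chart", scope = "billing")
  expect_length(candidate_definitions(specs, 9), 45)
  expect_length(candidate_definitions(specs, 3), 6)
  # s beyond the available features falls back to all of them
  expect_length(candidate_definitions(specs[1:2, ], 9), 3)
})

test_that("validation of a definition on held-out charts is rule-engine based", {
  co <- small_planted_cohort(n = 200, seed = 14)
  ids <- labelled_ids(co)
  rep <- validate_final(default_planted_definition(), co, ids)
  expect_equal(rep$estimates$est[1:2], c(1, 1))
  # a definition that matches nothing: Sn = 0, Sp = 1
  nothing <- case_definition(clause("code_prefix", "999"))
  rep0 <- validate_final(nothing, co, ids)
  e <- rep0$estimates
  expect_equal(e$est[e$metric == "sensitivity"], 0)
  expect_equal(e$est[e$metric == "specificity"], 1)
})
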