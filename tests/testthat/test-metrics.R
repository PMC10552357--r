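test_that("confusion counts partition labelled charts", {
  cm <- confusion(rep("case", 5), rep(TRUE, 5))
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(5, 0, 0, 0))
  cm <- confusion(c("case", "non_case"), c(FALSE, TRUE))
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(0, 1, 1, 0))
  cm <- confusion(character(0), logical(0))
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 0)
  expect_error(confusion(c("case", "non_case"), TRUE), "length")
  expect_error(confusion(c("case", "maybe"), c(TRUE, TRUE)), "case/non_case")
})

test_that("validity metrics match their closed forms and CI", {
  cm <- structure(list(tp = 10, fp = 0, fn = 0, tn = 90),
                  class = "confusion_matrix")
  vm <- validity_metrics(cm)
  expect_equal(vm$estimates$est, c(1, 1, 1, 1))
  expect_equal(vm$f1, 1)

  cm <- structure(list(tp = 50, fp = 50, fn = 50, tn = 50),
                  class = "confusion_matrix")
  vm <- validity_metrics(cm)
  expect_equal(vm$estimates$est, rep(0.5, 4))

  # Wald: 0.5 +/- 1.96 * sqrt(0.25/100)
  ci <- prop_ci(50, 100, "wald")
  expect_equal(unname(round(ci, 3)), c(0.402, 0.598))
  # Wilson and Clopper-Pearson stay inside [0, 1] at the boundary
  expect_gte(prop_ci(0, 20, "wilson")[1], 0)
  expect_equal(unname(prop_ci(20, 20, "clopper-pearson")[2]), 1)
})

test_that("zero-denominator metrics are undefined, not zero", {
  cm <- structure(list(tp = 0, fp = 0, fn = 0, tn = 10),
                  class = "confusion_matrix")
  vm <- validity_metrics(cm)
  e <- vm$estimates
  expect_true(is.na(e$est[e$metric == "sensitivity"]))  # no true cases
  expect_true(is.na(e$est[e$metric == "ppv"]))          # nothing flagged
  expect_equal(e$est[e$metric == "specificity"], 1)
  expect_true(is.na(vm$f1))
})

test_that("transposing the confusion matrix swaps Sn<->Sp and PPV<->NPV", {
  set.seed(5)
  for (i in 1:10) {
    v <- sample(0:30, 4, replace = TRUE)
    cm <- structure(list(tp = v[1], fp = v[2], fn = v[3], tn = v[4]),
                    class = "confusion_matrix")
    tcm <- structure(list(tp = v[4], fp = v[3], fn = v[2], tn = v[1]),
                     class = "confusion_matrix")
    a <- validity_metrics(cm)$estimates
    b <- validity_metrics(tcm)$estimates
    expect_equal(a$est[a$metric == "sensitivity"],
                 b$est[b$metric == "specificity"])
    expect_equal(a$est[a$metric == "ppv"], b$est[b$metric == "npv"])
  }
})

test_that("F1 is the harmonic mean of sensitivity and PPV", {
  # printed combination-table rows: mean Sn / mean PPV reproduce the F1
  expect_equal(round(f1_score(0.812, 0.786), 3), 0.799)
  expect_equal(round(f1_score(0.903, 0.598), 3), 0.720)
  expect_equal(round(f1_score(0.612, 0.854), 3), 0.713)
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0.9), 0)
  expect_equal(f1_score(0.9, 0), 0)

  # bounded by its two inputs everywhere in (0, 1]
  set.seed(9)
  sn <- runif(200, 0.01, 1); ppv <- runif(200, 0.01, 1)
  f1 <- f1_score(sn, ppv)
  expect_true(all(f1 >= pmin(sn, ppv) - 1e-12))
  expect_true(all(f1 <= pmax(sn, ppv) + 1e-12))
})

test_that("validation-set sample size follows the Wald formula", {
  # 1.96^2 * 0.16 / (0.05^2 * 0.19) = 1294.0126..., rounded up
  expect_equal(sample_size(0.80, 0.10, 0.19), 1295L)
  expect_equal(sample_size(0.50, 0.20, 1.0), 97L)
  # vanishes as expected sensitivity approaches 1
  expect_lte(sample_size(0.9999, 0.10, 0.19), 1L)
  # strictly decreasing in prevalence and in CI width
  ps <- c(0.05, 0.1, 0.19, 0.5, 0.9)
  ns <- vapply(ps, function(p) sample_size(0.8, 0.1, p), integer(1))
  expect_true(all(diff(ns) < 0))
  cs <- c(0.05, 0.1, 0.2, 0.4)
  ns <- vapply(cs, function(cc) sample_size(0.8, cc, 0.19), integer(1))
  expect_true(all(diff(ns) < 0))
  expect_error(sample_size(0.8, 0, 0.19), "ci_full_width")
  expect_error(sample_size(0.8, 0.1, 0), "prevalence")
})

test_that("Fleiss kappa matches a brute-force pairwise-agreement oracle", {
  # unanimous raters
  unan <- matrix(c(3, 0, 0, 3, 3, 0), ncol = 2, byrow = TRUE)
  expect_equal(fleiss_kappa(unan)$kappa, 1)

  # per-subject agreement exactly at the chance level
  chance <- matrix(c(2, 0, 0, 2, 1, 1, 1, 1), ncol = 2, byrow = TRUE)
  expect_equal(fleiss_kappa(chance)$kappa, 0)

  # 4-subject, 3-rater, 2-category toy table vs the oracle
  toy <- matrix(c(3, 0, 2, 1, 1, 2, 0, 3), ncol = 2, byrow = TRUE)
  expect_equal(fleiss_kappa(toy)$kappa, bf_fleiss(toy))

  set.seed(31)
  for (i in 1:10) {
    r <- sample(2:5, 1)
    tab <- t(vapply(1:6, function(s) {
      x <- sample(0:r, 1); c(x, r - x)
    }, numeric(2)))
    if (any(colSums(tab) == 0)) next  # degenerate single-category table
    expect_equal(fleiss_kappa(tab)$kappa, bf_fleiss(tab), tolerance = 1e-12)
  }
  expect_error(fleiss_kappa(matrix(c(2, 0, 1, 0), 2)), "same number")
})

test_that("prevalence counts only classifiable charts", {
  labs <- c(rep("case", 3), rep("non_case", 6), "unclassifiable")
  expect_equal(prevalence(labs), 1 / 3)
  expect_error(prevalence(rep("unlabelled", 5)), "classifiable")
})
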