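test_that("code-prefix clauses honour counts, windows and sub-code matching", {
  diag_scope <- c("billing", "encounter_diagnosis", "health_condition")
  cl24 <- clause("code_prefix", "627", min_count = 2, window_months = "24",
                 scope = diag_scope)

  # two 627.2 billings ~17 months apart fall inside the 24-month window
  expect_true(evaluate_clause(chart_627(c("2018-01-10", "2019-06-01")), cl24))
  # ~26 months apart falls outside it
  expect_false(evaluate_clause(chart_627(c("2018-01-10", "2020-03-01")), cl24))
  # a single record never satisfies min_count = 2
  expect_false(evaluate_clause(chart_627("2018-01-10"), cl24))

  # prefix semantics: G03CA03 is a sub-code of G03CA
  med <- mk_chart(rec("p1", "medication", "2019-05-05", "ATC", "G03CA03"))
  expect_true(evaluate_clause(
    med, clause("code_prefix", "G03CA", 1, "whole_chart", "medication")))
  # ...but not of G03D, and scope is respected
  expect_false(evaluate_clause(
    med, clause("code_prefix", "G03D", 1, "whole_chart", "medication")))
  expect_false(evaluate_clause(
    med, clause("code_prefix", "G03CA", 1, "whole_chart", "billing")))

  # dotted / spaced / lower-case codes normalize before matching
  dotted <- mk_chart(rec("p1", "billing", "2019-01-01", "ICD9CM", "6272"))
  expect_true(evaluate_clause(
    dotted, clause("code_prefix", "627", 1, "whole_chart", "billing")))
})

test_that("an empty chart never satisfies any clause", {
  co <- mk_cohort(rec("p1", "billing", "2019-01-01", "ICD9CM", "627"))
  empty <- patient_chart(co, "p1")
  empty$records <- empty$records[0L, ]
  for (cl in list(clause("code_prefix", "627"),
                  clause("text_unigram", "menopause"),
                  clause("code_prefix", "627", 2, "12", "billing")))
    expect_false(evaluate_clause(empty, cl))
})

test_that("definitions are disjunctions of their clauses", {
  def <- default_planted_definition()
  only_med <- mk_chart(rec("p1", "medication", "2019-05-05", "ATC", "G03CA03"))
  expect_true(evaluate_definition(only_med, def))
  both <- mk_chart(rbind(
    rec("p1", "medication", "2019-05-05", "ATC", "G03CA03"),
    rec("p1", "billing", "2018-01-01", "ICD9CM", "627"),
    rec("p1", "billing", "2018-06-01", "ICD9CM", "627.4")))
  expect_true(evaluate_definition(both, def))
  neither <- mk_chart(rec("p1", "billing", "2019-01-01", "ICD9CM", "401"))
  expect_false(evaluate_definition(neither, def))
})

test_that("text clauses match n-grams only after negation filtering", {
  affirm <- mk_chart(rec("p1", "encounter_diagnosis", "2019-01-01",
                         text = "menopausal symptoms severe"))
  cl_uni <- clause("text_unigram", "menopausal")
  cl_bi <- clause("text_bigram", "menopausal symptoms")
  expect_true(evaluate_clause(affirm, cl_uni))
  expect_true(evaluate_clause(affirm, cl_bi))

  negated <- mk_chart(rec("p1", "encounter_diagnosis", "2019-01-01",
                          text = "rule out menopausal symptoms"))
  expect_false(evaluate_clause(negated, cl_uni))
  expect_false(evaluate_clause(negated, cl_bi))
})

test_that("rolling-window evaluation equals brute force over all subsets", {
  # exhaustive cross-check on charts with up to 8 matching records
  set.seed(101)
  diag_scope <- c("billing", "encounter_diagnosis", "health_condition")
  for (trial in 1:60) {
    k <- sample(0:8, 1)
    dates <- as.Date("2014-01-01") + sample(0:2000, max(k, 1))[seq_len(k)]
    chart <- if (k > 0) chart_627(dates) else {
      ch <- chart_627("2014-01-01")
      ch$records <- ch$records[0L, ]
      ch
    }
    mc <- sample(1:3, 1)
    win <- if (mc == 1) "whole_chart" else sample(c("12", "24", "whole_chart"), 1)
    cl <- clause("code_prefix", "627", mc, win, diag_scope)
    expect_identical(evaluate_clause(chart, cl),
                     bf_window_satisfied(dates[seq_len(k)], mc, win),
                     info = sprintf("trial %d: k=%d mc=%d win=%s",
                                    trial, k, mc, win))
  }
})

test_that("definition evaluation is monotone under record addition", {
  set.seed(7)
  def <- default_planted_definition()
  for (trial in 1:25) {
    n0 <- sample(1:6, 1)
    dates <- as.Date("2013-06-01") + sample(0:2500, n0)
    codes <- sample(c("627", "627.2", "401", "250"), n0, replace = TRUE)
    recs <- do.call(rbind, lapply(seq_len(n0), function(i)
      rec("p1", "billing", dates[i], "ICD9CM", codes[i])))
    before <- evaluate_definition(mk_chart(recs), def)
    extra <- rbind(recs, rec("p1", "medication",
                             as.Date("2016-01-01") + sample(0:500, 1),
                             "ATC", "G03CA03"))
    after <- evaluate_definition(mk_chart(extra), def)
    expect_true(after >= before)
    expect_true(after)  # the added record matches the estrogen clause
  }
})

test_that("case definitions round-trip through YAML", {
  def <- default_planted_definition()
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_case_definition(def, path)
  back <- read_case_definition(path)
  expect_equal(unclass(back)$clauses, unclass(def)$clauses,
               ignore_attr = FALSE)
})

test_that("clause invariants are enforced", {
  expect_error(clause("code_prefix", "627", 1, "12"), "whole_chart")
  expect_error(clause("code_prefix", ""), "non-empty")
  expect_error(clause("code_prefix", "627", scope = "pharmacy"), "scope")
  expect_error(clause("text_bigram", "single"), "two space-separated")
  expect_error(case_definition(), "clause")
})
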