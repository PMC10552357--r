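#' Confusion matrix from reference labels and predictions
#'
#' @param labels character/factor vector of "case" / "non_case" reference
#'   labels (unclassifiable and unlabelled charts must be excluded upstream).
#' @param predictions logical vector of case-definition verdicts.
#' @return Object of class `confusion_matrix` with fields tp, fp, fn, tn.
#' @export
confusion <- function(labels, predictions) {
  labels <- as.character(labels)
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length (",
         length(labels), " vs ", length(predictions), ")")
  bad <- setdiff(unique(labels), c("case", "non_case"))
  if (length(bad) > 0L)
    stop("labels must be case/non_case; found: ", paste(bad, collapse = ", "))
  predictions <- as.logical(predictions)
  if (anyNA(predictions)) stop("predictions contain NA")
  is_case <- labels == "case"
  structure(list(tp = sum(is_case & predictions),
                 fp = sum(!is_case & predictions),
                 fn = sum(is_case & !predictions),
                 tn = sum(!is_case & !predictions)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Binomial proportion confidence interval
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param method "wald" (default; `p +/- 1.96 sqrt(p(1-p)/n)`, clipped to
#'   `[0, 1]`), "wilson", or "clopper-pearson".
#' @param conf_level confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`; `c(NA, NA)` when `n = 0`.
#' @export
prop_ci <- function(x, n, method = c("wald", "wilson", "clopper-pearson"),
                    conf_level = 0.95) {
  method <- match.arg(method)
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  ci <- switch(method,
    wald = {
      half <- z * sqrt(p * (1 - p) / n)
      c(p - half, p + half)
    },
    wilson = {
      denom <- 1 + z^2 / n
      centre <- (p + z^2 / (2 * n)) / denom
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
      c(centre - half, centre + half)
    },
    "clopper-pearson" = {
      alpha <- 1 - conf_level
      lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
      hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
      c(lo, hi)
    })
  c(lower = max(0, ci[1L]), upper = min(1, ci[2L]))
}

#' F1-score: harmonic mean of sensitivity and PPV
#'
#' `F1 = 2 (1/Sn + 1/PPV)^-1`, the optimisation metric of the whole
#' pipeline: it weighs false negatives (through Sn) and false positives
#' (through PPV) symmetrically and ignores true negatives. Defined as 0 when
#' either input is 0 (continuous limit).
#'
#' @param sn sensitivity in `[0, 1]` (vectorized).
#' @param ppv positive predictive value in `[0, 1]` (vectorized).
#' @return F1 in `[0, 1]`; NA propagates.
#' @export
f1_score <- function(sn, ppv) {
  stopifnot(length(sn) == length(ppv))
  out <- ifelse(is.na(sn) | is.na(ppv), NA_real_,
                ifelse(sn == 0 | ppv == 0, 0, 2 * sn * ppv / (sn + ppv)))
  if (any(out < -1e-12 | out > 1 + 1e-12, na.rm = TRUE))
    stop("sn and ppv must lie in [0, 1]")
  out
}

#' Validity metrics of a case definition
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)` and
#' NPV `tn/(tn+fn)`, each with a binomial CI on its own denominator, plus the
#' F1-score. A metric with a zero denominator is reported as `NA`
#' (undefined), never silently as 0.
#'
#' @param cm a `confusion_matrix`.
#' @param ci_method CI method passed to [prop_ci()].
#' @param conf_level confidence level.
#' @return Object of class `validation_report`: data.frame `estimates`
#'   (metric, numerator, denominator, est, lower, upper), scalar `f1`, total
#'   `n`, and the input `cm`.
#' @export
validity_metrics <- function(cm, ci_method = "wald", conf_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  defs <- list(sensitivity = c(cm$tp, cm$tp + cm$fn),
               specificity = c(cm$tn, cm$tn + cm$fp),
               ppv         = c(cm$tp, cm$tp + cm$fp),
               npv         = c(cm$tn, cm$tn + cm$fn))
  est <- lapply(defs, function(v) {
    x <- v[1L]; n <- v[2L]
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(x / n, prop_ci(x, n, ci_method, conf_level))
  })
  estimates <- data.frame(
    metric = names(defs),
    numerator = vapply(defs, `[`, numeric(1), 1L),
    denominator = vapply(defs, `[`, numeric(1), 2L),
    est = vapply(est, `[`, numeric(1), 1L),
    lower = vapply(est, `[`, numeric(1), 2L),
    upper = vapply(est, `[`, numeric(1), 3L),
    row.names = NULL
  )
  sn <- estimates$est[estimates$metric == "sensitivity"]
  ppv <- estimates$est[estimates$metric == "ppv"]
  structure(list(estimates = estimates,
                 f1 = if (is.na(sn) || is.na(ppv)) NA_real_
                      else f1_score(sn, ppv),
                 n = cm$tp + cm$fp + cm$fn + cm$tn,
                 cm = cm,
                 ci_method = ci_method),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> n =", x$n, " (CI:", x$ci_method, ")\n")
  e <- x$estimates
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-11s %s", e$metric[i],
                if (is.na(e$est[i])) "undefined (zero denominator)\n"
                else sprintf("%5.1f%% (%.1f-%.1f%%)\n", 100 * e$est[i],
                             100 * e$lower[i], 100 * e$upper[i])))
  }
  cat(sprintf("  f1          %s\n",
              if (is.na(x$f1)) "undefined" else sprintf("%.3f", x$f1)))
  invisible(x)
}

#' Validation-set sample size from the Wald CI formula
#'
#' `N = 1.96^2 Sn (1 - Sn) / ((c/2)^2 p)`, rounded up: the number of charts
#' needed so that a case definition with expected sensitivity `sn` is
#' estimated with a 95% CI of full width at most `ci_full_width`, at disease
#' prevalence `prevalence`.
#'
#' @param sn expected sensitivity, in (0, 1).
#' @param ci_full_width full CI width `c`, in (0, 1].
#' @param prevalence expected prevalence `p`, in (0, 1].
#' @return Integer sample size (ceiling).
#' @export
sample_size <- function(sn, ci_full_width, prevalence) {
  if (!is.numeric(sn) || sn <= 0 || sn >= 1)
    stop("sn must lie strictly in (0, 1)")
  if (!is.numeric(ci_full_width) || ci_full_width <= 0 || ci_full_width > 1)
    stop("ci_full_width must lie in (0, 1]")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence > 1)
    stop("prevalence must lie in (0, 1]")
  as.integer(ceiling(1.96^2 * sn * (1 - sn) /
                     ((ci_full_width / 2)^2 * prevalence)))
}

#' Fleiss's kappa for multi-rater agreement
#'
#' Chance-corrected agreement of `r` raters assigning `N` subjects to
#' categories: `kappa = (Pbar - Pe) / (1 - Pe)` where `Pbar` is the mean
#' observed pairwise agreement per subject and `Pe` the agreement expected
#' from the marginal category frequencies.
#'
#' @param ratings integer matrix, subjects x categories, each cell the
#'   number of raters assigning that subject to that category. Every subject
#'   must be rated by the same number of raters (>= 2).
#' @return Object of class `kappa_result` with fields `kappa`, `n_subjects`,
#'   `n_raters`.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(ratings < 0) || any(ratings != round(ratings)))
    stop("ratings must be non-negative integer counts")
  r <- unique(rowSums(ratings))
  if (length(r) != 1L)
    stop("every subject must be rated by the same number of raters")
  if (r < 2) stop("at least 2 raters are required")
  N <- nrow(ratings)
  P_i <- (rowSums(ratings^2) - r) / (r * (r - 1))
  Pbar <- mean(P_i)
  p_j <- colSums(ratings) / (N * r)
  Pe <- sum(p_j^2)
  kappa <- if (abs(1 - Pe) < .Machine$double.eps^0.5) {
    if (abs(1 - Pbar) < .Machine$double.eps^0.5) 1 else NA_real_
  } else {
    (Pbar - Pe) / (1 - Pe)
  }
  structure(list(kappa = kappa, n_subjects = N, n_raters = as.integer(r)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa = %.3f (%d subjects, %d raters)\n",
              x$kappa, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Observed case prevalence among labelled charts
#'
#' @param labels character vector of labels; only "case" and "non_case"
#'   enter the denominator.
#' @return Proportion of cases among classifiable charts.
#' @export
prevalence <- function(labels) {
  labels <- as.character(labels)
  keep <- labels %in% c("case", "non_case")
  if (!any(keep)) stop("no classifiable (case/non_case) labels")
  mean(labels[keep] == "case")
}
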