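## CaRT phenotype learner: nested cross-validation over resampling x
## feature-reduction x order combinations, F1-optimised hyperparameter
## search, tree training, and importance-ranked simplification.

#' Hyperparameter grids for the CaRT learner
#'
#' Each hyperparameter set names the branching criterion ("gini" or
#' "entropy"), branching strategy (only "best" is supported by the rpart
#' backend; the field exists for config compatibility), maximum tree depth,
#' minimum samples per branch (terminal-node size), and class weight
#' ("none", "balanced", or a numeric case:non-case weight ratio).
#' `default_grid()` is the full search space; `reduced_grid()` is a small
#' grid for desk-scale runs.
#'
#' @param criterion,strategy,max_depth,min_bucket,class_weight vectors of
#'   values to cross.
#' @return List of hyperparameter sets (named lists).
#' @export
make_grid <- function(criterion = "gini", strategy = "best", max_depth = 5,
                      min_bucket = 5, class_weight = "none") {
  g <- expand.grid(criterion = criterion, strategy = strategy,
                   max_depth = max_depth, min_bucket = min_bucket,
                   class_weight = as.character(class_weight),
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
}

#' @rdname make_grid
#' @export
default_grid <- function() {
  make_grid(criterion = c("gini", "entropy"), strategy = "best",
            max_depth = c(2, 3, 4, 5, 8, 30), min_bucket = c(2, 5, 10, 20),
            class_weight = c("none", "balanced", "2", "4"))
}

#' @rdname make_grid
#' @export
reduced_grid <- function() {
  make_grid(criterion = "gini", strategy = "best", max_depth = c(3, 5),
            min_bucket = 5, class_weight = c("none", "balanced"))
}

#' Learner configuration
#'
#' @param grid list of hyperparameter sets from [make_grid()].
#' @param sampling_methods subset of "none", "random_over", "random_under",
#'   "combined".
#' @param reducers subset of "RFE", "kBF".
#' @param orders subset of "reduce_then_sample", "sample_then_reduce" (the
#'   two orders coincide for sampling method "none", which therefore
#'   contributes a single combination).
#' @param outer_folds,inner_folds fold counts of the nested CV (default 10
#'   and 10).
#' @param top_k prescreen size (default 300), applied inside each outer
#'   training fold.
#' @param target_count number of features the reducers keep (default 30).
#' @param rfe_step fraction of remaining features dropped per RFE iteration
#'   (default 0.5).
#' @param seed run seed; every random stage derives a named substream.
#' @return Object of class `learner_config`.
#' @export
learner_config <- function(grid = default_grid(),
                           sampling_methods = c("none", "random_over",
                                                "random_under", "combined"),
                           reducers = c("RFE", "kBF"),
                           orders = c("reduce_then_sample",
                                      "sample_then_reduce"),
                           outer_folds = 10L, inner_folds = 10L,
                           top_k = 300L, target_count = 30L,
                           rfe_step = 0.5, seed = 1L) {
  if (!is.list(grid) || length(grid) == 0L)
    stop("hyperparameter grid must be a non-empty list")
  sampling_methods <- match.arg(sampling_methods,
                                c("none", "random_over", "random_under",
                                  "combined"), several.ok = TRUE)
  reducers <- match.arg(reducers, c("RFE", "kBF"), several.ok = TRUE)
  orders <- match.arg(orders, c("reduce_then_sample", "sample_then_reduce"),
                      several.ok = TRUE)
  if (outer_folds < 2L || inner_folds < 2L) stop("fold counts must be >= 2")
  structure(list(grid = grid, sampling_methods = sampling_methods,
                 reducers = reducers, orders = orders,
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 top_k = as.integer(top_k),
                 target_count = as.integer(target_count),
                 rfe_step = rfe_step, seed = as.integer(seed)),
            class = "learner_config")
}

## deterministic named substream seed derived from the run seed
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_len(nchar(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Split labelled charts into a train/test set and a validation set
#'
#' Random disjoint halves (sizes differing by at most one; e.g. 2,775
#' labelled charts split 1,388 / 1,387). The validation half must stay
#' untouched until the final assessment.
#'
#' @param ids character vector of labelled patient ids.
#' @param seed integer seed.
#' @return List with `train_test` and `validation` id vectors.
#' @export
split_train_validation <- function(ids, seed) {
  ids <- as.character(ids)
  if (length(ids) < 2L) stop("need at least 2 labelled charts to split")
  set.seed(substream_seed(seed, "split"))
  perm <- sample(ids)
  n_train <- ceiling(length(ids) / 2)
  list(train_test = sort(perm[seq_len(n_train)]),
       validation = sort(perm[-seq_len(n_train)]))
}

#' Assert that no validation patient leaks into a training stage
#'
#' @param validation_ids ids of the held-out validation set.
#' @param train_ids ids used by any training-stage input.
#' @return TRUE invisibly; error if the sets intersect.
#' @export
audit_no_leakage <- function(validation_ids, train_ids) {
  leak <- intersect(as.character(validation_ids), as.character(train_ids))
  if (length(leak) > 0L)
    stop("leakage: ", length(leak),
         " validation patient(s) present in a training-stage input")
  invisible(TRUE)
}

#' Stratified fold assignment
#'
#' Deals each class round-robin into `k` folds after shuffling, so per-fold
#' case counts differ by at most one across folds.
#'
#' @param labels "case"/"non_case" vector.
#' @param k number of folds (>= 2); every class must have >= k members.
#' @param seed optional seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(labels, k, seed = NULL) {
  labels <- as.character(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  tab <- table(labels)
  if (length(tab) < 2L) stop("both classes must be present")
  small <- names(tab)[tab < k]
  if (length(small) > 0L)
    stop("class smaller than k folds: ", paste(small, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cls in names(tab)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Rebalance classes by random resampling
#'
#' "random_under" drops majority-class rows at random down to the minority
#' count; "random_over" duplicates minority rows at random up to the
#' majority count; "combined" meets at the (rounded) geometric mean of the
#' two class sizes; "none" is the identity.
#'
#' @param X feature matrix (rows = patients).
#' @param y "case"/"non_case" labels.
#' @param method resampling method.
#' @param seed optional seed.
#' @return List with resampled `X` and `y`.
#' @export
resample <- function(X, y, method = c("none", "random_over", "random_under",
                                      "combined"), seed = NULL) {
  method <- match.arg(method)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (method == "none") return(list(X = X, y = y))
  if (!is.null(seed)) set.seed(seed)
  tab <- table(y)
  if (length(tab) < 2L) stop("both classes must be present")
  if (tab[1L] == tab[2L]) return(list(X = X, y = y))  # already balanced
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  min_idx <- which(y == minority)
  maj_idx <- which(y == majority)
  idx <- switch(method,
    random_under = c(min_idx, sample(maj_idx, length(min_idx))),
    random_over = c(maj_idx, min_idx,
                    sample(min_idx, length(maj_idx) - length(min_idx),
                           replace = TRUE)),
    combined = {
      target <- round(sqrt(length(min_idx) * length(maj_idx)))
      c(sample(maj_idx, min(target, length(maj_idx))),
        min_idx,
        if (target > length(min_idx))
          sample(min_idx, target - length(min_idx), replace = TRUE))
    })
  idx <- sort(idx)
  list(X = X[idx, , drop = FALSE], y = y[idx])
}

## ---- CaRT backend ------------------------------------------------------

safe_names <- function(feature_names) {
  setNames(paste0("f", seq_along(feature_names)), feature_names)
}

class_weights_vector <- function(y, class_weight) {
  if (identical(class_weight, "none")) return(NULL)
  tab <- table(y)
  if (identical(class_weight, "balanced")) {
    w <- length(y) / (length(tab) * tab)
    return(as.numeric(w[y]))
  }
  ratio <- suppressWarnings(as.numeric(class_weight))
  if (is.na(ratio) || ratio <= 0)
    stop("class_weight must be 'none', 'balanced' or a positive ratio")
  ifelse(y == "case", ratio, 1)
}

fit_cart <- function(X, y, hp) {
  if (length(unique(y)) < 2L) {
    # constant labels: a single-leaf tree with no splits and no rules
    return(structure(list(verdict = unique(y)), class = "cart_leaf"))
  }
  nmap <- safe_names(colnames(X))
  df <- as.data.frame(X)
  names(df) <- unname(nmap)
  df$.outcome <- factor(y, levels = c("non_case", "case"))
  w <- class_weights_vector(y, hp$class_weight)
  ctrl <- rpart::rpart.control(
    maxdepth = min(as.numeric(hp$max_depth), 30),
    minbucket = as.integer(hp$min_bucket),
    minsplit = max(2L, 2L * as.integer(hp$min_bucket)),
    cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0, usesurrogate = 0)
  fit <- if (is.null(w)) {
    rpart::rpart(.outcome ~ ., data = df, method = "class",
                 parms = list(split = if (hp$criterion == "entropy")
                   "information" else "gini"),
                 control = ctrl)
  } else {
    rpart::rpart(.outcome ~ ., data = df, method = "class", weights = w,
                 parms = list(split = if (hp$criterion == "entropy")
                   "information" else "gini"),
                 control = ctrl)
  }
  attr(fit, "name_map") <- nmap
  fit
}

predict_cart <- function(fit, X) {
  if (inherits(fit, "cart_leaf"))
    return(rep(fit$verdict == "case", nrow(X)))
  nmap <- attr(fit, "name_map")
  df <- as.data.frame(X[, names(nmap), drop = FALSE])
  names(df) <- unname(nmap)
  predict(fit, newdata = df, type = "class") == "case"
}

## Gini/entropy-improvement importances of the primary splits, normalized to
## sum to 1 over features with nonzero importance (no surrogate credit).
cart_importances <- function(fit) {
  if (inherits(fit, "cart_leaf"))
    return(setNames(numeric(0), character(0)))
  nmap <- attr(fit, "name_map")
  sp <- fit$splits
  if (is.null(sp) || nrow(sp) == 0L)
    return(setNames(numeric(0), character(0)))
  raw <- tapply(sp[, "improve"], rownames(sp), sum)
  raw <- raw[raw > 0]
  if (length(raw) == 0L) return(setNames(numeric(0), character(0)))
  real <- names(nmap)[match(names(raw), nmap)]
  out <- as.numeric(raw) / sum(raw)
  names(out) <- real
  sort(out, decreasing = TRUE)
}

cart_rules <- function(fit) {
  if (inherits(fit, "cart_leaf"))
    return(list(list(conditions = character(0), verdict = fit$verdict)))
  frame <- fit$frame
  leaves <- which(frame$var == "<leaf>")
  if (length(leaves) == 0L) return(list())
  nmap <- attr(fit, "name_map")
  ylev <- attr(fit, "ylevels")
  nodes <- as.integer(rownames(frame))[leaves]
  paths <- rpart::path.rpart(fit, nodes, print.it = FALSE)
  lapply(seq_along(leaves), function(i) {
    conds <- paths[[i]][-1L]  # drop "root"
    for (j in seq_along(nmap))
      conds <- gsub(paste0("\\b", nmap[j], "\\b"), names(nmap)[j], conds)
    list(conditions = unname(conds),
         verdict = ylev[frame$yval[leaves[i]]])
  })
}

## ---- feature reduction -------------------------------------------------

## sklearn-style chi-squared score of binary features against binary labels
chi2_scores <- function(X, y) {
  is_case <- as.character(y) == "case"
  n <- length(is_case)
  n_case <- sum(is_case)
  obs1 <- colSums(X[is_case, , drop = FALSE])
  obs0 <- colSums(X[!is_case, , drop = FALSE])
  tot <- obs1 + obs0
  exp1 <- tot * n_case / n
  exp0 <- tot * (n - n_case) / n
  score <- ifelse(tot == 0, 0,
                  (obs1 - exp1)^2 / pmax(exp1, .Machine$double.eps) +
                  (obs0 - exp0)^2 / pmax(exp0, .Machine$double.eps))
  setNames(as.numeric(score), colnames(X))
}

#' Reduce a feature matrix to its most informative columns
#'
#' "RFE" (recursive feature elimination) repeatedly fits a tree and drops
#' the lowest-importance fraction of the remaining columns until
#' `target_count` remain; "kBF" (k-best features) keeps the `target_count`
#' columns with the highest univariate chi-squared association with the
#' labels. Ties are broken by lexicographic column name.
#'
#' @param X binary feature matrix.
#' @param y "case"/"non_case" labels.
#' @param reducer "RFE" or "kBF".
#' @param target_count number of columns to keep (>= 1; if >= ncol(X) the
#'   full column set is returned).
#' @param rfe_step fraction of remaining columns dropped per RFE iteration.
#' @param hp hyperparameters of the RFE scoring tree.
#' @return Character vector of retained column names.
#' @export
reduce_features <- function(X, y, reducer = c("RFE", "kBF"), target_count,
                            rfe_step = 0.5,
                            hp = list(criterion = "gini", strategy = "best",
                                      max_depth = 8, min_bucket = 5,
                                      class_weight = "balanced")) {
  reducer <- match.arg(reducer)
  target_count <- as.integer(target_count)
  if (target_count < 1L) stop("target_count must be >= 1")
  cols <- colnames(X)
  if (target_count >= length(cols)) return(cols)
  if (reducer == "kBF") {
    sc <- chi2_scores(X, y)
    ord <- order(-sc, names(sc))
    return(sort(names(sc)[ord[seq_len(target_count)]]))
  }
  while (length(cols) > target_count) {
    fit <- fit_cart(X[, cols, drop = FALSE], y, hp)
    imp <- cart_importances(fit)
    full <- setNames(rep(0, length(cols)), cols)
    full[names(imp)] <- imp
    n_drop <- min(length(cols) - target_count,
                  max(1L, floor(length(cols) * rfe_step)))
    ord <- order(full, -xtfrm(names(full)))  # lowest score, largest name first
    cols <- sort(setdiff(cols, names(full)[ord[seq_len(n_drop)]]))
  }
  cols
}

## ---- nested cross-validation -------------------------------------------

sampling_label <- c(none = "None",
                    random_over = "random over-sampling",
                    random_under = "random under-sampling",
                    combined = "random over- & under-sampling")

#' The resampling x reducer x order combination set
#'
#' Four sampling methods crossed with two reducers and two orders of
#' operation, with the order-duplicates of sampling method "none" collapsed:
#' 14 combinations in the default configuration.
#'
#' @param config a `learner_config`.
#' @return data.frame with columns `sampling`, `reducer`, `order`, `label`.
#' @export
combination_table <- function(config) {
  rows <- list()
  for (s in config$sampling_methods) {
    for (r in config$reducers) {
      ords <- if (s == "none") "reduce_then_sample" else config$orders
      for (o in ords) {
        lab <- if (o == "reduce_then_sample")
          paste0(r, ";", sampling_label[[s]])
        else
          paste0(sampling_label[[s]], ";", r)
        rows[[length(rows) + 1L]] <-
          data.frame(sampling = s, reducer = r, order = o, label = lab,
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

fold_metrics <- function(labels, pred) {
  cm <- confusion(labels, pred)
  vm <- validity_metrics(cm)
  e <- vm$estimates
  list(sn = e$est[e$metric == "sensitivity"],
       sp = e$est[e$metric == "specificity"],
       ppv = e$est[e$metric == "ppv"],
       npv = e$est[e$metric == "npv"],
       f1 = vm$f1)
}

hp_key <- function(hp) paste(hp$criterion, hp$strategy, hp$max_depth,
                             hp$min_bucket, hp$class_weight, sep = "|")

## inner CV: mean F1 of each hyperparameter set, best one returned
select_hyperparameters <- function(X, y, config) {
  grid <- config$grid
  if (length(grid) == 1L) return(grid[[1L]])
  ifold <- stratified_folds(y, config$inner_folds)
  scores <- vapply(grid, function(hp) {
    f1s <- rep(NA_real_, config$inner_folds)
    for (f in seq_len(config$inner_folds)) {
      itr <- ifold != f
      if (length(unique(y[itr])) < 2L || length(unique(y[!itr])) < 2L) {
        warning("inner fold ", f, " has a single class; evaluation skipped")
        next
      }
      fit <- fit_cart(X[itr, , drop = FALSE], y[itr], hp)
      m <- fold_metrics(y[!itr], predict_cart(fit, X[!itr, , drop = FALSE]))
      f1s[f] <- m$f1
    }
    mean(f1s, na.rm = TRUE)
  }, numeric(1))
  grid[[which.max(scores)]]  # ties: first in grid order
}

apply_combo <- function(X, y, combo, config) {
  if (combo$sampling == "none" || combo$order == "reduce_then_sample") {
    cols <- reduce_features(X, y, combo$reducer, config$target_count,
                            config$rfe_step)
    rs <- resample(X[, cols, drop = FALSE], y, combo$sampling)
    list(X = rs$X, y = rs$y, cols = cols)
  } else {
    rs <- resample(X, y, combo$sampling)
    cols <- reduce_features(rs$X, rs$y, combo$reducer, config$target_count,
                            config$rfe_step)
    list(X = rs$X[, cols, drop = FALSE], y = rs$y, cols = cols)
  }
}

#' Nested cross-validation over all combinations
#'
#' For each sampling/reducer/order combination: the outer loop trains on
#' nine stratified folds and tests on the tenth; inside each outer training
#' fold the top-`top_k` prescreen, the combination's feature reduction and
#' resampling (in its configured order) and an inner stratified
#' cross-validated hyperparameter search are applied to training data only.
#' Outer test folds are never resampled, reduced on, or otherwise touched
#' before prediction.
#'
#' @param fm a `feature_matrix` of the train/test patients.
#' @param labels named "case"/"non_case" vector over `fm$patient_ids`.
#' @param config a `learner_config`.
#' @return Object of class `cv_results`: one entry per combination with
#'   per-fold and mean sensitivity, specificity, PPV, NPV (fold-quantile
#'   intervals) and mean F1, plus the per-fold selected hyperparameters.
#' @export
nested_cv <- function(fm, labels, config) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "learner_config"))
  X <- fm$values
  y <- as.character(labels[fm$patient_ids])
  if (anyNA(y)) stop("labels missing for some patients in the matrix")
  set.seed(substream_seed(config$seed, "nested_cv"))
  fold <- stratified_folds(y, config$outer_folds)
  combos <- combination_table(config)
  per_fold <- vector("list", nrow(combos))
  hp_sel <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    per_fold[[i]] <- data.frame(fold = integer(0), sn = numeric(0),
                                sp = numeric(0), ppv = numeric(0),
                                npv = numeric(0), f1 = numeric(0))
    hp_sel[[i]] <- list()
  }

  for (f in seq_len(config$outer_folds)) {
    tr <- fold != f
    keep <- prescreen_columns(X[tr, , drop = FALSE], y[tr], config$top_k)
    Xtr <- X[tr, keep, drop = FALSE]
    ytr <- y[tr]
    Xte <- X[!tr, keep, drop = FALSE]
    yte <- y[!tr]
    for (i in seq_len(nrow(combos))) {
      prep <- apply_combo(Xtr, ytr, combos[i, ], config)
      hp <- select_hyperparameters(prep$X, prep$y, config)
      fit <- fit_cart(prep$X, prep$y, hp)
      m <- fold_metrics(yte, predict_cart(fit, Xte[, prep$cols, drop = FALSE]))
      per_fold[[i]] <- rbind(per_fold[[i]],
                             data.frame(fold = f, sn = m$sn, sp = m$sp,
                                        ppv = m$ppv, npv = m$npv, f1 = m$f1))
      hp_sel[[i]][[f]] <- hp
    }
  }

  results <- lapply(seq_len(nrow(combos)), function(i) {
    pf <- per_fold[[i]]
    qs <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) return(c(NA_real_, NA_real_))
      as.numeric(quantile(v, c(0.025, 0.975), type = 7))
    }
    keys <- vapply(hp_sel[[i]], hp_key, character(1))
    mode_key <- names(sort(table(keys), decreasing = TRUE))[1L]
    structure(list(
      sampling = combos$sampling[i], reducer = combos$reducer[i],
      order = combos$order[i], label = combos$label[i],
      per_fold = pf,
      mean_sn = mean(pf$sn, na.rm = TRUE),
      mean_sp = mean(pf$sp, na.rm = TRUE),
      mean_ppv = mean(pf$ppv, na.rm = TRUE),
      mean_npv = mean(pf$npv, na.rm = TRUE),
      mean_f1 = mean(pf$f1, na.rm = TRUE),
      ## harmonic mean of the fold-averaged Sn and PPV; equals mean_f1 only
      ## in the degenerate single-fold case
      f1_of_means = f1_score(mean(pf$sn, na.rm = TRUE),
                             mean(pf$ppv, na.rm = TRUE)),
      ci_sn = qs(pf$sn), ci_sp = qs(pf$sp), ci_ppv = qs(pf$ppv),
      ci_npv = qs(pf$npv),
      fold_hp = hp_sel[[i]],
      hp_mode = hp_sel[[i]][[match(mode_key, keys)]]),
      class = "combination_result")
  })
  structure(results, class = "cv_results")
}

#' @export
print.cv_results <- function(x, ...) {
  df <- as.data.frame(x)
  cat("<cv_results> ", nrow(df), " combinations\n", sep = "")
  print(df, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.cv_results <- function(x, ...) {
  do.call(rbind, lapply(x, function(r)
    data.frame(combination = r$label, sampling = r$sampling,
               reducer = r$reducer, order = r$order,
               mean_sn = r$mean_sn, mean_sp = r$mean_sp,
               mean_ppv = r$mean_ppv, mean_npv = r$mean_npv,
               mean_f1 = r$mean_f1, f1_of_means = r$f1_of_means,
               sn_lo = r$ci_sn[1L], sn_hi = r$ci_sn[2L],
               sp_lo = r$ci_sp[1L], sp_hi = r$ci_sp[2L],
               ppv_lo = r$ci_ppv[1L], ppv_hi = r$ci_ppv[2L],
               npv_lo = r$ci_npv[1L], npv_hi = r$ci_npv[2L],
               stringsAsFactors = FALSE)))
}

#' Select the best combination by mean F1
#'
#' Ties are broken by mean sensitivity, then mean PPV, then combination
#' label (stable).
#'
#' @param results a `cv_results`.
#' @return The winning `combination_result`.
#' @export
select_best_combination <- function(results) {
  stopifnot(length(results) >= 1L)
  f1 <- vapply(results, `[[`, numeric(1), "mean_f1")
  sn <- vapply(results, `[[`, numeric(1), "mean_sn")
  ppv <- vapply(results, `[[`, numeric(1), "mean_ppv")
  lab <- vapply(results, `[[`, character(1), "label")
  ord <- order(-f1, -sn, -ppv, lab)
  results[[ord[1L]]]
}

#' Train the final tree on the full train/test set
#'
#' Applies the winning combination's prescreen, reduction and resampling to
#' the entire train/test matrix and fits one tree with the hyperparameter
#' set most frequently selected across the outer folds. Root-to-leaf rule
#' sets and normalized split-improvement feature importances are extracted.
#'
#' @param fm the train/test `feature_matrix`.
#' @param labels named labels over `fm$patient_ids`.
#' @param combo a `combination_result` (from [select_best_combination()]).
#' @param config the `learner_config` used for the CV.
#' @return Object of class `trained_tree`: `fit` (rpart), `importances`
#'   (named, summing to 1), `rules` (list of condition sets with verdicts),
#'   `features` (columns available to the tree), `hp`, `combo_label`.
#' @export
train_final_tree <- function(fm, labels, combo, config) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$values
  y <- as.character(labels[fm$patient_ids])
  set.seed(substream_seed(config$seed, "final_tree"))
  keep <- prescreen_columns(X, y, config$top_k)
  prep <- apply_combo(X[, keep, drop = FALSE], y, combo, config)
  hp <- combo$hp_mode
  fit <- fit_cart(prep$X, prep$y, hp)
  structure(list(fit = fit,
                 importances = cart_importances(fit),
                 rules = cart_rules(fit),
                 features = prep$cols,
                 hp = hp,
                 combo_label = combo$label),
            class = "trained_tree")
}

#' @export
print.trained_tree <- function(x, ...) {
  cat("<trained_tree> combo ", x$combo_label, ", ",
      length(x$rules), " rule sets, ", length(x$importances),
      " features with nonzero importance\n", sep = "")
  if (length(x$importances) > 0L) {
    top <- head(x$importances, 9L)
    for (i in seq_along(top))
      cat(sprintf("  %-45s %.5f\n", names(top)[i], top[i]))
  }
  invisible(x)
}

#' Candidate simplified definitions from ranked features
#'
#' Given `s` top-ranked feature specs, builds the `s` singleton case
#' definitions and the `choose(s, 2)` pairwise OR definitions.
#'
#' @param specs data.frame of feature specs (rows ranked by importance).
#' @param s number of top features to combine.
#' @return Named list of `case_definition` objects.
#' @export
candidate_definitions <- function(specs, s) {
  s <- min(s, nrow(specs))
  if (s < 1L) stop("no features to build candidates from")
  clauses <- lapply(seq_len(s), function(i)
    spec_to_clause(specs[i, , drop = FALSE]))
  names(clauses) <- specs$name[seq_len(s)]
  out <- list()
  for (i in seq_len(s))
    out[[names(clauses)[i]]] <- case_definition(clauses[[i]])
  if (s >= 2L) {
    prs <- combn(s, 2L)
    for (j in seq_len(ncol(prs))) {
      i1 <- prs[1L, j]; i2 <- prs[2L, j]
      out[[paste(names(clauses)[i1], names(clauses)[i2], sep = " OR ")]] <-
        case_definition(clauses[[i1]], clauses[[i2]])
    }
  }
  out
}

#' Simplify a trained tree into a one- or two-clause case definition
#'
#' Takes the top-`s` features of the tree by importance, converts each back
#' into a rule-engine clause, forms all singleton and pairwise-OR candidate
#' definitions, evaluates every candidate on the full train/test charts via
#' the rule engine, and selects the candidate with the highest F1 (ties:
#' sensitivity, then PPV, then fewer clauses, then name).
#'
#' @param tree a `trained_tree`.
#' @param fm the train/test `feature_matrix` (for feature provenance).
#' @param cohort the `emr_cohort` holding the train/test charts.
#' @param labels named labels over the train/test patients.
#' @param s number of top features to combine (default 9; fewer if the tree
#'   used fewer).
#' @return Object of class `simplification_result`: `candidates` (metric
#'   table), `definitions`, `chosen`, `chosen_name`.
#' @export
simplify_definition <- function(tree, fm, cohort, labels, s = 9L) {
  stopifnot(inherits(tree, "trained_tree"))
  if (length(tree$importances) == 0L)
    stop("tree has no nonzero-importance features to simplify from")
  ranked <- names(tree$importances)
  specs <- fm$specs[match(ranked, fm$specs$name), , drop = FALSE]
  specs <- specs[!is.na(specs$name), , drop = FALSE]
  defs <- candidate_definitions(specs, s)

  ids <- names(labels)
  sub <- subset_cohort(cohort, ids)
  rows <- lapply(names(defs), function(nm) {
    verdict <- evaluate_definition_cohort(sub, defs[[nm]])[ids]
    m <- fold_metrics(labels, verdict)
    data.frame(name = nm, n_clauses = length(defs[[nm]]$clauses),
               sn = m$sn, sp = m$sp, ppv = m$ppv, npv = m$npv, f1 = m$f1,
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  ord <- order(-ifelse(is.na(cand$f1), -Inf, cand$f1),
               -ifelse(is.na(cand$sn), -Inf, cand$sn),
               -ifelse(is.na(cand$ppv), -Inf, cand$ppv),
               cand$n_clauses, cand$name)
  chosen_name <- cand$name[ord[1L]]
  structure(list(candidates = cand[ord, ],
                 definitions = defs,
                 chosen = defs[[chosen_name]],
                 chosen_name = chosen_name),
            class = "simplification_result")
}

#' @export
print.simplification_result <- function(x, ...) {
  cat("<simplification_result> ", nrow(x$candidates),
      " candidates; chosen: ", x$chosen_name, "\n", sep = "")
  print(head(x$candidates, 5L), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Validate a case definition on held-out charts
#'
#' Applies the rule engine to every labelled chart of the validation set and
#' reports the full validity metrics.
#'
#' @param definition a `case_definition`.
#' @param cohort the `emr_cohort`.
#' @param validation_ids ids of the held-out validation patients.
#' @param ci_method CI method for [validity_metrics()].
#' @return A `validation_report`.
#' @export
validate_final <- function(definition, cohort, validation_ids,
                           ci_method = "wald") {
  sub <- subset_cohort(cohort, validation_ids)
  lab <- setNames(sub$patients$label, sub$patients$patient_id)
  lab <- lab[lab %in% c("case", "non_case")]
  verdict <- evaluate_definition_cohort(sub, definition)[names(lab)]
  validity_metrics(confusion(lab, verdict), ci_method = ci_method)
}
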