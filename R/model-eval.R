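#' Feature columns for each model input-variable set
#'
#' The four Random-Forest models use nested input-variable sets: demographics
#' only (`age_apoe`), the 19 driving features (14 indicators plus the five
#' trip-distance subgroup counts; `driving`), and the driving features
#' augmented with age (`driving_age`) or age and APOE e4 carrier status
#' (`driving_age_apoe`).
#'
#' @param feature_set One of `"age_apoe"`, `"driving"`, `"driving_age"`,
#'   `"driving_age_apoe"`.
#' @return Character vector of column names.
#' @export
feature_columns <- function(feature_set = c("driving_age_apoe", "age_apoe",
                                            "driving", "driving_age")) {
  feature_set <- match.arg(feature_set)
  driving <- c(indicator_names(),
               c("nTrips_0_1", "nTrips_1_5", "nTrips_5_10", "nTrips_10_20",
                 "nTrips_20p"))
  switch(feature_set,
    age_apoe = c("age", "apoe_e4"),
    driving = driving,
    driving_age = c(driving, "age"),
    driving_age_apoe = c(driving, "age", "apoe_e4"))
}

#' Train/test split of participant-month records
#'
#' `"record"` mode reproduces the study protocol: participant-months are
#' treated as independent points and split 70/30 at random, stratified by
#' label — the same participant may then contribute to both sides.
#' `"grouped"` mode is the leakage-controlled alternative: the split is drawn
#' at participant level (stratified by participant label) so no participant
#' spans both sets. Deterministic given `seed`.
#'
#' @param records Labelled feature records ([monthly_features()]).
#' @param split_fraction Training fraction in (0,1).
#' @param split_mode `"record"` or `"grouped"`.
#' @param seed Integer seed.
#' @return List with integer row indices `train` and `test`.
#' @export
split_data <- function(records, split_fraction = 0.7,
                       split_mode = c("record", "grouped"), seed = 1) {
  split_mode <- match.arg(split_mode)
  stopifnot(split_fraction > 0, split_fraction < 1)
  records <- data.table::as.data.table(records)
  if (anyNA(records$label)) stop("records must be labelled")
  set.seed(seed)
  if (split_mode == "record") {
    train <- integer(0)
    for (lv in sort(unique(records$label))) {
      idx <- which(records$label == lv)
      train <- c(train, sample(idx, round(split_fraction * length(idx))))
    }
  } else {
    ids <- records[, .(label = label[1L]), by = participant_id]
    train_ids <- character(0)
    for (lv in sort(unique(ids$label))) {
      grp <- ids$participant_id[ids$label == lv]
      train_ids <- c(train_ids, sample(grp, round(split_fraction * length(grp))))
    }
    train <- which(records$participant_id %in% train_ids)
  }
  train <- sort(train)
  test <- setdiff(seq_len(nrow(records)), train)
  if (length(unique(records$label[train])) < 2L ||
      length(unique(records$label[test])) < 2L)
    stop("a class is absent from one side of the split; re-seed or enlarge the data")
  list(train = train, test = test)
}

#' Rank-statistic AUC with half tie credit
#'
#' Area under the ROC curve computed as the normalised Mann-Whitney rank
#' statistic of the positive-class scores, crediting ties between a positive
#' and a negative score with 1/2.
#'
#' @param scores Predicted positive-class probabilities or scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(as.character(labels))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

# Precision/recall/F1 at a threshold; positive class = 1 (preclinical AD).
# Zero predicted positives => precision reported as 0 with a flag.
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(as.character(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  no_positives <- (tp + fp) == 0L
  precision <- if (no_positives) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       no_predicted_positives = no_positives)
}

roc_points <- function(scores, labels) {
  labels <- as.integer(as.character(labels))
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]; scores <- scores[ord]
  tp <- cumsum(labels == 1L); fp <- cumsum(labels == 0L)
  last <- !duplicated(scores, fromLast = TRUE)  # one point per threshold
  data.table::data.table(
    fpr = c(0, fp[last] / sum(labels == 0L)),
    tpr = c(0, tp[last] / sum(labels == 1L))
  )
}

#' Evaluate predicted scores with bootstrap confidence intervals
#'
#' Point precision, recall, F1 (at `threshold`) and AUC on a test set, with
#' 95% percentile confidence intervals over `n_boot` bootstrap resamples of
#' the test records (resamples missing a class are redrawn).
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels 0/1 test labels.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param threshold Classification threshold for precision/recall/F1.
#' @param seed Integer seed for the resampling.
#' @return List of class `drf_eval`: `metrics` (point values), `ci`
#'   (2.5/97.5 percentiles per metric), `roc` (FPR/TPR table), and flags.
#' @export
evaluate_scores <- function(scores, labels, n_boot = 1000, threshold = 0.5,
                            seed = 1) {
  labels <- as.integer(as.character(labels))
  pt <- classification_metrics(scores, labels, threshold)
  pt$auc <- auc_score(scores, labels)
  set.seed(seed)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = 4,
                 dimnames = list(NULL, c("precision", "recall", "f1", "auc")))
  n <- length(labels)
  for (b in seq_len(n_boot)) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    m <- classification_metrics(scores[idx], labels[idx], threshold)
    boot[b, ] <- c(m$precision, m$recall, m$f1, auc_score(scores[idx], labels[idx]))
  }
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(
    metrics = list(precision = pt$precision, recall = pt$recall,
                   f1 = pt$f1, auc = pt$auc),
    ci = list(precision = ci[, 1], recall = ci[, 2], f1 = ci[, 3],
              auc = ci[, 4]),
    roc = roc_points(scores, labels),
    no_predicted_positives = pt$no_predicted_positives,
    n_boot = n_boot, threshold = threshold
  ), class = "drf_eval")
}

#' Fit and evaluate a Random-Forest preclinical-AD classifier
#'
#' The package's central model fit. Participant-month driving records are
#' split into training and test sets ([split_data()]), missing feature values
#' (e.g. OverV/UnderV in months without posted limits) are imputed with
#' training-set medians, Random-Forest hyperparameters are selected by
#' cross-validated F1 on the training set over `tuning_grid`, the best
#' configuration is refit on the full training set, and the test set is
#' scored with bootstrap confidence intervals ([evaluate_scores()]).
#' Feature importances are Gini (mean impurity decrease), normalised to sum
#' to one and sorted with a stable alphabetical tie-break.
#'
#' @param records Labelled feature records ([monthly_features()]).
#' @param feature_set Input-variable set; see [feature_columns()].
#' @param split_mode,split_fraction See [split_data()].
#' @param seed Integer seed governing split, tuning CV, forest and bootstrap.
#' @param tuning_grid Data frame with columns `num_trees`, `max_depth`
#'   (0 = unlimited), `min_node`; default
#'   `{100,300,500} x {0,5,10} x {1,3,5}`. An empty grid (0 rows) falls back
#'   to `num_trees = 500, max_depth = 0, min_node = 1` with a warning.
#' @param n_boot Bootstrap resamples for the confidence intervals.
#' @param cv_folds Cross-validation folds for tuning.
#' @param split Optional precomputed split (list with `train`, `test`) so
#'   several models can share one split.
#' @return An object of class `drf_fit` with `print`, `summary`, `predict`
#'   and `plot` methods: contains the fitted `ranger` forest, the split, the
#'   selected hyperparameters, the `drf_eval` report and the ranked
#'   importances.
#' @export
fit_drf <- function(records, feature_set = "driving_age_apoe",
                    split_mode = "record", split_fraction = 0.7, seed = 1,
                    tuning_grid = NULL, n_boot = 1000, cv_folds = 3,
                    split = NULL) {
  records <- data.table::as.data.table(records)[!is.na(label)]
  cols <- feature_columns(feature_set)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("records lack feature column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(split))
    split <- split_data(records, split_fraction, split_mode, seed = seed)

  dat <- records[, c(cols, "label"), with = FALSE]
  dat[, label := factor(label, levels = c(0, 1))]
  if ("apoe_e4" %in% cols) dat[, apoe_e4 := as.integer(apoe_e4)]
  train <- dat[split$train]; test <- dat[split$test]

  # training-set median imputation for missing features
  n_imputed <- 0L
  medians <- vapply(cols, function(cl) median(train[[cl]], na.rm = TRUE), 0)
  for (cl in cols) {
    miss_tr <- is.na(train[[cl]]); miss_te <- is.na(test[[cl]])
    n_imputed <- n_imputed + sum(miss_tr) + sum(miss_te)
    if (any(miss_tr)) data.table::set(train, which(miss_tr), cl, medians[[cl]])
    if (any(miss_te)) data.table::set(test, which(miss_te), cl, medians[[cl]])
  }
  if (n_imputed > 0)
    message(n_imputed, " missing feature value(s) imputed with training medians")

  if (is.null(tuning_grid))
    tuning_grid <- expand.grid(num_trees = c(100, 300, 500),
                               max_depth = c(0, 5, 10), min_node = c(1, 3, 5))
  if (nrow(tuning_grid) == 0) {
    warning("empty tuning grid; using default hyperparameters")
    tuning_grid <- data.frame(num_trees = 500, max_depth = 0, min_node = 1)
  }
  best <- tune_rf(train, tuning_grid, cv_folds, seed)

  fit <- ranger::ranger(label ~ ., data = train, probability = TRUE,
                        num.trees = best$num_trees, max.depth = best$max_depth,
                        min.node.size = best$min_node, importance = "impurity",
                        seed = seed, num.threads = 1)
  scores <- predict(fit, data = test, num.threads = 1)$predictions[, "1"]
  eval <- evaluate_scores(scores, test$label, n_boot = n_boot, seed = seed)

  structure(list(
    feature_set = feature_set, features = cols,
    split_mode = split_mode, split_fraction = split_fraction,
    split = split, seed = seed, medians = medians,
    hyperparameters = best, forest = fit,
    eval = eval, importance = rank_importance(fit),
    n_train = nrow(train), n_test = nrow(test),
    call = match.call()
  ), class = "drf_fit")
}

# grid search by stratified cross-validated F1 on the training set
tune_rf <- function(train, grid, cv_folds, seed) {
  if (nrow(grid) == 1L) return(as.list(grid[1L, ]))
  set.seed(seed + 1L)
  fold <- integer(nrow(train))
  for (lv in levels(train$label)) {
    idx <- which(train$label == lv)
    fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    f1s <- vapply(seq_len(cv_folds), function(k) {
      fit <- ranger::ranger(label ~ ., data = train[fold != k],
                            probability = TRUE,
                            num.trees = grid$num_trees[g],
                            max.depth = grid$max_depth[g],
                            min.node.size = grid$min_node[g],
                            seed = seed + k, num.threads = 1)
      p <- predict(fit, data = train[fold == k], num.threads = 1)$predictions[, "1"]
      classification_metrics(p, train$label[fold == k])$f1
    }, 0)
    mean(f1s)
  }, 0)
  as.list(grid[which.max(scores), ])
}

#' Ranked Gini feature importance
#'
#' Mean impurity-decrease (Gini) importances of a fitted forest, normalised
#' to sum to 1 and sorted in decreasing order with a stable alphabetical
#' tie-break.
#'
#' @param fit A `ranger` fit trained with `importance = "impurity"`, or a
#'   `drf_fit`.
#' @return A `data.table` with columns `feature` and `importance`.
#' @export
rank_importance <- function(fit) {
  if (inherits(fit, "drf_fit")) return(fit$importance)
  imp <- ranger::importance(fit)
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  ord <- order(-imp, names(imp))
  data.table::data.table(feature = names(imp)[ord],
                         importance = unname(imp[ord]))
}

#' Fit the four input-variable-set models on one shared split
#'
#' Fits one Random-Forest model per input-variable set (demographics only,
#' driving only, driving + age, driving + age + APOE) on a single shared
#' train/test split so their metrics are directly comparable.
#'
#' @inheritParams fit_drf
#' @param base_seed Seed shared by split, tuning, forests and bootstrap.
#' @return A named list of `drf_fit` objects of class `drf_suite`, with a
#'   `print` method rendering a comparison table.
#' @export
run_four_models <- function(records, base_seed = 1, split_mode = "record",
                            split_fraction = 0.7, tuning_grid = NULL,
                            n_boot = 1000, cv_folds = 3) {
  records <- data.table::as.data.table(records)[!is.na(label)]
  split <- split_data(records, split_fraction, split_mode, seed = base_seed)
  sets <- c("age_apoe", "driving", "driving_age", "driving_age_apoe")
  fits <- lapply(sets, function(fs)
    fit_drf(records, feature_set = fs, split_mode = split_mode,
            split_fraction = split_fraction, seed = base_seed,
            tuning_grid = tuning_grid, n_boot = n_boot, cv_folds = cv_folds,
            split = split))
  names(fits) <- sets
  structure(fits, class = "drf_suite")
}

#' @export
print.drf_fit <- function(x, ...) {
  m <- x$eval$metrics; ci <- x$eval$ci
  cat("Random-Forest preclinical-AD classifier  (features: ", x$feature_set,
      ")\n", sep = "")
  cat(sprintf("  split: %s, %d train / %d test records\n",
              x$split_mode, x$n_train, x$n_test))
  cat(sprintf("  hyperparameters: %d trees, max depth %s, min node %d\n",
              x$hyperparameters$num_trees,
              ifelse(x$hyperparameters$max_depth == 0, "unlimited",
                     x$hyperparameters$max_depth),
              x$hyperparameters$min_node))
  for (metric in c("precision", "recall", "f1", "auc"))
    cat(sprintf("  %-9s %.3f  [%.3f, %.3f]\n", metric, m[[metric]],
                ci[[metric]][1], ci[[metric]][2]))
  invisible(x)
}

#' @export
summary.drf_fit <- function(object, n_features = 10, ...) {
  print(object)
  cat("Top feature importances (Gini, normalised):\n")
  top <- head(object$importance, n_features)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-14s %.4f\n", top$feature[i], top$importance[i]))
  invisible(object)
}

#' Predict preclinical-AD probabilities for new records
#'
#' @param object A `drf_fit`.
#' @param newdata Feature records with the model's feature columns (missing
#'   values are imputed with the stored training medians).
#' @param type `"prob"` for positive-class probabilities, `"class"` for 0/1
#'   labels at the fitted threshold.
#' @param ... Unused.
#' @return Numeric probabilities or integer labels.
#' @export
predict.drf_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  nd <- data.table::as.data.table(newdata)[, object$features, with = FALSE]
  if ("apoe_e4" %in% object$features) nd[, apoe_e4 := as.integer(apoe_e4)]
  for (cl in object$features) {
    miss <- is.na(nd[[cl]])
    if (any(miss)) data.table::set(nd, which(miss), cl, object$medians[[cl]])
  }
  p <- predict(object$forest, data = nd, num.threads = 1)$predictions[, "1"]
  if (type == "prob") p else as.integer(p >= object$eval$threshold)
}

#' ROC curve of a fitted classifier
#'
#' @param x A `drf_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.drf_fit <- function(x, ...) {
  roc <- x$eval$roc
  graphics::plot(roc$fpr, roc$tpr, type = "l",
                 xlab = "False-positive rate", ylab = "True-positive rate",
                 main = sprintf("ROC (%s), AUC = %.3f", x$feature_set,
                                x$eval$metrics$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' @export
print.drf_suite <- function(x, ...) {
  cat("Model                precision  recall     F1         AUC\n")
  for (nm in names(x)) {
    m <- x[[nm]]$eval$metrics
    cat(sprintf("%-20s %-10.3f %-10.3f %-10.3f %-10.3f\n", nm,
                m$precision, m$recall, m$f1, m$auc))
  }
  invisible(x)
}

#' Serialise an evaluation suite to JSON
#'
#' @param x A `drf_suite` or single `drf_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(x, path) {
  as_report <- function(f) list(
    model = f$feature_set,
    precision = f$eval$metrics$precision, recall = f$eval$metrics$recall,
    f1 = f$eval$metrics$f1, auc = f$eval$metrics$auc,
    precision_ci = f$eval$ci$precision, recall_ci = f$eval$ci$recall,
    f1_ci = f$eval$ci$f1, auc_ci = f$eval$ci$auc,
    importances = f$importance
  )
  reports <- if (inherits(x, "drf_suite")) lapply(unclass(x), as_report)
             else list(as_report(x))
  jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
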