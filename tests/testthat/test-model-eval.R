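test_that("record and grouped splits honour their contracts", {
  rec <- make_records(n_per_class = 50)
  sp <- split_data(rec, 0.7, "record", seed = 4)
  expect_equal(length(sp$train), 70)
  expect_equal(length(sp$test), 30)
  expect_identical(sp, split_data(rec, 0.7, "record", seed = 4))
  expect_false(identical(sp, split_data(rec, 0.7, "record", seed = 5)))

  spg <- split_data(rec, 0.7, "grouped", seed = 4)
  expect_length(intersect(rec$participant_id[spg$train],
                          rec$participant_id[spg$test]), 0)
})

test_that("rank AUC equals the all-pairs concordance oracle", {
  auc_oracle <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    s <- 0
    for (p in pos) for (q in neg)
      s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
  }
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auc_score(scores, labels), auc_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("F1 is exactly the harmonic mean of precision and recall", {
  m <- drivemarkers:::classification_metrics(c(0.9, 0.9, 0.1, 0.9),
                                             c(1, 0, 1, 1))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(4:60, 1)
    scores <- runif(n); labels <- sample(0:1, n, replace = TRUE)
    m <- drivemarkers:::classification_metrics(scores, labels)
    if (m$precision + m$recall > 0)
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-15)
  }
  # precision 0.5, recall 1.0 -> F1 = 2/3
  m2 <- drivemarkers:::classification_metrics(c(.9, .9), c(1, 0))
  expect_equal(m2$f1, 2 / 3)
})

test_that("evaluation reports flag degenerate predictions and order their CIs", {
  ev <- evaluate_scores(c(0.1, 0.2, 0.3, 0.1), c(1, 0, 1, 0), n_boot = 50)
  expect_true(ev$no_predicted_positives)
  expect_equal(ev$metrics$precision, 0)
  ev2 <- evaluate_scores(runif(40), sample(0:1, 40, replace = TRUE),
                         n_boot = 100)
  for (metric in c("precision", "recall", "f1", "auc")) {
    expect_lte(ev2$ci[[metric]][1], ev2$metrics[[metric]] + 1e-12)
    expect_gte(ev2$ci[[metric]][2], ev2$metrics[[metric]] - 1e-12)
  }
})

test_that("bootstrap intervals tighten with larger test sets", {
  set.seed(31)
  width <- sapply(c(40, 400), function(n) {
    scores <- runif(n) + 0.4 * rep(0:1, n / 2)
    ev <- evaluate_scores(scores, rep(0:1, n / 2), n_boot = 300, seed = 9)
    ev$ci$auc[2] - ev$ci$auc[1]
  })
  expect_lt(width[2], width[1])
})

test_that("the fitted classifier separates a separable problem and is reproducible", {
  rec <- make_records(n_per_class = 60, separation = 4)
  grid <- data.frame(num_trees = 100, max_depth = 0, min_node = 1)
  fit <- fit_drf(rec, "driving", seed = 2, tuning_grid = grid, n_boot = 100)
  expect_s3_class(fit, "drf_fit")
  expect_gt(fit$eval$metrics$auc, 0.95)
  fit2 <- fit_drf(rec, "driving", seed = 2, tuning_grid = grid, n_boot = 100)
  expect_equal(fit$eval$metrics, fit2$eval$metrics)
  expect_equal(fit$hyperparameters, fit2$hyperparameters)
  # predictions on new data live in [0, 1]
  p <- predict(fit, rec[1:5])
  expect_true(all(p >= 0 & p <= 1))
})

test_that("empty tuning grids fall back to defaults with a warning", {
  rec <- make_records(n_per_class = 30, separation = 4)
  expect_warning(
    fit <- fit_drf(rec, "driving", seed = 1,
                   tuning_grid = data.frame(num_trees = integer(0),
                                            max_depth = integer(0),
                                            min_node = integer(0)),
                   n_boot = 50),
    "empty tuning grid")
  expect_s3_class(fit, "drf_fit")
})

test_that("Gini importances are normalised, sorted, and identify the signal", {
  rec <- make_records(n_per_class = 60, separation = 0)
  set.seed(8)
  rec$TotalDist <- rec$label * 2 + rnorm(nrow(rec), 0, 0.1)  # dominant signal
  grid <- data.frame(num_trees = 200, max_depth = 0, min_node = 1)
  fit <- fit_drf(rec, "driving", seed = 3, tuning_grid = grid, n_boot = 50)
  imp <- fit$importance
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(diff(imp$importance) <= 1e-12))
  expect_equal(imp$feature[1], "TotalDist")
})

test_that("duplicated features share importance rather than doubling it", {
  # with every feature available at each split, an exact duplicate of the
  # informative column splits the credit instead of adding to it
  rec <- make_records(n_per_class = 100, separation = 0, seed = 4)
  set.seed(9)
  rec$TotalDist <- rec$label + rnorm(nrow(rec))
  cols <- feature_columns("driving")
  d1 <- rec[, c(cols, "label"), with = FALSE]
  d1[, label := factor(label)]
  f1 <- ranger::ranger(label ~ ., d1, num.trees = 500,
                       importance = "impurity", mtry = length(cols),
                       seed = 5, num.threads = 1)
  imp_single <- rank_importance(f1)[feature == "TotalDist", importance]
  d2 <- data.table::copy(d1)
  d2$TripDist <- d2$TotalDist
  f2 <- ranger::ranger(label ~ ., d2, num.trees = 500,
                       importance = "impurity", mtry = length(cols),
                       seed = 5, num.threads = 1)
  imp_dup <- rank_importance(f2)[feature %in% c("TotalDist", "TripDist"),
                                 sum(importance)]
  expect_lt(abs(imp_dup - imp_single) / imp_single, 0.2)
})

test_that("the four-model runner emits comparable reports with CI fields", {
  rec <- make_records(n_per_class = 60, separation = 2)
  grid <- data.frame(num_trees = 100, max_depth = 0, min_node = 1)
  suite <- run_four_models(rec, base_seed = 1, tuning_grid = grid, n_boot = 50)
  expect_named(suite, c("age_apoe", "driving", "driving_age",
                        "driving_age_apoe"))
  expect_equal(length(suite$age_apoe$features), 2L)
  for (fit in suite) {
    expect_length(fit$eval$ci$auc, 2)
    expect_length(fit$eval$ci$f1, 2)
    # all four models share one split
    expect_identical(fit$split, suite$age_apoe$split)
  }
  path <- tempfile(fileext = ".json")
  write_eval_json(suite, path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed, 4)
  expect_true(all(c("precision", "recall", "f1", "auc", "auc_ci") %in%
                  names(parsed[[1]])))
})
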