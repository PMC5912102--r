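test_that("outer folds rotate contiguous blocks and partition the cohort", {
  ids <- sprintf("p%02d", 1:42)
  folds <- outer_folds(ids, 5)
  expect_length(folds, 9)
  expect_equal(lengths(lapply(folds, `[[`, "test")),
               c(rep(5L, 8), 2L), ignore_attr = TRUE)
  # test sets partition the cohort exactly once
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), ids)
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$validation, f$test), 0)
    expect_equal(sort(c(f$train, f$validation, f$test)), ids)
  }
  # validation is the cyclically following block
  expect_equal(folds[[1]]$validation, ids[6:10])
  expect_equal(folds[[9]]$validation, ids[1:5])
  expect_error(outer_folds(ids[1:8], 5), "at least 3 blocks")
})

test_that("majority voting follows the count, probability, order tie rules", {
  expect_equal(as.character(majority_vote(c("low", "low", "high"))), "low")
  probs <- rbind(c(0.6, 0.1, 0.3), c(0.3, 0.1, 0.8))
  colnames(probs) <- c("low", "medium", "high")
  expect_equal(as.character(majority_vote(c("low", "high"), probs)), "high")
  # remaining ties resolve to the lower range
  expect_equal(as.character(majority_vote(c("medium", "high"))), "medium")
  expect_error(majority_vote(character(0)), "no retained windows")
})

test_that("the window classifier scales on training data and is seeded", {
  set.seed(2)
  n <- 90
  X <- cbind(sep = rep(c(0, 5, 10), each = 30) + rnorm(n, 0, 0.1),
             noise = rnorm(n), flat = rep(1, n))
  y <- factor(rep(c("low", "medium", "high"), each = 30),
              levels = c("low", "medium", "high"))
  clf <- fit_trait_classifier(X, y, forest_spec(seed = 7))
  # scaler parameters come from the training rows only
  expect_equal(clf$center, colMeans(X))
  expect_equal(unname(clf$scale["flat"]), 1)  # zero-variance: centred only
  pr <- predict(clf, X)
  expect_equal(mean(pr$pred == y), 1)  # perfectly separable
  pr2 <- predict(fit_trait_classifier(X, y, forest_spec(seed = 7)), X)
  expect_identical(pr$pred, pr2$pred)

  imp <- feature_importances(list(clf))
  expect_equal(sum(imp$per_model[1, ]), 1)
  expect_equal(imp$summary$feature[1], "sep")
  expect_equal(unname(imp$per_model[1, "flat"]), 0)

  expect_error(fit_trait_classifier(X, factor(rep("low", n),
                                              levels = c("low", "medium",
                                                         "high"))),
               "at least 2 classes")
})

test_that("nested cross-validation predicts every participant once", {
  sc <- small_cohort()
  bins <- bin_traits(sc$cohort$traits)
  cand <- candidate_grid(c(15, 30), c("all", "event"))
  ps <- nested_cross_validation(sc$featsets, bins$extraversion$assignment,
                                spec = forest_spec(), candidates = cand,
                                seed = 31, block_size = 3)
  expect_equal(sort(names(ps$predictions)),
               sort(sc$cohort$traits$participant_id))
  expect_false(anyDuplicated(names(ps$predictions)) > 0)
  # selections come from the candidate grid with in-range validation F1
  expect_true(all(ps$selections$size %in% c(15, 30)))
  expect_true(all(ps$selections$subset %in% c("all", "event")))
  expect_true(all(ps$selections$val_f1 >= 0 & ps$selections$val_f1 <= 1))
  # test windows belong to test participants of their fold only
  folds <- ps$folds
  for (f in seq_along(folds)) {
    wp <- ps$window_preds[ps$window_preds$fold == f, ]
    expect_true(all(wp$participant %in% folds[[f]]$test))
  }
  # same seed reproduces the predictions; a different seed may differ
  ps2 <- nested_cross_validation(sc$featsets, bins$extraversion$assignment,
                                 spec = forest_spec(), candidates = cand,
                                 seed = 31, block_size = 3)
  expect_identical(ps$predictions, ps2$predictions)
  expect_error(nested_cross_validation(sc$featsets,
                                       bins$extraversion$assignment,
                                       candidates = cand[0, ], seed = 1),
               "empty")
})

test_that("feature subsets cover the families and their complements", {
  subs <- feature_subsets()
  expect_named(subs, c("all", "raw", "heatmap", "event", "ngram",
                       "no_raw", "no_heatmap", "no_event", "no_ngram"))
  expect_equal(lengths(subs)[c("raw", "heatmap", "event", "ngram")],
               c(raw = 34, heatmap = 64, event = 53, ngram = 56))
  for (fam in c("raw", "heatmap", "event", "ngram")) {
    expect_equal(sort(c(subs[[fam]], subs[[paste0("no_", fam)]])), 1:207)
  }
})
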