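balanced_truth <- function(n = 42) {
  stats::setNames(factor(rep(c("low", "medium", "high"), length.out = n),
                         levels = c("low", "medium", "high")),
                  sprintf("p%02d", seq_len(n)))
}

test_that("macro F1 handles identity, constant predictors and errors", {
  truth <- balanced_truth(12)
  expect_equal(macro_f1(truth, truth), 1)
  # constant single-range prediction on balanced truth: the predicted range
  # has precision 1/3 and recall 1 (F1 = 1/2), the others 0
  const <- stats::setNames(factor(rep("low", 12),
                                  levels = c("low", "medium", "high")),
                           names(truth))
  expect_equal(macro_f1(const, truth), 1 / 6)
  # permutation-invariant in participant order
  perm <- sample(names(truth))
  expect_equal(macro_f1(const[perm], truth), 1 / 6)
  other <- stats::setNames(truth, paste0("q", seq_along(truth)))
  expect_error(macro_f1(other, truth), "disjoint")
})

test_that("uniform-random baseline matches exhaustive enumeration", {
  p1 <- uniform_random_baseline(sprintf("p%02d", 1:42), seed = 4)
  expect_identical(p1, uniform_random_baseline(sprintf("p%02d", 1:42),
                                               seed = 4))
  # all-low truth, n = 4: expectation over all 3^4 equally likely outcomes
  truth <- stats::setNames(factor(rep("low", 4),
                                  levels = c("low", "medium", "high")),
                           sprintf("p%d", 1:4))
  grid <- expand.grid(rep(list(c("low", "medium", "high")), 4),
                      stringsAsFactors = FALSE)
  exact <- mean(apply(grid, 1, function(g) {
    macro_f1(stats::setNames(factor(g, levels = levels(truth)),
                             names(truth)), truth)
  }))
  sim <- mean(vapply(1:3000, function(s) {
    macro_f1(uniform_random_baseline(names(truth), seed = s), truth)
  }, numeric(1)))
  expect_lt(abs(sim - exact), 3 * 0.11 / sqrt(3000))
})

test_that("most-frequent baseline predicts the training-pool mode", {
  assignment <- balanced_truth(12)
  assignment[1:7] <- "low"  # 7 low / 3 medium / 2 high
  folds <- list(list(train = names(assignment)[1:8],
                     validation = names(assignment)[9:10],
                     test = names(assignment)[11:12]))
  mf <- most_frequent_baseline(folds, assignment)
  expect_equal(unname(as.character(mf)), rep("low", 2))
  # ties go to the lower range
  tied <- stats::setNames(factor(c("low", "high", "low", "high"),
                                 levels = c("low", "medium", "high")),
                          sprintf("p%d", 1:4))
  folds2 <- list(list(train = sprintf("p%d", 1:4), validation = character(0),
                      test = "p1"))
  expect_equal(as.character(most_frequent_baseline(folds2, tied)), "low")
})

test_that("label permutation preserves the class multiset and the seed", {
  sc <- small_cohort()
  bins <- bin_traits(sc$cohort$traits)
  cand <- candidate_grid(15, "event")
  pp <- label_permutation_run(sc$featsets, bins$pcs$assignment,
                              candidates = cand, seed = 8, block_size = 3)
  expect_equal(table(pp$permuted_assignment), table(bins$pcs$assignment))
  pp2 <- label_permutation_run(sc$featsets, bins$pcs$assignment,
                               candidates = cand, seed = 8, block_size = 3)
  expect_identical(pp$permuted_assignment, pp2$permuted_assignment)
  expect_identical(pp$predictions, pp2$predictions)
})

test_that("bootstrap CIs are degenerate-safe, bounded, and calibrated", {
  expect_equal(bootstrap_ci(rep(0.4, 100), seed = 1), c(0.4, 0.4))
  set.seed(5)
  scores <- runif(60)
  ci <- bootstrap_ci(scores, seed = 2)
  expect_gte(ci[1], min(scores))
  expect_lte(ci[2], max(scores))
  expect_error(bootstrap_ci(0.5), "at least 2")
  # empirical coverage of the true mean for Gaussian samples
  hits <- vapply(1:300, function(s) {
    set.seed(s + 10000)
    x <- stats::rnorm(50)  # true mean 0
    ci <- bootstrap_ci(x, iters = 400, seed = s)
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.88)
  expect_lt(mean(hits), 0.99)
})

test_that("reliability Fisher-averages pairs and flags degenerate ones", {
  a <- balanced_truth(12)
  # identical vectors in every pair: r exactly 1
  rel <- prediction_reliability(list(list(a = a, b = a),
                                     list(a = a, b = a)))
  expect_equal(rel$r, 1)
  # Fisher-averaging {0.5, 0.5} returns 0.5
  expect_equal(tanh(mean(atanh(c(0.5, 0.5)))), 0.5)
  # degenerate pairs are skipped and counted
  const <- stats::setNames(factor(rep("low", 12),
                                  levels = c("low", "medium", "high")),
                           names(a))
  rel2 <- prediction_reliability(list(list(a = a, b = a),
                                      list(a = const, b = a)))
  expect_equal(rel2$n_skipped, 1)
  expect_error(prediction_reliability(list(list(a = const, b = const))),
               "degenerate")
})

test_that("context predictions vote only over the requested windows", {
  wp <- data.frame(
    participant = rep(c("pA", "pB"), each = 4),
    start = rep(c(0, 10, 20, 30), 2), mid = rep(c(5, 15, 25, 35), 2),
    context = rep(c("way1", "shop", "shop", "way2"), 2),
    pred = c("low", "high", "high", "low", "medium", "low", "low", "medium"),
    fold = 1, size = 10, subset = "all", stringsAsFactors = FALSE)
  wp$p_low <- 0.4; wp$p_medium <- 0.3; wp$p_high <- 0.3
  ps <- structure(list(window_preds = wp), class = "prediction_set")
  shop <- context_prediction(ps, "shop")
  expect_equal(as.character(shop[c("pA", "pB")]), c("high", "low"))
  way <- context_prediction(ps, "way")
  expect_equal(as.character(way[c("pA", "pB")]), c("low", "medium"))
  # half splits use recording durations
  dur <- c(pA = 40, pB = 40)
  h1 <- context_prediction(ps, "half1", dur)
  expect_equal(as.character(h1["pA"]), "low")   # windows at mid 5 and 15
  # a participant with no window in the context is dropped
  wp2 <- wp[!(wp$participant == "pB" & wp$context == "shop"), ]
  ps2 <- structure(list(window_preds = wp2), class = "prediction_set")
  expect_false("pB" %in% names(context_prediction(ps2, "shop")))
})

test_that("feature-trait correlations recover identity and flag constants", {
  sc <- small_cohort()
  fs <- sc$featsets[["15"]]
  traits <- sc$cohort$traits
  # plant a feature equal to the participant's extraversion score
  X <- fs$X
  X[, 1] <- traits$extraversion[match(fs$meta$participant,
                                      traits$participant_id)]
  X[, 2] <- 7  # constant across all windows
  planted <- structure(list(X = X, meta = fs$meta),
                       class = "window_features")
  res <- feature_trait_correlations(planted, traits)
  expect_equal(unname(res$r[1, "extraversion"]), 1)
  expect_true(res$flagged[2])
  expect_equal(unname(res$r[2, ]), rep(0, 7))
  expect_true(all(abs(res$r) <= 1 + 1e-12))
})
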