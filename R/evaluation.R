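# Scoring and evaluation machinery: macro F1, the three baselines,
# bootstrap confidence intervals, context-split prediction reliability and
# feature-trait correlations.

#' Macro-averaged F1 score over the three score ranges
#'
#' Per-range F1 is the harmonic mean of precision and recall, with the 0/0
#' convention mapped to 0 (needed for constant predictors); the macro score
#' is the unweighted mean over low/medium/high.
#'
#' @param pred Named factor/character of predicted ranges.
#' @param truth Named factor/character of true ranges (same participants).
#' @return Macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(pred, truth) {
  if (!is.null(names(pred)) && !is.null(names(truth))) {
    common <- intersect(names(pred), names(truth))
    if (length(common) == 0) stop("disjoint participant sets", call. = FALSE)
    pred <- pred[common]; truth <- truth[common]
  } else if (length(pred) != length(truth)) {
    stop("prediction and truth lengths differ", call. = FALSE)
  }
  pred <- factor(pred, levels = RANGE_LEVELS)
  truth <- factor(truth, levels = RANGE_LEVELS)
  f1s <- vapply(RANGE_LEVELS, function(r) {
    tp <- sum(pred == r & truth == r)
    fp <- sum(pred == r & truth != r)
    fn <- sum(pred != r & truth == r)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

#' Uniform-random baseline predictions
#'
#' Samples one of the three score ranges per participant from a uniform
#' distribution; seed-reproducible.
#'
#' @param participants Participant ids.
#' @param seed Integer seed.
#' @return Named factor of predicted ranges.
#' @export
uniform_random_baseline <- function(participants, seed) {
  with_seed(seed, {
    p <- factor(sample(RANGE_LEVELS, length(participants), replace = TRUE),
                levels = RANGE_LEVELS)
    names(p) <- participants
    p
  })
}

#' Most-frequent-range baseline predictions
#'
#' Per outer fold, the modal range of the training pool (training plus
#' validation participants; ties towards the lower range) is predicted for
#' every test participant.
#'
#' @param folds Output of [outer_folds()].
#' @param assignment Named factor participant -> range.
#' @return Named factor of predicted ranges covering all participants.
#' @export
most_frequent_baseline <- function(folds, assignment) {
  preds <- unlist(lapply(folds, function(fold) {
    pool <- assignment[c(fold$train, fold$validation)]
    counts <- table(factor(pool, levels = RANGE_LEVELS))
    mode_range <- names(counts)[which.max(counts)]
    stats::setNames(rep(mode_range, length(fold$test)), fold$test)
  }))
  out <- factor(preds, levels = RANGE_LEVELS)
  names(out) <- names(preds)
  out
}

#' Label-permutation run
#'
#' Permutes the participant-to-range assignment once (preserving the class
#' multiset) and runs the full nested cross-validation unchanged, severing
#' any relation between gaze features and score ranges.
#'
#' @inheritParams nested_cross_validation
#' @return A `prediction_set`; the permuted assignment is attached as
#'   `$permuted_assignment`.
#' @export
label_permutation_run <- function(featsets, assignment,
                                  spec = forest_spec(), candidates = NULL,
                                  seed = 1, block_size = 5) {
  seeds <- derive_seeds(seed, 2)
  permuted <- with_seed(seeds[1], {
    p <- sample(assignment)
    names(p) <- names(assignment)
    p
  })
  res <- nested_cross_validation(featsets, permuted, spec = spec,
                                 candidates = candidates, seed = seeds[2],
                                 block_size = block_size)
  res$permuted_assignment <- permuted
  res
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param scores Numeric vector (at least 2 values).
#' @param iters Bootstrap iterations.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(scores, iters = 1000, seed = 1, conf = 0.95) {
  if (length(scores) < 2) stop("need at least 2 scores", call. = FALSE)
  with_seed(seed, {
    means <- vapply(seq_len(iters), function(i) {
      mean(sample(scores, length(scores), replace = TRUE))
    }, numeric(1))
    alpha <- (1 - conf) / 2
    stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  })
}

# Subset a prediction set's test windows by a context filter and re-vote.
# `filter` receives the window_preds data frame and returns a logical mask.
revote_windows <- function(pred_set, filter) {
  wp <- pred_set$window_preds
  keep <- filter(wp)
  wp <- wp[keep, , drop = FALSE]
  probs <- as.matrix(wp[, paste0("p_", RANGE_LEVELS)])
  colnames(probs) <- RANGE_LEVELS
  ids <- unique(pred_set$window_preds$participant)
  votes <- lapply(ids, function(id) {
    rows <- which(wp$participant == id)
    if (length(rows) == 0) return(NULL)
    majority_vote(wp$pred[rows], probs[rows, , drop = FALSE])
  })
  names(votes) <- ids
  votes <- votes[!vapply(votes, is.null, logical(1))]
  out <- factor(unlist(lapply(votes, as.character)), levels = RANGE_LEVELS)
  names(out) <- names(votes)
  out
}

#' Context-restricted participant predictions
#'
#' Reconstructs each participant's prediction from the stored window-level
#' test predictions, majority-voting only over windows of the requested
#' context. Participants with no retained window in that context are
#' dropped (their absence is visible in the returned names).
#'
#' @param pred_set A `prediction_set` from [nested_cross_validation()].
#' @param context One of `"shop"`, `"way1"`, `"way2"`, `"way"` (both way
#'   segments), `"half1"`, `"half2"` (first/second half of the recording by
#'   window midpoint), or `"all"`.
#' @param durations Named vector of recording durations (needed for the
#'   half splits).
#' @return Named factor of predicted ranges for the covered participants.
#' @export
context_prediction <- function(pred_set, context, durations = NULL) {
  filter <- switch(
    context,
    all = function(wp) rep(TRUE, nrow(wp)),
    shop = function(wp) wp$context == "shop",
    way1 = function(wp) wp$context == "way1",
    way2 = function(wp) wp$context == "way2",
    way = function(wp) wp$context %in% c("way1", "way2"),
    half1 = function(wp) wp$mid < durations[wp$participant] / 2,
    half2 = function(wp) wp$mid >= durations[wp$participant] / 2,
    stop("unknown context: ", context, call. = FALSE))
  if (context %in% c("half1", "half2") && is.null(durations)) {
    stop("half splits need recording durations", call. = FALSE)
  }
  revote_windows(pred_set, filter)
}

# Fisher-transform average of correlations, back-transformed.
fisher_mean <- function(r) {
  tanh(mean(atanh(pmin(1, pmax(-1, r)))))
}

#' Prediction reliability across repeated prediction pairs
#'
#' Predictions are encoded ordinally (low = 0, medium = 1, high = 2); each
#' pair contributes the Pearson correlation over its common participants,
#' and pairs are averaged on the Fisher z scale (correcting for the
#' skewness of the sampling distribution of correlation coefficients) and
#' back-transformed. Pairs where either vector has zero variance are
#' skipped and counted.
#'
#' @param pairs List of lists with elements `a` and `b`: named factors of
#'   predicted ranges covering (mostly) the same participants.
#' @return A list with `r` (the Fisher-averaged correlation), `n_pairs`
#'   (pairs used) and `n_skipped`.
#' @export
prediction_reliability <- function(pairs) {
  rs <- vapply(pairs, function(p) {
    common <- intersect(names(p$a), names(p$b))
    if (length(common) < 3) return(NA_real_)
    a <- as.numeric(factor(p$a[common], levels = RANGE_LEVELS)) - 1
    b <- as.numeric(factor(p$b[common], levels = RANGE_LEVELS)) - 1
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  used <- !is.na(rs)
  if (!any(used)) stop("all prediction pairs are degenerate", call. = FALSE)
  list(r = fisher_mean(rs[used]), n_pairs = sum(used),
       n_skipped = sum(!used))
}

#' Correlations between trait scores and per-participant mean features
#'
#' Features (extracted at one window size, 15 s in the reference analysis)
#' are averaged per participant over retained windows and correlated with
#' each trait's raw score across participants. Zero-variance features get
#' r = 0 with a flag.
#'
#' @param fs A cohort `window_features` object (see [build_feature_sets()]).
#' @param traits Trait-score data frame.
#' @return A list with `r` (features x traits matrix) and `flagged`
#'   (logical vector marking zero-variance features).
#' @export
feature_trait_correlations <- function(fs, traits) {
  ids <- unique(fs$meta$participant)
  M <- t(vapply(ids, function(id) {
    colMeans(fs$X[fs$meta$participant == id, , drop = FALSE])
  }, numeric(ncol(fs$X))))
  rownames(M) <- ids
  traits <- traits[match(ids, traits$participant_id), ]
  sds <- apply(M, 2, stats::sd)
  flagged <- !is.finite(sds) | sds == 0
  r <- matrix(0, nrow = ncol(M), ncol = length(TRAIT_NAMES),
              dimnames = list(colnames(M), TRAIT_NAMES))
  for (tr in TRAIT_NAMES) {
    v <- traits[[tr]]
    r[!flagged, tr] <- suppressWarnings(
      as.numeric(stats::cor(M[, !flagged, drop = FALSE], v)))
  }
  r[!is.finite(r)] <- 0
  list(r = r, flagged = flagged)
}

#' Evaluate one trait: classifier and baselines over repetitions
#'
#' Runs the nested cross-validation `reps` times with distinct seeds,
#' together with the uniform-random, most-frequent and label-permutation
#' baselines, and summarises each method's macro F1 scores with a
#' percentile-bootstrap confidence interval.
#'
#' @inheritParams nested_cross_validation
#' @param reps Number of repetitions (100 in the reference analysis).
#' @param run_permutation Whether to run the (expensive) label-permutation
#'   baseline.
#' @param keep_sets Whether to keep the per-repetition `prediction_set`s
#'   (needed for reliability analyses).
#' @return A list of class `evaluation_result` with per-method F1 vectors
#'   (`f1$classifier`, `f1$random`, `f1$most_frequent`,
#'   `f1$permutation`), a `summary` data frame with means and 95% CIs, and
#'   optionally `sets`.
#' @export
evaluate_trait <- function(featsets, assignment, spec = forest_spec(),
                           candidates = NULL, reps = 100, seed = 1,
                           block_size = 5, run_permutation = TRUE,
                           keep_sets = FALSE) {
  participants <- names(assignment)
  folds <- outer_folds(participants, block_size)
  seeds <- matrix(derive_seeds(seed, 3 * reps), ncol = 3)
  sets <- if (keep_sets) vector("list", reps) else NULL
  f1 <- list(classifier = numeric(reps), random = numeric(reps),
             most_frequent = numeric(reps),
             permutation = if (run_permutation) numeric(reps) else NULL)
  mf <- most_frequent_baseline(folds, assignment)
  for (i in seq_len(reps)) {
    ps <- nested_cross_validation(featsets, assignment, spec = spec,
                                  candidates = candidates,
                                  seed = seeds[i, 1],
                                  block_size = block_size)
    f1$classifier[i] <- macro_f1(ps$predictions, assignment)
    f1$random[i] <- macro_f1(
      uniform_random_baseline(participants, seeds[i, 2]), assignment)
    f1$most_frequent[i] <- macro_f1(mf, assignment)
    if (run_permutation) {
      pp <- label_permutation_run(featsets, assignment, spec = spec,
                                  candidates = candidates,
                                  seed = seeds[i, 3],
                                  block_size = block_size)
      f1$permutation[i] <- macro_f1(pp$predictions, assignment)
    }
    if (keep_sets) sets[[i]] <- ps
  }
  methods <- names(f1)[!vapply(f1, is.null, logical(1))]
  summary_df <- do.call(rbind, lapply(methods, function(m) {
    ci <- bootstrap_ci(f1[[m]], iters = 1000, seed = seeds[1, 1])
    data.frame(method = m, mean_f1 = mean(f1[[m]]),
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  }))
  structure(list(f1 = f1, summary = summary_df, sets = sets,
                 folds = folds),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Context-split reliability over repeated prediction sets
#'
#' For each of the three comparisons -- split halves, way I vs way II, shop
#' vs way -- repetition i's prediction set is paired with itself restricted
#' to the two context subsets, and the pairs are Fisher-averaged.
#'
#' @param sets List of `prediction_set`s (one per repetition, from
#'   [evaluate_trait()] with `keep_sets = TRUE`).
#' @param durations Named vector of recording durations per participant.
#' @return Data frame with one row per comparison: `comparison`, `r`,
#'   `n_pairs`, `n_skipped`.
#' @export
reliability_table <- function(sets, durations) {
  comparisons <- list(
    split_halves = c("half1", "half2"),
    way1_vs_way2 = c("way1", "way2"),
    shop_vs_way = c("shop", "way"))
  do.call(rbind, lapply(names(comparisons), function(cmp) {
    ctx <- comparisons[[cmp]]
    pairs <- lapply(sets, function(ps) {
      list(a = context_prediction(ps, ctx[1], durations),
           b = context_prediction(ps, ctx[2], durations))
    })
    rel <- prediction_reliability(pairs)
    data.frame(comparison = cmp, r = rel$r, n_pairs = rel$n_pairs,
               n_skipped = rel$n_skipped, stringsAsFactors = FALSE)
  }))
}
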