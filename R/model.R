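# Per-trait three-class classification: standard scaling + random forest,
# majority voting over windows, nested cross-validation with window-size and
# feature-subset selection, and impurity-based feature importance.

#' Random-forest hyperparameters
#'
#' Defaults follow the reference configuration: 100 trees, maximum depth 5,
#' up to 15 features considered per split.
#'
#' @param n_trees Number of trees.
#' @param max_depth Maximum tree depth.
#' @param max_features Features considered per split (mtry).
#' @param seed Integer seed for the forest.
#' @return A list of class `forest_spec`.
#' @export
forest_spec <- function(n_trees = 100, max_depth = 5, max_features = 15,
                        seed = 1) {
  structure(list(n_trees = n_trees, max_depth = max_depth,
                 max_features = max_features, seed = seed),
            class = "forest_spec")
}

#' Fit the scaler + random-forest window classifier for one trait
#'
#' A standard scaler (per-feature centre and scale) is fit on the training
#' rows and applied before the forest; zero-variance features are centred
#' only. Window labels are the participant's low/medium/high range.
#'
#' @param X Feature matrix (training windows x features).
#' @param y Factor of range labels (levels low/medium/high), one per row.
#' @param spec A [forest_spec()].
#' @return An object of class `trait_classifier`.
#' @export
fit_trait_classifier <- function(X, y, spec = forest_spec()) {
  y <- factor(y, levels = RANGE_LEVELS)
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("need at least 2 classes in the training labels", call. = FALSE)
  }
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  Xs <- scale(X, center = center, scale = scale_)
  fit <- ranger::ranger(x = Xs, y = droplevels(y),
                        num.trees = spec$n_trees,
                        mtry = min(spec$max_features, ncol(X)),
                        max.depth = spec$max_depth,
                        probability = TRUE,
                        importance = "impurity",
                        seed = spec$seed, num.threads = 1)
  structure(list(fit = fit, center = center, scale = scale_,
                 features = colnames(X), spec = spec),
            class = "trait_classifier")
}

#' Predict window classes and class probabilities
#'
#' @param object A [fit_trait_classifier()] result.
#' @param newdata Feature matrix with the classifier's feature columns.
#' @param ... Unused.
#' @return A list with `pred` (factor, ties resolved towards the lower
#'   range) and `probs` (matrix with columns low/medium/high).
#' @export
predict.trait_classifier <- function(object, newdata, ...) {
  newdata <- newdata[, object$features, drop = FALSE]
  Xs <- scale(newdata, center = object$center, scale = object$scale)
  raw <- stats::predict(object$fit, data = Xs, num.threads = 1)$predictions
  probs <- matrix(0, nrow = nrow(newdata), ncol = 3,
                  dimnames = list(NULL, RANGE_LEVELS))
  probs[, colnames(raw)] <- raw
  pred <- factor(RANGE_LEVELS[max.col(probs, ties.method = "first")],
                 levels = RANGE_LEVELS)
  list(pred = pred, probs = probs)
}

#' Majority vote over window predictions
#'
#' The participant is assigned the most frequent window-level range; ties
#' are broken by the highest summed class probability, remaining ties by the
#' lower range (low < medium < high).
#'
#' @param preds Factor or character vector of window predictions.
#' @param probs Optional matrix of window class probabilities
#'   (columns low/medium/high).
#' @return A single factor level.
#' @export
majority_vote <- function(preds, probs = NULL) {
  if (length(preds) == 0) {
    stop("no retained windows for participant", call. = FALSE)
  }
  preds <- factor(preds, levels = RANGE_LEVELS)
  counts <- table(preds)
  top <- which(counts == max(counts))
  if (length(top) > 1 && !is.null(probs)) {
    sums <- colSums(probs[, RANGE_LEVELS, drop = FALSE])[names(top)]
    top <- top[sums == max(sums)]
  }
  factor(names(top)[1], levels = RANGE_LEVELS)
}

#' Outer folds for nested cross-validation
#'
#' Rotates contiguous participant blocks: fold k uses block k as the test
#' set and the cyclically following block as the validation set, with all
#' remaining participants as the training set. Test blocks partition the
#' cohort; with n not divisible by the block size the last block is smaller.
#'
#' @param ids Participant ids in cohort order.
#' @param block_size Test/validation block size.
#' @return List of folds, each with `train`, `validation`, `test`.
#' @export
outer_folds <- function(ids, block_size = 5) {
  n <- length(ids)
  nb <- ceiling(n / block_size)
  if (nb < 3) stop("need at least 3 blocks for nested cross-validation",
                   call. = FALSE)
  block <- ceiling(seq_len(n) / block_size)
  lapply(seq_len(nb), function(k) {
    test <- ids[block == k]
    validation <- ids[block == (k %% nb) + 1L]
    list(train = setdiff(ids, c(test, validation)),
         validation = validation, test = test)
  })
}

#' The candidate feature subsets
#'
#' All 207 features, each of the four feature families alone, and all
#' features minus each family (9 subsets).
#'
#' @return Named list of column-index vectors into the canonical feature
#'   order.
#' @export
feature_subsets <- function() {
  blocks <- attr(feature_names(), "blocks")
  all_idx <- seq_len(207)
  out <- c(list(all = all_idx),
           blocks,
           lapply(blocks, function(b) setdiff(all_idx, b)))
  names(out) <- c("all", names(blocks), paste0("no_", names(blocks)))
  out
}

#' Candidate grid for nested cross-validation
#'
#' @param sizes Window sizes (seconds) with available feature sets.
#' @param subsets Names of feature subsets (see [feature_subsets()]).
#' @return Data frame with columns `size` and `subset`.
#' @export
candidate_grid <- function(sizes = c(5, 10, 15, 30, 45, 60),
                           subsets = names(feature_subsets())) {
  expand.grid(size = sizes, subset = subsets,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# Fit on `train_ids`, predict windows of `eval_ids`; returns window-level
# predictions plus per-participant votes.
fit_and_predict <- function(fs, cols, train_ids, eval_ids, assignment,
                            spec) {
  tr_rows <- fs$meta$participant %in% train_ids
  if (sum(tr_rows) == 0) stop("no training windows", call. = FALSE)
  clf <- fit_trait_classifier(fs$X[tr_rows, cols, drop = FALSE],
                              assignment[fs$meta$participant[tr_rows]],
                              spec)
  ev_rows <- which(fs$meta$participant %in% eval_ids)
  pr <- stats::predict(clf, fs$X[ev_rows, cols, drop = FALSE])
  votes <- lapply(eval_ids, function(id) {
    rows <- which(fs$meta$participant[ev_rows] == id)
    if (length(rows) == 0) return(NULL)
    majority_vote(pr$pred[rows], pr$probs[rows, , drop = FALSE])
  })
  names(votes) <- eval_ids
  votes <- votes[!vapply(votes, is.null, logical(1))]
  list(clf = clf,
       window_preds = data.frame(
         participant = fs$meta$participant[ev_rows],
         start = fs$meta$start[ev_rows], mid = fs$meta$mid[ev_rows],
         context = fs$meta$context[ev_rows],
         pred = pr$pred, stringsAsFactors = FALSE),
       window_probs = pr$probs,
       votes = factor(unlist(lapply(votes, as.character)),
                      levels = RANGE_LEVELS))
}

#' Nested cross-validation for one trait
#'
#' For each outer fold, every candidate (window size, feature subset) is
#' trained on the training block and scored by participant-level macro F1 on
#' the validation block; the best candidate (ties towards the larger window,
#' then the larger subset) is retrained on the union of training and
#' validation participants and applied to the test block. Concatenated test
#' predictions -- one per participant -- form the result.
#'
#' @param featsets Named list of cohort `window_features` per window size
#'   (see [build_feature_sets()]).
#' @param assignment Named factor participant -> range (from
#'   [tertile_bins()]).
#' @param spec A [forest_spec()].
#' @param candidates A [candidate_grid()]; defaults to all available sizes
#'   crossed with all 9 subsets.
#' @param seed Integer seed for this repetition.
#' @param block_size Outer-fold block size.
#' @return A list of class `prediction_set`: `predictions` (named factor),
#'   `window_preds` (per-window test predictions with probabilities),
#'   `selections` (chosen candidate per fold), `models` (final per-fold
#'   classifiers), `folds`.
#' @export
nested_cross_validation <- function(featsets, assignment,
                                    spec = forest_spec(),
                                    candidates = NULL, seed = 1,
                                    block_size = 5) {
  participants <- names(assignment)
  if (is.null(candidates)) {
    candidates <- candidate_grid(as.numeric(names(featsets)))
  }
  if (nrow(candidates) == 0) stop("candidate grid is empty", call. = FALSE)
  missing_sizes <- setdiff(as.character(unique(candidates$size)),
                           names(featsets))
  if (length(missing_sizes) > 0) {
    stop("no feature set for window size(s): ",
         paste(missing_sizes, collapse = ", "), call. = FALSE)
  }
  subsets <- feature_subsets()
  folds <- outer_folds(participants, block_size)
  seeds <- matrix(derive_seeds(seed, length(folds) * (nrow(candidates) + 1L)),
                  nrow = length(folds))
  all_preds <- list(); all_windows <- list(); all_probs <- list()
  selections <- list(); models <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    val_f1 <- numeric(nrow(candidates))
    for (ci in seq_len(nrow(candidates))) {
      fs <- featsets[[as.character(candidates$size[ci])]]
      cols <- subsets[[candidates$subset[ci]]]
      sp <- spec; sp$seed <- seeds[f, ci]
      res <- fit_and_predict(fs, cols, fold$train, fold$validation,
                             assignment, sp)
      val_f1[ci] <- macro_f1(res$votes,
                             assignment[names(res$votes)])
    }
    # best candidate; ties -> larger window, then larger subset, then first
    subset_len <- lengths(subsets)[candidates$subset]
    ord <- order(-val_f1, -candidates$size, -subset_len)
    best <- ord[1]
    fs <- featsets[[as.character(candidates$size[best])]]
    cols <- subsets[[candidates$subset[best]]]
    sp <- spec; sp$seed <- seeds[f, nrow(candidates) + 1L]
    res <- fit_and_predict(fs, cols, c(fold$train, fold$validation),
                           fold$test, assignment, sp)
    all_preds[[f]] <- res$votes
    wp <- res$window_preds
    wp$fold <- f
    wp$size <- candidates$size[best]
    wp$subset <- candidates$subset[best]
    all_windows[[f]] <- wp
    all_probs[[f]] <- res$window_probs
    selections[[f]] <- data.frame(fold = f, size = candidates$size[best],
                                  subset = candidates$subset[best],
                                  val_f1 = val_f1[best],
                                  stringsAsFactors = FALSE)
    models[[f]] <- res$clf
  }
  predictions <- factor(unlist(lapply(all_preds, as.character)),
                        levels = RANGE_LEVELS)
  names(predictions) <- unlist(lapply(all_preds, names))
  window_preds <- do.call(rbind, all_windows)
  window_probs <- do.call(rbind, all_probs)
  colnames(window_probs) <- paste0("p_", RANGE_LEVELS)
  structure(list(predictions = predictions,
                 window_preds = cbind(window_preds,
                                      as.data.frame(window_probs)),
                 selections = do.call(rbind, selections),
                 models = models, folds = folds, seed = seed),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d participants over %d folds\n",
              length(x$predictions), length(x$folds)))
  print(table(x$predictions))
  invisible(x)
}

#' Aggregate impurity-based feature importances across models
#'
#' Each model's importance is the mean impurity decrease across its trees,
#' normalised to sum 1; features outside the model's subset, or never used
#' in a split, have importance 0. The summary reports the median, IQR,
#' minimum and maximum across models, sorted by median.
#'
#' @param models List of [fit_trait_classifier()] results.
#' @return A list of class `importance_table`: `per_model` (models x 207
#'   matrix) and `summary` (sorted data frame).
#' @export
feature_importances <- function(models) {
  if (length(models) == 0) stop("need at least one model", call. = FALSE)
  nms <- as.character(feature_names())
  seen <- unique(unlist(lapply(models, function(m) m$features)))
  nms <- c(nms[nms %in% seen | length(setdiff(seen, nms)) == 0],
           setdiff(seen, nms))
  per_model <- matrix(0, nrow = length(models), ncol = length(nms),
                      dimnames = list(NULL, nms))
  for (i in seq_along(models)) {
    imp <- models[[i]]$fit$variable.importance
    imp[imp < 0] <- 0
    if (sum(imp) > 0) imp <- imp / sum(imp)
    per_model[i, names(imp)] <- imp
  }
  summary_df <- data.frame(
    feature = nms,
    median = apply(per_model, 2, stats::median),
    iqr = apply(per_model, 2, stats::IQR),
    min = apply(per_model, 2, min),
    max = apply(per_model, 2, max))
  summary_df <- summary_df[order(-summary_df$median, summary_df$feature), ]
  rownames(summary_df) <- NULL
  structure(list(per_model = per_model, summary = summary_df),
            class = "importance_table")
}
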