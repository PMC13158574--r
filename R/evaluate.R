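#' Classification metrics from a confusion matrix
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`, `accuracy = (TP+TN)/total`; a zero denominator yields
#' the metric 0 with a `degenerate` flag.
#'
#' @param TP,FP,FN,TN Non-negative confusion counts (positive class =
#'   impaired).
#' @return An `eval_result` list with `accuracy`, `precision`, `recall`,
#'   `f1`, `confusion` and `degenerate`.
#' @export
#' @examples
#' metrics_from_confusion(20, 1, 4, 23)$f1   # rounds to 0.89
metrics_from_confusion <- function(TP, FP, FN, TN) {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(counts < 0)) stop("negative confusion counts")
  total <- sum(counts)
  if (total == 0) stop("all confusion counts are zero")
  degenerate <- FALSE
  div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; return(0) }
    num / den
  }
  precision <- div(TP, TP + FP)
  recall <- div(TP, TP + FN)
  f1 <- if (precision + recall == 0) { degenerate <- TRUE; 0 }
        else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = (TP + TN) / total, precision = precision,
                 recall = recall, f1 = f1, confusion = counts,
                 degenerate = degenerate),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("acc %.3f  prec %.3f  rec %.3f  F1 %.3f  (TP %d FP %d FN %d TN %d)\n",
              x$accuracy, x$precision, x$recall, x$f1,
              x$confusion["TP"], x$confusion["FP"], x$confusion["FN"],
              x$confusion["TN"]))
  invisible(x)
}

eval_from_predictions <- function(pred, truth) {
  metrics_from_confusion(TP = sum(pred == 1 & truth == 1),
                         FP = sum(pred == 1 & truth == 0),
                         FN = sum(pred == 0 & truth == 1),
                         TN = sum(pred == 0 & truth == 0))
}

#' Fit a model on a train matrix and evaluate on a test matrix
#'
#' @param spec A [model_spec()].
#' @param train,test Labeled `adspeech_fm`s sharing feature names.
#' @return An `eval_result` with `model` and `n_features_used` attached.
#' @export
fit_predict <- function(spec, train, test) {
  if (!setequal(train$feature_names, test$feature_names))
    stop("train and test feature names differ")
  model <- train_model(spec, train)
  prob <- predict_prob(model, test)
  res <- eval_from_predictions(as.integer(prob >= 0.5),
                               binary_labels(test$labels))
  res$model <- spec
  res$n_features_used <- length(train$feature_names)
  res
}

# column subset of a feature matrix
fm_subset <- function(fm, features) {
  feature_matrix(fm$values[, features, drop = FALSE], fm$row_ids, features,
                 fm$labels)
}

#' Incremental top-k feature sweep
#'
#' For each `k` in the grid, every model is fitted on the `k` top-ranked
#' features and evaluated on the test set; the maximizing `(k, model)` pair
#' (by F1) is recorded. The default grid is `1..64` then geometric thinning
#' (factor 1.5) up to the full feature count. Selecting the argmax on the
#' test curve mirrors the common challenge protocol; it is optimistic, and a
#' held-out protocol should be preferred for unbiased estimates.
#'
#' @param ranking A ranking data.frame from [rank_features()] (or a
#'   character vector of feature names, best first).
#' @param models List of [model_spec()]s.
#' @param train,test Labeled `adspeech_fm`s.
#' @param k_grid Integer vector of feature counts (default as above).
#' @return A `sweep_curve` data.frame (one row per `(k, model)`) with
#'   attribute `best`.
#' @export
incremental_sweep <- function(ranking, models, train, test, k_grid = NULL) {
  feats <- if (is.data.frame(ranking)) ranking$feature else ranking
  feats <- intersect(feats, train$feature_names)
  n <- length(feats)
  if (is.null(k_grid)) k_grid <- default_k_grid(n)
  if (length(k_grid) == 0L) stop("empty k grid")
  k_grid <- sort(unique(pmin(k_grid, n)))

  rows <- list()
  best <- NULL
  for (k in k_grid) {
    tr_k <- fm_subset(train, feats[seq_len(k)])
    te_k <- fm_subset(test, feats[seq_len(k)])
    for (mn in names(models)) {
      res <- fit_predict(models[[mn]], tr_k, te_k)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, model = mn, accuracy = res$accuracy,
        precision = res$precision, recall = res$recall, f1 = res$f1,
        stringsAsFactors = FALSE)
      if (is.null(best) || res$f1 > best$f1)
        best <- list(k = k, model = mn, f1 = res$f1, result = res)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_curve", class(out))
  attr(out, "best") <- best
  out
}

default_k_grid <- function(n) {
  small <- seq_len(min(64L, n))
  if (n <= 64L) return(small)
  k <- 64
  geo <- integer(0)
  while (k < n) {
    k <- ceiling(k * 1.5)
    geo <- c(geo, min(k, n))
  }
  unique(c(small, geo))
}

#' Voting and stacking ensembles
#'
#' `hard`: majority vote of member class predictions, ties to the positive
#' class (screening favors sensitivity). `soft`: argmax of the mean
#' predicted probability. `stacking`: an AdaBoost meta-learner trained on
#' out-of-fold (5-fold, seeded) member probabilities from the train set,
#' applied to member probabilities on the test set.
#'
#' @param members Named list of [model_spec()]s (default SVM, RF, AB, LR,
#'   XG).
#' @param mode `"hard"`, `"soft"` or `"stacking"`.
#' @param train,test Labeled `adspeech_fm`s.
#' @param seed Seed for fold assignment.
#' @return An `eval_result`.
#' @export
ensemble_predict <- function(members = model_zoo(c("SVM", "RF", "AB", "LR",
                                                   "XG")),
                             mode = c("hard", "soft", "stacking"),
                             train, test, seed = 1L) {
  mode <- match.arg(mode)
  if (length(members) < 2L) stop("need at least 2 ensemble members")
  y_tr <- binary_labels(train$labels)
  y_te <- binary_labels(test$labels)

  fits <- lapply(members, train_model, train = train)
  test_probs <- vapply(fits, predict_prob, numeric(length(y_te)), fm = test)

  if (mode == "hard") {
    votes <- rowMeans(test_probs >= 0.5)
    pred <- as.integer(votes >= 0.5)         # ties (0.5) go positive
  } else if (mode == "soft") {
    pred <- as.integer(rowMeans(test_probs) >= 0.5)
  } else {
    oof <- matrix(NA_real_, nrow(train$values), length(members))
    set.seed(seed)
    folds <- sample(rep(seq_len(5L), length.out = length(y_tr)))
    for (f in seq_len(5L)) {
      tr_idx <- which(folds != f); te_idx <- which(folds == f)
      if (length(te_idx) == 0L || length(unique(y_tr[tr_idx])) < 2L) next
      tr_f <- feature_matrix(train$values[tr_idx, , drop = FALSE],
                             train$row_ids[tr_idx], train$feature_names,
                             train$labels[tr_idx])
      te_f <- fm_subset(feature_matrix(train$values[te_idx, , drop = FALSE],
                                       train$row_ids[te_idx],
                                       train$feature_names,
                                       train$labels[te_idx]),
                        train$feature_names)
      for (m in seq_along(members)) {
        fit_f <- train_model(members[[m]], tr_f)
        oof[te_idx, m] <- predict_prob(fit_f, te_f)
      }
    }
    keep <- stats::complete.cases(oof)
    meta <- adaboost_fit(oof[keep, , drop = FALSE], y_tr[keep], 100L)
    pred <- as.integer(adaboost_prob(meta, test_probs) >= 0.5)
  }
  res <- eval_from_predictions(pred, y_te)
  res$n_features_used <- length(train$feature_names)
  res$model <- paste0("ensemble_", mode)
  res
}

#' Train-on-A / test-on-B cross-corpus evaluation
#'
#' Restricts both corpora to the intersection of their feature names, fits
#' on corpus A (imputation and scaling statistics from A only) and
#' evaluates on corpus B.
#'
#' @param spec A [model_spec()] (or list for an ensemble via `mode`).
#' @param corpusA,corpusB Labeled `adspeech_fm`s.
#' @param mode `NULL` for a single model, else an ensemble mode.
#' @return An `eval_result`.
#' @export
cross_corpus_eval <- function(spec, corpusA, corpusB, mode = NULL) {
  shared <- intersect(corpusA$feature_names, corpusB$feature_names)
  if (length(shared) == 0L) stop("no shared features between corpora")
  trA <- fm_subset(corpusA, shared)
  teB <- fm_subset(corpusB, shared)
  if (is.null(mode)) fit_predict(spec, trA, teB)
  else ensemble_predict(spec, mode, trA, teB)
}

#' Permutation feature importance
#'
#' Model-agnostic importance: the mean drop in test F1 when one feature's
#' test column is randomly permuted, over `n_repeats` seeded permutations,
#' with its standard deviation.
#'
#' @param model An `adspeech_model` from [train_model()].
#' @param test A labeled `adspeech_fm`.
#' @param n_repeats Permutations per feature.
#' @param seed RNG seed.
#' @return data.frame `feature`, `importance`, `sd`, sorted descending.
#' @export
permutation_importance <- function(model, test, n_repeats = 20L, seed = 1L) {
  y <- binary_labels(test$labels)
  base <- eval_from_predictions(
    as.integer(predict_prob(model, test) >= 0.5), y)$f1
  set.seed(seed)
  X <- test$values[, model$feature_names, drop = FALSE]
  imp <- vapply(seq_along(model$feature_names), function(j) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
      fmp <- feature_matrix(Xp, test$row_ids, model$feature_names,
                            test$labels)
      base - eval_from_predictions(
        as.integer(predict_prob(model, fmp) >= 0.5), y)$f1
    }, numeric(1))
    c(mean(drops), stats::sd(drops))
  }, numeric(2))
  out <- data.frame(feature = model$feature_names, importance = imp[1, ],
                    sd = imp[2, ], stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature), ]
}
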