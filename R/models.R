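#' Classifier specifications
#'
#' The model zoo: SVM (radial, e1071), LR (logistic regression), LD (linear
#' discriminant), AB (AdaBoost.M1 over depth-1 trees, 100 estimators),
#' Bagging (100 bootstrap trees), RF (random forest, depth limited to 2 via
#' `maxnodes = 4`), XG (gradient boosting: `eta = 0.001`,
#' `nrounds = 5600`, `max_depth = 5`, `min_child_weight = 1`, `gamma = 0`,
#' `subsample = 0.8`, `colsample_bytree = 0.9`, binary-logistic objective)
#' and MLP (single hidden layer of 50 units, 200 iterations, weight decay
#' 1e-8).
#'
#' @param name One of `"SVM"`, `"LR"`, `"LD"`, `"AB"`, `"Bagging"`, `"RF"`,
#'   `"XG"`, `"MLP"`.
#' @param params Named list overriding the defaults above.
#' @param seed Integer seed used at fit time.
#' @return A `model_spec`.
#' @export
model_spec <- function(name = c("SVM", "LR", "LD", "AB", "Bagging", "RF",
                                "XG", "MLP"),
                       params = list(), seed = 25L) {
  name <- match.arg(name)
  defaults <- switch(name,
    SVM = list(kernel = "radial", cost = 1),
    LR = list(),
    LD = list(),
    AB = list(n_estimators = 100L),
    Bagging = list(n_estimators = 100L),
    RF = list(ntree = 500L, maxnodes = 4L),
    XG = list(eta = 0.001, nrounds = 5600L, max_depth = 5L,
              min_child_weight = 1, gamma = 0, subsample = 0.8,
              colsample_bytree = 0.9),
    MLP = list(size = 50L, maxit = 200L, decay = 1e-8))
  defaults[names(params)] <- params
  structure(list(name = name, params = defaults, seed = as.integer(seed)),
            class = "model_spec")
}

#' @rdname model_spec
#' @param names Model names to instantiate.
#' @return `model_zoo()`: named list of `model_spec`s.
#' @export
model_zoo <- function(names = c("SVM", "LR", "LD", "AB", "Bagging", "RF",
                                "XG", "MLP"), seed = 25L) {
  stats::setNames(lapply(names, model_spec, seed = seed), names)
}

# train-set preprocessing statistics: median imputation + z-scoring
preprocess_fit <- function(X) {
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  Xi <- X
  for (j in seq_len(ncol(Xi))) Xi[!is.finite(Xi[, j]), j] <- med[j]
  mu <- colMeans(Xi)
  sdv <- apply(Xi, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(median = med, mu = mu, sd = sdv)
}

preprocess_apply <- function(X, prep) {
  for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- prep$median[j]
  sweep(sweep(X, 2, prep$mu), 2, prep$sd, `/`)
}

#' Train one classifier on a labeled feature matrix
#'
#' Features are median-imputed and z-scored with train statistics; the
#' fitted pipeline carries those statistics so test data never leak into
#' them.
#'
#' @param spec A [model_spec()].
#' @param train A labeled `adspeech_fm`.
#' @return An `adspeech_model` (use [predict_prob()] on new data).
#' @export
train_model <- function(spec, train) {
  y <- binary_labels(train$labels)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  prep <- preprocess_fit(train$values)
  X <- preprocess_apply(train$values, prep)
  set.seed(spec$seed)
  fit <- fit_backend(spec, X, y)
  structure(list(spec = spec, prep = prep, fit = fit,
                 feature_names = train$feature_names),
            class = "adspeech_model")
}

#' Positive-class probabilities of a fitted model
#'
#' @param model An `adspeech_model`.
#' @param fm An `adspeech_fm` with the same feature names.
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict_prob <- function(model, fm) {
  if (!setequal(fm$feature_names, model$feature_names))
    stop("feature names of test data do not match the fitted model")
  X <- fm$values[, model$feature_names, drop = FALSE]
  X <- preprocess_apply(X, model$prep)
  p <- predict_backend(model$spec, model$fit, X)
  pmin(pmax(as.numeric(p), 0), 1)
}

fit_backend <- function(spec, X, y) {
  p <- spec$params
  switch(spec$name,
    SVM = suppressWarnings(
      e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                 kernel = p$kernel, cost = p$cost, probability = TRUE)),
    LR = suppressWarnings(
      stats::glm.fit(cbind(1, X), y, family = stats::binomial())$coefficients),
    LD = {
      keep <- apply(X, 2, function(col)
        all(tapply(col, y, stats::sd) > 1e-9))
      keep[is.na(keep)] <- FALSE
      if (!any(keep)) keep[1] <- TRUE
      list(keep = which(keep),
           fit = suppressWarnings(
             MASS::lda(X[, keep, drop = FALSE], grouping = factor(y))))
    },
    AB = adaboost_fit(X, y, p$n_estimators),
    Bagging = bagging_fit(X, y, p$n_estimators),
    RF = randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                    ntree = p$ntree, maxnodes = p$maxnodes),
    XG = xgboost::xgb.train(
      params = list(eta = p$eta, max_depth = p$max_depth,
                    min_child_weight = p$min_child_weight, gamma = p$gamma,
                    subsample = p$subsample,
                    colsample_bytree = p$colsample_bytree,
                    objective = "binary:logistic", nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = p$nrounds,
      verbose = 0),
    MLP = nnet_fit(X, y, p))
}

predict_backend <- function(spec, fit, X) {
  switch(spec$name,
    SVM = {
      pr <- stats::predict(fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    LR = {
      beta <- fit
      beta[!is.finite(beta)] <- 0
      stats::plogis(as.numeric(cbind(1, X) %*% beta))
    },
    LD = as.numeric(stats::predict(fit$fit,
                                   X[, fit$keep, drop = FALSE])$posterior[, "1"]),
    AB = adaboost_prob(fit, X),
    Bagging = bagging_prob(fit, X),
    RF = stats::predict(fit, X, type = "prob")[, "1"],
    XG = stats::predict(fit, xgboost::xgb.DMatrix(X)),
    MLP = as.numeric(stats::predict(fit, X)))
}

nnet_fit <- function(X, y, p) {
  utils::capture.output(
    fit <- nnet::nnet(X, y, size = p$size, maxit = p$maxit, decay = p$decay,
                      trace = FALSE, MaxNWts = 1e6, entropy = TRUE))
  fit
}

# ---- AdaBoost.M1 over depth-1 trees --------------------------------------

adaboost_fit <- function(X, y, n_estimators = 100L) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$.y <- factor(y, levels = c(0, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = 0, minsplit = 2,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != df$.y)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != df$.y, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas, p = ncol(X))
}

adaboost_margin <- function(fit, X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  f <- numeric(nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- stats::predict(fit$stumps[[m]], df, type = "class")
    f <- f + fit$alphas[m] * ifelse(pred == "1", 1, -1)
  }
  if (length(fit$alphas)) f / sum(fit$alphas) else f
}

adaboost_prob <- function(fit, X) stats::plogis(4 * adaboost_margin(fit, X))

# ---- bootstrap-aggregated trees ------------------------------------------

bagging_fit <- function(X, y, n_estimators = 100L) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$.y <- factor(y, levels = c(0, 1))
  n <- nrow(df)
  ctrl <- rpart::rpart.control(cp = 0.01, xval = 0, maxcompete = 0,
                               maxsurrogate = 0)
  trees <- lapply(seq_len(n_estimators), function(m) {
    idx <- sample.int(n, n, replace = TRUE)
    rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "class",
                 control = ctrl)
  })
  list(trees = trees)
}

bagging_prob <- function(fit, X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  probs <- vapply(fit$trees, function(tr)
    stats::predict(tr, df, type = "prob")[, "1"], numeric(nrow(df)))
  rowMeans(as.matrix(probs))
}
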