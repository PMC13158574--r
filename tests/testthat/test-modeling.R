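test_that("confusion metrics are internally consistent", {
  r <- metrics_from_confusion(20, 1, 4, 23)
  expect_equal(r$precision, 20 / 21)
  expect_equal(r$recall, 20 / 24)
  expect_equal(r$accuracy, 43 / 48)
  expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall),
               tolerance = 1e-12)

  perfect <- metrics_from_confusion(10, 0, 0, 10)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  deg <- metrics_from_confusion(0, 0, 5, 5)
  expect_true(deg$degenerate)
  expect_equal(deg$f1, 0)
  expect_error(metrics_from_confusion(0, 0, 0, 0), "zero")
  expect_error(metrics_from_confusion(-1, 0, 0, 5), "negative")
})

test_that("every model separates a strong two-Gaussian corpus", {
  sp <- split_fm(gauss_fm(n = 100, shift = 6), 70)
  for (m in c("SVM", "LR", "LD", "AB", "Bagging", "RF", "MLP")) {
    r <- fit_predict(model_spec(m), sp$train, sp$test)
    expect_gte(r$f1, 0.95, label = m)
    expect_equal(sum(r$confusion), nrow(sp$test$values))
  }
  r <- fit_predict(model_spec("XG", params = list(nrounds = 300L)),
                   sp$train, sp$test)
  expect_gte(r$f1, 0.95)
})

test_that("fits are deterministic under a fixed seed", {
  sp <- split_fm(gauss_fm(n = 60, shift = 2, seed = 19), 40)
  for (m in c("RF", "Bagging", "MLP")) {
    r1 <- fit_predict(model_spec(m, seed = 11), sp$train, sp$test)
    r2 <- fit_predict(model_spec(m, seed = 11), sp$train, sp$test)
    expect_identical(r1$confusion, r2$confusion, info = m)
  }
})

test_that("permuted labels score at chance", {
  set.seed(23)
  f1s <- vapply(1:20, function(s) {
    fm <- gauss_fm(n = 60, shift = 4, seed = s)
    set.seed(1000 + s)
    fm$labels <- sample(fm$labels)
    sp <- split_fm(fm, 40, seed = s)
    fit_predict(model_spec("LR"), sp$train, sp$test)$f1
  }, numeric(1))
  expect_lt(abs(mean(f1s) - 0.5), 0.12)
})

test_that("mismatched or degenerate inputs are rejected", {
  sp <- split_fm(gauss_fm(n = 40), 30)
  extra <- feature_matrix(cbind(sp$test$values, z = 1), sp$test$row_ids,
                          c(sp$test$feature_names, "z"), sp$test$labels)
  expect_error(fit_predict(model_spec("LR"), sp$train, extra), "differ")
  onecls <- feature_matrix(sp$train$values, sp$train$row_ids,
                           sp$train$feature_names,
                           rep("control", nrow(sp$train$values)))
  expect_error(fit_predict(model_spec("LR"), onecls, sp$test),
               "single class")
})

test_that("the incremental sweep reduces to the full fit at k = n", {
  sp <- split_fm(gauss_fm(n = 60, d = 8, shift = 3), 40)
  ranking <- rank_features(sp$train, method = "anova")
  models <- model_zoo(c("LR", "RF"))
  sw <- incremental_sweep(ranking, models, sp$train, sp$test,
                          k_grid = c(2, 4, 8))
  expect_identical(nrow(sw), 6L)            # one row per (k, model)
  full <- fit_predict(models$LR, sp$train, sp$test)
  expect_equal(sw$f1[sw$k == 8 & sw$model == "LR"], full$f1)
  expect_error(incremental_sweep(ranking, models, sp$train, sp$test,
                                 integer(0)), "empty")
})

test_that("noise features beyond the informative set do not lift the max", {
  fm <- gauss_fm(n = 80, d = 20, shift = 5, n_informative = 2, seed = 3)
  sp <- split_fm(fm, 56)
  ranking <- rank_features(sp$train, method = "anova")
  sw <- incremental_sweep(ranking, model_zoo("LR"), sp$train, sp$test,
                          k_grid = c(2, 5, 10, 20))
  best_small <- max(sw$f1[sw$k <= 2])
  expect_gte(best_small + 1e-9, max(sw$f1))
})

test_that("ensembles vote and stack correctly", {
  sp <- split_fm(gauss_fm(n = 80, shift = 5), 56)
  fast <- model_zoo(c("LR", "RF", "SVM"))
  # identical members equal any single member
  same <- list(a = model_spec("LR"), b = model_spec("LR"),
               c = model_spec("LR"))
  e <- ensemble_predict(same, "hard", sp$train, sp$test)
  single <- fit_predict(model_spec("LR"), sp$train, sp$test)
  expect_identical(e$confusion, single$confusion)

  singles <- vapply(fast, function(m)
    fit_predict(m, sp$train, sp$test)$f1, numeric(1))
  st <- ensemble_predict(fast, "stacking", sp$train, sp$test, seed = 2)
  expect_gte(st$f1, max(singles) - 0.05)
  soft <- ensemble_predict(fast, "soft", sp$train, sp$test)
  expect_gte(soft$f1, 0.9)
  expect_error(ensemble_predict(fast[1], "hard", sp$train, sp$test),
               "at least 2")
})

test_that("hard-vote ties break toward the positive class", {
  votes <- c(1, 1, 0, 0, 1)
  expect_identical(as.integer(mean(votes >= 0.5) >= 0.5), 1L)
  # two-member tie: one positive, one negative vote -> positive
  expect_identical(as.integer(mean(c(1, 0) >= 0.5) >= 0.5), 1L)
})

test_that("cross-corpus evaluation restricts to shared features", {
  spA <- split_fm(gauss_fm(n = 80, shift = 5, seed = 40), 56)
  r_self <- cross_corpus_eval(model_spec("LR"), spA$train, spA$test)
  r_direct <- fit_predict(model_spec("LR"), spA$train, spA$test)
  expect_identical(r_self$confusion, r_direct$confusion)

  weakB <- gauss_fm(n = 60, shift = 0.8, seed = 41, ids = "w")
  r_weak <- cross_corpus_eval(model_spec("LR"), spA$train, weakB)
  expect_lt(r_weak$f1, r_self$f1)

  disjoint <- feature_matrix(weakB$values, weakB$row_ids,
                             paste0("other", seq_len(10)), weakB$labels)
  expect_error(cross_corpus_eval(model_spec("LR"), spA$train, disjoint),
               "shared")
})

test_that("permutation importance isolates the informative feature", {
  sp <- split_fm(gauss_fm(n = 80, d = 6, shift = 5, seed = 13), 56)
  model <- train_model(model_spec("RF"), sp$train)
  imp <- permutation_importance(model, sp$test, n_repeats = 10, seed = 3)
  expect_identical(imp$feature[1], "f1")
  noise_rows <- imp[imp$feature != "f1", ]
  expect_true(all(abs(noise_rows$importance) <=
                    2 * pmax(noise_rows$sd, 0.02)))
  # invariant to feature column order
  shuf <- sample(sp$train$feature_names)
  model2 <- train_model(model_spec("RF"),
                        adspeech:::fm_subset(sp$train, shuf))
  imp2 <- permutation_importance(model2,
                                 adspeech:::fm_subset(sp$test, shuf),
                                 n_repeats = 10, seed = 3)
  expect_identical(imp2$feature[1], "f1")
})
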