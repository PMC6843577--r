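# The eight base learners: contracts, probability semantics, tuning.

test_that("learner specs validate algorithms and hyperparameters", {
  expect_error(learner_spec("deep_net"), class = "hepascreen_config_error")
  expect_error(learner_spec("svm_rbf", K = 3),
               class = "hepascreen_config_error")
  expect_error(learner_spec("svm_rbf", C = -1),
               class = "hepascreen_config_error")
  expect_error(learner_spec("decision_tree", Cf = 1.5),
               class = "hepascreen_config_error")
  expect_error(learner_spec("kstar", B = 150),
               class = "hepascreen_config_error")
  ok <- learner_spec("svm_rbf", C = 0.5, gamma = 0.125, seed = 9)
  expect_equal(ok$hyperparameters$C, 0.5)
  expect_equal(ok$hyperparameters$gamma, 0.125)
})

test_that("RBF SVM separates a linearly separable toy set perfectly", {
  toy <- separable_set(n = 20, p = 2, gap = 6, seed = 1)
  clf <- train(learner_spec("svm_rbf", seed = 1), toy$fm, toy$labels)
  pr <- predict_proba(clf, toy$fm)
  expect_equal(mean(pr$label == toy$labels), 1)
})

test_that("1-NN reproduces training labels on duplicate-free data", {
  toy <- separable_set(n = 30, p = 3, gap = 2, seed = 2)
  clf <- train(learner_spec("knn", K = 1, seed = 1), toy$fm, toy$labels)
  pr <- predict_proba(clf, toy$fm)
  expect_equal(mean(pr$label == toy$labels), 1)
})

test_that("the positive call requires probability strictly above threshold", {
  ids <- c("a", "b", "c")
  stub <- make_stub_bases(matrix(c(1, 0, 1), ncol = 1), ids,
                          family = "toy")[[1]]
  stub$outputs$probability <- c(0.51, 0.500, 0.4999)
  fm <- fm_from_matrix(matrix(0:2, ncol = 1,
                              dimnames = list(NULL, "f1")), ids = ids)
  pr <- predict_proba(stub, fm)
  expect_equal(pr$label,
               c("hepatotoxic", "non_hepatotoxic", "non_hepatotoxic"))
})

test_that("every learner emits valid complementary probabilities and is deterministic", {
  gen <- make_classification_set(synth_spec(
    n = 60, p_informative = 3, p_noise = 3, effect_size = 1.5, seed = 8))
  for (alg in c("naive_bayes", "svm_rbf", "knn", "kstar", "adaboost_tree",
                "bagging_knn", "decision_tree", "random_forest")) {
    spec <- learner_spec(alg, seed = 4)
    p1 <- predict_proba(train(spec, gen$features, gen$labels), gen$features)
    p2 <- predict_proba(train(spec, gen$features, gen$labels), gen$features)
    expect_true(all(p1$probability >= 0 & p1$probability <= 1), info = alg)
    expect_identical(p1$probability, p2$probability, info = alg)
    # P(pos) + P(neg) = 1 by construction of the probability scale:
    # label decisions must be consistent with the single positive score
    expect_equal(p1$label == "hepatotoxic", p1$probability > 0.5,
                 info = alg)
  }
  expect_error(train(learner_spec("knn"), gen$features, rep("pos", 60)),
               class = "hepascreen_data_error")
})

test_that("single-round boosting equals its base tree", {
  gen <- make_classification_set(synth_spec(
    n = 80, p_informative = 2, p_noise = 4, effect_size = 1.5, seed = 3))
  boost1 <- train(learner_spec("adaboost_tree", n_rounds = 1, Cf = 0.25,
                               seed = 6), gen$features, gen$labels)
  tree <- train(learner_spec("decision_tree", Cf = 0.25, seed = 6),
                gen$features, gen$labels)
  expect_equal(predict_proba(boost1, gen$features)$label,
               predict_proba(tree, gen$features)$label)
})

test_that("unlimited forest depth fits training data at least as well as a cap", {
  gen <- make_classification_set(synth_spec(
    n = 100, p_informative = 4, p_noise = 4, effect_size = 1.2, seed = 9))
  acc <- function(depth) {
    clf <- train(learner_spec("random_forest", Depth = depth,
                              num_trees = 100, seed = 2),
                 gen$features, gen$labels)
    mean(predict_proba(clf, gen$features)$label == gen$labels)
  }
  expect_gte(acc(0), acc(2))
})

test_that("prediction fails informatively when feature columns are missing", {
  toy <- separable_set(n = 20, p = 3, seed = 5)
  clf <- train(learner_spec("decision_tree", seed = 1), toy$fm, toy$labels)
  short <- fm_select(toy$fm, c("f1", "f2"))
  expect_error(predict_proba(clf, short), "f3",
               class = "hepascreen_data_error")
})

test_that("grid tuning scores every cell and penalizes overfit K on noisy data", {
  # single-point grid returns that point
  toy <- separable_set(n = 40, p = 2, seed = 6)
  res <- tune(learner_spec("knn", seed = 1), toy$fm, toy$labels,
              grid = list(K = 3), k_folds = 5, seed = 2)
  expect_equal(res$best_spec$hyperparameters$K, 3)
  expect_equal(nrow(res$scores), 1)

  # duplicated clusters with label noise: K = 1 memorizes the noise
  noisy <- withr::with_seed(13, {
    base <- separable_set(n = 40, p = 2, gap = 3, seed = 13)
    x <- fm_values(base$fm)
    x2 <- rbind(x, x + rnorm(length(x), sd = 0.01))
    labs <- c(base$labels, base$labels)
    flip <- sample(length(labs), round(0.15 * length(labs)))
    labs[flip] <- ifelse(labs[flip] == "hepatotoxic",
                         "non_hepatotoxic", "hepatotoxic")
    list(fm = fm_from_matrix(x2, ids = sprintf("n%02d", seq_len(nrow(x2)))),
         labels = labs)
  })
  res2 <- tune(learner_spec("knn", seed = 1), noisy$fm, noisy$labels,
               grid = list(K = c(1, 3, 5)), k_folds = 5, seed = 3)
  expect_gt(res2$best_spec$hyperparameters$K, 1)
  expect_equal(nrow(res2$scores), 3)

  # the winning cell is the argmax of the returned score table
  expect_equal(res2$scores$K[which.max(res2$scores$score)],
               res2$best_spec$hyperparameters$K)
})

test_that("an SVM grid includes the published best cell in its score table", {
  toy <- separable_set(n = 40, p = 2, seed = 7)
  grid <- list(C = c(0.5, 1), gamma = c(0.125, 0.5))
  res <- tune(learner_spec("svm_rbf", seed = 1), toy$fm, toy$labels,
              grid = grid, k_folds = 5, seed = 4)
  expect_true(any(res$scores$C == 0.5 & res$scores$gamma == 0.125))
  expect_equal(nrow(res$scores), 4)
})
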