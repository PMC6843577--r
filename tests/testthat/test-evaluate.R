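# Metrics arithmetic, ROC/AUC, cross-validation structure, Y-randomization,
# external evaluation.

test_that("confusion-matrix metrics follow the published definitions", {
  m <- compute_metrics(confusion_matrix(TP = 3, TN = 4, FP = 2, FN = 1))
  expect_equal(round_half_up(m$acc, 3), 70.000)
  expect_equal(round_half_up(m$se, 3), 0.750)
  expect_equal(round_half_up(m$sp, 3), 0.667)
  expect_equal(round_half_up(m$bacc, 3), 0.708)
  expect_equal(m$bacc, (m$se + m$sp) / 2)

  perfect <- compute_metrics(confusion_matrix(TP = 10, TN = 10))
  expect_equal(perfect$acc, 100)
  expect_equal(c(perfect$se, perfect$sp, perfect$bacc), c(1, 1, 1))

  expect_error(compute_metrics(confusion_matrix(TP = 0, TN = 5, FN = 0)),
               "positive", class = "hepascreen_data_error")
})

test_that("balanced accuracy rounds half away from zero for display", {
  expect_equal(bacc(0.725, 0.720), 0.723)   # 0.7225 -> 0.723, not 0.722
  expect_equal(bacc(0.813, 0.750), 0.782)   # 0.7815 -> 0.782
  expect_equal(bacc(0.732, 0.724), 0.728)
  expect_equal(bacc(0.725, 0.720, digits = NULL), 0.7225)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-0.0005, 3), -0.001)
})

test_that("AUC matches the rank statistic with half-weighted ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("pos", "pos", "neg", "neg"))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c("pos", "pos", "pos",
                                      "neg", "neg", "neg"))$auc, 0.5)
  # pos {0.9, 0.4}, neg {0.6, 0.1}: 3 of 4 pairs concordant
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1),
                       c("pos", "pos", "neg", "neg"))$auc, 0.75)
  expect_error(roc_auc(c(0.1, 0.9), c("pos", "pos")),
               class = "hepascreen_data_error")
})

test_that("AUC is invariant under strictly increasing transforms and
           matches an independent implementation", {
  for (seed in 1:5) {
    dat <- withr::with_seed(seed, list(
      scores = runif(40),
      labels = sample(c("pos", "neg"), 40, replace = TRUE,
                      prob = c(0.5, 0.5))))
    if (length(unique(dat$labels)) < 2) next
    a1 <- roc_auc(dat$scores, dat$labels)$auc
    expect_equal(roc_auc(qlogis(dat$scores), dat$labels)$auc, a1)
    expect_equal(roc_auc(dat$scores^3, dat$labels)$auc, a1)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = dat$labels, predictor = dat$scores,
      levels = c("neg", "pos"), direction = "<", quiet = TRUE)))
    expect_equal(a1, ref, tolerance = 1e-12)
  }
})

test_that("cross-validation predicts each compound exactly once", {
  toy <- separable_set(n = 50, p = 3, gap = 5, seed = 4)
  cv <- cross_validate(single_recipe(learner_spec("knn", K = 3, seed = 1),
                                     "toy"),
                       toy$fm, toy$labels, k = 5, seed = 7)
  expect_equal(nrow(cv$predictions), 50)
  expect_equal(sort(unique(cv$predictions$fold)), 1:5)
  expect_equal(anyDuplicated(cv$predictions$compound_id), 0)
  expect_equal(cv$metrics$cm$N, 50)       # pooled cells sum to n
  expect_equal(cv$metrics$acc, 100)       # separable fixture
  expect_error(cross_validate(single_recipe(learner_spec("knn"), "toy"),
                              toy$fm, toy$labels, k = 30),
               class = "hepascreen_data_error")
})

test_that("Y-randomization sits at chance on balanced data and preserves counts", {
  gen <- make_classification_set(synth_spec(
    n = 60, p_informative = 3, p_noise = 3, effect_size = 1.5,
    class_balance = 0.5, seed = 6))
  yr <- y_randomization(single_recipe(learner_spec("naive_bayes", seed = 1),
                                      "synthetic"),
                        gen$features, gen$labels, runs = 20, k = 5, seed = 3)
  expect_length(yr$acc, 20)
  expect_lt(abs(yr$mean - 50), 3 * yr$sd / sqrt(yr$runs) + 5)
  expect_equal(yr$mean, mean(yr$acc))
  # the real signal survives: true-label CV beats the permuted mean
  cv <- cross_validate(single_recipe(learner_spec("naive_bayes", seed = 1),
                                     "synthetic"),
                       gen$features, gen$labels, k = 5, seed = 3)
  expect_gt(cv$metrics$acc, yr$mean + 3 * yr$sd)
})

test_that("external evaluation reports an all-positive degenerate model honestly", {
  ids <- sprintf("e%d", 1:8)
  stub <- make_stub_bases(matrix(1, 8, 1), ids, family = "toy")[[1]]
  stub$train_ids <- character(0)  # external set is genuinely unseen
  fm <- fm_from_matrix(matrix(rnorm(8), ncol = 1,
                              dimnames = list(NULL, "f1")),
                       ids = ids, family = "toy")
  labels <- rep(c("pos", "neg"), each = 4)
  res <- evaluate_external(stub, fm, labels)
  expect_equal(res$metrics$acc, 50)
  expect_equal(res$metrics$se, 1)
  expect_equal(res$metrics$sp, 0)
  expect_equal(res$metrics$bacc, (res$metrics$se + res$metrics$sp) / 2)
  expect_equal(nrow(res$predictions), 8)
})

test_that("training/external overlap is flagged and escalates in strict mode", {
  toy <- separable_set(n = 20, p = 2, gap = 5, seed = 8)
  clf <- train(learner_spec("decision_tree", seed = 1), toy$fm, toy$labels)
  expect_warning(evaluate_external(clf, toy$fm, toy$labels), "overlap")
  expect_error(evaluate_external(clf, toy$fm, toy$labels, strict = TRUE),
               class = "hepascreen_data_error")
})
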