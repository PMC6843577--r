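# Stacked combined classifier and its Bernoulli Naive Bayes meta-learner.

stub_setup <- function(truth, labels, family = "toy") {
  ids <- sprintf("m%02d", seq_len(nrow(truth)))
  fm <- fm_from_matrix(matrix(rnorm(nrow(truth)), ncol = 1,
                              dimnames = list(NULL, "f1")),
                       ids = ids, family = family)
  list(bases = make_stub_bases(truth, ids, family = family),
       fms = setNames(list(fm), family), labels = labels, ids = ids)
}

test_that("meta features replay the stub truth table exactly", {
  truth <- matrix(c(1, 1, 0, 0,
                    1, 0, 1, 0,
                    1, 1, 1, 1), ncol = 3)
  s <- stub_setup(truth, c("pos", "pos", "neg", "neg"))
  meta <- build_meta_features(s$bases, s$fms)
  expect_equal(unname(meta), truth)
  expect_equal(dim(meta), c(4, 3))
  expect_true(all(meta %in% c(0, 1)))
  # a compound all bases call positive gets an all-ones row
  expect_equal(unname(meta[4, ]), c(0, 0, 1))
  expect_equal(unname(meta[1, ]), c(1, 1, 1))
})

test_that("mismatched compound ids across families are rejected", {
  fm1 <- fm_from_matrix(matrix(1:3, ncol = 1, dimnames = list(NULL, "a")),
                        ids = c("x", "y", "z"), family = "A")
  fm2 <- fm_from_matrix(matrix(1:3, ncol = 1, dimnames = list(NULL, "a")),
                        ids = c("x", "z", "y"), family = "B")
  expect_error(cross_validate(single_recipe(learner_spec("knn"), "A"),
                              list(A = fm1, B = fm2), c(1, 0, 1), k = 2),
               class = "hepascreen_data_error")
})

test_that("bases that reproduce the labels give a perfect stack", {
  labels <- rep(c("hepatotoxic", "non_hepatotoxic"), each = 10)
  truth <- matrix(rep(as.numeric(labels == "hepatotoxic"), 3), ncol = 3)
  s <- stub_setup(truth, labels)
  st <- fit_stacked(s$bases, s$fms, s$labels)
  pr <- predict_stacked(st, s$fms)
  expect_equal(mean(pr$label == labels), 1)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
})

test_that("meta posteriors match hand-computed smoothed Bernoulli NB", {
  labels <- c("pos", "pos", "pos", "neg", "neg", "neg", "neg", "pos")
  truth <- matrix(c(1, 1, 0, 0, 0, 1, 0, 1,
                    1, 0, 1, 0, 1, 0, 0, 1,
                    0, 1, 1, 1, 0, 0, 0, 1), ncol = 3)
  s <- stub_setup(truth, labels)
  st <- fit_stacked(s$bases, s$fms, s$labels)
  got <- predict_stacked(st, s$fms)$probability

  # independent closed-form computation: priors n_c/n, Laplace(+1)
  # likelihoods (count + 1)/(n_c + 2)
  pos <- labels == "pos"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  th_pos <- (colSums(truth[pos, ]) + 1) / (n_pos + 2)
  th_neg <- (colSums(truth[!pos, ]) + 1) / (n_neg + 2)
  expected <- vapply(seq_len(nrow(truth)), function(i) {
    x <- truth[i, ]
    lp <- prod(th_pos^x * (1 - th_pos)^(1 - x)) * n_pos / length(labels)
    ln <- prod(th_neg^x * (1 - th_neg)^(1 - x)) * n_neg / length(labels)
    lp / (lp + ln)
  }, numeric(1))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("permuting base order leaves stacked predictions unchanged", {
  labels <- rep(c("pos", "neg"), each = 8)
  truth <- withr::with_seed(21, matrix(rbinom(16 * 4, 1, 0.5), ncol = 4))
  s <- stub_setup(truth, labels)
  st1 <- fit_stacked(s$bases, s$fms, s$labels)
  perm <- c(3, 1, 4, 2)
  st2 <- fit_stacked(s$bases[perm], s$fms, s$labels)
  expect_equal(predict_stacked(st1, s$fms)$probability,
               predict_stacked(st2, s$fms)$probability)
})

test_that("the meta-learner discounts a label-inverted base", {
  labels <- rep(c("pos", "neg"), each = 20)
  y <- as.numeric(labels == "pos")
  truth <- cbind(y, y, 1 - y)
  s <- stub_setup(truth, labels)
  st <- fit_stacked(s$bases, s$fms, s$labels)
  th <- st$meta_model$theta
  # faithful bases: P(x=1 | pos) high; inverted base: P(x=1 | pos) low
  expect_gt(th["base_1", "hepatotoxic"], 0.9)
  expect_lt(th["base_3", "hepatotoxic"], 0.1)
  # and the stack still classifies perfectly
  expect_equal(mean(predict_stacked(st, s$fms)$label ==
                      ifelse(y == 1, "hepatotoxic", "non_hepatotoxic")), 1)
})

test_that("random bases give chance-level stacked cross-validation", {
  labels <- rep(c("pos", "neg"), 20)
  truth <- withr::with_seed(5, matrix(rbinom(40 * 8, 1, 0.5), ncol = 8))
  s <- stub_setup(truth, labels)
  cv <- cross_validate(stacked_recipe(s$bases), s$fms, s$labels,
                       k = 5, seed = 2)
  expect_lt(abs(cv$metrics$acc - 50), 25)
})

test_that("majority vote calls positive only on a strict majority", {
  labels <- c("pos", "neg", "pos", "neg")
  truth <- matrix(c(1, 1, 1, 1,
                    1, 1, 0, 0,
                    1, 0, 0, 0,
                    1, 1, 1, 0), ncol = 4, byrow = TRUE)
  s <- stub_setup(truth, labels)
  mv <- majority_vote(s$bases, s$fms)
  expect_equal(mv$probability, c(1, 0.5, 0.25, 0.75))
  expect_equal(mv$label, c("hepatotoxic", "non_hepatotoxic",
                           "non_hepatotoxic", "hepatotoxic"))
})

test_that("out-of-fold and resubstitution modes both train real base stacks", {
  gen <- make_classification_set(synth_spec(
    n = 80, p_informative = 3, p_noise = 3, effect_size = 1.5, seed = 14))
  fms <- list(synthetic = gen$features)
  recipes <- list(
    base_recipe(learner_spec("naive_bayes", seed = 1), "synthetic"),
    base_recipe(learner_spec("knn", K = 3, seed = 1), "synthetic"),
    base_recipe(learner_spec("decision_tree", seed = 1), "synthetic"))
  for (mode in c("out_of_fold", "resubstitution")) {
    st <- fit_stacked(recipes, fms, gen$labels, mode = mode, seed = 2)
    expect_identical(st$mode, mode)
    pr <- predict_stacked(st, fms)
    expect_gt(mean(pr$label == gen$labels), 0.8)
  }
})
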