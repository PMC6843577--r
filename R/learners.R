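# Registry of the eight base learning algorithms: naive Bayes, RBF-kernel
# SVM, k-nearest neighbors, an entropic-blend instance learner (K*-style),
# boosted pruned trees (AdaBoost.M1), bagged KNN, a pruning-capable
# entropy-split decision tree (CART standing in for C4.5), and random
# forest. Each produces a probability of hepatotoxicity; the positive label
# is assigned on strict probability > decision threshold (default 0.500).

ALGORITHMS <- c("naive_bayes", "svm_rbf", "knn", "kstar", "adaboost_tree",
                "bagging_knn", "decision_tree", "random_forest")

# hyperparameters meaningful per algorithm, with defaults
.HYPER_DEFAULTS <- list(
  naive_bayes   = list(laplace = 1),
  svm_rbf       = list(C = 1, gamma = NA_real_),  # NA => 1/p at fit time
  knn           = list(K = 5),
  kstar         = list(B = 20),
  adaboost_tree = list(Cf = 0.25, n_rounds = 10),
  bagging_knn   = list(K = 5, n_bags = 10),
  decision_tree = list(Cf = 0.25),
  random_forest = list(Depth = 0, num_trees = 200)
)

#' Specify a base learning algorithm
#'
#' @param algorithm One of `"naive_bayes"`, `"svm_rbf"`, `"knn"`,
#'   `"kstar"`, `"adaboost_tree"`, `"bagging_knn"`, `"decision_tree"`,
#'   `"random_forest"`.
#' @param ... Hyperparameters meaningful for that algorithm: `C` (SVM
#'   penalty, > 0), `gamma` (RBF kernel width, > 0), `K` (neighbor count,
#'   >= 1), `B` (global blending in \[0, 100\]), `Depth` (maximum tree
#'   depth, 0 = unlimited), `Cf` (pruning confidence in (0, 1)), plus
#'   `laplace`, `n_rounds`, `n_bags`, `num_trees` where applicable.
#'   Unknown names are rejected.
#' @param seed Integer seed; identical (spec, data, seed) gives identical
#'   predictions.
#' @return A `learner_spec`.
#' @export
learner_spec <- function(algorithm, ..., seed = 1L) {
  if (!algorithm %in% ALGORITHMS) {
    abort_config(paste0("unknown algorithm: ", algorithm, " (known: ",
                        paste(ALGORITHMS, collapse = ", "), ")"))
  }
  supplied <- list(...)
  defaults <- .HYPER_DEFAULTS[[algorithm]]
  bad <- setdiff(names(supplied), names(defaults))
  if (length(bad) > 0) {
    abort_config(paste0("hyperparameter(s) not meaningful for ", algorithm,
                        ": ", paste(bad, collapse = ", ")))
  }
  hp <- modifyList(defaults, supplied)
  if (!is.null(hp$C) && !is.na(hp$C) && hp$C <= 0) abort_config("C must be > 0")
  if (!is.null(hp$gamma) && !is.na(hp$gamma) && hp$gamma <= 0) {
    abort_config("gamma must be > 0")
  }
  if (!is.null(hp$K) && hp$K < 1) abort_config("K must be >= 1")
  if (!is.null(hp$Depth) && hp$Depth < 0) abort_config("Depth must be >= 0")
  if (!is.null(hp$Cf) && (hp$Cf <= 0 || hp$Cf >= 1)) {
    abort_config("Cf must lie in (0, 1)")
  }
  if (!is.null(hp$B) && (hp$B < 0 || hp$B > 100)) {
    abort_config("B must lie in [0, 100]")
  }
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = " = ", collapse = ", ")
  cat("<learner_spec> ", x$algorithm, " (", hp, "), seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# standardization fitted on training data only (identity for binary cols)
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sig <- apply(x, 2, sd)
  sig[sig == 0 | is.na(sig)] <- 1
  list(mu = mu, sig = sig)
}
apply_scaler <- function(x, sc) {
  sweep(sweep(x, 2, sc$mu, "-"), 2, sc$sig, "/")
}

# J48's pruning-confidence knob mapped onto rpart's complexity parameter:
# smaller Cf (more pruning confidence) => larger cp (heavier pruning)
cf_to_cp <- function(cf) 0.04 * (1 - cf)

fit_tree <- function(x, y, cf, weights = NULL, seed = 1L) {
  df <- as.data.frame(x, check.names = FALSE)
  names(df) <- paste0("f", seq_len(ncol(df)))  # rpart-safe names
  df$.outcome <- label_factor(y)
  with_seed(seed, rpart::rpart(
    .outcome ~ ., data = df, weights = weights, method = "class",
    parms = list(split = "information"),
    control = rpart::rpart.control(cp = cf_to_cp(cf), minsplit = 4,
                                   minbucket = 2, xval = 0)
  ))
}
predict_tree <- function(fit, x) {
  df <- as.data.frame(x, check.names = FALSE)
  names(df) <- paste0("f", seq_len(ncol(df)))
  predict(fit, newdata = df, type = "prob")[, .POS]
}

#' Train a base classifier
#'
#' @param spec A [learner_spec()].
#' @param fm A `feature_matrix`, already restricted to the feature subset
#'   the model should consume.
#' @param labels Binary labels aligned with `fm` rows.
#' @param decision_threshold Probability above which (strictly) a compound
#'   is called hepatotoxic (default 0.500).
#' @return A `trained_classifier` holding the spec, the ordered feature
#'   names it consumes, and the fitted state.
#' @export
train <- function(spec, fm, labels, decision_threshold = 0.500) {
  stopifnot(inherits(spec, "learner_spec"))
  labels <- normalize_label(labels)
  if (length(unique(labels)) < 2) {
    abort_data("training requires both classes present")
  }
  feats <- fm_features(fm)
  x <- fm_values(fm)
  if (anyNA(x)) abort_data("training data contains missing values")
  hp <- spec$hyperparameters
  alg <- spec$algorithm

  fit <- with_seed(spec$seed, switch(
    alg,
    naive_bayes = {
      df <- nb_frame(x)
      list(model = e1071::naiveBayes(df, label_factor(labels),
                                     laplace = hp$laplace),
           binary_cols = attr(df, "binary_cols"))
    },
    svm_rbf = {
      gamma <- if (is.na(hp$gamma)) 1 / ncol(x) else hp$gamma
      sc <- fit_scaler(x)
      list(model = e1071::svm(apply_scaler(x, sc), label_factor(labels),
                              kernel = "radial", cost = hp$C, gamma = gamma,
                              probability = TRUE, scale = FALSE),
           scaler = sc)
    },
    knn = {
      sc <- fit_scaler(x)
      list(train_x = apply_scaler(x, sc), train_y = label_factor(labels),
           scaler = sc, K = hp$K)
    },
    kstar = {
      sc <- fit_scaler(x)
      list(train_x = apply_scaler(x, sc), train_y = label_factor(labels),
           scaler = sc, B = hp$B)
    },
    adaboost_tree = fit_adaboost(x, labels, hp, spec$seed),
    bagging_knn = {
      sc <- fit_scaler(x)
      xs <- apply_scaler(x, sc)
      bags <- lapply(seq_len(hp$n_bags), function(b) {
        sample(nrow(xs), replace = TRUE)
      })
      list(train_x = xs, train_y = label_factor(labels), scaler = sc,
           bags = bags, K = hp$K)
    },
    decision_tree = list(model = fit_tree(x, labels, hp$Cf,
                                          seed = spec$seed)),
    random_forest = {
      df <- as.data.frame(x, check.names = FALSE)
      df$.outcome <- label_factor(labels)
      list(model = ranger::ranger(
        dependent.variable.name = ".outcome", data = df,
        probability = TRUE, num.trees = hp$num_trees,
        max.depth = hp$Depth, seed = spec$seed, num.threads = 1,
        verbose = FALSE))
    }
  ))
  structure(list(spec = spec, family = fm_family(fm),
                 feature_names = feats, fit = fit,
                 train_ids = fm$compound_id,
                 decision_threshold = decision_threshold),
            class = "trained_classifier")
}

# mixed-likelihood frame for naive Bayes: binary columns become two-level
# factors (Bernoulli likelihood with Laplace smoothing), the rest stay
# numeric (Gaussian likelihood)
nb_frame <- function(x, binary_cols = NULL) {
  df <- as.data.frame(x, check.names = FALSE)
  if (is.null(binary_cols)) {
    binary_cols <- names(df)[vapply(df, function(v) all(v %in% c(0, 1)),
                                    logical(1))]
  }
  for (cl in binary_cols) df[[cl]] <- factor(df[[cl]], levels = c(0, 1))
  attr(df, "binary_cols") <- binary_cols
  df
}

fit_adaboost <- function(x, labels, hp, seed) {
  y <- label_factor(labels)
  n <- nrow(x)
  w <- rep(1 / n, n)
  models <- list(); alphas <- numeric(0)
  for (m in seq_len(hp$n_rounds)) {
    fit <- fit_tree(x, labels, hp$Cf, weights = w * n, seed = seed + m)
    pred <- predict_tree(fit, x) > 0.5
    miss <- pred != (y == .POS)
    err <- sum(w[miss])
    if (err >= 0.5) break
    alpha <- if (err <= 0) 10 else log((1 - err) / err)
    models[[length(models) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 0) break
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (length(models) == 0) {  # base tree no better than chance: keep one
    models <- list(fit_tree(x, labels, hp$Cf, weights = w * n, seed = seed))
    alphas <- 1
  }
  list(models = models, alphas = alphas)
}

# distance-weighted instance scoring used by kstar; b interpolates between
# nearest-neighbor sharpness (B = 0) and uniform blending (B = 100)
kstar_probs <- function(train_x, train_y, test_x, B) {
  d <- as.matrix(stats::dist(rbind(test_x, train_x)))
  d <- d[seq_len(nrow(test_x)), nrow(test_x) + seq_len(nrow(train_x)),
         drop = FALSE]
  pos <- train_y == .POS
  vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, ]
    b <- min(di) + (B / 100) * (max(di) - min(di)) + 1e-8
    wgt <- exp(-di / b)
    sum(wgt[pos]) / sum(wgt)
  }, numeric(1))
}

knn_pos_prob <- function(train_x, train_y, test_x, K, seed) {
  pred <- with_seed(seed, class::knn(train = train_x, test = test_x,
                                     cl = train_y, k = K, prob = TRUE))
  p_win <- attr(pred, "prob")
  ifelse(pred == .POS, p_win, 1 - p_win)
}

#' Predict hepatotoxicity probabilities
#'
#' @param clf A `trained_classifier` (or stub from [make_stub_bases()]).
#' @param fm A `feature_matrix` containing (at least) the classifier's
#'   feature columns; missing columns raise an error naming them.
#' @return A tibble (`compound_id`, `probability`, `label`) where `label`
#'   is `"hepatotoxic"` iff `probability` strictly exceeds the decision
#'   threshold (a probability of exactly 0.500 is non-hepatotoxic).
#' @export
predict_proba <- function(clf, fm) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.trained_classifier <- function(clf, fm) {
  x <- fm_values(fm, clf$feature_names)
  hp <- clf$spec$hyperparameters
  fit <- clf$fit
  prob <- switch(
    clf$spec$algorithm,
    naive_bayes = {
      nd <- nb_frame(x, binary_cols = fit$binary_cols)
      predict(fit$model, nd, type = "raw", threshold = 0.001,
              eps = 1e-6)[, .POS]
    },
    svm_rbf = {
      pr <- predict(fit$model, apply_scaler(x, fit$scaler),
                    probability = TRUE)
      attr(pr, "probabilities")[, .POS]
    },
    knn = knn_pos_prob(fit$train_x, fit$train_y,
                       apply_scaler(x, fit$scaler), fit$K, clf$spec$seed),
    kstar = kstar_probs(fit$train_x, fit$train_y,
                        apply_scaler(x, fit$scaler), fit$B),
    adaboost_tree = {
      votes <- vapply(fit$models, function(m) {
        as.numeric(predict_tree(m, x) > 0.5)
      }, numeric(nrow(x)))
      votes <- matrix(votes, nrow = nrow(x))
      as.numeric(votes %*% fit$alphas / sum(fit$alphas))
    },
    bagging_knn = {
      xs <- apply_scaler(x, fit$scaler)
      probs <- vapply(seq_along(fit$bags), function(b) {
        idx <- fit$bags[[b]]
        knn_pos_prob(fit$train_x[idx, , drop = FALSE], fit$train_y[idx],
                     xs, min(fit$K, length(idx)), clf$spec$seed + b)
      }, numeric(nrow(xs)))
      rowMeans(matrix(probs, nrow = nrow(xs)))
    },
    decision_tree = predict_tree(fit$model, x),
    random_forest = {
      df <- as.data.frame(x, check.names = FALSE)
      predict(fit$model, data = df, num.threads = 1)$predictions[, .POS]
    }
  )
  prob <- unname(as.numeric(prob))
  tibble(compound_id = fm$compound_id,
         probability = prob,
         label = ifelse(prob > clf$decision_threshold, .POS, .NEG))
}

#' Grid-search hyperparameter tuning
#'
#' Exhaustively evaluates a hyperparameter grid by stratified k-fold
#' cross-validation; the winning cell maximizes the mean of AUC and
#' ACC/100 (ties break toward the earlier grid row).
#'
#' @param spec Base [learner_spec()] whose hyperparameters the grid
#'   overrides.
#' @param fm,labels Training data.
#' @param grid Named list of hyperparameter value vectors (crossed); must
#'   be non-empty. See [default_grids()].
#' @param k_folds,seed Cross-validation folds and partition seed.
#' @return List with `best_spec` and `scores` (one row per grid cell:
#'   hyperparameters, acc, auc, score).
#' @export
tune <- function(spec, fm, labels, grid, k_folds = 10, seed = 1L) {
  if (length(grid) == 0) abort_config("tuning grid must be non-empty")
  labels <- normalize_label(labels)
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  folds <- make_folds(labels, k_folds, seed = seed)
  scores <- purrr::map(seq_len(nrow(cells)), function(i) {
    hp <- as.list(cells[i, , drop = FALSE])
    spec_i <- do.call(learner_spec,
                      c(list(algorithm = spec$algorithm, seed = spec$seed),
                        modifyList(spec$hyperparameters, hp)))
    pr <- cv_probs(spec_i, fm, labels, folds)
    cm <- confusion_matrix(truth = labels, predicted = pr$label)
    acc <- 100 * (cm$TP + cm$TN) / cm$N
    auc <- roc_auc(pr$probability, labels)$auc
    bind_cols(as_tibble(cells[i, , drop = FALSE]),
              tibble(acc = acc, auc = auc, score = mean(c(auc, acc / 100))))
  })
  scores <- bind_rows(scores)
  best_i <- which.max(scores$score)
  best_hp <- as.list(cells[best_i, , drop = FALSE])
  best_spec <- do.call(learner_spec,
                       c(list(algorithm = spec$algorithm, seed = spec$seed),
                         modifyList(spec$hyperparameters, best_hp)))
  list(best_spec = best_spec, scores = scores)
}

#' Default hyperparameter search grids
#'
#' One grid per tunable algorithm: the tuned knob follows the published
#' optimization table (SVM penalty and kernel width on a log-2 lattice,
#' neighbor counts, pruning confidence, tree depth, global blending); the
#' plain naive Bayes learner has no tuned knob and gets no grid.
#'
#' @return Named list of grids suitable for [tune()].
#' @export
default_grids <- function() {
  list(
    svm_rbf       = list(C = 2^(-5:5), gamma = 2^(-7:3)),
    knn           = list(K = c(1, 3, 5, 7, 9)),
    kstar         = list(B = c(1, 20, 40)),
    adaboost_tree = list(Cf = c(0.1, 0.25, 0.5)),
    bagging_knn   = list(K = c(1, 3, 5, 7, 9)),
    decision_tree = list(Cf = c(0.1, 0.25, 0.5)),
    random_forest = list(Depth = c(0, 5, 10, 20))
  )
}
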