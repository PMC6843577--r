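# Combined classifier: heterogeneous base classifiers, each bound to its
# own descriptor family and feature subset, fused by a Bernoulli Naive
# Bayes meta-learner over the bases' hard (0/1) predictions. The reference
# configuration uses eight bases, one per base algorithm; reduced stacks
# are permitted for testing and ablation.

#' Recipe triplet for one stacked base
#'
#' @param spec A [learner_spec()].
#' @param family Descriptor family the base consumes.
#' @param features Feature subset within that family (default: all).
#' @return A `base_recipe`.
#' @export
base_recipe <- function(spec, family, features = NULL) {
  structure(list(spec = spec, family = family, features = features),
            class = "base_recipe")
}

# ---- Bernoulli Naive Bayes meta-model ------------------------------------
# Laplace(+1) smoothed: theta[j, c] = (n_{x_j = 1, y = c} + 1) / (n_c + 2);
# unsmoothed class priors n_c / n. Kept as an explicit closed form so meta
# posteriors are hand-checkable.

bernoulli_nb_fit <- function(x, labels) {
  y <- normalize_label(labels)
  classes <- c(.NEG, .POS)
  n_c <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  theta <- vapply(classes, function(cl) {
    (colSums(x[y == cl, , drop = FALSE]) + 1) / (n_c[[cl]] + 2)
  }, numeric(ncol(x)))
  theta <- matrix(theta, ncol = 2,
                  dimnames = list(colnames(x), classes))
  list(prior = n_c / sum(n_c), theta = theta, classes = classes)
}

bernoulli_nb_posterior <- function(model, x) {
  loglik <- vapply(model$classes, function(cl) {
    th <- model$theta[, cl]
    x %*% log(th) + (1 - x) %*% log(1 - th) + log(model$prior[[cl]])
  }, numeric(nrow(x)))
  loglik <- matrix(loglik, ncol = 2, dimnames = list(NULL, model$classes))
  m <- apply(loglik, 1, max)
  lik <- exp(loglik - m)
  lik[, .POS] / rowSums(lik)
}

# ---- meta features -------------------------------------------------------

base_is_fitted <- function(b) {
  inherits(b, "trained_classifier") || inherits(b, "stub_classifier")
}

base_family <- function(b) {
  if (base_is_fitted(b)) b$family else b$family
}

predict_base <- function(base, fms) {
  fam <- base_family(base)
  fm <- fms[[fam]]
  if (is.null(fm)) {
    abort_data(paste0("no feature matrix supplied for family: ", fam))
  }
  predict_proba(base, fm)
}

#' Binary meta-feature matrix from base classifiers
#'
#' Entry (i, j) is 1 iff base j labels compound i hepatotoxic. Bases must
#' be fitted classifiers; all supplied feature matrices must share compound
#' ids and order.
#'
#' @param bases List of fitted base classifiers, each carrying its family
#'   tag.
#' @param fms Named list of `feature_matrix` objects keyed by family.
#' @return An n x length(bases) 0/1 matrix, columns `base_1..base_k` in
#'   base order.
#' @export
build_meta_features <- function(bases, fms) {
  fms <- as_fms(fms)
  cols <- lapply(bases, function(b) {
    as.numeric(predict_base(b, fms)$label == .POS)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- paste0("base_", seq_along(bases))
  rownames(out) <- fms[[1]]$compound_id
  out
}

#' Fit the combined (stacked) classifier
#'
#' Trains each base on its own family/subset, derives the n x k binary
#' meta-feature matrix from the bases' predictions on the training
#' compounds, and fits the Laplace-smoothed Bernoulli Naive Bayes
#' meta-model on it. In `"out_of_fold"` mode (the default) each training
#' compound's meta-features come from cross-fitted copies of the bases, so
#' no base predicts a compound it trained on; `"resubstitution"` mode uses
#' the final bases' own training-set predictions, which is optimistic but
#' matches the classical combined-classifier description.
#'
#' @param base_recipes List of [base_recipe()]s and/or already-fitted
#'   classifiers (fitted bases are used as-is in either mode).
#' @param fms Named list of `feature_matrix` objects keyed by family,
#'   sharing compound ids and order.
#' @param labels Training labels.
#' @param mode Meta-feature mode, `"out_of_fold"` or `"resubstitution"`.
#' @param k_folds Folds for cross-fitting in out-of-fold mode.
#' @param seed Seed for the cross-fitting partition.
#' @param decision_threshold Strict probability threshold for the positive
#'   call (default 0.500).
#' @return A `stacked_classifier`: `bases` (fitted, family-tagged),
#'   `meta_model`, `meta_features`, `mode`, `seed`.
#' @export
fit_stacked <- function(base_recipes, fms, labels,
                        mode = c("out_of_fold", "resubstitution"),
                        k_folds = 5, seed = 1L,
                        decision_threshold = 0.500) {
  mode <- match.arg(mode)
  fms <- as_fms(fms)
  labels <- normalize_label(labels)
  n <- length(labels)
  ids <- fms[[1]]$compound_id

  fitted <- vector("list", length(base_recipes))
  meta_cols <- vector("list", length(base_recipes))
  needs_folds <- mode == "out_of_fold" &&
    !all(vapply(base_recipes, base_is_fitted, logical(1)))
  folds <- if (needs_folds) make_folds(labels, k_folds, seed = seed) else NULL

  for (j in seq_along(base_recipes)) {
    b <- base_recipes[[j]]
    if (base_is_fitted(b)) {
      fitted[[j]] <- b
      meta_cols[[j]] <- as.numeric(predict_base(b, fms)$label == .POS)
      next
    }
    fm <- fms[[b$family]]
    if (is.null(fm)) {
      abort_data(paste0("no feature matrix supplied for family: ",
                        b$family))
    }
    if (!is.null(b$features)) fm <- fm_select(fm, b$features)
    clf <- tryCatch(train(b$spec, fm, labels),
                    error = function(e) abort_model(paste0(
                      "base '", b$spec$algorithm, "' (", b$family,
                      ") failed to train: ", conditionMessage(e))))
    fitted[[j]] <- clf
    if (mode == "resubstitution") {
      meta_cols[[j]] <- as.numeric(predict_proba(clf, fm)$label == .POS)
    } else {
      col <- numeric(n)
      for (f in seq_len(k_folds)) {
        tr <- folds != f
        cf <- train(b$spec, fm_slice(fm, which(tr)), labels[tr])
        col[!tr] <- as.numeric(
          predict_proba(cf, fm_slice(fm, which(!tr)))$label == .POS)
      }
      meta_cols[[j]] <- col
    }
  }
  meta <- do.call(cbind, meta_cols)
  colnames(meta) <- paste0("base_", seq_along(base_recipes))
  rownames(meta) <- ids
  structure(list(bases = fitted,
                 meta_model = bernoulli_nb_fit(meta, labels),
                 meta_features = meta,
                 mode = mode, seed = as.integer(seed),
                 decision_threshold = decision_threshold,
                 train_ids = ids),
            class = "stacked_classifier")
}

#' Predict with the combined classifier
#'
#' @param stacked A `stacked_classifier`.
#' @param fms Named list of feature matrices covering every base's family
#'   for the same compounds.
#' @return A tibble (`compound_id`, `probability`, `label`) where
#'   `probability` is the meta Naive Bayes posterior for the hepatotoxic
#'   class and the label is positive on strict `> decision_threshold`.
#' @export
predict_stacked <- function(stacked, fms) {
  fms <- as_fms(fms)
  meta <- build_meta_features(stacked$bases, fms)
  prob <- unname(bernoulli_nb_posterior(stacked$meta_model, meta))
  tibble(compound_id = fms[[1]]$compound_id,
         probability = prob,
         label = ifelse(prob > stacked$decision_threshold, .POS, .NEG))
}

#' Recipe wrapper for cross-validating the combined classifier
#'
#' @inheritParams fit_stacked
#' @return A `model_recipe` usable with [cross_validate()] and
#'   [y_randomization()].
#' @export
stacked_recipe <- function(base_recipes,
                           mode = c("out_of_fold", "resubstitution"),
                           k_folds = 5, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(
    families = unique(vapply(base_recipes, base_family, character(1))),
    fit = function(fms, labels) {
      fit_stacked(base_recipes, fms, labels, mode = mode,
                  k_folds = k_folds, seed = seed)
    },
    predict = function(model, fms) predict_stacked(model, fms)
  ), class = "model_recipe")
}

#' Reference majority-vote fusion
#'
#' Simple fusion baseline used in tests and comparisons: a compound is
#' called hepatotoxic when more than half of the bases call it positive
#' (exact half is negative, mirroring the strict probability rule).
#'
#' @param bases Fitted base classifiers.
#' @param fms Named list of feature matrices.
#' @return A tibble (`compound_id`, `probability`, `label`); `probability`
#'   is the positive-vote fraction.
#' @export
majority_vote <- function(bases, fms) {
  fms <- as_fms(fms)
  meta <- build_meta_features(bases, fms)
  frac <- unname(rowMeans(meta))
  tibble(compound_id = fms[[1]]$compound_id,
         probability = frac,
         label = ifelse(frac > 0.5, .POS, .NEG))
}
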