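# Performance evaluation: confusion-matrix metrics (ACC on the 0-100 scale,
# sensitivity/specificity/balanced accuracy on 0-1), ROC/AUC, stratified
# k-fold cross-validation with pooled-fold metrics, external-set evaluation,
# and Y-randomization (response permutation).

#' Confusion matrix
#'
#' Build from truth/prediction vectors or directly from cell counts.
#' Positives are hepatotoxicants.
#'
#' @param truth,predicted Label vectors (any encoding
#'   [normalize_label()] accepts).
#' @param TP,TN,FP,FN Cell counts (used when `truth` is missing).
#' @return A `confusion_matrix` list with `TP`, `TN`, `FP`, `FN`, `N`.
#' @export
confusion_matrix <- function(truth = NULL, predicted = NULL,
                             TP = 0, TN = 0, FP = 0, FN = 0) {
  if (!is.null(truth)) {
    truth <- normalize_label(truth)
    predicted <- normalize_label(predicted)
    TP <- sum(truth == .POS & predicted == .POS)
    TN <- sum(truth == .NEG & predicted == .NEG)
    FP <- sum(truth == .NEG & predicted == .POS)
    FN <- sum(truth == .POS & predicted == .NEG)
  }
  if (any(c(TP, TN, FP, FN) < 0)) abort_data("cell counts must be >= 0")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 N = TP + TN + FP + FN),
            class = "confusion_matrix")
}

#' Balanced accuracy
#'
#' @param se,sp Sensitivity and specificity on the 0-1 scale.
#' @param digits Decimals for the (round-half-up) displayed value; `NULL`
#'   returns full precision.
#' @return `(se + sp) / 2`, rounded half-up when `digits` is given.
#' @examples
#' bacc(0.725, 0.720) # 0.723 (0.7225 rounds half-up)
#' @export
bacc <- function(se, sp, digits = 3) {
  v <- (se + sp) / 2
  if (is.null(digits)) v else round_half_up(v, digits)
}

#' Classification metrics from a confusion matrix
#'
#' ACC = 100 (TP + TN) / N; SE = TP / (TP + FN); SP = TN / (TN + FP);
#' BACC = (SE + SP) / 2 (exact, pre-rounding). Display rounds half-up to
#' three decimals; stored values keep full precision.
#'
#' @param cm A [confusion_matrix()].
#' @param auc Optional AUC to carry in the report.
#' @return A `metrics_report` list: `acc`, `se`, `sp`, `bacc`, `auc`, `cm`.
#' @export
compute_metrics <- function(cm, auc = NA_real_) {
  if (cm$N <= 0) abort_data("confusion matrix is empty")
  if (cm$TP + cm$FN == 0) {
    abort_data("no positive (hepatotoxic) compounds: sensitivity undefined")
  }
  if (cm$TN + cm$FP == 0) {
    abort_data("no negative (non-hepatotoxic) compounds: specificity undefined")
  }
  se <- cm$TP / (cm$TP + cm$FN)
  sp <- cm$TN / (cm$TN + cm$FP)
  structure(list(acc = 100 * (cm$TP + cm$TN) / cm$N,
                 se = se, sp = sp, bacc = (se + sp) / 2,
                 auc = auc, cm = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> ACC %.3f | AUC %s | SE %.3f | SP %.3f | BACC %.3f\n",
    round_half_up(x$acc, 3),
    if (is.na(x$auc)) "NA" else sprintf("%.3f", round_half_up(x$auc, 3)),
    round_half_up(x$se, 3), round_half_up(x$sp, 3),
    round_half_up(x$bacc, 3)))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d  (N = %d)\n",
              x$cm$TP, x$cm$TN, x$cm$FP, x$cm$FN, x$cm$N))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC via the rank (Wilcoxon) statistic, equal to the trapezoidal area
#' under the full-threshold ROC sweep: the probability a random positive
#' outscores a random negative, with ties contributing one half. The point
#' list traces the curve across all distinct score thresholds.
#'
#' @param scores Predicted probabilities of hepatotoxicity.
#' @param labels True labels (both classes must be present).
#' @return A `roc_result` list: `auc` and `points` (tibble `threshold`,
#'   `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- normalize_label(labels)
  pos <- labels == .POS
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort_data("ROC analysis requires both classes present")
  }
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  points <- tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(pos & scores >= t) / n_pos, 0),
    fpr = vapply(thr, function(t) sum(!pos & scores >= t) / n_neg, 0)
  )
  structure(list(auc = auc, points = points), class = "roc_result")
}

# ---- model recipes -------------------------------------------------------

# A recipe bundles fit/predict closures over a named list of per-family
# feature matrices, so cross_validate and y_randomization handle single
# learners and the stacked classifier uniformly.

#' Recipe for a single base classifier
#'
#' @param spec A [learner_spec()].
#' @param family Descriptor family whose matrix the learner consumes.
#' @param features Feature subset (default: all columns at fit time).
#' @return A `model_recipe`.
#' @export
single_recipe <- function(spec, family, features = NULL) {
  structure(list(
    families = family,
    fit = function(fms, labels) {
      fm <- fms[[family]]
      if (is.null(fm)) abort_data(paste0("missing feature matrix: ", family))
      if (!is.null(features)) fm <- fm_select(fm, features)
      train(spec, fm, labels)
    },
    predict = function(model, fms) predict_proba(model, fms[[family]])
  ), class = "model_recipe")
}

# normalize the fms argument: a bare feature_matrix becomes a one-element
# named list keyed by its family tag
as_fms <- function(fms) {
  if (inherits(fms, "feature_matrix")) {
    out <- list(fms)
    names(out) <- fm_family(fms)
    return(out)
  }
  if (!is.list(fms) || is.null(names(fms))) {
    abort_data("fms must be a named list of feature matrices")
  }
  ids <- lapply(fms, function(f) f$compound_id)
  if (length(unique(ids)) > 1) {
    abort_data("feature matrices disagree on compound ids or row order")
  }
  fms
}

fms_slice <- function(fms, idx) lapply(fms, fm_slice, idx = idx)

#' Stratified k-fold cross-validation
#'
#' Stratified partition fixed by `seed`; every compound is predicted
#' exactly once, by a model whose training fold excluded it. All
#' preprocessing a learner performs (scaling, imputation, probability
#' calibration) happens inside [train()] per fold, so no information leaks
#' from test folds. Metrics come from the single pooled confusion matrix
#' over all folds.
#'
#' @param recipe A `model_recipe` ([single_recipe()], [stacked_recipe()]).
#' @param fms Named list of `feature_matrix` objects (or a single one).
#' @param labels True labels.
#' @param k Number of folds (default 10); every class must have >= k
#'   members.
#' @param seed Partition seed (recorded in the result for replay).
#' @return A `cv_result`: `predictions` (tibble `compound_id`,
#'   `probability`, `label`, `truth`, `fold`), `metrics`
#'   (a `metrics_report` including AUC), `k`, `seed`.
#' @export
cross_validate <- function(recipe, fms, labels, k = 10, seed = 1L) {
  fms <- as_fms(fms)
  labels <- normalize_label(labels)
  n <- length(labels)
  folds <- make_folds(labels, k, seed = seed)
  ids <- fms[[1]]$compound_id
  prob <- numeric(n); lab <- character(n)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    model <- recipe$fit(fms_slice(fms, which(tr)), labels[tr])
    pr <- recipe$predict(model, fms_slice(fms, which(te)))
    prob[te] <- pr$probability
    lab[te] <- pr$label
  }
  cm <- confusion_matrix(truth = labels, predicted = lab)
  auc <- roc_auc(prob, labels)$auc
  structure(list(
    predictions = tibble(compound_id = ids, probability = prob,
                         label = lab, truth = labels, fold = folds),
    metrics = compute_metrics(cm, auc = auc),
    k = k, seed = as.integer(seed)
  ), class = "cv_result")
}

# internal fast path used by subset_sweep and tune: single learner, single
# matrix, precomputed folds; returns pooled predictions in row order
cv_probs <- function(spec, fm, labels, folds) {
  n <- length(labels)
  prob <- numeric(n); lab <- character(n)
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    model <- train(spec, fm_slice(fm, which(tr)), labels[tr])
    pr <- predict_proba(model, fm_slice(fm, which(te)))
    prob[te] <- pr$probability
    lab[te] <- pr$label
  }
  tibble(probability = prob, label = lab)
}

#' Y-randomization (response permutation) validation
#'
#' Repeatedly permutes the labels uniformly at random (features untouched,
#' class counts preserved exactly), re-runs the full cross-validated
#' pipeline on each permuted copy, and reports the accuracy distribution.
#' A sound model scores at chance here, certifying that the real model's
#' performance comes from structure-label association.
#'
#' @inheritParams cross_validate
#' @param runs Number of permutation runs (default 100).
#' @return A `yrand_result`: `acc` (per-run pooled CV accuracies on the
#'   0-100 scale), `mean`, `sd`, `runs`.
#' @export
y_randomization <- function(recipe, fms, labels, runs = 100, k = 10,
                            seed = 1L) {
  fms <- as_fms(fms)
  labels <- normalize_label(labels)
  accs <- with_seed(seed, {
    vapply(seq_len(runs), function(r) {
      perm <- sample(labels)
      cv <- cross_validate(recipe, fms, perm, k = k, seed = seed + r)
      cv$metrics$acc
    }, numeric(1))
  })
  structure(list(acc = accs, mean = mean(accs), sd = sd(accs),
                 runs = runs),
            class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat(sprintf("<yrand_result> %d runs: ACC %.4f +/- %.4f\n",
              x$runs, x$mean, x$sd))
  invisible(x)
}

#' Evaluate a fitted model on an external validation set
#'
#' Checks training/external disjointness by compound id (the model records
#' its training ids); overlap beyond `overlap_limit` warns, or errors in
#' strict mode. Reports pooled metrics plus the per-compound prediction
#' table.
#'
#' @param model A `trained_classifier` or `stacked_classifier`.
#' @param fms Named list of feature matrices for the external compounds
#'   (or a single `feature_matrix` for a base classifier).
#' @param labels True external labels.
#' @param overlap_limit Tolerated training-overlap fraction (default 0).
#' @param strict Escalate overlap warning to an error.
#' @return List with `metrics` (a `metrics_report` incl. AUC),
#'   `predictions` (tibble `compound_id`, `probability`, `label`, `truth`),
#'   and `overlap` (offending compound ids).
#' @export
evaluate_external <- function(model, fms, labels, overlap_limit = 0,
                              strict = FALSE) {
  fms <- as_fms(fms)
  labels <- normalize_label(labels)
  ids <- fms[[1]]$compound_id
  overlap <- intersect(ids, model$train_ids %||% character(0))
  if (length(overlap) / max(length(ids), 1) > overlap_limit) {
    msg <- paste0(length(overlap),
                  " external compound(s) overlap the training set")
    if (strict) abort_data(msg) else warn(msg)
  }
  pr <- if (inherits(model, "stacked_classifier")) {
    predict_stacked(model, fms)
  } else {
    predict_proba(model, fms[[model$family]])
  }
  cm <- confusion_matrix(truth = labels, predicted = pr$label)
  auc <- roc_auc(pr$probability, labels)$auc
  list(metrics = compute_metrics(cm, auc = auc),
       predictions = mutate(pr, truth = labels),
       overlap = overlap)
}
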