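# Feature-selection cascade: all-relevant (Boruta-style) selection,
# pairwise-correlation pruning, recursive feature elimination, and the
# nested-subset sweep that fixes each learner's optimal subset size.

#' Selection configuration
#'
#' @param correlation_cutoff Pairwise absolute Pearson correlation above
#'   which one of a feature pair is pruned (default 0.90).
#' @param boruta_max_iter Iteration cap for the all-relevant selector.
#' @param boruta_alpha Significance level of the binomial hit tests.
#' @param rfe_step Features removed per elimination round (default 1,
#'   giving a complete ranking).
#' @param num_trees Trees in the random-forest importance estimator used by
#'   both the all-relevant selector and the eliminator.
#' @param seed Integer seed governing all stochastic steps.
#' @return A `selection_config` list.
#' @export
selection_config <- function(correlation_cutoff = 0.90,
                             boruta_max_iter = 100L,
                             boruta_alpha = 0.05,
                             rfe_step = 1L,
                             num_trees = 200L,
                             seed = 1L) {
  if (correlation_cutoff <= 0 || correlation_cutoff >= 1) {
    abort_config("correlation_cutoff must lie in (0, 1)")
  }
  if (rfe_step < 1) abort_config("rfe_step must be >= 1")
  structure(list(correlation_cutoff = correlation_cutoff,
                 boruta_max_iter = as.integer(boruta_max_iter),
                 boruta_alpha = boruta_alpha,
                 rfe_step = as.integer(rfe_step),
                 num_trees = as.integer(num_trees),
                 seed = as.integer(seed)),
            class = "selection_config")
}

# random-forest impurity importance on a plain matrix + binary labels
rf_importance <- function(x, y, num_trees, seed) {
  df <- as.data.frame(x, check.names = FALSE)
  df$.outcome <- label_factor(y)
  fit <- ranger::ranger(
    dependent.variable.name = ".outcome", data = df,
    num.trees = num_trees, importance = "impurity",
    seed = seed, num.threads = 1, verbose = FALSE
  )
  fit$variable.importance
}

#' All-relevant feature selection with shadow features
#'
#' Implements the Boruta scheme: each iteration appends a shuffled "shadow"
#' copy of every still-undecided feature, fits a random-forest importance
#' estimator to the augmented matrix, and scores a hit for every real
#' feature whose importance exceeds the maximum shadow importance. Features
#' are confirmed or rejected by two-sided binomial tests on their hit
#' counts at `boruta_alpha`, Bonferroni-corrected for the initial feature
#' count; rejected features leave the candidate pool. Features still
#' undecided at the iteration cap remain tentative (and are treated as not
#' selected downstream).
#'
#' @param fm A `feature_matrix`.
#' @param labels Binary label vector aligned with `fm` rows
#'   (hepatotoxic / non_hepatotoxic, or anything [normalize_label()]
#'   accepts).
#' @param cfg A [selection_config()].
#' @return A list with character vectors `confirmed`, `rejected`,
#'   `tentative` (disjoint; union = input features) and a `history` tibble
#'   of per-feature hit counts.
#' @export
boruta_select <- function(fm, labels, cfg = selection_config()) {
  labels <- normalize_label(labels)
  if (length(unique(labels)) < 2) {
    abort_data("all-relevant selection requires both classes present")
  }
  if (nrow(fm) < 10) abort_data("need at least 10 observations")
  feats <- fm_features(fm)
  x_all <- fm_values(fm)
  p0 <- length(feats)
  status <- setNames(rep("tentative", p0), feats)
  hits <- setNames(rep(0L, p0), feats)
  iters <- setNames(rep(0L, p0), feats)
  thr <- cfg$boruta_alpha / 2 / p0  # per-tail, Bonferroni over features

  with_seed(cfg$seed, {
    for (it in seq_len(cfg$boruta_max_iter)) {
      active <- names(status)[status != "rejected"]
      undecided <- names(status)[status == "tentative"]
      if (length(undecided) == 0) break
      x <- x_all[, active, drop = FALSE]
      shadows <- apply(x, 2, sample)
      colnames(shadows) <- paste0(".shadow_", active)
      imp <- rf_importance(cbind(x, shadows), labels,
                           cfg$num_trees, seed = cfg$seed + it)
      shadow_max <- max(imp[grepl("^\\.shadow_", names(imp))])
      hit <- imp[undecided] > shadow_max
      hits[undecided] <- hits[undecided] + as.integer(hit)
      iters[undecided] <- iters[undecided] + 1L
      for (f in undecided) {
        n_it <- iters[[f]]; h <- hits[[f]]
        if (pbinom(h - 1, n_it, 0.5, lower.tail = FALSE) < thr) {
          status[[f]] <- "confirmed"
        } else if (pbinom(h, n_it, 0.5) < thr) {
          status[[f]] <- "rejected"
        }
      }
    }
  })
  list(
    confirmed = feats[status[feats] == "confirmed"],
    rejected = feats[status[feats] == "rejected"],
    tentative = feats[status[feats] == "tentative"],
    history = tibble(feature = feats, hits = as.integer(hits[feats]),
                     iterations = as.integer(iters[feats]),
                     status = unname(status[feats]))
  )
}

#' Prune highly correlated features
#'
#' Removes features until no pair has absolute Pearson correlation above
#' `cutoff`, dropping from each offending pair the member with the larger
#' mean absolute correlation to all other features (the `findCorrelation`
#' rule from caret, which is used as the engine).
#'
#' @param fm A `feature_matrix` with no constant columns (run
#'   [drop_degenerate()] first).
#' @param cutoff Absolute correlation threshold (default 0.90).
#' @return Character vector of retained feature names, in input order.
#' @export
correlation_prune <- function(fm, cutoff = 0.90) {
  feats <- fm_features(fm)
  if (length(feats) < 2) return(feats)
  x <- fm_values(fm)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort_data(paste0("constant column(s) present (drop_degenerate first): ",
                      paste(feats[sds == 0], collapse = ", ")))
  }
  r <- cor(x)
  drop <- caret::findCorrelation(r, cutoff = cutoff, exact = TRUE,
                                 names = TRUE)
  setdiff(feats, drop)
}

#' Recursive feature elimination ranking
#'
#' Iteratively fits the random-forest importance estimator and eliminates
#' the least-important `rfe_step` features until one remains. Rank 1 is the
#' last survivor; the returned ranking is a permutation of the input
#' features.
#'
#' @inheritParams boruta_select
#' @return A tibble (`feature`, `rank`, `eliminated_round`) sorted by rank.
#' @export
rfe_rank <- function(fm, labels, cfg = selection_config()) {
  labels <- normalize_label(labels)
  if (length(unique(labels)) < 2) {
    abort_data("RFE requires both classes present")
  }
  feats <- fm_features(fm)
  if (length(feats) < 1) abort_data("RFE requires at least one feature")
  x_all <- fm_values(fm)
  remaining <- feats
  round_of <- setNames(rep(NA_integer_, length(feats)), feats)
  rnd <- 0L
  while (length(remaining) > 1) {
    rnd <- rnd + 1L
    imp <- rf_importance(x_all[, remaining, drop = FALSE], labels,
                         cfg$num_trees, seed = cfg$seed + rnd)
    n_drop <- min(cfg$rfe_step, length(remaining) - 1L)
    worst <- names(sort(imp))[seq_len(n_drop)]
    round_of[worst] <- rnd
    remaining <- setdiff(remaining, worst)
  }
  p <- length(feats)
  # eliminated earlier => larger rank; survivors (round NA) get rank 1
  ord <- order(ifelse(is.na(round_of[feats]), Inf, round_of[feats]),
               decreasing = TRUE)
  out <- tibble(feature = feats[ord],
                rank = seq_len(p),
                eliminated_round = unname(round_of[feats[ord]]))
  out$rank <- rev(seq_len(p))[rank(ifelse(is.na(out$eliminated_round), Inf,
                                          out$eliminated_round),
                                   ties.method = "first")]
  arrange(out, .data$rank)
}

#' Nested-subset sweep over a feature ranking
#'
#' For every subset size k from p down to 1, cross-validates the learner on
#' the k top-ranked features (one evaluation per size, so exactly p
#' evaluations), using one fixed stratified fold partition shared across
#' sizes for comparability. The optimal size maximizes the mean of AUC and
#' ACC/100; ties break toward the smaller subset. Per-size learner failures
#' are recorded in the table, not fatal.
#'
#' @param fm A `feature_matrix`.
#' @param labels Binary labels aligned with `fm`.
#' @param ranking Ranking tibble from [rfe_rank()] covering `fm`'s features.
#' @param spec A [learner_spec()].
#' @param k_folds Cross-validation folds (default 10).
#' @param seed Seed for the fold partition.
#' @return A `sweep_result`: list with `table` (k, acc, auc, score, error),
#'   `best_k`, `best_features`, `algorithm`, `family`.
#' @export
subset_sweep <- function(fm, labels, ranking, spec, k_folds = 10,
                         seed = 1L) {
  labels <- normalize_label(labels)
  feats <- fm_features(fm)
  if (!setequal(ranking$feature, feats)) {
    abort_data("ranking must cover exactly the feature matrix's features")
  }
  folds <- make_folds(labels, k_folds, seed = seed)
  ordered_feats <- ranking$feature[order(ranking$rank)]
  p <- length(ordered_feats)
  rows <- purrr::map(rev(seq_len(p)), function(k) {
    sub <- fm_select(fm, ordered_feats[seq_len(k)])
    res <- tryCatch({
      pr <- cv_probs(spec, sub, labels, folds)
      cm <- confusion_matrix(truth = labels, predicted = pr$label)
      acc <- 100 * (cm$TP + cm$TN) / cm$N
      auc <- roc_auc(pr$probability, labels)$auc
      tibble(k = k, acc = acc, auc = auc,
             score = mean(c(auc, acc / 100)), error = NA_character_)
    }, error = function(e) {
      tibble(k = k, acc = NA_real_, auc = NA_real_, score = NA_real_,
             error = conditionMessage(e))
    })
    res
  })
  table <- bind_rows(rows)
  ok <- table[!is.na(table$score), ]
  if (nrow(ok) == 0) abort_model("every subset size failed to train")
  best <- ok[ok$score == max(ok$score), ]
  best_k <- min(best$k)
  structure(list(table = table,
                 best_k = best_k,
                 best_features = ordered_feats[seq_len(best_k)],
                 algorithm = spec$algorithm,
                 family = fm_family(fm)),
            class = "sweep_result")
}

#' Sweep bookkeeping: planned evaluations per learner
#'
#' The exhaustive sweep trains one model per retained subset size, per
#' family, per learning algorithm. Given per-family post-pruning widths
#' this enumerates every (family, k) evaluation a single learner performs;
#' with the published widths of the reference training set the plan has 677
#' rows per learner (5416 across the eight algorithms).
#'
#' @param widths Named integer vector of post-pruning feature counts per
#'   family; defaults to the registry's published `pruned_width`.
#' @return A tibble (`family`, `k`), one row per planned model fit.
#' @export
sweep_plan <- function(widths = setNames(descriptor_families$pruned_width,
                                         descriptor_families$family)) {
  if (any(widths < 1)) abort_config("widths must be positive")
  bind_rows(purrr::imap(widths, function(w, fam) {
    tibble(family = fam, k = rev(seq_len(w)))
  }))
}
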