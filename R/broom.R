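# broom-style tidiers for the fitted/result objects.

#' @export
tidy.metrics_report <- function(x, ...) {
  tibble(metric = c("acc", "auc", "se", "sp", "bacc"),
         value = c(x$acc, x$auc, x$se, x$sp, x$bacc))
}

#' @export
glance.metrics_report <- function(x, ...) {
  tibble(acc = x$acc, auc = x$auc, se = x$se, sp = x$sp, bacc = x$bacc,
         tp = x$cm$TP, tn = x$cm$TN, fp = x$cm$FP, fn = x$cm$FN,
         n = x$cm$N)
}

#' @export
tidy.cv_result <- function(x, ...) x$predictions

#' @export
glance.cv_result <- function(x, ...) {
  bind_cols(glance(x$metrics), tibble(k = x$k, seed = x$seed))
}

#' @export
tidy.sweep_result <- function(x, ...) x$table

#' @export
glance.sweep_result <- function(x, ...) {
  tibble(algorithm = x$algorithm, family = x$family, best_k = x$best_k,
         best_score = max(x$table$score, na.rm = TRUE),
         n_evaluations = nrow(x$table))
}

#' @export
tidy.screening_result <- function(x, ...) x$table

#' @export
glance.screening_result <- function(x, ...) {
  tibble(n_union = length(x$union),
         n_s1 = x$subgroup_sizes[["s1"]], n_s2 = x$subgroup_sizes[["s2"]],
         n_s3 = x$subgroup_sizes[["s3"]],
         unique_s1 = x$unique_counts[["s1"]],
         unique_s2 = x$unique_counts[["s2"]],
         unique_s3 = x$unique_counts[["s3"]])
}

#' @export
tidy.trained_classifier <- function(x, ...) {
  tibble(feature = x$feature_names,
         position = seq_along(x$feature_names))
}

#' @export
glance.trained_classifier <- function(x, ...) {
  tibble(algorithm = x$spec$algorithm, family = x$family,
         n_features = length(x$feature_names),
         decision_threshold = x$decision_threshold, seed = x$spec$seed)
}

#' @export
tidy.stacked_classifier <- function(x, ...) {
  bind_rows(lapply(seq_along(x$bases), function(j) {
    b <- x$bases[[j]]
    tibble(base = paste0("base_", j),
           algorithm = if (inherits(b, "stub_classifier")) "stub" else
             b$spec$algorithm,
           family = b$family,
           n_features = length(b$feature_names))
  }))
}

#' @export
glance.stacked_classifier <- function(x, ...) {
  tibble(n_bases = length(x$bases), mode = x$mode,
         decision_threshold = x$decision_threshold, seed = x$seed)
}

#' @export
tidy.yrand_result <- function(x, ...) {
  tibble(run = seq_along(x$acc), acc = x$acc)
}

#' @export
glance.yrand_result <- function(x, ...) {
  tibble(mean_acc = x$mean, sd_acc = x$sd, runs = x$runs)
}
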