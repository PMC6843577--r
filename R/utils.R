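# Shared small helpers: rounding, label handling, seeded RNG scopes.

#' Round half away from zero
#'
#' Fixed-decimal rounding where exact halves round up (0.7225 -> 0.723 at
#' three decimals), unlike [base::round()]'s round-half-even. Used only for
#' display of performance metrics; internal arithmetic keeps full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(0.7225, 3) # 0.723
#' @export
round_half_up <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-12) / scale
}

# Normalize arbitrary label encodings to the internal 3-value vocabulary.
# Accepts 1/0, pos/neg, hepatotoxic/non-hepatotoxic (and common variants).
normalize_label <- function(x) {
  raw <- stringr::str_squish(tolower(as.character(x)))
  out <- dplyr::case_when(
    raw %in% c("1", "pos", "positive", "hepatotoxic", "toxic", "true") ~ .POS,
    raw %in% c("0", "neg", "negative", "non_hepatotoxic", "non-hepatotoxic",
               "nonhepatotoxic", "nontoxic", "non-toxic", "false") ~ .NEG,
    is.na(x) | raw %in% c("", "na", "unknown") ~ .UNK,
    TRUE ~ NA_character_
  )
  bad <- unique(raw[is.na(out)])
  if (length(bad) > 0) {
    abort_data(paste0("unrecognized label value(s): ",
                      paste(bad, collapse = ", ")))
  }
  out
}

# factor with a fixed level order so "hepatotoxic" is always the positive /
# second level in model matrices
label_factor <- function(x) factor(x, levels = c(.NEG, .POS))

# condition helpers: error classes mirror the exit-code taxonomy of the CLI
abort_config <- function(msg) rlang::abort(msg, class = "hepascreen_config_error")
abort_data   <- function(msg) rlang::abort(msg, class = "hepascreen_data_error")
abort_model  <- function(msg) rlang::abort(msg, class = "hepascreen_model_error")

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic internals route through this.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stratified k-fold assignment: returns an integer vector of fold ids in
# 1..k, one per observation, each class split as evenly as possible.
make_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (any(table(labels) < k)) {
    abort_data(paste0("smallest class has fewer than k = ", k,
                      " members; use a smaller k"))
  }
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
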