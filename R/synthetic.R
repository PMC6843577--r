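# Synthetic data and shipped fixtures: a labeled feature-table generator
# with planted informative / redundant / irrelevant features (the structure
# the selection cascade assumes), stub base classifiers that isolate the
# meta-learner, and the case-study screening fixture.

#' Specification for a synthetic classification set
#'
#' @param n Number of compounds.
#' @param p_informative Features whose distribution differs between
#'   classes.
#' @param p_redundant Near-copies of informative parents (at most one per
#'   parent), correlated at `redundancy_rho`; exercises the correlation
#'   pruning step on both sides of its cutoff.
#' @param p_noise Label-independent features.
#' @param class_balance Fraction of hepatotoxic compounds, in (0, 1).
#' @param effect_size Class separation of informative features: mean shift
#'   in SD units for continuous features, bit-probability gap for binary
#'   ones. Defaults: 1.5 (continuous/mixed), 0.6 (binary).
#' @param redundancy_rho Target parent-copy correlation, in (0.9, 1].
#' @param value_kind `"continuous"`, `"binary"`, or `"mixed"` (first half
#'   of each block binary, rest continuous).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `synth_spec`.
#' @export
synth_spec <- function(n = 200, p_informative = 5, p_redundant = 0,
                       p_noise = 10, class_balance = 0.5,
                       effect_size = NULL, redundancy_rho = 0.95,
                       value_kind = c("continuous", "binary", "mixed"),
                       seed = 1L) {
  value_kind <- match.arg(value_kind)
  if (p_redundant > p_informative) {
    abort_config("p_redundant must be <= p_informative")
  }
  if (class_balance <= 0 || class_balance >= 1) {
    abort_config("class_balance must lie in (0, 1)")
  }
  if (redundancy_rho <= 0.9 || redundancy_rho > 1) {
    abort_config("redundancy_rho must lie in (0.9, 1]")
  }
  if (is.null(effect_size)) {
    effect_size <- if (value_kind == "binary") 0.6 else 1.5
  }
  if (value_kind == "binary" && effect_size > 1) {
    abort_config("binary effect_size is a probability gap; must be <= 1")
  }
  structure(list(n = as.integer(n), p_informative = as.integer(p_informative),
                 p_redundant = as.integer(p_redundant),
                 p_noise = as.integer(p_noise),
                 class_balance = class_balance, effect_size = effect_size,
                 redundancy_rho = redundancy_rho, value_kind = value_kind,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# one synthetic feature block; kind "binary" or "continuous"
synth_block <- function(n, labels_pos, role, kind, effect, rho,
                        parents = NULL) {
  p <- if (is.null(parents)) length(role) else ncol(parents)
  if (p == 0) return(matrix(numeric(0), nrow = n, ncol = 0))
  if (!is.null(parents)) {  # redundant copies of parents
    if (kind == "binary") {
      flip <- (1 - rho) / 2
      out <- apply(parents, 2, function(v) {
        ifelse(runif(n) < flip, 1 - v, v)
      })
    } else {
      sigma <- sqrt(1 / rho^2 - 1)
      out <- parents + matrix(rnorm(n * p, sd = sigma), n, p)
    }
    return(matrix(out, nrow = n))
  }
  if (kind == "binary") {
    shift <- if (role == "informative") effect / 2 else 0
    p1 <- ifelse(labels_pos, 0.5 + shift, 0.5 - shift)
    matrix(rbinom(n * p, 1, rep(p1, p)), n, p)
  } else {
    shift <- if (role == "informative") effect / 2 else 0
    mu <- ifelse(labels_pos, shift, -shift)
    matrix(rnorm(n * p, mean = rep(if (role == "informative") mu else
      rep(0, n), p)), n, p)
  }
}

#' Generate a synthetic labeled feature table
#'
#' Informative features differ between classes by `effect_size`; redundant
#' features are noisy copies of informative parents correlated at (about)
#' `redundancy_rho`; noise features are independent of the labels. The
#' ground-truth role of every feature is returned for validating the
#' selection cascade.
#'
#' @param spec A [synth_spec()].
#' @return List: `features` (a `feature_matrix`), `labels`, and `roles`
#'   (tibble `feature`, `role`, `parent`).
#' @export
make_classification_set <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n
  with_seed(spec$seed, {
    n_pos <- round(n * spec$class_balance)
    labels <- sample(c(rep(.POS, n_pos), rep(.NEG, n - n_pos)))
    pos <- labels == .POS

    kind_of <- function(j, p_block) {
      if (spec$value_kind != "mixed") return(spec$value_kind)
      if (j <= ceiling(p_block / 2)) "binary" else "continuous"
    }
    gen_cols <- function(p_block, role) {
      cols <- lapply(seq_len(p_block), function(j) {
        synth_block(n, pos, role, kind_of(j, p_block),
                    spec$effect_size, spec$redundancy_rho)
      })
      if (p_block == 0) matrix(numeric(0), n, 0) else do.call(cbind, cols)
    }
    informative <- gen_cols(spec$p_informative, "informative")
    noise <- gen_cols(spec$p_noise, "noise")
    redundant <- if (spec$p_redundant > 0) {
      parent_idx <- seq_len(spec$p_redundant)
      cols <- lapply(parent_idx, function(j) {
        parent <- informative[, j, drop = FALSE]
        kind <- if (all(parent %in% c(0, 1))) "binary" else "continuous"
        synth_block(n, pos, "redundant", kind, spec$effect_size,
                    spec$redundancy_rho, parents = parent)
      })
      do.call(cbind, cols)
    } else matrix(numeric(0), n, 0)

    x <- cbind(informative, redundant, noise)
    feat_names <- c(
      sprintf("inf_%02d", seq_len(spec$p_informative)),
      if (spec$p_redundant > 0) sprintf("red_%02d", seq_len(spec$p_redundant)),
      if (spec$p_noise > 0) sprintf("noise_%02d", seq_len(spec$p_noise))
    )
    colnames(x) <- feat_names
    roles <- tibble(
      feature = feat_names,
      role = c(rep("informative", spec$p_informative),
               rep("redundant", spec$p_redundant),
               rep("noise", spec$p_noise)),
      parent = c(rep(NA_character_, spec$p_informative),
                 if (spec$p_redundant > 0)
                   sprintf("inf_%02d", seq_len(spec$p_redundant)),
                 rep(NA_character_, spec$p_noise))
    )
    df <- bind_cols(tibble(compound_id = sprintf("cpd_%03d", seq_len(n))),
                    as_tibble(x))
    vk <- if (spec$value_kind == "binary") "binary" else "continuous"
    list(features = feature_matrix(df, family = "synthetic",
                                   value_kind = vk),
         labels = labels, roles = roles)
  })
}

# ---- stub base classifiers -----------------------------------------------

#' Stub base classifiers that replay a fixed truth table
#'
#' Stub j ignores features entirely and replays column j of `truth_table`
#' as its hard prediction for each compound (matched by id), isolating the
#' meta-learner for unit tests.
#'
#' @param truth_table An n x k 0/1 matrix of base predictions.
#' @param ids Compound ids for the rows.
#' @param family Family tag the stubs claim to consume (any matrix of that
#'   family with matching ids satisfies them).
#' @return A list of `stub_classifier` objects.
#' @export
make_stub_bases <- function(truth_table, ids, family = "synthetic") {
  truth_table <- as.matrix(truth_table)
  if (!all(truth_table %in% c(0, 1))) {
    abort_data("truth table must be binary")
  }
  if (nrow(truth_table) != length(ids)) {
    abort_data("truth table rows must match ids")
  }
  lapply(seq_len(ncol(truth_table)), function(j) {
    structure(list(
      outputs = tibble(compound_id = as.character(ids),
                       probability = truth_table[, j]),
      family = family,
      feature_names = character(0),
      train_ids = as.character(ids),
      decision_threshold = 0.500
    ), class = "stub_classifier")
  })
}

#' @export
predict_proba.stub_classifier <- function(clf, fm) {
  hit <- match(fm$compound_id, clf$outputs$compound_id)
  if (anyNA(hit)) {
    abort_data("stub classifier has no stored prediction for some compounds")
  }
  prob <- clf$outputs$probability[hit]
  tibble(compound_id = fm$compound_id, probability = prob,
         label = ifelse(prob > clf$decision_threshold, .POS, .NEG))
}

# ---- case-study screening fixture ----------------------------------------

#' Case-study screening fixture
#'
#' Loads the shipped fixture for the *Polygonum multiflorum* Thunb (He Shou
#' Wu) case: the ingredient table of the herbal medicine (union members
#' that occur among its catalogued ingredients plus known non-hepatotoxic
#' fillers), the 6-name HILI subset, the star-shaped
#' herb-ingredient network around "he shou wu", and the expected screening
#' result (subgroup memberships, union, unique contributions) for
#' regression testing. Subgroup-1 membership comes from the published
#' combined-classifier calls and is supplied as a fixed set, since
#' reproducing it would require the original training data.
#'
#' @return List: `ingredients` (compound tibble), `hili`, `network`,
#'   `expected` (list `s1`, `s2`, `s3`, `union`, `unique_counts`).
#' @export
make_pmt_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "hepascreen",
                                 mustWork = TRUE)
  t5 <- readr::read_csv(ext("pmt_table5.csv"),
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  t5$ingredient <- normalize_name(t5$ingredient)
  ingredients <- read_compounds(ext("pmt_ingredients.csv"), "csv")
  hili <- read_hili(ext("pmt_hili.csv"))
  network <- read_network(ext("pmt_network.tsv"))
  expected <- list(
    s1 = sort(t5$ingredient[t5$s1 == "+"]),
    s2 = sort(t5$ingredient[t5$s2 == "+"]),
    s3 = sort(t5$ingredient[t5$s3 == "+"]),
    union = sort(t5$ingredient),
    unique_counts = c(
      s1 = sum(t5$s1 == "+" & t5$s2 != "+" & t5$s3 != "+"),
      s2 = sum(t5$s2 == "+" & t5$s1 != "+" & t5$s3 != "+"),
      s3 = sum(t5$s3 == "+" & t5$s1 != "+" & t5$s2 != "+")
    )
  )
  list(ingredients = ingredients, hili = hili, network = network,
       expected = expected)
}

#' Small anthraquinone structure set
#'
#' Six named anthraquinone-type ingredients with SMILES, for end-to-end
#' featurization tests on real-looking structures.
#'
#' @return A compound tibble.
#' @export
anthraquinone_set <- function() {
  read_compounds(system.file("extdata", "anthraquinones.csv",
                             package = "hepascreen", mustWork = TRUE),
                 "csv")
}
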