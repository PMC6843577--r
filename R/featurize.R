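# Featurization: per-family feature matrices behind a pluggable backend
# contract. Thirteen descriptor/fingerprint families are supported: twelve
# binary fingerprint families and one continuous 2D-descriptor family.

#' Descriptor family registry
#'
#' The thirteen feature families the modeling pipeline operates over, with
#' their nominal (raw) widths under the reference descriptor calculator and
#' the published widths after all-relevant selection ("boruta") and
#' correlation pruning ("pruned") on the reference liver-injury training
#' set. The pruned widths drive the subset-sweep bookkeeping: an exhaustive
#' sweep trains one model per retained feature count, so
#' `sum(pruned_width)` models per learning algorithm.
#'
#' @format A tibble with columns `family` (tag), `label` (display name),
#'   `value_kind` (`"binary"` or `"continuous"`), `raw_width`,
#'   `boruta_width`, `pruned_width`.
#' @export
descriptor_families <- tibble::tibble(
  family = c("FP", "ExtFP", "EStateFP", "GraphFP", "MACCSFP", "PubchemFP",
             "SubFP", "SubFPC", "KRFP", "KRFPC", "AP2D", "APC2D", "Desc2D"),
  label = c("FP", "ExtFP", "EStateFP", "GraphFP", "MACCSFP", "PubchemFP",
            "SubFP", "SubFPC", "KRFP", "KRFPC", "AP2D", "APC2D",
            "2D Descriptor"),
  value_kind = c(rep("binary", 12), "continuous"),
  raw_width = c(1024L, 1024L, 79L, 1024L, 166L, 881L, 307L, 307L, 4860L,
                4860L, 780L, 780L, 1444L),
  boruta_width = c(117L, 111L, 13L, 83L, 59L, 77L, 25L, 18L, 61L, 38L,
                   38L, 33L, 138L),
  pruned_width = c(117L, 111L, 12L, 73L, 52L, 58L, 22L, 15L, 49L, 26L,
                   34L, 17L, 91L)
)

family_info <- function(family) {
  row <- descriptor_families[descriptor_families$family == family, ]
  if (nrow(row) != 1) {
    abort_config(paste0("unsupported descriptor family: ", family,
                        " (known: ",
                        paste(descriptor_families$family, collapse = ", "),
                        ")"))
  }
  row
}

# ---- feature_matrix container -------------------------------------------

#' Construct a feature matrix
#'
#' A feature matrix is a tibble whose first column is `compound_id` and
#' whose remaining columns are uniquely named numeric features, tagged with
#' its descriptor `family` and `value_kind` (`"binary"` features contain
#' only 0/1). It behaves as an ordinary tibble under dplyr verbs.
#'
#' @param df Data frame with a `compound_id` column and numeric features.
#' @param family Family tag; defaults to `"custom"` for ad-hoc matrices.
#' @param value_kind `"binary"` or `"continuous"`.
#' @return A `feature_matrix` tibble.
#' @export
feature_matrix <- function(df, family = "custom",
                           value_kind = c("continuous", "binary")) {
  value_kind <- match.arg(value_kind)
  df <- as_tibble(df)
  if (!"compound_id" %in% names(df)) {
    abort_data("feature matrix requires a 'compound_id' column")
  }
  feats <- setdiff(names(df), "compound_id")
  if (anyDuplicated(feats)) abort_data("duplicate feature names")
  df <- df[, c("compound_id", feats)]
  df$compound_id <- as.character(df$compound_id)
  if (length(feats) > 0 && !all(vapply(df[feats], is.numeric, logical(1)))) {
    abort_data("feature columns must be numeric")
  }
  if (value_kind == "binary" && length(feats) > 0) {
    vals <- as.matrix(df[feats])
    if (!all(vals %in% c(0, 1))) {
      abort_data("binary feature matrix contains values outside {0, 1}")
    }
  }
  structure(df, family = family, value_kind = value_kind,
            class = c("feature_matrix", class(df)))
}

#' @export
fm_family <- function(fm) attr(fm, "family")

#' @export
fm_value_kind <- function(fm) attr(fm, "value_kind")

#' Feature names of a feature matrix
#' @param fm A `feature_matrix`.
#' @export
fm_features <- function(fm) setdiff(names(fm), "compound_id")

#' Numeric matrix view of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param features Columns to extract, in order (default all); missing
#'   names raise an error naming them.
#' @return A numeric matrix with compound ids as rownames.
#' @export
fm_values <- function(fm, features = fm_features(fm)) {
  missing_f <- setdiff(features, fm_features(fm))
  if (length(missing_f) > 0) {
    abort_data(paste0("feature matrix lacks required column(s): ",
                      paste(missing_f, collapse = ", ")))
  }
  m <- as.matrix(as_tibble(fm)[, features, drop = FALSE])
  rownames(m) <- fm$compound_id
  m
}

# row subset preserving class/attrs
fm_slice <- function(fm, idx) {
  out <- as_tibble(fm)[idx, , drop = FALSE]
  feature_matrix(out, family = fm_family(fm), value_kind = fm_value_kind(fm))
}

#' Restrict a feature matrix to a feature subset
#'
#' @param fm A `feature_matrix`.
#' @param features Feature names to keep (order respected); missing names
#'   raise an error naming them.
#' @return A `feature_matrix` with the same rows and only those columns.
#' @export
fm_select <- function(fm, features) {
  missing_f <- setdiff(features, fm_features(fm))
  if (length(missing_f) > 0) {
    abort_data(paste0("feature matrix lacks required column(s): ",
                      paste(missing_f, collapse = ", ")))
  }
  feature_matrix(as_tibble(fm)[, c("compound_id", features), drop = FALSE],
                 family = fm_family(fm), value_kind = fm_value_kind(fm))
}

#' Write / read a feature matrix with its sidecar metadata
#'
#' The on-disk form is a CSV (first column `compound_id`, header = feature
#' names) plus a `<path>.meta` YAML sidecar recording `family` and
#' `value_kind`.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `feature_matrix` (read).
#' @export
write_feature_matrix <- function(fm, path) {
  readr::write_csv(as_tibble(fm), path, progress = FALSE)
  yaml::write_yaml(list(family = fm_family(fm),
                        value_kind = fm_value_kind(fm)),
                   paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  meta_path <- paste0(path, ".meta")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else {
    list(family = "custom", value_kind = "continuous")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    compound_id = "c", .default = "d"), progress = FALSE)
  feature_matrix(df, family = meta$family, value_kind = meta$value_kind)
}

# ---- featurizer backends -------------------------------------------------

# A backend is a list(name, supports, compute) where compute(smiles, family)
# returns an n x p numeric matrix with unique column names (NA rows for
# failures). This contract keeps the modeling pipeline independent of any
# particular descriptor calculator.

#' Hashed-substructure featurizer backend
#'
#' A self-contained descriptor calculator: for the twelve binary fingerprint
#' families it tokenizes the SMILES string into atom/bond tokens, enumerates
#' contiguous token n-grams (local substructure paths), and hashes each
#' n-gram into the family's nominal bit width with a family-specific salt;
#' for the 2D-descriptor family it computes a small set of constitutional
#' descriptors (atom counts, ring/branch/bond counts, approximate molecular
#' weight, composition ratios). Deterministic, dependency-free, and suitable
#' for exercising the full modeling pipeline; it does not reproduce the
#' reference calculator's bit definitions.
#'
#' @param ngram_max Longest token n-gram hashed into fingerprint bits.
#' @return A featurizer backend.
#' @export
backend_hashed <- function(ngram_max = 4) {
  list(
    name = "hashed",
    supports = descriptor_families$family,
    compute = function(smiles, family) {
      info <- family_info(family)
      if (info$value_kind == "binary") {
        hashed_fingerprints(smiles, width = info$raw_width,
                            salt = family, ngram_max = ngram_max)
      } else {
        constitutional_descriptors(smiles)
      }
    }
  )
}

#' Precomputed-feature backend
#'
#' Adapter for external descriptor calculators (e.g. a PaDEL-style tool run
#' offline): serves feature rows from per-family CSV files named
#' `<family>.csv` under `dir`, matched to compounds by id.
#'
#' @param dir Directory holding `<family>.csv` feature tables (first column
#'   `compound_id`).
#' @return A featurizer backend.
#' @export
backend_precomputed <- function(dir) {
  list(
    name = "precomputed",
    supports = descriptor_families$family,
    compute = NULL,  # bypassed: compute_features reads rows by id
    dir = dir
  )
}

# deterministic, platform-independent string hash into 0..(width-1)
hash_string <- function(s, width) {
  codes <- utf8ToInt(s)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% width
  h
}

# tokenizes a SMILES string into atoms (incl. two-letter organic symbols and
# bracket atoms), bonds, branches and ring-closure digits
smiles_tokens <- function(s) {
  stringr::str_extract_all(
    s,
    "\\[[^]]*\\]|Cl|Br|Si|Se|[BCNOPSFIbcnops]|[=#$/\\\\]|[()]|%[0-9]{2}|[0-9]"
  )[[1]]
}

hashed_fingerprints <- function(smiles, width, salt, ngram_max = 4) {
  p <- width
  out <- matrix(NA_real_, nrow = length(smiles), ncol = p)
  colnames(out) <- sprintf("%s_bit%04d", salt, seq_len(p) - 1)
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s)) next
    toks <- smiles_tokens(s)
    if (length(toks) == 0) next
    row <- numeric(p)
    for (n in seq_len(min(ngram_max, length(toks)))) {
      for (start in seq_len(length(toks) - n + 1)) {
        gram <- paste0(salt, "|",
                       paste(toks[start:(start + n - 1)], collapse = ""))
        row[hash_string(gram, p) + 1] <- 1
      }
    }
    out[i, ] <- row
  }
  out
}

# approximate monoisotopic-free atomic weights for common organic elements
.ATOMIC_WEIGHTS <- c(B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06, F = 18.998, Cl = 35.45,
                     Br = 79.904, I = 126.9, Si = 28.085, Se = 78.971)

constitutional_descriptors <- function(smiles) {
  desc_names <- c("n_atoms", "n_carbon", "n_nitrogen", "n_oxygen",
                  "n_sulfur", "n_phosphorus", "n_halogen", "n_aromatic",
                  "n_rings", "n_branches", "n_double", "n_triple",
                  "n_bracket", "n_charge_pos", "n_charge_neg", "mol_weight",
                  "frac_aromatic", "frac_hetero", "frac_carbon",
                  "smiles_length")
  out <- matrix(NA_real_, nrow = length(smiles), ncol = length(desc_names))
  colnames(out) <- desc_names
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s)) next
    toks <- smiles_tokens(s)
    atom_tok <- toks[grepl("^(\\[|Cl$|Br$|Si$|Se$|[BCNOPSFIbcnops]$)", toks)]
    if (length(atom_tok) == 0) next
    sym <- toupper(sub("^\\[([A-Za-z][a-z]?).*", "\\1", atom_tok))
    sym <- ifelse(sym %in% c("CL"), "Cl", ifelse(sym %in% c("BR"), "Br",
           ifelse(sym %in% c("SI"), "Si", ifelse(sym %in% c("SE"), "Se",
                                                 substr(sym, 1, 1)))))
    n_atoms <- length(sym)
    n_arom <- sum(grepl("^[bcnops]$", atom_tok))
    counts <- c(
      n_atoms,
      sum(sym == "C"), sum(sym == "N"), sum(sym == "O"),
      sum(sym == "S"), sum(sym == "P"),
      sum(sym %in% c("F", "Cl", "Br", "I")),
      n_arom,
      sum(grepl("^[0-9]$|^%[0-9]{2}$", toks)) / 2,
      sum(toks == "("),
      sum(toks == "="), sum(toks == "#"),
      sum(grepl("^\\[", toks)),
      sum(stringr::str_count(atom_tok, "\\+")),
      sum(stringr::str_count(atom_tok, "-")),
      sum(.ATOMIC_WEIGHTS[sym], na.rm = TRUE),
      n_arom / n_atoms,
      sum(sym != "C") / n_atoms,
      sum(sym == "C") / n_atoms,
      nchar(s)
    )
    out[i, ] <- counts
  }
  out
}

# ---- compute_features ----------------------------------------------------

#' Compute a per-family feature matrix for a compound table
#'
#' One row per compound with a valid structure, in input order. Compounds
#' whose structure is missing, failed validation, or could not be
#' featurized by the backend are collected in a rejection report (attribute
#' `"rejections"`), never silently dropped.
#'
#' @param ds Compound tibble from [as_compounds()]/[read_compounds()].
#' @param family One of `descriptor_families$family`.
#' @param backend A featurizer backend ([backend_hashed()],
#'   [backend_precomputed()], or a user-supplied list honoring the
#'   contract).
#' @return A `feature_matrix` with attribute `"rejections"` (tibble of
#'   `compound_id`, `reason`).
#' @export
compute_features <- function(ds, family, backend = backend_hashed()) {
  info <- family_info(family)
  if (!family %in% backend$supports) {
    abort_config(paste0("backend '", backend$name,
                        "' does not support family ", family))
  }
  rej <- tibble(compound_id = ds$compound_id[!ds$parse_ok],
                reason = "unparseable structure")
  ok <- ds[ds$parse_ok, ]

  if (backend$name == "precomputed") {
    path <- file.path(backend$dir, paste0(family, ".csv"))
    if (!file.exists(path)) {
      abort_data(paste0("precomputed feature table not found: ", path))
    }
    full <- read_feature_matrix(path)
    hit <- ok$compound_id %in% full$compound_id
    rej <- bind_rows(rej, tibble(compound_id = ok$compound_id[!hit],
                                 reason = "not in precomputed table"))
    df <- as_tibble(full)[match(ok$compound_id[hit], full$compound_id), ]
    out <- feature_matrix(df, family = family, value_kind = info$value_kind)
    attr(out, "rejections") <- rej
    return(out)
  }

  vals <- backend$compute(ok$smiles, family)
  if (nrow(ok) > 0 && (is.null(vals) || nrow(vals) != nrow(ok))) {
    abort_model(paste0("backend '", backend$name,
                       "' returned a malformed matrix for family ", family))
  }
  failed <- if (nrow(ok) == 0) logical(0) else apply(is.na(vals), 1, all)
  if (nrow(ok) > 0 && all(failed)) {
    abort_model(paste0("backend '", backend$name,
                       "' failed on every compound for family ", family))
  }
  rej <- bind_rows(rej, tibble(compound_id = ok$compound_id[failed],
                               reason = "featurization failed"))
  df <- bind_cols(tibble(compound_id = ok$compound_id[!failed]),
                  as_tibble(vals[!failed, , drop = FALSE]))
  out <- feature_matrix(df, family = family, value_kind = info$value_kind)
  attr(out, "rejections") <- rej
  out
}

#' Drop degenerate feature columns
#'
#' Median-imputes missing values in continuous families (column-wise), then
#' removes zero-variance columns. Run this before correlation analysis,
#' which requires non-constant columns.
#'
#' @param fm A `feature_matrix`.
#' @return The filtered `feature_matrix`, with attribute `"removed"` naming
#'   the dropped columns.
#' @export
drop_degenerate <- function(fm) {
  feats <- fm_features(fm)
  df <- as_tibble(fm)
  if (fm_value_kind(fm) == "continuous") {
    for (f in feats) {
      v <- df[[f]]
      if (anyNA(v)) {
        med <- median(v, na.rm = TRUE)
        if (is.na(med)) med <- 0
        v[is.na(v)] <- med
        df[[f]] <- v
      }
    }
  }
  keep <- vapply(feats, function(f) {
    v <- df[[f]]
    length(unique(v[!is.na(v)])) > 1
  }, logical(1))
  out <- feature_matrix(df[, c("compound_id", feats[keep])],
                        family = fm_family(fm),
                        value_kind = fm_value_kind(fm))
  attr(out, "removed") <- feats[!keep]
  out
}
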