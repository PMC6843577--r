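# Compound table I/O: reading, standardization, deduplication, name
# normalization. A compound table is an ordinary tibble with one row per
# compound and the columns listed in `as_compounds()`, so it composes with
# dplyr verbs directly.

COMPOUND_COLS <- c("compound_id", "name", "smiles", "structure_key",
                   "label", "source", "probability", "parse_ok")

#' Coerce a data frame to a compound table
#'
#' Validates and completes the canonical compound-table columns: unique
#' `compound_id`, free-text `name`, optional `smiles`, a `structure_key`
#' derived from the SMILES (see [structure_key()]), a three-valued `label`
#' (`"hepatotoxic"`, `"non_hepatotoxic"`, `"unknown"`), a provenance
#' `source`, an optional predicted `probability` in \[0, 1\], and a
#' `parse_ok` flag for records whose structure failed syntactic validation.
#'
#' @param df A data frame with at least `compound_id` and `name` columns.
#'   `label` accepts `1/0`, `pos/neg` or `hepatotoxic/non-hepatotoxic`
#'   spellings and is normalized internally.
#' @param source Provenance tag recorded for rows lacking one.
#' @return A tibble with the canonical compound columns, input order
#'   preserved.
#' @export
as_compounds <- function(df, source = "user") {
  df <- as_tibble(df)
  if (!all(c("compound_id", "name") %in% names(df))) {
    abort_data("compound table requires 'compound_id' and 'name' columns")
  }
  df$compound_id <- as.character(df$compound_id)
  if (anyDuplicated(df$compound_id)) {
    abort_data("compound_id values must be unique within a dataset")
  }
  if (!"smiles" %in% names(df)) df$smiles <- NA_character_
  df$smiles <- as.character(df$smiles)
  df$smiles[!is.na(df$smiles) & df$smiles == ""] <- NA_character_
  if (!"label" %in% names(df)) df$label <- .UNK else {
    df$label <- normalize_label(df$label)
  }
  if (!"source" %in% names(df)) df$source <- source
  if (!"probability" %in% names(df)) df$probability <- NA_real_
  if (any(!is.na(df$probability) &
          (df$probability < 0 | df$probability > 1))) {
    abort_data("probability must lie in [0, 1]")
  }
  df$parse_ok <- !is.na(df$smiles) & vapply(df$smiles, smiles_valid, logical(1))
  if (any(!df$parse_ok & !is.na(df$smiles))) {
    warn(paste0(sum(!df$parse_ok & !is.na(df$smiles)),
                " structure(s) failed SMILES validation; ",
                "records kept with smiles unset"))
  }
  df$structure_key <- ifelse(df$parse_ok,
                             vapply(df$smiles, structure_key, character(1)),
                             NA_character_)
  df$smiles[!df$parse_ok] <- NA_character_
  df[, union(COMPOUND_COLS, names(df))]
}

# Lightweight syntactic SMILES validation: legal character set and balanced
# (), []. This is a gatekeeper for obviously corrupt records, not a full
# grammar; featurization backends do their own parsing.
smiles_valid <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]", s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  depth_p <- cumsum((chars == "(") - (chars == ")"))
  depth_b <- cumsum((chars == "[") - (chars == "]"))
  all(depth_p >= 0) && all(depth_b >= 0) &&
    depth_p[length(chars)] == 0 && depth_b[length(chars)] == 0 &&
    grepl("[A-Za-z]", s)
}

#' Structure key for deduplication
#'
#' A deterministic key identifying the parent structure: salt/solvent
#' fragments are stripped by keeping the largest dot-separated fragment
#' (ties broken lexicographically) and whitespace is removed. This package's
#' standardization is intentionally simple and documented here; it is a
#' string-level stand-in for a full canonicalization (it will not merge two
#' genuinely different SMILES spellings of one molecule).
#'
#' @param smiles A single SMILES string.
#' @return A character key, or `NA` for invalid input.
#' @export
structure_key <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(NA_character_)
  frags <- strsplit(gsub("\\s+", "", smiles), ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0) return(NA_character_)
  # heavy-atom count approximated by letters outside charge/H annotations
  weight <- vapply(frags, function(f) {
    sum(strsplit(gsub("\\[[^]]*H[^]]*\\]", "[X]", f), "")[[1]] %in%
          c(LETTERS, letters))
  }, integer(1))
  cand <- frags[weight == max(weight)]
  sort(cand)[1]
}

#' Read a compound table from disk
#'
#' @param path File path.
#' @param format One of `"csv"` (columns `id,name,smiles,label`; `label`
#'   optional), `"smiles"` (one `SMILES<TAB>id` per line), or `"sdf"`
#'   (V2000/V3000; requires the ChemmineR package; name taken from the
#'   title line).
#' @return A compound tibble (see [as_compounds()]); record order follows
#'   the file. Unparseable structures are retained with `parse_ok = FALSE`
#'   and a warning, never dropped.
#' @export
read_compounds <- function(path, format = c("csv", "smiles", "sdf")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort_config(
                       paste0("unknown compound format: ", format[1])))
  if (!file.exists(path)) abort_data(paste0("file not found: ", path))
  src <- basename(path)
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    if (nrow(df) == 0 && ncol(df) == 0) {
      return(as_compounds(tibble(compound_id = character(),
                                 name = character()), source = src))
    }
    need <- c("id", "name", "smiles")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols) > 0) {
      abort_data(paste0("csv compound table missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
    }
    df <- rename(df, compound_id = "id")
    return(as_compounds(df, source = src))
  }
  if (format == "smiles") {
    lines <- readr::read_lines(path, progress = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(as_compounds(tibble(compound_id = character(),
                                 name = character()), source = src))
    }
    parts <- stringr::str_split_fixed(lines, "\t", 2)
    ids <- ifelse(nzchar(parts[, 2]), parts[, 2],
                  paste0("smi_", seq_along(lines)))
    return(as_compounds(tibble(compound_id = ids, name = ids,
                               smiles = trimws(parts[, 1])), source = src))
  }
  # sdf
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort_config("reading SDF requires the ChemmineR package")
  }
  sdf <- ChemmineR::read.SDFset(path)
  nm <- vapply(seq_along(sdf), function(i) {
    h <- ChemmineR::header(sdf[[i]])
    if (length(h) >= 1 && nzchar(h[[1]])) h[[1]] else paste0("sdf_", i)
  }, character(1))
  smi <- tryCatch(as.character(ChemmineR::sdf2smiles(sdf)),
                  error = function(e) rep(NA_character_, length(sdf)))
  as_compounds(tibble(compound_id = make.unique(nm), name = nm,
                      smiles = smi), source = src)
}

#' Write a compound table to CSV
#'
#' Inverse of [read_compounds()] for the CSV dialect; a write/read
#' round-trip preserves ids, names, and labels exactly.
#'
#' @param ds Compound tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(ds, path) {
  out <- tibble(id = ds$compound_id, name = ds$name,
                smiles = ds$smiles, label = ds$label)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Tally class membership
#'
#' @param ds Compound tibble.
#' @return Named integer vector over the three-value label vocabulary.
#' @export
class_counts <- function(ds) {
  vapply(c(.POS, .NEG, .UNK), function(l) sum(ds$label == l), integer(1))
}

#' Normalize an ingredient or herb name for dictionary matching
#'
#' Lowercases, strips leading/trailing whitespace, collapses internal
#' whitespace runs, and maps hyphens to single spaces. Idempotent, so
#' already-normalized names pass through unchanged; all name matching in
#' the screening procedure goes through this function on both sides.
#'
#' @param raw Character vector of free-text names.
#' @return Character vector of canonical names.
#' @examples
#' normalize_name("Aloe-Emodin") # "aloe emodin"
#' @export
normalize_name <- function(raw) {
  if (any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    abort_data("cannot normalize an empty name")
  }
  out <- tolower(raw)
  out <- gsub("-", " ", out, fixed = TRUE)
  stringr::str_squish(out)
}

#' Remove duplicate structures from a compound table
#'
#' Duplicates are detected on `structure_key` where present, else on the
#' normalized name. Under `keep_first` the first record of each key wins;
#' under `drop_conflicts` keys whose duplicates carry contradictory
#' (non-unknown) labels are removed entirely. Idempotent.
#'
#' @param ds Compound tibble.
#' @param policy `"keep_first"` or `"drop_conflicts"`.
#' @return The deduplicated tibble, with a `"dedup_report"` attribute: a
#'   tibble of removed keys and the reason (`duplicate` or
#'   `label_conflict`). Retrieve it with `attr(x, "dedup_report")`.
#' @export
deduplicate_compounds <- function(ds, policy = c("keep_first",
                                                 "drop_conflicts")) {
  policy <- match.arg(policy)
  if (nrow(ds) == 0) {
    attr(ds, "dedup_report") <- tibble(key = character(),
                                       reason = character())
    return(ds)
  }
  key <- ifelse(!is.na(ds$structure_key), ds$structure_key,
                normalize_name(ifelse(nzchar(ds$name), ds$name,
                                      ds$compound_id)))
  dup_keys <- unique(key[duplicated(key)])
  conflict_keys <- character(0)
  if (policy == "drop_conflicts" && length(dup_keys) > 0) {
    conflict_keys <- dup_keys[vapply(dup_keys, function(k) {
      labs <- unique(ds$label[key == k & ds$label != .UNK])
      length(labs) > 1
    }, logical(1))]
  }
  keep <- !duplicated(key) & !(key %in% conflict_keys)
  report <- bind_rows(
    tibble(key = key[duplicated(key) & !(key %in% conflict_keys)],
           reason = "duplicate"),
    tibble(key = unique(key[key %in% conflict_keys]),
           reason = "label_conflict")
  )
  out <- ds[keep, ]
  attr(out, "dedup_report") <- distinct(report)
  out
}
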