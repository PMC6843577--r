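# Three-channel screening of hepatotoxic ingredients in a multi-ingredient
# herbal medicine: (1) combined-classifier prediction, (2) name match
# against a herb-induced liver injury (HILI) reference list, (3) lookup in
# a herb-hepatotoxic-ingredient bipartite network; integrated by union with
# per-ingredient provenance.

#' Herb-ingredient bipartite network
#'
#' @param edges Data frame with columns `herb` and `ingredient`; both sides
#'   are name-normalized on construction, and all queries are normalized
#'   too, so lookups are case/spacing/hyphen-insensitive.
#' @return A `herb_ingredient_network`.
#' @export
herb_ingredient_network <- function(edges) {
  edges <- as_tibble(edges)
  if (!all(c("herb", "ingredient") %in% names(edges))) {
    abort_data("network edge list requires 'herb' and 'ingredient' columns")
  }
  edges <- distinct(tibble(herb = normalize_name(edges$herb),
                           ingredient = normalize_name(edges$ingredient)))
  if (any(edges$herb == edges$ingredient)) {
    abort_data("self-loop in herb-ingredient network")
  }
  structure(list(edges = edges,
                 n_herbs = length(unique(edges$herb)),
                 n_ingredients = length(unique(edges$ingredient))),
            class = "herb_ingredient_network")
}

#' @export
print.herb_ingredient_network <- function(x, ...) {
  cat(sprintf("<herb_ingredient_network> %d herbs, %d ingredients, %d edges\n",
              x$n_herbs, x$n_ingredients, nrow(x$edges)))
  invisible(x)
}

#' Read a herb-ingredient network from a TSV edge list
#'
#' Expects two tab-separated columns, `herb<TAB>ingredient`, with or
#' without a header line.
#'
#' @param path TSV path.
#' @return A `herb_ingredient_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) abort_data(paste0("file not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("herb", "ingredient") %in% names(df))) {
    # headerless form
    df <- readr::read_tsv(path, col_names = c("herb", "ingredient"),
                          col_types = "cc", progress = FALSE)
  }
  herb_ingredient_network(df)
}

#' HILI reference set
#'
#' A deduplicated set of normalized ingredient names with documented
#' herb-induced liver injury, with optional source citations.
#'
#' @param names Character vector of ingredient names.
#' @param source Optional citation vector aligned with `names`.
#' @return A `hili_dataset`.
#' @export
hili_dataset <- function(names, source = NULL) {
  nm <- normalize_name(names)
  keep <- !duplicated(nm)
  structure(list(names = nm[keep],
                 source = if (is.null(source)) NULL else source[keep]),
            class = "hili_dataset")
}

#' Read a HILI list from CSV (`name[,source]`)
#' @param path CSV path.
#' @return A `hili_dataset`.
#' @export
read_hili <- function(path) {
  if (!file.exists(path)) abort_data(paste0("file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!"name" %in% names(df)) {
    abort_data("HILI table requires a 'name' column")
  }
  hili_dataset(df$name, df$source)
}

#' Subgroup 1: classifier-predicted hepatotoxicants
#'
#' Featurizable ingredients are scored by the combined classifier;
#' ingredients with predicted hepatotoxicity probability strictly above
#' `threshold` form the subgroup. Ingredients without a usable structure
#' are excluded here with a notice (the name-based channels still cover
#' them) and listed in the `"excluded"` attribute.
#'
#' @param ingredients Compound tibble of the medicine's ingredients.
#' @param model A `stacked_classifier`.
#' @param fms Named list of feature matrices for the featurizable
#'   ingredients, covering every base family.
#' @param threshold Strict probability cutoff (default 0.500).
#' @return Character vector of normalized ingredient names, with
#'   attributes `"probabilities"` (tibble) and `"excluded"`.
#' @export
screen_subgroup1 <- function(ingredients, model, fms, threshold = 0.500) {
  fms <- as_fms(fms)
  scored_ids <- fms[[1]]$compound_id
  excluded <- ingredients$compound_id[!ingredients$compound_id %in%
                                        scored_ids]
  if (length(excluded) > 0) {
    inform(paste0(length(excluded), " ingredient(s) without usable ",
                  "structures excluded from classifier screening"))
  }
  pr <- predict_stacked(model, fms)
  pr <- left_join(pr,
                  tibble(compound_id = ingredients$compound_id,
                         name = normalize_name(ingredients$name)),
                  by = "compound_id")
  hits <- pr$name[pr$probability > threshold]
  structure(sort(unique(hits)),
            probabilities = pr, excluded = excluded)
}

#' Subgroup 2: HILI-list name matches
#'
#' Exact intersection of the normalized ingredient names with the HILI
#' reference set; no fuzzy matching.
#'
#' @param ingredients Compound tibble.
#' @param hili A [hili_dataset()].
#' @return Character vector of normalized matching names.
#' @export
screen_subgroup2 <- function(ingredients, hili) {
  nm <- normalize_name(ingredients$name)
  sort(unique(intersect(nm, hili$names)))
}

#' Subgroup 3: network neighbors of the herb
#'
#' Looks up the herb node (query normalized) and returns its hepatotoxic
#' ingredient neighbors. An absent herb yields an empty set with a notice,
#' not an error.
#'
#' @param herb Herb name (e.g. the pinyin name used as the network key).
#' @param net A [herb_ingredient_network()].
#' @return Character vector of normalized ingredient names.
#' @export
screen_subgroup3 <- function(herb, net) {
  h <- normalize_name(herb)
  hits <- net$edges$ingredient[net$edges$herb == h]
  if (length(hits) == 0 && !h %in% net$edges$herb) {
    inform(paste0("herb not found in network: ", h))
  }
  sort(unique(hits))
}

#' Integrate the three screening subgroups
#'
#' Union with duplicate removal, plus per-ingredient provenance (which
#' channels found it) and per-subgroup unique contributions. Commutative
#' and idempotent in its set arguments.
#'
#' @param s1,s2,s3 Normalized ingredient-name sets from the classifier,
#'   HILI, and network channels.
#' @return A `screening_result`: `table` (tibble `ingredient`, `in_s1`,
#'   `in_s2`, `in_s3`, `provenance`), `union`, `subgroup_sizes`,
#'   `unique_counts`.
#' @export
integrate_subgroups <- function(s1, s2, s3) {
  s1 <- unique(s1); s2 <- unique(s2); s3 <- unique(s3)
  u <- sort(unique(c(s1, s2, s3)))
  table <- tibble(
    ingredient = u,
    in_s1 = u %in% s1, in_s2 = u %in% s2, in_s3 = u %in% s3
  )
  table$provenance <- purrr::pmap_chr(
    table[c("in_s1", "in_s2", "in_s3")],
    function(in_s1, in_s2, in_s3) {
      paste(c("classifier", "hili", "network")[c(in_s1, in_s2, in_s3)],
            collapse = "+")
    })
  uniq <- c(
    s1 = sum(table$in_s1 & !table$in_s2 & !table$in_s3),
    s2 = sum(table$in_s2 & !table$in_s1 & !table$in_s3),
    s3 = sum(table$in_s3 & !table$in_s1 & !table$in_s2)
  )
  structure(list(table = table, union = u,
                 subgroup_sizes = c(s1 = length(s1), s2 = length(s2),
                                    s3 = length(s3)),
                 unique_counts = uniq),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    "<screening_result> union %d (subgroups %d/%d/%d; unique %d/%d/%d)\n",
    length(x$union), x$subgroup_sizes[["s1"]], x$subgroup_sizes[["s2"]],
    x$subgroup_sizes[["s3"]], x$unique_counts[["s1"]],
    x$unique_counts[["s2"]], x$unique_counts[["s3"]]))
  invisible(x)
}

#' Write a screening result as CSV + JSON reports
#'
#' @param res A `screening_result`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_screening_result <- function(res, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    readr::write_csv(res$table, csv_path, progress = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(union = res$union,
           subgroup_sizes = as.list(res$subgroup_sizes),
           unique_counts = as.list(res$unique_counts)),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(csv_path, json_path))
}

#' Hierarchical clustering of ingredient feature spectra
#'
#' Agglomerative clustering on Euclidean distance (binary features treated
#' as 0/1 reals), cut into `n_groups` non-empty groups. The linkage is a
#' recorded parameter (average by default); deterministic.
#'
#' @param fm A `feature_matrix` of the ingredients.
#' @param n_groups Number of groups to cut the tree into (<= n).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A list: `groups` (named integer vector by compound id),
#'   `tree` (the `hclust` merge tree), `linkage`.
#' @export
cluster_ingredients <- function(fm, n_groups, linkage = "average") {
  x <- fm_values(fm)
  if (nrow(x) < 2) abort_data("clustering requires at least 2 ingredients")
  if (n_groups > nrow(x)) {
    abort_data("n_groups cannot exceed the number of ingredients")
  }
  tree <- hclust(dist(x, method = "euclidean"), method = linkage)
  groups <- cutree(tree, k = n_groups)
  names(groups) <- fm$compound_id
  list(groups = groups, tree = tree, linkage = linkage)
}
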