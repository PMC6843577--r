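# Workflow orchestration: resolved run configuration, the end-to-end
# modeling pipeline (featurize -> select -> sweep -> stack -> validate),
# and the screening workflow. A thin command-line wrapper over these
# functions ships in inst/cli/hepascreen.

.CONFIG_DEFAULTS <- list(
  paths = list(compounds = NULL, out_dir = "hepascreen_run",
               features_dir = NULL),
  families = c("FP", "MACCSFP", "Desc2D"),
  learners = ALGORITHMS,
  selection = list(correlation_cutoff = 0.90, boruta_max_iter = 50,
                   boruta_alpha = 0.05, num_trees = 150),
  cv = list(k = 10, seed = 1),
  ensemble = list(meta_feature_mode = "out_of_fold"),
  tune_learners = FALSE,
  yrand_runs = 0,
  synthetic = NULL,
  screening = list(threshold = 0.500, herb = NULL, network = NULL,
                   hili = NULL, no_classifier = FALSE, s1_override = NULL),
  log_level = "info"
)

#' Resolve a run configuration
#'
#' Merges user settings (a YAML file path or a nested list) over the
#' package defaults; unknown top-level keys are rejected. Every pipeline
#' run writes its resolved configuration next to its outputs so runs are
#' replayable.
#'
#' @param config Path to a YAML file, a list, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(config = NULL) {
  user <- if (is.null(config)) list() else if (is.character(config)) {
    yaml::read_yaml(config)
  } else if (is.list(config)) config else {
    abort_config("config must be a YAML path or a list")
  }
  unknown <- setdiff(names(user), names(.CONFIG_DEFAULTS))
  if (length(unknown) > 0) {
    abort_config(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")))
  }
  structure(modifyList(.CONFIG_DEFAULTS, user), class = "run_config")
}

# per-family input matrices: synthetic generation (independent structure
# per family, shared labels) or featurization of a compound table
pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    sargs <- cfg$synthetic
    base_seed <- sargs$seed %||% cfg$cv$seed
    labels <- NULL
    fms <- list()
    for (i in seq_along(cfg$families)) {
      fam <- cfg$families[i]
      vk <- family_info(fam)$value_kind
      fam_args <- modifyList(sargs, list(value_kind = vk,
                                         seed = base_seed + i))
      if (vk == "binary" && !is.null(fam_args$effect_size)) {
        # translate a continuous mean shift d into the bit-probability gap
        # a threshold at 0 on the shifted Gaussian would induce
        fam_args$effect_size <- 2 * stats::pnorm(fam_args$effect_size / 2) - 1
      }
      sp <- do.call(synth_spec, fam_args)
      gen <- make_classification_set(sp)
      if (is.null(labels)) {
        labels <- gen$labels
      } else {
        # all families share one label vector: the generator draws the same
        # class counts under a fixed class_balance, so rows of this family
        # are realigned class-by-class to the first family's labels
        perm <- integer(sp$n)
        perm[labels == .POS] <- which(gen$labels == .POS)
        perm[labels == .NEG] <- which(gen$labels == .NEG)
        gen$features <- fm_slice(gen$features, perm)
        gen$features$compound_id <- fms[[1]]$compound_id
      }
      attr(gen$features, "family") <- fam
      fms[[fam]] <- gen$features
    }
    return(list(fms = fms, labels = labels, compounds = NULL))
  }
  if (is.null(cfg$paths$compounds)) {
    abort_config("config needs either paths$compounds or a synthetic block")
  }
  ds <- read_compounds(cfg$paths$compounds, "csv")
  backend <- if (!is.null(cfg$paths$features_dir)) {
    backend_precomputed(cfg$paths$features_dir)
  } else backend_hashed()
  fms <- lapply(setNames(cfg$families, cfg$families), function(fam) {
    compute_features(ds, fam, backend)
  })
  list(fms = fms, labels = ds$label[ds$parse_ok], compounds = ds)
}

#' Run the combined-classifier pipeline end to end
#'
#' Featurizes (or synthesizes) per-family matrices, runs the selection
#' cascade per family (hygiene filter, all-relevant selection, correlation
#' pruning, RFE ranking), sweeps nested subsets per (family, learner),
#' picks each learner's best family and subset, optionally grid-tunes each
#' winner, fits the stacked combined classifier, cross-validates it, and
#' writes all artifacts (sweep tables, chosen subsets, metrics JSON,
#' resolved config) under `out_dir`.
#'
#' @param config Passed to [run_config()].
#' @return Invisibly, a list: `stacked`, `cv`, `sweeps`, `bases`, `fms`,
#'   `labels`, `out_dir`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- run_config(config)
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "resolved_config.yaml"))

  inputs <- pipeline_inputs(cfg)
  labels <- inputs$labels
  seed <- cfg$cv$seed
  scfg <- do.call(selection_config,
                  c(cfg$selection, list(seed = seed)))

  selected <- list()
  for (fam in names(inputs$fms)) {
    fm <- drop_degenerate(inputs$fms[[fam]])
    bor <- boruta_select(fm, labels, scfg)
    if (length(bor$confirmed) == 0) next
    fm2 <- fm_select(fm, bor$confirmed)
    kept <- if (length(bor$confirmed) > 1) {
      correlation_prune(fm2, scfg$correlation_cutoff)
    } else bor$confirmed
    fm3 <- fm_select(fm2, kept)
    ranking <- rfe_rank(fm3, labels, scfg)
    selected[[fam]] <- list(fm = fm3, ranking = ranking)
  }
  if (length(selected) == 0) {
    abort_model("no family retained any confirmed features")
  }

  sweeps <- list()
  best_per_learner <- list()
  for (alg in cfg$learners) {
    spec <- learner_spec(alg, seed = seed)
    fam_results <- lapply(names(selected), function(fam) {
      subset_sweep(selected[[fam]]$fm, labels, selected[[fam]]$ranking,
                   spec, k_folds = cfg$cv$k, seed = seed)
    })
    names(fam_results) <- names(selected)
    sweeps[[alg]] <- fam_results
    scores <- vapply(fam_results, function(s) {
      max(s$table$score, na.rm = TRUE)
    }, numeric(1))
    best_fam <- names(which.max(scores))
    best <- fam_results[[best_fam]]
    best_spec <- spec
    if (isTRUE(cfg$tune_learners)) {
      grid <- default_grids()[[alg]]
      if (!is.null(grid)) {
        tuned <- tune(spec, fm_select(selected[[best_fam]]$fm,
                                      best$best_features),
                      labels, grid, k_folds = cfg$cv$k, seed = seed)
        best_spec <- tuned$best_spec
      }
    }
    best_per_learner[[alg]] <- base_recipe(best_spec, best_fam,
                                           best$best_features)
    readr::write_csv(best$table,
                     file.path(out_dir, paste0("sweep_", alg, ".csv")),
                     progress = FALSE)
  }

  fms_sel <- lapply(selected, `[[`, "fm")
  stacked <- fit_stacked(best_per_learner, fms_sel, labels,
                         mode = cfg$ensemble$meta_feature_mode,
                         seed = seed)
  recipe <- stacked_recipe(best_per_learner,
                           mode = cfg$ensemble$meta_feature_mode,
                           seed = seed)
  cv <- cross_validate(recipe, fms_sel, labels, k = cfg$cv$k, seed = seed)
  yr <- NULL
  if (cfg$yrand_runs > 0) {
    yr <- y_randomization(recipe, fms_sel, labels, runs = cfg$yrand_runs,
                          k = cfg$cv$k, seed = seed)
  }

  m <- cv$metrics
  jsonlite::write_json(
    list(acc = m$acc, auc = m$auc, se = m$se, sp = m$sp, bacc = m$bacc,
         seed = seed, k = cfg$cv$k,
         mode = cfg$ensemble$meta_feature_mode,
         yrand = if (is.null(yr)) NULL else
           list(mean = yr$mean, sd = yr$sd, runs = yr$runs),
         bases = lapply(best_per_learner, function(b) {
           list(algorithm = b$spec$algorithm, family = b$family,
                n_features = length(b$features))
         })),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  readr::write_csv(cv$predictions, file.path(out_dir, "cv_predictions.csv"),
                   progress = FALSE)
  invisible(list(stacked = stacked, cv = cv, yrand = yr, sweeps = sweeps,
                 bases = best_per_learner, fms = fms_sel, labels = labels,
                 out_dir = out_dir))
}

#' Run the three-channel screening workflow
#'
#' Applies the three screening channels to an ingredient table and
#' integrates them. Channel 1 (classifier) can be supplied as a fitted
#' stacked model plus feature matrices, as a precomputed name set
#' (`s1_override`, e.g. from an earlier prediction run), or disabled
#' (`no_classifier = TRUE`, leaving subgroup 1 empty).
#'
#' @param ingredients Compound tibble of the medicine's ingredients.
#' @param herb Herb name queried against the network.
#' @param network A [herb_ingredient_network()].
#' @param hili A [hili_dataset()].
#' @param model Optional `stacked_classifier` for channel 1.
#' @param fms Optional feature matrices for `model`.
#' @param s1_override Optional precomputed subgroup-1 name set.
#' @param no_classifier Disable channel 1.
#' @param threshold Strict probability cutoff for channel 1.
#' @param out_dir Optional directory for the CSV/JSON reports.
#' @return A `screening_result`.
#' @export
run_screen <- function(ingredients, herb, network, hili,
                       model = NULL, fms = NULL, s1_override = NULL,
                       no_classifier = FALSE, threshold = 0.500,
                       out_dir = NULL) {
  s1 <- if (no_classifier) {
    character(0)
  } else if (!is.null(s1_override)) {
    normalize_name(s1_override)
  } else if (!is.null(model)) {
    screen_subgroup1(ingredients, model, fms, threshold = threshold)
  } else {
    abort_config(paste0("channel 1 needs a model, an s1_override set, ",
                        "or no_classifier = TRUE"))
  }
  s2 <- screen_subgroup2(ingredients, hili)
  s3 <- screen_subgroup3(herb, network)
  res <- integrate_subgroups(s1, s2, s3)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_screening_result(res,
                           csv_path = file.path(out_dir, "screening.csv"),
                           json_path = file.path(out_dir, "screening.json"))
  }
  res
}

#' Reproduce the published training-set workflow from a compound table
#'
#' Runs the complete published workflow on a drug-induced liver injury
#' training table (CSV with columns `id,name,smiles,label`): featurization
#' of all thirteen families, the selection cascade, the per-learner subset
#' sweep over all eight algorithms, the stacked combined classifier with
#' resubstitution meta-features, 10-fold cross-validation, and (optionally)
#' Y-randomization. This is the entry point for reproducing the reference
#' cross-validation results when the original training compounds are
#' available as a local file; nothing is downloaded.
#'
#' @param compounds_csv Path to the training compound table.
#' @param out_dir Output directory for artifacts.
#' @param yrand_runs Y-randomization runs (0 to skip).
#' @param seed Seed for partitions and learners.
#' @return The [run_pipeline()] result list.
#' @export
reproduce_training_cv <- function(compounds_csv,
                                  out_dir = "dili_reproduction",
                                  yrand_runs = 0, seed = 1L) {
  if (!file.exists(compounds_csv)) {
    abort_data(paste0("training compound table not found: ", compounds_csv,
                      " (supply the published training set as ",
                      "id,name,smiles,label CSV)"))
  }
  run_pipeline(list(
    paths = list(compounds = compounds_csv, out_dir = out_dir),
    families = descriptor_families$family,
    learners = ALGORITHMS,
    ensemble = list(meta_feature_mode = "resubstitution"),
    cv = list(k = 10, seed = seed),
    yrand_runs = yrand_runs
  ))
}
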