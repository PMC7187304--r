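# Pipeline orchestration: declarative config, the two-phase workflow
# (train, apply), and battery persistence.  All randomness flows from
# one global seed through named per-stage substreams, so the split, CV
# folds, SMOTE and forests are independently reproducible.

# Hash of the scientifically relevant configuration (output locations
# excluded, so reruns into different directories compare equal).
config_hash <- function(config) {
  config <- unclass(config)
  config$output_dir <- NULL
  hash_ints(utf8ToInt(paste(deparse(config), collapse = "")))
}

#' Read and validate a pipeline configuration
#'
#' The configuration is one declarative YAML file.  Recognized keys:
#' `library` + `library_format` (`smiles_table`/`csv`/`sdf`/`raw_csv`),
#' `scores` (long score CSV), `structures` (CSV with `structure_id`,
#' `cocrystal_ligand_smiles` — needed by the similarity method),
#' `output_dir`, `fingerprint` (`kind`, `radius`, `n_bits`), `split`
#' (`test_fraction`), `grid` (`"default"` to grid-search, absent to use
#' the default forest), `rf` (`n_estimators`, `max_features`),
#' `cv_folds`, `smote_k`, `ef_fractions`, `similarity_cutoffs`,
#' `methods`, `seed`.  Referenced paths are checked at validation time;
#' a broken configuration fails before any compute.
#'
#' @param path YAML file path.
#' @return Validated config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config a config list built in code.
#' @export
validate_pipeline_config <- function(config) {
  defaults <- list(
    library_format = "smiles_table",
    fingerprint = list(kind = "hashed_circular", radius = 2, n_bits = 1024),
    split = list(test_fraction = 0.2),
    rf = default_battery_config(),
    cv_folds = 10,
    smote_k = 5,
    ef_fractions = c(0.01, 0.05, 0.10),
    similarity_cutoffs = c(0.8, 0.7),
    methods = c("aladdin", "ensemble", "similarity"),
    seed = 1
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      config[[k]] <- utils::modifyList(defaults[[k]], as.list(config[[k]]))
    }
  }
  if (is.null(config[["library"]])) stop("config: 'library' path is required")
  if (is.null(config[["scores"]])) stop("config: 'scores' path is required")
  for (k in c("library", "scores", "structures")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      stop("config: path for '", k, "' does not exist: ", config[[k]])
    }
  }
  bad <- setdiff(config$methods, c("aladdin", "ensemble", "similarity", "single"))
  if (length(bad)) stop("config: unknown method(s): ", paste(bad, collapse = ", "))
  if ("similarity" %in% config$methods && is.null(config$structures) &&
      config$fingerprint$kind != "raw") {
    stop("config: method 'similarity' requires a 'structures' file with ",
         "co-crystal ligand SMILES")
  }
  class(config) <- c("pipeline_config", "list")
  config
}

read_library_any <- function(config) {
  if (identical(config$library_format, "raw_csv")) {
    read_raw_library_csv(config$library)
  } else {
    lib <- read_compound_library(config$library, format = config$library_format)
    featurize(lib, kind = config$fingerprint$kind,
              radius = config$fingerprint$radius,
              n_bits = config$fingerprint$n_bits)
  }
}

#' Run the training phase
#'
#' Executes the training workflow on a validated config: load and
#' featurize the library, load the docking score matrix, split 80:20
#' (stratified, seeded), derive per-structure correctness labels on the
#' training compounds, optionally grid-search the forest configuration,
#' train the SMOTE-balanced classifier battery, and persist the battery
#' with a manifest recording the fingerprint configuration, selected
#' hyperparameters, per-structure label balance, CV results, seeds and
#' the config hash.
#'
#' @param config a validated [read_pipeline_config()] list.
#' @return List of class `training_result`: `battery`, `library`,
#'   `split`, `labels`, `matrix`, `cv`, `config`.
#' @export
run_training_phase <- function(config) {
  config <- validate_pipeline_config(unclass(config))
  seed <- config$seed
  library <- read_library_any(config)
  matrix <- read_score_csv(config$scores)
  unknown <- setdiff(compound_ids(library), rownames(matrix))
  if (length(unknown)) {
    stop("training: compounds without docking scores: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  split <- split_train_test(library, config$split$test_fraction, seed = seed)
  train_ids <- split$compound_id[split$split == "train"]
  train <- subset_library(library, train_ids)
  train_matrix <- score_matrix(unclass(matrix)[train_ids, , drop = FALSE])
  labels <- label_structures(train_matrix, activity_classes(library))

  cv <- NULL
  rf_config <- config$rf
  if (identical(config$grid, "default")) {
    cv <- grid_search_cv(compound_features(train), labels,
                         grid = default_hyper_grid(),
                         k_folds = config$cv_folds,
                         seed = stage_seed(seed, "grid"))
    rf_config <- cv$config
  }
  battery <- train_battery(compound_features(train), labels,
                           config = rf_config,
                           seed = stage_seed(seed, "battery"),
                           smote_k = config$smote_k, cv = cv,
                           feature_kind = library$feature_kind,
                           feature_params = config$fingerprint)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    save_battery(battery, file.path(config$output_dir, "battery"),
                 extra = list(seed = seed, config_hash = config_hash(config)))
    write_labels_csv(labels, file.path(config$output_dir, "labels.csv"))
    utils::write.csv(split, file.path(config$output_dir, "split.csv"),
                     row.names = FALSE)
  }
  structure(list(battery = battery, library = library, split = split,
                 labels = labels, matrix = matrix, cv = cv, config = config),
            class = "training_result")
}

#' Run the application phase
#'
#' Screens the held-out test set (and its training-set-dissimilar
#' subsets at the configured Tanimoto cutoffs) with every requested
#' method, and evaluates each screen with AUC and enrichment factors.
#' Battery/config fingerprint mismatches are a hard error.
#'
#' @param training a [run_training_phase()] result (or a list with
#'   `battery`, `library`, `split`, `matrix`, `config`).
#' @param cocrystal_fps optional co-crystal fingerprints overriding the
#'   config's `structures` file (used by the synthetic path).
#' @return List of class `application_result`: per subset (`test`,
#'   `subset_0.8`, ...) a named list of [eval_report()]s, plus
#'   `screens`, `diagnostics` for selection methods, and `subsets`
#'   (compound id lists).
#' @export
run_application_phase <- function(training, cocrystal_fps = NULL) {
  config <- training$config
  battery <- training$battery
  if (!is.null(battery) &&
      !identical(battery$feature_kind, training$library$feature_kind)) {
    stop("battery fingerprint kind (", battery$feature_kind,
         ") does not match the library's (", training$library$feature_kind, ")")
  }
  cls <- activity_classes(training$library)
  test_ids <- training$split$compound_id[training$split$split == "test"]
  train_ids <- training$split$compound_id[training$split$split == "train"]
  test <- subset_library(training$library, test_ids)
  train <- subset_library(training$library, train_ids)

  if (is.null(cocrystal_fps) && !is.null(config$structures)) {
    st <- utils::read.csv(config$structures, stringsAsFactors = FALSE)
    stopifnot(all(c("structure_id", "cocrystal_ligand_smiles") %in% names(st)))
    has <- !is.na(st$cocrystal_ligand_smiles) & nzchar(st$cocrystal_ligand_smiles)
    if (any(has)) {
      cocrystal_fps <- smiles_fingerprint(st$cocrystal_ligand_smiles[has],
                                          radius = config$fingerprint$radius,
                                          n_bits = config$fingerprint$n_bits)
      rownames(cocrystal_fps) <- st$structure_id[has]
    }
  }

  subsets <- list(test = test)
  for (cutoff in config$similarity_cutoffs) {
    subsets[[paste0("subset_", cutoff)]] <-
      filter_test_by_train_similarity(test, train, cutoff)
  }
  ensemble_ids <- if (!is.null(battery)) names(battery$models)
                  else colnames(training$matrix)

  results <- list()
  screens <- list()
  diagnostics <- list()
  for (sub_name in names(subsets)) {
    sub <- subsets[[sub_name]]
    if (length(sub) == 0 ||
        length(unique(activity_classes(sub))) < 2) next
    reports <- list()
    for (method in config$methods) {
      scr <- run_screen(method, sub, matrix = training$matrix,
                        battery = battery, cocrystal_fps = cocrystal_fps,
                        structure_id = config$single_structure,
                        structure_ids = ensemble_ids)
      reports[[method]] <- eval_report(scr$hits, cls, method = scr$method,
                                       ef_fractions = config$ef_fractions)
      if (sub_name == "test") {
        screens[[method]] <- scr
        if (method %in% c("aladdin", "similarity")) {
          diagnostics[[method]] <- selection_diagnostics(scr$assignments, cls)
        }
      }
    }
    results[[sub_name]] <- reports
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_csv(results, file.path(config$output_dir, "metrics.csv"))
  }
  structure(list(reports = results, screens = screens,
                 diagnostics = diagnostics,
                 subsets = lapply(subsets, compound_ids)),
            class = "application_result")
}

#' Export evaluation reports as CSV
#'
#' Flattens nested per-subset, per-method [eval_report()]s into one
#' metrics table (`subset`, `method`, `auc`, one column per EF
#' fraction, `n_actives`, `n_decoys`).
#'
#' @param results nested list of reports (subset -> method).
#' @param path output CSV path.
#' @export
write_report_csv <- function(results, path) {
  rows <- list()
  for (sub_name in names(results)) {
    for (r in results[[sub_name]]) {
      row <- data.frame(subset = sub_name, method = r$method, auc = r$auc,
                        n_actives = r$n_actives, n_decoys = r$n_decoys,
                        stringsAsFactors = FALSE)
      for (nm in names(r$ef)) row[[nm]] <- r$ef[[nm]]
      rows[[length(rows) + 1]] <- row
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Persist and restore a classifier battery
#'
#' A battery directory holds the per-structure model blobs
#' (`models.rds`) and a human-readable `manifest.yaml` with the forest
#' configuration, fingerprint settings, dropped structures, CV summary
#' and any extra metadata (seeds, config hash).
#'
#' @param battery a [train_battery()] result.
#' @param dir directory to create/read.
#' @param extra named list merged into the manifest.
#' @return `save_battery()` the directory, invisibly; `load_battery()`
#'   the battery.
#' @export
save_battery <- function(battery, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(battery, file.path(dir, "models.rds"))
  manifest <- c(list(
    format_version = 1L,
    n_structures = length(battery$models),
    structure_ids = names(battery$models),
    dropped = battery$dropped,
    config = battery$config,
    feature_kind = battery$feature_kind,
    feature_params = battery$feature_params,
    n_features = battery$n_features,
    cv_mean_mcc = if (!is.null(battery$cv)) battery$cv$mean_mcc,
    cv_sd_mcc = if (!is.null(battery$cv)) battery$cv$sd_mcc
  ), extra)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname save_battery
#' @export
load_battery <- function(dir) {
  f <- file.path(dir, "models.rds")
  if (!file.exists(f)) stop("no battery found in ", dir)
  readRDS(f)
}

#' Write and read synthetic datasets as plain text
#'
#' `write_synthetic_dataset()` materializes one synthetic benchmark
#' draw as three CSV files under `dir`: `library.csv` (compound id,
#' activity class and the feature vector as a bit string),
#' `scores.csv` (the long score-matrix dialect of
#' [write_score_csv()]), and `truth.csv` (the planted cluster and
#' compatible structure per compound).  `read_raw_library_csv()` loads
#' such a library back as a featurized [compound_library()].
#'
#' @param spec a [synthetic_bench_spec()].
#' @param dir output directory.
#' @param seed optional seed override.
#' @param path a `library.csv` written by `write_synthetic_dataset()`.
#' @export
write_synthetic_dataset <- function(spec, dir, seed = spec$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_library(spec, seed = seed)
  matrix <- simulate_scores(spec, gen$library, gen$truth, seed = seed)
  feats <- compound_features(gen$library)
  utils::write.csv(data.frame(
    compound_id = compound_ids(gen$library),
    activity_class = unname(activity_classes(gen$library)),
    features = apply(feats, 1, paste, collapse = ""),
    stringsAsFactors = FALSE
  ), file.path(dir, "library.csv"), row.names = FALSE)
  write_score_csv(matrix, file.path(dir, "scores.csv"))
  utils::write.csv(gen$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_synthetic_dataset
#' @export
read_raw_library_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(features = "character"))
  stopifnot(all(c("compound_id", "activity_class", "features") %in% names(df)))
  bits <- strsplit(df$features, "")
  n_bits <- unique(lengths(bits))
  if (length(n_bits) != 1) stop("inconsistent feature vector lengths")
  feats <- matrix(as.integer(unlist(bits)), nrow = nrow(df), byrow = TRUE,
                  dimnames = list(df$compound_id, NULL))
  compound_library(df$compound_id, df$activity_class, features = feats,
                   feature_kind = "raw")
}
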