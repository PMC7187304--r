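# Per-structure correctness classifiers: cross-validated grid search,
# SMOTE-balanced final fits, and structure selection.

#' Random-forest configuration and hyperparameter grid
#'
#' `default_rf_config()` is the package's default forest setup (100
#' trees, `sqrt` feature subsampling) — a mid-grid setting that keeps
#' cross-validation and scrambling diagnostics fast;
#' `default_battery_config()` is the default for the final
#' per-structure probability forests (500 trees, `sqrt`, minimum leaf
#' size 50): the larger forest and leaves stabilize the predicted
#' correctness *probabilities* that drive structure selection, which
#' need to be well calibrated rather than merely on the right side of
#' 0.5.  `default_hyper_grid()` enumerates the full search space:
#' 50/100/500 trees crossed with maximum-feature choices `sqrt`, 0.2,
#' 0.4, 0.6, 0.8 and `all`.
#'
#' @param n_estimators number of trees.
#' @param max_features `"sqrt"`, `"all"`, or a fraction in (0, 1\].
#' @param min_node_size minimum terminal node size (`NULL` = the forest
#'   engine's default); larger leaves give lower-variance probability
#'   estimates.
#' @return `default_rf_config()` a named list; `default_hyper_grid()` a
#'   data frame of grid cells in tie-break order (smaller forests
#'   first, `sqrt` first).
#' @export
default_rf_config <- function(n_estimators = 100, max_features = "sqrt",
                              min_node_size = NULL) {
  list(n_estimators = n_estimators, max_features = max_features,
       min_node_size = min_node_size)
}

#' @rdname default_rf_config
#' @export
default_battery_config <- function() {
  default_rf_config(n_estimators = 500, max_features = "sqrt",
                    min_node_size = 50)
}

#' @rdname default_rf_config
#' @export
default_hyper_grid <- function() {
  expand.grid(
    max_features = c("sqrt", "0.2", "0.4", "0.6", "0.8", "all"),
    n_estimators = c(50, 100, 500),
    stringsAsFactors = FALSE
  )[, c("n_estimators", "max_features")]
}

# Translate a max_features choice into ranger's mtry.
mtry_from_max_features <- function(max_features, p) {
  if (identical(max_features, "sqrt")) return(max(1L, floor(sqrt(p))))
  if (max_features %in% c("all", "none", "None")) return(p)
  f <- suppressWarnings(as.numeric(max_features))
  if (is.na(f) || f <= 0 || f > 1) stop("invalid max_features: ", max_features)
  max(1L, floor(f * p))
}

# ranger needs named covariates; feature matrices get canonical bit
# names so training and prediction always line up.
name_features <- function(features) {
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  features
}

# One probability forest fit.  `class_weights = TRUE` weights classes
# inversely proportional to their frequencies (the CV setting); the
# final battery fits instead rebalance via SMOTE and fit unweighted.
fit_rf <- function(features, labels, config, seed, class_weights = FALSE) {
  features <- name_features(features)
  y <- factor(labels, levels = c("correct", "incorrect"))
  cw <- NULL
  if (class_weights) {
    freq <- table(y)
    cw <- as.numeric(length(y) / (length(freq) * freq))
    names(cw) <- names(freq)
  }
  args <- list(
    x = features, y = y,
    num.trees = config$n_estimators,
    mtry = mtry_from_max_features(config$max_features, ncol(features)),
    probability = TRUE,
    class.weights = cw,
    seed = seed,
    num.threads = 1
  )
  if (!is.null(config$min_node_size)) args$min.node.size <- config$min_node_size
  do.call(ranger::ranger, args)
}

predict_rf <- function(model, features) {
  p <- stats::predict(model, data = name_features(features),
                      num.threads = 1)$predictions
  p[, "correct"]
}

#' Cross-validated MCC of one forest configuration
#'
#' Stratified k-fold cross-validation of a correctness classifier:
#' per fold, a class-weighted random forest is fit on the remaining
#' folds and the held-out compounds are classified (probability of
#' "correct" thresholded at 0.5); the Matthews correlation coefficient
#' is computed per fold and averaged.
#'
#' @param features numeric feature matrix.
#' @param labels `"correct"`/`"incorrect"` labels (vector or
#'   `correctness_labels`).
#' @param config see [default_rf_config()].
#' @param k_folds number of folds (default 10).
#' @param seed integer seed (folds and forests are both seeded).
#' @return List with `mean_mcc`, `sd_mcc`, `fold_mcc`.
#' @export
cv_mcc <- function(features, labels, config = default_rf_config(),
                   k_folds = 10, seed = 1) {
  if (inherits(labels, "correctness_labels")) {
    labels <- stats::setNames(labels$label, labels$compound_id)[rownames(features)]
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(features))
  fold <- stratified_folds(labels, k_folds, stage_seed(seed, "folds"))
  fold_mcc <- numeric(k_folds)
  for (k in seq_len(k_folds)) {
    tr <- fold != k
    model <- fit_rf(features[tr, , drop = FALSE], labels[tr], config,
                    seed = stage_seed(seed, paste0("fold", k)),
                    class_weights = TRUE)
    prob <- predict_rf(model, features[!tr, , drop = FALSE])
    # inverse-frequency class weighting at prediction time: rescale the
    # leaf probabilities so the weighted class prior is 1:1 (the forest
    # engine's class weights enter the split search only), then
    # classify at 1/2
    prior <- mean(labels[tr] == "correct")
    odds <- (prob / prior) / ((1 - prob) / (1 - prior))
    pred <- ifelse(odds >= 1, "correct", "incorrect")
    fold_mcc[k] <- mcc(pred, labels[!tr], positive = "correct")
  }
  list(mean_mcc = mean(fold_mcc), sd_mcc = stats::sd(fold_mcc),
       fold_mcc = fold_mcc)
}

#' Grid search for the forest configuration
#'
#' Evaluates every grid cell by [cv_mcc()] and returns the cell with
#' the highest fold-averaged MCC.  Cells are visited in tie-break order
#' (fewer trees first, then `sqrt` features first), so exact ties
#' resolve toward the simpler model.  When `labels` is a list of
#' per-structure label sets, each cell's score is the MCC averaged over
#' all structures' classifiers and one global configuration is selected
#' for the whole battery.
#'
#' @param features numeric feature matrix.
#' @param labels labels as in [cv_mcc()], or a named list of them (one
#'   per structure).
#' @param grid data frame of cells, see [default_hyper_grid()].
#' @param k_folds CV folds.
#' @param seed integer seed.
#' @return List with `config` (selected), `mean_mcc`, `sd_mcc`, and
#'   `table` (per-cell results).
#' @export
grid_search_cv <- function(features, labels, grid = default_hyper_grid(),
                           k_folds = 10, seed = 1) {
  stopifnot(nrow(grid) >= 1)
  label_sets <- if (is.list(labels) && !inherits(labels, "correctness_labels") &&
                    !is.data.frame(labels)) labels else list(labels)
  res <- grid
  res$mean_mcc <- NA_real_
  res$sd_mcc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- list(n_estimators = grid$n_estimators[i],
                max_features = grid$max_features[i])
    per_struct <- vapply(seq_along(label_sets), function(j) {
      cv_mcc(features, label_sets[[j]], cfg, k_folds = k_folds,
             seed = stage_seed(seed, paste0("grid", i, "s", j)))$mean_mcc
    }, 1)
    res$mean_mcc[i] <- mean(per_struct)
    res$sd_mcc[i] <- if (length(per_struct) > 1) stats::sd(per_struct) else NA_real_
  }
  best <- which.max(res$mean_mcc)  # first max = tie-break order
  list(config = list(n_estimators = res$n_estimators[best],
                     max_features = res$max_features[best]),
       mean_mcc = res$mean_mcc[best], sd_mcc = res$sd_mcc[best],
       table = res)
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a binary training set by synthesizing minority-class
#' samples: each synthetic sample interpolates between a random
#' minority sample and one of its `k` nearest minority neighbors
#' (Euclidean), at a uniform random position along the segment.  Used
#' for the battery's final fits (the cross-validation fits use class
#' weighting instead).
#'
#' @param features numeric feature matrix.
#' @param labels binary label vector aligned with rows.
#' @param k number of nearest neighbors (default 5, capped at
#'   minority size - 1).
#' @param seed integer seed.
#' @return List with balanced `features` and `labels`; synthetic rows
#'   are appended after the originals.
#' @export
smote_balance <- function(features, labels, k = 5, seed = 1) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2) stop("SMOTE requires exactly two classes")
  minority <- names(tab)[which.min(tab)]
  n_new <- max(tab) - min(tab)
  if (n_new == 0) return(list(features = features, labels = labels))
  idx <- which(labels == minority)
  X_min <- features[idx, , drop = FALSE]
  k <- min(k, nrow(X_min) - 1)
  if (k < 1) stop("minority class too small for SMOTE (need >= 2 samples)")
  d <- as.matrix(stats::dist(X_min))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  synth <- with_seed(stage_seed(seed, "smote"), {
    base_i <- sample(nrow(X_min), n_new, replace = TRUE)
    nb_i <- nn[cbind(base_i, sample(k, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    X_min[base_i, , drop = FALSE] +
      u * (X_min[nb_i, , drop = FALSE] - X_min[base_i, , drop = FALSE])
  })
  rownames(synth) <- paste0("synthetic_", minority, "_", seq_len(n_new))
  list(features = rbind(features, synth),
       labels = c(labels, rep(minority, n_new)))
}

#' Train the per-structure classifier battery
#'
#' Fits one binary random-forest correctness classifier per protein
#' structure, all with one global configuration.  Each structure's
#' training labels are first rebalanced with [smote_balance()] (the
#' final-fit counterpart of the class-weighted CV fits), then a
#' probability forest is fit.  Structures whose labels are single-class
#' (degenerate docking columns) are dropped from the battery with a
#' warning and recorded in `dropped`.
#'
#' @param features numeric feature matrix of the training compounds
#'   (rownames = compound ids).
#' @param labels_by_structure named list of `correctness_labels` (one
#'   per structure, from [label_structures()]).
#' @param config forest configuration (default [default_rf_config()]),
#'   e.g. the output of [grid_search_cv()].
#' @param seed integer seed.
#' @param smote_k SMOTE neighbor count (default 5).
#' @param cv optional CV metadata (stored verbatim in the battery).
#' @param feature_kind,feature_params fingerprint configuration stored
#'   for compatibility checks at prediction time.
#' @return An object of class `classifier_battery`.
#' @export
train_battery <- function(features, labels_by_structure,
                          config = default_battery_config(), seed = 1,
                          smote_k = 5, cv = NULL,
                          feature_kind = "raw", feature_params = list()) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  models <- list()
  dropped <- character(0)
  for (sid in names(labels_by_structure)) {
    l <- labels_by_structure[[sid]]
    lab <- stats::setNames(l$label, l$compound_id)[rownames(features)]
    if (anyNA(lab)) stop("labels for structure ", sid,
                         " do not cover the training compounds")
    if (length(unique(lab)) < 2) {
      warning("structure ", sid, " has single-class labels; dropped from battery")
      dropped <- c(dropped, sid)
      next
    }
    bal <- smote_balance(features, lab, k = smote_k,
                         seed = stage_seed(seed, paste0("smote_", sid)))
    models[[sid]] <- fit_rf(bal$features, bal$labels, config,
                            seed = stage_seed(seed, paste0("fit_", sid)),
                            class_weights = FALSE)
  }
  if (!length(models)) stop("no structure yielded two-class labels; battery empty")
  structure(list(
    models = models[order(names(models))],
    config = config,
    feature_kind = feature_kind,
    feature_params = feature_params,
    dropped = dropped,
    cv = cv,
    n_features = ncol(features)
  ), class = "classifier_battery")
}

#' @export
print.classifier_battery <- function(x, ...) {
  cat("<classifier_battery> ", length(x$models), " structures (",
      length(x$dropped), " dropped); forest: ", x$config$n_estimators,
      " trees, max_features = ", x$config$max_features,
      "; features: ", x$feature_kind, "/", x$n_features, "\n", sep = "")
  invisible(x)
}

#' Predicted correctness probabilities
#'
#' Presents each compound to every classifier of the battery and
#' returns the probability of the "correctly predicted" class per
#' retained structure.
#'
#' @param battery a [train_battery()] result.
#' @param features feature matrix of the query compounds, featurized
#'   with the battery's fingerprint configuration.
#' @return Numeric matrix (compounds x structures) of probabilities in
#'   \[0, 1\]; columns in lexicographic structure order.
#' @export
predict_probabilities <- function(battery, features) {
  stopifnot(inherits(battery, "classifier_battery"))
  features <- as.matrix(features)
  if (ncol(features) != battery$n_features) {
    stop("feature length ", ncol(features), " does not match the battery's ",
         battery$n_features)
  }
  probs <- vapply(battery$models, function(m) predict_rf(m, features),
                  numeric(nrow(features)))
  if (nrow(features) == 1) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(rownames(features),
                                                           names(battery$models)))
  rownames(probs) <- rownames(features)
  probs
}

# Argmax over columns with deterministic lexicographic tie-break: the
# columns are sorted by id, and which.max takes the first maximum.
argmax_by_structure <- function(stat_matrix) {
  sids <- sort(colnames(stat_matrix))
  m <- stat_matrix[, sids, drop = FALSE]
  picked <- sids[apply(m, 1, which.max)]
  stats::setNames(picked, rownames(stat_matrix))
}

#' Structure selection
#'
#' `select_structure_aladdin()` picks, per compound, the structure
#' whose correctness classifier returns the highest probability.
#' `select_structure_similarity()` is the similarity baseline: it picks
#' the structure whose co-crystallized ligand is most similar (Tanimoto
#' on binary fingerprints) to the compound.  Both break exact ties by
#' lexicographic structure id.
#'
#' @param probabilities matrix (compounds x structures) from
#'   [predict_probabilities()], or a single named vector.
#' @param features query compound fingerprint matrix.
#' @param cocrystal_fps binary fingerprint matrix of the structures'
#'   co-crystallized ligands (rownames = structure ids); structures
#'   without a co-crystal ligand are simply absent.
#' @return Named character vector of selected structure ids; attribute
#'   `statistic` carries the winning probability / Tanimoto per
#'   compound.
#' @export
select_structure_aladdin <- function(probabilities) {
  if (is.null(dim(probabilities))) {
    probabilities <- matrix(probabilities, nrow = 1,
                            dimnames = list("query", names(probabilities)))
  }
  if (!ncol(probabilities)) stop("empty probability vector")
  sel <- argmax_by_structure(probabilities)
  attr(sel, "statistic") <- probabilities[cbind(seq_len(nrow(probabilities)),
                                                match(sel, colnames(probabilities)))]
  sel
}

#' @rdname select_structure_aladdin
#' @export
select_structure_similarity <- function(features, cocrystal_fps) {
  if (is.null(cocrystal_fps) || nrow(cocrystal_fps) == 0) {
    stop("no structure has a co-crystallized ligand; similarity selection impossible")
  }
  tc <- tanimoto_matrix(as.matrix(features), cocrystal_fps)
  sel <- argmax_by_structure(tc)
  attr(sel, "statistic") <- tc[cbind(seq_len(nrow(tc)),
                                     match(sel, colnames(tc)))]
  sel
}
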