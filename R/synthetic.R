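# Synthetic docking benchmark: seeded generator of compound libraries
# and docking-score matrices with planted compound-structure
# compatibility.  It emulates the two statistical facts a
# structure-selection method exploits: (i) docking success is compound-
# and structure-dependent (each compound cluster has one compatible
# structure on which its actives score well), and (ii) decoys pick up
# spuriously favorable scores on random structures, which inflates
# their best-over-structures ensemble score.

#' Synthetic benchmark specification
#'
#' Parameters of the simulated screening campaign.  Compounds are
#' abstract binary feature vectors grouped into `n_clusters` chemotype
#' clusters; a planted map assigns each cluster one compatible protein
#' structure.  Actives bind strongly (affinity `mu_active`) on their
#' compatible structure and at baseline (`mu_base`) elsewhere; each
#' (decoy, structure) pair independently acquires a spurious affinity
#' `mu_spurious` with probability `p_spurious`.  Docking scores are
#' `-affinity + N(0, sigma)`, lower = more favorable.
#'
#' @param n_structures number of protein structures S (default 10).
#' @param n_clusters number of compound clusters K (default 10); with
#'   the default one-to-one map K must not exceed S.
#' @param n_actives,n_decoys library composition (defaults 200 / 2000).
#' @param n_bits feature vector length (default 1024).
#' @param n_signature_bits signature bits per cluster (default 40).
#' @param p_sig_in,p_sig_out,p_background bit-set probabilities for a
#'   cluster's own signature bits (0.9), other clusters' signature bits
#'   (0.05), and background bits (0.02).
#' @param mu_active affinity of an active on its compatible structure
#'   (default 4.0, in score units).
#' @param mu_base baseline affinity (default 0.0).
#' @param p_spurious per-(decoy, structure) spurious-affinity
#'   probability (default 0.05).
#' @param mu_spurious spurious affinity magnitude (default 3.0).
#' @param sigma docking-score noise SD (default 1.0).
#' @param seed integer seed driving all generation.
#' @param cluster_map integer vector mapping cluster k to a structure
#'   index (default the identity `1:n_clusters`); supply a many-to-one
#'   map when `n_clusters > n_structures`.
#' @return An object of class `synthetic_bench_spec`.
#' @export
synthetic_bench_spec <- function(n_structures = 10, n_clusters = 10,
                                 n_actives = 200, n_decoys = 2000,
                                 n_bits = 1024, n_signature_bits = 40,
                                 p_sig_in = 0.9, p_sig_out = 0.05,
                                 p_background = 0.02,
                                 mu_active = 4.0, mu_base = 0.0,
                                 p_spurious = 0.05, mu_spurious = 3.0,
                                 sigma = 1.0, seed = 7,
                                 cluster_map = NULL) {
  counts <- c(n_structures, n_clusters, n_actives, n_decoys, n_bits,
              n_signature_bits)
  if (any(counts < 1)) stop("all counts must be positive")
  probs <- c(p_sig_in, p_sig_out, p_background, p_spurious)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (sigma < 0) stop("sigma must be non-negative")
  if (n_signature_bits * n_clusters > n_bits) {
    stop("not enough bits for ", n_clusters, " disjoint cluster signatures")
  }
  if (is.null(cluster_map)) {
    if (n_clusters > n_structures) {
      stop("n_clusters > n_structures requires an explicit many-to-one cluster_map")
    }
    cluster_map <- seq_len(n_clusters)
  }
  stopifnot(length(cluster_map) == n_clusters,
            all(cluster_map >= 1), all(cluster_map <= n_structures))
  structure(list(
    n_structures = n_structures, n_clusters = n_clusters,
    n_actives = n_actives, n_decoys = n_decoys, n_bits = n_bits,
    n_signature_bits = n_signature_bits, p_sig_in = p_sig_in,
    p_sig_out = p_sig_out, p_background = p_background,
    mu_active = mu_active, mu_base = mu_base, p_spurious = p_spurious,
    mu_spurious = mu_spurious, sigma = sigma, seed = seed,
    cluster_map = cluster_map
  ), class = "synthetic_bench_spec")
}

synthetic_structure_ids <- function(spec) {
  sprintf("S%02d", seq_len(spec$n_structures))
}

#' Generate a synthetic compound library with planted truth
#'
#' Draws the compound library of a [synthetic_bench_spec()]: each
#' compound is assigned a cluster uniformly at random (actives and
#' decoys alike, so features carry no activity signal), and its binary
#' feature vector is drawn from the cluster's bit-pattern model
#' (disjoint signature bit blocks per cluster, plus sparse background
#' bits).  Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_bench_spec()].
#' @param seed optional seed override (defaults to `spec$seed`).
#' @return List with `library` (a featurized [compound_library()] of
#'   abstract compounds, feature kind `"raw"`) and `truth` (data frame
#'   `compound_id`, `cluster`, `structure_id` — the planted compatible
#'   structure per compound).
#' @export
generate_library <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_bench_spec"))
  n <- spec$n_actives + spec$n_decoys
  ids <- c(sprintf("A%04d", seq_len(spec$n_actives)),
           sprintf("D%04d", seq_len(spec$n_decoys)))
  cls <- rep(c("active", "decoy"), c(spec$n_actives, spec$n_decoys))
  sids <- synthetic_structure_ids(spec)

  out <- with_seed(stage_seed(seed, "library"), {
    cluster <- sample(spec$n_clusters, n, replace = TRUE)
    sig_positions <- matrix(
      sample(spec$n_bits, spec$n_clusters * spec$n_signature_bits),
      nrow = spec$n_clusters
    )
    p_bit <- matrix(spec$p_background, spec$n_clusters, spec$n_bits)
    for (k in seq_len(spec$n_clusters)) {
      p_bit[, sig_positions[k, ]] <- spec$p_sig_out
    }
    for (k in seq_len(spec$n_clusters)) {
      p_bit[k, sig_positions[k, ]] <- spec$p_sig_in
    }
    features <- matrix(0L, n, spec$n_bits, dimnames = list(ids, NULL))
    for (k in seq_len(spec$n_clusters)) {
      members <- which(cluster == k)
      if (!length(members)) next
      draws <- matrix(
        stats::rbinom(length(members) * spec$n_bits, 1, rep(p_bit[k, ],
                                                            each = length(members))),
        nrow = length(members)
      )
      features[members, ] <- draws
    }
    list(cluster = cluster, features = features)
  })

  library <- compound_library(ids, cls, features = out$features,
                              feature_kind = "raw")
  truth <- data.frame(
    compound_id = ids,
    cluster = out$cluster,
    structure_id = sids[spec$cluster_map[out$cluster]],
    stringsAsFactors = FALSE
  )
  list(library = library, truth = truth)
}

#' Simulate a docking score matrix with planted compatibility
#'
#' Scores every (compound, structure) pair under the synthetic docking
#' model: `score = -affinity + N(0, sigma)` where the latent affinity
#' is `mu_active` for an active on its planted compatible structure,
#' `mu_spurious` with probability `p_spurious` for a (decoy, structure)
#' pair (independently per pair), and `mu_base` otherwise.
#' Deterministic given the seed; the latent affinities are returned in
#' the `affinity` attribute.
#'
#' @param spec a [synthetic_bench_spec()].
#' @param library,truth output of [generate_library()].
#' @param seed optional seed override (defaults to `spec$seed`).
#' @return A [score_matrix()] (compounds x structures) with attribute
#'   `affinity`.
#' @export
simulate_scores <- function(spec, library, truth, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_bench_spec"))
  ids <- compound_ids(library)
  stopifnot(identical(ids, truth$compound_id))
  cls <- activity_classes(library)
  sids <- synthetic_structure_ids(spec)
  n <- length(ids); S <- length(sids)

  affinity <- matrix(spec$mu_base, n, S, dimnames = list(ids, sids))
  scores <- with_seed(stage_seed(seed, "scores"), {
    is_decoy <- cls == "decoy"
    if (any(is_decoy)) {
      spurious <- matrix(stats::rbinom(sum(is_decoy) * S, 1, spec$p_spurious),
                         nrow = sum(is_decoy))
      block <- affinity[is_decoy, , drop = FALSE]
      block[spurious == 1] <- spec$mu_spurious
      affinity[is_decoy, ] <- block
    }
    is_active <- cls == "active"
    affinity[cbind(which(is_active),
                   match(truth$structure_id[is_active], sids))] <- spec$mu_active
    noise <- matrix(stats::rnorm(n * S, 0, spec$sigma), n, S)
    -affinity + noise
  })
  out <- score_matrix(scores, ids, sids)
  attr(out, "affinity") <- affinity
  out
}

#' Pick synthetic co-crystal ligands for the similarity baseline
#'
#' The similarity baseline needs one "co-crystallized ligand" per
#' structure.  On synthetic data this is emulated by sampling, for each
#' structure, one training compound from its compatible cluster; the
#' returned fingerprints play the role of the co-crystal ligand
#' fingerprints.  Structures with no compatible cluster get no ligand
#' and are absent from the result.
#'
#' @param spec a [synthetic_bench_spec()].
#' @param library,truth output of [generate_library()].
#' @param train_ids compound ids eligible as ligands (the training
#'   set).
#' @param seed optional seed override.
#' @return Binary matrix of ligand fingerprints, rownames = structure
#'   ids.
#' @export
synthetic_cocrystal_fps <- function(spec, library, truth,
                                    train_ids = compound_ids(library),
                                    seed = spec$seed) {
  sids <- synthetic_structure_ids(spec)
  feats <- compound_features(library)
  truth_train <- truth[truth$compound_id %in% train_ids, ]
  rows <- with_seed(stage_seed(seed, "cocrystal"), {
    lapply(seq_along(sids), function(s) {
      pool <- truth_train$compound_id[
        spec$cluster_map[truth_train$cluster] == s]
      if (!length(pool)) return(NULL)
      pick <- pool[sample.int(length(pool), 1)]
      feats[pick, , drop = FALSE]
    })
  })
  keep <- !vapply(rows, is.null, TRUE)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- sids[keep]
  out
}

#' Run the full comparative benchmark on synthetic data
#'
#' End-to-end pipeline on one generated dataset: generate library and
#' score matrix, split 80:20 stratified, derive per-structure
#' correctness labels on the training compounds, train the classifier
#' battery (optionally grid-searching the forest configuration), screen
#' the test set with all four protocols, and evaluate each with
#' AUC and enrichment factors.  Also reports the planted-structure
#' recovery rate (fraction of test actives whose selected structure is
#' their planted compatible structure) and the structure-selection
#' diagnostics.
#'
#' @param spec a [synthetic_bench_spec()].
#' @param seed seed override (defaults to `spec$seed`).
#' @param config forest configuration used when `grid` is `NULL`
#'   (default [default_battery_config()]).
#' @param grid optional hyperparameter grid; when supplied,
#'   [grid_search_cv()] selects the configuration by structure-averaged
#'   CV MCC before training.
#' @param test_fraction held-out fraction (default 0.2).
#' @param ef_fractions enrichment fractions (default 1%, 5%, 10%).
#' @return List of class `synthetic_benchmark` with elements `reports`
#'   (named list of [eval_report()]s for `aladdin`, `ensemble`,
#'   `similarity`), `single_auc` (named per-structure AUC vector),
#'   `mean_single_auc`, `recovery` (planted-structure recovery on test
#'   actives), `diagnostics` (from [selection_diagnostics()]),
#'   `battery`, `labels`, `split`, `screens`, and the `spec`.
#' @export
benchmark_methods <- function(spec, seed = spec$seed,
                              config = default_battery_config(), grid = NULL,
                              test_fraction = 0.2,
                              ef_fractions = c(0.01, 0.05, 0.10)) {
  gen <- generate_library(spec, seed = seed)
  library <- gen$library
  truth <- gen$truth
  matrix <- simulate_scores(spec, library, truth, seed = seed)

  split <- split_train_test(library, test_fraction = test_fraction,
                            seed = stage_seed(seed, "bench_split"))
  train_ids <- split$compound_id[split$split == "train"]
  test_ids <- split$compound_id[split$split == "test"]
  train <- subset_library(library, train_ids)
  test <- subset_library(library, test_ids)
  cls <- activity_classes(library)

  train_matrix <- score_matrix(unclass(matrix)[train_ids, , drop = FALSE])
  labels <- label_structures(train_matrix, cls)

  cv <- NULL
  if (!is.null(grid)) {
    cv <- grid_search_cv(compound_features(train), labels, grid = grid,
                         seed = stage_seed(seed, "bench_grid"))
    config <- cv$config
  }
  battery <- train_battery(compound_features(train), labels, config = config,
                           seed = stage_seed(seed, "bench_battery"),
                           cv = cv, feature_kind = library$feature_kind)

  cocrystal <- synthetic_cocrystal_fps(spec, library, truth,
                                       train_ids = train_ids, seed = seed)
  ensemble_ids <- names(battery$models)

  screens <- list(
    aladdin = run_screen("aladdin", test, matrix = matrix, battery = battery,
                         structure_ids = ensemble_ids),
    ensemble = run_screen("ensemble", test, matrix = matrix,
                          structure_ids = ensemble_ids),
    similarity = run_screen("similarity", test, matrix = matrix,
                            cocrystal_fps = cocrystal,
                            structure_ids = ensemble_ids)
  )
  reports <- lapply(screens, function(s) {
    eval_report(s$hits, cls, method = s$method, ef_fractions = ef_fractions)
  })

  single_auc <- vapply(ensemble_ids, function(sid) {
    s <- run_screen("single", test, matrix = matrix, structure_id = sid,
                    structure_ids = ensemble_ids)
    roc_auc(s$hits, cls)$auc
  }, 1)

  sel <- screens$aladdin$assignments
  test_actives <- test_ids[cls[test_ids] == "active"]
  planted <- stats::setNames(truth$structure_id, truth$compound_id)
  recovery <- mean(sel$structure_id[match(test_actives, sel$compound_id)] ==
                     planted[test_actives])

  structure(list(
    spec = spec, seed = seed, split = split, labels = labels,
    battery = battery, screens = screens, reports = reports,
    single_auc = single_auc, mean_single_auc = mean(single_auc),
    recovery = recovery,
    diagnostics = selection_diagnostics(sel, cls),
    truth = truth
  ), class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat("<synthetic_benchmark> S = ", x$spec$n_structures, ", ",
      x$spec$n_actives, " actives / ", x$spec$n_decoys, " decoys\n", sep = "")
  for (r in x$reports) {
    cat(sprintf("  %-10s AUC %.3f  EF5%% %.2f\n", r$method, r$auc,
                r$ef[["EF5%"]]))
  }
  cat(sprintf("  mean single-structure AUC %.3f\n", x$mean_single_auc))
  cat(sprintf("  planted-structure recovery (test actives): %.2f\n",
              x$recovery))
  invisible(x)
}
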