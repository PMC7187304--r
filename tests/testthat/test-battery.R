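test_that("cross-validated MCC separates signal from null", {
  set.seed(21)
  X <- matrix(rbinom(100 * 30, 1, 0.4), 100, 30)
  rownames(X) <- sprintf("c%03d", 1:100)
  cfg <- default_rf_config(n_estimators = 50)
  # labels perfectly determined by one feature bit
  y_sep <- ifelse(X[, 7] == 1, "correct", "incorrect")
  expect_gt(cv_mcc(X, y_sep, cfg, k_folds = 5, seed = 1)$mean_mcc, 0.95)
  # labels independent of the features
  y_null <- sample(rep(c("correct", "incorrect"), 50))
  expect_lt(abs(cv_mcc(X, y_null, cfg, k_folds = 5, seed = 1)$mean_mcc), 0.25)
})

test_that("grid search picks by fold-averaged MCC with documented tie-breaks", {
  set.seed(22)
  X <- matrix(rbinom(60 * 10, 1, 0.5), 60, 10)
  rownames(X) <- sprintf("c%02d", 1:60)
  y <- ifelse(X[, 3] == 1, "correct", "incorrect")
  grid <- data.frame(n_estimators = c(20, 50),
                     max_features = c("sqrt", "sqrt"),
                     stringsAsFactors = FALSE)
  gs <- grid_search_cv(X, y, grid, k_folds = 5, seed = 3)
  expect_true(all(gs$table$mean_mcc > 0.9))  # separable for every cell
  # near-equal cells resolve toward the earlier (smaller) configuration
  expect_equal(gs$config$n_estimators,
               gs$table$n_estimators[which.max(gs$table$mean_mcc)])
  expect_equal(nrow(gs$table), 2)
})

test_that("the default grid enumerates the documented search space", {
  g <- default_hyper_grid()
  expect_equal(nrow(g), 18)
  expect_setequal(unique(g$n_estimators), c(50, 100, 500))
  expect_setequal(unique(g$max_features),
                  c("sqrt", "0.2", "0.4", "0.6", "0.8", "all"))
  # tie-break order: smaller forests first, sqrt first within a size
  expect_equal(g$n_estimators[1], 50)
  expect_equal(g$max_features[1], "sqrt")
  p <- 1024
  expect_equal(mtry_from_max_features("sqrt", p), 32)
  expect_equal(mtry_from_max_features("0.2", p), 204)
  expect_equal(mtry_from_max_features("all", p), p)
  expect_error(mtry_from_max_features("bogus", p), "max_features")
})

test_that("SMOTE balances classes by seeded minority interpolation", {
  set.seed(23)
  X <- matrix(rnorm(100 * 5), 100, 5)
  rownames(X) <- sprintf("c%03d", 1:100)
  y <- rep(c("correct", "incorrect"), c(90, 10))
  bal <- smote_balance(X, y, k = 5, seed = 4)
  expect_equal(unname(table(bal$labels)["correct"]),
               unname(table(bal$labels)["incorrect"]))
  # synthetic rows interpolate minority samples: stay in their bounding box
  synth <- bal$features[-(1:100), , drop = FALSE]
  mins <- apply(X[91:100, ], 2, min); maxs <- apply(X[91:100, ], 2, max)
  expect_true(all(t(synth) >= mins - 1e-9))
  expect_true(all(t(synth) <= maxs + 1e-9))
  expect_identical(bal$features, smote_balance(X, y, k = 5, seed = 4)$features)
  # already balanced input passes through untouched
  bal2 <- smote_balance(X[1:20, ], rep(c("a", "b"), 10))
  expect_equal(nrow(bal2$features), 20)
})

test_that("battery training drops degenerate structures and predicts in [0,1]", {
  spec <- small_spec(seed = 5)
  gen <- generate_library(spec)
  m <- simulate_scores(spec, gen$library, gen$truth)
  cls <- activity_classes(gen$library)
  labels <- label_structures(m, cls)
  X <- compound_features(gen$library)
  cfg <- default_rf_config(n_estimators = 50)
  battery <- train_battery(X, labels, cfg, seed = 6)
  expect_s3_class(battery, "classifier_battery")
  expect_equal(names(battery$models), sort(names(labels)))

  probs <- predict_probabilities(battery, X[1:20, , drop = FALSE])
  expect_equal(dim(probs), c(20, spec$n_structures))
  expect_true(all(probs >= 0 & probs <= 1))
  # deterministic given the trained battery
  expect_identical(probs, predict_probabilities(battery, X[1:20, , drop = FALSE]))

  # a single-class (degenerate) structure is dropped with a warning
  single <- labels
  single[["S01"]]$label <- "correct"
  expect_warning(b2 <- train_battery(X, single, cfg, seed = 6), "single-class")
  expect_false("S01" %in% names(b2$models))
  expect_equal(b2$dropped, "S01")

  # two identical score columns give two classifiers with identical labels
  m_dup <- score_matrix(cbind(unclass(m)[, "S01", drop = FALSE],
                              SDU = unclass(m)[, "S01"]))
  lab_dup <- label_structures(m_dup, cls)
  expect_equal(lab_dup[["S01"]]$label, lab_dup[["SDU"]]$label)
})

test_that("structure selection takes the argmax with lexicographic ties", {
  expect_equal(as.character(select_structure_aladdin(c(S1 = 0.9, S2 = 0.4))), "S1")
  expect_equal(as.character(select_structure_aladdin(c(S2 = 0.5, S1 = 0.5))), "S1")
  u <- setNames(rep(0.37, 30), sprintf("S%02d", 30:1))
  expect_equal(as.character(select_structure_aladdin(u)), "S01")
  expect_error(select_structure_aladdin(numeric(0)), "empty")

  probs <- rbind(c1 = c(SA = 0.2, SB = 0.8), c2 = c(SA = 0.6, SB = 0.1))
  sel <- select_structure_aladdin(probs)
  expect_equal(as.character(sel), c("SB", "SA"))
  expect_equal(unname(attr(sel, "statistic")), c(0.8, 0.6))
})

test_that("similarity selection picks the most similar co-crystal ligand", {
  fps <- rbind(q = c(1, 1, 1, 1, 0, 0))
  coc <- rbind(S1 = c(1, 0, 0, 0, 1, 1),   # Tc = 1/6
               S2 = c(1, 1, 1, 0, 0, 0),   # Tc = 3/4
               S3 = c(1, 1, 0, 0, 1, 0))   # Tc = 2/5
  sel <- select_structure_similarity(fps, coc)
  expect_equal(as.character(sel), "S2")
  expect_equal(unname(attr(sel, "statistic")), 0.75)
  # compound identical to one ligand selects that structure with Tc 1
  sel2 <- select_structure_similarity(rbind(q = coc["S3", ]), coc)
  expect_equal(as.character(sel2), "S3")
  expect_equal(unname(attr(sel2, "statistic")), 1)
  # all ligands identical: first structure by tie-break
  same <- rbind(S2 = c(1, 1, 0), S1 = c(1, 1, 0))
  expect_equal(as.character(select_structure_similarity(rbind(q = c(1, 1, 0)), same)),
               "S1")
  expect_error(select_structure_similarity(fps, NULL), "co-crystal")
})
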