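test_that("ROC AUC matches the pairwise concordance oracle, including ties", {
  tc <- toy_column()
  r <- roc_auc(rank_compounds(toy_matrix(), "S1"), tc$classes)
  expect_equal(r$auc, 6 / 9)
  expect_equal(r$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))

  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    n_act <- sample(1:(n - 1), 1)
    ids <- sprintf("c%02d", 1:n)
    classes <- setNames(sample(rep(c("active", "decoy"), c(n_act, n - n_act))), ids)
    scores <- setNames(sample(round(rnorm(n), 1)), ids)  # ties likely
    got <- roc_auc(scores, classes)$auc
    expect_equal(got, brute_force_auc(scores, classes), tolerance = 1e-12)
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  set.seed(4)
  for (i in 1:5) {
    ids <- sprintf("c%02d", 1:60)
    classes <- setNames(rep(c("active", "decoy"), c(20, 40)), ids)
    scores <- setNames(round(rnorm(60) - 0.8 * (classes == "active"), 1), ids)
    ref <- suppressMessages(pROC::auc(
      response = factor(classes, levels = c("decoy", "active")),
      predictor = scores, direction = ">"))
    expect_equal(roc_auc(scores, classes)$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("degenerate ROC inputs are rejected and extremes are exact", {
  classes <- c(a = "active", b = "active", d1 = "decoy", d2 = "decoy")
  perfect <- c(a = -9, b = -8, d1 = -2, d2 = -1)
  expect_equal(roc_auc(perfect, classes)$auc, 1)
  expect_error(roc_auc(c(a = -1, b = -2), c(a = "active", b = "active")),
               "both classes")
})

test_that("enrichment factors follow the ceiling-top-set definition", {
  tc <- toy_column()
  hits <- rank_compounds(toy_matrix(), "S1")
  # top 2 of 6 holds A1 and D1: active rate 1/2 equals the base rate
  expect_equal(enrichment_factor(hits, tc$classes, 1 / 3), 1)
  # all actives at the top and the top set all active: maximal N/N_actives
  ids <- c("A1", "A2", "D1", "D2", "D3", "D4", "D5", "D6", "D7", "D8")
  classes <- setNames(rep(c("active", "decoy"), c(2, 8)), ids)
  scores <- setNames(seq(-10, -1), ids)
  expect_equal(enrichment_factor(scores, classes, 0.2), 10 / 2)
  # invariance under monotone score transforms
  expect_equal(enrichment_factor(exp(scores), classes, 0.2),
               enrichment_factor(scores, classes, 0.2))
  expect_error(enrichment_factor(scores, classes, 0), "fraction")
  # EF bounds: 0 <= EF_f <= min(1/f, N/N_actives)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:40, 1); n_act <- sample(1:(n - 1), 1)
    idr <- sprintf("x%02d", 1:n)
    cl <- setNames(sample(rep(c("active", "decoy"), c(n_act, n - n_act))), idr)
    sc <- setNames(rnorm(n), idr)
    f <- runif(1, 0.05, 1)
    ef <- enrichment_factor(sc, cl, f)
    expect_gte(ef, 0)
    expect_lte(ef, min(1 / f, n / n_act) + 1e-12)
  }
})

test_that("MCC matches the closed form with the zero-denominator convention", {
  truth <- rep(c("correct", "incorrect"), c(6, 4))
  expect_equal(mcc(truth, truth, positive = "correct"), 1)
  flipped <- ifelse(truth == "correct", "incorrect", "correct")
  expect_equal(mcc(flipped, truth, positive = "correct"), -1)
  # TP=4 TN=3 FP=1 FN=2
  truth2 <- rep(c("correct", "incorrect"), c(6, 4))
  pred2 <- c(rep("correct", 4), rep("incorrect", 2),
             "correct", rep("incorrect", 3))
  expect_equal(mcc(pred2, truth2, positive = "correct"),
               (4 * 3 - 1 * 2) / sqrt(5 * 6 * 5 * 4))
  # all-positive prediction: zero denominator convention
  expect_equal(mcc(rep("correct", 10), truth, positive = "correct"), 0)
})

test_that("selection diagnostics conserve counts and proportions", {
  asg <- data.frame(compound_id = sprintf("c%d", 1:6),
                    structure_id = c("S1", "S1", "S1", "S2", "S2", "S1"))
  classes <- setNames(rep(c("active", "decoy"), 3), sprintf("c%d", 1:6))
  d <- selection_diagnostics(asg, classes)
  expect_equal(sum(d$n), 6)
  expect_true(all(d$active_prop >= 0 & d$active_prop <= 1))
  expect_equal(attr(d, "overall_active_prop"), 0.5)
  # all compounds to one structure: point mass
  asg2 <- transform(asg, structure_id = "S9")
  d2 <- selection_diagnostics(asg2, classes)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$n, 6)
})

test_that("scrambling destroys a separable signal and is seeded", {
  set.seed(8)
  X <- matrix(rbinom(80 * 20, 1, 0.5), 80, 20)
  rownames(X) <- sprintf("c%02d", 1:80)
  y <- ifelse(X[, 1] == 1, "correct", "incorrect")
  cfg <- default_rf_config(n_estimators = 50)
  real <- cv_mcc(X, y, cfg, k_folds = 5, seed = 2)
  expect_gt(real$mean_mcc, 0.9)
  scr <- y_scramble(X, y, cfg, n_repeats = 3, k_folds = 5, seed = 2)
  expect_lt(abs(scr$mean_mcc), 0.25)
  # single repeat with a fixed seed is deterministic
  one <- y_scramble(X, y, cfg, n_repeats = 1, k_folds = 5, seed = 5)
  two <- y_scramble(X, y, cfg, n_repeats = 1, k_folds = 5, seed = 5)
  expect_identical(one$mean_mcc, two$mean_mcc)
})
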