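# Virtual-screening and classifier metrics.

# Coerce a hit list or a named score vector to (scores, classes) in a
# common form; missing scores become +Inf so failed compounds sit at
# the unfavorable end and tie with each other.
screen_scores <- function(hits) {
  if (inherits(hits, "ranked_hits") || is.data.frame(hits)) {
    s <- stats::setNames(hits$score, hits$compound_id)
  } else {
    s <- hits
  }
  s[is.na(s)] <- Inf
  s
}

#' ROC curve and AUC of a ranked hit list
#'
#' Computes the receiver operating characteristic of a virtual screen:
#' compounds are thresholded by docking score (lower = predicted
#' active), giving one (FPR, TPR) point per distinct score.  The AUC is
#' the trapezoidal integral of that curve, which equals the
#' Mann-Whitney pairwise concordance (ties between an active and a
#' decoy contribute 1/2).
#'
#' @param hits a `ranked_hits` data frame (or named score vector,
#'   lower = better; `NA` = failed docking, ranked worst).
#' @param classes named activity-class vector (`"active"`/`"decoy"`).
#' @return List with `auc` and `points` (data frame `fpr`, `tpr`
#'   starting at (0,0) and ending at (1,1)).
#' @export
roc_auc <- function(hits, classes) {
  s <- screen_scores(hits)
  cls <- classes[names(s)]
  if (anyNA(cls)) stop("activity class missing for some compounds")
  n_act <- sum(cls == "active")
  n_dec <- sum(cls == "decoy")
  if (n_act == 0 || n_dec == 0) stop("both classes required for ROC analysis")
  ord <- order(s)
  s <- s[ord]; cls <- cls[ord]
  # group ties: one ROC vertex per distinct score
  grp <- cumsum(!duplicated(s))
  tp <- tapply(cls == "active", grp, sum)
  fp <- tapply(cls == "decoy", grp, sum)
  tpr <- c(0, cumsum(tp) / n_act)
  fpr <- c(0, cumsum(fp) / n_dec)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = unname(auc),
       points = data.frame(fpr = unname(fpr), tpr = unname(tpr)))
}

#' Enrichment factor at a screening fraction
#'
#' EF_f compares the active rate among the top fraction `f` of the
#' ranked hit list with the library-wide active rate:
#' `EF_f = (actives in top m / m) / (N_actives / N)` with
#' `m = ceiling(f * N)`.  The ceiling guarantees a non-empty top set;
#' because EF values are sensitive to this choice and to library
#' composition, they should not be compared across differently composed
#' libraries.  Ties at the boundary are resolved by the hit list's
#' deterministic ordering.
#'
#' @param hits a `ranked_hits` data frame (or named score vector).
#' @param classes named activity-class vector.
#' @param fraction screening fraction in (0, 1].
#' @return EF value in `[0, N/N_actives]`.
#' @export
enrichment_factor <- function(hits, classes, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  s <- screen_scores(hits)
  cls <- classes[names(s)]
  if (anyNA(cls)) stop("activity class missing for some compounds")
  n <- length(s)
  n_act <- sum(cls == "active")
  if (n_act == 0 || n_act == n) stop("both classes required for enrichment")
  m <- ceiling(fraction * n)
  top <- order(s, names(s))[seq_len(m)]
  (sum(cls[top] == "active") / m) / (n_act / n)
}

#' Matthews correlation coefficient
#'
#' Standard MCC of binary predictions from the 2x2 confusion matrix,
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.  When any
#' marginal is zero the denominator vanishes and the MCC is defined as
#' 0 (no better than chance), the usual convention.
#'
#' @param predicted,truth vectors of binary labels (same coding).
#' @param positive the label treated as positive (default: the first
#'   level encountered in `truth`).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(predicted, truth, positive = NULL) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  positive <- positive %||% truth[1]
  tp <- sum(predicted == positive & truth == positive)
  tn <- sum(predicted != positive & truth != positive)
  fp <- sum(predicted == positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Y-scrambling null check
#'
#' Refits the correctness classifier under permuted labels to verify
#' that its cross-validated performance collapses to chance, excluding
#' spurious correlation.  Each repeat permutes the labels uniformly at
#' random (seeded), reruns the k-fold cross-validation of
#' [cv_mcc()] with the given configuration, and records the
#' fold-averaged MCC; the scrambled mean should round to 0.00.
#'
#' @param features numeric feature matrix (rows = compounds).
#' @param labels character vector of `"correct"`/`"incorrect"` labels
#'   (or a `correctness_labels` data frame).
#' @param config hyperparameter list, see [default_rf_config()].
#' @param n_repeats number of permutations (default 10).
#' @param k_folds CV folds per repeat (default 10).
#' @param seed integer seed.
#' @return List with `mean_mcc`, `sd_mcc` and `per_repeat`.
#' @export
y_scramble <- function(features, labels, config = default_rf_config(),
                       n_repeats = 10, k_folds = 10, seed = 1) {
  if (inherits(labels, "correctness_labels")) {
    labels <- stats::setNames(labels$label, labels$compound_id)[rownames(features)]
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(features))
  reps <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    perm <- with_seed(stage_seed(seed, paste0("scramble", r)),
                      sample(labels))
    cv <- cv_mcc(features, perm, config = config, k_folds = k_folds,
                 seed = stage_seed(seed, paste0("scramble_cv", r)))
    reps[r] <- cv$mean_mcc
  }
  list(mean_mcc = mean(reps), sd_mcc = stats::sd(reps), per_repeat = reps)
}

#' Structure-selection diagnostics
#'
#' Summarizes which structures a selection-based screen picked and how
#' actives and decoys distribute over them: an unbiased selector should
#' not funnel actives to "good" structures and decoys to "bad" ones, so
#' per-structure active proportions should stay close to the
#' library-wide proportion.
#'
#' @param assignments data frame of selection assignments (from
#'   [run_screen()]) with columns `compound_id` and `structure_id`.
#' @param classes named activity-class vector.
#' @return Data frame with one row per selected structure: `n`,
#'   `n_active`, `n_decoy`, `active_prop`; attribute `overall_active_prop`.
#' @export
selection_diagnostics <- function(assignments, classes) {
  cls <- classes[assignments$compound_id]
  if (anyNA(cls)) stop("activity class missing for some compounds")
  sids <- sort(unique(assignments$structure_id))
  rows <- lapply(sids, function(s) {
    sel <- assignments$structure_id == s
    data.frame(structure_id = s,
               n = sum(sel),
               n_active = sum(sel & cls == "active"),
               n_decoy = sum(sel & cls == "decoy"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$active_prop <- out$n_active / out$n
  stopifnot(sum(out$n) == nrow(assignments))
  attr(out, "overall_active_prop") <- mean(cls == "active")
  out
}

#' Evaluation report for one screening method
#'
#' Bundles AUC, ROC points and enrichment factors for one ranked hit
#' list, the per-method unit the comparative benchmark reports.
#'
#' @param hits a `ranked_hits` data frame.
#' @param classes named activity-class vector.
#' @param method method tag stored in the report.
#' @param ef_fractions enrichment fractions (default 1%, 5%, 10%).
#' @return List of class `eval_report`: `method`, `auc`, `roc_points`,
#'   `ef` (named vector), `n_actives`, `n_decoys`.
#' @export
eval_report <- function(hits, classes, method = "screen",
                        ef_fractions = c(0.01, 0.05, 0.10)) {
  roc <- roc_auc(hits, classes)
  ef <- vapply(ef_fractions, function(f) enrichment_factor(hits, classes, f), 1)
  names(ef) <- paste0("EF", ef_fractions * 100, "%")
  cls <- classes[hits$compound_id]
  structure(list(method = method, auc = roc$auc, roc_points = roc$points,
                 ef = ef, n_actives = sum(cls == "active"),
                 n_decoys = sum(cls == "decoy")),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$method, ": AUC = ", sprintf("%.3f", x$auc), "; ",
      paste(names(x$ef), sprintf("%.2f", x$ef), sep = " = ", collapse = ", "),
      " (", x$n_actives, " actives / ", x$n_decoys, " decoys)\n", sep = "")
  invisible(x)
}
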