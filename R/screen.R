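#' Run a virtual screen with one of the four protocols
#'
#' Screens a compound library with one of:
#' \describe{
#'   \item{`aladdin`}{each compound is scored only on the single
#'     structure its correctness classifier battery selects (highest
#'     predicted correctness probability) — one docking call per
#'     compound under a live backend.}
#'   \item{`similarity`}{each compound is scored on the structure with
#'     the most similar co-crystallized ligand (Tanimoto).}
#'   \item{`ensemble`}{classic all-against-all ensemble docking; the
#'     screen score is the best score over all structures.}
#'   \item{`single`}{single-structure docking against `structure_id`.}
#' }
#' Scores come from a precomputed [score_matrix()] (default mode) or
#' from a live [csv_backend()]/[synthetic_backend()]; configuration
#' mismatches (e.g. `aladdin` without a battery) fail before any
#' compound is processed.
#'
#' @param method one of `"aladdin"`, `"similarity"`, `"ensemble"`,
#'   `"single"`.
#' @param library a featurized [compound_library()] (features required
#'   for `aladdin`/`similarity`).
#' @param matrix a [score_matrix()] covering the library (or `NULL`
#'   when a backend is supplied).
#' @param backend a live `dock_backend` (or `NULL`).
#' @param battery a [train_battery()] result (`aladdin` only).
#' @param cocrystal_fps co-crystal ligand fingerprints (`similarity`
#'   only), see [select_structure_similarity()].
#' @param structure_id the structure to dock against (`single` only).
#' @param structure_ids structures making up the ensemble; defaults to
#'   the matrix columns, the backend's structures, or the battery's
#'   retained structures (battery-dropped structures are excluded so
#'   methods are compared on the same ensemble).
#' @return An object of class `screen_result`: list with `method`,
#'   `assignments` (data frame `compound_id`, `method`, `structure_id`,
#'   `statistic`, `score`) and `hits` (a `ranked_hits` data frame).
#' @export
run_screen <- function(method = c("aladdin", "similarity", "ensemble", "single"),
                       library, matrix = NULL, backend = NULL,
                       battery = NULL, cocrystal_fps = NULL,
                       structure_id = NULL, structure_ids = NULL) {
  method <- match.arg(method)
  if (is.null(matrix) && is.null(backend)) {
    stop("either a score matrix or a live backend is required")
  }
  if (method == "aladdin" && is.null(battery)) {
    stop("method 'aladdin' requires a classifier battery")
  }
  if (method == "similarity" && is.null(cocrystal_fps)) {
    stop("method 'similarity' requires co-crystal ligand fingerprints")
  }
  if (method == "single" && is.null(structure_id)) {
    stop("method 'single' requires a structure_id")
  }
  ids <- compound_ids(library)
  if (is.null(structure_ids)) {
    structure_ids <- if (!is.null(battery) && method == "aladdin") {
      names(battery$models)
    } else if (!is.null(matrix)) {
      colnames(matrix)
    } else {
      backend$structure_ids
    }
  }
  structure_ids <- sort(structure_ids)

  get_score <- function(cid, sid) {
    if (!is.null(matrix)) unclass(matrix)[cid, sid] else backend$dock(cid, sid)
  }

  if (method == "aladdin") {
    probs <- predict_probabilities(battery, compound_features(library)[ids, , drop = FALSE])
    sel <- select_structure_aladdin(probs[, intersect(colnames(probs), structure_ids),
                                          drop = FALSE])
    stat <- attr(sel, "statistic")
    scores <- vapply(ids, function(cid) get_score(cid, sel[[cid]]), 1)
    assignments <- data.frame(compound_id = ids, method = "aladdin",
                              structure_id = unname(sel[ids]),
                              statistic = unname(stat[match(ids, names(sel))]),
                              score = unname(scores), stringsAsFactors = FALSE)
  } else if (method == "similarity") {
    fps <- cocrystal_fps[intersect(rownames(cocrystal_fps), structure_ids), ,
                         drop = FALSE]
    sel <- select_structure_similarity(compound_features(library)[ids, , drop = FALSE], fps)
    stat <- attr(sel, "statistic")
    scores <- vapply(ids, function(cid) get_score(cid, sel[[cid]]), 1)
    assignments <- data.frame(compound_id = ids, method = "similarity",
                              structure_id = unname(sel[ids]),
                              statistic = unname(stat[match(ids, names(sel))]),
                              score = unname(scores), stringsAsFactors = FALSE)
  } else if (method == "ensemble") {
    all_scores <- vapply(structure_ids, function(sid) {
      vapply(ids, function(cid) get_score(cid, sid), 1)
    }, numeric(length(ids)))
    if (length(ids) == 1) all_scores <- matrix(all_scores, nrow = 1,
                                               dimnames = list(ids, structure_ids))
    best <- apply(all_scores, 1, function(r) {
      if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE)
    })
    assignments <- data.frame(compound_id = ids, method = "ensemble",
                              structure_id = NA_character_,
                              statistic = NA_real_,
                              score = unname(best), stringsAsFactors = FALSE)
  } else {
    if (!structure_id %in% structure_ids) {
      stop("structure ", structure_id, " not part of the ensemble")
    }
    scores <- vapply(ids, function(cid) get_score(cid, structure_id), 1)
    assignments <- data.frame(compound_id = ids,
                              method = paste0("single:", structure_id),
                              structure_id = structure_id,
                              statistic = NA_real_,
                              score = unname(scores), stringsAsFactors = FALSE)
  }
  hits <- rank_scores(stats::setNames(assignments$score, assignments$compound_id))
  structure(list(method = assignments$method[1], assignments = assignments,
                 hits = hits),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", x$method, ": ", nrow(x$assignments),
      " compounds screened\n", sep = "")
  invisible(x)
}
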