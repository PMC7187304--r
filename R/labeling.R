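#' Rank-based docking correctness labels
#'
#' Converts one structure's rank-ordered hit list into the binary
#' training labels of the structure-selection classifiers: whether the
#' docking protocol predicted each compound *correctly* on that
#' structure.  With `n` the number of active compounds in the ranked
#' set, "high ranks" are ranks `<= n` and the four-way rule is:
#' active at high rank = correct, active at low rank = incorrect,
#' decoy at high rank = incorrect, decoy at low rank = correct.
#'
#' Because exactly `n` compounds occupy the high ranks, the number of
#' misranked actives always equals the number of misranked decoys; this
#' count invariant is asserted on every call.  Labels depend only on
#' ranks, so they are invariant under any strictly monotone transform
#' of the docking scores.  Compounds whose docking failed sit at the
#' end of the hit list (see [rank_compounds()]) and are labeled like
#' any low-ranked compound: failure to dock is information the
#' classifier should learn.
#'
#' @param hits a `ranked_hits` data frame from [rank_compounds()].
#' @param classes named character vector (`"active"`/`"decoy"`) covering
#'   every ranked compound.
#' @param structure_id optional id stored with the label set.
#' @return A `correctness_labels` data frame with columns
#'   `compound_id`, `activity_class`, `rank`, `label`
#'   (`"correct"`/`"incorrect"`), plus attributes `structure_id` and
#'   `n_actives`.
#' @export
assign_correctness_labels <- function(hits, classes, structure_id = NULL) {
  stopifnot(is.data.frame(hits), all(c("compound_id", "rank") %in% names(hits)))
  cls <- classes[hits$compound_id]
  if (anyNA(cls)) {
    stop("activity class missing for: ",
         paste(utils::head(hits$compound_id[is.na(cls)], 5), collapse = ", "))
  }
  n <- sum(cls == "active")
  if (n == 0) stop("no active compounds in the ranked set; rank threshold undefined")
  high <- hits$rank <= n
  active <- cls == "active"
  label <- ifelse(active == high, "correct", "incorrect")
  # threshold-at-n construction: misranked actives == misranked decoys
  stopifnot(sum(active & !high) == sum(!active & high))
  out <- data.frame(
    compound_id = hits$compound_id,
    activity_class = unname(cls),
    rank = hits$rank,
    label = label,
    stringsAsFactors = FALSE
  )
  class(out) <- c("correctness_labels", "data.frame")
  attr(out, "structure_id") <- structure_id
  attr(out, "n_actives") <- n
  out
}

#' Correctness labels for every structure of a score matrix
#'
#' Runs [rank_compounds()] + [assign_correctness_labels()] per
#' structure, typically on the training subset of the score matrix.
#'
#' @param matrix a [score_matrix()] (restrict its rows to the training
#'   compounds first; the rank threshold must live on the same list as
#'   the ranks).
#' @param classes named activity-class vector.
#' @return Named list of `correctness_labels`, one per structure.
#' @export
label_structures <- function(matrix, classes) {
  sids <- colnames(matrix)
  out <- lapply(sids, function(s) {
    assign_correctness_labels(rank_compounds(matrix, s), classes,
                              structure_id = s)
  })
  stats::setNames(out, sids)
}

#' Export correctness labels as CSV
#'
#' Writes `structure_id,compound_id,activity_class,rank,label` rows for
#' one or several label sets.
#'
#' @param labels a `correctness_labels` data frame or a list of them.
#' @param path output CSV path.
#' @export
write_labels_csv <- function(labels, path) {
  if (inherits(labels, "correctness_labels")) labels <- list(labels)
  rows <- do.call(rbind, lapply(labels, function(l) {
    cbind(structure_id = attr(l, "structure_id") %||% NA_character_,
          as.data.frame(l))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
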