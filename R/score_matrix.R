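#' Docking score matrices
#'
#' A `score_matrix` stores docking scores for a compound library against
#' an ensemble of protein structures as a numeric matrix (rows =
#' compounds, columns = structures).  Scores follow binding-free-energy
#' semantics: lower (more negative) is more favorable.  Missing entries
#' (failed docking) are `NA` — never coerced to 0; all stored scores
#' must be finite.
#'
#' @param scores numeric matrix with compound rows and structure
#'   columns, or a value vector matching `compound_ids`/`structure_ids`.
#' @param compound_ids,structure_ids optional dimnames when `scores`
#'   lacks them.
#' @return An object of class `score_matrix` (a numeric matrix with
#'   dimnames).
#' @export
score_matrix <- function(scores, compound_ids = NULL, structure_ids = NULL) {
  scores <- as.matrix(scores)
  if (!is.null(compound_ids)) rownames(scores) <- compound_ids
  if (!is.null(structure_ids)) colnames(scores) <- structure_ids
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("score_matrix needs compound and structure ids")
  }
  if (anyDuplicated(rownames(scores)) || anyDuplicated(colnames(scores))) {
    stop("compound and structure ids must be unique")
  }
  if (any(is.infinite(scores))) stop("scores must be finite or NA")
  storage.mode(scores) <- "double"
  class(scores) <- c("score_matrix", class(scores))
  scores
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> ", nrow(x), " compounds x ", ncol(x),
      " structures; ", sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

#' Collapse per-representation scores to one score per compound
#'
#' A ligand docked as several representations (tautomers/protomers)
#' yields several raw scores per structure; the compound-level score is
#' the most favorable one across representations.  With
#' `favor = "lowest"` (default, free-energy semantics) that is the
#' numerical minimum; `favor = "highest"` takes the maximum.
#'
#' @param raw numeric vector of per-representation scores (`NA` for
#'   failed representations).
#' @param favor `"lowest"` (default) or `"highest"`.
#' @return A single score, or `NA` if every representation is missing.
#' @export
collapse_representations <- function(raw, favor = c("lowest", "highest")) {
  favor <- match.arg(favor)
  raw <- raw[!is.na(raw)]
  if (!length(raw)) return(NA_real_)
  if (favor == "lowest") min(raw) else max(raw)
}

#' Read and write docking score matrices as CSV
#'
#' The on-disk format is long CSV with header
#' `compound_id,structure_id,representation_id,score`, one row per
#' (compound, structure, representation); an empty score field encodes
#' a missing (failed) docking.  On reading, per-representation scores
#' are collapsed with [collapse_representations()]; the raw long table
#' is kept in the `raw` attribute.
#'
#' @param path CSV file path.
#' @param favor collapsing direction, see [collapse_representations()].
#' @param matrix a [score_matrix()] (for writing).
#' @return `read_score_csv()` a [score_matrix()]; `write_score_csv()`
#'   the path, invisibly.
#' @export
read_score_csv <- function(path, favor = "lowest") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(score = "numeric"))
  need <- c("compound_id", "structure_id", "representation_id", "score")
  if (!all(need %in% names(df))) {
    stop("score CSV must have columns: ", paste(need, collapse = ", "))
  }
  cids <- unique(df$compound_id)
  sids <- unique(df$structure_id)
  m <- matrix(NA_real_, length(cids), length(sids),
              dimnames = list(cids, sids))
  key <- paste(df$compound_id, df$structure_id, sep = "\r")
  for (k in unique(key)) {
    rows <- which(key == k)
    m[df$compound_id[rows[1]], df$structure_id[rows[1]]] <-
      collapse_representations(df$score[rows], favor = favor)
  }
  out <- score_matrix(m)
  attr(out, "raw") <- df
  out
}

#' @rdname read_score_csv
#' @export
write_score_csv <- function(matrix, path) {
  df <- data.frame(
    compound_id = rep(rownames(matrix), times = ncol(matrix)),
    structure_id = rep(colnames(matrix), each = nrow(matrix)),
    representation_id = "r1",
    score = as.vector(unclass(matrix)[, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# Rank a named score vector into a hit list: ascending score (most
# favorable first), ties and missing scores broken/ordered by
# compound_id so rankings are stable across runs and platforms.
# Missing scores rank after all scored compounds.
rank_scores <- function(scores) {
  ids <- names(scores)
  stopifnot(!is.null(ids))
  ord <- order(is.na(scores), scores, ids)
  hits <- data.frame(
    compound_id = ids[ord],
    rank = seq_along(ord),
    score = unname(scores[ord]),
    stringsAsFactors = FALSE
  )
  class(hits) <- c("ranked_hits", "data.frame")
  hits
}

#' Rank compounds on one structure of a score matrix
#'
#' Produces the rank-ordered hit list for one structure: compounds
#' sorted by ascending docking score (most favorable first).  Ties are
#' broken by compound id (lexicographic, documented and stable);
#' compounds with missing scores are placed after all scored compounds,
#' ordered by compound id.
#'
#' @param matrix a [score_matrix()].
#' @param structure_id column to rank.
#' @return A `ranked_hits` data frame with columns `compound_id`,
#'   `rank` (1-based), `score`.
#' @export
rank_compounds <- function(matrix, structure_id) {
  if (!structure_id %in% colnames(matrix)) {
    stop("unknown structure: ", structure_id)
  }
  col <- unclass(matrix)[, structure_id]
  if (all(is.na(col))) {
    stop("structure ", structure_id, " has no docking scores")
  }
  rank_scores(col)
}

#' Best-over-structures ensemble score
#'
#' The all-against-all ensemble reduction: each compound's screen score
#' is its most favorable (lowest) docking score over all ensemble
#' structures.  Compounds without any score are excluded with a warning
#' and listed in the `excluded` attribute.
#'
#' @param matrix a [score_matrix()].
#' @return Named numeric vector of per-compound best scores.
#' @export
ensemble_best_score <- function(matrix) {
  m <- unclass(matrix)
  all_na <- rowSums(!is.na(m)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " compound(s) without any docking score excluded: ",
            paste(utils::head(rownames(m)[all_na], 5), collapse = ", "))
  }
  keep <- m[!all_na, , drop = FALSE]
  out <- apply(keep, 1, min, na.rm = TRUE)
  attr(out, "excluded") <- rownames(m)[all_na]
  out
}
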