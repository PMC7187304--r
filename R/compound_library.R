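#' Compound libraries
#'
#' A `compound_library` holds the screening library: one record per
#' compound with a unique `compound_id`, an `activity_class` of
#' `"active"` or `"decoy"`, an optional SMILES string (absent for
#' abstract, purely feature-vector compounds such as those produced by
#' the synthetic benchmark), optional alternative representations
#' (tautomers/protomers), and an optional feature matrix attached by
#' [featurize()].
#'
#' @param compound_id character vector of unique compound identifiers.
#' @param activity_class character vector, each element `"active"` or
#'   `"decoy"`.
#' @param smiles optional character vector of SMILES strings (`NA`
#'   allowed per compound).
#' @param representations optional data frame with columns
#'   `compound_id`, `representation_id`, `smiles` listing alternative
#'   molecular representations; every compound with a SMILES gets a
#'   default representation `"r1"` if none is supplied.
#' @param features optional numeric matrix of per-compound feature
#'   vectors, one row per compound (rownames must be the compound ids).
#' @param feature_kind descriptor kind of `features` (see [featurize()]);
#'   `"raw"` for abstract feature vectors.
#'
#' @return An object of class `compound_library`: a list with elements
#'   `compounds` (data frame), `representations` (data frame or `NULL`),
#'   `features` (matrix or `NULL`) and `feature_kind`.
#' @export
compound_library <- function(compound_id, activity_class, smiles = NULL,
                             representations = NULL, features = NULL,
                             feature_kind = NULL) {
  compound_id <- as.character(compound_id)
  activity_class <- as.character(activity_class)
  if (anyDuplicated(compound_id)) {
    dup <- unique(compound_id[duplicated(compound_id)])
    stop("duplicate compound_id: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (length(activity_class) != length(compound_id)) {
    stop("activity_class must match compound_id in length")
  }
  bad <- setdiff(unique(activity_class), c("active", "decoy"))
  if (length(bad) || anyNA(activity_class)) {
    stop("activity_class must be 'active' or 'decoy'")
  }
  if (is.null(smiles)) smiles <- rep(NA_character_, length(compound_id))
  compounds <- data.frame(
    compound_id = compound_id,
    smiles = as.character(smiles),
    activity_class = activity_class,
    stringsAsFactors = FALSE
  )
  if (is.null(representations)) {
    has <- !is.na(compounds$smiles)
    if (any(has)) {
      representations <- data.frame(
        compound_id = compounds$compound_id[has],
        representation_id = "r1",
        smiles = compounds$smiles[has],
        stringsAsFactors = FALSE
      )
    }
  } else {
    stopifnot(all(c("compound_id", "representation_id", "smiles") %in%
                    names(representations)))
    if (!all(representations$compound_id %in% compound_id)) {
      stop("representations reference unknown compound ids")
    }
  }
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (is.null(rownames(features))) {
      stopifnot(nrow(features) == length(compound_id))
      rownames(features) <- compound_id
    }
    if (!setequal(rownames(features), compound_id)) {
      stop("feature matrix rownames must equal the compound ids")
    }
    features <- features[compound_id, , drop = FALSE]
    feature_kind <- feature_kind %||% "raw"
  }
  structure(
    list(compounds = compounds, representations = representations,
         features = features, feature_kind = feature_kind),
    class = "compound_library"
  )
}

#' @export
print.compound_library <- function(x, ...) {
  tab <- table(x$compounds$activity_class)
  cat("<compound_library> ", nrow(x$compounds), " compounds (",
      tab["active"] %||% 0L, " active / ", tab["decoy"] %||% 0L,
      " decoy)\n", sep = "")
  if (!is.null(x$features)) {
    cat("  features: ", x$feature_kind, ", length ", ncol(x$features),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.compound_library <- function(x) nrow(x$compounds)

#' Compound ids, activity classes and features of a library
#'
#' @param library a [compound_library()].
#' @return `compound_ids()` a character vector; `activity_classes()` a
#'   named character vector (`"active"`/`"decoy"`, names = compound
#'   ids); `compound_features()` the feature matrix (error if the
#'   library has not been featurized).
#' @export
compound_ids <- function(library) library$compounds$compound_id

#' @rdname compound_ids
#' @export
activity_classes <- function(library) {
  stats::setNames(library$compounds$activity_class,
                  library$compounds$compound_id)
}

#' @rdname compound_ids
#' @export
compound_features <- function(library) {
  if (is.null(library$features)) {
    stop("library has no features; call featurize() first")
  }
  library$features
}

#' Subset a compound library by compound id
#'
#' @param library a [compound_library()].
#' @param ids compound ids to keep (order preserved).
#' @return A `compound_library` restricted to `ids`, carrying over
#'   representations and features.
#' @export
subset_library <- function(library, ids) {
  ids <- as.character(ids)
  missing <- setdiff(ids, library$compounds$compound_id)
  if (length(missing)) {
    stop("unknown compound ids: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  keep <- library$compounds[match(ids, library$compounds$compound_id), ]
  reps <- library$representations
  if (!is.null(reps)) reps <- reps[reps$compound_id %in% ids, , drop = FALSE]
  feats <- library$features
  if (!is.null(feats)) feats <- feats[ids, , drop = FALSE]
  compound_library(keep$compound_id, keep$activity_class, keep$smiles,
                   representations = reps, features = feats,
                   feature_kind = library$feature_kind)
}

#' Read a compound library from disk
#'
#' Three on-disk formats are supported:
#' \describe{
#'   \item{`smiles_table`}{whitespace- or tab-delimited text with
#'     columns `smiles`, `compound_id`, `activity_class` (in that
#'     order, no header; a header line is detected and skipped).}
#'   \item{`csv`}{comma-separated with a header row naming at least
#'     `compound_id`, `smiles`, `activity_class`; an optional
#'     `representation_id` column turns rows into per-representation
#'     entries of one compound.}
#'   \item{`sdf`}{an SD file; the activity class is read from the data
#'     field named by `activity_field` and the compound id from the
#'     molecule title (requires the ChemmineR chemistry backend).}
#' }
#' Rows whose SMILES cannot be parsed are skipped with a warning (the
#' count of rejected rows is recorded in the `rejected` attribute);
#' duplicated compound ids are an error.
#'
#' @param path file to read.
#' @param format one of `"smiles_table"`, `"csv"`, `"sdf"`.
#' @param activity_field SDF data field holding the activity class.
#' @param validate_smiles if `TRUE` (default) SMILES are canonicalized
#'   through the chemistry backend and unparseable records dropped; set
#'   to `FALSE` to accept SMILES strings as given.
#' @return A [compound_library()]; attribute `rejected` holds the
#'   number of skipped records.
#' @export
read_compound_library <- function(path,
                                  format = c("smiles_table", "csv", "sdf"),
                                  activity_field = "activity_class",
                                  validate_smiles = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smiles_table") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    ok_len <- vapply(parts, length, 1L) >= 3
    if (!all(ok_len)) stop("smiles_table rows need 3 fields: smiles, compound_id, activity_class")
    df <- data.frame(
      smiles = vapply(parts, `[[`, "", 1),
      compound_id = vapply(parts, `[[`, "", 2),
      activity_class = tolower(vapply(parts, `[[`, "", 3)),
      stringsAsFactors = FALSE
    )
    # header line, if any, will not carry a valid activity class
    if (nrow(df) && !df$activity_class[1] %in% c("active", "decoy") &&
        all(df$activity_class[-1] %in% c("active", "decoy"))) {
      df <- df[-1, , drop = FALSE]
    }
    reps <- NULL
  } else if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("compound_id", "smiles", "activity_class")
    if (!all(need %in% names(df))) {
      stop("csv must have columns: ", paste(need, collapse = ", "))
    }
    df$activity_class <- tolower(df$activity_class)
    reps <- if ("representation_id" %in% names(df)) {
      data.frame(compound_id = as.character(df$compound_id),
                 representation_id = as.character(df$representation_id),
                 smiles = df$smiles, stringsAsFactors = FALSE)
    }
    if (!is.null(reps)) {
      first <- !duplicated(df$compound_id)
      df <- df[first, c("compound_id", "smiles", "activity_class")]
    }
  } else {
    require_chemistry()
    sdfs <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdfs)
    blocks <- ChemmineR::datablock(sdfs)
    act <- vapply(blocks, function(b) {
      if (activity_field %in% names(b)) tolower(b[[activity_field]]) else NA_character_
    }, "")
    if (anyNA(act)) stop("SDF records missing data field '", activity_field, "'")
    df <- data.frame(compound_id = ids,
                     smiles = as.character(ChemmineR::sdf2smiles(sdfs)),
                     activity_class = act, stringsAsFactors = FALSE)
    reps <- NULL
  }

  bad_class <- !df$activity_class %in% c("active", "decoy")
  if (any(bad_class)) {
    stop("invalid activity_class values: ",
         paste(unique(df$activity_class[bad_class]), collapse = ", "))
  }
  rejected <- 0L
  if (validate_smiles && format != "sdf") {
    canon <- canonical_smiles(df$smiles)
    drop <- is.na(canon)
    if (any(drop)) {
      warning(sum(drop), " record(s) with unparseable SMILES skipped: ",
              paste(utils::head(df$compound_id[drop], 5), collapse = ", "))
      rejected <- sum(drop)
      df <- df[!drop, , drop = FALSE]
      if (!is.null(reps)) reps <- reps[reps$compound_id %in% df$compound_id, ]
    }
  }
  lib <- compound_library(df$compound_id, df$activity_class, df$smiles,
                          representations = reps)
  attr(lib, "rejected") <- rejected
  lib
}

#' Stratified train/test split of a compound library
#'
#' Splits the library into training and test portions, stratified by
#' activity class so that actives and decoys are held out at the same
#' rate, as is standard for screening benchmarks.
#'
#' @param library a [compound_library()].
#' @param test_fraction fraction of each class assigned to the test set
#'   (default 0.2, i.e. an 80:20 split).
#' @param seed integer seed; the assignment is deterministic given the
#'   seed.
#' @return A data frame with columns `compound_id` and `split`
#'   (`"train"`/`"test"`), in library order.
#' @export
split_train_test <- function(library, test_fraction = 0.2, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  cls <- activity_classes(library)
  if (!length(cls)) stop("empty library")
  split <- rep("train", length(cls))
  names(split) <- names(cls)
  with_seed(stage_seed(seed, "split"), {
    for (lev in unique(cls)) {
      idx <- which(cls == lev)
      if (length(idx) < 2) {
        stop("class '", lev, "' has fewer than 2 members; cannot stratify")
      }
      n_test <- max(1L, round(test_fraction * length(idx)))
      split[sample(idx, n_test)] <- "test"
    }
  })
  data.frame(compound_id = names(split), split = unname(split),
             stringsAsFactors = FALSE)
}

#' Filter test compounds by maximum similarity to the training set
#'
#' Keeps only the test compounds whose maximum Tanimoto coefficient
#' against *all* training compounds is at or below `cutoff`, producing
#' the harder, training-set-dissimilar evaluation subsets used to probe
#' a screening protocol's robustness to novel chemotypes.
#'
#' @param test,train [compound_library()] objects featurized with the
#'   same binary fingerprint configuration.
#' @param cutoff Tanimoto cutoff in \[0, 1\].
#' @param strict if `FALSE` (default) the rule is `max Tc <= cutoff`;
#'   if `TRUE`, `max Tc < cutoff`.
#' @return The filtered test `compound_library` (possibly empty).
#' @export
filter_test_by_train_similarity <- function(test, train, cutoff,
                                            strict = FALSE) {
  if (length(train) == 0) stop("empty training set")
  ft <- compound_features(test)
  fr <- compound_features(train)
  if (ncol(ft) != ncol(fr)) stop("test and train fingerprints differ in length")
  tc <- tanimoto_matrix(ft, fr)
  max_tc <- apply(tc, 1, max)
  keep <- if (strict) max_tc < cutoff else max_tc <= cutoff
  subset_library(test, compound_ids(test)[keep])
}
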