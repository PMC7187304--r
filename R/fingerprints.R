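# Featurization: hashed circular fingerprints, structural keys,
# physicochemical descriptors, and Tanimoto similarity.

require_chemistry <- function() {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("descriptor backend unavailable: ChemmineR/ChemmineOB required ",
         "for SMILES-based featurization", call. = FALSE)
  }
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to their canonical form via the OpenBabel backend so
#' that alternative writings of the same molecule map to one string.
#' Unparseable entries come back as `NA`.
#'
#' @param smiles character vector of SMILES.
#' @return Character vector of canonical SMILES, `NA` where parsing
#'   failed.
#' @export
canonical_smiles <- function(smiles) {
  require_chemistry()
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  for (i in which(ok)) {
    res <- suppressWarnings(tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles[i], "\n")),
      error = function(e) ""
    ))
    res <- sub("\t.*$", "", sub("\n$", "", res))
    res <- trimws(res)
    if (nzchar(res)) out[i] <- res
  }
  out
}

# Parse one canonical SMILES into a molecular graph: element symbol per
# heavy atom plus a bond table (i, j, order).  Aromatic systems arrive
# kekulized from the SDF conversion; since input is canonicalized first,
# equal molecules always yield equal graphs.
smiles_to_graph <- function(canonical) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(canonical))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  bonds <- if (nrow(bb)) {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else {
    data.frame(i = integer(), j = integer(), order = integer())
  }
  list(elements = elements, bonds = bonds)
}

# Hashed circular fingerprint of one molecular graph (ECFP-style):
# every atom starts from an invariant built from its element, degree and
# total bond order; each round rehashes the invariant together with the
# sorted (bond order, neighbor invariant) pairs, and every invariant
# from every round sets one bit of the hashed vector.
circular_bits <- function(graph, radius, n_bits) {
  n <- length(graph$elements)
  if (n == 0) return(integer(0))
  elem_code <- vapply(graph$elements,
                      function(e) hash_ints(utf8ToInt(e), init = 7), 1L)
  nbrs <- vector("list", n)
  for (r in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[r]; j <- graph$bonds$j[r]; o <- graph$bonds$order[r]
    nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
    nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
  }
  degree <- vapply(nbrs, function(x) if (is.null(x)) 0L else nrow(x), 1L)
  bond_sum <- vapply(nbrs, function(x) if (is.null(x)) 0L else sum(x[, 2]), 1L)
  inv <- mapply(function(e, d, b) hash_ints(c(e, d, b)), elem_code,
                degree, bond_sum)
  all_inv <- inv
  if (radius > 0) {
    for (round in seq_len(radius)) {
      new_inv <- inv
      for (a in seq_len(n)) {
        nb <- nbrs[[a]]
        if (is.null(nb)) next
        pairs <- cbind(nb[, 2], inv[nb[, 1]])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        new_inv[a] <- hash_ints(c(round, inv[a], t(pairs)))
      }
      inv <- new_inv
      all_inv <- c(all_inv, inv)
    }
  }
  sort(unique(all_inv %% n_bits)) + 1L
}

#' Featurize a compound library
#'
#' Attaches a feature matrix to a [compound_library()].  Four descriptor
#' kinds are supported:
#' \describe{
#'   \item{`hashed_circular`}{hashed circular substructure fingerprint
#'     (Morgan-type), default radius 2 and 1024 bits — the package
#'     default, mirroring the Morgan2/1024 configuration that is
#'     standard for this class of models.}
#'   \item{`structural_keys`}{MACCS structural keys via the OpenBabel
#'     backend (binary, 166 keys).}
#'   \item{`physchem_2d`}{a small open set of 2D physicochemical
#'     descriptors (molecular weight, logP, TPSA, H-bond donor/acceptor
#'     counts, molar refractivity, fluorine count) computed by
#'     OpenBabel; continuous-valued.}
#'   \item{`raw`}{the feature vectors already attached to the library
#'     (abstract compounds from the synthetic benchmark); a no-op check.}
#' }
#' Featurization is pure and deterministic: the same SMILES always
#' yields the same vector, and SMILES aliases of one molecule are
#' canonicalized to the same fingerprint.
#'
#' @param library a [compound_library()].
#' @param kind descriptor kind, see above.
#' @param radius neighborhood radius for `hashed_circular`.
#' @param n_bits fingerprint length for `hashed_circular`.
#' @return The library with `features` (rows = compounds) and
#'   `feature_kind` set.  Compounds whose SMILES cannot be parsed are an
#'   error for `hashed_circular` (the library reader already drops
#'   them).
#' @export
featurize <- function(library,
                      kind = c("hashed_circular", "structural_keys",
                               "physchem_2d", "raw"),
                      radius = 2, n_bits = 1024) {
  kind <- match.arg(kind)
  if (kind == "raw") {
    if (is.null(library$features)) {
      stop("kind 'raw' requires feature vectors already attached")
    }
    library$feature_kind <- "raw"
    return(library)
  }
  require_chemistry()
  smiles <- library$compounds$smiles
  if (anyNA(smiles)) stop("all compounds need SMILES for kind '", kind, "'")
  if (kind == "hashed_circular") {
    feats <- smiles_fingerprint(smiles, radius = radius, n_bits = n_bits)
  } else if (kind == "structural_keys") {
    sdfs <- suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(canonical_smiles(smiles), library$compounds$compound_id)))
    fp <- ChemmineR::fingerprintOB(sdfs, "MACCS")
    feats <- methods::slot(fp, "fpma")
    storage.mode(feats) <- "integer"
  } else {
    sdfs <- suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(canonical_smiles(smiles), library$compounds$compound_id)))
    props <- ChemmineR::propOB(sdfs)
    num <- vapply(props, is.numeric, TRUE)
    feats <- as.matrix(props[, num, drop = FALSE])
  }
  rownames(feats) <- library$compounds$compound_id
  library$features <- feats
  library$feature_kind <- kind
  attr(library$features, "radius") <- if (kind == "hashed_circular") radius
  library
}

#' Hashed circular fingerprints from SMILES
#'
#' Low-level featurizer behind [featurize()]: canonicalizes each SMILES
#' and computes a hashed circular substructure fingerprint on the
#' molecular graph.
#'
#' @param smiles character vector of SMILES.
#' @param radius neighborhood radius (default 2).
#' @param n_bits fingerprint length (default 1024).
#' @return Binary integer matrix, one row per input molecule.
#' @export
smiles_fingerprint <- function(smiles, radius = 2, n_bits = 1024) {
  require_chemistry()
  canon <- canonical_smiles(smiles)
  if (anyNA(canon)) {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[is.na(canon)], 5), collapse = ", "))
  }
  out <- matrix(0L, nrow = length(smiles), ncol = n_bits)
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(canon)) {
    key <- canon[i]
    bits <- if (!is.null(cache[[key]])) {
      cache[[key]]
    } else {
      cache[[key]] <- circular_bits(smiles_to_graph(key), radius, n_bits)
    }
    out[i, bits] <- 1L
  }
  out
}

#' Tanimoto similarity of binary feature vectors
#'
#' `tanimoto()` compares two vectors; `tanimoto_matrix()` computes all
#' pairwise similarities between the rows of two binary matrices.  The
#' coefficient is |A and B| / |A or B|; two all-zero vectors are defined
#' to have similarity 1 (documented convention: identical emptiness).
#'
#' @param a,b binary vectors of equal length.
#' @param A,B binary matrices with equal column counts.
#' @return `tanimoto()` a number in \[0, 1\]; `tanimoto_matrix()` a
#'   `nrow(A)` x `nrow(B)` matrix.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    stop("tanimoto requires binary vectors")
  }
  inter <- sum(a == 1 & b == 1)
  union <- sum(a == 1 | b == 1)
  if (union == 0) return(1)
  inter / union
}

#' @rdname tanimoto
#' @export
tanimoto_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("fingerprint lengths differ")
  inter <- A %*% t(B)
  na <- rowSums(A)
  nb <- rowSums(B)
  union <- outer(na, nb, `+`) - inter
  out <- ifelse(union == 0, 1, inter / union)
  dimnames(out) <- list(rownames(A), rownames(B))
  out
}
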