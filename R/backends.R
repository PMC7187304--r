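# Docking backend contract.  A backend is the pluggable stand-in for a
# real docking engine: an object with a `dock(compound_id,
# structure_id)` operation returning one finite lower-is-better score or
# NA on docking failure.  Two backends ship with the package: `csv`
# (precomputed score matrix, the default mode) and `synthetic` (the
# seeded simulator).  Backends must behave as pure functions of
# (compound, structure, backend config).

#' Docking backends
#'
#' `csv_backend()` wraps a precomputed [score_matrix()] (scores exported
#' from any real docking engine, or from the simulator);
#' `synthetic_backend()` docks on demand under the synthetic score model
#' of [simulate_scores()], deterministically per (compound, structure);
#' `counting_backend()` wraps any backend and counts dock calls, which
#' makes the efficiency contract of structure-selection screening
#' testable.
#'
#' @param matrix a [score_matrix()].
#' @param spec a [synthetic_bench_spec()].
#' @param library,truth output of [generate_library()].
#' @param backend a backend to wrap.
#' @return An object of class `dock_backend` with elements `name` and
#'   `dock(compound_id, structure_id)`.
#' @export
csv_backend <- function(matrix) {
  stopifnot(inherits(matrix, "score_matrix"))
  m <- unclass(matrix)
  structure(list(
    name = "csv",
    structure_ids = colnames(m),
    dock = function(compound_id, structure_id) {
      if (!compound_id %in% rownames(m)) {
        stop("compound not in score matrix: ", compound_id)
      }
      if (!structure_id %in% colnames(m)) {
        stop("structure not in score matrix: ", structure_id)
      }
      m[compound_id, structure_id]
    }
  ), class = "dock_backend")
}

#' @rdname csv_backend
#' @export
synthetic_backend <- function(spec, library, truth) {
  stopifnot(inherits(spec, "synthetic_bench_spec"))
  # the full score table is drawn once from the seeded simulator, so
  # every dock call is a pure function of (compound, structure, spec)
  m <- unclass(simulate_scores(spec, library, truth))
  structure(list(
    name = "synthetic",
    structure_ids = colnames(m),
    dock = function(compound_id, structure_id) {
      if (!compound_id %in% rownames(m)) {
        stop("unknown compound: ", compound_id)
      }
      if (!structure_id %in% colnames(m)) {
        stop("unknown structure: ", structure_id)
      }
      m[compound_id, structure_id]
    }
  ), class = "dock_backend")
}

#' @rdname csv_backend
#' @export
counting_backend <- function(backend) {
  stopifnot(inherits(backend, "dock_backend"))
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  structure(list(
    name = paste0("counting(", backend$name, ")"),
    structure_ids = backend$structure_ids,
    counter = counter,
    dock = function(compound_id, structure_id) {
      counter$n <- counter$n + 1L
      backend$dock(compound_id, structure_id)
    }
  ), class = "dock_backend")
}

#' @rdname csv_backend
#' @export
backend_call_count <- function(backend) {
  if (is.null(backend$counter)) stop("not a counting backend")
  backend$counter$n
}
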