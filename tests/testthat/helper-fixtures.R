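# Shared fixtures, built in code at test time.

# A fast, small-scale benchmark spec for unit tests (the acceptance
# tests use the full default spec).
small_spec <- function(seed = 3, ...) {
  synthetic_bench_spec(n_structures = 4, n_clusters = 4, n_actives = 60,
                       n_decoys = 300, n_bits = 256, n_signature_bits = 20,
                       seed = seed, ...)
}

# Toy 6-compound docking column used across labeling and evaluation
# tests: actives A1 (-9), A2 (-5), A3 (-2); decoys D1 (-8), D2 (-4),
# D3 (-1).
toy_column <- function() {
  list(
    scores = c(A1 = -9, D1 = -8, A2 = -5, D2 = -4, A3 = -2, D3 = -1),
    classes = c(A1 = "active", A2 = "active", A3 = "active",
                D1 = "decoy", D2 = "decoy", D3 = "decoy")
  )
}

toy_matrix <- function() {
  tc <- toy_column()
  score_matrix(matrix(tc$scores, ncol = 1,
                      dimnames = list(names(tc$scores), "S1")))
}

# Independent brute-force correctness labeler: literal restatement of
# the four-way rule, used as the oracle against the implementation.
brute_force_labels <- function(ranks, classes) {
  n <- sum(classes == "active")
  out <- character(length(ranks))
  for (i in seq_along(ranks)) {
    high <- ranks[i] <= n
    out[i] <- if (classes[i] == "active") {
      if (high) "correct" else "incorrect"
    } else {
      if (high) "incorrect" else "correct"
    }
  }
  out
}

# Independent pairwise-concordance AUC oracle (Mann-Whitney with 1/2
# per tie), brute force over all active-decoy pairs.
brute_force_auc <- function(scores, classes) {
  act <- scores[classes == "active"]
  dec <- scores[classes == "decoy"]
  total <- 0
  for (a in act) {
    for (d in dec) {
      total <- total + if (a < d) 1 else if (a == d) 0.5 else 0
    }
  }
  total / (length(act) * length(dec))
}

# Memoized small end-to-end benchmark shared by battery/screen tests.
.fixture_env <- new.env(parent = emptyenv())
small_bench <- function() {
  if (is.null(.fixture_env$bench)) {
    .fixture_env$bench <- suppressWarnings(benchmark_methods(small_spec()))
  }
  .fixture_env$bench
}
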