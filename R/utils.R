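# Internal helpers shared across modules.

# Deterministic polynomial hash of an integer vector, modulo the Mersenne
# prime 2^31 - 1.  All arithmetic stays below 2^53 so it is exact in doubles.
hash_ints <- function(x, init = 17) {
  h <- init
  for (v in x) {
    h <- (h * 31 + (v %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

# Derive a reproducible sub-seed for a named pipeline stage from a global
# seed, so that the stochastic stages (split, CV folds, SMOTE, forests,
# scrambling, simulation) draw from independent, individually reproducible
# streams.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  hash_ints(c(as.integer(seed), utf8ToInt(as.character(stage))))
}

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratified k-fold assignment: returns an integer vector of fold ids in
# 1..k, balanced within each level of `y`.
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      if (length(idx) < k) {
        stop("class '", lev, "' has fewer members (", length(idx),
             ") than folds (", k, ")")
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}
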