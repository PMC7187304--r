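test_that("representation collapsing keeps the most favorable score", {
  expect_equal(collapse_representations(c(-7.2, -6.1)), -7.2)
  expect_equal(collapse_representations(-5.0), -5.0)
  expect_equal(collapse_representations(c(NA, -4.2)), -4.2)
  expect_true(is.na(collapse_representations(c(NA_real_, NA_real_))))
  expect_equal(collapse_representations(c(-7.2, -6.1), favor = "highest"), -6.1)
})

test_that("ranking sorts ascending with documented tie and missing handling", {
  m <- score_matrix(matrix(c(-9, -5, -2), ncol = 1,
                           dimnames = list(c("A", "B", "C"), "S1")))
  hits <- rank_compounds(m, "S1")
  expect_equal(hits$compound_id, c("A", "B", "C"))
  expect_equal(hits$rank, 1:3)

  # ties break lexicographically by compound id
  m2 <- score_matrix(matrix(c(-5, -5), ncol = 1,
                            dimnames = list(c("B", "A"), "S1")))
  expect_equal(rank_compounds(m2, "S1")$compound_id, c("A", "B"))

  # missing scores go last, ordered by compound id
  m3 <- score_matrix(matrix(c(-5, NA, -7, NA), ncol = 1,
                            dimnames = list(c("A", "D", "B", "C"), "S1")))
  expect_equal(rank_compounds(m3, "S1")$compound_id, c("B", "A", "C", "D"))

  m4 <- score_matrix(matrix(NA_real_, 2, 1,
                            dimnames = list(c("A", "B"), "S1")))
  expect_error(rank_compounds(m4, "S1"), "S1")
  expect_error(rank_compounds(m, "nope"), "unknown structure")
})

test_that("ranking is invariant under adding a constant to a column", {
  set.seed(5)
  ids <- sprintf("c%02d", 1:30)
  for (i in 1:10) {
    col <- round(rnorm(30), 2)
    m_a <- score_matrix(matrix(col, ncol = 1, dimnames = list(ids, "S")))
    m_b <- score_matrix(matrix(col + 13.7, ncol = 1, dimnames = list(ids, "S")))
    expect_identical(rank_compounds(m_a, "S")$compound_id,
                     rank_compounds(m_b, "S")$compound_id)
  }
})

test_that("ensemble best score is the element-wise most favorable", {
  m <- score_matrix(matrix(c(-6, -1, -8, NA, NA, -3), nrow = 2,
                           dimnames = list(c("a", "b"),
                                           c("S1", "S2", "S3"))))
  best <- ensemble_best_score(m)
  expect_equal(best[["a"]], -8)
  expect_equal(best[["b"]], -3)
  # element-wise bound against every column
  for (s in colnames(m)) {
    col <- unclass(m)[, s]
    ok <- !is.na(col)
    expect_true(all(best[names(col)[ok]] <= col[ok]))
  }
  # one-structure matrix reduces to that column
  m1 <- score_matrix(matrix(c(-6, -1), ncol = 1,
                            dimnames = list(c("a", "b"), "S1")))
  expect_equal(ensemble_best_score(m1), c(a = -6, b = -1),
               ignore_attr = TRUE)
  # a compound with no score anywhere is excluded with a warning
  m5 <- score_matrix(matrix(c(-6, NA, -2, NA), nrow = 2,
                            dimnames = list(c("a", "b"), c("S1", "S2"))))
  expect_warning(best5 <- ensemble_best_score(m5), "excluded")
  expect_equal(attr(best5, "excluded"), "b")
  expect_false("b" %in% names(best5))
})

test_that("score CSV round trip preserves scores, missing entries and collapsing", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- score_matrix(matrix(c(-6.5, NA, -1.25, 0.5), nrow = 2,
                           dimnames = list(c("a", "b"), c("S1", "S2"))))
  write_score_csv(m, path)
  m2 <- read_score_csv(path)
  expect_equal(unclass(m)[rownames(m2), colnames(m2)], unclass(m2),
               ignore_attr = TRUE)

  # multi-representation rows collapse to the most favorable score
  writeLines(c("compound_id,structure_id,representation_id,score",
               "a,S1,r1,-7.2", "a,S1,r2,-6.1", "b,S1,r1,",
               "b,S1,r2,-4.2", "c,S1,r1,"), path)
  m3 <- read_score_csv(path)
  expect_equal(unclass(m3)["a", "S1"], -7.2)
  expect_equal(unclass(m3)["b", "S1"], -4.2)
  expect_true(is.na(unclass(m3)["c", "S1"]))
})

test_that("backends honor the docking contract", {
  m <- score_matrix(matrix(c(-6, -1, NA, -3), nrow = 2,
                           dimnames = list(c("a", "b"), c("S1", "S2"))))
  be <- csv_backend(m)
  expect_equal(be$dock("a", "S1"), -6)
  expect_true(is.na(be$dock("a", "S2")))  # missing propagates as missing
  expect_error(be$dock("zz", "S1"), "compound")

  cb <- counting_backend(be)
  expect_equal(backend_call_count(cb), 0L)
  cb$dock("a", "S1"); cb$dock("b", "S2")
  expect_equal(backend_call_count(cb), 2L)
})

test_that("the synthetic backend favors the planted-compatible structure in expectation", {
  spec <- small_spec(seed = 9)
  gen <- generate_library(spec)
  be <- synthetic_backend(spec, gen$library, gen$truth)
  cls <- activity_classes(gen$library)
  actives <- names(cls)[cls == "active"]
  planted <- setNames(gen$truth$structure_id, gen$truth$compound_id)
  other <- function(sid) setdiff(be$structure_ids, sid)[1]
  compat <- vapply(actives, function(a) be$dock(a, planted[[a]]), 1)
  incompat <- vapply(actives, function(a) be$dock(a, other(planted[[a]])), 1)
  expect_lt(mean(compat), mean(incompat))
  # pure function of (compound, structure, config)
  be2 <- synthetic_backend(spec, gen$library, gen$truth)
  expect_equal(be$dock(actives[1], "S01"), be2$dock(actives[1], "S01"))
})
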