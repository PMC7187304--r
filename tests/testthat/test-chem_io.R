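test_that("smiles_table libraries parse, skip bad SMILES, reject duplicates", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO cpd1 active", "c1ccccc1 cpd2 decoy"), path)
  lib <- read_compound_library(path, "smiles_table")
  expect_s3_class(lib, "compound_library")
  expect_length(lib, 2)
  expect_equal(sum(activity_classes(lib) == "active"), 1)
  expect_equal(attr(lib, "rejected"), 0L)

  writeLines(c("CCO c1 active", "CCN c2 active", "C1CC( c3 decoy",
               "CCC c4 decoy", "CCCC c5 decoy"), path)
  expect_warning(lib <- read_compound_library(path, "smiles_table"),
                 "unparseable")
  expect_length(lib, 4)
  expect_equal(attr(lib, "rejected"), 1L)

  writeLines(c("CCO c1 active", "CCN c1 decoy"), path)
  expect_error(read_compound_library(path, "smiles_table"), "duplicate")
})

test_that("csv libraries carry representations and validate classes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,smiles,activity_class,representation_id",
               "c1,CCO,active,r1", "c1,CC[O-],active,r2",
               "c2,CCN,decoy,r1"), path)
  lib <- read_compound_library(path, "csv")
  expect_length(lib, 2)
  expect_equal(nrow(lib$representations[lib$representations$compound_id == "c1", ]), 2)

  writeLines(c("compound_id,smiles,activity_class",
               "c1,CCO,unknown_class"), path)
  expect_error(read_compound_library(path, "csv"), "activity_class")
})

test_that("hashed circular fingerprints are deterministic and canonical", {
  lib <- compound_library(c("e1", "e2", "b1", "b2"),
                          c("active", "active", "decoy", "decoy"),
                          smiles = c("CC", "CCO", "c1ccccc1", "C1=CC=CC=C1"))
  lib <- featurize(lib, "hashed_circular")
  f <- compound_features(lib)
  expect_equal(dim(f), c(4, 1024))
  expect_true(all(f %in% c(0, 1)))
  # two SMILES writings of benzene give the identical fingerprint
  expect_equal(unname(f["b1", ]), unname(f["b2", ]))
  # featurization is pure: a second pass is bitwise identical
  f2 <- compound_features(featurize(lib, "hashed_circular"))
  expect_identical(f, f2)
  # ethane vs ethanol share some substructure bits but are not identical
  tc <- tanimoto(f["e1", ], f["e2", ])
  expect_lt(tc, 1)
  expect_gt(tc, 0)
})

test_that("structural keys and physchem descriptors come from the chemistry backend", {
  lib <- compound_library(c("c1", "c2"), c("active", "decoy"),
                          smiles = c("CCO", "c1ccccc1O"))
  keys <- compound_features(featurize(lib, "structural_keys"))
  expect_true(all(keys %in% c(0, 1)))
  phys <- compound_features(featurize(lib, "physchem_2d"))
  expect_true(is.numeric(phys))
  expect_gt(phys["c2", "MW"], phys["c1", "MW"])
})

test_that("tanimoto follows the set definition and its conventions", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  # bit sets {1,2,3} vs {2,3,4}: intersection 2, union 4
  a <- c(1, 1, 1, 0, 0); b <- c(0, 1, 1, 1, 0)
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(b, a), tanimoto(a, b))
  expect_equal(tanimoto(numeric(3), numeric(3)), 1)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
  set.seed(42)
  for (i in 1:20) {
    x <- rbinom(32, 1, 0.3); y <- rbinom(32, 1, 0.3)
    expect_equal(tanimoto(x, y), tanimoto(y, x))
    if (any(x == 1)) {
      expect_equal(tanimoto(x, y) == 1, identical(x, y))
    }
  }
})

test_that("train/test split is stratified, deterministic and guarded", {
  lib <- compound_library(sprintf("c%02d", 1:20),
                          rep(c("active", "decoy"), each = 10))
  s1 <- split_train_test(lib, 0.2, seed = 11)
  cls <- activity_classes(lib)
  test_ids <- s1$compound_id[s1$split == "test"]
  expect_equal(sum(cls[test_ids] == "active"), 2)
  expect_equal(sum(cls[test_ids] == "decoy"), 2)
  expect_identical(s1, split_train_test(lib, 0.2, seed = 11))
  expect_false(identical(s1, split_train_test(lib, 0.2, seed = 12)))

  tiny <- compound_library(c("a", "b"), c("active", "decoy"))
  expect_error(split_train_test(tiny, 0.2, seed = 1), "stratify")
})

test_that("similarity filter matches brute force and nests with cutoff", {
  # six abstract compounds with hand-set bit patterns
  feats <- rbind(
    t1 = c(1, 1, 1, 1, 0, 0, 0, 0),
    t2 = c(1, 1, 0, 0, 1, 1, 0, 0),
    t3 = c(0, 0, 0, 0, 1, 1, 1, 1),
    r1 = c(1, 1, 1, 1, 0, 0, 0, 0),
    r2 = c(1, 1, 0, 0, 0, 0, 1, 1),
    r3 = c(0, 0, 0, 0, 0, 0, 1, 1)
  )
  lib <- compound_library(rownames(feats),
                          rep(c("active", "decoy"), each = 3),
                          features = feats)
  test <- subset_library(lib, c("t1", "t2", "t3"))
  train <- subset_library(lib, c("r1", "r2", "r3"))

  brute_max <- vapply(c("t1", "t2", "t3"), function(i) {
    max(vapply(c("r1", "r2", "r3"),
               function(j) tanimoto(feats[i, ], feats[j, ]), 1))
  }, 1)
  for (cutoff in c(0, 0.5, 0.8, 1)) {
    kept <- compound_ids(filter_test_by_train_similarity(test, train, cutoff))
    expect_identical(kept, names(brute_max)[brute_max <= cutoff],
                     info = paste("cutoff", cutoff))
  }
  # cutoff 1 keeps everything; subsets nest as the cutoff tightens
  expect_length(filter_test_by_train_similarity(test, train, 1), 3)
  k07 <- compound_ids(filter_test_by_train_similarity(test, train, 0.7))
  k08 <- compound_ids(filter_test_by_train_similarity(test, train, 0.8))
  expect_true(all(k07 %in% k08))
  empty <- compound_library(character(0), character(0))
  expect_error(filter_test_by_train_similarity(test, empty, 0.5), "empty")
})
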