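test_that("trait_matrix validates and normalizes", {
  tm <- trait_matrix(rbind(a = c(1, 0, 1), b = c(0, 1, 1)),
                     feature_names = c("f1", "f2", "f3"))
  expect_s3_class(tm, "trait_matrix")
  expect_identical(dim(tm), c(2L, 3L))
  expect_identical(storage.mode(tm), "integer")
  expect_identical(rownames(tm), c("a", "b"))

  expect_error(trait_matrix(rbind(a = c(1, 2), b = c(0, 1)),
                            feature_names = c("f1", "f2")),
               "non-binary trait value 2 at organism 'a', feature 'f2'")
  expect_error(trait_matrix(rbind(a = 1, a = 0), feature_names = "f1"),
               "duplicate organism ids")
  expect_error(trait_matrix(rbind(a = c(1, 0)), feature_names = c("f", "f")),
               "duplicate feature names")
  expect_error(trait_matrix(matrix(1, 1, 1)), "feature names")
  expect_error(trait_matrix(matrix(integer(), 2, 0),
                            feature_names = character()),
               "at least one feature")
})

test_that("trait matrix TSV round-trips", {
  tm <- trait_matrix(rbind(a = c(1, 0, 1), b = c(0, 1, 1), c = c(1, 1, 0)),
                     feature_names = c("upt_M1", "upt_M2", "sec_M1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trait_matrix(tm, path)
  expect_identical(readLines(path)[1], "organism\tupt_M1\tupt_M2\tsec_M1")
  expect_equal(read_trait_matrix(path), tm)
})

test_that("build_composite is responder-first with _p suffix", {
  expect_identical(build_composite(c(1, 0), c(0, 1)), c(1L, 0L, 0L, 1L))
  out <- build_composite(c(f1 = 1, f2 = 0), c(f1 = 0, f2 = 1))
  expect_identical(names(out), c("f1", "f2", "f1_p", "f2_p"))
  expect_error(build_composite(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(build_composite(c(1, 2), c(1, 0)), "binary")
  expect_identical(composite_feature_names(c("a", "b")),
                   c("a", "b", "a_p", "b_p"))
})

test_that("composite representation is asymmetric for distinct organisms", {
  set.seed(71)
  for (k in 1:50) {
    fi <- rbinom(8, 1, 0.5)
    fj <- rbinom(8, 1, 0.5)
    if (all(fi == fj)) next
    expect_false(identical(build_composite(fi, fj), build_composite(fj, fi)))
  }
})

test_that("jaccard_distance matches hand values and is symmetric", {
  expect_equal(jaccard_distance(c(1, 1, 0, 1), c(1, 0, 0, 1)), 1 / 3)
  set.seed(5)
  for (k in 1:25) {
    a <- rbinom(10, 1, 0.6)
    b <- rbinom(10, 1, 0.6)
    if (sum(a | b) == 0) next
    expect_identical(jaccard_distance(a, b), jaccard_distance(b, a))
  }
  a <- c(1, 0, 1)
  expect_identical(jaccard_distance(a, a), 0)
  expect_error(jaccard_distance(c(0, 0), c(0, 0)), "all-zero")
})

test_that("relative_yield and its guard", {
  expect_equal(relative_yield(2, 4), -0.5)
  expect_equal(relative_yield(4, 4), 0)
  expect_equal(relative_yield(c(6, 2), 4), c(0.5, -0.5))
  expect_error(relative_yield(1, 0), "positive")
  expect_error(relative_yield(1, -2), "positive")
})

test_that("sign label rule: zero and tolerance boundary", {
  rule <- label_rule("sign")
  x <- c(-1, -1e-8, -1e-10, 0, 1e-10, 2)
  lab <- apply_label_rule(rule, x)
  expect_identical(as.character(lab),
                   c("negative", "negative", "nonnegative", "nonnegative",
                     "nonnegative", "nonnegative"))
  expect_identical(levels(lab), c("negative", "nonnegative"))
})

test_that("cutoff label rule: fold change exactly at the cutoff is weak", {
  rule <- label_rule("cutoff", cutoff = 2)
  expect_identical(as.character(apply_label_rule(rule, c(1.9, 2, 2.0001, 7))),
                   c("weak", "weak", "strong", "strong"))
  expect_error(label_rule("cutoff"), "finite cutoff")
})

test_that("binary label rule passes 0/1 through and rejects others", {
  rule <- label_rule("binary", classes = c("dead", "alive"))
  expect_identical(as.character(apply_label_rule(rule, c(0, 1, 1))),
                   c("dead", "alive", "alive"))
  expect_error(apply_label_rule(rule, c(0, 2)), "0/1")
})

test_that("label rules are total: every finite response maps to one class", {
  set.seed(8)
  x <- c(rnorm(200), 0, -0, 1e-300, -1e-300)
  for (rule in list(label_rule("sign"), label_rule("cutoff", cutoff = 0.5))) {
    lab <- apply_label_rule(rule, x)
    expect_false(anyNA(lab))
    expect_identical(length(lab), length(x))
  }
})

test_that("label_rule validates classes and positive_class", {
  expect_error(label_rule("sign", classes = c("a", "a")), "distinct")
  expect_error(label_rule("sign", positive_class = "zzz"), "one of classes")
  r <- label_rule("sign", positive_class = "negative")
  expect_identical(r$positive_class, "negative")
})

test_that("interaction_table validates shape and round-trips TSV", {
  X <- matrix(c(1, -0.5, NA, 2), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  it <- interaction_table(X)
  expect_identical(attr(it, "response_mode"), "relative_yield")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_table(it, path)
  it2 <- read_interaction_table(path)
  expect_equal(unclass(it2), unclass(it), ignore_attr = TRUE)
  expect_error(interaction_table(matrix(1, 2, 3)), "square")
  expect_error(interaction_table(matrix(1, 2, 2)), "organism ids")
  bad <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("b", "a")))
  expect_error(interaction_table(bad), "must match")
})

test_that("assemble_dataset builds one row per measured ordered pair", {
  tm <- trait_matrix(rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1)),
                     feature_names = c("f1", "f2"))
  X <- matrix(c(5, -0.2, 0.1,
                0.3, 5, NA,
                0, NA, 5), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ds <- assemble_dataset(tm, interaction_table(X), label_rule("sign"))
  # diagonal excluded; (b,c) and (c,b) unmeasured
  expect_identical(nrow(ds$design), 4L)
  expect_identical(rownames(ds$design), c("a:b", "a:c", "b:a", "c:a"))
  expect_identical(ds$feature_names, c("f1", "f2", "f1_p", "f2_p"))
  # responder-first concatenation
  expect_identical(unname(ds$design["a:b", ]), c(1L, 0L, 0L, 1L))
  expect_identical(unname(ds$design["b:a", ]), c(0L, 1L, 1L, 0L))
  expect_identical(as.character(ds$labels),
                   c("negative", "nonnegative", "nonnegative", "nonnegative"))
  # requesting an unmeasured pair is an error
  expect_error(assemble_dataset(tm, interaction_table(X), label_rule("sign"),
                                pairs = cbind("b", "c")),
               "missing responses for pairs: b:c")
  # diagonal pairs are rejected
  expect_error(assemble_dataset(tm, interaction_table(X), label_rule("sign"),
                                pairs = cbind("a", "a")),
               "diagonal")
})

test_that("pair manifest records included pairs", {
  tm <- trait_matrix(rbind(a = 1, b = 0), feature_names = "f1")
  X <- matrix(c(1, 0.5, -0.5, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  ds <- assemble_dataset(tm, interaction_table(X), label_rule("sign"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_manifest(ds, path)
  mf <- read.delim(path)
  expect_identical(nrow(mf), 2L)
  expect_identical(names(mf), c("responder", "partner", "response", "label"))
})

test_that("score_threshold_roc matches the hand-counted 8/9 example", {
  r <- score_threshold_roc(c(.9, .8, .7, .4, .3, .1), c(1, 1, 0, 1, 0, 0),
                           positive = 1)
  expect_equal(r$auc, 8 / 9)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_equal(range(r$curve$tpr), c(0, 1))
})

test_that("score_threshold_roc degenerate and error cases", {
  expect_equal(score_threshold_roc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1),
                                   positive = 1)$auc, 0.5)
  expect_error(score_threshold_roc(1:4, rep(1, 4), positive = 1),
               "each class")
  expect_error(score_threshold_roc(1:3, c(0, 1, NA)), "NA")
})

test_that("jaccard baseline scores align with dataset rows", {
  tm <- trait_matrix(rbind(a = c(1, 1, 0), b = c(1, 0, 0), c = c(0, 0, 1)),
                     feature_names = c("f1", "f2", "f3"))
  X <- matrix(0.5, 3, 3, dimnames = list(rownames(tm), rownames(tm)))
  diag(X) <- 1
  ds <- assemble_dataset(tm, interaction_table(X), label_rule("sign"))
  jd <- jaccard_baseline_scores(tm, ds)
  expect_identical(length(jd), nrow(ds$design))
  k <- match("a:b", rownames(ds$design))
  expect_equal(jd[k], jaccard_distance(tm["a", ], tm["b", ]))
})
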