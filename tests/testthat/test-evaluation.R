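test_that("fold sizes follow the floor rule with the remainder in fold 5", {
  expect_equal(make_folds(714, 1)$sizes, c(142, 142, 142, 142, 146))
  expect_equal(make_folds(504, 1)$sizes, c(100, 100, 100, 100, 104))
  f <- make_folds(10, 3)
  expect_equal(f$sizes, rep(2, 5))
  expect_equal(sort(tabulate(f$fold_of, 5)), sort(f$sizes))
  expect_error(make_folds(4, 1), "n >= 5")
})

test_that("folds partition the indices and are seed-reproducible", {
  for (n in c(23, 101, 504)) {
    f1 <- make_folds(n, 99)
    f2 <- make_folds(n, 99)
    f3 <- make_folds(n, 100)
    expect_identical(f1$fold_of, f2$fold_of)
    expect_false(identical(f1$fold_of, f3$fold_of))
    expect_equal(tabulate(f1$fold_of, 5), f1$sizes)  # every index once
  }
})

test_that("stratified folds spread each class across folds", {
  labels <- rep(c("big", "small"), c(95, 10))
  f <- make_folds(105, 7, labels = labels, stratified = TRUE)
  expect_equal(tabulate(f$fold_of, 5), f$sizes)
  per_fold_small <- tabulate(f$fold_of[labels == "small"], 5)
  expect_true(all(per_fold_small >= 1))
})

test_that("per-class metrics reproduce hand-computed binary counts", {
  # 20 items: TP=8 FN=2 FP=1 TN=9 for class "pos"
  conf <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE,
                 dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- per_class_metrics(conf, "pos")
  expect_equal(m[["SE"]], 0.8)
  expect_equal(m[["SP"]], 8 / 9)
  expect_equal(m[["MCC"]], 70 / sqrt(9900))
  # textbook specificity switch
  expect_equal(per_class_metrics(conf, "pos", "tnr")[["SP"]], 0.9)
})

test_that("perfect prediction gives SE = SP = MCC = 1 for every class", {
  conf <- diag(c(5L, 9L, 2L))
  dimnames(conf) <- list(letters[1:3], letters[1:3])
  for (cl in 1:3)
    expect_equal(unname(per_class_metrics(conf, cl)), c(1, 1, 1))
})

test_that("undefined ratios are flagged and MCC uses the zero convention", {
  # class "b" never predicted: SP undefined, MCC = 0
  conf <- matrix(c(5, 0, 3, 0), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("a", "b")))
  m <- per_class_metrics(conf, "b")
  expect_true(is.nan(m[["SP"]]))
  expect_equal(m[["MCC"]], 0)
  expect_equal(m[["SE"]], 0)
})

test_that("metrics agree with a per-item recount oracle on random matrices", {
  set.seed(41)
  for (rep in 1:10) {
    nc <- sample(2:6, 1)
    truth <- sample(letters[1:nc], 60, replace = TRUE)
    pred <- sample(letters[1:nc], 60, replace = TRUE)
    conf <- confusion_matrix(truth, pred, letters[1:nc])
    expect_equal(sum(conf), 60)
    for (cl in letters[1:nc]) {
      # independent recount straight from the item lists
      tp <- sum(truth == cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      fp <- sum(truth != cl & pred == cl)
      tn <- sum(truth != cl & pred != cl)
      m <- per_class_metrics(conf, cl)
      if (tp + fn > 0) expect_equal(m[["SE"]], tp / (tp + fn))
      if (tp + fp > 0) expect_equal(m[["SP"]], tp / (tp + fp))
      d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      expect_equal(m[["MCC"]],
                   if (d > 0) (tp * tn - fp * fn) / sqrt(d) else 0)
      expect_gte(m[["MCC"]], -1)
      expect_lte(m[["MCC"]], 1)
    }
  }
})

test_that("evaluation reports pool all folds and match the trace identity", {
  set.seed(2)
  truth <- sample(c("x", "y", "z"), 50, replace = TRUE)
  pred <- sample(c("x", "y", "z"), 50, replace = TRUE)
  fold <- rep(1:5, each = 10)
  rep_ <- evaluation_report(truth, pred, fold)
  expect_equal(sum(rep_$confusion), 50)
  expect_equal(rep_$overall_accuracy,
               sum(diag(rep_$confusion)) / 50)
  expect_length(rep_$per_fold, 5)
})

test_that("cross-validation tests every example exactly once", {
  ds <- tiny_motif_dataset(n_per_class = 10, seed = 31)
  rep_ <- cross_validate(ds$sequences, ds$labels, variant = "I", seed = 5)
  expect_equal(rep_$n, length(ds$labels))
  expect_equal(sum(rep_$confusion), length(ds$labels))
  expect_gte(rep_$overall_accuracy, 0.9)  # strong planted signal
  expect_equal(rep_$meta$seed, 5)
})

test_that("null-label cross-validation sits at chance level", {
  # labels independent of content, 2 balanced classes: accuracy within
  # 3 sigma binomial bounds of 0.5 over pooled seeds
  cfg <- generator_config(n_classes = 2, per_class_sizes = c(30, 30),
                          length_range = c(60, 150),
                          motifs_per_class = list(), seed = 19)
  ds <- generate_dataset(cfg)
  spec <- fusion_spec_variant("I")
  K <- fuse(component_kernels(ds$sequences, spec), spec$weight)
  accs <- vapply(1:4, function(s)
    cross_validate_kernel(K, ds$labels, seed = s)$overall_accuracy,
    numeric(1))
  n_total <- 4 * length(ds$labels)
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / n_total))
})

test_that("reports serialize to the three text files", {
  ds <- tiny_motif_dataset(n_per_class = 8, seed = 17)
  rep_ <- cross_validate(ds$sequences, ds$labels, variant = "I", seed = 2)
  dir <- withr::local_tempdir()
  write_report(rep_, dir)
  metrics <- readLines(file.path(dir, "metrics.tsv"))
  expect_match(metrics[1], "location\tsize\tSP\tSE\tMCC")
  expect_match(metrics[length(metrics)], "Overall Accuracy")
  conf <- utils::read.table(file.path(dir, "confusion.tsv"), sep = "\t",
                            header = TRUE, check.names = FALSE)
  expect_equal(sum(conf[, -1]), rep_$n)
  meta <- readLines(file.path(dir, "run_meta.txt"))
  expect_true(any(grepl("^seed=2$", meta)))
})
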