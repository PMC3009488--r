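# Run code under a private RNG stream so that library calls neither
# disturb nor depend on the caller's .Random.seed.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Assign examples to 5 cross-validation folds
#'
#' A seeded uniform random permutation of the indices is sliced into
#' five disjoint parts of equal size `floor(n/5)`; the last part takes
#' the `n %% 5` leftover examples, so it may have 0-4 more than the
#' others. Every example is tested exactly once.
#'
#' @param n dataset size (at least 5).
#' @param seed integer seed; identical seeds give identical folds.
#' @param labels optional class labels of length n; when supplied and
#'   `stratified = TRUE`, each class is spread as evenly as possible
#'   across folds.
#' @param stratified default `FALSE` (plain random split).
#' @return object of class `fold_assignment`: list with `n`, `fold_of`
#'   (integer in 1..5 per example), `seed`, `sizes`.
#' @export
make_folds <- function(n, seed, labels = NULL, stratified = FALSE) {
  if (n < 5) stop("need n >= 5 for 5-fold cross-validation")
  base <- n %/% 5L
  sizes <- c(rep(base, 4L), base + n %% 5L)
  fold_of <- integer(n)
  .with_seed(seed, {
    if (stratified) {
      if (is.null(labels) || length(labels) != n)
        stop("stratified folds need labels of length n")
      # deal each class round-robin over a random fold order, starting
      # from a random offset, after permuting within class
      counts <- integer(5)
      for (cl in sample(unique(as.character(labels)))) {
        idx <- sample(which(labels == cl))
        ord <- order(counts + stats::runif(5) / 2, sample(5) / 10)
        f <- rep(ord, length.out = length(idx))
        fold_of[idx] <- f
        counts <- counts + tabulate(f, 5)
      }
      # rebalance to the exact target sizes
      for (from in 1:5) {
        while (sum(fold_of == from) > sizes[from]) {
          to <- which.max(sizes - tabulate(fold_of, 5))
          move <- sample(which(fold_of == from), 1L)
          fold_of[move] <- to
        }
      }
    } else {
      perm <- sample.int(n)
      fold_of[perm] <- rep.int(1:5, times = sizes)
    }
  })
  structure(list(n = n, fold_of = fold_of, seed = seed, sizes = sizes,
                 stratified = stratified),
            class = "fold_assignment")
}

#' Build a confusion matrix over a fixed class set
#'
#' @param truth,predicted character vectors of equal length.
#' @param classes class order for rows (truth) and columns (predicted);
#'   default the sorted union.
#' @return square integer matrix of counts.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  as.matrix(table(factor(truth, levels = classes),
                  factor(predicted, levels = classes)))
}

#' Per-class sensitivity, specificity and MCC
#'
#' One-vs-rest binarization of a multi-class confusion matrix. For the
#' target class: TP is the diagonal entry, FN the rest of its row, FP
#' the rest of its column, TN everything else. Then
#' SE = TP/(TP+FN), and by the convention adopted here (prevailing in
#' the subcellular-localization literature) SP = TP/(TP+FP), the
#' positive predictive value; `sp_definition = "tnr"` switches to the
#' textbook true-negative rate TN/(TN+FP). MCC is the Matthews
#' correlation coefficient, defined as 0 when any denominator factor is
#' 0. Undefined SE/SP ratios (empty class or never-predicted class) are
#' reported as `NaN`.
#'
#' @param confusion square count matrix, rows = truth, columns =
#'   predicted.
#' @param class_index row/column index or class name.
#' @param sp_definition `"ppv"` (default) or `"tnr"`.
#' @return named numeric vector with elements `SE`, `SP`, `MCC`.
#' @export
per_class_metrics <- function(confusion, class_index,
                              sp_definition = c("ppv", "tnr")) {
  sp_definition <- match.arg(sp_definition)
  confusion <- as.matrix(confusion)
  i <- if (is.character(class_index))
    match(class_index, rownames(confusion)) else class_index
  tp <- as.numeric(confusion[i, i])  # doubles: MCC denominator overflows
  fn <- sum(as.numeric(confusion[i, ])) - tp  # 32-bit ints at modest n
  fp <- sum(as.numeric(confusion[, i])) - tp
  tn <- sum(as.numeric(confusion)) - tp - fn - fp
  se <- if (tp + fn > 0) tp / (tp + fn) else NaN
  sp <- if (sp_definition == "ppv") {
    if (tp + fp > 0) tp / (tp + fp) else NaN
  } else {
    if (tn + fp > 0) tn / (tn + fp) else NaN
  }
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 > 0)
    (tp * tn - fp * fn) / sqrt(denom2) else 0
  c(SE = se, SP = sp, MCC = mcc)
}

.metrics_table <- function(confusion, sp_definition) {
  classes <- rownames(confusion)
  per <- t(vapply(classes, function(cl)
    per_class_metrics(confusion, cl, sp_definition), numeric(3)))
  data.frame(class = classes, size = as.integer(rowSums(confusion)),
             SP = per[, "SP"], SE = per[, "SE"], MCC = per[, "MCC"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluate pooled cross-validation predictions
#'
#' @param truth,predicted aligned label vectors over all test folds.
#' @param fold_of fold id per example (for the per-fold breakdown).
#' @param sp_definition see [per_class_metrics()].
#' @param meta run metadata list stored in the report.
#' @return object of class `cv_report`: list with `confusion`,
#'   `per_class` (data frame of size/SP/SE/MCC), `overall_accuracy`,
#'   `per_fold` accuracies, `n`, `meta`.
#' @export
evaluation_report <- function(truth, predicted, fold_of = NULL,
                              sp_definition = c("ppv", "tnr"), meta = list()) {
  sp_definition <- match.arg(sp_definition)
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- sort(unique(c(truth, predicted)))
  confusion <- confusion_matrix(truth, predicted, classes)
  per_fold <- NULL
  if (!is.null(fold_of))
    per_fold <- vapply(sort(unique(fold_of)), function(f)
      mean(truth[fold_of == f] == predicted[fold_of == f]), numeric(1))
  structure(list(confusion = confusion,
                 per_class = .metrics_table(confusion, sp_definition),
                 overall_accuracy = mean(truth == predicted),
                 per_fold = per_fold, n = length(truth),
                 sp_definition = sp_definition, meta = meta),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("5-fold cross-validation report (n = %d)\n", x$n))
  tab <- x$per_class
  tab$SP <- sprintf("%.4f", tab$SP)
  tab$SE <- sprintf("%.4f", tab$SE)
  tab$MCC <- sprintf("%.4f", tab$MCC)
  print(tab, row.names = FALSE)
  cat(sprintf("Overall accuracy: %.2f%%\n", 100 * x$overall_accuracy))
  invisible(x)
}

#' Cross-validate a precomputed kernel
#'
#' Runs the 5-fold protocol on an already-built kernel matrix: for each
#' fold the training block trains the SVM and the test-vs-training
#' block is scored. Spectrum/Gaussian kernels are pairwise functions of
#' the two sequences with no training-set fitting, so computing the
#' matrix once on the full set and slicing it per fold leaks no
#' information.
#'
#' @param K square `kernel_matrix` over the full dataset.
#' @param labels class labels aligned to `kernel_ids(K)`.
#' @param config an [svm_config()].
#' @param seed integer seed for the fold permutation.
#' @param stratified stratify folds by class (default `FALSE`).
#' @param sp_definition see [per_class_metrics()].
#' @return a `cv_report`.
#' @export
cross_validate_kernel <- function(K, labels, config = svm_config(), seed = 1,
                                  stratified = FALSE,
                                  sp_definition = c("ppv", "tnr")) {
  sp_definition <- match.arg(sp_definition)
  ids <- kernel_ids(K)
  labels <- as.character(labels)
  stopifnot(length(labels) == length(ids))
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  folds <- make_folds(length(ids), seed, labels = labels,
                      stratified = stratified)
  predicted <- character(length(ids))
  for (f in 1:5) {
    te <- which(folds$fold_of == f)
    tr <- which(folds$fold_of != f)
    if (length(unique(labels[tr])) < 2L)
      stop("fold ", f, " leaves fewer than 2 classes in training; ",
           "try a different seed or stratified = TRUE")
    model <- train_svm(kernel_matrix(unclass(K)[tr, tr, drop = FALSE],
                                     ids[tr]),
                       labels[tr], config)
    predicted[te] <- predict(model,
                             unclass(K)[te, tr, drop = FALSE])
  }
  evaluation_report(labels, predicted, fold_of = folds$fold_of,
                    sp_definition = sp_definition,
                    meta = list(seed = seed, stratified = stratified,
                                C = config$C, epsilon = config$epsilon,
                                strategy = config$multiclass_strategy,
                                kernel = {
                                  km <- attr(K, "meta")
                                  km[intersect(c("type", "n_components",
                                                 "scheme", "k", "gamma",
                                                 "normalization"),
                                               names(km))]
                                }))
}

#' Full 5-fold cross-validation of the fused spectrum kernel
#'
#' Builds every component kernel of the fusion spec on the full
#' sequence set, fuses them, and runs [cross_validate_kernel()].
#'
#' @param sequences named character vector of protein sequences.
#' @param labels class labels aligned to `sequences`.
#' @param spec a `fusion_spec`; default the scheme-set `variant`.
#' @param variant `"I"` or `"II"` (used when `spec` is `NULL`).
#' @param normalization spectrum normalization for every component.
#' @inheritParams cross_validate_kernel
#' @return a `cv_report`.
#' @export
cross_validate <- function(sequences, labels, spec = NULL, variant = "I",
                           config = svm_config(), seed = 1,
                           normalization = c("l2", "frequency", "raw"),
                           stratified = FALSE,
                           sp_definition = c("ppv", "tnr")) {
  normalization <- match.arg(normalization)
  stopifnot(length(sequences) == length(labels))
  if (is.null(spec)) spec <- fusion_spec_variant(variant)
  K <- fuse(component_kernels(sequences, spec, normalization), spec$weight)
  cross_validate_kernel(K, labels, config = config, seed = seed,
                        stratified = stratified,
                        sp_definition = sp_definition)
}

#' Write an evaluation report to a directory
#'
#' Emits three text files: `metrics.tsv` (per-class size/SP/SE/MCC with
#' an overall-accuracy footer), `confusion.tsv` (tab-separated counts)
#' and `run_meta.txt` (`key=value` metadata incl. the seed).
#'
#' @param report a `cv_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- report$per_class
  lines <- c(paste(c("location", "size", "SP", "SE", "MCC"), collapse = "\t"),
             vapply(seq_len(nrow(tab)), function(i)
               paste(c(tab$class[i], tab$size[i],
                       sprintf("%.4f", c(tab$SP[i], tab$SE[i], tab$MCC[i]))),
                     collapse = "\t"), character(1)),
             sprintf("Overall Accuracy\t\t%.2f%%",
                     100 * report$overall_accuracy))
  writeLines(lines, file.path(dir, "metrics.tsv"))
  conf <- report$confusion
  writeLines(c(paste(c("truth\\predicted", colnames(conf)), collapse = "\t"),
               vapply(seq_len(nrow(conf)), function(i)
                 paste(c(rownames(conf)[i], conf[i, ]), collapse = "\t"),
                 character(1))),
             file.path(dir, "confusion.tsv"))
  meta <- c(list(n = report$n, overall_accuracy = report$overall_accuracy,
                 sp_definition = report$sp_definition),
            report$meta)
  flat <- vapply(meta, function(v)
    paste(format(unlist(v), digits = 17), collapse = ","), character(1))
  writeLines(paste0(names(flat), "=", flat), file.path(dir, "run_meta.txt"))
  invisible(dir)
}
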