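#' @importFrom e1071 svm
NULL

#' SVM configuration
#'
#' Defaults mirror the C-SVC / precomputed-kernel solver configuration
#' used throughout: cost C = 1000 and termination tolerance 1e-4.
#'
#' @param C positive cost parameter.
#' @param epsilon positive termination tolerance of the solver.
#' @param multiclass_strategy `"one-vs-one"` (majority voting, ties to
#'   the lower class index in label sort order) or `"one-vs-rest"`
#'   (argmax of decision values).
#' @param class_weighting if `TRUE`, weight each class inversely to its
#'   training frequency; off by default (no cost rebalancing).
#' @return a list of class `svm_config`.
#' @export
svm_config <- function(C = 1000, epsilon = 1e-4,
                       multiclass_strategy = c("one-vs-one", "one-vs-rest"),
                       class_weighting = FALSE) {
  stopifnot(C > 0, epsilon > 0)
  structure(list(C = C, epsilon = epsilon,
                 multiclass_strategy = match.arg(multiclass_strategy),
                 class_weighting = class_weighting),
            class = "svm_config")
}

# Fit one binary C-SVC on a precomputed kernel and return a
# self-contained decision rule: f(q) = K[q, sv_ids] %*% coefs - offset,
# oriented so that f > 0 votes for `pos` and f <= 0 for `neg`.
#
# The solver is libsvm (via e1071) run on an exact empirical kernel
# map: the eigendecomposition K = V L V' yields finite-dimensional
# features F = V L^{1/2} with F F' = K, so a linear C-SVC on F is the
# precomputed-kernel C-SVC on K. The learned feature-space rule is
# mapped back to kernel space as a coefficient per training point
# (beta = V V'[, sv] alpha), which keeps prediction a pure function of
# query-vs-training kernel values.
.fit_binary <- function(K, y2, pos, neg, config) {
  cw <- NULL
  if (isTRUE(config$class_weighting)) {
    tab <- table(y2)
    cw <- stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  }
  K <- unclass(K)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-10
  V <- e$vectors[, keep, drop = FALSE]
  Feat <- V %*% diag(sqrt(e$values[keep]), sum(keep))
  fit <- svm(Feat, factor(y2, levels = c(neg, pos)), kernel = "linear",
             cost = config$C, tolerance = config$epsilon, scale = FALSE,
             class.weights = cw)
  alpha <- as.numeric(fit$coefs)
  beta <- as.numeric(V %*% (t(V[fit$index, , drop = FALSE]) %*% alpha))
  offset <- fit$rho
  dec <- as.numeric(K %*% beta - offset)
  # libsvm codes +1 for whichever class comes first in the data, so fix
  # the orientation from the training decision values
  if (mean(dec[y2 == pos]) < mean(dec[y2 == neg])) {
    beta <- -beta
    offset <- -offset
  }
  list(sv_ids = rownames(K), coefs = beta, offset = offset,
       pos = pos, neg = neg)
}

#' Train a multi-class SVM on a precomputed kernel matrix
#'
#' The classifier never sees sequences: similarity enters only through
#' the supplied kernel matrix, so any valid (symmetric PSD) kernel —
#' a single spectrum component or the fused sum — can be used.
#' Multi-class problems are decomposed per `config$multiclass_strategy`.
#'
#' @param K_train square `kernel_matrix` over the training sequences.
#' @param labels class labels aligned to `kernel_ids(K_train)`.
#' @param config an [svm_config()].
#' @return object of class `spectrum_svm` with `training_ids`,
#'   `class_labels` (sorted), `config`, and the per-subproblem decision
#'   rules.
#' @export
train_svm <- function(K_train, labels, config = svm_config()) {
  ids <- kernel_ids(K_train)
  if (length(labels) != length(ids))
    stop("labels length (", length(labels), ") does not match kernel size (",
         length(ids), ")")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("training requires at least 2 distinct class labels")
  subproblems <- list()
  if (config$multiclass_strategy == "one-vs-one") {
    for (a in seq_len(length(classes) - 1L)) {
      for (b in seq(a + 1L, length(classes))) {
        sel <- labels %in% c(classes[a], classes[b])
        Ksub <- unclass(K_train)[sel, sel, drop = FALSE]
        subproblems[[length(subproblems) + 1L]] <-
          .fit_binary(Ksub, labels[sel], pos = classes[b], neg = classes[a],
                      config = config)
      }
    }
  } else {
    for (a in seq_along(classes)) {
      y2 <- ifelse(labels == classes[a], classes[a], ".rest")
      subproblems[[length(subproblems) + 1L]] <-
        .fit_binary(unclass(K_train), y2, pos = classes[a], neg = ".rest",
                    config = config)
    }
  }
  structure(list(training_ids = ids, class_labels = classes,
                 config = config, subproblems = subproblems),
            class = "spectrum_svm")
}

#' Predict class labels from a query-vs-training kernel block
#'
#' @param object a `spectrum_svm` from [train_svm()].
#' @param K_query_train numeric matrix of kernel values, one row per
#'   query; columns must be aligned to (and named by)
#'   `object$training_ids`.
#' @param ... unused.
#' @return character vector of predicted labels, one per query row;
#'   deterministic, with one-vs-one ties broken toward the lower class
#'   index in sorted label order.
#' @export
predict.spectrum_svm <- function(object, K_query_train, ...) {
  K <- unclass(as.matrix(K_query_train))
  cn <- colnames(K)
  if (is.null(cn) || !identical(cn, object$training_ids)) {
    if (!is.null(cn) && setequal(cn, object$training_ids)) {
      K <- K[, object$training_ids, drop = FALSE]
    } else {
      stop("query kernel columns are not aligned to the model's training IDs")
    }
  }
  classes <- object$class_labels
  n <- nrow(K)
  if (object$config$multiclass_strategy == "one-vs-one") {
    votes <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
    for (sp in object$subproblems) {
      dec <- as.numeric(K[, sp$sv_ids, drop = FALSE] %*% sp$coefs - sp$offset)
      winner <- ifelse(dec > 0, sp$pos, sp$neg)
      for (cl in classes) votes[, cl] <- votes[, cl] + (winner == cl)
    }
    # which.max takes the first maximum: lower class index wins ties
    classes[apply(votes, 1L, which.max)]
  } else {
    dec <- vapply(object$subproblems, function(sp)
      as.numeric(K[, sp$sv_ids, drop = FALSE] %*% sp$coefs - sp$offset),
      numeric(n))
    dec <- matrix(dec, nrow = n)
    classes[apply(dec, 1L, which.max)]
  }
}

#' Persist / restore a trained model as text
#'
#' The file holds the class labels, training IDs and configuration in a
#' header, then one block per binary subproblem with support-vector IDs,
#' coefficients (17 significant digits) and the offset; loading restores
#' bit-identical predictions.
#'
#' @param model a `spectrum_svm`.
#' @param path output file.
#' @export
write_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  writeLines(c("spectrum_svm\tv1",
               paste0("classes\t", paste(model$class_labels, collapse = ",")),
               paste0("training_ids\t",
                      paste(model$training_ids, collapse = ",")),
               paste0("C\t", fmt(model$config$C)),
               paste0("epsilon\t", fmt(model$config$epsilon)),
               paste0("strategy\t", model$config$multiclass_strategy),
               paste0("n_subproblems\t", length(model$subproblems))), con)
  for (sp in model$subproblems) {
    writeLines(c(paste0("subproblem\t", sp$neg, "\t", sp$pos),
                 paste0("sv_ids\t", paste(sp$sv_ids, collapse = ",")),
                 paste0("coefs\t", paste(fmt(sp$coefs), collapse = ",")),
                 paste0("offset\t", fmt(sp$offset))), con)
  }
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()` returns the restored `spectrum_svm`.
#' @export
read_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  field <- function(i) strsplit(lines[i], "\t", fixed = TRUE)[[1]]
  stopifnot(field(1)[1] == "spectrum_svm")
  split1 <- function(i) strsplit(field(i)[2], ",", fixed = TRUE)[[1]]
  n_sub <- as.integer(field(7)[2])
  subproblems <- vector("list", n_sub)
  at <- 8L
  for (s in seq_len(n_sub)) {
    hd <- field(at)
    subproblems[[s]] <- list(
      sv_ids = strsplit(strsplit(lines[at + 1L], "\t")[[1]][2], ",")[[1]],
      coefs = as.numeric(strsplit(strsplit(lines[at + 2L], "\t")[[1]][2],
                                  ",")[[1]]),
      offset = as.numeric(strsplit(lines[at + 3L], "\t")[[1]][2]),
      neg = hd[2], pos = hd[3])
    at <- at + 4L
  }
  structure(list(training_ids = split1(3), class_labels = split1(2),
                 config = svm_config(C = as.numeric(field(4)[2]),
                                     epsilon = as.numeric(field(5)[2]),
                                     multiclass_strategy = field(6)[2]),
                 subproblems = subproblems),
            class = "spectrum_svm")
}
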