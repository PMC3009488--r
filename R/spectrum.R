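#' @importFrom Matrix sparseMatrix tcrossprod
NULL

#' Count k-mers of a reduced sequence
#'
#' Slides a length-k window over the recoded symbols; every window made
#' of valid symbols contributes one occurrence to its k-mer. Windows
#' overlapping an invalid position (an ambiguity code in the source)
#' contribute nothing. A sequence shorter than k yields the empty
#' spectrum.
#'
#' k-mers are keyed by their rank in the mixed-radix encoding over the
#' group alphabet: a k-mer with 1-based group indices (g1, ..., gk) has
#' id \eqn{\sum_j (g_j - 1) l^{k-j}} with l the alphabet size, stored as
#' a double to accommodate large user alphabets.
#'
#' @param reduced a `reduced_seq` from [reduce_sequence()].
#' @param k positive integer window size.
#' @return object of class `spectrum_vector`: list with `scheme_name`,
#'   `k`, `alphabet_size`, `kmer_ids` (sorted, 0-based, double),
#'   `counts` (parallel integer occurrence counts), `n_valid_kmers`.
#' @export
count_kmers <- function(reduced, k) {
  stopifnot(is(reduced, "reduced_seq"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  s <- reduced$symbols
  l <- reduced$alphabet_size
  n <- length(s)
  if (n < k) {
    ids <- numeric(0); cnt <- integer(0)
  } else {
    m <- n - k + 1L
    idx <- numeric(m)  # NA propagates through windows with invalid symbols
    for (j in seq_len(k)) {
      idx <- idx * l + (s[j:(m + j - 1L)] - 1)
    }
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) {
      ids <- numeric(0); cnt <- integer(0)
    } else {
      r <- rle(sort(idx))
      ids <- r$values
      cnt <- r$lengths
    }
  }
  structure(
    list(scheme_name = reduced$scheme_name, k = k, alphabet_size = l,
         kmer_ids = ids, counts = cnt, n_valid_kmers = sum(cnt)),
    class = "spectrum_vector")
}

.check_same_spectrum_space <- function(u, v) {
  stopifnot(is(u, "spectrum_vector"), is(v, "spectrum_vector"))
  if (!identical(u$scheme_name, v$scheme_name))
    stop("spectrum vectors use different schemes: '",
         u$scheme_name, "' vs '", v$scheme_name, "'")
  if (u$k != v$k)
    stop("spectrum vectors use different window sizes: ", u$k, " vs ", v$k)
}

.spectrum_weights <- function(v, normalization) {
  x <- as.numeric(v$counts)
  if (normalization == "raw" || length(x) == 0L) return(x)
  if (normalization == "frequency") return(x / v$n_valid_kmers)
  if (normalization == "l2") return(x / sqrt(sum(x^2)))
  stop("unknown normalization '", normalization, "'")
}

#' Spectrum inner product
#'
#' The classic k-spectrum kernel value: the dot product of the two raw
#' k-mer occurrence-count vectors, summed over shared k-mers.
#'
#' @param u,v `spectrum_vector`s over the same scheme and k.
#' @return a non-negative number.
#' @export
spectrum_inner_product <- function(u, v) {
  .check_same_spectrum_space(u, v)
  m <- match(u$kmer_ids, v$kmer_ids)
  keep <- !is.na(m)
  sum(as.numeric(u$counts[keep]) * as.numeric(v$counts[m[keep]]))
}

#' Squared Euclidean distance between spectrum vectors
#'
#' \eqn{\|\Phi(x)-\Phi(y)\|^2}, expanded as
#' \eqn{\langle u,u\rangle - 2\langle u,v\rangle + \langle v,v\rangle}
#' under the chosen count normalization. This is the quantity the
#' Gaussian spectrum kernel exponentiates.
#'
#' @inheritParams spectrum_inner_product
#' @param normalization `"frequency"` (counts divided by the number of
#'   valid k-mers; default), `"raw"`, or `"l2"` (unit Euclidean norm).
#' @return a non-negative number; 0 iff the normalized count maps are
#'   identical.
#' @export
squared_spectrum_distance <- function(u, v,
                                      normalization = c("frequency", "raw", "l2")) {
  normalization <- match.arg(normalization)
  .check_same_spectrum_space(u, v)
  wu <- .spectrum_weights(u, normalization)
  wv <- .spectrum_weights(v, normalization)
  m <- match(u$kmer_ids, v$kmer_ids)
  keep <- !is.na(m)
  cross <- sum(wu[keep] * wv[m[keep]])
  max(sum(wu^2) - 2 * cross + sum(wv^2), 0)
}

#' Default Gaussian bandwidth for a spectrum component
#'
#' The package default is \eqn{\gamma = 1/2} on L2-normalized spectrum
#' vectors: there the squared distance between two spectra is
#' \eqn{2(1-\cos\theta) \le 2} regardless of the feature-space
#' dimension, so a dimension-independent unit bandwidth keeps every
#' component kernel in the working range \eqn{[e^{-1}, 1]}. See the
#' methods vignette for the rationale and for overriding per component.
#'
#' @param alphabet_size number of groups l of the scheme (unused by the
#'   default policy; kept so alternative dimension-dependent policies
#'   share the signature).
#' @param k window size (unused, as above).
#' @return positive number.
#' @export
default_gamma <- function(alphabet_size, k) 0.5

# Sparse (n sequences) x (observed k-mers) weight matrix plus the row
# squared norms, shared by the square and rectangular kernel builders.
.spectrum_feature_matrix <- function(spectra, normalization) {
  ids_all <- sort(unique(unlist(lapply(spectra, `[[`, "kmer_ids"))))
  n <- length(spectra)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (s in seq_len(n)) {
    w <- .spectrum_weights(spectra[[s]], normalization)
    if (length(w) == 0L) next
    i <- c(i, rep.int(s, length(w)))
    j <- c(j, match(spectra[[s]]$kmer_ids, ids_all))
    x <- c(x, w)
  }
  sparseMatrix(i = i, j = j, x = x, dims = c(n, length(ids_all)))
}

.as_reduced_list <- function(sequences) {
  if (is(sequences, "reduced_seq")) sequences <- list(sequences)
  stopifnot(all(vapply(sequences, is, logical(1), "reduced_seq")))
  sequences
}

.reduced_ids <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids))
    ids <- vapply(sequences, `[[`, character(1), "source_id")
  if (anyNA(ids)) ids <- as.character(seq_along(sequences))
  ids
}

.warn_window_limit <- function(sequences, k, scheme) {
  if (!is.null(scheme) && k > scheme$window_limit)
    warning("k = ", k, " exceeds window limit ", scheme$window_limit,
            " of scheme '", scheme$name, "' (computational-budget ",
            "recommendation, not a validity constraint)")
}

#' Gaussian spectrum kernel matrix
#'
#' Entry (i, j) is \eqn{\exp(-\gamma \|\Phi(x_i)-\Phi(x_j)\|^2)} where
#' \eqn{\Phi} is the k-mer spectrum map over the reduced alphabet under
#' the chosen normalization. The result is symmetric positive
#' semi-definite with unit diagonal.
#'
#' Sequences whose spectrum is empty (shorter than k, or every window
#' hits an invalid position) get the zero feature vector, with a
#' warning: two such sequences have kernel value 1.
#'
#' @param sequences list of `reduced_seq`, all under one scheme.
#' @param k window size.
#' @param gamma positive bandwidth; default [default_gamma()].
#' @param normalization see [squared_spectrum_distance()]; default
#'   `"l2"` for kernels (unit-sphere features give the Gaussian a
#'   data-independent working range).
#' @param scheme optional `aa_scheme` used only to warn when k exceeds
#'   the scheme's window limit.
#' @return a `kernel_matrix`: base numeric matrix with sequence IDs as
#'   dimnames and a `meta` attribute (scheme, k, gamma, normalization).
#' @export
gaussian_kernel_matrix <- function(sequences, k, gamma = NULL,
                                   normalization = c("l2", "frequency", "raw"),
                                   scheme = NULL) {
  normalization <- match.arg(normalization)
  sequences <- .as_reduced_list(sequences)
  if (length(sequences) == 0L) stop("empty sequence list")
  .warn_window_limit(sequences, k, scheme)
  spectra <- lapply(sequences, count_kmers, k = k)
  if (any(vapply(spectra, `[[`, numeric(1), "n_valid_kmers") == 0))
    warning("some sequences have an empty ", k, "-spectrum; ",
            "their feature vector is the zero vector")
  if (is.null(gamma)) gamma <- default_gamma(sequences[[1]]$alphabet_size, k)
  stopifnot(gamma > 0)
  X <- .spectrum_feature_matrix(spectra, normalization)
  G <- as.matrix(tcrossprod(X))
  sq <- outer(diag(G), diag(G), `+`) - 2 * G
  K <- exp(-gamma * pmax(sq, 0))
  diag(K) <- 1
  ids <- .reduced_ids(sequences)
  kernel_matrix(K, ids, meta = list(
    type = "gaussian", scheme = sequences[[1]]$scheme_name, k = k,
    gamma = gamma, normalization = normalization))
}

#' Rectangular Gaussian kernel block (query vs training sequences)
#'
#' Same kernel function as [gaussian_kernel_matrix()], evaluated between
#' each query sequence (rows) and each training sequence (columns);
#' consistent with the square matrix on the union of the two sets.
#'
#' @param test,train lists of `reduced_seq` under one scheme.
#' @inheritParams gaussian_kernel_matrix
#' @return numeric matrix, rows named by test IDs, columns by train IDs,
#'   with the same `meta` attribute as the square builder.
#' @export
cross_kernel_matrix <- function(test, train, k, gamma = NULL,
                                normalization = c("l2", "frequency", "raw"),
                                scheme = NULL) {
  normalization <- match.arg(normalization)
  test <- .as_reduced_list(test)
  train <- .as_reduced_list(train)
  if (length(test) == 0L || length(train) == 0L) stop("empty sequence list")
  if (!identical(test[[1]]$scheme_name, train[[1]]$scheme_name))
    stop("test and train sequences reduced under different schemes")
  .warn_window_limit(train, k, scheme)
  spectra <- lapply(c(test, train), count_kmers, k = k)
  if (is.null(gamma)) gamma <- default_gamma(train[[1]]$alphabet_size, k)
  stopifnot(gamma > 0)
  X <- .spectrum_feature_matrix(spectra, normalization)
  nt <- length(test)
  Xt <- X[seq_len(nt), , drop = FALSE]
  Xr <- X[nt + seq_len(length(train)), , drop = FALSE]
  G <- as.matrix(tcrossprod(Xt, Xr))
  sq <- outer(Matrix::rowSums(Xt^2), Matrix::rowSums(Xr^2), `+`) - 2 * G
  K <- exp(-gamma * pmax(sq, 0))
  dimnames(K) <- list(.reduced_ids(test), .reduced_ids(train))
  attr(K, "meta") <- list(type = "gaussian", scheme = train[[1]]$scheme_name,
                          k = k, gamma = gamma, normalization = normalization)
  K
}

#' Construct a kernel matrix object
#'
#' Thin wrapper around a base numeric matrix: row/column names carry the
#' sequence ID order that indexes the kernel, and a `meta` attribute
#' records how it was built.
#'
#' @param values square numeric matrix.
#' @param ids character vector of sequence IDs, one per row.
#' @param meta named list describing the component(s).
#' @return matrix of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, ids, meta = list()) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), length(ids) == nrow(values))
  dimnames(values) <- list(ids, ids)
  structure(values, meta = meta, class = c("kernel_matrix", "matrix", "array"))
}

#' Sequence IDs indexing a kernel matrix
#' @param K a `kernel_matrix` (or any matrix with rownames).
#' @return character vector of IDs.
#' @export
kernel_ids <- function(K) rownames(K)

#' Check kernel-matrix validity
#'
#' Verifies symmetry (tolerance 1e-10) and positive semi-definiteness
#' (minimum eigenvalue no smaller than `-1e-8` times the largest
#' diagonal entry).
#'
#' @param K square numeric matrix.
#' @return invisibly, a list with `symmetric` (logical), `min_eigenvalue`
#'   and `valid`; raises no condition.
#' @export
check_kernel <- function(K) {
  K <- unclass(K)
  sym <- max(abs(K - t(K))) <= 1e-10
  ev <- min(eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  invisible(list(symmetric = sym, min_eigenvalue = ev,
                 valid = sym && ev >= -1e-8 * max(diag(K))))
}

#' Write / read a kernel matrix as tab-separated text
#'
#' Values are rendered with 17 significant digits so that write + read
#' round-trips exactly. A `<path>.meta` sidecar stores the `meta`
#' attribute as `key=value` lines.
#'
#' @param K a `kernel_matrix`.
#' @param path output file.
#' @export
write_kernel_tsv <- function(K, path) {
  ids <- kernel_ids(K)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", ids), collapse = "\t"), con)
  vals <- format(unclass(K), digits = 17, scientific = TRUE, trim = TRUE)
  for (i in seq_along(ids))
    writeLines(paste(c(ids[i], vals[i, ]), collapse = "\t"), con)
  meta <- attr(K, "meta")
  if (!is.null(meta)) {
    flat <- vapply(meta, function(v) paste(format(v, digits = 17),
                                           collapse = ","), character(1))
    writeLines(paste0(names(flat), "=", flat), paste0(path, ".meta"))
  }
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @return `read_kernel_tsv()` returns the `kernel_matrix`.
#' @export
read_kernel_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1, colClasses = "character")
  vals <- apply(as.matrix(tab), c(1, 2), as.numeric)
  meta <- list()
  mpath <- paste0(path, ".meta")
  if (file.exists(mpath)) {
    kv <- strsplit(readLines(mpath, warn = FALSE), "=", fixed = TRUE)
    meta <- stats::setNames(lapply(kv, function(p) {
      v <- paste(p[-1], collapse = "=")
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    }), vapply(kv, `[[`, character(1), 1))
  }
  kernel_matrix(vals, rownames(tab), meta = meta)
}
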