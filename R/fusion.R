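#' Enumerate the kernel components of a scheme list
#'
#' Each classification scheme contributes one spectrum kernel per
#' window size k = 1 ... window_limit; components are ordered by scheme,
#' then ascending k, and all weights default to exactly 1 (unweighted
#' fusion). Scheme set I yields 25 components, set II yields 34.
#'
#' @param schemes ordered list of `aa_scheme` (e.g. from
#'   [scheme_set()]).
#' @param gamma optional fixed bandwidth applied to every component;
#'   default `NA` means each component uses [default_gamma()].
#' @return a `fusion_spec`: data frame with columns `scheme`, `k`,
#'   `gamma`, `weight`, plus the scheme objects in attribute `schemes`.
#' @export
enumerate_components <- function(schemes, gamma = NA_real_) {
  if (length(schemes) == 0L) stop("empty scheme list")
  stopifnot(all(vapply(schemes, is, logical(1), "aa_scheme")))
  rows <- do.call(rbind, lapply(schemes, function(s)
    data.frame(scheme = s$name, k = seq_len(s$window_limit),
               gamma = gamma, weight = 1, stringsAsFactors = FALSE)))
  rownames(rows) <- NULL
  structure(rows, schemes = stats::setNames(
    schemes, vapply(schemes, `[[`, character(1), "name")),
    class = c("fusion_spec", "data.frame"))
}

#' Fusion spec for a published scheme-set variant
#'
#' Convenience wrapper: `fusion_spec_variant("I")` enumerates the 25
#' components of scheme set I, `"II"` the 34 of set II.
#'
#' @inheritParams scheme_set
#' @inheritParams enumerate_components
#' @export
fusion_spec_variant <- function(variant = c("I", "II"), gamma = NA_real_) {
  enumerate_components(scheme_set(variant), gamma = gamma)
}

#' Fuse kernel matrices by weighted summation
#'
#' Elementwise weighted sum of component kernel matrices sharing one
#' sequence-ID order. With non-negative weights the sum of positive
#' semi-definite matrices stays positive semi-definite, so the fused
#' matrix remains a valid SVM kernel. No re-normalization is applied:
#' with m unit-diagonal components and unit weights, the fused diagonal
#' is exactly m.
#'
#' @param matrices list of `kernel_matrix` with identical ID order.
#' @param weights non-negative numeric vector, one per matrix; default
#'   all 1.
#' @return the fused `kernel_matrix`; `meta` lists the components.
#' @export
fuse <- function(matrices, weights = rep(1, length(matrices))) {
  if (length(matrices) == 0L) stop("empty matrix list")
  if (length(weights) != length(matrices))
    stop("weights length (", length(weights), ") does not match number of ",
         "matrices (", length(matrices), ")")
  if (any(weights < 0)) stop("negative weights break positive ",
                             "semi-definiteness; all weights must be >= 0")
  ids <- kernel_ids(matrices[[1]])
  for (m in matrices[-1])
    if (!identical(kernel_ids(m), ids))
      stop("kernel matrices have mismatched sequence-ID order; ",
           "refusing to fuse (no silent reordering)")
  acc <- matrix(0, length(ids), length(ids))
  for (i in seq_along(matrices))
    acc <- acc + weights[i] * unclass(matrices[[i]])
  comp <- lapply(matrices, attr, "meta")
  kernel_matrix(acc, ids,
                meta = list(type = "fused", n_components = length(matrices),
                            weights = weights, components = comp))
}

#' Compute all component kernel matrices of a fusion spec
#'
#' Reduces the sequences once per scheme and builds one Gaussian
#' spectrum kernel per (scheme, k) component.
#'
#' @param sequences named character vector of protein sequences.
#' @param spec a `fusion_spec` from [enumerate_components()].
#' @param normalization spectrum count normalization, see
#'   [gaussian_kernel_matrix()].
#' @return list of `kernel_matrix`, one per component row of `spec`.
#' @export
component_kernels <- function(sequences, spec,
                              normalization = c("l2", "frequency", "raw")) {
  normalization <- match.arg(normalization)
  schemes <- attr(spec, "schemes")
  reduced <- lapply(schemes, function(s) reduce_sequences(sequences, s))
  lapply(seq_len(nrow(spec)), function(i) {
    sc <- spec$scheme[i]
    g <- spec$gamma[i]
    gaussian_kernel_matrix(reduced[[sc]], k = spec$k[i],
                           gamma = if (is.na(g)) NULL else g,
                           normalization = normalization,
                           scheme = schemes[[sc]])
  })
}

#' The fused spectrum kernel of a sequence set
#'
#' End-to-end convenience: enumerate the components of a scheme-set
#' variant, build every component kernel, and fuse them with the spec's
#' weights.
#'
#' @inheritParams component_kernels
#' @param variant `"I"` (25 components) or `"II"` (34); ignored when
#'   `spec` is supplied.
#' @param spec optional explicit `fusion_spec`.
#' @return the fused `kernel_matrix`.
#' @export
fused_spectrum_kernel <- function(sequences, variant = "I", spec = NULL,
                                  normalization = c("l2", "frequency", "raw")) {
  normalization <- match.arg(normalization)
  if (is.null(spec)) spec <- fusion_spec_variant(variant)
  fuse(component_kernels(sequences, spec, normalization), spec$weight)
}
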